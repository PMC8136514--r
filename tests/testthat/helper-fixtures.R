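# Shared fixture builders. Everything is generated in code at test time.

# a noise-free DepthProfileSet: counts are the exact expectations for the
# given per-window copy-number vectors (reference is all-CN2)
noiselessProfiles <- function(cnList, meanDepth = 100, windowBp = 1e4,
                              chrom = "13", startBp = 63e6) {
    nw <- length(cnList[[1L]])
    stopifnot(all(lengths(cnList) == nw))
    windows <- GRanges(chrom,
                       IRanges(startBp + (seq_len(nw) - 1L) * windowBp + 1,
                               width = windowBp))
    counts <- vapply(cnList, function(cn) meanDepth * cn / 2,
                     numeric(nw))
    DepthProfileSet(counts, windows,
                    librarySize = rep(meanDepth * nw, length(cnList)),
                    reference = names(cnList)[1L])
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

revcompStr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# random PAF-like segment table
randomSegments <- function(n, refLength = 1e6) {
    start <- floor(runif(n, 0, refLength - 5000))
    len <- floor(runif(n, 200, 5000))
    qstart <- floor(runif(n, 0, refLength))
    data.frame(qname = sample(sprintf("q%02d", 1:5), n, TRUE),
               qstart = qstart, qend = qstart + len,
               tname = "13", tstart = start, tend = start + len,
               identity = runif(n, 95, 100),
               orientation = sample(c("forward", "reverse"), n, TRUE))
}
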
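# Segment filtering, multiplicity, unique regions, vector removal,
# scaffolding.

test_that("segment filter applies inclusive thresholds and is idempotent", {
    segs <- data.frame(qname = "q", qstart = c(0, 0, 0), qend = c(999, 1000, 5000),
                       tname = "t", tstart = c(0, 0, 0),
                       tend = c(999, 1000, 5000),
                       identity = c(99, 98.0, 97.9),
                       orientation = "forward")
    kept <- filterSegments(segs)
    expect_identical(nrow(kept), 1L)          # only the 1000 bp / 98.0 one
    expect_identical(kept$qend, 1000)
    expect_identical(filterSegments(kept), kept)
    # brute-force recheck on 500 random segments
    set.seed(59)
    rnd <- randomSegments(500)
    kept2 <- filterSegments(rnd, 1000, 98)
    oracle <- rnd[sapply(seq_len(nrow(rnd)), function(i)
        (rnd$qend[i] - rnd$qstart[i]) >= 1000 && rnd$identity[i] >= 98), ]
    expect_identical(kept2, oracle)
})

test_that("reference multiplicity matches an interval-stabbing oracle", {
    # engineered double coverage
    segs <- data.frame(qname = c("a", "b"), qstart = 0, qend = 2e4,
                       tname = "t", tstart = 3e4, tend = 5e4,
                       identity = 99, orientation = "forward")
    mult <- referenceMultiplicity(segs, windowBp = 1e4,
                                  refRange = c(0, 8e4))
    expect_identical(mcols(mult)$count, c(0L, 0L, 0L, 2L, 2L, 0L, 0L, 0L))
    dup <- duplicatedRegions(segs, 1e4, refRange = c(0, 8e4))
    expect_identical(start(dup) - 1L, 30000L)
    expect_identical(end(dup), 50000L)
    # no segments: all zero
    none <- referenceMultiplicity(segs[0, ], 1e4, refRange = c(0, 4e4))
    expect_true(all(mcols(none)$count == 0L))
    expect_error(referenceMultiplicity(segs, 0), "positive")
    # random set vs brute force
    set.seed(61)
    rnd <- randomSegments(300)
    win <- referenceMultiplicity(rnd, 5e3)
    ws <- start(win) - 1; we <- end(win)
    oracle <- vapply(seq_along(win), function(i)
        sum(rnd$tstart < we[i] & rnd$tend > ws[i]), 0L)
    expect_identical(mcols(win)$count, oracle)
})

test_that("per-window multiplicity conserves total segment coverage", {
    # segments aligned to the window grid: sum(count) * window = coverage
    set.seed(67)
    w <- 1e4
    start <- sample(0:50, 20) * w
    len <- sample(1:10, 20, replace = TRUE) * w
    segs <- data.frame(qname = "q", qstart = 0, qend = len,
                       tname = "t", tstart = start, tend = start + len,
                       identity = 99, orientation = "forward")
    win <- referenceMultiplicity(segs, w)
    expect_identical(sum(mcols(win)$count) * w, sum(len))
})

test_that("unique query regions are the complement of segment coverage", {
    segs <- data.frame(qname = c("full", "part"),
                       qstart = c(0, 2000), qend = c(10000, 4000),
                       tname = "t", tstart = 0, tend = c(10000, 2000),
                       identity = 99, orientation = "forward")
    uniq <- queryUniqueRegions(segs, c(full = 10000, part = 10000,
                                       bare = 5000))
    expect_false("full" %in% as.character(seqnames(uniq)))
    bare <- uniq[seqnames(uniq) == "bare"]
    expect_identical(width(bare), 5000L)      # wholly uncovered query
    part <- uniq[seqnames(uniq) == "part"]
    expect_identical(start(part) - 1L, c(0L, 4000L))
    expect_identical(end(part), c(2000L, 10000L))
    expect_error(queryUniqueRegions(segs, c(full = 9000, part = 1e4)),
                 "exceeds")
    # random set against a complement-of-union oracle
    set.seed(71)
    rnd <- randomSegments(200)
    qlen <- setNames(rep(1.2e6, 5), sprintf("q%02d", 1:5))
    uniq2 <- queryUniqueRegions(rnd, qlen)
    for (qn in names(qlen)) {
        covered <- rep(FALSE, qlen[[qn]])
        qs <- rnd[rnd$qname == qn, ]
        for (i in seq_len(nrow(qs)))
            covered[(qs$qstart[i] + 1):qs$qend[i]] <- TRUE
        got <- uniq2[seqnames(uniq2) == qn]
        gotMask <- rep(FALSE, qlen[[qn]])
        for (i in seq_along(got))
            gotMask[start(got)[i]:end(got)[i]] <- TRUE
        expect_identical(gotMask, !covered)
    }
})

test_that("vector removal excises merged hits and keeps ordered fragments", {
    set.seed(73)
    s <- randomDna(9000)
    expect_identical(as.character(removeVector(s, IRanges())[[1L]]), s)
    # vector at both ends leaves a single interior fragment
    ends <- IRanges(c(1, 8001), c(1000, 9000))
    frag <- removeVector(s, ends, name = "bac1")
    expect_identical(length(frag), 1L)
    expect_identical(as.character(frag[[1L]]), substr(s, 1001, 8000))
    # internal vector gives two fragments whose lengths sum correctly
    frag2 <- removeVector(s, IRanges(4001, 5000), name = "bac2")
    expect_identical(length(frag2), 2L)
    expect_identical(sum(BiocGenerics::width(frag2)), 9000L - 1000L)
    expect_identical(names(frag2), c("bac2.1", "bac2.2"))
    # overlapping hits are merged before excision; short fragments dropped
    frag3 <- removeVector(s, IRanges(c(1, 500), c(800, 8800)))
    expect_identical(length(frag3), 0L)
    expect_error(removeVector(s, IRanges(8500, 9500)), "bounds")
})

test_that("scaffolding joins engineered overlaps and leaves strangers apart", {
    set.seed(79)
    # disjoint clones: one singleton scaffold each
    lone <- DNAStringSet(c(a = randomDna(3000), b = randomDna(3000)))
    sc <- joinScaffolds(lone, minOverlapBp = 500)
    expect_identical(length(scaffolds(sc)), 2L)
    # a chain of three clones with ~2 kb engineered overlaps
    chain <- simBacClones(seed = 83, componentSizes = 3,
                          cloneLenBp = 6000, overlapBp = c(2000, 2500))
    sc3 <- joinScaffolds(chain$clones, minOverlapBp = 1000)
    expect_identical(length(scaffolds(sc3)), 1L)
    expect_setequal(scaffolds(sc3)[[1L]], chain$truth[[1L]])
    # merged length equals total minus overlaps
    lens <- sum(BiocGenerics::width(chain$clones))
    expect_lt(mergedLengths(sc3), lens)
})

test_that("scaffold count equals the overlap-graph component count", {
    for (seed in c(89, 97, 101)) {
        layout <- list(c(3, 3, 2, 2, 2, 1, 1, 1), c(2, 2, 1), c(4, 1, 1))
        sizes <- layout[[(seed %% 3) + 1]]
        bacs <- simBacClones(seed = seed, componentSizes = sizes,
                             cloneLenBp = 5000, overlapBp = c(1500, 2500))
        sc <- joinScaffolds(bacs$clones, minOverlapBp = 1000)
        expect_identical(length(scaffolds(sc)), length(bacs$truth))
        # each scaffold is exactly one ground-truth component
        got <- lapply(scaffolds(sc), sort)
        want <- lapply(bacs$truth, sort)
        expect_setequal(vapply(got, paste, "", collapse = ","),
                        vapply(want, paste, "", collapse = ","))
    }
})
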
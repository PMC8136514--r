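# Assembly-versus-reference alignment-segment analysis: the >= 1 kb /
# >= 98 % identity dotplot filter, duplicated- and unique-region
# detection, vector removal, and greedy end-overlap scaffolding of clone
# sequences.

.checkSegments <- function(segs) {
    segs <- as.data.frame(segs)
    need <- c("qname", "qstart", "qend", "tname", "tstart", "tend",
              "identity", "orientation")
    if (!all(need %in% colnames(segs)))
        stop("segments need columns: ", paste(need, collapse = ", "))
    if (any(segs$qend <= segs$qstart) || any(segs$tend <= segs$tstart))
        stop("segments must have end > start on both axes")
    if (any(segs$identity < 0 | segs$identity > 100))
        stop("identity must lie in [0, 100]")
    segs
}

#' Filter alignment segments by length and identity
#'
#' Keeps segments whose query span is at least \code{minLenBp} \emph{and}
#' whose identity is at least \code{minIdentity}; both thresholds are
#' inclusive and the input order is preserved. The defaults are the
#' dotplot display rule: areas >= 1 kb with >= 98 % identity.
#'
#' @param segs data.frame of alignment segments (columns \code{qname},
#'   \code{qstart}, \code{qend}, \code{tname}, \code{tstart}, \code{tend},
#'   \code{identity}, \code{orientation}).
#' @param minLenBp minimum query span in bp (default 1000).
#' @param minIdentity minimum percent identity (default 98).
#' @return the kept subset, same columns and order. Idempotent.
#' @export
filterSegments <- function(segs, minLenBp = 1000, minIdentity = 98) {
    segs <- .checkSegments(segs)
    keep <- (segs$qend - segs$qstart) >= minLenBp &
        segs$identity >= minIdentity
    segs[keep, , drop = FALSE]
}

#' Per-window segment multiplicity on the reference axis
#'
#' Counts, for each reference window, the number of distinct segments
#' overlapping it. Windows covered by >= 2 segments mark duplicated
#' sequence (multiple query paths over the same reference range).
#'
#' @param segs filtered alignment segments.
#' @param windowBp window width in bp (> 0).
#' @param refRange optional numeric \code{c(start, end)} of the reference
#'   axis to tile (0-based half-open); defaults to the segment span,
#'   aligned down/up to the window grid.
#' @return \code{GRanges} of windows with a \code{count} metadata column.
#' @export
referenceMultiplicity <- function(segs, windowBp, refRange = NULL) {
    segs <- .checkSegments(segs)
    if (windowBp <= 0) stop("windowBp must be positive")
    tn <- unique(segs$tname)
    if (length(tn) > 1L)
        stop("segments span multiple reference sequences")
    if (nrow(segs) == 0L) {
        if (is.null(refRange))
            stop("refRange is required when no segments are given")
        starts0 <- seq(refRange[1L], refRange[2L] - windowBp, by = windowBp)
        win <- GRanges("ref", IRanges(starts0 + 1, width = windowBp))
        mcols(win)$count <- 0L
        return(win)
    }
    if (is.null(refRange)) {
        lo <- floor(min(segs$tstart) / windowBp) * windowBp
        hi <- ceiling(max(segs$tend) / windowBp) * windowBp
    } else {
        lo <- refRange[1L]; hi <- refRange[2L]
    }
    starts0 <- seq(lo, hi - windowBp, by = windowBp)
    win <- GRanges(tn, IRanges(starts0 + 1, width = windowBp))
    segGr <- GRanges(tn, IRanges(segs$tstart + 1, segs$tend))
    mcols(win)$count <- countOverlaps(win, segGr)
    win
}

#' Duplicated reference regions (multiplicity >= 2)
#'
#' @inheritParams referenceMultiplicity
#' @param minCount multiplicity threshold (default 2).
#' @param minWindows minimum run length in windows (default 2; a single
#'   window straddling the joint of two abutting segments is a tiling
#'   artifact, not duplicated sequence).
#' @return \code{GRanges} of maximal runs of windows with
#'   \code{count >= minCount}.
#' @export
duplicatedRegions <- function(segs, windowBp, minCount = 2L,
                              minWindows = 2L, refRange = NULL) {
    win <- referenceMultiplicity(segs, windowBp, refRange)
    runs <- reduce(win[mcols(win)$count >= minCount])
    runs[width(runs) >= minWindows * windowBp]
}

#' Query ranges not covered by any segment
#'
#' The per-query complement of the union of segment query intervals —
#' query sequence with no path to the reference.
#'
#' @param segs alignment segments.
#' @param queryLengths named vector of query sequence lengths (bp).
#' @return \code{GRanges} (seqnames = query names, 1-based) of uncovered
#'   ranges, merged and sorted.
#' @export
queryUniqueRegions <- function(segs, queryLengths) {
    segs <- .checkSegments(segs)
    if (is.null(names(queryLengths)))
        stop("queryLengths must be named by query")
    out <- list()
    for (qn in names(queryLengths)) {
        qs <- segs[segs$qname == qn, , drop = FALSE]
        if (nrow(qs) && any(qs$qend > queryLengths[[qn]]))
            stop("segment exceeds declared length of query '", qn, "'")
        full <- IRanges(1, queryLengths[[qn]])
        cov <- if (nrow(qs)) reduce(IRanges(qs$qstart + 1, qs$qend))
               else IRanges()
        gap <- setdiff(full, cov)
        if (length(gap))
            out[[qn]] <- GRanges(qn, gap)
    }
    if (!length(out)) return(GRanges())
    sort(unlist(GRangesList(out), use.names = FALSE))
}

#' Excise vector sequence from a clone
#'
#' Merges overlapping vector hits, removes them, and returns the ordered
#' non-vector fragments at least \code{minFragmentBp} long (fragment
#' names are \code{<clone>.1}, \code{<clone>.2}, ...).
#'
#' @param cloneSeq a \code{DNAString}/character clone sequence.
#' @param vectorHits \code{IRanges} (1-based) or data.frame of
#'   \code{start}, \code{end} (0-based half-open) vector matches, within
#'   the sequence bounds.
#' @param minFragmentBp fragments shorter than this are discarded
#'   (default 500).
#' @param name clone name used to label fragments.
#' @return \code{DNAStringSet} of retained fragments.
#' @export
removeVector <- function(cloneSeq, vectorHits, minFragmentBp = 500,
                         name = "clone") {
    s <- DNAString(as.character(cloneSeq))
    L <- length(s)
    if (is.data.frame(vectorHits))
        vectorHits <- IRanges(vectorHits$start + 1, vectorHits$end)
    if (length(vectorHits) == 0L) {
        out <- DNAStringSet(s)
        names(out) <- name
        return(out)
    }
    if (min(start(vectorHits)) < 1L || max(end(vectorHits)) > L)
        stop("vector hits outside sequence bounds")
    keep <- setdiff(IRanges(1, L), reduce(vectorHits))
    keep <- keep[width(keep) >= minFragmentBp]
    if (length(keep) == 0L) return(DNAStringSet())
    out <- DNAStringSet(lapply(seq_along(keep), function(i)
        subseq(s, start(keep)[i], end(keep)[i])))
    names(out) <- if (length(out) == 1L) name
                  else sprintf("%s.%d", name, seq_along(out))
    out
}

# longest suffix(a)/prefix(b) overlap meeting the identity threshold,
# anchored on an exact match of b's first `seedLen` bases within a
.bestOverlap <- function(a, b, minOverlapBp, minIdentity, seedLen = 24L) {
    na <- nchar(a); nb <- nchar(b)
    seedLen <- min(seedLen, minOverlapBp)
    seed <- substr(b, 1L, seedLen)
    from <- max(1L, na - min(na, nb) + 1L)
    tailA <- substr(a, from, na)
    hits <- gregexpr(seed, tailA, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) return(0L)
    for (p in from + hits - 1L) {          # leftmost hit = longest overlap
        k <- na - p + 1L
        if (k < minOverlapBp || k > nb) next
        av <- charToRaw(substr(a, p, na))
        bv <- charToRaw(substr(b, 1L, k))
        if (100 * sum(av == bv) / k >= minIdentity) return(k)
    }
    0L
}

#' Join clone sequences into scaffolds by end-overlap
#'
#' Considers every ordered clone pair and relative orientation, detecting
#' suffix-prefix overlaps of at least \code{minOverlapBp} bases and
#' \code{minOverlapIdentity} percent identity (anchored on an exact match
#' of the leading bases of the candidate prefix). Overlaps are applied
#' greedily, longest first with ties broken by clone-name order; each
#' clone end is used at most once and joins closing a cycle are skipped,
#' so every scaffold is a simple clone path. Unjoined clones become
#' singleton scaffolds.
#'
#' @param clones a named \code{DNAStringSet} (or character vector).
#' @param minOverlapBp minimum end-overlap (default 1000).
#' @param minOverlapIdentity minimum percent identity of the overlap
#'   (default 99).
#' @return A \linkS4class{ScaffoldSet}.
#' @export
joinScaffolds <- function(clones, minOverlapBp = 1000,
                          minOverlapIdentity = 99) {
    seqs <- as.character(clones)
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("clones must have unique names")
    if (length(seqs) < 1L) stop("at least one clone is required")
    nm <- sort(names(seqs))
    seqs <- seqs[nm]
    rc <- vapply(seqs, function(s)
        as.character(reverseComplement(DNAString(s))), "")
    # candidate joins: (donor suffix end, acceptor prefix end)
    combos <- list(
        function(a, b) list(k = .bestOverlap(seqs[a], seqs[b],
                                             minOverlapBp,
                                             minOverlapIdentity),
                            ends = c(paste0(a, ".R"), paste0(b, ".L"))),
        function(a, b) list(k = .bestOverlap(seqs[a], rc[b],
                                             minOverlapBp,
                                             minOverlapIdentity),
                            ends = c(paste0(a, ".R"), paste0(b, ".R"))),
        function(a, b) list(k = .bestOverlap(rc[a], seqs[b],
                                             minOverlapBp,
                                             minOverlapIdentity),
                            ends = c(paste0(a, ".L"), paste0(b, ".L"))))
    cand <- list()
    for (i in seq_along(nm)) for (j in seq_along(nm)) {
        if (i == j) next
        a <- nm[i]; b <- nm[j]
        for (ci in seq_along(combos)) {
            # orientation combos 2 and 3 are symmetric in (a, b); only
            # evaluate each unordered pair once for those
            if (ci > 1L && i > j) next
            got <- combos[[ci]](a, b)
            if (got$k >= minOverlapBp)
                cand[[length(cand) + 1L]] <-
                    data.frame(a = a, b = b, k = got$k,
                               endA = got$ends[1L], endB = got$ends[2L])
        }
    }
    parent <- setNames(nm, nm)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    edges <- list()
    if (length(cand)) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(-cand$k, cand$a, cand$b), , drop = FALSE]
        used <- character()
        for (e in seq_len(nrow(cand))) {
            ea <- cand$endA[e]; eb <- cand$endB[e]
            if (ea %in% used || eb %in% used) next
            ra <- find(cand$a[e]); rb <- find(cand$b[e])
            if (ra == rb) next                      # would close a cycle
            parent[ra] <- rb
            used <- c(used, ea, eb)
            edges[[length(edges) + 1L]] <- cand[e, , drop = FALSE]
        }
    }
    comp <- vapply(nm, find, "")
    scaffolds <- list(); lens <- numeric()
    adj <- if (length(edges)) do.call(rbind, edges) else NULL
    for (root in unique(comp)) {
        members <- nm[comp == root]
        if (length(members) == 1L) {
            path <- members
            mlen <- nchar(seqs[members])
        } else {
            sub <- adj[adj$a %in% members | adj$b %in% members, ,
                       drop = FALSE]
            deg <- table(c(sub$a, sub$b))
            start <- sort(names(deg)[deg == 1L])[1L]
            path <- start; prev <- NA_character_
            repeat {
                nxt <- c(sub$b[sub$a == path[length(path)]],
                         sub$a[sub$b == path[length(path)]])
                nxt <- nxt[!(nxt %in% path)]
                if (!length(nxt)) break
                path <- c(path, nxt[1L])
            }
            mlen <- sum(nchar(seqs[path])) - sum(sub$k)
        }
        scaffolds[[length(scaffolds) + 1L]] <- unname(path)
        lens <- c(lens, unname(mlen))
    }
    ord <- order(vapply(scaffolds, `[`, "", 1L))
    new("ScaffoldSet", scaffolds = scaffolds[ord],
        mergedLengths = lens[ord], unplaced = character())
}
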
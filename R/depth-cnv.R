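# Read-depth-ratio CNV profiling: per-window ratios against a reference
# strain, median-filter segmentation into copy-number calls, interval
# spans, and median-absolute-error clustering of strain profiles.

.checkSameGrid <- function(a, b) {
    ga <- rowRanges(a); gb <- rowRanges(b)
    if (length(ga) != length(gb))
        stop("window grids differ in length (", length(ga), " vs ",
             length(gb), ")")
    bad <- which(as.character(seqnames(ga)) != as.character(seqnames(gb)) |
                 start(ga) != start(gb) | end(ga) != end(gb))
    if (length(bad))
        stop("window grids differ; first mismatching window is #", bad[1L],
             " (", as.character(ga[bad[1L]]), " vs ",
             as.character(gb[bad[1L]]), ")")
    invisible(TRUE)
}

#' Library-size-normalized depth ratios against a reference strain
#'
#' For window i with strain count c, reference count r, pseudocount p and
#' library sizes Ls, Lr:
#' \deqn{ratio_i = ((c_i + p)/L_s) / ((r_i + p)/L_r),}
#' whose expectation is CN_strain / CN_ref when the reference is diploid.
#'
#' @param x a \linkS4class{DepthProfileSet}.
#' @param reference reference strain name (defaults to
#'   \code{referenceStrain(x)}), or a single-strain \code{DepthProfileSet}
#'   on the identical window grid.
#' @param pseudocount added to every count so zero-depth windows stay
#'   finite (default 0.5).
#' @return A \linkS4class{RatioProfileSet} with one ratio column per strain
#'   in \code{x}.
#' @export
depthRatio <- function(x, reference = referenceStrain(x), pseudocount = 0.5) {
    stopifnot(is(x, "DepthProfileSet"), pseudocount >= 0)
    if (is(reference, "DepthProfileSet")) {
        .checkSameGrid(x, reference)
        if (ncol(reference) != 1L)
            stop("a DepthProfileSet reference must have exactly one strain")
        refCounts <- assay(reference, "counts")[, 1L]
        refLib <- librarySizes(reference)[1L]
        refName <- strainNames(reference)
    } else {
        if (is.null(reference) || !reference %in% strainNames(x))
            stop("reference strain not found")
        refCounts <- assay(x, "counts")[, reference]
        refLib <- librarySizes(x)[reference]
        refName <- reference
    }
    libs <- librarySizes(x)
    if (any(libs <= 0) || refLib <= 0) stop("library sizes must be positive")
    cts <- assay(x, "counts")
    refRate <- (refCounts + pseudocount) / refLib
    ratio <- sweep((cts + pseudocount), 2, libs, "/") / refRate
    se <- SummarizedExperiment(assays = list(ratio = ratio),
                               rowRanges = rowRanges(x),
                               colData = colData(x))
    metadata(se)$reference <- unname(refName)
    metadata(se)$pseudocount <- pseudocount
    new("RatioProfileSet", se)
}

.CN_STATES <- c("0", "1", "2", "3", "4+")

#' Segment a ratio profile into copy-number calls
#'
#' Median-filters the ratio track, maps each smoothed window to a
#' copy-number state by fixed bounds (defaults are the midpoints between
#' the CN/2 expectations: CN0 < 0.25 <= CN1 < 0.75 <= CN2 < 1.25 <= CN3 <
#' 1.75 <= CN4+), merges adjacent same-state windows and reports the
#' non-diploid calls at least \code{minSpanWindows} long.
#'
#' @param x a \linkS4class{RatioProfileSet}.
#' @param strains strains to segment (default: all).
#' @param smoothWindows odd median-filter width (default 5).
#' @param stateBounds increasing vector of the four state boundaries.
#' @param minSpanWindows minimum reportable call span, in windows
#'   (default 5; suppresses single-window noise calls).
#' @return A \code{GRanges} of calls with metadata columns \code{strain},
#'   \code{state}, \code{meanRatio} and \code{spanKb} (exactly
#'   \code{width/1000}).
#' @export
segmentRatio <- function(x, strains = strainNames(x), smoothWindows = 5L,
                         stateBounds = c(0.25, 0.75, 1.25, 1.75),
                         minSpanWindows = 5L) {
    stopifnot(is(x, "RatioProfileSet"))
    if (smoothWindows %% 2L != 1L) stop("smoothWindows must be odd")
    if (nrow(x) < smoothWindows)
        stop("profile has fewer windows than the smoothing width")
    if (is.unsorted(stateBounds, strictly = TRUE) ||
        length(stateBounds) != 4L)
        stop("stateBounds must be four increasing values")
    gr <- rowRanges(x)
    calls <- list()
    for (s in strains) {
        r <- assay(x, "ratio")[, s]
        sm <- if (smoothWindows > 1L) runmed(r, smoothWindows,
                                             endrule = "median") else r
        state <- .CN_STATES[findInterval(sm, stateBounds) + 1L]
        rl <- rle(state)
        ends <- cumsum(rl$lengths)
        starts <- ends - rl$lengths + 1L
        keep <- rl$values != "2" & rl$lengths >= minSpanWindows
        for (k in which(keep)) {
            i <- starts[k]; j <- ends[k]
            calls[[length(calls) + 1L]] <- GRanges(
                seqnames(gr)[i], IRanges(start(gr)[i], end(gr)[j]),
                strain = s, state = rl$values[k],
                meanRatio = mean(r[i:j]),
                spanKb = (end(gr)[j] - start(gr)[i] + 1) / 1000)
        }
    }
    if (!length(calls))
        return(GRanges(strain = character(), state = character(),
                       meanRatio = numeric(), spanKb = numeric()))
    unlist(GRangesList(calls))
}

#' Span of a genomic interval in chosen units
#'
#' Exact arithmetic on 0-based half-open coordinates: \code{(end - start)}
#' scaled to bp, kb or Mb. Mb-quoted coordinates can be given directly as
#' base pairs after \code{\link{parseMbInterval}}.
#'
#' @param startBp,endBp interval bounds in bp, \code{endBp > startBp}; a
#'   \code{GRanges} of length one may be given as the first argument.
#' @param unit "bp", "kb" or "Mb".
#' @return numeric span.
#' @examples
#' intervalSpan(65.79e6, 66.60e6, "kb")   # the 810 kb deletion
#' intervalSpan(65.47e6, 66.96e6, "Mb")   # the 1.49 Mb CNV region
#' @export
intervalSpan <- function(startBp, endBp = NULL, unit = c("bp", "kb", "Mb")) {
    unit <- match.arg(unit)
    if (is(startBp, "GRanges")) {
        stopifnot(length(startBp) == 1L)
        endBp <- end(startBp)
        startBp <- start(startBp) - 1   # back to 0-based half-open
    }
    if (endBp <= startBp) stop("inverted or empty interval")
    (endBp - startBp) / switch(unit, bp = 1, kb = 1e3, Mb = 1e6)
}

#' Median (or mean) absolute error between two ratio profiles
#'
#' The strain-distance measure of the depth analysis: the median over
#' windows of the absolute ratio difference. The acronym MAE is
#' implemented literally as the \emph{median}; \code{fun = "mean"} gives
#' the conventional mean absolute error.
#'
#' @param x a \linkS4class{RatioProfileSet}, or a numeric vector of ratios.
#' @param a,b strain names (when \code{x} is a set) or a second numeric
#'   vector in \code{a}.
#' @param fun "median" (default) or "mean".
#' @return non-negative scalar.
#' @export
maeDistance <- function(x, a, b = NULL, fun = c("median", "mean")) {
    fun <- match.arg(fun)
    agg <- if (fun == "median") median else mean
    if (is.numeric(x)) {
        if (length(x) != length(a)) stop("profiles differ in length")
        return(agg(abs(x - a)))
    }
    stopifnot(is(x, "RatioProfileSet"))
    r <- assay(x, "ratio")
    agg(abs(r[, a] - r[, b]))
}

#' All-pairs MAE distance matrix for a strain panel
#'
#' @param x a \linkS4class{RatioProfileSet}.
#' @param fun "median" (default) or "mean"; see \code{\link{maeDistance}}.
#' @return symmetric matrix with zero diagonal.
#' @export
maeDistanceMatrix <- function(x, fun = c("median", "mean")) {
    fun <- match.arg(fun)
    s <- strainNames(x)
    d <- matrix(0, length(s), length(s), dimnames = list(s, s))
    for (i in seq_along(s)) for (j in seq_len(i - 1L)) {
        d[i, j] <- d[j, i] <- maeDistance(x, s[i], s[j], fun = fun)
    }
    d
}

#' Agglomerative clustering of strains on an MAE distance matrix
#'
#' @param d symmetric non-negative matrix with zero diagonal (as from
#'   \code{\link{maeDistanceMatrix}}).
#' @param linkage "average" (default), "single" or "complete".
#' @param k number of flat groups to cut (default 2, the two-lineage
#'   split); ignored when \code{cutHeight} is given.
#' @param cutHeight optional dendrogram cut height.
#' @return list with \code{tree} (an \code{hclust}) and \code{groups}
#'   (named integer vector of flat cluster memberships).
#' @export
clusterStrains <- function(d, linkage = c("average", "single", "complete"),
                           k = 2, cutHeight = NULL) {
    linkage <- match.arg(linkage)
    d <- as.matrix(d)
    if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
    if (any(d < 0)) stop("distances must be non-negative")
    if (any(diag(d) != 0)) stop("diagonal must be zero")
    tree <- hclust(as.dist(d), method = linkage)
    groups <- if (is.null(cutHeight)) cutree(tree, k = k)
              else cutree(tree, h = cutHeight)
    list(tree = tree, groups = groups)
}
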
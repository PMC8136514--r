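# Per-locus ERV expression analysis: CPM normalization, a permutation
# test on log2-CPM group-mean differences with Benjamini-Hochberg
# correction and the q < 0.01 / |log2FC| > 1 regulation rule, subclass
# fold summaries, PBS stratification, and qRT-PCR 2^-dCt normalization.

#' Counts-per-million normalization
#'
#' \code{value = count / librarySize * 1e6}. When no explicit library
#' sizes are available the column sums are used, in which case every
#' column of the result sums to exactly 1e6. An
#' \linkS4class{ErvExpressionSet} contributes its \code{colData}
#' \code{librarySize} (normally a transcriptome-wide total).
#'
#' @param m counts matrix or \linkS4class{ErvExpressionSet}.
#' @param librarySize optional per-sample totals (> 0).
#' @return CPM matrix of the same shape.
#' @export
normalizeCpm <- function(m, librarySize = NULL) {
    if (is(m, "SummarizedExperiment")) {
        if (is.null(librarySize)) librarySize <- colData(m)$librarySize
        m <- assay(m, "counts")
    }
    m <- as.matrix(m)
    if (is.null(librarySize)) librarySize <- colSums(m)
    if (any(librarySize <= 0)) stop("library sizes must be positive")
    sweep(m, 2, librarySize, "/") * 1e6
}

# sample-permutation columns: exhaustive group-A index sets when feasible,
# otherwise `n` random relabelings
.permIndices <- function(groupA, nSamples, nPermutations) {
    nA <- length(groupA)
    if (choose(nSamples, nA) <= nPermutations) {
        list(idx = combn(nSamples, nA), exhaustive = TRUE)
    } else {
        idx <- replicate(nPermutations, sort(sample(nSamples, nA)))
        list(idx = idx, exhaustive = FALSE)
    }
}

#' Permutation differential-expression test
#'
#' The per-locus statistic is the difference of group means of
#' \code{log2(CPM + 1)} (B minus A). Its null distribution is obtained by
#' relabeling samples: exhaustively over all \code{choose(n, nA)}
#' relabelings when that count does not exceed \code{nPermutations}
#' (always the case at 3 vs 3, where there are 20), otherwise from
#' \code{nPermutations} random relabelings with the add-one correction
#' \code{p = (b + 1) / (n + 1)}. Exhaustive p-values are exact,
#' \code{b / n} over all relabelings including the identity, so the
#' smallest attainable p is \code{1 / choose(n, nA)}. q-values are
#' Benjamini-Hochberg over all loci and a locus is \code{regulated} when
#' \code{q < qThreshold} and \code{|log2FC| > lfcThreshold}.
#'
#' @param m an \linkS4class{ErvExpressionSet} (>= 2 samples per group).
#' @param nPermutations random relabelings to draw when exhaustive
#'   enumeration is infeasible (default 10000, >= 100).
#' @param seed integer seed for the random relabelings.
#' @param qThreshold,lfcThreshold the regulation rule (defaults 0.01 and
#'   1).
#' @return \code{DataFrame} with one row per locus: \code{locus},
#'   \code{subclass}, \code{pbs}, \code{log2FC}, \code{p}, \code{q},
#'   \code{regulated}; the permutation scheme is recorded in
#'   \code{metadata()}.
#' @export
deTest <- function(m, nPermutations = 10000, seed = 1,
                   qThreshold = 0.01, lfcThreshold = 1) {
    stopifnot(is(m, "ErvExpressionSet"))
    if (nPermutations < 100) stop("use at least 100 permutations")
    grp <- colData(m)$group
    lv <- sort(unique(grp))
    iA <- which(grp == lv[1L]); iB <- which(grp == lv[2L])
    n <- ncol(m)
    x <- log2(normalizeCpm(m) + 1)
    obs <- rowMeans(x[, iB, drop = FALSE]) -
        rowMeans(x[, iA, drop = FALSE])
    set.seed(seed)
    perms <- .permIndices(iA, n, nPermutations)
    nA <- length(iA); nB <- length(iB)
    # contrast weights per relabeling: -1/nA on pseudo-A, +1/nB on pseudo-B
    W <- matrix(1 / nB, nrow = n, ncol = ncol(perms$idx))
    for (j in seq_len(ncol(W))) W[perms$idx[, j], j] <- -1 / nA
    S <- x %*% W
    tol <- 1e-12
    if (perms$exhaustive) {
        p <- rowMeans(abs(S) >= abs(obs) - tol)
    } else {
        b <- rowSums(abs(S) >= abs(obs) - tol)
        p <- (b + 1) / (ncol(S) + 1)
    }
    q <- p.adjust(p, method = "BH")
    out <- DataFrame(locus = rownames(m), subclass = rowData(m)$subclass,
                     pbs = rowData(m)$pbs, log2FC = unname(obs),
                     p = unname(p), q = unname(q),
                     regulated = unname(q < qThreshold &
                                        abs(obs) > lfcThreshold))
    metadata(out) <- list(exhaustive = perms$exhaustive,
                          nRelabelings = ncol(S),
                          groups = lv, qThreshold = qThreshold,
                          lfcThreshold = lfcThreshold)
    out
}

#' Per-subclass average fold change
#'
#' The arithmetic mean (or, optionally, geometric mean) of the per-locus
#' linear folds \code{2^log2FC} within each MLV subclass; zero-baseline
#' loci are already handled by the +1 CPM offset inside the log2FC.
#' Either all loci of a subclass or only its significantly regulated loci
#' can be averaged.
#'
#' @param r a \code{deTest} result.
#' @param m the matching \linkS4class{ErvExpressionSet} (optional; only
#'   used to validate locus order).
#' @param significantOnly average regulated loci only.
#' @param geometric use the geometric mean.
#' @return named numeric vector of mean folds per subclass; subclasses
#'   with no contributing loci are omitted with a warning.
#' @export
subclassFoldSummary <- function(r, m = NULL, significantOnly = FALSE,
                                geometric = FALSE) {
    if (!is.null(m) && !identical(r$locus, rownames(m)))
        stop("result and expression set disagree on loci")
    keep <- if (significantOnly) r$regulated else rep(TRUE, nrow(r))
    empty <- setdiff(unique(r$subclass), unique(r$subclass[keep]))
    if (length(empty))
        warning("no contributing loci for subclass(es): ",
                paste(empty, collapse = ", "))
    folds <- 2^r$log2FC[keep]
    cls <- r$subclass[keep]
    if (geometric)
        vapply(split(folds, cls), function(f) exp(mean(log(f))), 0)
    else
        vapply(split(folds, cls), mean, 0)
}

#' Stratify fold changes by tRNA primer-binding-site class
#'
#' Summarizes per-locus log2 fold changes by PBS class and tests for a
#' between-class difference with a rank-based comparison (Wilcoxon for
#' two classes, Kruskal-Wallis for more). "No stratification" is reported
#' when p >= 0.05.
#'
#' @param r a \code{deTest} result.
#' @param minLoci classes with fewer loci are dropped (default 2).
#' @return list with \code{summary} (data.frame of class, n, mean
#'   log2FC), \code{p}, and \code{stratified} (logical).
#' @export
pbsStratification <- function(r, minLoci = 2L) {
    tab <- table(r$pbs)
    keep <- names(tab)[tab >= minLoci]
    if (length(keep) < 2L)
        stop("need >= 2 PBS classes with >= ", minLoci, " loci")
    sub <- r[r$pbs %in% keep, , drop = FALSE]
    lfc <- split(sub$log2FC, sub$pbs)
    summary <- data.frame(pbs = names(lfc),
                          n = lengths(lfc),
                          meanLog2FC = vapply(lfc, mean, 0),
                          row.names = NULL)
    p <- if (length(lfc) == 2L)
        wilcox.test(lfc[[1L]], lfc[[2L]], exact = FALSE)$p.value
    else
        kruskal.test(lfc)$p.value
    list(summary = summary, p = p, stratified = p < 0.05)
}

#' Relative expression from qRT-PCR Ct values
#'
#' The 2^-dCt method against a reference gene:
#' \code{2^-(ctTarget - ctReference)}. Targets at or beyond the
#' amplification cycle cap (default 40) are reported as negligible or
#' absent: relative expression 0 with \code{absent = TRUE}.
#'
#' @param ctTarget,ctReference Ct values (vectorized).
#' @param cycleCap amplification cap (default 40 cycles).
#' @return data.frame with \code{relExpression} and \code{absent}.
#' @examples
#' qpcrRelative(23, 20)   # dCt = 3 -> 0.125
#' @export
qpcrRelative <- function(ctTarget, ctReference, cycleCap = 40) {
    absent <- ctTarget >= cycleCap
    rel <- ifelse(absent, 0, 2^(-(ctTarget - ctReference)))
    data.frame(relExpression = rel, absent = absent)
}
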
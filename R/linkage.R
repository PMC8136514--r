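# Backcross linkage mapping: per-marker recombination fractions, LOD
# scores, and genetic-to-physical interpolation of the linkage peak.

#' Haldane's map function and its inverse
#'
#' \code{haldaneR} converts a genetic distance in cM to a recombination
#' fraction, \code{r = (1 - exp(-2 d / 100)) / 2}; \code{haldaneD} inverts
#' it, \code{d = -50 * log(1 - 2 r)}. Recombination fractions at or above
#' 0.5 are capped just below 0.5 before inversion (the genetic distance is
#' unbounded there).
#'
#' @param dCm genetic distance(s) in cM.
#' @param r recombination fraction(s) in [0, 0.5].
#' @param cap largest fraction used for inversion.
#' @return numeric vector.
#' @export
haldaneR <- function(dCm) (1 - exp(-2 * dCm / 100)) / 2

#' @rdname haldaneR
#' @export
haldaneD <- function(r, cap = 0.4999) -50 * log(1 - 2 * pmin(r, cap))

#' Single-marker linkage in an N2 backcross
#'
#' Counts animals whose phenotype disagrees with the genotype-predicted
#' phenotype, with linkage phase chosen per marker to make \code{R <= N/2}
#' (the phase is unknown a priori). The LOD is the log10 likelihood ratio
#' of the binomial recombination model at \code{rHat = R/N} against free
#' recombination (r = 0.5):
#' \deqn{LOD = (N - R) \log_{10} 2(1 - \hat r) + R \log_{10} 2 \hat r,}
#' with \code{rHat} floored at \code{1/(2N)} inside the logs so the score
#' is finite at R = 0 (the R term vanishes there anyway).
#'
#' @param data a \linkS4class{BackcrossDataset}.
#' @param marker marker name.
#' @return list with \code{rHat}, \code{R}, \code{N}, \code{lod},
#'   \code{flag} ("" or a diagnostic).
#' @export
markerLinkage <- function(data, marker) {
    stopifnot(is(data, "BackcrossDataset"))
    g <- genotypes(data)
    if (!marker %in% colnames(g)) stop("unknown marker '", marker, "'")
    gm <- g[, marker]
    ph <- phenotype(data)
    keep <- !is.na(gm) & !is.na(ph)
    if (!any(keep)) stop("marker '", marker, "' has no informative animals")
    gm <- gm[keep]; ph <- ph[keep]
    N <- length(gm)
    if (length(unique(ph)) == 1L) {
        return(list(rHat = 0.5, R = as.integer(N / 2), N = N, lod = 0,
                    flag = "constant phenotype"))
    }
    disagree <- sum((gm == "H") != (ph == 1L))
    R <- min(disagree, N - disagree)
    rHat <- R / N
    # floor only matters inside the R term (which vanishes at R = 0)
    lod <- (N - R) * log10(2 * (1 - rHat)) +
        if (R > 0) R * log10(2 * max(rHat, 1 / (2 * N))) else 0
    list(rHat = rHat, R = as.integer(R), N = N, lod = lod, flag = "")
}

#' Interpolate a physical peak position from flanking genetic distances
#'
#' Scales the trait-to-flanking-marker genetic distances to the physical
#' interval between the flanking markers:
#' \code{peak = posA + dA / (dA + dB) * (posB - posA)}. The distance units
#' cancel, so any monotone genetic measure (cM, or raw recombination
#' fractions) may be supplied.
#'
#' @param posAMb,posBMb flanking physical positions (Mb), \code{posAMb <
#'   posBMb}.
#' @param dACm,dBCm trait-to-flanking genetic distances (>= 0, not both 0).
#' @return interpolated position in Mb, always inside \code{[posAMb,
#'   posBMb]}.
#' @export
interpolatePeak <- function(posAMb, posBMb, dACm, dBCm) {
    if (posAMb >= posBMb) stop("posAMb must be < posBMb")
    if (dACm < 0 || dBCm < 0) stop("genetic distances must be >= 0")
    if (dACm + dBCm == 0) stop("dA + dB must be positive")
    posAMb + dACm / (dACm + dBCm) * (posBMb - posAMb)
}

#' Genome-scan linkage over all markers
#'
#' Runs \code{\link{markerLinkage}} for every marker and interpolates the
#' physical peak between the two markers flanking the maximum-LOD marker,
#' using trait-to-flank genetic distances obtained from the flanking
#' markers' recombination fractions via Haldane's inverse
#' \code{d = -50 ln(1 - 2 r)}. A maximum at either end of the map places
#' the peak at that marker's own position.
#'
#' @param data a \linkS4class{BackcrossDataset} with >= 2 markers.
#' @return A \linkS4class{LinkageResult}.
#' @export
linkageScan <- function(data) {
    stopifnot(is(data, "BackcrossDataset"))
    mk <- markers(data)
    if (nrow(mk) < 2L) stop("at least two markers are required")
    per <- lapply(mk$name, function(m) markerLinkage(data, m))
    tb <- DataFrame(marker = mk$name, posMb = mk$posMb,
                    rHat = vapply(per, `[[`, 0, "rHat"),
                    R = vapply(per, `[[`, 0L, "R"),
                    N = vapply(per, `[[`, 0L, "N"),
                    lod = vapply(per, `[[`, 0, "lod"),
                    flag = vapply(per, `[[`, "", "flag"))
    imax <- which.max(tb$lod)
    if (imax == 1L || imax == nrow(tb)) {
        peak <- mk$posMb[imax]
    } else {
        dA <- haldaneD(tb$rHat[imax - 1L])
        dB <- haldaneD(tb$rHat[imax + 1L])
        peak <- if (dA + dB == 0) mk$posMb[imax] else
            interpolatePeak(mk$posMb[imax - 1L], mk$posMb[imax + 1L], dA, dB)
    }
    new("LinkageResult", table = tb, peakMb = peak)
}
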
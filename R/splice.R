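# Splice-acceptor consensus classification.
#
# The consensus mammalian 3' splice acceptor is N[C/T]AG|G: the last four
# intronic bases (any base, a pyrimidine, A, G) followed by G as the first
# exonic base, with | marking the splice point. Only this five-position
# window is scored; branch points and polypyrimidine tracts are out of
# scope.

.revcompSite <- function(site) {
    L <- nchar(site@seq)
    acceptorSite(as.character(reverseComplement(DNAString(site@seq))),
                 L - site@splicePoint, "+", site@label)
}

.verdict <- function(passes, failed, impact = "none", note = "") {
    new("AcceptorVerdict", passes = passes, failed = failed,
        impact = impact, note = note)
}

.noFail <- data.frame(offset = integer(), expected = character(),
                      observed = character(), stringsAsFactors = FALSE)

#' Classify an acceptor context against the N[C/T]AG|G consensus
#'
#' Positions -4..-1 relative to the splice point must read N (any base),
#' C or T, A, G, and position 0 (the exon's first base) must be G.
#' Minus-strand sites are reverse-complemented first (the splice point
#' maps to \code{nchar(seq) - splicePoint}). An \code{N} in the input
#' matches nothing except the consensus N slot — degenerate bases never
#' silently pass.
#'
#' @param site an \linkS4class{AcceptorSite} with at least four intronic
#'   and one exonic base around the splice point.
#' @return An \linkS4class{AcceptorVerdict}.
#' @export
classifyAcceptor <- function(site) {
    stopifnot(is(site, "AcceptorSite"))
    if (site@strand == "-") site <- .revcompSite(site)
    sp <- site@splicePoint
    L <- nchar(site@seq)
    if (sp < 4L || sp >= L)
        stop("acceptor context too short: need 4 intronic and 1 exonic ",
             "base around the splice point")
    obs <- strsplit(substr(site@seq, sp - 3L, sp + 1L), "")[[1L]]
    expected <- c("N", "[C/T]", "A", "G", "G")
    ok <- c(TRUE,                       # N slot: any base including N
            obs[2L] %in% c("C", "T"),
            obs[3L] == "A",
            obs[4L] == "G",
            obs[5L] == "G")
    failed <- data.frame(offset = (-4:0)[!ok], expected = expected[!ok],
                         observed = obs[!ok], stringsAsFactors = FALSE)
    .verdict(all(ok), failed)
}

#' Call variant impact between reference and alternate acceptor alleles
#'
#' The alternate allele is a "high" impact splice-acceptor variant when
#' the reference context passes the consensus and the alternate does not
#' (canonical splicing predicted to be occluded); all other combinations
#' are "none". A failing reference is flagged in the verdict note.
#'
#' @param ref,alt \linkS4class{AcceptorSite} objects under the same
#'   splice-point convention.
#' @return The alternate's \linkS4class{AcceptorVerdict} with its
#'   \code{impact} filled in.
#' @export
compareAcceptors <- function(ref, alt) {
    vr <- classifyAcceptor(ref)
    va <- classifyAcceptor(alt)
    if (passes(vr) && !passes(va))
        return(.verdict(FALSE, failedPositions(va), impact = "high"))
    note <- if (!passes(vr)) "reference allele itself fails the consensus"
            else ""
    .verdict(passes(va), failedPositions(va), impact = "none", note = note)
}

#' Scan a sequence for consensus acceptor matches
#'
#' Locates every offset at which the five-base N[C/T]AG|G window matches,
#' on the given strand(s). Offsets are reported as 0-based splice points
#' in the scanned orientation (for minus-strand hits, in the
#' reverse-complemented sequence; the original-coordinate splice point is
#' \code{nchar(seq) - offset}).
#'
#' @param seq a nucleotide string (A/C/G/T/N) of length >= 5.
#' @param strand "+", "-" or "both".
#' @return data.frame with columns \code{offset} and \code{strand}.
#' @export
scanAcceptors <- function(seq, strand = c("+", "-", "both")) {
    strand <- match.arg(strand)
    seq <- toupper(as.character(seq))
    if (!grepl("^[ACGTN]*$", seq))
        stop("seq must be over {A,C,G,T,N}")
    if (nchar(seq) < 5L) stop("sequence shorter than the consensus window")
    scan1 <- function(s) {
        y <- strsplit(s, "")[[1L]]
        L <- length(y)
        e <- 5:L   # 1-based exon positions with full context
        hit <- (y[e - 3L] %in% c("C", "T")) & y[e - 2L] == "A" &
            y[e - 1L] == "G" & y[e] == "G"
        (e - 1L)[hit]   # 0-based splice points
    }
    out <- data.frame(offset = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    if (strand %in% c("+", "both")) {
        o <- scan1(seq)
        out <- rbind(out, data.frame(offset = o,
                                     strand = rep("+", length(o))))
    }
    if (strand %in% c("-", "both")) {
        rc <- as.character(reverseComplement(DNAString(seq)))
        o <- scan1(rc)
        out <- rbind(out, data.frame(offset = o,
                                     strand = rep("-", length(o))))
    }
    out
}
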
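# S4 containers for the pipeline stages.
#
# Depth and ratio profiles are RangedSummarizedExperiments whose rowRanges
# hold the (equal-width, sorted, non-overlapping) window grid and whose
# columns are strains; ERV count matrices are SummarizedExperiments with
# locus annotation in rowData and group labels in colData.

.validWindowGrid <- function(gr) {
    if (length(gr) == 0L)
        return("window grid is empty")
    if (length(unique(as.character(seqnames(gr)))) != 1L)
        return("windows must lie on a single chromosome")
    w <- width(gr)
    if (length(unique(w)) != 1L)
        return("windows must be equal width")
    s <- start(gr)
    if (is.unsorted(s, strictly = TRUE))
        return("windows must be sorted and non-overlapping")
    if (length(gr) > 1L && any(s[-1L] < end(gr)[-length(gr)] + 1L))
        return("windows overlap")
    TRUE
}

#' Per-strain windowed read-depth counts
#'
#' A \linkS4class{RangedSummarizedExperiment} holding a \code{"counts"} assay
#' of windowed read depths (windows x strains). The window grid is a single
#' chromosome, equal-width, sorted and non-overlapping; coordinates are the
#' usual 1-based GRanges representation of 0-based half-open windows written
#' to bedGraph. \code{colData} carries \code{strain}, \code{lineage} and
#' \code{librarySize} (total mapped reads; defaults to the column sums but is
#' normally a genome-scale total so that large CNVs in the profiled region do
#' not distort normalization).
#'
#' @export
setClass("DepthProfileSet", contains = "RangedSummarizedExperiment")

setValidity("DepthProfileSet", function(object) {
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    msg <- .validWindowGrid(rowRanges(object))
    if (!isTRUE(msg)) return(msg)
    cts <- assay(object, "counts")
    if (any(cts < 0) || any(!is.finite(cts)))
        return("counts must be finite and non-negative")
    if (!all(c("strain", "librarySize") %in% colnames(colData(object))))
        return("colData must contain 'strain' and 'librarySize'")
    if (any(colData(object)$librarySize <= 0))
        return("library sizes must be positive")
    TRUE
})

#' Per-strain windowed depth-ratio profiles
#'
#' Like \linkS4class{DepthProfileSet} but with a \code{"ratio"} assay of
#' library-size-normalized depth ratios against a reference strain (named in
#' \code{metadata()$reference}). The expectation of a window's ratio is
#' CN/2 when the reference is diploid.
#'
#' @export
setClass("RatioProfileSet", contains = "RangedSummarizedExperiment")

setValidity("RatioProfileSet", function(object) {
    if (!"ratio" %in% assayNames(object))
        return("assay 'ratio' is required")
    msg <- .validWindowGrid(rowRanges(object))
    if (!isTRUE(msg)) return(msg)
    r <- assay(object, "ratio")
    if (any(!is.finite(r)) || any(r < 0))
        return("ratios must be finite and non-negative")
    if (is.null(metadata(object)$reference))
        return("metadata()$reference must name the reference strain")
    TRUE
})

#' @describeIn DepthProfileSet constructor.
#'
#' @param counts integer-like matrix, windows x strains.
#' @param windows \code{GRanges} window grid (equal width, sorted).
#' @param librarySize optional per-strain total mapped counts; defaults to
#'   \code{colSums(counts)}.
#' @param lineage optional per-strain lineage labels.
#' @param reference optional name of the designated reference strain.
#' @return A \code{DepthProfileSet}.
#' @export
DepthProfileSet <- function(counts, windows, librarySize = NULL,
                            lineage = NULL, reference = NULL) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        stop("counts must have strain column names")
    if (nrow(counts) != length(windows))
        stop("nrow(counts) must equal length(windows)")
    if (is.null(librarySize)) librarySize <- colSums(counts)
    if (is.null(lineage)) lineage <- rep(NA_character_, ncol(counts))
    cd <- DataFrame(strain = colnames(counts), lineage = lineage,
                    librarySize = as.numeric(librarySize),
                    row.names = colnames(counts))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowRanges = windows, colData = cd)
    obj <- new("DepthProfileSet", se)
    if (!is.null(reference)) {
        if (!reference %in% colnames(counts))
            stop("reference strain '", reference, "' not among profiles")
        metadata(obj)$reference <- reference
    }
    validObject(obj)
    obj
}

#' An N2 backcross dataset
#'
#' Markers with physical (Mb) and optional genetic (cM) positions, an
#' animals x markers genotype matrix coded \code{"H"} (heterozygous,
#' carrying the donor allele) / \code{"B"} (homozygous backcross parent) /
#' \code{NA} (missing), and a binary phenotype per animal. In an N2 backcross
#' every informative animal is het or homo at every locus, so recombination
#' fractions are directly countable.
#'
#' @slot markers \code{DataFrame} with columns \code{name}, \code{posMb} and
#'   optionally \code{posCm}, sorted by \code{posMb}.
#' @slot genotypes character matrix, animals x markers.
#' @slot phenotype integer vector of 0/1 per animal.
#' @slot metadata list; simulators record the true trait position here.
#' @export
setClass("BackcrossDataset",
    representation(markers = "DataFrame", genotypes = "matrix",
                   phenotype = "integer", metadata = "list"))

setValidity("BackcrossDataset", function(object) {
    m <- object@markers
    if (!all(c("name", "posMb") %in% colnames(m)))
        return("markers need 'name' and 'posMb' columns")
    if (is.unsorted(m$posMb))
        return("markers must be sorted by posMb")
    g <- object@genotypes
    if (nrow(g) < 1L)
        return("at least one animal is required")
    if (ncol(g) != nrow(m))
        return("genotype columns must match markers")
    if (!all(g %in% c("H", "B") | is.na(g)))
        return("genotype codes must be 'H', 'B' or NA")
    if (length(object@phenotype) != nrow(g))
        return("phenotype length must equal number of animals")
    if (!all(object@phenotype %in% c(0L, 1L) | is.na(object@phenotype)))
        return("phenotype must be binary (0/1) or NA")
    TRUE
})

#' @describeIn BackcrossDataset constructor.
#' @param markers data.frame/DataFrame of marker name, posMb, (posCm).
#' @param genotypes character matrix of "H"/"B"/NA, animals x markers.
#' @param phenotype 0/1 vector per animal.
#' @param metadata optional list of provenance (e.g. simulation truth).
#' @export
BackcrossDataset <- function(markers, genotypes, phenotype,
                             metadata = list()) {
    obj <- new("BackcrossDataset", markers = as(markers, "DataFrame"),
               genotypes = as.matrix(genotypes),
               phenotype = as.integer(phenotype), metadata = metadata)
    validObject(obj)
    obj
}

#' Per-marker linkage statistics and the interpolated physical peak
#'
#' @slot table \code{DataFrame} with one row per marker: \code{marker},
#'   \code{rHat} (recombination fraction), \code{R} (recombinant count),
#'   \code{N} (informative count), \code{lod}, \code{flag}.
#' @slot peakMb interpolated physical position of peak linkage (Mb).
#' @export
setClass("LinkageResult",
    representation(table = "DataFrame", peakMb = "numeric"))

setValidity("LinkageResult", function(object) {
    tb <- object@table
    need <- c("marker", "rHat", "R", "N", "lod")
    if (!all(need %in% colnames(tb)))
        return("linkage table is missing columns")
    if (any(tb$R > tb$N))
        return("R must not exceed N")
    if (any(tb$rHat < 0 | tb$rHat > 0.5))
        return("rHat must lie in [0, 0.5]")
    TRUE
})

#' A splice-acceptor context sequence
#'
#' Holds the sequence around a 3' splice site, the 0-based index of the
#' exon's first base within \code{seq}, and the strand. For minus-strand
#' sites the stored sequence is genome-forward; classification first takes
#' the reverse complement (the splice point maps to \code{nchar(seq) -
#' splicePoint}).
#'
#' @export
setClass("AcceptorSite",
    representation(seq = "character", splicePoint = "integer",
                   strand = "character", label = "character"))

setValidity("AcceptorSite", function(object) {
    if (length(object@seq) != 1L || nchar(object@seq) == 0L)
        return("seq must be a single non-empty string")
    if (!grepl("^[ACGTN]*$", object@seq))
        return("seq must be over {A,C,G,T,N} (other IUPAC codes rejected)")
    sp <- object@splicePoint
    if (sp < 0L || sp > nchar(object@seq))
        return("splicePoint must lie within [0, nchar(seq)]")
    if (!object@strand %in% c("+", "-"))
        return("strand must be '+' or '-'")
    TRUE
})

#' @describeIn AcceptorSite constructor.
#' @param seq acceptor-context sequence (A/C/G/T/N; upper-cased).
#' @param splicePoint 0-based index of the exon's first base within seq.
#' @param strand "+" or "-".
#' @param label free-text site label.
#' @export
acceptorSite <- function(seq, splicePoint, strand = "+", label = "") {
    obj <- new("AcceptorSite", seq = toupper(as.character(seq)),
               splicePoint = as.integer(splicePoint),
               strand = strand, label = as.character(label))
    validObject(obj)
    obj
}

#' Verdict of a splice-acceptor classification
#'
#' @slot passes does the context match the N[C/T]AG|G consensus?
#' @slot failed data.frame of failed positions: \code{offset} (relative to
#'   the splice point), \code{expected} (base class), \code{observed}.
#' @slot impact "high" for a ref-pass/alt-fail comparison, else "none".
#' @slot note diagnostic flag (e.g. when the reference itself fails).
#' @export
setClass("AcceptorVerdict",
    representation(passes = "logical", failed = "data.frame",
                   impact = "character", note = "character"))

setValidity("AcceptorVerdict", function(object) {
    if (object@passes != (nrow(object@failed) == 0L))
        return("passes must agree with emptiness of failed positions")
    if (!object@impact %in% c("none", "high"))
        return("impact must be 'none' or 'high'")
    TRUE
})

#' Scaffolds built from clone end-overlaps
#'
#' @slot scaffolds list of ordered clone-name vectors, one per scaffold.
#' @slot mergedLengths merged length (bp) of each scaffold.
#' @slot unplaced names of clones excluded before joining (e.g. all-vector).
#' @export
setClass("ScaffoldSet",
    representation(scaffolds = "list", mergedLengths = "numeric",
                   unplaced = "character"))

setValidity("ScaffoldSet", function(object) {
    ids <- unlist(object@scaffolds)
    if (anyDuplicated(c(ids, object@unplaced)))
        return("each clone must appear in exactly one scaffold or unplaced")
    if (length(object@mergedLengths) != length(object@scaffolds))
        return("one merged length per scaffold required")
    TRUE
})

#' Per-locus ERV expression counts with subclass annotation
#'
#' A \linkS4class{SummarizedExperiment} with a \code{"counts"} assay
#' (loci x samples), \code{rowData} columns \code{subclass} (eMLV, mpMLV,
#' pMLV or xMLV) and \code{pbs} (tRNA primer-binding-site class), and
#' \code{colData} columns \code{group} (two levels, >= 2 samples each) and
#' \code{librarySize} (total mapped reads; defaults to column sums, but
#' normally the transcriptome-wide total so that strong ERV induction does
#' not deflate the CPMs of unchanged loci).
#'
#' @export
setClass("ErvExpressionSet", contains = "SummarizedExperiment")

.ERV_SUBCLASSES <- c("eMLV", "mpMLV", "pMLV", "xMLV")
.PBS_CLASSES <- c("Pro", "Gln1", "other", "unknown")

setValidity("ErvExpressionSet", function(object) {
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    cts <- assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
        return("counts must be non-negative integers")
    rd <- rowData(object)
    if (!"subclass" %in% colnames(rd))
        return("rowData must contain 'subclass'")
    if (!all(rd$subclass %in% .ERV_SUBCLASSES))
        return("subclass must be one of eMLV/mpMLV/pMLV/xMLV")
    cd <- colData(object)
    if (!all(c("group", "librarySize") %in% colnames(cd)))
        return("colData must contain 'group' and 'librarySize'")
    tab <- table(cd$group)
    if (length(tab) != 2L || any(tab < 2L))
        return("two groups with >= 2 samples each are required")
    TRUE
})

#' @describeIn ErvExpressionSet constructor.
#' @param counts non-negative integer matrix, loci x samples.
#' @param subclass MLV subclass per locus (eMLV/mpMLV/pMLV/xMLV).
#' @param group group label per sample (two levels).
#' @param pbs optional tRNA primer-binding-site class per locus.
#' @param librarySize optional per-sample total mapped reads.
#' @export
ErvExpressionSet <- function(counts, subclass, group, pbs = NULL,
                             librarySize = NULL) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("locus_%03d", seq_len(nrow(counts)))
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("sample_%02d", seq_len(ncol(counts)))
    if (is.null(pbs)) pbs <- rep("unknown", nrow(counts))
    if (is.null(librarySize)) librarySize <- colSums(counts)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(subclass = subclass, pbs = pbs),
        colData = DataFrame(group = as.character(group),
                            librarySize = as.numeric(librarySize),
                            row.names = colnames(counts)))
    obj <- new("ErvExpressionSet", se)
    validObject(obj)
    obj
}
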
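# Accessors and show methods.

#' @rdname LinkageResult-class
#' @export
setMethod("peakMb", "LinkageResult", function(x) x@peakMb)

#' @rdname LinkageResult-class
#' @export
setMethod("linkageTable", "LinkageResult", function(x) x@table)

#' @rdname BackcrossDataset-class
#' @export
setMethod("markers", "BackcrossDataset", function(x) x@markers)

#' @rdname BackcrossDataset-class
#' @export
setMethod("genotypes", "BackcrossDataset", function(x) x@genotypes)

#' @rdname BackcrossDataset-class
#' @export
setMethod("phenotype", "BackcrossDataset", function(x) x@phenotype)

#' @rdname ScaffoldSet-class
#' @export
setMethod("scaffolds", "ScaffoldSet", function(x) x@scaffolds)

#' @rdname ScaffoldSet-class
#' @export
setMethod("unplaced", "ScaffoldSet", function(x) x@unplaced)

#' @rdname ScaffoldSet-class
#' @export
setMethod("mergedLengths", "ScaffoldSet", function(x) x@mergedLengths)

#' @rdname AcceptorVerdict-class
#' @export
setMethod("passes", "AcceptorVerdict", function(x) x@passes)

#' @rdname AcceptorVerdict-class
#' @export
setMethod("impact", "AcceptorVerdict", function(x) x@impact)

#' @rdname AcceptorVerdict-class
#' @export
setMethod("failedPositions", "AcceptorVerdict", function(x) x@failed)

#' @rdname DepthProfileSet-class
#' @export
setMethod("strainNames", "SummarizedExperiment", function(x) colnames(x))

#' @rdname DepthProfileSet-class
#' @export
setMethod("librarySizes", "SummarizedExperiment",
    function(x) setNames(colData(x)$librarySize, colnames(x)))

#' @rdname DepthProfileSet-class
#' @export
setMethod("referenceStrain", "SummarizedExperiment",
    function(x) metadata(x)$reference)

setMethod("show", "BackcrossDataset", function(object) {
    cat("BackcrossDataset:", nrow(object@genotypes), "animals x",
        nrow(object@markers), "markers\n")
    cat("  physical span:",
        sprintf("%.2f-%.2f Mb", min(object@markers$posMb),
                max(object@markers$posMb)), "\n")
    cat("  phenotype: ", sum(object@phenotype == 1L), " affected / ",
        sum(object@phenotype == 0L), " unaffected\n", sep = "")
})

setMethod("show", "LinkageResult", function(object) {
    cat("LinkageResult over", nrow(object@table), "markers\n")
    top <- object@table[which.max(object@table$lod), , drop = FALSE]
    cat(sprintf("  max LOD %.2f at %s; interpolated peak %.2f Mb\n",
                top$lod, top$marker, object@peakMb))
})

setMethod("show", "AcceptorSite", function(object) {
    sp <- object@splicePoint
    cat(sprintf("AcceptorSite%s [%s strand] %s|%s\n",
                if (nzchar(object@label)) paste0(" '", object@label, "'") else "",
                object@strand,
                substr(object@seq, 1L, sp),
                substr(object@seq, sp + 1L, nchar(object@seq))))
})

setMethod("show", "AcceptorVerdict", function(object) {
    cat("AcceptorVerdict:", if (object@passes) "PASS" else "FAIL",
        "| impact:", object@impact, "\n")
    if (nrow(object@failed) > 0L) {
        with(object@failed, cat(sprintf(
            "  offset %+d: expected %s, observed %s\n",
            offset, expected, observed)))
    }
    if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "ScaffoldSet", function(object) {
    cat("ScaffoldSet:", length(object@scaffolds), "scaffolds from",
        length(unlist(object@scaffolds)), "clones\n")
    for (i in seq_along(object@scaffolds))
        cat(sprintf("  [%d] %s (%.0f bp)\n", i,
                    paste(object@scaffolds[[i]], collapse = " - "),
                    object@mergedLengths[i]))
    if (length(object@unplaced))
        cat("  unplaced:", paste(object@unplaced, collapse = ", "), "\n")
})
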
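#' @rdname LinkageResult-class
#' @param x an object.
#' @export
setGeneric("peakMb", function(x) standardGeneric("peakMb"))

#' @rdname LinkageResult-class
#' @export
setGeneric("linkageTable", function(x) standardGeneric("linkageTable"))

#' @rdname BackcrossDataset-class
#' @param x an object.
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname BackcrossDataset-class
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname BackcrossDataset-class
#' @export
setGeneric("phenotype", function(x) standardGeneric("phenotype"))

#' @rdname ScaffoldSet-class
#' @param x an object.
#' @export
setGeneric("scaffolds", function(x) standardGeneric("scaffolds"))

#' @rdname ScaffoldSet-class
#' @export
setGeneric("unplaced", function(x) standardGeneric("unplaced"))

#' @rdname ScaffoldSet-class
#' @export
setGeneric("mergedLengths", function(x) standardGeneric("mergedLengths"))

#' @rdname AcceptorVerdict-class
#' @param x an object.
#' @export
setGeneric("passes", function(x) standardGeneric("passes"))

#' @rdname AcceptorVerdict-class
#' @export
setGeneric("impact", function(x) standardGeneric("impact"))

#' @rdname AcceptorVerdict-class
#' @export
setGeneric("failedPositions", function(x) standardGeneric("failedPositions"))

#' @rdname DepthProfileSet-class
#' @param x an object.
#' @export
setGeneric("strainNames", function(x) standardGeneric("strainNames"))

#' @rdname DepthProfileSet-class
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname DepthProfileSet-class
#' @export
setGeneric("referenceStrain", function(x) standardGeneric("referenceStrain"))
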
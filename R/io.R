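# Shared readers and writers. Internal coordinates are 0-based half-open
# throughout (GRanges objects carry the usual 1-based starts); only the
# parsers and serializers convert, so the mixed Mb- and bp-quoted
# coordinate styles of the literature never leak inward.

.stopLine <- function(file, line, why) {
    stop("malformed record in '", file, "' at line ", line, ": ", why)
}

#' Parse a printed genomic interval
#'
#' Accepts the two coordinate styles used for this region:
#' \itemize{
#'   \item Mb-quoted, e.g. \code{"13:65.79-66.60 Mb"}: boundaries are
#'     scaled by 1e6 exactly at the printed precision (65.79 becomes
#'     65,790,000) and treated as 0-based half-open.
#'   \item bp-quoted integers, e.g. \code{"13:66432223-66432240"}:
#'     1-based inclusive, so that example spans 18 bp.
#' }
#' En-dash and hyphen separators are both accepted.
#'
#' @param text interval string \code{chrom:lo-hi} with optional
#'   \code{" Mb"} suffix.
#' @return \code{GRanges} of length one.
#' @examples
#' parseMbInterval("13:65.79-66.60 Mb")
#' @export
parseMbInterval <- function(text) {
    stopifnot(length(text) == 1L)
    txt <- gsub("–", "-", trimws(text))
    m <- regmatches(txt, regexec(
        "^([A-Za-z0-9_.]+):([0-9.]+)-([0-9.]+)( ?Mb)?$", txt))[[1L]]
    if (length(m) == 0L) stop("malformed interval: '", text, "'")
    chrom <- m[2L]
    lo <- as.numeric(m[3L]); hi <- as.numeric(m[4L])
    mb <- nzchar(m[5L]) || grepl("\\.", m[3L]) || grepl("\\.", m[4L])
    if (mb) {
        startBp <- round(lo * 1e6); endBp <- round(hi * 1e6)
        if (endBp <= startBp) stop("inverted or empty interval: '", text, "'")
        GRanges(chrom, IRanges(startBp + 1, endBp))
    } else {
        startBp <- as.integer(lo); endBp <- as.integer(hi)
        if (endBp < startBp) stop("inverted interval: '", text, "'")
        GRanges(chrom, IRanges(startBp, endBp))    # 1-based inclusive
    }
}

#' Read and write bedGraph-style depth profiles
#'
#' One 4-column TSV per strain (chrom, start, end, count; 0-based
#' half-open, no header). All files must share an identical window grid.
#'
#' @param x a \linkS4class{DepthProfileSet}.
#' @param dir output directory (one \code{<strain>.bedgraph} per strain).
#' @return \code{writeDepthProfiles} returns the written paths
#'   invisibly; \code{readDepthProfiles} returns a
#'   \linkS4class{DepthProfileSet}.
#' @export
writeDepthProfiles <- function(x, dir) {
    stopifnot(is(x, "DepthProfileSet"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    gr <- rowRanges(x)
    paths <- character()
    for (s in strainNames(x)) {
        df <- data.frame(chrom = as.character(seqnames(gr)),
                         start = start(gr) - 1L, end = end(gr),
                         count = assay(x, "counts")[, s])
        p <- file.path(dir, paste0(s, ".bedgraph"))
        write.table(df, p, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' @rdname writeDepthProfiles
#' @param files bedGraph paths; strain names default to the file base
#'   names.
#' @param strains optional strain names matching \code{files}.
#' @param librarySize,lineage,reference passed to
#'   \code{\link{DepthProfileSet}}.
#' @export
readDepthProfiles <- function(files, strains = NULL, librarySize = NULL,
                              lineage = NULL, reference = NULL) {
    if (is.null(strains))
        strains <- sub("\\.(bedgraph|bg|tsv)$", "", basename(files))
    cols <- NULL; windows <- NULL
    counts <- matrix(0, nrow = 0, ncol = 0)
    for (i in seq_along(files)) {
        df <- tryCatch(
            read.delim(files[i], header = FALSE,
                       col.names = c("chrom", "start", "end", "count"),
                       colClasses = c("character", "integer", "integer",
                                      "numeric")),
            error = function(e) stop("cannot parse '", files[i], "': ",
                                     conditionMessage(e)))
        if (nrow(df) == 0L) stop("empty depth file: '", files[i], "'")
        bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$count))
        if (length(bad)) .stopLine(files[i], bad[1L], "non-numeric field")
        gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
        if (is.null(windows)) {
            windows <- gr
            counts <- matrix(0, nrow = length(gr), ncol = length(files),
                             dimnames = list(NULL, strains))
        } else if (length(gr) != length(windows) ||
                   any(start(gr) != start(windows)) ||
                   any(end(gr) != end(windows))) {
            stop("window grid of '", files[i],
                 "' differs from the first file")
        }
        counts[, i] <- df$count
    }
    DepthProfileSet(counts, windows, librarySize = librarySize,
                    lineage = lineage, reference = reference)
}

#' Read and write a backcross dataset as two TSVs
#'
#' The map TSV has columns \code{name}, \code{posMb}, \code{posCm}; the
#' genotype TSV has one row per animal, one column per marker (codes
#' \code{"H"}/\code{"B"}, empty for missing) plus a final
#' \code{phenotype} column (0/1).
#'
#' @param x a \linkS4class{BackcrossDataset}.
#' @param mapFile,genoFile output/input paths.
#' @return \code{readBackcross} returns a
#'   \linkS4class{BackcrossDataset}.
#' @export
writeBackcross <- function(x, mapFile, genoFile) {
    stopifnot(is(x, "BackcrossDataset"))
    write.table(as.data.frame(markers(x)), mapFile, sep = "\t",
                quote = FALSE, row.names = FALSE)
    df <- as.data.frame(genotypes(x))
    df$phenotype <- phenotype(x)
    write.table(df, genoFile, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
    invisible(c(mapFile, genoFile))
}

#' @rdname writeBackcross
#' @export
readBackcross <- function(mapFile, genoFile) {
    mk <- read.delim(mapFile)
    if (!all(c("name", "posMb") %in% colnames(mk)))
        .stopLine(mapFile, 1L, "missing 'name'/'posMb' header")
    gn <- read.delim(genoFile, na.strings = c("", "NA"),
                     colClasses = "character", check.names = FALSE)
    if (!"phenotype" %in% colnames(gn))
        .stopLine(genoFile, 1L, "missing 'phenotype' column")
    ph <- as.integer(gn$phenotype)
    g <- as.matrix(gn[, setdiff(colnames(gn), "phenotype"), drop = FALSE])
    if (!identical(colnames(g), as.character(mk$name)))
        stop("genotype columns do not match the marker map")
    BackcrossDataset(mk, g, ph)
}

#' Read and write alignment segments as minimal PAF
#'
#' Standard 12-column PAF (qname, qlen, qstart, qend, strand, tname,
#' tlen, tstart, tend, matches, block length, mapq) plus an \code{id:f:}
#' tag carrying percent identity. On reading, identity falls back to
#' \code{100 * matches / block} when the tag is absent.
#'
#' @param segs segment data.frame (see \code{\link{filterSegments}}).
#' @param file path.
#' @param queryLengths,targetLengths named length vectors; unknown
#'   lengths are written as the largest coordinate seen.
#' @return \code{readPaf} returns a list with \code{segments} and
#'   \code{queryLengths}.
#' @export
writePaf <- function(segs, file, queryLengths = NULL,
                     targetLengths = NULL) {
    segs <- .checkSegments(segs)
    ql <- function(n) {
        if (!is.null(queryLengths) && n %in% names(queryLengths))
            queryLengths[[n]] else max(segs$qend[segs$qname == n])
    }
    tl <- function(n) {
        if (!is.null(targetLengths) && n %in% names(targetLengths))
            targetLengths[[n]] else max(segs$tend[segs$tname == n])
    }
    blk <- segs$qend - segs$qstart
    df <- data.frame(
        qname = segs$qname, qlen = vapply(segs$qname, ql, 0),
        qstart = segs$qstart, qend = segs$qend,
        strand = ifelse(segs$orientation == "forward", "+", "-"),
        tname = segs$tname, tlen = vapply(segs$tname, tl, 0),
        tstart = segs$tstart, tend = segs$tend,
        matches = round(blk * segs$identity / 100), block = blk,
        mapq = 60L, id = sprintf("id:f:%.4f", segs$identity))
    write.table(df, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' @rdname writePaf
#' @export
readPaf <- function(file) {
    lines <- readLines(file)
    if (!length(lines))
        return(list(segments = data.frame(), queryLengths = numeric()))
    parts <- strsplit(lines, "\t")
    short <- which(lengths(parts) < 12L)
    if (length(short))
        .stopLine(file, short[1L], "fewer than 12 PAF columns")
    get <- function(i) vapply(parts, `[`, "", i)
    num <- function(i) {
        v <- suppressWarnings(as.numeric(get(i)))
        bad <- which(is.na(v))
        if (length(bad)) .stopLine(file, bad[1L], "non-numeric field")
        v
    }
    idTag <- vapply(parts, function(p) {
        hit <- grep("^id:f:", p, value = TRUE)
        if (length(hit)) as.numeric(sub("^id:f:", "", hit[1L]))
        else NA_real_
    }, 0)
    matches <- num(10); block <- num(11)
    identity <- ifelse(is.na(idTag), 100 * matches / block, idTag)
    segs <- data.frame(
        qname = get(1), qstart = num(3), qend = num(4),
        tname = get(6), tstart = num(8), tend = num(9),
        identity = identity,
        orientation = ifelse(get(5) == "+", "forward", "reverse"))
    qlen <- num(2)
    list(segments = segs,
         queryLengths = setNames(qlen, get(1))[!duplicated(get(1))])
}

#' Write genomic ranges as BED
#'
#' Plain 3-6 column BED (0-based half-open); a \code{name} metadata
#' column is written in column 4 when present.
#'
#' @param gr a \code{GRanges}.
#' @param file path.
#' @return \code{readBed} returns a \code{GRanges}.
#' @export
writeBed <- function(gr, file) {
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr))
    if ("name" %in% colnames(mcols(gr)))
        df$name <- mcols(gr)$name
    write.table(df, file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' @rdname writeBed
#' @export
readBed <- function(file) {
    lines <- readLines(file)
    if (!length(lines)) return(GRanges())
    parts <- strsplit(lines, "\t")
    short <- which(lengths(parts) < 3L)
    if (length(short))
        .stopLine(file, short[1L], "fewer than 3 BED columns")
    start0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
    bad <- which(is.na(start0) | is.na(end0))
    if (length(bad)) .stopLine(file, bad[1L], "non-integer coordinates")
    gr <- GRanges(vapply(parts, `[`, "", 1L),
                  IRanges(start0 + 1L, end0))
    if (all(lengths(parts) >= 4L))
        mcols(gr)$name <- vapply(parts, `[`, "", 4L)
    gr
}

#' Read and write an ERV count table
#'
#' TSV with columns \code{locus}, \code{subclass}, \code{pbs}, then one
#' count column per sample.
#'
#' @param m an \linkS4class{ErvExpressionSet}.
#' @param file path.
#' @param group per-sample group labels for \code{readCountsTsv} (named
#'   or in column order).
#' @param librarySize optional per-sample totals.
#' @return \code{readCountsTsv} returns an
#'   \linkS4class{ErvExpressionSet}.
#' @export
writeCountsTsv <- function(m, file) {
    stopifnot(is(m, "ErvExpressionSet"))
    df <- data.frame(locus = rownames(m),
                     subclass = rowData(m)$subclass,
                     pbs = rowData(m)$pbs,
                     assay(m, "counts"), check.names = FALSE)
    write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' @rdname writeCountsTsv
#' @export
readCountsTsv <- function(file, group, librarySize = NULL) {
    df <- read.delim(file, check.names = FALSE)
    need <- c("locus", "subclass", "pbs")
    if (!all(need %in% colnames(df)))
        .stopLine(file, 1L, "missing locus/subclass/pbs header")
    samples <- setdiff(colnames(df), need)
    cts <- as.matrix(df[, samples, drop = FALSE])
    rownames(cts) <- df$locus
    ErvExpressionSet(cts, df$subclass, group = group, pbs = df$pbs,
                     librarySize = librarySize)
}

#' Round-trip a flat key=value run configuration
#'
#' @param config named list of scalar settings.
#' @param file path.
#' @return \code{readRunConfig} returns the named list (numbers
#'   re-typed).
#' @export
writeRunConfig <- function(config, file) {
    writeLines(sprintf("%s=%s", names(config),
                       vapply(config, as.character, "")), file)
    invisible(file)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(file) {
    lines <- readLines(file)
    lines <- lines[nzchar(trimws(lines))]
    kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
    bad <- which(lengths(kv) == 0L)
    if (length(bad)) .stopLine(file, bad[1L], "expected key=value")
    vals <- lapply(kv, function(x) {
        v <- x[3L]
        n <- suppressWarnings(as.numeric(v))
        if (!is.na(n)) n else v
    })
    setNames(vals, vapply(kv, `[`, "", 2L))
}
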
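# End-to-end orchestration over synthetic inputs, in the analysis order
# of the study: linkage scan -> depth-ratio CNV profiling and strain
# clustering -> assembly comparison and acceptor classification -> ERV
# expression analysis.

#' Build a validated run configuration
#'
#' @param seed master integer seed; every stage derives its seed from it.
#' @param windowBp depth window width (default 10 kb).
#' @param nAnimals backcross size (default 1108).
#' @param penetrance trait penetrance (default 0.95).
#' @param traitPosMb true trait position for the simulated backcross.
#' @param minLenBp,minIdentity segment filter thresholds (1 kb, 98).
#' @param q,lfc regulation rule thresholds (0.01, 1).
#' @param nPermutations permutation budget for the DE test.
#' @return named list of class \code{"RunConfig"}.
#' @export
runConfig <- function(seed = 1, windowBp = 1e4, nAnimals = 1108,
                      penetrance = 0.95, traitPosMb = 66.58,
                      minLenBp = 1000, minIdentity = 98, q = 0.01,
                      lfc = 1, nPermutations = 10000) {
    stopifnot(windowBp > 0, nAnimals >= 1, penetrance > 0.5,
              penetrance <= 1, minLenBp >= 0, minIdentity >= 0,
              minIdentity <= 100, q > 0, q < 1, lfc >= 0,
              nPermutations >= 100)
    structure(list(seed = as.integer(seed), windowBp = windowBp,
                   nAnimals = nAnimals, penetrance = penetrance,
                   traitPosMb = traitPosMb, minLenBp = minLenBp,
                   minIdentity = minIdentity, q = q, lfc = lfc,
                   nPermutations = nPermutations),
              class = c("RunConfig", "list"))
}

.stageSeed <- function(config, offset)
    as.integer((as.numeric(config$seed) * 101 + offset) %% 2147483647)

#' Run the full synthetic pipeline
#'
#' Generates every input at the study conditions, runs all stages, and
#' returns (optionally writes) a machine-readable summary. Deterministic
#' given \code{config$seed}.
#'
#' @param config a \code{\link{runConfig}}.
#' @param outDir optional directory; when given, per-stage artifacts
#'   (TSV/BED/FASTA/PAF) and a \code{summary.json} are written there.
#' @param verbose log stage progress to stderr.
#' @return list of per-stage results plus a \code{summary} list.
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL,
                        verbose = FALSE) {
    stopifnot(inherits(config, "RunConfig"))
    say <- function(...) if (verbose) message("[gv1scan] ", ...)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)

    say("linkage scan")
    linkage <- stage("linkage", {
        map <- gv1MarkerMap()
        traitCm <- stats::approx(map$posMb, map$posCm,
                                 xout = config$traitPosMb)$y
        bc <- simBackcross(map, traitCm, nAnimals = config$nAnimals,
                           penetrance = config$penetrance,
                           seed = .stageSeed(config, 1L))
        list(dataset = bc, result = linkageScan(bc))
    })

    say("depth-ratio CNV profiling")
    cnv <- stage("depth_cnv", {
        cfg <- simConfig(windowBp = config$windowBp,
                         seed = .stageSeed(config, 2L))
        dps <- simDepthProfiles(gv1StrainPanel(), cfg, reference = "B6J")
        rps <- depthRatio(dps)
        calls <- segmentRatio(rps)
        d <- maeDistanceMatrix(rps)
        cl <- clusterStrains(d, k = 2)
        list(profiles = dps, ratios = rps, calls = calls,
             distance = d, clustering = cl)
    })

    say("assembly comparison")
    assembly <- stage("assembly_compare", {
        sim <- simAlignmentSegments(
            dupRegions = data.frame(start = c(4e4, 1.2e5),
                                    end = c(6e4, 1.5e5)),
            uniqueRegions = data.frame(start = 2.1e5, end = 2.3e5),
            seed = .stageSeed(config, 3L))
        kept <- filterSegments(sim$segments, config$minLenBp,
                               config$minIdentity)
        dup <- duplicatedRegions(kept, windowBp = 1e4)
        unique <- queryUniqueRegions(kept, sim$queryLengths)
        bacs <- simBacClones(seed = .stageSeed(config, 4L))
        scaff <- joinScaffolds(bacs$clones)
        list(segments = sim$segments, queryLengths = sim$queryLengths,
             kept = kept, duplicated = dup, unique = unique,
             clones = bacs, scaffolds = scaff)
    })

    say("splice-acceptor classification")
    splice <- stage("splice_sites", {
        sites <- simAcceptorSites(seed = .stageSeed(config, 5L))
        verdicts <- lapply(sites, classifyAcceptor)
        # the two broken copies stand for the two assembled scaffold
        # alleles compared against the reference gene
        impacts <- lapply(sites[c("broken_pyrimidine", "broken_exonic")],
                          function(alt)
                              compareAcceptors(sites$reference, alt))
        list(sites = sites, verdicts = verdicts, impacts = impacts)
    })

    say("ERV expression analysis")
    expr <- stage("expression", {
        se <- simExpressionCounts(seed = .stageSeed(config, 6L))
        de <- deTest(se, nPermutations = config$nPermutations,
                     seed = .stageSeed(config, 7L),
                     qThreshold = config$q, lfcThreshold = config$lfc)
        folds <- subclassFoldSummary(de, se)
        pbs <- pbsStratification(de)
        list(counts = se, de = de, folds = folds, pbs = pbs)
    })

    summary <- list(
        schemaVersion = 1L,
        seed = config$seed,
        peakMb = peakMb(linkage$result),
        maxLod = max(linkageTable(linkage$result)$lod),
        nCnvCalls = length(cnv$calls),
        cnvStrains = unique(mcols(cnv$calls)$strain),
        clusterGroups = as.list(cnv$clustering$groups),
        nSegmentsKept = nrow(assembly$kept),
        nDuplicatedRegions = length(assembly$duplicated),
        nUniqueRegions = length(assembly$unique),
        nScaffolds = length(scaffolds(assembly$scaffolds)),
        acceptorPasses = vapply(splice$verdicts, passes, TRUE),
        highImpactVariants = sum(vapply(splice$impacts, impact,
                                        "") == "high"),
        nRegulated = sum(expr$de$regulated),
        subclassFolds = as.list(expr$folds),
        pbsStratified = expr$pbs$stratified)

    if (!is.null(outDir)) {
        writeBackcross(linkage$dataset,
                       file.path(outDir, "backcross_map.tsv"),
                       file.path(outDir, "backcross_genotypes.tsv"))
        write.table(as.data.frame(linkageTable(linkage$result)),
                    file.path(outDir, "linkage.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        writeDepthProfiles(cnv$profiles, file.path(outDir, "depth"))
        writeBed(cnv$calls, file.path(outDir, "cnv_calls.bed"))
        write.table(cnv$distance, file.path(outDir, "mae_matrix.tsv"),
                    sep = "\t", quote = FALSE)
        writePaf(assembly$kept, file.path(outDir, "segments.paf"),
                 queryLengths = assembly$queryLengths)
        writeBed(assembly$duplicated,
                 file.path(outDir, "duplicated_regions.bed"))
        writeBed(assembly$unique, file.path(outDir, "unique_regions.bed"))
        writeXStringSet(assembly$clones$clones,
                        file.path(outDir, "bac_clones.fa"))
        writeCountsTsv(expr$counts, file.path(outDir, "erv_counts.tsv"))
        write.table(as.data.frame(expr$de),
                    file.path(outDir, "de_results.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        jsonlite::write_json(summary,
                             file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    say("done")
    list(linkage = linkage, cnv = cnv, assembly = assembly,
         splice = splice, expression = expr, summary = summary)
}
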
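# Synthetic-data generators.
#
# These emulate the inputs of the real study at its stated conditions: a
# 1,108-animal, nine-marker backcross; strain depth profiles over a ~4 Mb
# region carrying ~Mb-scale deletions/duplications on two lineage
# backgrounds; acceptor contexts in consensus and broken forms; alignment
# segment sets with duplicated and unique regions; and two-group ERV count
# matrices with subclass-specific fold changes (14.5x pMLV / 5.3x xMLV,
# three mice per group).

#' Strain specification for depth simulation
#'
#' @param name strain name.
#' @param lineage lineage label, e.g. \code{"C57"} or \code{"nonC57"}.
#' @param cnSegments data.frame with columns \code{start}, \code{end}
#'   (0-based half-open bp) and \code{cn} (integer copy number >= 0).
#'   Copy number defaults to 2 outside listed segments.
#' @param meanDepth expected reads per window at copy number 2.
#' @return A \code{list} of class \code{"StrainSpec"}.
#' @export
strainSpec <- function(name, lineage = "C57",
                       cnSegments = data.frame(start = numeric(),
                                               end = numeric(),
                                               cn = integer()),
                       meanDepth = 100) {
    stopifnot(is.character(name), length(name) == 1L, meanDepth > 0)
    seg <- as.data.frame(cnSegments)
    if (nrow(seg)) {
        stopifnot(all(c("start", "end", "cn") %in% colnames(seg)))
        seg <- seg[order(seg$start), , drop = FALSE]
        if (any(seg$end <= seg$start))
            stop("cnSegments must have end > start")
        if (any(seg$cn < 0))
            stop("copy numbers must be >= 0")
        if (nrow(seg) > 1L && any(seg$start[-1L] < seg$end[-nrow(seg)]))
            stop("cnSegments must be non-overlapping")
    }
    structure(list(name = name, lineage = lineage, cnSegments = seg,
                   meanDepth = meanDepth), class = "StrainSpec")
}

#' Simulation configuration for depth profiles
#'
#' The last partial window at the region end is dropped, not padded, so all
#' windows are equal width and ratios stay comparable.
#'
#' @param chrom chromosome name.
#' @param startBp,endBp region bounds, 0-based half-open.
#' @param windowBp window width in bp (default 10 kb).
#' @param noise \code{"poisson"} or \code{"nb"} (negative binomial with
#'   variance mu + dispersion * mu^2; dispersion 0 degrades to Poisson).
#' @param dispersion NB dispersion alpha.
#' @param seed integer seed; identical seeds give identical outputs.
#' @return A \code{list} of class \code{"SimConfig"}.
#' @export
simConfig <- function(chrom = "13", startBp = 63e6, endBp = 67e6,
                      windowBp = 1e4, noise = c("poisson", "nb"),
                      dispersion = 0, seed = 1) {
    noise <- match.arg(noise)
    if (endBp <= startBp) stop("zero-width or inverted region")
    if (windowBp > endBp - startBp) stop("window larger than region")
    if (dispersion < 0) stop("dispersion must be >= 0")
    structure(list(chrom = chrom, startBp = startBp, endBp = endBp,
                   windowBp = as.integer(windowBp), noise = noise,
                   dispersion = dispersion, seed = as.integer(seed)),
              class = "SimConfig")
}

# window grid as GRanges (1-based starts for 0-based half-open windows)
.makeWindows <- function(chrom, startBp, endBp, windowBp) {
    n <- floor((endBp - startBp) / windowBp)   # drop last partial window
    if (n < 1L) stop("window larger than region")
    starts0 <- startBp + (seq_len(n) - 1L) * windowBp
    GRanges(chrom, IRanges(start = starts0 + 1, width = windowBp))
}

# per-window copy number by window-midpoint rule
.windowCn <- function(spec, windows) {
    cn <- rep(2L, length(windows))
    mid <- (start(windows) - 1 + end(windows)) / 2
    seg <- spec$cnSegments
    for (i in seq_len(nrow(seg)))
        cn[mid >= seg$start[i] & mid < seg$end[i]] <- as.integer(seg$cn[i])
    cn
}

#' Simulate windowed depth profiles for a strain panel
#'
#' Expected count per window is \code{meanDepth * CN / 2}; counts are drawn
#' per the configured noise model on a window grid shared by all strains.
#' Library sizes are set to \code{meanDepth * nWindows} (the expected
#' diploid total), standing in for a genome-scale total so that large CNVs
#' inside the profiled region do not distort normalization.
#'
#' @param specs list of \code{\link{strainSpec}} objects (>= 2).
#' @param cfg a \code{\link{simConfig}}.
#' @param reference name of the designated reference strain; must be all-CN2.
#' @return A \linkS4class{DepthProfileSet}; the per-window copy-number truth
#'   matrix is stored in \code{metadata()$cnTruth}.
#' @export
simDepthProfiles <- function(specs, cfg, reference) {
    stopifnot(inherits(cfg, "SimConfig"), length(specs) >= 2L)
    names(specs) <- vapply(specs, `[[`, "", "name")
    if (!reference %in% names(specs))
        stop("reference strain '", reference, "' not among specs")
    if (nrow(specs[[reference]]$cnSegments) &&
        any(specs[[reference]]$cnSegments$cn != 2L))
        stop("the reference strain must be copy-number 2 throughout")
    windows <- .makeWindows(cfg$chrom, cfg$startBp, cfg$endBp, cfg$windowBp)
    nw <- length(windows)
    set.seed(cfg$seed)
    counts <- matrix(0, nrow = nw, ncol = length(specs),
                     dimnames = list(NULL, names(specs)))
    cnTruth <- counts
    for (s in names(specs)) {
        cn <- .windowCn(specs[[s]], windows)
        mu <- specs[[s]]$meanDepth * cn / 2
        counts[, s] <- if (cfg$noise == "poisson" || cfg$dispersion == 0)
            rpois(nw, mu)
        else
            rnbinom(nw, mu = mu, size = 1 / cfg$dispersion)
        cnTruth[, s] <- cn
    }
    libs <- vapply(specs, function(sp) sp$meanDepth * nw, 0)
    dps <- DepthProfileSet(counts, windows, librarySize = libs,
                           lineage = vapply(specs, `[[`, "", "lineage"),
                           reference = reference)
    metadata(dps)$cnTruth <- cnTruth
    dps
}

#' The exemplar strain panel of the depth analysis
#'
#' Nine inbred strains over 13:63-67 Mb in two lineage backgrounds. The
#' C57 lineage is diploid apart from the engineered deletions (an 810 kb
#' deletion at 13:65.79-66.60 Mb shared by B6N and B10, extended to 1.15 Mb
#' at 13:65.45-66.60 Mb in C57BR); the non-C57 lineage carries an alternate
#' chromosomal conformation (region-wide gains and losses including a
#' duplication of the 1.49 Mb 13:65.47-66.96 Mb interval) plus small private
#' variants, so within-lineage profiles agree over most windows while
#' between-lineage profiles disagree over the majority.
#'
#' @return A named list of \code{\link{strainSpec}} objects; the reference
#'   strain is \code{"B6J"}.
#' @export
gv1StrainPanel <- function() {
    seg <- function(...) {
        m <- matrix(c(...), ncol = 3, byrow = TRUE)
        data.frame(start = m[, 1], end = m[, 2], cn = as.integer(m[, 3]))
    }
    backbone <- seg(63.0e6, 64.5e6, 1,
                    64.5e6, 65.2e6, 3,
                    65.47e6, 66.96e6, 4)
    panel <- list(
        strainSpec("B6J", "C57"),
        strainSpec("C57L", "C57"),
        strainSpec("B6N", "C57", seg(65.79e6, 66.60e6, 0)),
        strainSpec("B10", "C57", seg(65.79e6, 66.60e6, 0)),
        strainSpec("C57BR", "C57", seg(65.45e6, 66.60e6, 0)),
        strainSpec("ZALENDE", "nonC57", backbone),
        strainSpec("SPRET", "nonC57",
                   rbind(backbone, seg(65.25e6, 65.40e6, 1))),
        strainSpec("NZB", "nonC57",
                   rbind(backbone, seg(66.96e6, 67.0e6, 3))),
        strainSpec("129", "nonC57", backbone))
    names(panel) <- vapply(panel, `[[`, "", "name")
    panel
}

#' Simulate an N2 backcross
#'
#' One meiosis per animal over the marker map, with recombination
#' probability between adjacent loci given by Haldane's map function
#' \code{r = (1 - exp(-2 d / 100)) / 2} (memoryless crossovers). Genotypes
#' are coded \code{"H"} (heterozygous, donor allele present) / \code{"B"}
#' (homozygous backcross parent). The phenotype equals the trait-locus
#' genotype, flipped with probability \code{1 - penetrance} symmetrically in
#' both genotype classes.
#'
#' @param markers data.frame with columns \code{name}, \code{posMb},
#'   \code{posCm}, sorted by \code{posCm}.
#' @param traitPosCm genetic position of the trait locus (cM).
#' @param nAnimals number of N2 animals (>= 1).
#' @param penetrance probability the phenotype reflects the trait genotype,
#'   in (0.5, 1].
#' @param seed integer seed.
#' @param traitPosMb optional physical truth position recorded in metadata
#'   (linearly interpolated from the map when omitted).
#' @return A \linkS4class{BackcrossDataset}; metadata records
#'   \code{traitPosCm} and \code{traitPosMb}.
#' @export
simBackcross <- function(markers, traitPosCm, nAnimals = 1108,
                         penetrance = 0.95, seed = 1, traitPosMb = NULL) {
    markers <- as.data.frame(markers)
    stopifnot(all(c("name", "posMb", "posCm") %in% colnames(markers)))
    if (nAnimals < 1L) stop("nAnimals must be >= 1")
    if (is.unsorted(markers$posCm) || is.unsorted(markers$posMb))
        stop("marker map must be sorted")
    if (penetrance <= 0.5 || penetrance > 1)
        stop("penetrance must be in (0.5, 1]")
    set.seed(seed)
    # insert the trait locus into the cM map
    cm <- c(markers$posCm, traitPosCm)
    ord <- order(cm, c(rep(0, nrow(markers)), 1))  # trait after a tied marker
    cm <- cm[ord]
    traitIdx <- which(ord == nrow(markers) + 1L)
    nLoci <- length(cm)
    alleles <- matrix(0L, nrow = nAnimals, ncol = nLoci)
    alleles[, 1L] <- rbinom(nAnimals, 1L, 0.5)
    if (nLoci > 1L) {
        r <- haldaneR(diff(cm))
        for (l in 2:nLoci) {
            rec <- rbinom(nAnimals, 1L, r[l - 1L])
            alleles[, l] <- ifelse(rec == 1L, 1L - alleles[, l - 1L],
                                   alleles[, l - 1L])
        }
    }
    pheno <- alleles[, traitIdx]
    flip <- rbinom(nAnimals, 1L, 1 - penetrance)
    pheno <- ifelse(flip == 1L, 1L - pheno, pheno)
    # markers enter sorted, so dropping the trait column restores their order
    geno <- alleles[, -traitIdx, drop = FALSE]
    gchar <- matrix(c("B", "H")[geno + 1L], nrow = nAnimals,
                    dimnames = list(NULL, markers$name))
    if (is.null(traitPosMb)) {
        traitPosMb <- if (length(unique(markers$posCm)) < 2L)
            markers$posMb[which.min(abs(markers$posCm - traitPosCm))]
        else
            stats::approx(markers$posCm, markers$posMb, xout = traitPosCm,
                          rule = 2, ties = mean)$y
    }
    BackcrossDataset(markers, gchar, pheno,
                     metadata = list(traitPosCm = traitPosCm,
                                     traitPosMb = traitPosMb,
                                     penetrance = penetrance, seed = seed))
}

#' The nine-marker map of the linkage reanalysis conditions
#'
#' Nine evenly spaced markers over 13:63-68 Mb with genetic positions at
#' 0.5 cM/Mb (the mouse genome-average rate), emulating the geometry of the
#' 1,108-animal backcross the linkage stage reanalyses.
#'
#' @return data.frame with columns \code{name}, \code{posMb}, \code{posCm}.
#' @export
gv1MarkerMap <- function() {
    posMb <- seq(63, 68, length.out = 9)
    data.frame(name = sprintf("D13S%02d", seq_along(posMb)),
               posMb = posMb, posCm = (posMb - 63) * 0.5)
}

#' Simulate splice-acceptor contexts
#'
#' Returns a consensus-passing reference site plus sites broken at defined
#' consensus positions (the intronic pyrimidine and the exonic +1 base),
#' each also represented on the minus strand (sequence stored
#' genome-forward).
#'
#' @param seed integer seed for the random flanking bases.
#' @param contextLen total context length (intron + 5 exonic bases).
#' @return named list of \linkS4class{AcceptorSite} objects.
#' @export
simAcceptorSites <- function(seed = 1, contextLen = 18L) {
    set.seed(seed)
    nIntron <- contextLen - 5L
    stopifnot(nIntron >= 4L)
    rb <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                            collapse = "")
    mk <- function(pyr = "C", exon1 = "G") {
        paste0(rb(nIntron - 4L), rb(1L), pyr, "A", "G", exon1, rb(4L))
    }
    sp <- nIntron
    refSeq <- mk()
    brokenPyr <- mk(pyr = "A")              # purine at the pyrimidine slot
    brokenExon <- mk(exon1 = "A")           # exonic +1 base not G
    rc <- function(s) as.character(reverseComplement(DNAString(s)))
    L <- nchar(refSeq)
    list(
        reference = acceptorSite(refSeq, sp, "+", "reference"),
        broken_pyrimidine = acceptorSite(brokenPyr, sp, "+",
                                         "broken_pyrimidine"),
        broken_exonic = acceptorSite(brokenExon, sp, "+", "broken_exonic"),
        reference_minus = acceptorSite(rc(refSeq), L - sp, "-",
                                       "reference_minus"),
        broken_pyrimidine_minus = acceptorSite(rc(brokenPyr), L - sp, "-",
                                               "broken_pyrimidine_minus"))
}

#' Simulate assembly-versus-reference alignment segments
#'
#' Builds a PAF-like segment set for one assembled query against a
#' reference axis: near-diagonal background segments tile the reference,
#' each duplicated region receives a second, query-distal copy (so its
#' reference windows are covered by >= 2 segments), and declared unique
#' query intervals are left uncovered.
#'
#' @param dupRegions data.frame of \code{start}, \code{end} on the
#'   reference axis (0-based half-open bp); may be empty.
#' @param uniqueRegions data.frame of \code{start}, \code{end} on the query
#'   axis; may be empty.
#' @param baseIdentity central percent identity of simulated segments.
#' @param seed integer seed.
#' @param refLength reference axis length (bp).
#' @param segLen nominal background segment length (bp).
#' @param qname,tname sequence names.
#' @return list with \code{segments} (data.frame of qname, qstart, qend,
#'   tname, tstart, tend, identity, orientation) and \code{queryLengths}
#'   (named vector).
#' @export
simAlignmentSegments <- function(dupRegions = data.frame(),
                                 uniqueRegions = data.frame(),
                                 baseIdentity = 99, seed = 1,
                                 refLength = 2e5, segLen = 2e4,
                                 qname = "assembly_129", tname = "13") {
    set.seed(seed)
    dup <- as.data.frame(dupRegions); uni <- as.data.frame(uniqueRegions)
    chk <- function(d, axisLen, what) {
        if (!nrow(d)) return(d)
        d <- d[order(d$start), , drop = FALSE]
        if (any(d$end <= d$start) || any(d$start < 0) || any(d$end > axisLen))
            stop(what, " regions must be non-empty intervals within the region")
        if (nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)]))
            stop("overlapping contradictory ", what, " specs")
        d
    }
    dup <- chk(dup, refLength, "duplicated")
    uni <- chk(uni, Inf, "unique")
    jitterId <- function(n) pmin(100, baseIdentity + stats::rnorm(n, 0, 0.3))
    segs <- list(); qpos <- 0; rpos <- 0
    while (rpos < refLength) {
        # reserve declared unique query space
        hit <- which(nrow(uni) > 0 & uni$start <= qpos & qpos < uni$end)
        if (length(hit)) qpos <- uni$end[hit[1L]]
        len <- round(segLen * runif(1, 0.7, 1.3))
        len <- min(len, refLength - rpos)
        nxt <- if (nrow(uni)) uni$start[uni$start > qpos] else numeric()
        if (length(nxt)) len <- min(len, nxt[1L] - qpos)
        segs[[length(segs) + 1L]] <- data.frame(
            qname = qname, qstart = qpos, qend = qpos + len,
            tname = tname, tstart = rpos, tend = rpos + len,
            identity = jitterId(1L), orientation = "forward")
        qpos <- qpos + len; rpos <- rpos + len
    }
    for (i in seq_len(nrow(dup))) {
        len <- dup$end[i] - dup$start[i]
        segs[[length(segs) + 1L]] <- data.frame(
            qname = qname, qstart = qpos, qend = qpos + len,
            tname = tname, tstart = dup$start[i], tend = dup$end[i],
            identity = jitterId(1L),
            orientation = if (i %% 2L) "reverse" else "forward")
        qpos <- qpos + len
    }
    qlen <- max(qpos, if (nrow(uni)) max(uni$end) else 0)
    list(segments = do.call(rbind, segs),
         queryLengths = setNames(qlen, qname))
}

#' Simulate BAC clone sequences with engineered end-overlaps
#'
#' Each overlap component is a random DNA stretch cut into clones whose
#' ends overlap exactly by a configurable amount; alternate clones are
#' stored reverse-complemented so both orientations are exercised. The
#' default layout engineers 15 clones into 8 overlap components, mirroring
#' the scaffolding outcome of the BAC analysis.
#'
#' @param seed integer seed.
#' @param componentSizes clones per component.
#' @param cloneLenBp nominal clone length.
#' @param overlapBp range (min, max) of engineered overlap lengths.
#' @return list with \code{clones} (\code{DNAStringSet}) and \code{truth}
#'   (list of clone-name vectors per component).
#' @export
simBacClones <- function(seed = 1, componentSizes = c(3, 3, 2, 2, 2, 1, 1, 1),
                         cloneLenBp = 8000, overlapBp = c(2000, 3000)) {
    set.seed(seed)
    clones <- list(); truth <- list(); k <- 0L
    for (ci in seq_along(componentSizes)) {
        n <- componentSizes[ci]
        ov <- if (n > 1L) round(runif(n - 1L, overlapBp[1L], overlapBp[2L]))
              else integer()
        total <- n * cloneLenBp - sum(ov)
        comp <- paste(sample(c("A", "C", "G", "T"), total, TRUE),
                      collapse = "")
        startAt <- cumsum(c(1, rep(cloneLenBp, max(0, n - 1L)) - ov))
        nm <- character(n)
        for (j in seq_len(n)) {
            k <- k + 1L
            nm[j] <- sprintf("bMQ_%03d", k)
            s <- substr(comp, startAt[j], startAt[j] + cloneLenBp - 1L)
            if (j %% 2L == 0L)
                s <- as.character(reverseComplement(DNAString(s)))
            clones[[nm[j]]] <- s
        }
        truth[[ci]] <- nm
    }
    list(clones = DNAStringSet(unlist(clones)), truth = truth)
}

#' Simulate a two-group ERV count matrix
#'
#' Negative-binomial counts per locus and sample; group-B means equal
#' group-A means times the subclass fold change. Baseline means are
#' log-normal around \code{baseMean}; per-sample library sizes are set to
#' \code{librarySize} (jittered), standing in for the transcriptome-wide
#' total of which the ERV loci are a small part. Defaults reproduce the
#' study conditions: ~50 MLV loci, three mice per group, and 14.5x / 5.3x
#' upregulation of the pMLV and xMLV subclasses.
#'
#' @param nLociPerClass named integer vector, loci per subclass.
#' @param foldChanges named numeric vector, group-B/group-A fold per
#'   subclass (> 0).
#' @param nPerGroup samples per group (>= 2).
#' @param dispersion NB dispersion alpha (variance mu + alpha mu^2).
#' @param seed integer seed.
#' @param baseMean median baseline count.
#' @param sdlog log-normal spread of baseline means.
#' @param librarySize nominal per-sample total mapped reads.
#' @return An \linkS4class{ErvExpressionSet}; metadata records the true
#'   folds.
#' @export
simExpressionCounts <- function(nLociPerClass = c(eMLV = 6, mpMLV = 12,
                                                  pMLV = 15, xMLV = 17),
                                foldChanges = c(eMLV = 1, mpMLV = 1,
                                                pMLV = 14.5, xMLV = 5.3),
                                nPerGroup = 3, dispersion = 0.1, seed = 1,
                                baseMean = 100, sdlog = 1,
                                librarySize = 1e6) {
    stopifnot(nPerGroup >= 2, all(foldChanges > 0))
    set.seed(seed)
    subclass <- rep(names(nLociPerClass), nLociPerClass)
    m <- length(subclass)
    base <- rlnorm(m, meanlog = log(baseMean), sdlog = sdlog)
    fold <- unname(foldChanges[subclass])
    nb <- function(mu) {
        if (dispersion == 0) rpois(length(mu), mu)
        else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    counts <- matrix(0L, nrow = m, ncol = 2 * nPerGroup)
    for (j in seq_len(nPerGroup)) counts[, j] <- nb(base)
    for (j in seq_len(nPerGroup)) counts[, nPerGroup + j] <- nb(base * fold)
    rownames(counts) <- sprintf("MLV_%s_%02d", subclass,
                                stats::ave(seq_len(m), subclass,
                                           FUN = seq_along))
    colnames(counts) <- c(sprintf("A_%d", seq_len(nPerGroup)),
                          sprintf("B_%d", seq_len(nPerGroup)))
    pbs <- sample(c("Pro", "Gln1", "other"), m, TRUE,
                  prob = c(0.4, 0.4, 0.2))
    libs <- round(librarySize * runif(2 * nPerGroup, 0.9, 1.1))
    se <- ErvExpressionSet(counts, subclass,
                           group = rep(c("A", "B"), each = nPerGroup),
                           pbs = pbs, librarySize = libs)
    metadata(se)$trueFold <- foldChanges
    se
}
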
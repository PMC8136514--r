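# Generators: seed determinism, analytic expectations, Haldane behaviour.

test_that("identical seeds give byte-identical generator output", {
    cfg <- simConfig(startBp = 63e6, endBp = 63.5e6, seed = 7)
    specs <- gv1StrainPanel()[c("B6J", "B6N")]
    expect_identical(assay(simDepthProfiles(specs, cfg, "B6J"), "counts"),
                     assay(simDepthProfiles(specs, cfg, "B6J"), "counts"))
    map <- gv1MarkerMap()
    expect_identical(genotypes(simBackcross(map, 1.5, 50, seed = 3)),
                     genotypes(simBackcross(map, 1.5, 50, seed = 3)))
    expect_identical(simAcceptorSites(5), simAcceptorSites(5))
    expect_identical(simAlignmentSegments(seed = 9)$segments,
                     simAlignmentSegments(seed = 9)$segments)
    expect_identical(as.character(simBacClones(2)$clones),
                     as.character(simBacClones(2)$clones))
    expect_identical(assay(simExpressionCounts(seed = 4), "counts"),
                     assay(simExpressionCounts(seed = 4), "counts"))
})

test_that("depth counts follow the CN/2 expectation per noise model", {
    # diploid reference at meanDepth 100: every window expects 100
    cfg <- simConfig(startBp = 0, endBp = 2e7, windowBp = 1e4, seed = 11)
    specs <- list(strainSpec("ref", meanDepth = 100),
                  strainSpec("del", cnSegments = data.frame(
                      start = 0, end = 1e7, cn = 0)))
    dps <- simDepthProfiles(specs, cfg, reference = "ref")
    cts <- assay(dps, "counts")
    nw <- nrow(dps)
    se <- sqrt(100 / nw)   # Poisson MC error of the mean
    expect_lt(abs(mean(cts[, "ref"]) - 100), 3 * se)
    # CN0 windows have expectation zero: under Poisson they are exactly 0
    delWin <- metadata(dps)$cnTruth[, "del"] == 0
    expect_true(all(cts[delWin, "del"] == 0))
    expect_identical(sum(delWin), 1000L)
})

test_that("a CN4 segment yields a mean windowed ratio of 2 vs a CN2 reference", {
    # 10,000 windows inside the CN4 interval for tight MC error; deep
    # coverage so the ratio estimator's O(1/depth) bias is negligible
    cfg <- simConfig(chrom = "13", startBp = 65.47e6, endBp = 66.96e6,
                     windowBp = 149L, seed = 13)
    specs <- list(strainSpec("B6J", meanDepth = 1e4),
                  strainSpec("dup", meanDepth = 1e4,
                             cnSegments = data.frame(
                      start = 65.47e6, end = 66.96e6, cn = 4)))
    dps <- simDepthProfiles(specs, cfg, reference = "B6J")
    rps <- depthRatio(dps)
    r <- assay(rps, "ratio")[, "dup"]
    expect_identical(length(r), 10000L)
    se <- sd(r) / sqrt(length(r))
    expect_lt(abs(mean(r) - 2), 3 * se)
})

test_that("simulated meioses follow Haldane's map function", {
    # zero genetic distance: genotypes identical at both markers
    map0 <- data.frame(name = c("a", "b"), posMb = c(1, 2),
                       posCm = c(5, 5))
    bc0 <- simBackcross(map0, traitPosCm = 5, nAnimals = 300, seed = 2)
    g0 <- genotypes(bc0)
    expect_identical(g0[, "a"], g0[, "b"])
    # full penetrance with the trait at a marker: phenotype == genotype
    expect_true(all((g0[, "a"] == "H") ==
                    (phenotype(simBackcross(map0, 5, 300, penetrance = 1,
                                            seed = 2)) == 1L)))
    # 50 cM apart: recombinant fraction matches (1 - exp(-1))/2
    map50 <- data.frame(name = c("a", "b"), posMb = c(1, 2),
                        posCm = c(0, 50))
    bc <- simBackcross(map50, traitPosCm = 0, nAnimals = 10000, seed = 5)
    g <- genotypes(bc)
    rObs <- mean(g[, "a"] != g[, "b"])
    rTrue <- haldaneR(50)
    se <- sqrt(rTrue * (1 - rTrue) / 10000)
    expect_lt(abs(rObs - rTrue), 3 * se)
})

test_that("backcross generator validates its inputs", {
    map <- gv1MarkerMap()
    expect_error(simBackcross(map, 1, nAnimals = 0), "nAnimals")
    expect_error(simBackcross(map[c(3, 1, 2), ], 1, 10), "sorted")
    expect_error(simBackcross(map, 1, 10, penetrance = 0.4), "penetrance")
})

test_that("simulated acceptor panel has the promised structure", {
    sites <- simAcceptorSites(seed = 21)
    ok <- vapply(sites, function(s) passes(classifyAcceptor(s)), TRUE)
    expect_true(ok[["reference"]] && ok[["reference_minus"]])
    expect_false(any(ok[c("broken_pyrimidine", "broken_exonic",
                          "broken_pyrimidine_minus")]))
    expect_setequal(unique(vapply(sites, function(s) s@strand, "")),
                    c("+", "-"))
    # breakage sits at the defined consensus offsets
    expect_identical(
        failedPositions(classifyAcceptor(sites$broken_pyrimidine))$offset,
        -3L)
    expect_identical(
        failedPositions(classifyAcceptor(sites$broken_exonic))$offset, 0L)
})

test_that("alignment-segment generator honours dup and unique declarations", {
    sim <- simAlignmentSegments(
        dupRegions = data.frame(start = 5e4, end = 7e4),
        uniqueRegions = data.frame(start = 1.5e5, end = 1.7e5),
        seed = 3)
    mult <- referenceMultiplicity(sim$segments, windowBp = 1e4)
    dupWin <- start(mult) - 1 >= 5e4 & end(mult) <= 7e4
    expect_true(all(mcols(mult)$count[dupWin] >= 2))
    uniq <- queryUniqueRegions(sim$segments, sim$queryLengths)
    hit <- IRanges::overlapsAny(IRanges(1.5e5 + 1, 1.7e5), ranges(uniq))
    expect_true(hit)
    expect_error(simAlignmentSegments(
        dupRegions = data.frame(start = c(1e4, 1.5e4),
                                end = c(2e4, 2.5e4))),
        "contradictory")
})

test_that("expression generator recovers its planted folds", {
    # fold 1 everywhere: per-locus log2FC centred on zero
    se0 <- simExpressionCounts(
        nLociPerClass = c(pMLV = 60), foldChanges = c(pMLV = 1),
        nPerGroup = 10, dispersion = 0.05, seed = 6)
    de0 <- deTest(se0, seed = 6)
    expect_lt(abs(mean(de0$log2FC)),
              3 * sd(de0$log2FC) / sqrt(nrow(de0)))
    # fold 14.5 at large n comes back within Monte-Carlo error
    se1 <- simExpressionCounts(
        nLociPerClass = c(pMLV = 50, eMLV = 50),
        foldChanges = c(pMLV = 14.5, eMLV = 1),
        nPerGroup = 20, dispersion = 0.05, seed = 8)
    de1 <- deTest(se1, seed = 8)
    folds <- 2^de1$log2FC[de1$subclass == "pMLV"]
    se <- sd(folds) / sqrt(length(folds))
    expect_lt(abs(mean(folds) - 14.5), 3 * se)
})
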
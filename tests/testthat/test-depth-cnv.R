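# Depth ratios, segmentation, interval spans, MAE distances, clustering.

test_that("depth ratio is 1 for the reference against itself and ~0 in deletions", {
    dps <- noiselessProfiles(list(ref = rep(2, 50),
                                  del = c(rep(2, 20), rep(0, 10),
                                          rep(2, 20))))
    rps <- depthRatio(dps, pseudocount = 0.5)
    r <- assay(rps, "ratio")
    expect_equal(unname(r[, "ref"]), rep(1, 50))
    expect_true(all(r[21:30, "del"] < 0.02))
    expect_identical(referenceStrain(rps), "ref")
})

test_that("mismatching window grids are rejected with the first offender", {
    a <- noiselessProfiles(list(ref = rep(2, 10), s = rep(2, 10)))
    b <- noiselessProfiles(list(other = rep(2, 10)), startBp = 63e6 + 5e3)
    expect_error(depthRatio(a, reference = b), "#1")
})

test_that("segmentation recovers engineered CNV blocks and spans", {
    # an 81-window CN0 block at 10 kb windows: one call spanning 810 kb
    cn <- rep(2, 400); cn[80:160] <- 0
    dps <- noiselessProfiles(list(ref = rep(2, 400), del = cn))
    calls <- segmentRatio(depthRatio(dps))
    calls <- calls[mcols(calls)$strain == "del"]
    expect_identical(length(calls), 1L)
    expect_identical(mcols(calls)$state, "0")
    expect_equal(mcols(calls)$spanKb, 810)
    trueStart <- 63e6 + 79 * 1e4; trueEnd <- 63e6 + 160 * 1e4
    expect_lte(abs(start(calls) - 1 - trueStart), 1e4)
    expect_lte(abs(end(calls) - trueEnd), 1e4)
    # flat diploid profile: no calls
    expect_identical(length(segmentRatio(depthRatio(noiselessProfiles(
        list(ref = rep(2, 50), flat = rep(2, 50)))))), 0L)
})

test_that("abutting CN1 and CN0 blocks give two calls sharing a boundary", {
    cn <- rep(2, 200); cn[50:89] <- 1; cn[90:139] <- 0
    dps <- noiselessProfiles(list(ref = rep(2, 200), s = cn))
    calls <- segmentRatio(depthRatio(dps))
    calls <- calls[mcols(calls)$strain == "s"]
    expect_identical(length(calls), 2L)
    expect_setequal(mcols(calls)$state, c("0", "1"))
    boundary <- 63e6 + 89 * 1e4
    c1 <- calls[mcols(calls)$state == "1"]
    c0 <- calls[mcols(calls)$state == "0"]
    expect_lte(abs(end(c1) - boundary), 1e4)
    expect_lte(abs(start(c0) - 1 - boundary), 1e4)
})

test_that("noise-free boundary error never exceeds half the filter width", {
    set.seed(31)
    for (i in 1:10) {
        n <- 200
        b1 <- sample(20:100, 1); len <- sample(10:60, 1)
        cn <- rep(2, n); cn[b1:(b1 + len - 1)] <- 0
        k <- sample(c(3, 5, 7), 1)
        dps <- noiselessProfiles(list(ref = rep(2, n), s = cn))
        calls <- segmentRatio(depthRatio(dps), smoothWindows = k,
                              minSpanWindows = 3)
        calls <- calls[mcols(calls)$strain == "s"]
        expect_identical(length(calls), 1L)
        tol <- ceiling(k / 2) * 1e4
        expect_lte(abs(start(calls) - 1 - (63e6 + (b1 - 1) * 1e4)), tol)
        expect_lte(abs(end(calls) - (63e6 + (b1 + len - 1) * 1e4)), tol)
    }
})

test_that("interval spans reproduce the three printed CNV intervals", {
    expect_equal(intervalSpan(65.79e6, 66.60e6, "kb"), 810)
    expect_equal(intervalSpan(65.47e6, 66.96e6, "Mb"), 1.49)
    expect_equal(intervalSpan(65.45e6, 66.60e6, "Mb"), 1.15)
    expect_error(intervalSpan(10, 10), "interval")
    expect_error(intervalSpan(20, 10), "interval")
})

test_that("the MAE distance is the literal median of absolute differences", {
    dps <- noiselessProfiles(list(ref = rep(2, 100), s = rep(2, 100)))
    rps <- depthRatio(dps)
    expect_identical(maeDistance(rps, "ref", "s"), 0)
    # constant offset comes back exactly
    expect_equal(maeDistance(rep(1, 40), rep(1.3, 40)), 0.3)
    # brute-force sort-and-middle oracle on random profiles
    set.seed(37)
    a <- runif(1001, 0, 3); b <- runif(1001, 0, 3)
    d <- sort(abs(a - b))
    expect_identical(maeDistance(a, b), d[(length(d) + 1) / 2])
    # the mean variant is the conventional MAE
    expect_equal(maeDistance(a, b, fun = "mean"), mean(abs(a - b)))
    expect_error(maeDistance(a, b[-1]), "length")
})

test_that("MAE matrix is symmetric with zero diagonal and clusters lineages", {
    cfg <- simConfig(seed = 41)
    rps <- depthRatio(simDepthProfiles(gv1StrainPanel(), cfg, "B6J"))
    d <- maeDistanceMatrix(rps)
    expect_true(isSymmetric(unname(d)))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
    cl <- clusterStrains(d, k = 2)
    lin <- setNames(colData(rps)$lineage, strainNames(rps))
    expect_identical(length(unique(cl$groups[lin == "C57"])), 1L)
    expect_identical(length(unique(cl$groups[lin == "nonC57"])), 1L)
    expect_false(cl$groups[["B6J"]] == cl$groups[["ZALENDE"]])
})

test_that("clustering is invariant to strain input order", {
    cfg <- simConfig(seed = 43)
    rps <- depthRatio(simDepthProfiles(gv1StrainPanel(), cfg, "B6J"))
    d <- maeDistanceMatrix(rps)
    perm <- c(5, 3, 9, 1, 7, 2, 8, 4, 6)
    g1 <- clusterStrains(d, k = 2)$groups
    g2 <- clusterStrains(d[perm, perm], k = 2)$groups
    # same partition (labels may swap)
    same1 <- outer(g1, g1, "==")
    same2 <- outer(g2, g2, "==")[names(g1), names(g1)]
    expect_identical(same1, same2)
    # identical strains merge first at height zero
    dd <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3,
                 dimnames = list(letters[1:3], letters[1:3]))
    tr <- clusterStrains(dd)$tree
    expect_equal(tr$height[1], 0)
    expect_setequal(abs(tr$merge[1, ]), c(1, 2))
})

test_that("invalid distance matrices are rejected", {
    m <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"),
                                                  c("a", "b")))
    expect_error(clusterStrains(m), "symmetric")
    m2 <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
    expect_error(clusterStrains(m2), "non-negative")
})
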
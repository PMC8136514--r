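# CPM normalization, permutation DE, fold summaries, PBS stratification,
# qPCR.

test_that("CPM columns sum to 1e6 without explicit library sizes", {
    set.seed(103)
    m <- matrix(rpois(200, 50), 20, 10)
    cpm <- normalizeCpm(m)
    expect_equal(unname(colSums(cpm)), rep(1e6, 10))
    expect_equal(unname(normalizeCpm(matrix(7, 1, 1))[1, 1]), 1e6)
    expect_error(normalizeCpm(matrix(0, 2, 2)), "positive")
    # explicit library sizes take precedence
    expect_equal(unname(normalizeCpm(matrix(10, 1, 1),
                                     librarySize = 1e6)[1, 1]), 10)
})

test_that("identical groups give zero log2FC and no regulation", {
    cts <- matrix(rep(c(5L, 50L, 500L), 6), nrow = 3, byrow = FALSE,
                  dimnames = list(c("l1", "l2", "l3"), NULL))
    se <- ErvExpressionSet(cts, subclass = c("pMLV", "xMLV", "eMLV"),
                           group = rep(c("A", "B"), each = 3))
    de <- deTest(se, seed = 1)
    expect_equal(de$log2FC, rep(0, 3))
    expect_false(any(de$regulated))
})

test_that("3 vs 3 designs are enumerated exhaustively with a p floor of 1/20", {
    se <- simExpressionCounts(nLociPerClass = c(pMLV = 30),
                              foldChanges = c(pMLV = 8),
                              nPerGroup = 3, dispersion = 0.05, seed = 5)
    de <- deTest(se, seed = 5)
    expect_true(metadata(de)$exhaustive)
    expect_identical(metadata(de)$nRelabelings, 20L)
    expect_gte(min(de$p), 1 / 20)
    # BH q-values consequently never reach the q < 0.01 rule at this n
    expect_gte(min(de$q), 1 / 20)
    expect_false(any(de$regulated))
    # the planted signal still tops the ranking
    expect_true(all(de$log2FC > 1))
})

test_that("strong fold changes are flagged once the design allows q < 0.01", {
    # two-sided exhaustive p-values have a floor of 2/choose(2n, n)
    # (every relabeling and its complement tie on |log2FC|): at 6 vs 6
    # that is 2/924, so ten signal loci among twenty can reach q < 0.01
    flagged <- vapply(1:10, function(seed) {
        se <- simExpressionCounts(
            nLociPerClass = c(pMLV = 10, eMLV = 10),
            foldChanges = c(pMLV = 8, eMLV = 1),
            nPerGroup = 6, dispersion = 0.05, seed = 200 + seed)
        de <- deTest(se, seed = seed)
        mean(de$regulated[de$subclass == "pMLV"])
    }, 0)
    expect_gte(mean(flagged), 0.9)
})

test_that("permutation p-values are super-uniform under the null", {
    se <- simExpressionCounts(nLociPerClass = c(xMLV = 1000),
                              foldChanges = c(xMLV = 1),
                              nPerGroup = 5, dispersion = 0.1, seed = 7)
    de <- deTest(se, seed = 7)
    for (alpha in c(0.05, 0.1, 0.25)) {
        emp <- mean(de$p <= alpha)
        expect_lte(emp, alpha + 3 * sqrt(alpha * (1 - alpha) / 1000))
    }
})

test_that("subclass fold summaries average linear folds as documented", {
    r <- DataFrame(locus = c("a", "b", "c"),
                   subclass = c("pMLV", "pMLV", "xMLV"),
                   pbs = "Pro", log2FC = c(1, 2, 0),
                   p = 0.5, q = 0.5,
                   regulated = c(TRUE, FALSE, FALSE))
    out <- subclassFoldSummary(r)
    expect_equal(out[["pMLV"]], 3)           # mean of 2 and 4
    expect_equal(out[["xMLV"]], 1)
    expect_equal(subclassFoldSummary(r, geometric = TRUE)[["pMLV"]],
                 sqrt(8))
    expect_warning(sig <- subclassFoldSummary(r, significantOnly = TRUE),
                   "xMLV")
    expect_equal(sig[["pMLV"]], 2)
})

test_that("PBS stratification calibrates under the null and detects shifts", {
    set.seed(107)
    nullSig <- vapply(1:20, function(i) {
        r <- DataFrame(locus = sprintf("l%d", 1:40),
                       subclass = "pMLV",
                       pbs = rep(c("Pro", "Gln1"), 20),
                       log2FC = rnorm(40), p = 0.5, q = 0.5,
                       regulated = FALSE)
        pbsStratification(r)$stratified
    }, TRUE)
    expect_lte(mean(nullSig), 0.15)
    shiftSig <- vapply(1:20, function(i) {
        lfc <- rnorm(40)
        pbs <- rep(c("Pro", "Gln1"), each = 20)
        lfc[pbs == "Gln1"] <- lfc[pbs == "Gln1"] + 2   # a 4-fold shift
        r <- DataFrame(locus = sprintf("l%d", 1:40), subclass = "pMLV",
                       pbs = pbs, log2FC = lfc, p = 0.5, q = 0.5,
                       regulated = FALSE)
        pbsStratification(r)$stratified
    }, TRUE)
    expect_gte(mean(shiftSig), 0.9)
    r1 <- DataFrame(locus = "x", subclass = "pMLV", pbs = "Pro",
                    log2FC = 0, p = 1, q = 1, regulated = FALSE)
    expect_error(pbsStratification(r1), "PBS classes")
})

test_that("qPCR relative expression implements 2^-dCt with a 40-cycle cap", {
    expect_equal(qpcrRelative(20, 20)$relExpression, 1)
    out <- qpcrRelative(23, 20)
    expect_identical(out$relExpression, 0.125)
    expect_false(out$absent)
    capped <- qpcrRelative(40, 20)
    expect_identical(capped$relExpression, 0)
    expect_true(capped$absent)
    # vectorized
    v <- qpcrRelative(c(20, 25, 41), c(20, 20, 20))
    expect_equal(v$relExpression, c(1, 2^-5, 0))
    expect_identical(v$absent, c(FALSE, FALSE, TRUE))
})
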
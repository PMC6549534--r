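test_that("stage log2 fold change matches hand arithmetic", {
    mat <- rbind(g1 = c(1, 3, 5, 7), g2 = c(2, 2, 8, 4))
    se <- makeTestSE(mat, arm = c("control", "control", "disease",
                                  "disease"),
                     stage = rep("6wk", 4))
    expect_equal(stageLog2FC(se, "6wk"), c(g1 = 4, g2 = 4))
    ## identical arms -> 0
    se0 <- makeTestSE(cbind(mat, mat),
                      arm = rep(c("control", "disease"), each = 4),
                      stage = rep("6wk", 8))
    expect_equal(unname(stageLog2FC(se0, "6wk")), c(0, 0))
    expect_error(stageLog2FC(se, "12wk"), "not present")
})

test_that("deTest agrees with the t.test oracle and handles degeneracy", {
    set.seed(101)
    mat <- matrix(rnorm(40), nrow = 5)
    se <- makeTestSE(mat, arm = rep(c("control", "disease"), each = 4),
                     stage = rep("6wk", 8))
    p <- deTest(se, "6wk")
    for (i in 1:5) {
        want <- t.test(mat[i, 5:8], mat[i, 1:4], var.equal = TRUE)$p.value
        expect_equal(unname(p[i]), want)
    }
    pw <- deTest(se, "6wk", varEqual = FALSE)
    want <- t.test(mat[1, 5:8], mat[1, 1:4])$p.value
    expect_equal(unname(pw[1]), want)
    ## identical arms, zero variance -> p = 1; shifted constant -> p = 0
    cmat <- rbind(g1 = rep(5, 8), g2 = c(rep(1, 4), rep(3, 4)))
    se2 <- makeTestSE(cmat, arm = rep(c("control", "disease"), each = 4),
                      stage = rep("6wk", 8))
    expect_equal(unname(deTest(se2, "6wk")), c(1, 0))
    ## large planted effect, tiny noise -> tiny p
    set.seed(5)
    big <- matrix(c(rnorm(4, 0, 0.01), rnorm(4, 5, 0.01)), nrow = 1)
    se3 <- makeTestSE(big, arm = rep(c("control", "disease"), each = 4),
                      stage = rep("6wk", 8))
    expect_lt(deTest(se3, "6wk")[[1]], 1e-6)
})

test_that("null p-values are uniform (KS property)", {
    cfg <- nullConfig(seed = 7, nGenes = 1000)
    se <- generateExpression(cfg)
    p <- deTest(se, "6wk")
    expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment reproduces the step-up worked examples", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))   # fixed point
    expect_equal(bhAdjust(0.03), 0.03)                 # singleton
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    ## never decreases any p-value; permutation-invariant up to reordering
    set.seed(3)
    p <- runif(50)
    expect_true(all(bhAdjust(p) >= p))
    perm <- sample(50)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("DEG selection applies inclusive fold and strict p cutoffs", {
    lfc <- c(a = 1.0, b = 3, c = 0.99, d = -2)
    adj <- c(a = 0.01, b = 0.05, c = 0.001, d = 0.049)
    out <- selectDegs(lfc, adj)
    expect_equal(out$direction, c("up", "none", "none", "down"))
    ## monotone in both thresholds: stricter settings give a subset
    sel <- function(...) out <- selectDegs(lfc, adj, ...)$direction != "none"
    expect_true(all(sel(fcThreshold = 4) <= sel()))
    expect_true(all(sel(alpha = 0.01) <= sel()))
})

test_that("common-trend selection requires consistent direction", {
    degs <- list(
        s1 = data.frame(gene = c("a", "b", "c"),
                        direction = c("up", "up", "down")),
        s2 = data.frame(gene = c("a", "b", "c"),
                        direction = c("up", "up", "down")),
        s3 = data.frame(gene = c("a", "b", "c"),
                        direction = c("up", "down", "none")))
    got <- commonTrendGenes(degs)
    expect_equal(got$gene, "a")          # b flips, c loses significance
    expect_equal(got$direction, "up")
    expect_true(all(got$gene %in% degs$s1$gene))
    expect_error(commonTrendGenes(degs[1]), "two stages")
})

test_that("uniquely-final DEGs exclude genes selected at earlier stages", {
    degs <- list(
        s1 = data.frame(gene = c("a", "b"), direction = c("up", "none")),
        s2 = data.frame(gene = c("a", "b"), direction = c("none", "none")),
        s3 = data.frame(gene = c("a", "b"), direction = c("up", "down")))
    got <- uniqueStageDegs(degs, "s3")
    expect_equal(got$gene, "b")
})

test_that("stage trend statistics behave at the boundaries", {
    ## identical groups: F = 0, p = 1, slope = 0
    v <- rep(c(1, 2, 3, 4), 3)
    s <- rep(c("6wk", "12wk", "20wk"), each = 4)
    out <- stageTrendStats(v, factor(s, levels = c("6wk", "12wk", "20wk")))
    expect_equal(out$anova_p, 1)
    expect_equal(out$slope, 0)
    ## strictly monotone means, tiny noise: correct slope sign, tiny p
    set.seed(21)
    v2 <- rep(c(1, 2, 3), each = 4) + rnorm(12, 0, 0.01)
    out2 <- stageTrendStats(v2, factor(rep(c("a", "b", "c"), each = 4)))
    expect_gt(out2$slope, 0)
    expect_lt(out2$slope_p, 0.01)
    expect_equal(nrow(out2$tukey), 3)  # three pairwise comparisons
    ## two groups: ANOVA p equals the pooled t-test p (F = t^2)
    set.seed(22)
    v3 <- rnorm(10); g3 <- factor(rep(c("a", "b"), each = 5))
    out3 <- stageTrendStats(v3, g3)
    want <- t.test(v3[g3 == "a"], v3[g3 == "b"],
                   var.equal = TRUE)$p.value
    expect_equal(out3$anova_p, want)
    expect_error(stageTrendStats(v3, factor(rep("a", 10))), "two stages")
})

test_that("ddCt fold change reproduces the closed form", {
    cal <- data.frame(target_ct = 27, reference_ct = 20)
    smp <- data.frame(target_ct = 25, reference_ct = 20)
    expect_equal(ddctFoldChange(cal, smp), 4)       # ddCt = -2
    expect_equal(ddctFoldChange(cal, cal), 1)       # ddCt = 0
    expect_error(ddctFoldChange(cal, data.frame(target_ct = Inf,
                                                reference_ct = 20)),
                 "finite")
    expect_error(ddctFoldChange(cal[0, ], smp), "non-empty")
})
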
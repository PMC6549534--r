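test_that("configuration invariants are enforced", {
    expect_error(GeneratorConfig(driverMethControl = 0.1), ">= 0.20")
    expect_error(GeneratorConfig(promoterLength = 500,
                                 cgiPromoterFraction = 0.5), "600")
    expect_error(GeneratorConfig(nGenes = 10, nDrivers = 6, nPassengers = 6,
                                 cgiPromoterFraction = 1), "sum")
    expect_error(GeneratorConfig(nGenes = 100, nDrivers = 10,
                                 cgiPromoterFraction = 0.05),
                 "cgiPromoterFraction")
    expect_error(GeneratorConfig(driverExprLog2FC = c(3, 2, 1)),
                 "non-decreasing")
    expect_error(GeneratorConfig(h3k4Log2FC = c(0.5, 1, 2)),
                 "non-increasing")
    expect_s4_class(GeneratorConfig(), "GeneratorConfig")
})

test_that("truth table matches configured role counts and CGI rules", {
    cfg <- smallConfig(seed = 3)
    tr <- generateTruth(cfg)
    expect_equal(nrow(tr), 60)
    expect_false(anyDuplicated(tr$gene_id) > 0)
    expect_equal(as.vector(table(tr$role)[c("driver", "passenger",
                                            "late_dm")]), c(3, 4, 4))
    expect_true(all(tr$cgi_present[tr$role == "driver"]))
    expect_equal(sum(tr$cgi_present), round(0.5 * 60))
    methCols <- grep("^meth_", colnames(tr), value = TRUE)
    expect_true(all(as.matrix(tr[methCols]) >= 0 &
                    as.matrix(tr[methCols]) <= 1))
})

test_that("generation is byte-deterministic for a fixed seed", {
    cfg <- smallConfig(seed = 11)
    a <- generateSynthData(cfg)
    b <- generateSynthData(cfg)
    f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
    writePromotersFasta(promoterSet(a), f1)
    writePromotersFasta(promoterSet(b), f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(SummarizedExperiment::assay(exprData(a)),
                     SummarizedExperiment::assay(exprData(b)))
    expect_identical(SummarizedExperiment::assay(methData(a), "bound"),
                     SummarizedExperiment::assay(methData(b), "bound"))
    expect_identical(qpcrData(a), qpcrData(b))
    ## substream independence: skipping other tables leaves one unchanged
    onlyExpr <- generateSynthData(cfg, what = "expression")
    expect_identical(SummarizedExperiment::assay(exprData(onlyExpr)),
                     SummarizedExperiment::assay(exprData(a)))
})

test_that("promoter CGI flags agree with the scanner", {
    cfg <- GeneratorConfig(nGenes = 50, nDrivers = 0, nPassengers = 0,
                           nLateDM = 0, cgiPromoterFraction = 0.5,
                           seed = 1)
    tr <- generateTruth(cfg)
    expect_equal(sum(tr$cgi_present), 25)
    proms <- generatePromoters(cfg, tr)
    flags <- annotateCgiGenes(proms)
    expect_equal(unname(flags[tr$gene_id]), tr$cgi_present)
})

test_that("no islands are planted when the CGI fraction is zero", {
    cfg <- GeneratorConfig(nGenes = 12, nDrivers = 0, nPassengers = 0,
                           nLateDM = 0, cgiPromoterFraction = 0,
                           promoterLength = 1200, seed = 5)
    proms <- generatePromoters(cfg)
    expect_false(any(annotateCgiGenes(proms)))
})

test_that("expression table has the right shape and planted effects", {
    cfg <- noiselessConfig(seed = 2, driverExprLog2FC = c(1.5, 2.5, 3.5))
    tr <- generateTruth(cfg)
    se <- generateExpression(cfg, tr)
    expect_equal(dim(se), c(200L, 24L))  # 2 arms x 3 stages x 4 reps
    drivers <- tr$gene_id[tr$role == "driver"]
    lfc <- vapply(c("6wk", "12wk", "20wk"), function(s)
        stageLog2FC(se, s)[drivers[1]], numeric(1))
    expect_equal(unname(lfc), c(1.5, 2.5, 3.5))
    nulls <- tr$gene_id[tr$role == "null"]
    expect_equal(unname(stageLog2FC(se, "6wk")[nulls]),
                 rep(0, length(nulls)))
})

test_that("zero-noise methylation fractions equal the planted decreases", {
    cfg <- noiselessConfig(seed = 4)
    tr <- generateTruth(cfg)
    se <- generateMethylation(cfg, tr)
    pct <- percentMethylation(se)
    d <- tr$gene_id[tr$role == "driver"][1]
    expect_equal(unname(pct[d, "control_6wk_1"]), 60)
    expect_equal(unname(pct[d, c("disease_6wk_1", "disease_12wk_1",
                                 "disease_20wk_1")]),
                 c(46.2, 41.4, 33.0))
    late <- tr$gene_id[tr$role == "late_dm"][1]
    expect_equal(unname(pct[late, c("disease_6wk_1", "disease_20wk_1")]),
                 c(30, 55))
})

test_that("noisy methylation fractions stay in [0, 1]", {
    cfg <- GeneratorConfig(methConcentration = 5, lateDMDelta = 0.9,
                           seed = 8)
    tr <- generateTruth(cfg)
    expect_true(any(tr$clipped))  # 0.30 + 0.90 had to be clipped
    frac <- SummarizedExperiment::assay(generateMethylation(cfg, tr),
                                        "bound") / 100
    expect_true(all(frac >= 0 & frac <= 1))
})

test_that("null methylation shows no systematic arm difference", {
    cfg <- nullConfig(seed = 12, nGenes = 500)
    se <- generateMethylation(cfg)
    pct <- percentMethylation(se)
    cd <- SummarizedExperiment::colData(se)
    for (s in levels(cd$stage)) {
        dis <- cd$arm == "disease" & cd$stage == s
        ctl <- cd$arm == "control" & cd$stage == s
        diff <- rowMeans(pct[, dis]) - rowMeans(pct[, ctl])
        expect_lt(abs(mean(diff)), 0.5)  # percentage points
    }
})

test_that("zero-noise H3K4me3 enrichment equals the planted profile", {
    cfg <- noiselessConfig(seed = 6)
    tr <- generateTruth(cfg)
    se <- generateH3K4me3(cfg, tr)
    d <- tr$gene_id[tr$role == "driver"][1]
    folds <- vapply(c("6wk", "12wk", "20wk"), function(s)
        2^h3k4FoldEnrichment(se, s)[[d]], numeric(1))
    expect_equal(unname(folds), c(4, 2, 2^0.5), tolerance = 1e-12)
})

test_that("null H3K4me3 rarely crosses the twofold filter at sd 0.2", {
    cfg <- nullConfig(seed = 13, nGenes = 1000, h3k4NoiseSD = 0.2)
    se <- generateH3K4me3(cfg)
    enr <- h3k4FoldEnrichment(se, "6wk")
    ## normal-tail oracle: se(mean diff) = 0.2 * sqrt(2/4), so
    ## P(|enr| >= 1) = 2 * pnorm(-1 / 0.1414) ~ 1.5e-12
    expect_lt(length(h3k4Filter(enr)) / 1000, 0.05)
})

test_that("qPCR Ct tables recover planted fold changes", {
    cfg <- noiselessConfig(seed = 9, driverExprLog2FC = c(1.5, 2.5, 3.5))
    ct <- generateQpcr(cfg)
    fc <- qpcrFoldChanges(ct)
    expect_equal(fc$fold_change, 2^c(1.5, 2.5, 3.5))
    ## planted fold 1 (null gene) -> ddCt 0, fold 1
    tr <- generateTruth(cfg)
    ctNull <- generateQpcr(cfg, tr,
                           gene = tr$gene_id[tr$role == "null"][1])
    expect_equal(qpcrFoldChanges(ctNull)$fold_change, c(1, 1, 1))
})

test_that("noisy ddCt recovery is unbiased within 5 percent", {
    folds <- vapply(1:60, function(s) {
        cfg <- GeneratorConfig(nGenes = 10, nDrivers = 1, nPassengers = 0,
                               nLateDM = 0, driverExprLog2FC = c(2, 2, 2),
                               cgiPromoterFraction = 0.1,
                               qpcrNoiseSD = 0.1, seed = s)
        qpcrFoldChanges(generateQpcr(cfg))$fold_change[1]
    }, numeric(1))
    expect_lt(abs(mean(folds) - 4) / 4, 0.05)
})
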
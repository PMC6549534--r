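test_that("H3K4me3 enrichment matches hand arithmetic", {
    input <- matrix(100, 1, 8)
    chip <- matrix(100 * 2^c(0, 0, 0, 0, 2, 2, 2, 2), 1)
    se <- makeTestSE(chip, arm = rep(c("control", "disease"), each = 4),
                     stage = rep("6wk", 8), assayNames = "chip",
                     extra = list(input = input))
    expect_equal(unname(h3k4FoldEnrichment(se, "6wk")), 2)
    ## identical arms -> 0
    se0 <- makeTestSE(matrix(100, 1, 8),
                      arm = rep(c("control", "disease"), each = 4),
                      stage = rep("6wk", 8), assayNames = "chip",
                      extra = list(input = input))
    expect_equal(unname(h3k4FoldEnrichment(se0, "6wk")), 0)
})

test_that("twofold H3K4me3 filter is inclusive at log2 = 1", {
    enr <- c(a = 1.0, b = 0.9, c = -1.2, d = 0)
    expect_setequal(h3k4Filter(enr), c("a", "c"))
})

test_that("the planted H3K4me3 profile declines across stages", {
    cfg <- GeneratorConfig(seed = 17)
    se <- generateH3K4me3(cfg)
    counts <- vapply(c("6wk", "12wk", "20wk"), function(s)
        length(h3k4Filter(h3k4FoldEnrichment(se, s))), integer(1))
    expect_true(all(diff(counts) < 0))
})

test_that("correlations match perfect and oracle cases", {
    expr <- makeTestSE(rbind(g1 = c(0, 0, 0, 1, 2, 3)),
                       arm = rep(c("control", "disease"), each = 3),
                       stage = rep(c("6wk", "12wk", "20wk"), 2))
    anti <- makeMethSE(rbind(g1 = c(5, 5, 5, 6, 4, 2)),
                       arm = rep(c("control", "disease"), each = 3),
                       stage = rep(c("6wk", "12wk", "20wk"), 2))
    out <- exprOmicsCorrelation(expr, anti, axis = "methylation")
    expect_equal(out$r, -1)
    expect_equal(out$n, 3)
    same <- makeMethSE(rbind(g1 = c(5, 5, 5, 1, 2, 3)),
                       arm = rep(c("control", "disease"), each = 3),
                       stage = rep(c("6wk", "12wk", "20wk"), 2))
    expect_equal(exprOmicsCorrelation(expr, same,
                                      axis = "methylation")$r, 1)
    ## random data against the cor.test oracle (pooled disease samples)
    set.seed(41)
    cfg <- smallConfig(seed = 41)
    tr <- generateTruth(cfg)
    e <- generateExpression(cfg, tr)
    m <- generateMethylation(cfg, tr)
    got <- exprOmicsCorrelation(e, m, axis = "methylation")
    dis <- grep("^disease", colnames(e), value = TRUE)
    for (g in tr$gene_id[c(1, 20, 60)]) {
        want <- cor.test(
            SummarizedExperiment::assay(e, "log2expr")[g, dis],
            percentMethylation(m)[g, dis])
        row <- got[got$gene == g, ]
        expect_equal(row$r, unname(want$estimate))
        expect_equal(row$p, want$p.value)
    }
})

test_that("zero-noise drivers are strongly anticorrelated", {
    ## planted profiles are monotone (expression up as methylation down)
    ## but not affine, so r approaches but does not reach -1
    cfg <- noiselessConfig(seed = 19)
    tr <- generateTruth(cfg)
    e <- generateExpression(cfg, tr)
    m <- generateMethylation(cfg, tr)
    got <- exprOmicsCorrelation(e, m, axis = "methylation",
                                genes = tr$gene_id[tr$role == "driver"])
    expect_true(all(got$r < -0.95))
    expect_true(all(got$p < 0.001))
})

test_that("per-stage correlation mode returns one row per stage", {
    cfg <- smallConfig(seed = 23)
    tr <- generateTruth(cfg)
    e <- generateExpression(cfg, tr)
    m <- generateMethylation(cfg, tr)
    got <- exprOmicsCorrelation(e, m, axis = "methylation",
                                mode = "per-stage", genes = tr$gene_id[1])
    expect_equal(nrow(got), 3)
    expect_equal(unique(got$n), 4)
})

test_that("concordance classification covers all direction pairs", {
    expect_equal(classifyConcordance("up", "hypo"),
                 "hypomethylated_overexpressed")
    expect_equal(classifyConcordance("down", "hyper"),
                 "hypermethylated_downregulated")
    expect_equal(classifyConcordance("up", "hyper"), "discordant")
    expect_equal(classifyConcordance("down", "hypo"), "discordant")
    expect_error(classifyConcordance("none", "hypo"))
})

## Hand-built inputs for the common cascade: five genes, each designed
## to fail at exactly one downstream filter (or none).
.commonFixture <- function() {
    genes <- c("pass", "noCgi", "low20", "noDm", "noCor")
    deg <- data.frame(gene = genes, direction = "up")
    cgi <- setNames(c(TRUE, FALSE, TRUE, TRUE, TRUE), genes)
    ctl <- setdiff(genes, "low20")
    dm <- lapply(c("6wk", "12wk", "20wk"), function(s)
        data.frame(gene = genes,
                   p = ifelse(genes == "noDm", 0.9, 0.001),
                   direction = "hypo"))
    names(dm) <- c("6wk", "12wk", "20wk")
    cor <- data.frame(gene = genes,
                      r = ifelse(genes == "noCor", 0.8, -0.9),
                      p = 0.001)
    list(deg = deg, cgi = cgi, ctl = ctl, dm = dm, cor = cor)
}

test_that("common cascade eliminates genes at the designed filters", {
    f <- .commonFixture()
    rep <- commonGeneCascade(f$deg, f$cgi, f$ctl, f$dm, f$cor)
    expect_equal(cascadeSurvivors(rep), "pass")
    tab <- cascadeTable(rep)
    expect_equal(tab$class[tab$gene == "pass"],
                 "hypomethylated_overexpressed")
    ## the boolean trail is monotone: NA after the first failure
    noCgi <- tab[tab$gene == "noCgi", ]
    expect_false(noCgi$cgi_present)
    expect_true(is.na(noCgi$control_meth_ge_20))
    ## funnel counts are non-increasing
    expect_true(all(diff(filterCounts(rep)) <= 0))
    ## empty DEG input: everything is not_candidate
    repEmpty <- commonGeneCascade(f$deg[0, ], f$cgi, f$ctl, f$dm, f$cor)
    expect_length(cascadeSurvivors(repEmpty), 0)
    expect_true(all(cascadeTable(repEmpty)$class == "not_candidate"))
    ## universe mismatch is an error naming the offender
    expect_error(commonGeneCascade(f$deg, f$cgi, f$ctl,
        lapply(f$dm, function(d) d[d$gene != "noCor", ]), f$cor),
        "noCor")
})

test_that("dm_required_stages honours the any-stage relaxation", {
    f <- .commonFixture()
    f$dm[["6wk"]]$p[f$dm[["6wk"]]$gene == "pass"] <- 0.9
    strict <- commonGeneCascade(f$deg, f$cgi, f$ctl, f$dm, f$cor)
    relaxed <- commonGeneCascade(f$deg, f$cgi, f$ctl, f$dm, f$cor,
                                 dmScope = "any")
    expect_false("pass" %in% cascadeSurvivors(strict))
    expect_true("pass" %in% cascadeSurvivors(relaxed))
})

## Hand-built inputs for the final-stage cascade: four genes covering
## each elimination point plus one survivor.
.hccFixture <- function() {
    genes <- c("surv", "noDe", "noCall", "concord", "low20")
    de <- data.frame(gene = setdiff(genes, "noDe"),
                     direction = c("down", "down", "up", "down"))
    dm <- data.frame(gene = genes,
                     called = genes != "noCall",
                     direction = ifelse(genes == "noCall", "none",
                                        "hyper"))
    meth <- setNames(c(55, 55, 55, 55, 12), genes)
    list(de = de, dm = dm, meth = meth)
}

test_that("final-stage cascade eliminates genes at the designed filters", {
    f <- .hccFixture()
    rep <- hccUniqueCascade(f$de, f$dm, f$meth)
    expect_equal(cascadeSurvivors(rep), "surv")
    tab <- cascadeTable(rep)
    expect_equal(tab$class[tab$gene == "surv"],
                 "hypermethylated_downregulated")
    ## concordant gene (up + hyper) is excluded at the inverse filter
    expect_false(tab$inverse_relationship[tab$gene == "concord"])
    ## threshold is strict: exactly 20 percent does not pass
    f$meth["surv"] <- 20
    expect_length(cascadeSurvivors(hccUniqueCascade(f$de, f$dm, f$meth)),
                  0)
})

test_that("mirroring methylation directions swaps the two classes", {
    f <- .hccFixture()
    mirroredDe <- f$de
    mirroredDe$direction <- ifelse(f$de$direction == "up", "down", "up")
    mirroredDm <- f$dm
    mirroredDm$direction <- ifelse(f$dm$direction == "hyper", "hypo",
                                   f$dm$direction)
    a <- cascadeTable(hccUniqueCascade(f$de, f$dm, f$meth))
    b <- cascadeTable(hccUniqueCascade(mirroredDe, mirroredDm, f$meth))
    swap <- c(hypomethylated_overexpressed =
                  "hypermethylated_downregulated",
              hypermethylated_downregulated =
                  "hypomethylated_overexpressed")
    isCand <- a$class %in% names(swap)
    expect_equal(unname(swap[a$class[isCand]]), b$class[isCand])
})

test_that("synthetic recovery: each cascade finds exactly its targets", {
    cfg <- GeneratorConfig(seed = 29)
    res <- suppressMessages(runCascadePipeline(cfg, scanPromoters = FALSE))
    tr <- truthTable(res$synth)
    expect_setequal(cascadeSurvivors(res$common),
                    tr$gene_id[tr$role == "driver"])
    expect_setequal(cascadeSurvivors(res$hcc),
                    tr$gene_id[tr$role == "late_dm"])
    expect_true(all(cascadeTable(res$common)$class %in%
        c("hypomethylated_overexpressed", "not_candidate")))
    expect_true(all(cascadeTable(res$hcc)$class %in%
        c("hypermethylated_downregulated", "not_candidate")))
})
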
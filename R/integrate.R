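## Expression-methylation-H3K4me3 integration: Pearson correlation of
## per-sample expression with per-sample promoter methylation (or
## H3K4me3 enrichment), the twofold H3K4me3 filter, and the two filter
## cascades that nominate candidate genes:
##
##   common cascade   - stage-persistent differentially expressed genes
##                      -> CpG-island promoter -> control methylation
##                      >= 20% -> differentially methylated at every
##                      stage -> inverse expression-methylation
##                      correlation;
##   hcc cascade      - genes differentially expressed only at the final
##                      stage -> differential-methylation call ->
##                      inverse expression/methylation relationship ->
##                      final-stage methylation > 20% (strict).
##
## Survivors are classified by concordance of the expression and
## methylation directions.

#' Per-gene H3K4me3 log2 fold enrichment at one stage
#'
#' Mean log2(chip/input) in the disease arm minus the mean in the
#' age-matched control arm.
#'
#' @param se a SummarizedExperiment with \code{chip} and \code{input}
#'   assays and arm/stage colData.
#' @param stage stage label.
#' @return named numeric vector of log2 fold enrichments.
#' @export
h3k4FoldEnrichment <- function(se, stage) {
    chip <- SummarizedExperiment::assay(se, "chip")
    input <- SummarizedExperiment::assay(se, "input")
    if (any(input <= 0)) stop("'input' quantities must be positive")
    if (any(chip <= 0)) stop("'chip' quantities must be positive")
    l2 <- log2(chip / input)
    dis <- .armCols(se, stage, "disease")
    ctl <- .armCols(se, stage, "control")
    rowMeans(l2[, dis, drop = FALSE]) - rowMeans(l2[, ctl, drop = FALSE])
}

#' Twofold H3K4me3 enrichment filter
#'
#' Genes whose absolute log2 fold enrichment meets the threshold
#' (default 1, i.e. a twofold change in either direction, inclusive).
#'
#' @param enrichment named numeric vector of log2 fold enrichments.
#' @param thresholdLog2 absolute log2 threshold (default 1).
#' @return character vector of passing gene ids.
#' @export
h3k4Filter <- function(enrichment, thresholdLog2 = 1) {
    names(enrichment)[abs(enrichment) >= thresholdLog2]
}

## Workhorse: per-gene Pearson correlation between rows of two aligned
## matrices, vectorized, with exact t-distribution p-values.
.rowPearson <- function(x, y) {
    n <- ncol(x)
    cx <- x - rowMeans(x); cy <- y - rowMeans(y)
    sx <- sqrt(rowSums(cx^2)); sy <- sqrt(rowSums(cy^2))
    r <- rowSums(cx * cy) / (sx * sy)
    r[sx == 0 | sy == 0] <- NA_real_
    r <- pmin(1, pmax(-1, r))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), n - 2)
    data.frame(gene = rownames(x), r = unname(r), p = unname(p), n = n,
               stringsAsFactors = FALSE)
}

#' Per-gene expression-methylation (or -H3K4me3) Pearson correlation
#'
#' Pairs each disease-arm sample's log2 expression with the same
#' sample's percent promoter methylation (axis \code{"methylation"}) or
#' log2 chip/input H3K4me3 level (axis \code{"h3k4me3"}).  The default
#' \code{"pooled"} mode uses all disease samples across stages (n =
#' stages x replicates), capturing the progression trajectory;
#' \code{"per-stage"} computes one underpowered n = replicates
#' correlation per stage.
#'
#' @param exprSE expression SummarizedExperiment (assay
#'   \code{log2expr}).
#' @param otherSE methylation (bound/input) or H3K4me3 (chip/input)
#'   SummarizedExperiment sharing sample ids with \code{exprSE}.
#' @param axis which second axis \code{otherSE} carries.
#' @param mode pool disease samples across stages (default) or
#'   correlate within each stage.
#' @param genes optional subset of gene ids.
#' @return data.frame with columns \code{gene}, \code{axis}, \code{r},
#'   \code{p}, \code{n} (plus \code{stage} in per-stage mode).  Genes
#'   with zero variance on either axis have \code{NA} correlation.
#' @export
exprOmicsCorrelation <- function(exprSE, otherSE,
        axis = c("methylation", "h3k4me3"),
        mode = c("pooled", "per-stage"), genes = NULL) {
    axis <- match.arg(axis)
    mode <- match.arg(mode)
    cd <- .designOf(exprSE)
    common <- intersect(colnames(exprSE), colnames(otherSE))
    x <- SummarizedExperiment::assay(exprSE, "log2expr")[, common,
                                                         drop = FALSE]
    y <- if (axis == "methylation") percentMethylation(otherSE)
         else log2(SummarizedExperiment::assay(otherSE, "chip") /
                   SummarizedExperiment::assay(otherSE, "input"))
    y <- y[rownames(x), common, drop = FALSE]
    if (!is.null(genes)) {
        missing <- setdiff(genes, rownames(x))
        if (length(missing)) stop("unknown gene(s): ",
                                  paste(missing, collapse = ", "))
        x <- x[genes, , drop = FALSE]; y <- y[genes, , drop = FALSE]
    }
    arm <- as.character(cd[common, "arm"])
    runOne <- function(cols, stageLabel = NULL) {
        if (length(cols) < 3L)
            stop("at least 3 paired observations are required")
        out <- .rowPearson(x[, cols, drop = FALSE], y[, cols, drop = FALSE])
        out$axis <- axis
        if (!is.null(stageLabel)) out$stage <- stageLabel
        out
    }
    if (mode == "pooled")
        return(runOne(which(arm == "disease")))
    stage <- as.character(cd[common, "stage"])
    do.call(rbind, lapply(unique(stage), function(s)
        runOne(which(arm == "disease" & stage == s), s)))
}

#' Classify expression/methylation concordance
#'
#' @param exprDirection \code{"up"} or \code{"down"} expression change.
#' @param methDirection \code{"hypo"} or \code{"hyper"} methylation
#'   change.
#' @return \code{"hypomethylated_overexpressed"} for (up, hypo),
#'   \code{"hypermethylated_downregulated"} for (down, hyper), otherwise
#'   \code{"discordant"}; vectorized.
#' @examples
#' classifyConcordance("up", "hypo")
#' @export
classifyConcordance <- function(exprDirection, methDirection) {
    stopifnot(all(exprDirection %in% c("up", "down")),
              all(methDirection %in% c("hypo", "hyper")))
    ifelse(exprDirection == "up" & methDirection == "hypo",
           "hypomethylated_overexpressed",
    ifelse(exprDirection == "down" & methDirection == "hyper",
           "hypermethylated_downregulated", "discordant"))
}

## Assemble a CascadeReport from a monotone list of per-gene booleans.
## Each element of 'trail' is a named logical vector over the universe;
## a gene's later entries are masked to NA once an earlier filter fails.
.buildReport <- function(universe, trail, classes, mode) {
    passAll <- rep(TRUE, length(universe))
    cols <- list(gene = universe)
    counts <- c(universe = length(universe))
    for (nm in names(trail)) {
        v <- trail[[nm]][universe]
        v[!passAll] <- NA
        cols[[nm]] <- unname(v)
        passAll <- passAll & !is.na(v) & v
        counts[[nm]] <- sum(passAll)
    }
    cls <- rep("not_candidate", length(universe))
    cls[passAll] <- classes[universe[passAll]]
    cols$class <- cls
    new("CascadeReport", table = do.call(S4Vectors::DataFrame, cols),
        mode = mode, filters = as.character(names(trail)),
        counts = setNames(as.integer(counts), names(counts)))
}

#' Common (stage-persistent) gene cascade
#'
#' Sequential filters over one gene universe: (1) differentially
#' expressed with the same direction at every stage; (2) CpG-island-
#' positive promoter; (3) control-tissue methylation at or above the
#' threshold; (4) differentially methylated (p < \code{dmAlpha}) at
#' every stage (or any stage with \code{dmScope = "any"}); (5) inverse
#' expression-methylation correlation (r < 0, p < \code{corAlpha}).
#' Survivors are classified by \code{\link{classifyConcordance}}, the
#' methylation direction being taken from the final-stage comparison.
#'
#' @param degCommon data.frame with \code{gene} and \code{direction}
#'   from \code{\link{commonTrendGenes}}.
#' @param cgiFlags named logical vector over the gene universe (from
#'   \code{\link{annotateCgiGenes}}); its names define the universe.
#' @param controlGenes character vector from
#'   \code{\link{controlMethylationFilter}}.
#' @param dmResults named list (one element per stage) of
#'   \code{\link{dmTest}} data.frames covering the universe.
#' @param correlations data.frame with \code{gene}, \code{r}, \code{p}
#'   covering the universe (from \code{\link{exprOmicsCorrelation}},
#'   methylation axis).
#' @param dmAlpha,corAlpha p-value cutoffs (default 0.05, strict).
#' @param dmScope require differential methylation at every stage
#'   (default) or at any stage.
#' @return a \linkS4class{CascadeReport} (mode \code{"common"}).
#' @export
commonGeneCascade <- function(degCommon, cgiFlags, controlGenes,
        dmResults, correlations, dmAlpha = 0.05, corAlpha = 0.05,
        dmScope = c("all", "any")) {
    dmScope <- match.arg(dmScope)
    universe <- names(cgiFlags)
    if (is.null(universe))
        stop("'cgiFlags' must be a named logical vector")
    for (d in dmResults)
        if (!all(universe %in% d$gene))
            stop("gene universe mismatch: dmResults missing ",
                 paste(setdiff(universe, d$gene), collapse = ", "))
    if (!all(universe %in% correlations$gene))
        stop("gene universe mismatch: correlations missing ",
             paste(setdiff(universe, correlations$gene), collapse = ", "))
    exprDir <- setNames(degCommon$direction, degCommon$gene)
    dmPassMat <- matrix(vapply(dmResults, function(d)
        setNames(d$p < dmAlpha, d$gene)[universe],
        logical(length(universe))), nrow = length(universe))
    dmPass <- if (dmScope == "all") rowSums(!dmPassMat) == 0L
              else rowSums(dmPassMat) > 0L
    corOK <- with(correlations,
                  setNames(!is.na(r) & r < 0 & p < corAlpha, gene))[universe]
    trail <- list(
        de_common_trend = setNames(universe %in% degCommon$gene, universe),
        cgi_present = cgiFlags,
        control_meth_ge_20 = setNames(universe %in% controlGenes, universe),
        dm_required_stages = setNames(dmPass, universe),
        inverse_correlation = corOK)
    ## methylation direction from the final-stage comparison
    finalDM <- dmResults[[length(dmResults)]]
    methDir <- setNames(finalDM$direction, finalDM$gene)
    classes <- setNames(rep("discordant", length(universe)), universe)
    ok <- universe[universe %in% names(exprDir) &
                   methDir[universe] %in% c("hypo", "hyper")]
    classes[ok] <- classifyConcordance(exprDir[ok], methDir[ok])
    .buildReport(universe, trail, classes, "common")
}

#' Final-stage-unique (HCC) gene cascade
#'
#' Filters for genes altered only at the final disease stage: (1)
#' differentially expressed at the final stage (the supplied set,
#' typically \code{\link{uniqueStageDegs}}); (2) differential-
#' methylation call from \code{\link{dmCallMicroarray}}; (3) inverse
#' expression/methylation relationship - by default opposite signs of
#' the expression change and the methylation change (mode
#' \code{"sign"}); a pooled Pearson alternative (r < 0, p < 0.05) is
#' available via \code{correlations}; (4) final-stage disease-tissue
#' methylation strictly greater than the threshold.  Survivors are
#' classified by \code{\link{classifyConcordance}}.
#'
#' @param deFinal data.frame with \code{gene} and \code{direction}
#'   columns: the final-stage differentially expressed set.
#' @param dmCalls data.frame from \code{\link{dmCallMicroarray}}; its
#'   \code{gene} column defines the universe.
#' @param methPercent named numeric vector of mean disease-arm percent
#'   methylation at the final stage.
#' @param correlations optional data.frame (\code{gene}, \code{r},
#'   \code{p}); when supplied with \code{inverseMode = "correlation"},
#'   replaces the sign rule.
#' @param methThreshold percent threshold (default 20, strict).
#' @param inverseMode \code{"sign"} (default) or \code{"correlation"}.
#' @param corAlpha cutoff for the correlation mode.
#' @return a \linkS4class{CascadeReport} (mode \code{"hcc"}).
#' @export
hccUniqueCascade <- function(deFinal, dmCalls, methPercent,
        correlations = NULL, methThreshold = 20,
        inverseMode = c("sign", "correlation"), corAlpha = 0.05) {
    inverseMode <- match.arg(inverseMode)
    universe <- dmCalls$gene
    if (!all(universe %in% names(methPercent)))
        stop("gene universe mismatch: methPercent missing ",
             paste(setdiff(universe, names(methPercent)), collapse = ", "))
    exprDir <- setNames(deFinal$direction, deFinal$gene)
    methDir <- setNames(dmCalls$direction, dmCalls$gene)
    inDE <- setNames(universe %in% deFinal$gene &
                     exprDir[universe] %in% c("up", "down"), universe)
    called <- setNames(dmCalls$called, dmCalls$gene)
    inverse <- if (inverseMode == "correlation") {
        if (is.null(correlations))
            stop("'correlations' must be supplied for correlation mode")
        with(correlations,
             setNames(!is.na(r) & r < 0 & p < corAlpha, gene))[universe]
    } else {
        setNames((exprDir[universe] == "up" &
                  methDir[universe] == "hypo") |
                 (exprDir[universe] == "down" &
                  methDir[universe] == "hyper"), universe)
    }
    inverse[is.na(inverse)] <- FALSE
    meth20 <- setNames(methPercent[universe] > methThreshold, universe)
    trail <- list(de_final_stage = inDE, dm_called = called,
                  inverse_relationship = inverse,
                  meth_gt_threshold = meth20)
    classes <- setNames(rep("discordant", length(universe)), universe)
    ok <- universe[inDE & methDir[universe] %in% c("hypo", "hyper")]
    classes[ok] <- classifyConcordance(exprDir[ok], methDir[ok])
    .buildReport(universe, trail, classes, "hcc")
}
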
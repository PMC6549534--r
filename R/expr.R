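## Stage-wise differential expression, common-trend selection, trend
## statistics, and 2^-ddCt relative quantitation.
##
## Each disease stage is compared against its age-matched controls with
## a Student (pooled-variance) two-sample t-test on log2 values; genes
## pass the differential-expression filter when |log2FC| >= log2(2)
## (inclusive) and the Benjamini-Hochberg adjusted p-value is < 0.05
## (strict), the family being all genes tested at that stage.

.designOf <- function(se) {
    cd <- SummarizedExperiment::colData(se)
    if (!all(c("arm", "stage") %in% colnames(cd)))
        stop("colData must contain 'arm' and 'stage' columns")
    cd
}

.armCols <- function(se, stage, arm) {
    cd <- .designOf(se)
    if (!stage %in% as.character(cd$stage))
        stop("stage '", stage, "' not present in the design")
    which(as.character(cd$stage) == stage & as.character(cd$arm) == arm)
}

.rowVars <- function(x) {
    n <- ncol(x)
    if (n < 2L) return(rep(NA_real_, nrow(x)))
    rowSums((x - rowMeans(x))^2) / (n - 1L)
}

#' Per-gene log2 fold change at one stage
#'
#' Mean log2 disease value minus mean log2 control value, controls being
#' the age-matched (same-stage) samples.
#'
#' @param se a \link[SummarizedExperiment]{SummarizedExperiment} whose
#'   colData carries \code{arm} and \code{stage}.
#' @param stage stage label.
#' @param assayName assay holding log2-scale values.
#' @return named numeric vector of log2 fold changes, one per gene.
#' @export
stageLog2FC <- function(se, stage, assayName = "log2expr") {
    dis <- .armCols(se, stage, "disease")
    ctl <- .armCols(se, stage, "control")
    if (length(dis) == 0L || length(ctl) == 0L)
        stop("both arms must be present at stage '", stage, "'")
    x <- SummarizedExperiment::assay(se, assayName)
    rowMeans(x[, dis, drop = FALSE]) - rowMeans(x[, ctl, drop = FALSE])
}

#' Per-gene two-sample t-test at one stage
#'
#' Student's pooled-variance t-test (the documented default; Welch via
#' \code{varEqual = FALSE}) of disease versus age-matched control
#' samples, computed on log2 values.  When both arms have zero variance,
#' the p-value is 1 for equal means and 0 otherwise.
#'
#' @inheritParams stageLog2FC
#' @param varEqual use the pooled-variance Student form (default) or
#'   Welch's unequal-variance form.
#' @return named numeric vector of two-sided raw p-values.
#' @export
deTest <- function(se, stage, assayName = "log2expr", varEqual = TRUE) {
    dis <- .armCols(se, stage, "disease")
    ctl <- .armCols(se, stage, "control")
    n1 <- length(dis); n2 <- length(ctl)
    if (n1 < 2L || n2 < 2L)
        stop("at least 2 replicates per arm are required at stage '",
             stage, "'")
    a <- SummarizedExperiment::assay(se, assayName)
    x <- a[, dis, drop = FALSE]; y <- a[, ctl, drop = FALSE]
    mx <- rowMeans(x); my <- rowMeans(y)
    vx <- .rowVars(x); vy <- .rowVars(y)
    if (varEqual) {
        sp2 <- ((n1 - 1L) * vx + (n2 - 1L) * vy) / (n1 + n2 - 2L)
        seDiff <- sqrt(sp2 * (1 / n1 + 1 / n2))
        df <- rep(n1 + n2 - 2L, length(mx))
    } else {
        seDiff <- sqrt(vx / n1 + vy / n2)
        df <- (vx / n1 + vy / n2)^2 /
            ((vx / n1)^2 / (n1 - 1L) + (vy / n2)^2 / (n2 - 1L))
    }
    tstat <- (mx - my) / seDiff
    p <- 2 * pt(-abs(tstat), df)
    degenerate <- seDiff == 0
    p[degenerate] <- ifelse(mx[degenerate] == my[degenerate], 1, 0)
    p
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via
#' \code{\link[stats]{p.adjust}}) with input validation; adjusted values
#' are monotone, capped at 1 and returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order and names as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric(0))
    if (anyNA(p) || !is.numeric(p) || any(p < 0 | p > 1))
        stop("p-values must be numeric in [0, 1] with no missing values")
    p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' A gene passes when \code{|log2fc| >= log2(fcThreshold)} (inclusive)
#' and its BH-adjusted p-value is strictly below \code{alpha}; its
#' direction is the sign of the fold change, or \code{"none"} when the
#' filter fails.
#'
#' @param log2fc named numeric vector of log2 fold changes.
#' @param adjP BH-adjusted p-values aligned with \code{log2fc}.
#' @param fcThreshold fold-change threshold on the linear scale
#'   (default 2).
#' @param alpha adjusted-p cutoff (default 0.05, strict).
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{adj_p}, \code{direction}.
#' @export
selectDegs <- function(log2fc, adjP, fcThreshold = 2, alpha = 0.05) {
    stopifnot(length(log2fc) == length(adjP))
    pass <- abs(log2fc) >= log2(fcThreshold) & adjP < alpha
    data.frame(gene = names(log2fc), log2fc = unname(log2fc),
               adj_p = unname(adjP),
               direction = ifelse(pass, ifelse(log2fc > 0, "up", "down"),
                                  "none"),
               stringsAsFactors = FALSE)
}

#' Full differential-expression result for one stage
#'
#' Convenience wrapper combining \code{\link{stageLog2FC}},
#' \code{\link{deTest}}, \code{\link{bhAdjust}} (family = all genes at
#' the stage) and \code{\link{selectDegs}}.
#'
#' @inheritParams deTest
#' @inheritParams selectDegs
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{p},
#'   \code{adj_p}, \code{direction}.
#' @export
stageDE <- function(se, stage, fcThreshold = 2, alpha = 0.05,
                    assayName = "log2expr", varEqual = TRUE) {
    lfc <- stageLog2FC(se, stage, assayName)
    p <- deTest(se, stage, assayName, varEqual)
    adj <- bhAdjust(p)
    out <- selectDegs(lfc, adj, fcThreshold, alpha)
    out$p <- unname(p)
    out[, c("gene", "log2fc", "p", "adj_p", "direction")]
}

#' Genes differentially expressed with the same trend at every stage
#'
#' @param degList named list of per-stage data.frames with \code{gene}
#'   and \code{direction} columns (e.g. from \code{\link{stageDE}});
#'   at least two stages.
#' @return data.frame with columns \code{gene} and \code{direction},
#'   containing the genes selected at every stage with an identical
#'   direction.
#' @export
commonTrendGenes <- function(degList) {
    if (length(degList) < 2L)
        stop("at least two stages are required")
    dirs <- lapply(degList, function(d)
        setNames(d$direction, d$gene))
    genes <- Reduce(intersect, lapply(dirs, names))
    keep <- vapply(genes, function(g) {
        d <- vapply(dirs, `[[`, character(1L), g)
        all(d != "none") && length(unique(d)) == 1L
    }, logical(1L))
    genes <- genes[keep]
    data.frame(gene = genes,
               direction = vapply(genes, function(g) dirs[[1L]][[g]],
                                  character(1L)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes differentially expressed only at one stage
#'
#' Selected at \code{stage} and not selected at any other stage; the
#' input set for the final-stage-unique cascade.
#'
#' @inheritParams commonTrendGenes
#' @param stage the stage of interest (a name of \code{degList}).
#' @return data.frame with columns \code{gene}, \code{log2fc},
#'   \code{direction} restricted to uniquely selected genes.
#' @export
uniqueStageDegs <- function(degList, stage) {
    if (!stage %in% names(degList))
        stop("stage '", stage, "' not found in 'degList'")
    this <- degList[[stage]]
    selHere <- this$gene[this$direction != "none"]
    others <- degList[setdiff(names(degList), stage)]
    selElsewhere <- unique(unlist(lapply(others, function(d)
        d$gene[d$direction != "none"])))
    keep <- setdiff(selHere, selElsewhere)
    this[this$gene %in% keep, intersect(c("gene", "log2fc", "direction"),
                                        colnames(this)), drop = FALSE]
}

#' Stage-trend statistics for one gene
#'
#' One-way ANOVA across stages followed by Tukey HSD pairwise
#' comparisons, plus an ordinary least-squares regression of the value
#' on the stage rank (trend slope with its t-test p-value).  Degenerate
#' all-constant input yields F = 0, p = 1, slope = 0.
#'
#' @param values numeric vector of per-replicate measurements.
#' @param stages stage label per measurement (at least 2 distinct
#'   stages, at least 2 replicates each); trend rank follows factor
#'   level order.
#' @return list with \code{anova_p}, \code{tukey} (matrix of pairwise
#'   comparisons), \code{slope}, \code{slope_p}.
#' @export
stageTrendStats <- function(values, stages) {
    stages <- if (is.factor(stages)) droplevels(stages)
              else factor(stages, levels = unique(stages))
    if (nlevels(stages) < 2L)
        stop("at least two stages are required")
    if (any(table(stages) < 2L))
        stop("at least two replicates per stage are required")
    if (all(values == values[[1L]]))
        return(list(anova_p = 1, tukey = NULL, slope = 0, slope_p = 1))
    fit <- aov(values ~ stages)
    an <- summary(fit)[[1L]]
    tuk <- TukeyHSD(fit)$stages
    rank <- as.numeric(stages)
    lmfit <- summary(lm(values ~ rank))$coefficients
    list(anova_p = an[["Pr(>F)"]][1L], tukey = tuk,
         slope = lmfit["rank", "Estimate"],
         slope_p = lmfit["rank", "Pr(>|t|)"])
}

## Per-measurement delta Ct (target minus reference).
.deltaCt <- function(ct) {
    req <- c("target_ct", "reference_ct")
    if (!all(req %in% colnames(ct)))
        stop("Ct table must have 'target_ct' and 'reference_ct' columns")
    d <- ct$target_ct - ct$reference_ct
    if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$reference_ct)))
        stop("Ct values must be finite")
    d
}

#' 2^-ddCt relative fold change
#'
#' The classical relative-quantitation statistic: per-measurement
#' \code{dCt = target Ct - reference Ct}, \code{ddCt = mean dCt(sample
#' group) - mean dCt(calibrator group)}, fold change \code{2^-ddCt}.
#' Group means of dCt are used (no per-sample pairing).
#'
#' @param calibrator,sample data.frames with \code{target_ct} and
#'   \code{reference_ct} columns (typically control and disease
#'   samples).
#' @return positive fold change of the sample group relative to the
#'   calibrator.
#' @examples
#' cal <- data.frame(target_ct = 27, reference_ct = 20)
#' smp <- data.frame(target_ct = 25, reference_ct = 20)
#' ddctFoldChange(cal, smp)  # ddCt = -2, fold = 4
#' @export
ddctFoldChange <- function(calibrator, sample) {
    if (nrow(calibrator) == 0L || nrow(sample) == 0L)
        stop("both groups must be non-empty")
    ddct <- mean(.deltaCt(sample)) - mean(.deltaCt(calibrator))
    2^(-ddct)
}

#' Per-stage 2^-ddCt fold changes from a Ct table
#'
#' For each stage, the disease samples are quantified relative to the
#' age-matched control samples as calibrator.
#'
#' @param ct data.frame with columns \code{arm}, \code{stage},
#'   \code{target_ct}, \code{reference_ct} (as produced by
#'   \code{\link{generateQpcr}}).
#' @return data.frame with columns \code{stage} and \code{fold_change}.
#' @export
qpcrFoldChanges <- function(ct) {
    stages <- unique(as.character(ct$stage))
    fc <- vapply(stages, function(s) {
        ddctFoldChange(ct[ct$arm == "control" & ct$stage == s, ],
                       ct[ct$arm == "disease" & ct$stage == s, ])
    }, numeric(1L))
    data.frame(stage = stages, fold_change = unname(fc),
               stringsAsFactors = FALSE)
}
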
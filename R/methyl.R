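## MeDIP-style percent-methylation quantitation, the 20% control-tissue
## threshold, per-gene differential methylation against age-matched
## controls, microarray-style differential-methylation calling
## (standardized fold change >= 1.5 and BH-adjusted p < 0.05), and the
## per-region percent-methylated-CpG summary.

#' Percent methylation from bound and input quantities
#'
#' \code{100 * bound / input}, the single-fraction-elution normalization
#' against total input DNA.  Values above 100 are reported as-is with an
#' out-of-range flag (attribute \code{outOfRange}) rather than silently
#' clipped.
#'
#' @param bound,input non-negative quantity vectors; \code{input} must
#'   be strictly positive.
#' @return numeric percent vector with a logical \code{outOfRange}
#'   attribute.
#' @examples
#' medipPercent(30, 100)  # 30
#' @export
medipPercent <- function(bound, input) {
    if (any(input <= 0)) stop("'input' quantities must be positive")
    if (any(bound < 0)) stop("'bound' quantities must be non-negative")
    pct <- 100 * bound / input
    attr(pct, "outOfRange") <- pct > 100
    if (any(pct > 100))
        warning(sum(pct > 100), " percent-methylation value(s) exceed 100;",
                " flagged, not clipped")
    pct
}

#' Percent-methylation matrix from a bound/input experiment
#'
#' @param se a SummarizedExperiment with \code{bound} and \code{input}
#'   assays.
#' @return genes x samples matrix of percent methylation.
#' @export
percentMethylation <- function(se) {
    b <- SummarizedExperiment::assay(se, "bound")
    i <- SummarizedExperiment::assay(se, "input")
    pct <- medipPercent(as.vector(b), as.vector(i))
    matrix(as.numeric(pct), nrow(b), ncol(b), dimnames = dimnames(b))
}

#' Genes clearing the control-tissue methylation threshold
#'
#' Keeps genes whose mean percent methylation across all control-arm
#' samples is at or above the threshold (inclusive, matching the
#' ">= 20 percent" rule); only sufficiently methylated promoters can
#' show a functionally meaningful loss of methylation.
#'
#' @param se a bound/input SummarizedExperiment with arm/stage colData.
#' @param threshold percent threshold (default 20, inclusive).
#' @return character vector of passing gene ids.
#' @export
controlMethylationFilter <- function(se, threshold = 20) {
    cd <- .designOf(se)
    ctl <- which(as.character(cd$arm) == "control")
    if (length(ctl) == 0L) stop("no control-arm samples present")
    pct <- percentMethylation(se)[, ctl, drop = FALSE]
    ok <- rowSums(!is.na(pct)) > 0L
    if (any(!ok))
        warning("excluding gene(s) with no control measurements: ",
                paste(rownames(pct)[!ok], collapse = ", "))
    means <- rowMeans(pct, na.rm = TRUE)
    rownames(pct)[ok & means >= threshold]
}

#' Differential methylation at one stage
#'
#' Two-sample t-test on percent methylation, disease versus age-matched
#' control samples, with both change summaries: \code{delta_percent}
#' (control mean minus disease mean, in percentage points, positive for
#' a methylation loss) and \code{relative_change}
#' (\code{1 - disease/control}, so the driver construction "a 45 percent
#' decrease" appears as 0.45).  The two agree in sign by the identity
#' \code{relative_change = delta_percent / control mean}.
#'
#' @inheritParams controlMethylationFilter
#' @param stage stage label.
#' @param varEqual Student pooled-variance form (default) or Welch.
#' @return data.frame with columns \code{gene}, \code{control_mean},
#'   \code{disease_mean}, \code{delta_percent}, \code{relative_change},
#'   \code{p}, \code{direction} (hypo/hyper/none by sign of the change).
#' @export
dmTest <- function(se, stage, varEqual = TRUE) {
    pct <- percentMethylation(se)
    pse <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = pct),
        colData = SummarizedExperiment::colData(se))
    dis <- .armCols(se, stage, "disease")
    ctl <- .armCols(se, stage, "control")
    cm <- rowMeans(pct[, ctl, drop = FALSE])
    dm <- rowMeans(pct[, dis, drop = FALSE])
    p <- deTest(pse, stage, varEqual = varEqual)
    delta <- cm - dm
    data.frame(gene = rownames(pct), control_mean = cm, disease_mean = dm,
               delta_percent = delta,
               relative_change = ifelse(cm > 0, delta / cm, NA_real_),
               p = unname(p),
               direction = ifelse(delta > 0, "hypo",
                                  ifelse(delta < 0, "hyper", "none")),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Microarray-style differential-methylation calls
#'
#' Standardizes per-gene log2 enrichment ratios across the gene set to
#' z-like scores (\code{(x - mean) / sd}), adjusts the p-values by
#' Benjamini-Hochberg, and calls a gene differentially methylated when
#' the adjusted p-value is below \code{alpha} and the absolute
#' standardized fold change is at least \code{fcThreshold}.  Direction
#' follows the sign of the standardized score (\code{hyper} for a gain,
#' \code{hypo} for a loss).
#'
#' @param log2Ratios named numeric vector of per-gene log2 enrichment
#'   ratios (disease vs control); \code{NA} entries are never called.
#' @param pvalues raw p-values aligned with \code{log2Ratios}.
#' @param fcThreshold standardized fold-change threshold (default 1.5).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return data.frame with columns \code{gene}, \code{log2_ratio},
#'   \code{z}, \code{p}, \code{adj_p}, \code{called}, \code{direction}.
#' @export
dmCallMicroarray <- function(log2Ratios, pvalues, fcThreshold = 1.5,
                             alpha = 0.05) {
    stopifnot(length(log2Ratios) == length(pvalues))
    usable <- is.finite(log2Ratios)
    if (sum(usable) < 2L || sd(log2Ratios[usable]) == 0)
        stop("cannot standardize: fewer than two distinct finite ratios")
    z <- rep(NA_real_, length(log2Ratios))
    z[usable] <- (log2Ratios[usable] - mean(log2Ratios[usable])) /
        sd(log2Ratios[usable])
    adj <- rep(NA_real_, length(pvalues))
    adj[usable] <- bhAdjust(pvalues[usable])
    called <- !is.na(z) & !is.na(adj) & adj < alpha &
        abs(z) >= fcThreshold
    data.frame(gene = names(log2Ratios), log2_ratio = unname(log2Ratios),
               z = unname(z), p = unname(pvalues), adj_p = unname(adj),
               called = unname(called),
               direction = ifelse(called, ifelse(z > 0, "hyper", "hypo"),
                                  "none"),
               stringsAsFactors = FALSE)
}

#' Per-gene log2 methylation enrichment ratio at one stage
#'
#' \code{log2(mean disease percent / mean control percent)} with
#' age-matched controls; genes with a non-positive mean in either arm
#' yield \code{NA} (they cannot be ratio-quantified).
#'
#' @inheritParams dmTest
#' @return named numeric vector of log2 ratios.
#' @export
dmLog2Ratios <- function(se, stage) {
    pct <- percentMethylation(se)
    dis <- .armCols(se, stage, "disease")
    ctl <- .armCols(se, stage, "control")
    cm <- rowMeans(pct[, ctl, drop = FALSE])
    dm <- rowMeans(pct[, dis, drop = FALSE])
    out <- ifelse(cm > 0 & dm > 0, log2(dm / cm), NA_real_)
    setNames(out, rownames(pct))
}

#' Percent of methylated CpG sites in a region
#'
#' Summary used for per-region methylation call sets: methylated CpGs as
#' a percentage of all CpGs in the region.
#'
#' @param states logical vector (TRUE = methylated) or character vector
#'   with values \code{"methylated"} / \code{"unmethylated"}.
#' @return percent in [0, 100].
#' @examples
#' dmrPercentMethylated(c(TRUE, TRUE, FALSE, TRUE))  # 75
#' @export
dmrPercentMethylated <- function(states) {
    if (length(states) == 0L)
        stop("a region must contain at least one CpG site")
    if (is.character(states)) {
        bad <- !states %in% c("methylated", "unmethylated")
        if (any(bad)) stop("unknown CpG state(s): ",
                           paste(unique(states[bad]), collapse = ", "))
        states <- states == "methylated"
    }
    if (!is.logical(states) || anyNA(states))
        stop("'states' must be logical or methylated/unmethylated labels")
    100 * sum(states) / length(states)
}

#' Per-region percent-methylated summary of a CpG call table
#'
#' @param calls data.frame with columns \code{region} and \code{state}.
#' @return data.frame with columns \code{region}, \code{n_cpg},
#'   \code{percent_methylated}.
#' @export
dmrPercentTable <- function(calls) {
    if (!all(c("region", "state") %in% colnames(calls)))
        stop("'calls' must have 'region' and 'state' columns")
    regions <- unique(as.character(calls$region))
    pct <- vapply(regions, function(r)
        dmrPercentMethylated(calls$state[calls$region == r]), numeric(1L))
    n <- vapply(regions, function(r) sum(calls$region == r), integer(1L))
    data.frame(region = regions, n_cpg = unname(n),
               percent_methylated = unname(pct), stringsAsFactors = FALSE)
}
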
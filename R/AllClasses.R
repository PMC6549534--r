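#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' CpG-island calling criteria
#'
#' Container for the classical "strong island" criteria used to decide
#' whether a promoter window qualifies as part of a CpG island: a minimum
#' length (strict), a minimum G+C fraction (strict), and a minimum
#' observed/expected CpG ratio (strict).  Windows whose fraction of
#' ambiguous (N) bases exceeds \code{maxNFraction} are disqualified.
#'
#' @slot minLength integer, minimum island length in bases; windows of
#'   width \code{minLength + 1} are scanned so that qualifying islands are
#'   strictly longer than \code{minLength}.
#' @slot minGC numeric in (0, 1], minimum G+C fraction (strict).
#' @slot minObsExp numeric, minimum observed/expected CpG ratio (strict).
#' @slot maxNFraction numeric in [0, 1], maximum tolerated fraction of N
#'   bases per window.
#' @export
setClass("CgiCriteria",
    representation(minLength = "integer", minGC = "numeric",
                   minObsExp = "numeric", maxNFraction = "numeric"))

setValidity("CgiCriteria", function(object) {
    msg <- NULL
    if (length(object@minLength) != 1L || is.na(object@minLength) ||
        object@minLength < 1L)
        msg <- c(msg, "'minLength' must be a single positive integer")
    if (length(object@minGC) != 1L || is.na(object@minGC) ||
        object@minGC <= 0 || object@minGC > 1)
        msg <- c(msg, "'minGC' must be a single value in (0, 1]")
    if (length(object@minObsExp) != 1L || is.na(object@minObsExp) ||
        object@minObsExp <= 0)
        msg <- c(msg, "'minObsExp' must be a single positive value")
    if (length(object@maxNFraction) != 1L || is.na(object@maxNFraction) ||
        object@maxNFraction < 0 || object@maxNFraction > 1)
        msg <- c(msg, "'maxNFraction' must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Construct CpG-island criteria
#'
#' Defaults follow the classical strong-island definition: length greater
#' than 500 bp, G+C content greater than 55 percent, and an
#' observed/expected CpG ratio greater than 0.65.  All three thresholds
#' are applied as strict inequalities.
#'
#' @param minLength minimum island length in bases (default 500, strict).
#' @param minGC minimum G+C fraction (default 0.55, strict).
#' @param minObsExp minimum observed/expected CpG ratio (default 0.65,
#'   strict).
#' @param maxNFraction maximum fraction of N bases tolerated per window
#'   (default 0.1).
#' @return A \linkS4class{CgiCriteria} object.
#' @examples
#' CgiCriteria()
#' CgiCriteria(minLength = 200, minGC = 0.5, minObsExp = 0.6)
#' @export
CgiCriteria <- function(minLength = 500L, minGC = 0.55, minObsExp = 0.65,
                        maxNFraction = 0.1) {
    new("CgiCriteria", minLength = as.integer(minLength), minGC = minGC,
        minObsExp = minObsExp, maxNFraction = maxNFraction)
}

setMethod("show", "CgiCriteria", function(object) {
    cat("CpG-island criteria: length >", object@minLength,
        "bp, G+C >", object@minGC,
        ", obs/exp CpG >", object@minObsExp, "\n")
})

#' Synthetic multi-omics generator configuration
#'
#' Parameters describing a progressive three-stage disease-vs-control
#' study design (two arms, ordered stages, a fixed number of replicates
#' per cell) plus the planted signals carried by each gene role:
#' \describe{
#'   \item{driver}{progressively over-expressed at every stage and
#'     progressively hypomethylated in the disease arm; always carries a
#'     CpG-island-positive promoter.}
#'   \item{passenger}{over-expressed at every stage but with unchanged
#'     promoter methylation.}
#'   \item{late_dm}{unchanged at early stages; at the final stage only,
#'     its methylation shifts by \code{lateDMDelta} and its expression by
#'     \code{lateDMExprLog2FC}.}
#'   \item{null}{no planted effect on any axis.}
#' }
#'
#' @slot nGenes,nReplicates total gene count and replicates per arm/stage.
#' @slot stages ordered stage labels, earliest first.
#' @slot nDrivers,nPassengers,nLateDM role counts; the remainder are null.
#' @slot exprBaseMean,exprNoiseSD log2-scale expression baseline and
#'   Gaussian noise standard deviation.
#' @slot driverExprLog2FC,passengerExprLog2FC per-stage planted log2 fold
#'   changes (disease vs control); the driver profile must be monotone
#'   non-decreasing.
#' @slot driverMethControl control-arm methylation fraction of driver
#'   promoters; must be at least 0.20 so drivers can clear the 20 percent
#'   control-tissue threshold.
#' @slot driverMethDecrease per-stage relative decreases of driver
#'   methylation in the disease arm (monotone non-decreasing).
#' @slot lateDMBaseMeth,lateDMDelta baseline methylation fraction of
#'   late-shift genes and the (signed) fraction shift applied at the final
#'   stage only.
#' @slot lateDMExprLog2FC planted expression log2 fold change of late-shift
#'   genes at the final stage only.
#' @slot h3k4Log2FC per-stage planted H3K4me3 log2 fold enrichment for
#'   driver and passenger genes; monotone non-increasing (maximal at the
#'   earliest stage).
#' @slot h3k4NoiseSD Gaussian noise on log2 chip/input values.
#' @slot methConcentration Beta concentration of the methylation noise
#'   model (\code{Inf} gives noiseless fractions).
#' @slot qpcrNoiseSD Gaussian noise on Ct values.
#' @slot cgiPromoterFraction fraction of genes given CpG-island-positive
#'   promoters (drivers always are).
#' @slot promoterLength promoter length in bases.
#' @slot seed root seed; every generated table draws from its own
#'   substream derived from this seed.
#' @export
setClass("GeneratorConfig",
    representation(
        nGenes = "integer", nReplicates = "integer", stages = "character",
        nDrivers = "integer", nPassengers = "integer", nLateDM = "integer",
        exprBaseMean = "numeric", exprNoiseSD = "numeric",
        driverExprLog2FC = "numeric", passengerExprLog2FC = "numeric",
        driverMethControl = "numeric", driverMethDecrease = "numeric",
        lateDMBaseMeth = "numeric", lateDMDelta = "numeric",
        lateDMExprLog2FC = "numeric",
        h3k4Log2FC = "numeric", h3k4NoiseSD = "numeric",
        methConcentration = "numeric", qpcrNoiseSD = "numeric",
        cgiPromoterFraction = "numeric", promoterLength = "integer",
        seed = "integer"))

setValidity("GeneratorConfig", function(object) {
    msg <- NULL
    ns <- length(object@stages)
    if (ns < 1L || anyDuplicated(object@stages))
        msg <- c(msg, "'stages' must be non-empty unique ordered labels")
    if (object@nGenes < 0L)
        msg <- c(msg, "'nGenes' must be non-negative")
    if (object@nReplicates < 2L)
        msg <- c(msg, "'nReplicates' must be at least 2 per arm and stage")
    roles <- c(object@nDrivers, object@nPassengers, object@nLateDM)
    if (any(roles < 0L))
        msg <- c(msg, "role counts must be non-negative")
    if (sum(roles) > object@nGenes)
        msg <- c(msg, "role counts must sum to at most 'nGenes'")
    for (nm in c("driverExprLog2FC", "passengerExprLog2FC",
                 "driverMethDecrease", "h3k4Log2FC"))
        if (length(slot(object, nm)) != ns)
            msg <- c(msg, sprintf("'%s' must have one value per stage", nm))
    if (is.unsorted(object@driverExprLog2FC))
        msg <- c(msg, "'driverExprLog2FC' must be monotone non-decreasing")
    if (is.unsorted(object@driverMethDecrease))
        msg <- c(msg, "'driverMethDecrease' must be monotone non-decreasing")
    if (is.unsorted(rev(object@h3k4Log2FC)))
        msg <- c(msg,
            "'h3k4Log2FC' must be monotone non-increasing (max at stage 1)")
    if (object@driverMethControl < 0.20)
        msg <- c(msg, paste0("'driverMethControl' must be >= 0.20 so that ",
            "drivers can pass the 20% control-methylation threshold"))
    if (object@driverMethControl > 1)
        msg <- c(msg, "'driverMethControl' must be a fraction in [0.20, 1]")
    if (any(object@driverMethDecrease < 0 | object@driverMethDecrease > 1))
        msg <- c(msg, "'driverMethDecrease' values must lie in [0, 1]")
    if (object@lateDMBaseMeth < 0 || object@lateDMBaseMeth > 1)
        msg <- c(msg, "'lateDMBaseMeth' must lie in [0, 1]")
    if (object@exprNoiseSD < 0 || object@h3k4NoiseSD < 0 ||
        object@qpcrNoiseSD < 0)
        msg <- c(msg, "noise standard deviations must be non-negative")
    if (object@methConcentration <= 0)
        msg <- c(msg, "'methConcentration' must be positive (Inf = no noise)")
    if (object@cgiPromoterFraction < 0 || object@cgiPromoterFraction > 1)
        msg <- c(msg, "'cgiPromoterFraction' must lie in [0, 1]")
    if (object@cgiPromoterFraction > 0 && object@promoterLength < 600L)
        msg <- c(msg, paste0("'promoterLength' must be >= 600 when ",
            "'cgiPromoterFraction' > 0: a qualifying island cannot be ",
            "planted in a shorter promoter"))
    if (object@nGenes > 0L && object@nDrivers >
        round(object@cgiPromoterFraction * object@nGenes))
        msg <- c(msg, paste0("'cgiPromoterFraction' too small: drivers are ",
            "always CpG-island-positive, so round(fraction * nGenes) must ",
            "be >= nDrivers"))
    if (is.na(object@seed) || object@seed < 0L)
        msg <- c(msg, "'seed' must be a single non-negative integer")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig:", object@nGenes, "genes x",
        2L * length(object@stages) * object@nReplicates, "samples (",
        paste(object@stages, collapse = " < "), "; n =",
        object@nReplicates, "/arm/stage)\n")
    cat("  roles: drivers", object@nDrivers, "| passengers",
        object@nPassengers, "| late-DM", object@nLateDM, "| null",
        object@nGenes - object@nDrivers - object@nPassengers -
        object@nLateDM, "\n")
    cat("  seed:", object@seed, "\n")
})

#' Synthetic multi-omics data bundle
#'
#' The output of \code{\link{generateSynthData}}: every table the filter
#' cascades consume, generated from one \linkS4class{GeneratorConfig}
#' and internally consistent with the planted ground truth.
#'
#' @slot config the generating \linkS4class{GeneratorConfig}.
#' @slot truth ground-truth data.frame (one row per gene: role, CpG-island
#'   flag, planted per-stage expression log2 fold changes, planted
#'   methylation fractions, planted H3K4me3 log2 fold enrichments, and a
#'   flag recording whether any planted fraction had to be clipped to
#'   [0, 1]).
#' @slot promoters \link[Biostrings]{DNAStringSet} of promoter sequences,
#'   one per gene (empty if not generated).
#' @slot expression \link[SummarizedExperiment]{SummarizedExperiment} with
#'   a \code{log2expr} assay and an arm/stage/replicate design in
#'   \code{colData}.
#' @slot methylation SummarizedExperiment with \code{bound} and
#'   \code{input} assays (MeDIP-style quantities).
#' @slot h3k4 SummarizedExperiment with \code{chip} and \code{input}
#'   assays (H3K4me3 ChIP-style quantities).
#' @slot qpcr data.frame of target/reference Ct values for one gene.
#' @export
setClass("SynthData",
    representation(config = "GeneratorConfig", truth = "data.frame",
                   promoters = "ANY", expression = "ANY",
                   methylation = "ANY", h3k4 = "ANY", qpcr = "data.frame"))

setMethod("show", "SynthData", function(object) {
    cat("SynthData:", nrow(object@truth), "genes;",
        "tables:", paste(c(
            if (length(object@promoters)) "promoters",
            if (!is.null(object@expression)) "expression",
            if (!is.null(object@methylation)) "methylation",
            if (!is.null(object@h3k4)) "h3k4",
            if (nrow(object@qpcr)) "qpcr"), collapse = ", "), "\n")
    print(table(role = object@truth$role))
})

#' Filter-cascade report
#'
#' One row per gene with the boolean trail through every cascade filter
#' and the final classification.  The trail is monotone: once a filter
#' fails, later filters are not evaluated (reported as \code{NA}).  Genes
#' surviving every filter are classified by the concordance of their
#' expression and methylation directions
#' (\code{hypomethylated_overexpressed}, \code{hypermethylated_downregulated}
#' or \code{discordant}); all other genes are \code{not_candidate}.
#'
#' @slot table an \link[S4Vectors]{DataFrame} with a \code{gene} column,
#'   one logical column per filter (in cascade order), and a \code{class}
#'   column.
#' @slot mode \code{"common"} (stage-persistent cascade) or \code{"hcc"}
#'   (final-stage-unique cascade).
#' @slot filters ordered filter column names.
#' @slot counts named integer vector: input universe size followed by the
#'   survivor count after each filter (non-increasing).
#' @export
setClass("CascadeReport",
    representation(table = "DataFrame", mode = "character",
                   filters = "character", counts = "integer"))

setValidity("CascadeReport", function(object) {
    msg <- NULL
    if (!all(object@filters %in% colnames(object@table)))
        msg <- c(msg, "every filter must be a column of 'table'")
    if (any(diff(object@counts) > 0L))
        msg <- c(msg, "survivor counts must be non-increasing")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CascadeReport", function(object) {
    cat(sprintf("CascadeReport (%s cascade): %d genes in\n", object@mode,
                object@counts[[1L]]))
    for (i in seq_along(object@filters))
        cat(sprintf("  %-24s -> %d\n", object@filters[i],
                    object@counts[[i + 1L]]))
    surv <- cascadeSurvivors(object)
    cat("survivors:", if (length(surv)) paste(surv, collapse = ", ")
        else "(none)", "\n")
})
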
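## End-to-end orchestration and plain-text I/O.  All tables travel as
## TSV with a one-line header, promoters as FASTA, islands as BED6, and
## the run manifest as JSON.  Every threshold actually applied is echoed
## to the message stream and recorded in the manifest (auditability);
## results go only to files / returned objects, never to stdout.

## ---- readers and writers -------------------------------------------

#' Read a sample-design table
#'
#' @param file TSV with columns \code{sample_id}, \code{arm},
#'   \code{stage}, \code{replicate}; stage order follows first
#'   appearance unless \code{stages} is given.
#' @param stages optional ordered stage labels.
#' @return a \link[S4Vectors]{DataFrame} keyed by sample id.
#' @export
readDesignTable <- function(file, stages = NULL) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    req <- c("sample_id", "arm", "stage", "replicate")
    if (!all(req %in% colnames(d)))
        stop("design table must have columns: ", paste(req, collapse = ", "))
    if (anyDuplicated(d$sample_id))
        stop("duplicate sample id(s): ",
             paste(unique(d$sample_id[duplicated(d$sample_id)]),
                   collapse = ", "))
    if (!all(d$arm %in% c("control", "disease")))
        stop("'arm' must be 'control' or 'disease'")
    if (is.null(stages)) stages <- unique(d$stage)
    S4Vectors::DataFrame(sample_id = d$sample_id,
        arm = factor(d$arm, levels = c("control", "disease")),
        stage = factor(d$stage, levels = stages),
        replicate = as.integer(d$replicate), row.names = d$sample_id)
}

#' Write the sample-design table of an experiment
#' @param se a SummarizedExperiment with arm/stage/replicate colData.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeDesignTable <- function(se, file) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    utils::write.table(cd, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

.checkGeneRows <- function(d, file) {
    if (colnames(d)[1L] != "gene")
        stop("first column of '", file, "' must be 'gene'")
    dup <- unique(d$gene[duplicated(d$gene)])
    if (length(dup))
        stop("duplicate gene row(s) in '", file, "': ",
             paste(dup, collapse = ", "))
    num <- d[, -1L, drop = FALSE]
    bad <- !vapply(num, is.numeric, logical(1L))
    if (any(bad))
        stop("non-numeric measurement column(s) in '", file, "': ",
             paste(colnames(num)[bad], collapse = ", "))
}

#' Read a genes-by-samples expression table
#'
#' @param file TSV whose first column is \code{gene} and remaining
#'   columns are per-sample log2 values.
#' @param designFile companion design TSV (see
#'   \code{\link{readDesignTable}}).
#' @return a SummarizedExperiment with assay \code{log2expr}.
#' @export
readExpressionTable <- function(file, designFile) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE,
                           check.names = FALSE)
    .checkGeneRows(d, file)
    design <- readDesignTable(designFile)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- d$gene
    missing <- setdiff(design$sample_id, colnames(m))
    if (length(missing))
        stop("samples in design but not in '", file, "': ",
             paste(missing, collapse = ", "))
    m <- m[, design$sample_id, drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = m), colData = design)
}

#' Write a genes-by-samples expression table
#' @inheritParams writeDesignTable
#' @param assayName assay to write.
#' @export
writeExpressionTable <- function(se, file, assayName = "log2expr") {
    m <- SummarizedExperiment::assay(se, assayName)
    d <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
    utils::write.table(d, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read a long-format two-quantity table (bound/input or chip/input)
#'
#' @param file TSV with columns \code{gene}, \code{sample} and the two
#'   quantity columns named in \code{quantities}.
#' @param designFile companion design TSV.
#' @param quantities the two quantity column names, in assay order.
#' @return a SummarizedExperiment with one assay per quantity.
#' @export
readQuantTable <- function(file, designFile,
                           quantities = c("bound", "input")) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    req <- c("gene", "sample", quantities)
    if (!all(req %in% colnames(d)))
        stop("'", file, "' must have columns: ",
             paste(req, collapse = ", "))
    if (anyDuplicated(d[, c("gene", "sample")]))
        stop("duplicate (gene, sample) row(s) in '", file, "'")
    design <- readDesignTable(designFile)
    genes <- unique(d$gene)
    assays <- lapply(quantities, function(q) {
        if (!is.numeric(d[[q]]))
            stop("non-numeric '", q, "' column in '", file, "'")
        m <- matrix(NA_real_, length(genes), nrow(design),
                    dimnames = list(genes, design$sample_id))
        m[cbind(match(d$gene, genes), match(d$sample, design$sample_id))] <-
            d[[q]]
        if (anyNA(m))
            stop("missing (gene, sample) combination(s) in '", file, "'")
        m
    })
    names(assays) <- quantities
    SummarizedExperiment::SummarizedExperiment(assays = assays,
                                               colData = design)
}

#' Write a long-format two-quantity table
#' @inheritParams writeDesignTable
#' @param quantities assay names to write as quantity columns.
#' @export
writeQuantTable <- function(se, file, quantities = c("bound", "input")) {
    a1 <- SummarizedExperiment::assay(se, quantities[1L])
    a2 <- SummarizedExperiment::assay(se, quantities[2L])
    d <- data.frame(gene = rep(rownames(a1), times = ncol(a1)),
                    sample = rep(colnames(a1), each = nrow(a1)),
                    q1 = as.vector(a1), q2 = as.vector(a2),
                    stringsAsFactors = FALSE)
    colnames(d)[3:4] <- quantities
    utils::write.table(d, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Read promoter sequences from FASTA
#' @param file FASTA path; record ids (first word of each header) become
#'   gene ids.
#' @return a named \link[Biostrings]{DNAStringSet}.
#' @export
readPromotersFasta <- function(file) {
    s <- Biostrings::readDNAStringSet(file)
    names(s) <- sub("\\s.*$", "", names(s))
    if (anyDuplicated(names(s)))
        stop("duplicate gene id(s) in '", file, "'")
    s
}

#' Write promoter sequences as FASTA
#' @param promoters a named \link[Biostrings]{DNAStringSet}.
#' @param file output path.
#' @export
writePromotersFasta <- function(promoters, file) {
    Biostrings::writeXStringSet(promoters, file)
    invisible(file)
}

#' Read a qPCR Ct table
#' @param file TSV with columns \code{sample_id}, \code{arm},
#'   \code{stage}, \code{replicate}, \code{target_ct},
#'   \code{reference_ct}.
#' @return data.frame.
#' @export
readCtTable <- function(file) {
    d <- utils::read.delim(file, stringsAsFactors = FALSE)
    req <- c("sample_id", "arm", "stage", "target_ct", "reference_ct")
    if (!all(req %in% colnames(d)))
        stop("Ct table must have columns: ", paste(req, collapse = ", "))
    d
}

#' Write a cascade report as TSV
#' @param report a \linkS4class{CascadeReport}.
#' @param file output path.
#' @export
writeCascadeReport <- function(report, file) {
    utils::write.table(as.data.frame(cascadeTable(report)), file,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

## ---- orchestration -------------------------------------------------

.echoThresholds <- function(th) {
    for (nm in names(th))
        message("threshold ", nm, " = ",
                paste(format(th[[nm]]), collapse = "/"))
}

#' Run the full filter-cascade pipeline
#'
#' Executes every stage in dependency order: synthetic-data generation
#' (or table reading), promoter CpG-island scanning, stage-wise
#' differential expression, common-trend selection, percent-methylation
#' quantitation and the control-tissue threshold, per-stage differential
#' methylation, expression-methylation correlation, H3K4me3 enrichment,
#' and both filter cascades.  All applied thresholds are echoed to the
#' message stream and recorded in the returned manifest; when
#' \code{outdir} is given, every input and intermediate table is written
#' there as plain text (the manifest as JSON).
#'
#' @param x a \linkS4class{GeneratorConfig} (synthetic mode), a
#'   \linkS4class{SynthData} bundle, or a named list of file paths with
#'   elements \code{expression}, \code{design}, \code{methylation},
#'   \code{promoters} and optionally \code{h3k4}.
#' @param outdir optional output directory (created if needed).
#' @param fcThreshold,alpha differential-expression thresholds
#'   (twofold, BH-adjusted p < 0.05).
#' @param methThreshold control-methylation percent threshold
#'   (inclusive in the common cascade, strict in the final-stage
#'   cascade).
#' @param dmFcThreshold,dmAlpha differential-methylation call
#'   thresholds (standardized fold change, adjusted p).
#' @param h3k4Threshold absolute log2 H3K4me3 enrichment threshold.
#' @param cgiCriteria a \linkS4class{CgiCriteria}.
#' @param correlationMode pooled across stages (default) or per-stage.
#' @param dmScope require differential methylation at all stages
#'   (default) or any.
#' @param scanPromoters scan generated promoters with the CpG-island
#'   detector (default); when \code{FALSE} in synthetic mode, the
#'   planted island flags are used directly and no FASTA/BED output is
#'   produced.
#' @return list with elements \code{common} and \code{hcc}
#'   (\linkS4class{CascadeReport}s), \code{de} (per-stage tables),
#'   \code{dm} (per-stage tables), \code{correlations},
#'   \code{h3k4Enrichment} (per-stage named vectors), \code{cgiFlags},
#'   \code{manifest}, and in synthetic mode \code{synth} (the
#'   \linkS4class{SynthData}).
#' @examples
#' cfg <- GeneratorConfig(nGenes = 40, nDrivers = 2, nPassengers = 3,
#'     nLateDM = 3, seed = 11)
#' res <- runCascadePipeline(cfg, scanPromoters = FALSE)
#' res$common
#' @export
runCascadePipeline <- function(x, outdir = NULL, fcThreshold = 2,
        alpha = 0.05, methThreshold = 20, dmFcThreshold = 1.5,
        dmAlpha = 0.05, h3k4Threshold = 1, cgiCriteria = CgiCriteria(),
        correlationMode = c("pooled", "per-stage"),
        dmScope = c("all", "any"), scanPromoters = TRUE) {
    correlationMode <- match.arg(correlationMode)
    dmScope <- match.arg(dmScope)
    th <- list(fc_threshold = fcThreshold, alpha = alpha,
               meth_threshold = methThreshold,
               dm_fold_threshold = dmFcThreshold, dm_alpha = dmAlpha,
               h3k4_threshold = h3k4Threshold,
               cgi_min_length = cgiCriteria@minLength,
               cgi_min_gc = cgiCriteria@minGC,
               cgi_min_obs_exp = cgiCriteria@minObsExp,
               correlation_mode = correlationMode, dm_scope = dmScope)
    .echoThresholds(th)

    synth <- NULL; promoters <- NULL; truth <- NULL; seed <- NA
    if (is(x, "GeneratorConfig")) {
        what <- c("expression", "methylation", "h3k4", "qpcr",
                  if (scanPromoters) "promoters")
        synth <- generateSynthData(x, what = what)
        seed <- x@seed
    } else if (is(x, "SynthData")) {
        synth <- x
        seed <- x@config@seed
    }
    if (!is.null(synth)) {
        exprSE <- exprData(synth); methSE <- methData(synth)
        h3k4SE <- h3k4Data(synth); truth <- truthTable(synth)
        if (length(promoterSet(synth))) promoters <- promoterSet(synth)
    } else {
        req <- c("expression", "design", "methylation", "promoters")
        if (!is.list(x) || !all(req %in% names(x)))
            stop("'x' must be a GeneratorConfig, SynthData, or a list of ",
                 "paths with elements ", paste(req, collapse = ", "))
        exprSE <- readExpressionTable(x$expression, x$design)
        methSE <- readQuantTable(x$methylation, x$design,
                                 c("bound", "input"))
        h3k4SE <- if (!is.null(x$h3k4))
            readQuantTable(x$h3k4, x$design, c("chip", "input")) else NULL
        promoters <- readPromotersFasta(x$promoters)
    }
    genes <- rownames(exprSE)
    if (!is.null(promoters) && !setequal(names(promoters), genes))
        stop("gene universe mismatch between promoters and expression: ",
             paste(union(setdiff(names(promoters), genes),
                         setdiff(genes, names(promoters))),
                   collapse = ", "))
    if (!setequal(rownames(methSE), genes))
        stop("gene universe mismatch between methylation and expression")
    stages <- levels(SummarizedExperiment::colData(exprSE)$stage)
    finalStage <- stages[length(stages)]

    if (length(genes) == 0L) {
        warning("empty gene set; producing empty reports")
        empty <- .buildReport(character(0), list(), character(0), "common")
        emptyH <- .buildReport(character(0), list(), character(0), "hcc")
        manifest <- list(thresholds = th, seed = seed,
                         counts = list(common = empty@counts,
                                       hcc = emptyH@counts))
        if (!is.null(outdir)) {
            dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
            writeCascadeReport(empty, file.path(outdir,
                                                "cascade_common.tsv"))
            writeCascadeReport(emptyH, file.path(outdir, "cascade_hcc.tsv"))
        }
        return(list(common = empty, hcc = emptyH, manifest = manifest,
                    synth = synth))
    }

    ## CpG-island annotation
    islands <- NULL
    if (!is.null(promoters)) {
        islands <- lapply(as.character(promoters), findCpGIslands,
                          criteria = cgiCriteria)
        names(islands) <- names(promoters)
        cgiFlags <- vapply(islands, function(ir) length(ir) > 0L,
                           logical(1L))[genes]
    } else {
        cgiFlags <- setNames(truth$cgi_present, truth$gene_id)[genes]
    }

    ## stage-wise differential expression and the two DEG sets
    de <- lapply(stages, function(s)
        stageDE(exprSE, s, fcThreshold = fcThreshold, alpha = alpha))
    names(de) <- stages
    degCommon <- commonTrendGenes(de)
    deUnique <- uniqueStageDegs(de, finalStage)

    ## methylation quantitation, thresholding, per-stage DM
    controlGenes <- controlMethylationFilter(methSE, methThreshold)
    dm <- lapply(stages, function(s) dmTest(methSE, s))
    names(dm) <- stages
    correlations <- exprOmicsCorrelation(exprSE, methSE,
        axis = "methylation", mode = correlationMode)
    if (correlationMode == "per-stage")
        corForCascade <- correlations[correlations$stage == finalStage, ]
    else corForCascade <- correlations

    ## H3K4me3 enrichment profile
    h3k4Enrichment <- NULL
    if (!is.null(h3k4SE)) {
        h3k4Enrichment <- lapply(stages, function(s)
            h3k4FoldEnrichment(h3k4SE, s))
        names(h3k4Enrichment) <- stages
    }

    common <- commonGeneCascade(degCommon, cgiFlags, controlGenes, dm,
                                corForCascade, dmAlpha = dmAlpha,
                                dmScope = dmScope)
    dmCalls <- dmCallMicroarray(dmLog2Ratios(methSE, finalStage),
                                setNames(dm[[finalStage]]$p,
                                         dm[[finalStage]]$gene),
                                fcThreshold = dmFcThreshold,
                                alpha = dmAlpha)
    methFinal <- setNames(dm[[finalStage]]$disease_mean,
                          dm[[finalStage]]$gene)
    hcc <- hccUniqueCascade(deUnique, dmCalls, methFinal,
                            methThreshold = methThreshold)

    manifest <- list(
        package_version = as.character(utils::packageVersion("methcascade")),
        seed = seed, thresholds = th, stages = stages,
        n_genes = length(genes),
        counts = list(common = as.list(filterCounts(common)),
                      hcc = as.list(filterCounts(hcc))),
        h3k4_pass_counts = if (!is.null(h3k4Enrichment))
            lapply(h3k4Enrichment, function(e)
                length(h3k4Filter(e, h3k4Threshold))) else NULL,
        timestamp = format(Sys.time(), tz = "UTC"))

    if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        wf <- function(fun, obj, name, ...) {
            fun(obj, file.path(outdir, name), ...); name }
        files <- c(
            wf(writeExpressionTable, exprSE, "expression.tsv"),
            wf(writeDesignTable, exprSE, "design.tsv"),
            wf(writeQuantTable, methSE, "methylation.tsv"),
            if (!is.null(h3k4SE))
                wf(writeQuantTable, h3k4SE, "h3k4.tsv",
                   quantities = c("chip", "input")),
            if (!is.null(promoters))
                wf(writePromotersFasta, promoters, "promoters.fasta"),
            if (!is.null(islands))
                wf(writeIslandsBed, islands, "islands.bed"),
            vapply(stages, function(s) wf(function(o, f)
                utils::write.table(o, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE),
                de[[s]], paste0("de_", s, ".tsv")), character(1L)),
            vapply(stages, function(s) wf(function(o, f)
                utils::write.table(o, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE),
                dm[[s]], paste0("dm_", s, ".tsv")), character(1L)),
            wf(function(o, f) utils::write.table(o, f, sep = "\t",
                quote = FALSE, row.names = FALSE),
               correlations, "correlations.tsv"),
            if (!is.null(truth))
                wf(function(o, f) utils::write.table(o, f, sep = "\t",
                    quote = FALSE, row.names = FALSE),
                   truth, "truth.tsv"),
            wf(writeCascadeReport, common, "cascade_common.tsv"),
            wf(writeCascadeReport, hcc, "cascade_hcc.tsv"))
        manifest$files <- as.list(tools::md5sum(file.path(outdir, files)))
        names(manifest$files) <- files
        jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    list(common = common, hcc = hcc, de = de, dm = dm,
         correlations = correlations, h3k4Enrichment = h3k4Enrichment,
         cgiFlags = cgiFlags, manifest = manifest, synth = synth)
}
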
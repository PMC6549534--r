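## Synthetic multi-omics generator.
##
## Emulates a three-stage disease-progression study: two arms (control,
## disease), ordered stages, n replicates per arm x stage; log2-scale
## expression with planted per-stage effects, MeDIP-style bound/input
## methylation with planted progressive hypomethylation in driver genes,
## H3K4me3 chip/input enrichment strongest at the earliest stage, and
## qPCR Ct tables whose 2^-ddCt recovers the planted fold change.
##
## All randomness flows from one root seed through per-table substreams
## (drawn once from the root), so generating or skipping one table never
## perturbs another.

#' Construct a synthetic-data generator configuration
#'
#' Defaults describe the study design the cascades target: 3 stages
#' (6, 12, 20 weeks) x 2 arms x 4 replicates, 200 genes of which 5 are
#' drivers (progressively over-expressed, log2FC 2/3/4 - clearly beyond
#' the twofold selection boundary at every stage - and
#' progressively hypomethylated by the relative decreases 23/31/45
#' percent from a 60 percent control baseline), 10 are passengers
#' (expression change only) and 10 shift methylation and expression only
#' at the final stage.  H3K4me3 enrichment of affected genes is maximal
#' at the earliest stage (log2 enrichment 2/1/0.5).
#'
#' @param nGenes number of genes.
#' @param nReplicates replicates per arm and stage.
#' @param stages ordered stage labels, earliest first.
#' @param nDrivers,nPassengers,nLateDM role counts (remainder null).
#' @param exprBaseMean,exprNoiseSD log2 expression baseline and noise sd.
#' @param driverExprLog2FC,passengerExprLog2FC per-stage planted log2
#'   fold changes.
#' @param driverMethControl driver control-arm methylation fraction
#'   (must be at least 0.20).
#' @param driverMethDecrease per-stage relative methylation decreases.
#' @param lateDMBaseMeth,lateDMDelta,lateDMExprLog2FC baseline fraction,
#'   final-stage methylation shift and final-stage expression log2 fold
#'   change of late-shift genes.
#' @param h3k4Log2FC per-stage planted H3K4me3 log2 enrichment
#'   (non-increasing).
#' @param h3k4NoiseSD noise sd on log2 chip/input values.
#' @param methConcentration Beta concentration of methylation noise;
#'   \code{Inf} disables noise.
#' @param qpcrNoiseSD noise sd on Ct values.
#' @param cgiPromoterFraction fraction of genes with CpG-island-positive
#'   promoters.
#' @param promoterLength promoter length in bases (>= 600 when islands
#'   are planted).
#' @param seed root seed (non-negative integer).
#' @return a validated \linkS4class{GeneratorConfig}.
#' @examples
#' cfg <- GeneratorConfig(nGenes = 50, seed = 1)
#' cfg
#' @export
GeneratorConfig <- function(nGenes = 200L, nReplicates = 4L,
        stages = c("6wk", "12wk", "20wk"),
        nDrivers = 5L, nPassengers = 10L, nLateDM = 10L,
        exprBaseMean = 8, exprNoiseSD = 0.25,
        driverExprLog2FC = c(2, 3, 4),
        passengerExprLog2FC = c(2, 2.5, 3),
        driverMethControl = 0.60,
        driverMethDecrease = c(0.23, 0.31, 0.45),
        lateDMBaseMeth = 0.30, lateDMDelta = 0.25,
        lateDMExprLog2FC = -2,
        h3k4Log2FC = c(2, 1, 0.5), h3k4NoiseSD = 0.2,
        methConcentration = 300, qpcrNoiseSD = 0.1,
        cgiPromoterFraction = 0.5, promoterLength = 2000L, seed = 1L) {
    ns <- length(stages)
    rep1 <- function(x) if (length(x) == 1L) rep(x, ns) else x
    new("GeneratorConfig",
        nGenes = as.integer(nGenes), nReplicates = as.integer(nReplicates),
        stages = as.character(stages),
        nDrivers = as.integer(nDrivers), nPassengers = as.integer(nPassengers),
        nLateDM = as.integer(nLateDM),
        exprBaseMean = exprBaseMean, exprNoiseSD = exprNoiseSD,
        driverExprLog2FC = rep1(driverExprLog2FC),
        passengerExprLog2FC = rep1(passengerExprLog2FC),
        driverMethControl = driverMethControl,
        driverMethDecrease = rep1(driverMethDecrease),
        lateDMBaseMeth = lateDMBaseMeth, lateDMDelta = lateDMDelta,
        lateDMExprLog2FC = lateDMExprLog2FC,
        h3k4Log2FC = rep1(h3k4Log2FC), h3k4NoiseSD = h3k4NoiseSD,
        methConcentration = methConcentration, qpcrNoiseSD = qpcrNoiseSD,
        cgiPromoterFraction = cgiPromoterFraction,
        promoterLength = as.integer(promoterLength),
        seed = as.integer(seed))
}

## Fixed-kind seeding for byte-reproducibility across sessions.
.seedRNG <- function(seed) {
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
}

## One substream seed per table, all derived from the root seed.  The
## order of this vector is frozen: new tables append, so adding a
## generator never changes an existing table's stream.
.substreams <- function(config) {
    .seedRNG(config@seed)
    s <- sample.int(2147483646L, 8L)
    names(s) <- c("truth", "promoters", "expression", "methylation",
                  "h3k4", "qpcr", "reserved1", "reserved2")
    s
}

#' Arm/stage/replicate design for a generator configuration
#'
#' Sample ids follow \code{<arm>_<stage>_<replicate>}; columns are
#' ordered controls first, stages ascending, replicates within stage.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return a \link[S4Vectors]{DataFrame} with columns \code{sample_id},
#'   \code{arm}, \code{stage}, \code{replicate}, rownames = sample ids.
#' @export
stageDesignFrame <- function(config) {
    arms <- c("control", "disease")
    grid <- expand.grid(replicate = seq_len(config@nReplicates),
                        stage = config@stages, arm = arms,
                        stringsAsFactors = FALSE)
    sid <- paste(grid$arm, grid$stage, grid$replicate, sep = "_")
    S4Vectors::DataFrame(
        sample_id = sid,
        arm = factor(grid$arm, levels = arms),
        stage = factor(grid$stage, levels = config@stages),
        replicate = as.integer(grid$replicate),
        row.names = sid)
}

#' Generate the planted ground truth
#'
#' Assigns roles (driver / passenger / late_dm / null) to genes at
#' random, flags CpG-island-positive promoters (drivers always are;
#' exactly \code{round(cgiPromoterFraction * nGenes)} genes in total),
#' and records every planted per-stage effect: expression log2 fold
#' change, disease-arm methylation fraction, and H3K4me3 log2
#' enrichment.  Planted fractions are clipped to [0, 1] and clipping is
#' recorded per gene.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return data.frame with one row per gene: \code{gene_id}, \code{role},
#'   \code{cgi_present}, \code{meth_control}, \code{clipped}, and
#'   per-stage columns \code{expr_lfc_<stage>}, \code{meth_<stage>},
#'   \code{h3k4_lfc_<stage>}.
#' @export
generateTruth <- function(config) {
    validObject(config)
    n <- config@nGenes
    stages <- config@stages
    ns <- length(stages)
    .seedRNG(.substreams(config)[["truth"]])
    gene_id <- sprintf("gene%04d", seq_len(n))
    role <- rep("null", n)
    if (n > 0L) {
        perm <- sample.int(n)
        k <- 0L
        take <- function(m) { i <- perm[k + seq_len(m)]; k <<- k + m; i }
        idxD <- take(config@nDrivers)
        idxP <- take(config@nPassengers)
        idxL <- take(config@nLateDM)
        role[idxD] <- "driver"; role[idxP] <- "passenger"
        role[idxL] <- "late_dm"
    } else idxD <- idxP <- idxL <- integer(0)
    ## CGI flags: drivers always positive; remaining flags spread at random
    cgi <- rep(FALSE, n)
    nCGI <- round(config@cgiPromoterFraction * n)
    cgi[idxD] <- TRUE
    extra <- nCGI - length(idxD)
    if (extra > 0L) {
        pool <- setdiff(seq_len(n), idxD)
        cgi[pool[sample.int(length(pool), extra)]] <- TRUE
    }
    ## baseline (control-arm) methylation fraction per gene
    meth_control <- runif(n, 0.05, 0.90)
    meth_control[idxD] <- config@driverMethControl
    meth_control[idxL] <- config@lateDMBaseMeth
    ## planted per-stage values
    expr_lfc <- matrix(0, n, ns)
    meth <- matrix(meth_control, n, ns)
    h3k4_lfc <- matrix(0, n, ns)
    fillRows <- function(m, idx, perStage) {
        if (length(idx))
            m[idx, ] <- matrix(perStage, length(idx), ns, byrow = TRUE)
        m
    }
    expr_lfc <- fillRows(expr_lfc, idxD, config@driverExprLog2FC)
    expr_lfc <- fillRows(expr_lfc, idxP, config@passengerExprLog2FC)
    expr_lfc[idxL, ns] <- config@lateDMExprLog2FC
    meth <- fillRows(meth, idxD,
        config@driverMethControl * (1 - config@driverMethDecrease))
    meth[idxL, ns] <- config@lateDMBaseMeth + config@lateDMDelta
    h3k4_lfc <- fillRows(h3k4_lfc, c(idxD, idxP), config@h3k4Log2FC)
    clipped <- rowSums(meth < 0 | meth > 1) > 0L
    meth <- pmin(pmax(meth, 0), 1)
    out <- data.frame(gene_id = gene_id,
                      role = factor(role, levels = c("driver", "passenger",
                                                     "late_dm", "null")),
                      cgi_present = cgi, meth_control = meth_control,
                      clipped = clipped, stringsAsFactors = FALSE,
                      check.names = FALSE)
    for (j in seq_len(ns)) out[[paste0("expr_lfc_", stages[j])]] <-
        expr_lfc[, j]
    for (j in seq_len(ns)) out[[paste0("meth_", stages[j])]] <- meth[, j]
    for (j in seq_len(ns)) out[[paste0("h3k4_lfc_", stages[j])]] <-
        h3k4_lfc[, j]
    rownames(out) <- gene_id
    out
}

## i.i.d. AT-rich background with post-hoc CpG depletion: each CG
## dinucleotide's G is mutated to A with probability 0.95.
.sampleBackground <- function(len) {
    v <- sample(c("A", "C", "G", "T"), len, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    cg <- which(v[-len] == "C" & v[-1L] == "G")
    if (length(cg)) {
        hit <- cg[runif(length(cg)) < 0.95]
        v[hit + 1L] <- "A"
    }
    v
}

## CpG-rich island segment: tokens are emitted as either an explicit CG
## dinucleotide (p = 0.25) or a uniform single base, giving ~70% G+C and
## an obs/exp CpG ratio well above 1.
.sampleIsland <- function(len) {
    out <- character(0)
    while (sum(nchar(out)) < len) {
        k <- ceiling((len - sum(nchar(out))) / 1.2) + 8L
        tok <- sample(c("CG", "C", "G", "A", "T"), k, replace = TRUE,
                      prob = c(0.25, 0.1875, 0.1875, 0.1875, 0.1875))
        out <- c(out, tok)
    }
    v <- strsplit(paste(out, collapse = ""), "", fixed = TRUE)[[1L]]
    v[seq_len(len)]
}

## Maximum obs/exp CpG ratio over all 500-base windows (0 if none fit).
.maxWindowObsExp <- function(v, width = 500L) {
    w <- .windowCounts(v, width)
    if (length(w$start) == 0L) return(obsExpCpG(paste(v, collapse = "")))
    eff <- width - w$nN
    denom <- as.numeric(w$nC) * as.numeric(w$nG)
    max(ifelse(denom > 0, w$nCG * eff / denom, 0))
}

#' Generate promoter sequences
#'
#' CpG-island-positive genes receive a promoter with a planted 700-base
#' CpG-rich segment (verified to have G+C >= 0.60 and obs/exp CpG >= 0.8;
#' regenerated on failure, at most 100 attempts) at a random position in
#' CpG-depleted background.  CpG-island-negative promoters are pure
#' depleted background, verified post hoc to keep the obs/exp CpG ratio
#' at or below 0.4 in every 500-base window (regenerated on failure).
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param truth ground truth from \code{\link{generateTruth}(config)}.
#' @return a named \link[Biostrings]{DNAStringSet}, one record per gene.
#' @export
generatePromoters <- function(config, truth = generateTruth(config)) {
    validObject(config)
    .seedRNG(.substreams(config)[["promoters"]])
    len <- config@promoterLength
    islandLen <- 700L
    seqs <- vapply(seq_len(nrow(truth)), function(i) {
        if (truth$cgi_present[i]) {
            for (attempt in seq_len(100L)) {
                isl <- .sampleIsland(islandLen)
                s <- paste(isl, collapse = "")
                if (gcContent(s) >= 0.60 && obsExpCpG(s) >= 0.8) break
                if (attempt == 100L)
                    stop("failed to plant a qualifying CpG island in 100 ",
                         "attempts")
            }
            pos <- sample.int(len - islandLen + 1L, 1L)
            bg <- .sampleBackground(len - islandLen)
            v <- append(bg, isl, after = pos - 1L)
        } else {
            for (attempt in seq_len(100L)) {
                v <- .sampleBackground(len)
                if (.maxWindowObsExp(v) <= 0.4) break
                if (attempt == 100L)
                    stop("failed to generate a CpG-depleted promoter in ",
                         "100 attempts")
            }
        }
        paste(v, collapse = "")
    }, character(1L))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- truth$gene_id
    out
}

## Build a SummarizedExperiment over the standard design.
.buildSE <- function(assays, design, gene_id) {
    assays <- lapply(assays, function(m) {
        dimnames(m) <- list(gene_id, design$sample_id)
        m
    })
    SummarizedExperiment::SummarizedExperiment(
        assays = assays, colData = design)
}

## Per-gene x per-sample matrix of planted values looked up from truth
## columns named <prefix>_<stage> (disease arm) with a fixed control
## value per gene.
.plantedMatrix <- function(truth, design, prefix, controlValue) {
    n <- nrow(truth)
    m <- matrix(rep(controlValue, length.out = n), n, nrow(design))
    dis <- which(design$arm == "disease")
    for (j in dis) {
        col <- paste0(prefix, "_", as.character(design$stage[j]))
        m[, j] <- truth[[col]]
    }
    m
}

#' Generate the expression table
#'
#' Each measurement is \code{exprBaseMean} plus the planted per-stage
#' log2 fold change (disease arm only) plus Gaussian noise with sd
#' \code{exprNoiseSD}, on the log2 scale.
#'
#' @inheritParams generatePromoters
#' @return a \link[SummarizedExperiment]{SummarizedExperiment} with assay
#'   \code{log2expr} and the arm/stage/replicate design as colData.
#' @export
generateExpression <- function(config, truth = generateTruth(config)) {
    validObject(config)
    design <- stageDesignFrame(config)
    .seedRNG(.substreams(config)[["expression"]])
    n <- nrow(truth); m <- nrow(design)
    effect <- .plantedMatrix(truth, design, "expr_lfc", 0)
    ## control-arm planted effect is zero for every role
    vals <- config@exprBaseMean + effect +
        matrix(rnorm(n * m, sd = config@exprNoiseSD), n, m)
    .buildSE(list(log2expr = vals), design, truth$gene_id)
}

## Bounded noise around a planted fraction: Beta with mean = fraction and
## the configured concentration; degenerate at the planted value when the
## concentration is infinite or the fraction sits on the boundary.
.betaNoise <- function(meanFrac, concentration) {
    if (!is.finite(concentration)) return(meanFrac)
    out <- meanFrac
    inner <- meanFrac > 0 & meanFrac < 1
    out[inner] <- rbeta(sum(inner), meanFrac[inner] * concentration,
                        (1 - meanFrac[inner]) * concentration)
    out
}

#' Generate the MeDIP-style methylation table
#'
#' Per-gene, per-sample methylation fractions are the planted values
#' (control baseline; disease-arm stage values, which for drivers encode
#' the progressive relative decreases) plus bounded Beta noise, emitted
#' as (bound, input) quantity pairs with \code{bound = fraction * input}
#' and a constant input of 100, so that \code{100 * bound / input}
#' recovers percent methylation.
#'
#' @inheritParams generatePromoters
#' @return a SummarizedExperiment with assays \code{bound} and
#'   \code{input}.
#' @export
generateMethylation <- function(config, truth = generateTruth(config)) {
    validObject(config)
    design <- stageDesignFrame(config)
    .seedRNG(.substreams(config)[["methylation"]])
    planted <- .plantedMatrix(truth, design, "meth", truth$meth_control)
    frac <- matrix(.betaNoise(as.vector(planted), config@methConcentration),
                   nrow(planted), ncol(planted))
    input <- matrix(100, nrow(planted), ncol(planted))
    .buildSE(list(bound = frac * input, input = input), design,
             truth$gene_id)
}

#' Generate the H3K4me3 ChIP-style table
#'
#' Disease-arm log2 chip/input values carry the planted per-stage
#' enrichment (maximal at the earliest stage for affected genes); control
#' values are centred at zero.  Gaussian noise with sd \code{h3k4NoiseSD}
#' is added on the log2 scale, and quantities are emitted as (chip,
#' input) pairs with input fixed at 100.
#'
#' @inheritParams generatePromoters
#' @return a SummarizedExperiment with assays \code{chip} and
#'   \code{input}.
#' @export
generateH3K4me3 <- function(config, truth = generateTruth(config)) {
    validObject(config)
    design <- stageDesignFrame(config)
    .seedRNG(.substreams(config)[["h3k4"]])
    n <- nrow(truth); m <- nrow(design)
    lfc <- .plantedMatrix(truth, design, "h3k4_lfc", 0)
    val <- lfc + matrix(rnorm(n * m, sd = config@h3k4NoiseSD), n, m)
    input <- matrix(100, n, m)
    .buildSE(list(chip = input * 2^val, input = input), design,
             truth$gene_id)
}

#' Generate a qPCR Ct table for one gene
#'
#' Ct values are constructed so that the 2^-ddCt statistic recovers the
#' gene's planted expression fold change in expectation: the reference
#' gene's Ct is constant across arms (up to noise) and the target Ct of
#' disease samples is lowered by the planted log2 fold change at their
#' stage.
#'
#' @inheritParams generatePromoters
#' @param gene gene id to emit Ct values for; defaults to the first
#'   driver (or the first gene when no drivers are planted).
#' @return data.frame with columns \code{sample_id}, \code{arm},
#'   \code{stage}, \code{replicate}, \code{target_ct},
#'   \code{reference_ct}.
#' @export
generateQpcr <- function(config, truth = generateTruth(config),
                         gene = NULL) {
    validObject(config)
    if (nrow(truth) == 0L)
        return(data.frame(sample_id = character(0), arm = character(0),
                          stage = character(0), replicate = integer(0),
                          target_ct = numeric(0), reference_ct = numeric(0)))
    if (is.null(gene)) {
        drivers <- truth$gene_id[truth$role == "driver"]
        gene <- if (length(drivers)) drivers[[1L]] else truth$gene_id[[1L]]
    }
    if (!gene %in% truth$gene_id) stop("unknown gene: ", gene)
    design <- stageDesignFrame(config)
    .seedRNG(.substreams(config)[["qpcr"]])
    m <- nrow(design)
    lfc <- .plantedMatrix(truth[truth$gene_id == gene, , drop = FALSE],
                          design, "expr_lfc", 0)[1L, ]
    refCt <- 20 + rnorm(m, sd = config@qpcrNoiseSD)
    targetCt <- 28 - lfc + rnorm(m, sd = config@qpcrNoiseSD)
    data.frame(sample_id = design$sample_id,
               arm = as.character(design$arm),
               stage = as.character(design$stage),
               replicate = design$replicate,
               target_ct = targetCt, reference_ct = refCt,
               stringsAsFactors = FALSE)
}

#' Generate a complete synthetic multi-omics bundle
#'
#' Runs every generator off the same root seed (independent substreams
#' per table) and returns the bundle with its ground truth.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param what tables to generate; promoter generation is the slowest
#'   step and can be skipped when only the quantitative tables are
#'   needed.
#' @return a \linkS4class{SynthData} object.
#' @examples
#' sd <- generateSynthData(GeneratorConfig(nGenes = 20, nDrivers = 2,
#'     nPassengers = 2, nLateDM = 2, cgiPromoterFraction = 0.5, seed = 7))
#' sd
#' @export
generateSynthData <- function(config,
        what = c("promoters", "expression", "methylation", "h3k4",
                 "qpcr")) {
    validObject(config)
    what <- match.arg(what, several.ok = TRUE)
    truth <- generateTruth(config)
    new("SynthData", config = config, truth = truth,
        promoters = if ("promoters" %in% what)
            generatePromoters(config, truth)
            else Biostrings::DNAStringSet(),
        expression = if ("expression" %in% what)
            generateExpression(config, truth) else NULL,
        methylation = if ("methylation" %in% what)
            generateMethylation(config, truth) else NULL,
        h3k4 = if ("h3k4" %in% what) generateH3K4me3(config, truth)
            else NULL,
        qpcr = if ("qpcr" %in% what) generateQpcr(config, truth)
            else data.frame())
}
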
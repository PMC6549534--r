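## Independent oracles and small fixture builders used across the suite.

## Naive CpG-island oracle: recomputes every window's statistics from
## scratch (no rolling counts) and unions qualifying windows.  Kept
## deliberately independent of the package's scanner internals.
naiveFindIslands <- function(seq, criteria = CgiCriteria()) {
    v <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
    W <- criteria@minLength + 1L
    n <- length(v)
    starts <- integer(0)
    i <- 1L
    while (i + W - 1L <= n) {
        win <- v[i:(i + W - 1L)]
        nN <- sum(win == "N")
        eff <- W - nN
        ok <- FALSE
        if (nN / W <= criteria@maxNFraction && eff > 0L) {
            nC <- sum(win == "C"); nG <- sum(win == "G")
            gc <- (nC + nG) / eff
            nCG <- sum(win[-W] == "C" & win[-1L] == "G")
            oe <- if (nC > 0L && nG > 0L) nCG * eff / (nC * nG) else 0
            ok <- gc > criteria@minGC && oe > criteria@minObsExp
        }
        if (ok) starts <- c(starts, i)
        i <- i + 1L
    }
    if (length(starts) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(start = starts, width = W))
}

## Random test sequence whose G+C content straddles the island criteria.
randomSeq <- function(len, gc = 0.5) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
}

## Hand-built SummarizedExperiment over an explicit design.
makeTestSE <- function(mat, arm, stage, assayNames = "log2expr",
                       extra = NULL) {
    sid <- paste(arm, stage, ave(seq_along(arm),
                                 paste(arm, stage), FUN = seq_along),
                 sep = "_")
    colnames(mat) <- sid
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
    assays <- c(setNames(list(mat), assayNames[1L]), extra)
    SummarizedExperiment::SummarizedExperiment(
        assays = assays,
        colData = S4Vectors::DataFrame(
            sample_id = sid,
            arm = factor(arm, levels = c("control", "disease")),
            stage = factor(stage, levels = unique(stage)),
            replicate = as.integer(ave(seq_along(arm),
                                       paste(arm, stage), FUN = seq_along)),
            row.names = sid))
}

## Hand-built bound/input methylation experiment from a percent matrix
## (input fixed at 100, so bound equals the intended percent).
makeMethSE <- function(pctMat, arm, stage) {
    makeTestSE(pctMat, arm, stage, assayNames = "bound",
               extra = list(input = matrix(100, nrow(pctMat),
                                           ncol(pctMat))))
}

## A small, fast generator configuration used by several tests.
smallConfig <- function(seed = 1L, ...) {
    GeneratorConfig(nGenes = 60, nDrivers = 3, nPassengers = 4,
                    nLateDM = 4, cgiPromoterFraction = 0.5,
                    promoterLength = 1500, seed = seed, ...)
}

## All-null configuration (no planted effects anywhere).
nullConfig <- function(seed = 1L, nGenes = 200, ...) {
    GeneratorConfig(nGenes = nGenes, nDrivers = 0, nPassengers = 0,
                    nLateDM = 0, cgiPromoterFraction = 0.5, seed = seed,
                    ...)
}

## Zero-noise configuration: planted values come through exactly.
noiselessConfig <- function(seed = 1L, ...) {
    GeneratorConfig(exprNoiseSD = 0, methConcentration = Inf,
                    h3k4NoiseSD = 0, qpcrNoiseSD = 0, seed = seed, ...)
}
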
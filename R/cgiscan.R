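## CpG-island scanning under the classical strong-island criteria
## (length > 500 bp, G+C > 55%, observed/expected CpG > 0.65).
##
## The scanner slides a window of exactly minLength + 1 bases with step 1
## (so qualifying islands are strictly longer than minLength), marks
## windows that pass all criteria, and reports maximal unions of
## overlapping qualifying windows.  Counts use cumulative sums so a full
## promoter scan is O(L); a naive per-window recount is the test oracle.

## Coerce a sequence to an uppercase character vector over {A,C,G,T,N}.
.dnaVec <- function(x) {
    if (is(x, "XString") || is(x, "XStringSet")) x <- as.character(x)
    if (!is.character(x) || length(x) != 1L)
        stop("'x' must be a single DNA sequence (character or DNAString)")
    v <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
    bad <- !(v %in% c("A", "C", "G", "T", "N"))
    if (any(bad))
        stop("sequence contains characters outside {A,C,G,T,N}: ",
             paste(unique(v[bad]), collapse = ", "))
    v
}

#' G+C content of a DNA sequence
#'
#' Fraction of G and C bases over the effective length (N bases are
#' excluded from both the counts and the length).
#'
#' @param x a single DNA sequence: character string or
#'   \link[Biostrings]{DNAString}.
#' @return numeric fraction in [0, 1].
#' @examples
#' gcContent("GCGC")  # 1
#' gcContent("ACGT")  # 0.5
#' @export
gcContent <- function(x) {
    v <- .dnaVec(x)
    eff <- sum(v != "N")
    if (eff == 0L)
        stop("sequence is empty or all-N; G+C content is undefined")
    sum(v == "C" | v == "G") / eff
}

#' Observed/expected CpG ratio
#'
#' Returns (N_CpG * L) / (N_C * N_G) where N_CpG counts CG dinucleotides,
#' N_C and N_G count the bases, and L is the effective (N-excluded)
#' length.  The ratio is near 1 for composition-random sequence and
#' depressed genome-wide by CpG decay.  A sequence lacking C or G cannot
#' host a CpG island; its ratio is defined as 0.
#'
#' @inheritParams gcContent
#' @return non-negative numeric ratio.
#' @examples
#' obsExpCpG("ACGT")  # 1 * 4 / (1 * 1) = 4
#' obsExpCpG("CCGG")  # 1 * 4 / (2 * 2) = 1
#' obsExpCpG("AAAA")  # 0 by the degenerate-denominator rule
#' @export
obsExpCpG <- function(x) {
    v <- .dnaVec(x)
    eff <- sum(v != "N")
    if (eff == 0L)
        stop("sequence is empty or all-N; obs/exp CpG is undefined")
    nC <- sum(v == "C"); nG <- sum(v == "G")
    if (nC == 0L || nG == 0L) return(0)
    n <- length(v)
    nCG <- sum(v[-n] == "C" & v[-1L] == "G")
    nCG * eff / (nC * nG)
}

## Per-window counts for all windows of a given width (step 1), via
## cumulative sums.  Returns a list of vectors, one entry per window
## start.  CG dinucleotides are counted over positions i..i+width-2 so a
## dinucleotide belongs to a window iff both bases do.
.windowCounts <- function(v, width) {
    n <- length(v)
    nw <- n - width + 1L
    if (nw < 1L)
        return(list(start = integer(0)))
    csC <- c(0L, cumsum(v == "C"))
    csG <- c(0L, cumsum(v == "G"))
    csN <- c(0L, cumsum(v == "N"))
    csCG <- c(0L, cumsum(v[-n] == "C" & v[-1L] == "G"))
    i <- seq_len(nw)
    list(start = i,
         nC = csC[i + width] - csC[i],
         nG = csG[i + width] - csG[i],
         nN = csN[i + width] - csN[i],
         ## dinucleotide starts i .. i+width-2 lie inside the window
         nCG = csCG[i + width - 1L] - csCG[i])
}

## Which windows qualify under the criteria (vectorized).
.qualifyingWindows <- function(v, criteria) {
    width <- criteria@minLength + 1L
    w <- .windowCounts(v, width)
    if (length(w$start) == 0L) return(integer(0))
    eff <- width - w$nN
    gc <- ifelse(eff > 0L, (w$nC + w$nG) / eff, 0)
    denom <- as.numeric(w$nC) * as.numeric(w$nG)
    oe <- ifelse(denom > 0, w$nCG * eff / denom, 0)
    ok <- (w$nN / width) <= criteria@maxNFraction & eff > 0L &
        gc > criteria@minGC & oe > criteria@minObsExp
    w$start[ok]
}

#' Find CpG islands in a promoter sequence
#'
#' Slides a window of \code{minLength + 1} bases (step 1) along the
#' sequence; a window qualifies when its G+C fraction and
#' observed/expected CpG ratio both strictly exceed their thresholds and
#' its N-base fraction does not exceed \code{maxNFraction}.  Islands are
#' the maximal unions of overlapping qualifying windows; each island is
#' reported with its own recomputed length, G+C fraction and obs/exp
#' ratio (a merged union may dip below the window thresholds, so
#' consumers can re-filter on the reported statistics).
#'
#' @param x a single DNA sequence (character or
#'   \link[Biostrings]{DNAString}).
#' @param criteria a \linkS4class{CgiCriteria} object.
#' @return an \link[IRanges]{IRanges} (1-based, sorted, non-overlapping)
#'   with metadata columns \code{island_length}, \code{gc_fraction} and
#'   \code{obs_exp_ratio}.  Empty when the sequence is shorter than
#'   \code{minLength + 1}.
#' @examples
#' isl <- findCpGIslands(strrep("CG", 300))
#' IRanges::width(isl)  # one island spanning all 600 bases
#' @export
findCpGIslands <- function(x, criteria = CgiCriteria()) {
    stopifnot(is(criteria, "CgiCriteria"))
    v <- .dnaVec(x)
    width <- criteria@minLength + 1L
    starts <- .qualifyingWindows(v, criteria)
    if (length(starts) == 0L) {
        empty <- IRanges::IRanges()
        S4Vectors::mcols(empty) <- S4Vectors::DataFrame(
            island_length = integer(0), gc_fraction = numeric(0),
            obs_exp_ratio = numeric(0))
        return(empty)
    }
    islands <- IRanges::reduce(
        IRanges::IRanges(start = starts, width = width))
    stats <- vapply(seq_along(islands), function(i) {
        sub <- v[IRanges::start(islands)[i]:IRanges::end(islands)[i]]
        eff <- sum(sub != "N")
        nC <- sum(sub == "C"); nG <- sum(sub == "G")
        m <- length(sub)
        nCG <- sum(sub[-m] == "C" & sub[-1L] == "G")
        c(gc = if (eff > 0L) (nC + nG) / eff else 0,
          oe = if (nC > 0L && nG > 0L) nCG * eff / (nC * nG) else 0)
    }, c(gc = 0, oe = 0))
    S4Vectors::mcols(islands) <- S4Vectors::DataFrame(
        island_length = IRanges::width(islands),
        gc_fraction = unname(stats["gc", ]),
        obs_exp_ratio = unname(stats["oe", ]))
    islands
}

#' Flag genes whose promoter contains a CpG island
#'
#' A gene is flagged as epigenetically regulatable when
#' \code{\link{findCpGIslands}} reports at least one island in its
#' promoter.
#'
#' @param promoters a named \link[Biostrings]{DNAStringSet} (or named
#'   character vector) of promoter sequences, one per gene.
#' @param criteria a \linkS4class{CgiCriteria} object.
#' @return named logical vector, one flag per gene.
#' @export
annotateCgiGenes <- function(promoters, criteria = CgiCriteria()) {
    nms <- names(promoters)
    if (length(promoters) == 0L)
        return(setNames(logical(0), character(0)))
    if (is.null(nms) || anyNA(nms) || any(nms == ""))
        stop("'promoters' must be named by gene id")
    if (anyDuplicated(nms))
        stop("duplicate gene ids in 'promoters': ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    seqs <- as.character(promoters)
    vapply(seqs, function(s) length(findCpGIslands(s, criteria)) > 0L,
           logical(1L), USE.NAMES = FALSE) |> setNames(nms)
}

#' Export CpG islands as BED6 records
#'
#' Writes one BED6 line per island: chrom is the gene id (promoters are
#' standalone sequences), coordinates are 0-based half-open, the score is
#' \code{round(1000 * obs_exp_ratio)} capped at 1000, strand is ".".
#'
#' @param islands named list of \link[IRanges]{IRanges} as returned by
#'   \code{\link{findCpGIslands}}, one element per gene.
#' @param file output path.
#' @return the file path, invisibly.
#' @export
writeIslandsBed <- function(islands, file) {
    rows <- lapply(names(islands), function(g) {
        ir <- islands[[g]]
        if (length(ir) == 0L) return(NULL)
        data.frame(chrom = g, start = IRanges::start(ir) - 1L,
                   end = IRanges::end(ir), name = g,
                   score = pmin(1000L, as.integer(round(
                       1000 * S4Vectors::mcols(ir)$obs_exp_ratio))),
                   strand = ".")
    })
    bed <- do.call(rbind, rows)
    if (is.null(bed))
        bed <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), name = character(0),
                          score = integer(0), strand = character(0))
    utils::write.table(bed, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(file)
}

#' Read a BED6 island file written by \code{\link{writeIslandsBed}}
#'
#' @param file path to a BED6 file.
#' @return named list of \link[IRanges]{IRanges}, one element per gene,
#'   with an \code{obs_exp_score} metadata column (the BED score).
#' @export
readIslandsBed <- function(file) {
    bed <- utils::read.table(file, sep = "\t", header = FALSE,
        col.names = c("chrom", "start", "end", "name", "score", "strand"),
        colClasses = c("character", "integer", "integer", "character",
                       "integer", "character"))
    split(seq_len(nrow(bed)), bed$chrom)[unique(bed$chrom)] |>
        lapply(function(i) {
            ir <- IRanges::IRanges(start = bed$start[i] + 1L,
                                   end = bed$end[i])
            S4Vectors::mcols(ir)$obs_exp_score <- bed$score[i]
            ir
        })
}
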
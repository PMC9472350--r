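#' @include AllClasses.R
NULL

#' Copy-number-variation percentage of gain
#'
#' \deqn{CNVPG = (SPC - RPC) / RPC \times 100} where SPC is the subject
#' pattern count and RPC the reference pattern count.  The value is exact;
#' round to 5 decimals for presentation.
#'
#' @param spc Subject pattern count(s), non-negative (vectorized).
#' @param rpc Reference pattern count, positive.
#' @return CNVPG in percent.
#' @examples
#' cnvpg(8137, 8139)          # -0.0245731...
#' round(cnvpg(8128, 8139), 5)  # -0.13515
#' @export
cnvpg <- function(spc, rpc) {
  if (length(rpc) != 1L || rpc <= 0) stop("'rpc' must be a single count > 0")
  if (any(spc < 0)) stop("'spc' must be non-negative")
  (spc - rpc) / rpc * 100
}

#' CNV report table
#'
#' One row per subject sample with its pattern count and CNVPG against the
#' reference count, rounded to 5 decimals for presentation.
#'
#' @param counts Named vector of subject pattern counts.
#' @param rpc Reference pattern count.
#' @return data.frame with columns \code{sample, pattern_count, cnvpg}.
#' @export
cnvReport <- function(counts, rpc) {
  data.frame(sample = if (is.null(names(counts)))
               paste0("sample", seq_along(counts)) else names(counts),
             pattern_count = as.integer(counts),
             cnvpg = round(cnvpg(as.numeric(counts), rpc), 5),
             stringsAsFactors = FALSE)
}

#' Pattern-match counts per chromosome
#'
#' Exact tally of matches per seqname, including zero rows for chromosomes
#' present in the genome but without matches.
#'
#' @param matches [GenomicRanges::GRanges] of detected elements.
#' @param seqids Chromosome names to report; defaults to
#'   \code{seqlevels(matches)}.
#' @return data.frame with columns \code{seqid, count}.
#' @export
countsPerChromosome <- function(matches, seqids = NULL) {
  if (is.null(seqids)) seqids <- seqlevels(matches)
  tab <- table(factor(as.character(seqnames(matches)), levels = seqids))
  data.frame(seqid = seqids, count = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Positional distribution of matches along a chromosome
#'
#' Counts of match start positions per fixed-width bin.  Bin \code{i} covers
#' positions \code{(i-1)*binSize + 1} through \code{i*binSize} (equivalently,
#' the 0-based half-open bin \code{[(i-1)*binSize, i*binSize)}).  Bin totals
#' sum to the number of matches on the chromosome.
#'
#' @param matches [GenomicRanges::GRanges] of detected elements.
#' @param seqid Chromosome to profile.
#' @param binSize Bin width in bases (> 0).
#' @param seqLength Optional chromosome length fixing the number of bins.
#' @return data.frame with columns \code{bin_start} (1-based), \code{bin_end}
#'   and \code{count}.
#' @export
positionalDistribution <- function(matches, seqid, binSize,
                                   seqLength = NA_integer_) {
  if (binSize <= 0) stop("'binSize' must be positive")
  binSize <- as.integer(binSize)
  sel <- matches[as.character(seqnames(matches)) == seqid]
  if (is.na(seqLength)) {
    sl <- seqlengths(matches)[seqid]
    seqLength <- if (!is.na(sl)) sl
                 else if (length(sel)) max(start(sel)) else binSize
  }
  nBins <- max(1L, as.integer(ceiling(seqLength / binSize)))
  bin <- pmin((start(sel) - 1L) %/% binSize + 1L, nBins)
  tab <- table(factor(bin, levels = seq_len(nBins)))
  data.frame(bin_start = (seq_len(nBins) - 1L) * binSize + 1L,
             bin_end = seq_len(nBins) * binSize,
             count = as.integer(tab))
}
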
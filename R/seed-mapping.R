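#' @include AllClasses.R
NULL

#' Map one probe onto a genome
#'
#' Finds every locus where the probe (plus strand) or its reverse complement
#' (minus strand) aligns end-to-end with Levenshtein distance at most
#' \code{delta}.  Qualifying windows have length within \code{delta} of the
#' probe length; clusters of mutually overlapping windows are collapsed to
#' the best-scoring hit (minimum edit distance, ties to the leftmost start).
#' \code{N} in the genome never matches.
#'
#' Sensitivity model: as in index-based read mappers, a window is only
#' reported if it shares an exact \code{anchorLength}-mer with the probe.
#' For 50-mer probes and \code{delta <= 3} this is provably equivalent to an
#' exhaustive scan (an alignment with at most 3 edits must leave one of four
#' 12+ base fragments untouched); at larger \code{delta} the anchor is the
#' sensitivity cap, mirroring the 12-mer index of the mapping stage this
#' function replaces.
#'
#' @param genome DNAStringSet (or character/DNAString) of target sequences.
#' @param probe A single ACGT sequence.
#' @param delta Maximum edit distance (default 20).
#' @param anchorLength Exact-match anchor length (default 12).
#' @return A [GenomicRanges::GRanges] of seeds with metadata column
#'   \code{editDistance}; strand records the probe orientation.
#' @examples
#' g <- c(chr1 = paste0(strrep("A", 100), "ACGTACGTGG", strrep("C", 100)))
#' mapProbe(g, "ACGTACGTGG", delta = 1)
#' @export
mapProbe <- function(genome, probe, delta = 20L, anchorLength = 12L) {
  genome <- .asGenome(genome)
  p <- .asProbeChar(probe)
  delta <- as.integer(delta)
  if (delta >= nchar(p))
    stop("delta must be smaller than the probe length")
  rc <- .revcompChar(p)
  res <- list()
  for (i in seq_along(genome)) {
    txt <- as.character(genome[[i]])
    for (str in c("+", "-")) {
      hits <- .cpp_map_probe(txt, if (str == "+") p else rc, delta,
                             as.integer(anchorLength))
      if (nrow(hits) > 0L)
        res[[length(res) + 1L]] <- GRanges(
          names(genome)[i], IRanges(hits$start, hits$end), strand = str,
          editDistance = hits$dist)
    }
  }
  if (length(res) == 0L)
    return(.emptyGR(names(genome), editDistance = integer()))
  gr <- do.call(c, unname(res))
  seqlevels(gr) <- names(genome)
  gr
}

#' Map a probe set onto a genome
#'
#' Union of [mapProbe()] over all probes, ordered deterministically by
#' (seqname, strand, start, probe).
#'
#' @param genome Target genome (DNAStringSet or character).
#' @param probeset A [ProbeSet-class].
#' @param params A [DetectionParams-class]; only \code{delta} is used here.
#' @param anchorLength Exact-match anchor length (default 12), see
#'   [mapProbe()].
#' @return A [GenomicRanges::GRanges] with metadata columns \code{probe}
#'   (ordinal into the probe set) and \code{editDistance}.
#' @export
mapProbeSet <- function(genome, probeset, params = detectionParams(),
                        anchorLength = 12L) {
  stopifnot(is(probeset, "ProbeSet"), is(params, "DetectionParams"))
  genome <- .asGenome(genome)
  if (params@delta >= probeLength(probeset))
    stop("delta must be smaller than the probe length")
  res <- list()
  for (pi in seq_len(length(probeset))) {
    gr <- mapProbe(genome, as.character(probeset@probes[[pi]]), params@delta,
                   anchorLength)
    if (length(gr) > 0L) mcols(gr)$probe <- pi
    res[[pi]] <- gr
  }
  res <- res[vapply(res, length, integer(1)) > 0L]
  if (length(res) == 0L)
    return(.emptyGR(names(genome), editDistance = integer(),
                    probe = integer()))
  gr <- do.call(c, unname(res))
  seqlevels(gr) <- names(genome)
  o <- order(as.integer(seqnames(gr)), as.integer(strand(gr)),
             start(gr), mcols(gr)$probe)
  gr[o]
}
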
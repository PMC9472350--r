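#' @include AllClasses.R
NULL

#' Expected gap between two probe starts
#'
#' The telescoped sum of adjacent average distances
#' \eqn{d_i + d_{i+1} + \dots + d_{j-1}}; for adjacent probes this is exactly
#' \eqn{d_i}.
#'
#' @param probeset A [ProbeSet-class].
#' @param i,j Probe ordinals with \code{i < j}.
#' @return Expected distance in bases between the starts of probes i and j.
#' @export
expectedGap <- function(probeset, i, j) {
  stopifnot(is(probeset, "ProbeSet"))
  if (i >= j) stop("'i' must be smaller than 'j'")
  if (i < 1L || j > length(probeset)) stop("probe index out of range")
  sum(probeset@adjacentDistances[i:(j - 1L)])
}

# assemble one chain record from seed indices (into `seeds`, chain order
# following the probe order 5'->3')
.chainRecord <- function(seeds, idx, probeset) {
  s <- seeds[idx]
  cum <- .cumOffsets(probeset)
  pr <- mcols(s)$probe
  expg <- diff(cum[pr])
  obs <- abs(diff(start(s)))
  list(seqname = as.character(seqnames(s))[1L],
       strand = as.character(strand(s))[1L],
       seedIdx = idx,
       probes = pr,
       nSeeds = length(idx),
       totalDeviation = sum(abs(expg - obs)),
       footprintStart = min(start(s)),
       footprintEnd = max(end(s)))
}

#' Chain seeds into candidate pattern matches
#'
#' Per chromosome and strand, finds all maximal chains of seeds whose probe
#' ordinals strictly increase along the strand's 5'→3' direction and whose
#' consecutive links each satisfy
#' \eqn{|expectedGap(p_i, p_j) - |start_j - start_i|| \le t}.  On the minus
#' strand probe order runs right to left along the genome.  A chain is
#' maximal when no single seed can be prepended, appended or inserted while
#' keeping every link valid; chains with fewer than \code{m} seeds are
#' discarded.
#'
#' @param seeds Seed [GenomicRanges::GRanges] from [mapProbeSet()] (metadata
#'   column \code{probe} required).
#' @param probeset A [ProbeSet-class].
#' @param params A [DetectionParams-class] supplying \code{m} and \code{t}.
#' @param cap Safety bound on the number of chains enumerated per
#'   chromosome/strand (default 1e5).
#' @return A list of chain records; each has \code{seqname}, \code{strand},
#'   \code{seedIdx} (indices into \code{seeds}, in probe order),
#'   \code{probes}, \code{nSeeds}, \code{totalDeviation} and the seed
#'   footprint.
#' @export
chainSeeds <- function(seeds, probeset, params = detectionParams(),
                       cap = 100000L) {
  stopifnot(is(probeset, "ProbeSet"), is(params, "DetectionParams"))
  if (length(seeds) == 0L) return(list())
  if (is.null(mcols(seeds)$probe)) stop("seeds need a 'probe' metadata column")
  cum <- .cumOffsets(probeset)
  chains <- list()
  key <- paste(as.character(seqnames(seeds)), as.character(strand(seeds)))
  for (grp in unique(key)) {
    idx <- which(key == grp)
    str <- as.character(strand(seeds))[idx[1L]]
    # transform positions so probe order increases with position
    pos <- if (str == "-") -start(seeds)[idx] else start(seeds)[idx]
    o <- order(pos, mcols(seeds)$probe[idx])
    idx <- idx[o]; pos <- pos[o]
    found <- .cpp_chain_seeds(as.integer(pos),
                              as.integer(mcols(seeds)$probe[idx]),
                              as.numeric(cum), params@t, params@m,
                              as.integer(cap))
    for (ch in found)
      chains[[length(chains) + 1L]] <- .chainRecord(seeds, idx[ch], probeset)
  }
  chains
}

#' Infer element boundaries from a chain
#'
#' Anchors the element start on the chain's 5'-most seed (subtracting that
#' probe's average offset from the element start) and the element end on the
#' 3'-most seed (adding the remaining layout through the last probe plus the
#' average tail).  Minus-strand chains are mirrored.  Bounds are clamped to
#' the chromosome.
#'
#' @param chain One chain record from [chainSeeds()].
#' @param probeset A [ProbeSet-class].
#' @param seqlen Chromosome length for clamping (optional).
#' @return Integer vector \code{c(start, end)} (1-based, inclusive).
#' @export
inferElementBounds <- function(chain, probeset, seqlen = NA_integer_) {
  stopifnot(is(probeset, "ProbeSet"))
  k <- probeLength(probeset)
  off <- probeset@offsetElement
  L <- elementLength(probeset)
  firstProbe <- chain$probes[1L]
  lastProbe <- chain$probes[chain$nSeeds]
  if (chain$strand == "-") {
    # rightmost seed carries the lowest probe ordinal
    es <- chain$footprintStart - (L - off[lastProbe] - k)
    ee <- chain$footprintEnd + off[firstProbe]
  } else {
    es <- chain$footprintStart - off[firstProbe]
    ee <- chain$footprintEnd + (L - off[lastProbe] - k)
  }
  es <- max(1, round(es))
  ee <- round(ee)
  if (!is.na(seqlen)) ee <- min(ee, seqlen)
  ee <- max(ee, es)
  c(start = as.integer(es), end = as.integer(ee))
}

#' Reduce overlapping chains to a non-conflicting set
#'
#' Chains sharing any seed, or whose inferred spans overlap on the same
#' chromosome and strand, are resolved greedily in the order (more seeds
#' first, then smaller total deviation, then leftmost start).
#'
#' @param chains Chain list from [chainSeeds()], each carrying
#'   \code{elementStart}/\code{elementEnd} fields (added by
#'   [detectElements()], or by the caller via [inferElementBounds()]).
#' @return The surviving subset of \code{chains}.
#' @export
resolveOverlaps <- function(chains) {
  if (length(chains) == 0L) return(chains)
  if (is.null(chains[[1L]]$elementStart))
    chains <- lapply(chains, function(ch) {
      ch$elementStart <- ch$footprintStart
      ch$elementEnd <- ch$footprintEnd
      ch
    })
  o <- order(-vapply(chains, `[[`, numeric(1), "nSeeds"),
             vapply(chains, `[[`, numeric(1), "totalDeviation"),
             vapply(chains, `[[`, numeric(1), "elementStart"))
  chains <- chains[o]
  kept <- list()
  usedSeeds <- list() # per seqname+strand: seed indices already claimed
  for (ch in chains) {
    grp <- paste(ch$seqname, ch$strand)
    conflict <- FALSE
    if (!is.null(usedSeeds[[grp]])) {
      if (any(ch$seedIdx %in% usedSeeds[[grp]]$idx)) conflict <- TRUE
      if (!conflict &&
          any(ch$elementStart <= usedSeeds[[grp]]$ends &
              ch$elementEnd >= usedSeeds[[grp]]$starts)) conflict <- TRUE
    }
    if (!conflict) {
      kept[[length(kept) + 1L]] <- ch
      usedSeeds[[grp]] <- list(
        idx = c(usedSeeds[[grp]]$idx, ch$seedIdx),
        starts = c(usedSeeds[[grp]]$starts, ch$elementStart),
        ends = c(usedSeeds[[grp]]$ends, ch$elementEnd))
    }
  }
  kept
}

#' Detect elements in a genome
#'
#' The full detection pipeline: map the probe set ([mapProbeSet()]), chain
#' seeds ([chainSeeds()]), infer element bounds ([inferElementBounds()]) and
#' resolve overlaps ([resolveOverlaps()]).  Deterministic for fixed inputs.
#'
#' @param genome Target genome (DNAStringSet or character).
#' @param probeset A [ProbeSet-class].
#' @param params A [DetectionParams-class] (defaults m = 9, t = 700,
#'   delta = 20).
#' @param seeds Optional precomputed seed GRanges from [mapProbeSet()] (used
#'   by [parameterSweep()] to avoid re-mapping).
#' @return A [GenomicRanges::GRanges] of detected elements, sorted by
#'   (seqname, start), with metadata columns \code{nSeeds} and
#'   \code{totalDeviation}.
#' @examples
#' model <- makeElementModel(seed = 1)
#' sim <- plantElements(model, nCopies = 2, backgroundLength = 30000,
#'                      seed = 2)
#' qs <- makeQuerySet(model, n = 10, seed = 3)
#' decoy <- plantElements(model, 0, 20000, seed = 4)$genome
#' ps <- designProbes(qs, decoy)
#' detectElements(sim$genome, ps)
#' @export
detectElements <- function(genome, probeset, params = detectionParams(),
                           seeds = NULL) {
  genome <- .asGenome(genome)
  if (is.null(seeds)) seeds <- mapProbeSet(genome, probeset, params)
  chains <- chainSeeds(seeds, probeset, params)
  lens <- setNames(width(genome), names(genome))
  chains <- lapply(chains, function(ch) {
    b <- inferElementBounds(ch, probeset, lens[[ch$seqname]])
    ch$elementStart <- b[["start"]]
    ch$elementEnd <- b[["end"]]
    ch
  })
  chains <- resolveOverlaps(chains)
  if (length(chains) == 0L)
    return(.emptyGR(names(genome), nSeeds = integer(),
                    totalDeviation = numeric()))
  gr <- GRanges(
    seqnames = vapply(chains, `[[`, character(1), "seqname"),
    ranges = IRanges(vapply(chains, `[[`, integer(1), "elementStart"),
                     vapply(chains, `[[`, integer(1), "elementEnd")),
    strand = vapply(chains, `[[`, character(1), "strand"),
    nSeeds = vapply(chains, `[[`, numeric(1), "nSeeds"),
    totalDeviation = vapply(chains, `[[`, numeric(1), "totalDeviation"))
  seqlevels(gr) <- names(genome)
  gr <- gr[order(as.integer(seqnames(gr)), start(gr))]
  gr
}
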
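#' @include utils.R
NULL

# ---------------------------------------------------------------------------
# AlignedQuerySet
# ---------------------------------------------------------------------------

#' Aligned query set
#'
#' A multiple alignment of the element copies that define the query class
#' (for LINE-1, full-length ORF-intact copies), together with the alignment
#' column ranges of the named ORF regions and of the full element span.
#' Probes are designed from the conserved columns of this alignment.
#'
#' @slot alignment A [Biostrings::DNAStringSet] of equal-width gapped rows
#'   over \{A,C,G,T,-,N\}.
#' @slot orfRanges A named [IRanges::IRanges] of alignment-column ranges, one
#'   per ORF-like region (e.g. \code{ORF1}, \code{ORF2}); non-overlapping and
#'   contained in \code{elementSpan}.
#' @slot elementSpan Single [IRanges::IRanges] giving the column range of the
#'   full element.
#'
#' @exportClass AlignedQuerySet
setClass("AlignedQuerySet",
  slots = c(alignment = "DNAStringSet",
            orfRanges = "IRanges",
            elementSpan = "IRanges"))

setValidity("AlignedQuerySet", function(object) {
  aln <- object@alignment
  if (length(aln) < 2L) return("query set needs at least 2 members")
  if (length(unique(width(aln))) != 1L)
    return("aligned sequences must all have the same length")
  if (length(object@elementSpan) != 1L)
    return("elementSpan must be a single range")
  orf <- object@orfRanges
  if (length(orf) < 1L || is.null(names(orf)) || any(names(orf) == ""))
    return("orfRanges must be a named IRanges with at least one region")
  w <- width(aln)[1L]
  if (start(object@elementSpan) < 1L || end(object@elementSpan) > w)
    return("elementSpan outside the alignment")
  if (any(start(orf) < start(object@elementSpan)) ||
      any(end(orf) > end(object@elementSpan)))
    return("orfRanges must lie within elementSpan")
  if (length(orf) > 1L) {
    o <- orf[order(start(orf))]
    if (any(start(o)[-1L] <= end(o)[-length(o)]))
      return("orfRanges must not overlap")
  }
  TRUE
})

#' Construct an aligned query set
#'
#' @param alignment Equal-width gapped sequences (DNAStringSet or character).
#' @param orfRanges Named [IRanges::IRanges] of ORF column ranges (1-based,
#'   inclusive alignment columns).
#' @param elementSpan Column range of the full element; defaults to the whole
#'   alignment.
#' @return An [AlignedQuerySet-class] object.
#' @examples
#' aln <- c(a = "ACGTACGT", b = "ACGTACGT")
#' AlignedQuerySet(aln, IRanges::IRanges(2, 7, names = "ORF1"))
#' @export
AlignedQuerySet <- function(alignment, orfRanges,
                            elementSpan = NULL) {
  if (is.character(alignment)) alignment <- DNAStringSet(alignment)
  if (is.null(names(alignment)))
    names(alignment) <- paste0("member", seq_along(alignment))
  if (is.null(elementSpan))
    elementSpan <- IRanges(1L, width(alignment)[1L])
  new("AlignedQuerySet", alignment = alignment, orfRanges = orfRanges,
      elementSpan = elementSpan)
}

#' @describeIn AlignedQuerySet-class number of members
#' @param x,object An \code{AlignedQuerySet}.
#' @export
setMethod("length", "AlignedQuerySet", function(x) length(x@alignment))

#' Accessors for AlignedQuerySet
#'
#' @param x An [AlignedQuerySet-class].
#' @return \code{queryAlignment}: the gapped [Biostrings::DNAStringSet];
#'   \code{orfRanges}: the named ORF column ranges; \code{elementSpan}: the
#'   element column range.
#' @export
queryAlignment <- function(x) x@alignment

#' @rdname queryAlignment
#' @export
orfRanges <- function(x) x@orfRanges

#' @rdname queryAlignment
#' @export
elementSpan <- function(x) x@elementSpan

setMethod("show", "AlignedQuerySet", function(object) {
  cat("AlignedQuerySet with", length(object), "members,",
      width(object@alignment)[1L], "columns\n")
  cat("  regions:", paste(sprintf("%s [%d-%d]", names(object@orfRanges),
      start(object@orfRanges), end(object@orfRanges)), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# ProbeSet
# ---------------------------------------------------------------------------

#' Ordered probe set with average layout
#'
#' The probes (conserved k-mers, 5'→3') together with the layout statistics
#' that the chainer compares observed seed spacing against: the average
#' offset of each probe start from the element start (and from the ORF1
#' start), the average distances between consecutive probe starts, and the
#' average tail length from the last probe end to the element end.
#'
#' @slot probes [Biostrings::DNAStringSet] of equal-length ACGT probes.
#' @slot region Character vector naming the source region of each probe.
#' @slot offsetElement Integer average offsets of probe starts from the
#'   element start (0-based offsets: element start + offset = probe start).
#' @slot offsetOrf1 Integer average offsets from the ORF1 start.
#' @slot adjacentDistances Numeric vector \eqn{d_1..d_{P-1}} of average
#'   base-pair gaps between consecutive probe starts.
#' @slot avgTailLength Average bases from the last probe end to element end.
#'
#' @exportClass ProbeSet
setClass("ProbeSet",
  slots = c(probes = "DNAStringSet",
            region = "character",
            offsetElement = "integer",
            offsetOrf1 = "integer",
            adjacentDistances = "numeric",
            avgTailLength = "numeric"))

setValidity("ProbeSet", function(object) {
  p <- object@probes
  if (length(p) < 1L) return("probe set is empty")
  if (length(unique(width(p))) != 1L) return("probes must share one length")
  if (any(grepl("[^ACGT]", as.character(p))))
    return("probe sequences must contain only A, C, G, T")
  np <- length(p)
  if (length(object@region) != np || length(object@offsetElement) != np ||
      length(object@offsetOrf1) != np)
    return("region/offset lengths must match the number of probes")
  if (is.unsorted(object@offsetElement, strictly = TRUE))
    return("probe offsets must be strictly increasing (5'->3' order)")
  if (length(object@adjacentDistances) != np - 1L)
    return("adjacentDistances must have length(probes) - 1 entries")
  if (np > 1L && any(object@adjacentDistances <= 0))
    return("adjacent distances must be positive")
  if (length(object@avgTailLength) != 1L || object@avgTailLength < 0)
    return("avgTailLength must be a single non-negative number")
  TRUE
})

#' Construct a probe set
#'
#' @param probes DNAStringSet or character vector of equal-length probes in
#'   5'→3' order.
#' @param region Source region name per probe.
#' @param offsetElement,offsetOrf1 Average probe-start offsets (bases) from
#'   the element start / ORF1 start.
#' @param adjacentDistances Average gaps between consecutive probe starts.
#' @param avgTailLength Average bases from last probe end to element end.
#' @return A [ProbeSet-class].
#' @export
ProbeSet <- function(probes, region, offsetElement, offsetOrf1 = NULL,
                     adjacentDistances = NULL, avgTailLength = 0) {
  if (is.character(probes)) probes <- DNAStringSet(probes)
  if (is.null(names(probes)))
    names(probes) <- paste0("probe", seq_along(probes))
  offsetElement <- as.integer(round(offsetElement))
  if (is.null(offsetOrf1)) offsetOrf1 <- offsetElement
  offsetOrf1 <- as.integer(round(offsetOrf1))
  if (is.null(adjacentDistances)) adjacentDistances <- diff(offsetElement)
  new("ProbeSet", probes = probes, region = as.character(region),
      offsetElement = offsetElement, offsetOrf1 = offsetOrf1,
      adjacentDistances = as.numeric(adjacentDistances),
      avgTailLength = as.numeric(avgTailLength))
}

#' @describeIn ProbeSet-class number of probes
#' @param x,object A \code{ProbeSet}.
#' @export
setMethod("length", "ProbeSet", function(x) length(x@probes))

#' Accessors for ProbeSet
#'
#' @param x A [ProbeSet-class].
#' @return \code{probeSequences}: DNAStringSet; \code{probeRegions}:
#'   character; \code{probeOffsets}: integer offsets from element start;
#'   \code{adjacentDistances}: numeric gaps; \code{probeLength}: probe k;
#'   \code{avgTailLength} and \code{elementLength}: layout scalars.
#' @export
probeSequences <- function(x) x@probes

#' @rdname probeSequences
#' @export
probeRegions <- function(x) x@region

#' @rdname probeSequences
#' @export
probeOffsets <- function(x) x@offsetElement

#' @rdname probeSequences
#' @export
adjacentDistances <- function(x) x@adjacentDistances

#' @rdname probeSequences
#' @export
probeLength <- function(x) width(x@probes)[1L]

#' @rdname probeSequences
#' @export
avgTailLength <- function(x) x@avgTailLength

#' @rdname probeSequences
#' @export
elementLength <- function(x) {
  x@offsetElement[length(x)] + probeLength(x) + x@avgTailLength
}

# cumulative expected offsets used by the chainer: C[i] - C[j] is the
# expected gap between probe starts j < i
.cumOffsets <- function(probeset) {
  c(0, cumsum(probeset@adjacentDistances))
}

setMethod("show", "ProbeSet", function(object) {
  cat("ProbeSet with", length(object), sprintf("%d-mer", probeLength(object)),
      "probes\n")
  tab <- table(object@region)
  cat("  regions:", paste(names(tab), tab, sep = ":", collapse = ", "), "\n")
  cat("  offsets:", paste(utils::head(object@offsetElement, 6),
      collapse = ", "),
      if (length(object) > 6) "...", "\n")
})

# ---------------------------------------------------------------------------
# DetectionParams
# ---------------------------------------------------------------------------

#' Detection parameters
#'
#' The three tunables of the detector: \code{m}, the minimum number of seeds
#' required to form a pattern match; \code{t}, the tolerance in bases on the
#' deviation between observed and expected inter-seed distances; and
#' \code{delta}, the maximum Levenshtein distance allowed between a probe and
#' a seed.  Defaults (m = 9, t = 700, delta = 20) are the F1-optimal values
#' for 50-mer LINE-1 probes.
#'
#' @slot m Minimum seeds per pattern (integer >= 2).
#' @slot t Distance threshold in bases (> 0).
#' @slot delta Maximum edit distance per probe hit (>= 0, < probe length).
#' @exportClass DetectionParams
setClass("DetectionParams",
  slots = c(m = "integer", t = "integer", delta = "integer"))

setValidity("DetectionParams", function(object) {
  if (length(object@m) != 1L || object@m < 2L)
    return("m must be a single integer >= 2")
  if (length(object@t) != 1L || object@t <= 0L)
    return("t must be a single positive integer")
  if (length(object@delta) != 1L || object@delta < 0L)
    return("delta must be a single non-negative integer")
  TRUE
})

#' @rdname DetectionParams-class
#' @param m,t,delta See slot descriptions.
#' @return A \code{DetectionParams} object.
#' @examples
#' detectionParams()          # defaults m = 9, t = 700, delta = 20
#' detectionParams(m = 14, t = 50, delta = 5)
#' @export
detectionParams <- function(m = 9L, t = 700L, delta = 20L) {
  new("DetectionParams", m = as.integer(m), t = as.integer(t),
      delta = as.integer(delta))
}

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf("DetectionParams: m = %d, t = %d, delta = %d\n",
              object@m, object@t, object@delta))
})

# ---------------------------------------------------------------------------
# ElementModel
# ---------------------------------------------------------------------------

#' Synthetic element model
#'
#' A generative model of a LINE-1-like element class: a consensus sequence
#' (~6 kb) tiled by the canonical regions (5'UTR, ORF1, inter-ORF, ORF2,
#' 3'UTR ending in a poly(A) run), a set of conserved blocks inside the ORFs
#' whose column identity across generated members is guaranteed to stay at or
#' above 95%, and the mutation parameters used to derive members and planted
#' genome copies from the consensus.
#'
#' @slot consensus [Biostrings::DNAString] consensus sequence.
#' @slot regions Named [IRanges::IRanges] tiling the consensus
#'   (\code{UTR5, ORF1, interORF, ORF2, UTR3}).
#' @slot conservedBlocks Named [IRanges::IRanges] of conserved blocks; names
#'   give the enclosing ORF region.
#' @slot mutationRate Per-base substitution probability outside blocks.
#' @slot blockMutationRate Per-base substitution probability inside blocks
#'   (capped per column at 5% of members when building query sets).
#' @slot deletionRate Per-base probability of a 1-base deletion outside
#'   blocks.
#' @slot polyALenRange Integer range of poly(A) tail lengths for planted
#'   copies.
#' @exportClass ElementModel
setClass("ElementModel",
  slots = c(consensus = "DNAString",
            regions = "IRanges",
            conservedBlocks = "IRanges",
            mutationRate = "numeric",
            blockMutationRate = "numeric",
            deletionRate = "numeric",
            polyALenRange = "integer"))

setValidity("ElementModel", function(object) {
  L <- length(object@consensus)
  reg <- object@regions
  need <- c("UTR5", "ORF1", "interORF", "ORF2", "UTR3")
  if (!identical(names(reg), need))
    return(sprintf("regions must be named %s in order",
                   paste(need, collapse = ", ")))
  if (start(reg)[1L] != 1L || end(reg)[length(reg)] != L ||
      any(start(reg)[-1L] != end(reg)[-length(reg)] + 1L))
    return("regions must tile the consensus")
  bl <- object@conservedBlocks
  if (length(bl) < 1L) return("at least one conserved block required")
  if (!all(names(bl) %in% c("ORF1", "ORF2")))
    return("conserved blocks must lie in ORF1 or ORF2")
  for (i in seq_along(bl)) {
    r <- reg[names(bl)[i]]
    if (start(bl)[i] < start(r) || end(bl)[i] > end(r))
      return("conserved blocks must lie inside their ORF region")
  }
  rates <- c(object@mutationRate, object@blockMutationRate,
             object@deletionRate)
  if (any(rates < 0) || any(rates > 1)) return("rates must be in [0, 1]")
  if (length(object@polyALenRange) != 2L ||
      any(object@polyALenRange < 0L) || diff(object@polyALenRange) < 0L)
    return("polyALenRange must be an increasing pair of non-negative ints")
  TRUE
})

setMethod("show", "ElementModel", function(object) {
  cat("ElementModel:", length(object@consensus), "bp consensus,",
      length(object@conservedBlocks), "conserved blocks",
      sprintf("(ORF1: %d, ORF2: %d)\n",
              sum(names(object@conservedBlocks) == "ORF1"),
              sum(names(object@conservedBlocks) == "ORF2")))
  cat(sprintf("  mutation rates: %.3f outside / %.3f inside blocks, deletion %.4f\n",
              object@mutationRate, object@blockMutationRate,
              object@deletionRate))
})
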
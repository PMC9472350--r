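#' @include AllClasses.R
NULL

# ungapped sequence and column -> member coordinate map for one member
.memberCoords <- function(alnRow) {
  chars <- strsplit(as.character(alnRow), "", fixed = TRUE)[[1L]]
  isBase <- chars != "-"
  list(seq = paste(chars[isBase], collapse = ""),
       # member position of each alignment column (position of the base, or
       # of the next base to the right for gap columns)
       colToPos = cumsum(isBase),
       isBase = isBase)
}

#' Per-column conservation of an aligned query set
#'
#' For every alignment column, the fraction of members carrying the modal
#' nucleotide of that column.  Only A, C, G, T compete for the modal base;
#' gaps and N still count in the denominator, so a column must be occupied by
#' a base in most members to score high.  This is deliberate: a probe must
#' exist as a contiguous k-mer in most members.
#'
#' @param query An [AlignedQuerySet-class].
#' @return Numeric vector of fractions in \[0, 1\], one per column.
#' @examples
#' q <- AlignedQuerySet(c("ACGT", "ACGT", "AC-T"),
#'                      IRanges::IRanges(1, 4, names = "ORF1"))
#' columnConservation(q)   # 1, 1, 2/3, 1
#' @export
columnConservation <- function(query) {
  stopifnot(is(query, "AlignedQuerySet"))
  cm <- consensusMatrix(query@alignment)
  bases <- intersect(rownames(cm), c("A", "C", "G", "T"))
  top <- apply(cm[bases, , drop = FALSE], 2L, max)
  as.numeric(top) / length(query)
}

#' Find conserved column blocks
#'
#' Maximal runs of consecutive columns whose conservation is at least
#' \code{minColumnSimilarity} ("at least" is inclusive), keeping runs of at
#' least \code{minBlockLen} columns.
#'
#' @param conservation Numeric vector from [columnConservation()].
#' @param minColumnSimilarity Minimum per-column modal-base fraction
#'   (default 0.95).
#' @param minBlockLen Minimum run length in columns (default 50).
#' @return An [IRanges::IRanges] of column ranges, sorted, non-overlapping.
#' @export
findConservedBlocks <- function(conservation, minColumnSimilarity = 0.95,
                                minBlockLen = 50L) {
  if (length(conservation) == 0L) return(IRanges())
  if (any(conservation < 0 | conservation > 1))
    stop("conservation values must be in [0, 1]")
  ok <- conservation >= minColumnSimilarity
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minBlockLen
  IRanges(starts[keep], ends[keep])
}

#' Extract candidate probe k-mers from conserved blocks
#'
#' Every window of \code{k} columns fully inside a conserved block and fully
#' inside one ORF region yields one candidate: the column-wise modal-base
#' consensus k-mer (ties broken alphabetically).  Windows containing a
#' gap-majority column are dropped, as are windows outside all ORF ranges
#' (probes are extracted exclusively from the ORFs).
#'
#' @param blocks [IRanges::IRanges] from [findConservedBlocks()].
#' @param query An [AlignedQuerySet-class].
#' @param k Probe length in columns (default 50).
#' @return A data.frame with columns \code{column} (window start column),
#'   \code{region} and \code{sequence}.
#' @export
extractCandidates <- function(blocks, query, k = 50L) {
  stopifnot(is(query, "AlignedQuerySet"))
  k <- as.integer(k)
  cm <- consensusMatrix(query@alignment)
  bases <- c("A", "C", "G", "T")
  basesIn <- intersect(rownames(cm), bases)
  sub <- matrix(0L, nrow = 4L, ncol = ncol(cm),
                dimnames = list(bases, NULL))
  sub[basesIn, ] <- cm[basesIn, , drop = FALSE]
  consBase <- bases[apply(sub, 2L, which.max)]  # ties: alphabetical
  gapMajority <- if ("-" %in% rownames(cm)) {
    cm["-", ] > apply(sub, 2L, max)   # more gaps than the top base
  } else rep(FALSE, ncol(cm))

  out <- list()
  for (bi in seq_along(blocks)) {
    bs <- start(blocks)[bi]; be <- end(blocks)[bi]
    if (be - bs + 1L < k) next
    for (ws in bs:(be - k + 1L)) {
      we <- ws + k - 1L
      region <- NA_character_
      for (ri in seq_along(query@orfRanges)) {
        if (ws >= start(query@orfRanges)[ri] &&
            we <= end(query@orfRanges)[ri]) {
          region <- names(query@orfRanges)[ri]
          break
        }
      }
      if (is.na(region)) next
      if (any(gapMajority[ws:we])) next
      out[[length(out) + 1L]] <- data.frame(
        column = ws, region = region,
        sequence = paste(consBase[ws:we], collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(column = integer(), region = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Refine probe candidates
#'
#' The three-step refinement: (1) keep candidates whose exact occurrences in
#' every ungapped query member fall only inside that candidate's own source
#' region (a probe must never hit the other ORF); (2) keep candidates whose
#' exact-match hit count on a decoy genome (both strands) is minimal, all
#' ties at the minimum surviving; (3) greedily select, left to right by
#' alignment column, a maximal set of mutually non-overlapping candidates.
#'
#' @param candidates Candidate data.frame from [extractCandidates()].
#' @param query An [AlignedQuerySet-class].
#' @param decoyGenome Genome used to count background hits (DNAStringSet or
#'   character).
#' @return A [ProbeSet-class] with provisional layout taken from the
#'   alignment columns; refine with [computeLayout()].
#' @export
refineCandidates <- function(candidates, query, decoyGenome) {
  stopifnot(is(query, "AlignedQuerySet"))
  if (nrow(candidates) == 0L) stop("no candidates supplied")
  decoy <- .asGenome(decoyGenome)
  members <- lapply(seq_along(query@alignment),
                    function(i) .memberCoords(query@alignment[[i]]))
  k <- nchar(candidates$sequence[1L])

  # member-coordinate span of each region, per member
  regionSpan <- lapply(members, function(mc) {
    spans <- lapply(seq_along(query@orfRanges), function(ri) {
      cols <- start(query@orfRanges)[ri]:end(query@orfRanges)[ri]
      pos <- mc$colToPos[cols]
      pos <- pos[mc$isBase[cols]]
      if (length(pos) == 0L) c(NA_integer_, NA_integer_)
      else c(min(pos), max(pos))
    })
    names(spans) <- names(query@orfRanges)
    spans
  })

  # Step 1: region specificity against every member (exact occurrences)
  keep1 <- vapply(seq_len(nrow(candidates)), function(ci) {
    pat <- candidates$sequence[ci]
    reg <- candidates$region[ci]
    for (mi in seq_along(members)) {
      st <- .exactHits(pat, members[[mi]]$seq)
      if (length(st) == 0L) next
      span <- regionSpan[[mi]][[reg]]
      if (anyNA(span)) return(FALSE)
      if (any(st < span[1L] | st + nchar(pat) - 1L > span[2L]))
        return(FALSE)
    }
    TRUE
  }, logical(1))
  cand <- candidates[keep1, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no probes survive refinement")

  # Step 2: minimal decoy hit count (exact, both strands)
  decoyChar <- as.character(decoy)
  hits <- vapply(cand$sequence, function(pat) {
    rc <- .revcompChar(pat)
    sum(vapply(decoyChar, function(chrom) {
      length(.exactHits(pat, chrom)) + length(.exactHits(rc, chrom))
    }, numeric(1)))
  }, numeric(1))
  cand <- cand[hits == min(hits), , drop = FALSE]

  # Step 3: greedy left-to-right non-overlapping selection
  cand <- cand[order(cand$column), , drop = FALSE]
  sel <- integer()
  lastEnd <- -Inf
  for (i in seq_len(nrow(cand))) {
    if (cand$column[i] > lastEnd) {
      sel <- c(sel, i)
      lastEnd <- cand$column[i] + k - 1L
    }
  }
  cand <- cand[sel, , drop = FALSE]
  if (nrow(cand) == 0L) stop("no probes survive refinement")

  # provisional layout from alignment columns (consensus coordinates)
  off <- cand$column - start(query@elementSpan)
  orf1col <- start(query@orfRanges)[match("ORF1", names(query@orfRanges))]
  ProbeSet(probes = cand$sequence, region = cand$region,
           offsetElement = off,
           offsetOrf1 = cand$column - orf1col,
           adjacentDistances = diff(off),
           avgTailLength = max(0, end(query@elementSpan) -
                                 (cand$column[nrow(cand)] + k - 1L)))
}

#' Compute the average probe layout from the query set
#'
#' Locates every probe in each ungapped member (exact match first, then a
#' unique approximate match within \code{maxEdit} edits) and replaces the
#' probe set's layout with arithmetic means over the members where the probe
#' was found, rounded to the nearest base: offsets from the element and ORF1
#' starts, gaps between consecutive probe starts, and the tail length from
#' the last probe end to the member end.  Probes located in fewer than half
#' of the members are dropped with a warning.
#'
#' @param probeset A [ProbeSet-class].
#' @param query An [AlignedQuerySet-class].
#' @param maxEdit Maximum edit distance when exact matching fails (default 2).
#' @param minMemberFraction Minimum fraction of members in which a probe must
#'   be located (default 0.5).
#' @return A [ProbeSet-class] with averaged layout.
#' @export
computeLayout <- function(probeset, query, maxEdit = 2L,
                          minMemberFraction = 0.5) {
  stopifnot(is(probeset, "ProbeSet"), is(query, "AlignedQuerySet"))
  members <- lapply(seq_along(query@alignment),
                    function(i) .memberCoords(query@alignment[[i]]))
  k <- probeLength(probeset)
  np <- length(probeset)
  nm <- length(members)

  orf1col <- start(query@orfRanges)[match("ORF1", names(query@orfRanges))]
  orf1pos <- vapply(members, function(mc) {
    # member position of the first base at or after the ORF1 start column
    p <- mc$colToPos[orf1col]
    if (!mc$isBase[orf1col]) p <- p + 1L
    as.integer(p)
  }, integer(1))

  pos <- matrix(NA_integer_, nrow = nm, ncol = np)
  for (pi in seq_len(np)) {
    pat <- as.character(probeset@probes[[pi]])
    for (mi in seq_len(nm)) {
      h <- matchPattern(pat, members[[mi]]$seq)
      if (length(h) == 0L && maxEdit > 0L)
        h <- matchPattern(pat, members[[mi]]$seq, max.mismatch = maxEdit,
                          with.indels = TRUE)
      if (length(h) == 1L) pos[mi, pi] <- start(h)
    }
  }

  found <- colSums(!is.na(pos)) / nm
  drop <- found < minMemberFraction
  if (any(drop)) {
    warning(sprintf("dropping %d probe(s) located in fewer than %.0f%% of members: %s",
                    sum(drop), 100 * minMemberFraction,
                    paste(names(probeset@probes)[drop], collapse = ", ")))
    pos <- pos[, !drop, drop = FALSE]
  }
  keepIdx <- which(!drop)
  if (length(keepIdx) == 0L) stop("no probes could be located in the members")

  offE <- as.integer(round(colMeans(pos - 1L, na.rm = TRUE)))
  offO <- as.integer(round(colMeans(pos - orf1pos, na.rm = TRUE)))
  dists <- vapply(seq_len(ncol(pos) - 1L), function(i) {
    g <- pos[, i + 1L] - pos[, i]
    round(mean(g, na.rm = TRUE))
  }, numeric(1))
  lastPos <- pos[, ncol(pos)]
  memLen <- vapply(members, function(mc) nchar(mc$seq), integer(1))
  tail <- round(mean(memLen - (lastPos + k - 1L), na.rm = TRUE))

  ProbeSet(probes = as.character(probeset@probes[keepIdx]),
           region = probeset@region[keepIdx],
           offsetElement = offE, offsetOrf1 = offO,
           adjacentDistances = dists, avgTailLength = max(0, tail))
}

#' Design a probe set from an aligned query set
#'
#' Runs the full probe-design pipeline: conserved-column scan, block finding,
#' candidate extraction from the ORFs, three-step refinement against the
#' query members and a decoy genome, and layout averaging.
#'
#' @inheritParams refineCandidates
#' @param k Probe length (default 50).
#' @param minColumnSimilarity Conservation threshold (default 0.95).
#' @param minBlockLen Minimum conserved block length in columns (default 50).
#' @return A [ProbeSet-class] ready for [detectElements()].
#' @export
designProbes <- function(query, decoyGenome, k = 50L,
                         minColumnSimilarity = 0.95, minBlockLen = 50L) {
  cons <- columnConservation(query)
  blocks <- findConservedBlocks(cons, minColumnSimilarity, minBlockLen)
  cand <- extractCandidates(blocks, query, k)
  if (nrow(cand) == 0L) stop("no candidate probes found")
  ps <- refineCandidates(cand, query, decoyGenome)
  computeLayout(ps, query)
}
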
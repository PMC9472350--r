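# independent brute-force oracles used to validate the mapper and chainer

# Exhaustive sliding-window mapper oracle: every window of length within
# delta of the probe length, Levenshtein distance via utils::adist, followed
# by the same canonicalization (per-start best, overlap-cluster collapse)
# written independently and plainly.  Valid as a map_probe oracle for 50-mer
# probes at delta <= 3, where anchored and exhaustive matching coincide.
oracleScanStrand <- function(text, pat, delta) {
  k <- nchar(pat)
  n <- nchar(text)
  hits <- list()
  for (len in max(1, k - delta):(k + delta)) {
    if (len > n) next
    starts <- seq_len(n - len + 1)
    ws <- substring(text, starts, starts + len - 1)
    d <- as.integer(utils::adist(pat, ws))
    ok <- which(d <= delta)
    if (length(ok))
      hits[[length(hits) + 1]] <- data.frame(start = starts[ok],
                                             end = starts[ok] + len - 1,
                                             dist = d[ok])
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), end = integer(), dist = integer()))
  raw <- do.call(rbind, hits)
  # per start: minimum distance, then smallest end
  raw <- raw[order(raw$start, raw$dist, raw$end), ]
  raw <- raw[!duplicated(raw$start), ]
  # transitive overlap clusters; per cluster minimum distance, leftmost
  raw <- raw[order(raw$start), ]
  out <- list()
  i <- 1
  while (i <= nrow(raw)) {
    j <- i
    maxEnd <- raw$end[i]
    while (j < nrow(raw) && raw$start[j + 1] <= maxEnd) {
      j <- j + 1
      maxEnd <- max(maxEnd, raw$end[j])
    }
    cl <- raw[i:j, ]
    best <- cl[order(cl$dist, cl$start), ][1, ]
    out[[length(out) + 1]] <- best
    i <- j + 1
  }
  do.call(rbind, out)
}

# both strands, as a sorted data.frame comparable to mapProbe output
oracleMapProbe <- function(text, pat, delta) {
  plus <- oracleScanStrand(text, pat, delta)
  minus <- oracleScanStrand(text, revcompChr(pat), delta)
  plus$strand <- rep("+", nrow(plus))
  minus$strand <- rep("-", nrow(minus))
  out <- rbind(plus, minus)
  out[order(out$strand, out$start, out$end), , drop = FALSE]
}

# convert a mapProbe GRanges (single chromosome) to the same layout
seedsAsFrame <- function(gr) {
  out <- data.frame(start = BiocGenerics::start(gr),
                    end = BiocGenerics::end(gr),
                    dist = S4Vectors::mcols(gr)$editDistance,
                    strand = as.character(BiocGenerics::strand(gr)))
  out[order(out$strand, out$start, out$end), , drop = FALSE]
}

# ---------------------------------------------------------------------------
# chainer oracle: enumerate every valid chain by depth-first extension, then
# keep chains that cannot be extended by inserting any single seed anywhere
# (including the ends), then filter by minimum length m.
# seeds: data.frame with columns pos, probe (pos on the transformed axis
# where probe order increases with pos).
oracleChains <- function(pos, probe, dists, t, m) {
  n <- length(pos)
  cum <- c(0, cumsum(dists))
  linkOk <- function(i, j) {
    probe[j] > probe[i] && pos[j] > pos[i] &&
      abs((cum[probe[j]] - cum[probe[i]]) - (pos[j] - pos[i])) <= t
  }
  valid <- function(idx) {
    if (length(idx) <= 1) return(TRUE)
    all(vapply(seq_len(length(idx) - 1),
               function(q) linkOk(idx[q], idx[q + 1]), logical(1)))
  }
  # enumerate all valid chains (depth-first over seeds sorted by pos)
  ord <- order(pos, probe)
  chains <- list()
  grow <- function(idx) {
    chains[[length(chains) + 1]] <<- idx
    last <- idx[length(idx)]
    for (v in ord) {
      if (pos[v] > pos[last] && linkOk(last, v)) grow(c(idx, v))
    }
  }
  for (v in ord) grow(v)
  # insertion-maximality
  maximal <- vapply(chains, function(idx) {
    others <- setdiff(seq_len(n), idx)
    for (v in others) {
      slot <- sum(pos[idx] < pos[v] | (pos[idx] == pos[v] & probe[idx] <= probe[v]))
      cand <- append(idx, v, after = slot)
      if (valid(cand)) return(FALSE)
    }
    TRUE
  }, logical(1))
  chains <- chains[maximal & vapply(chains, length, integer(1)) >= m]
  unique(lapply(chains, as.integer))
}

# canonical string form for set comparison of chain lists
chainKeys <- function(chains) sort(vapply(chains, function(x)
  paste(x, collapse = ","), character(1)))
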
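# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.  `seed = NULL` uses the current stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single number or NULL")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Coerce a genome given as character vector, DNAString or DNAStringSet to a
# named DNAStringSet.
.asGenome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    x <- genome
  } else if (is(genome, "DNAString")) {
    x <- DNAStringSet(genome)
  } else if (is.character(genome)) {
    x <- DNAStringSet(genome)
  } else {
    stop("genome must be a DNAStringSet, DNAString or character vector")
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    names(x) <- paste0("seq", seq_along(x))
  x
}

.asProbeChar <- function(probe) {
  p <- toupper(as.character(probe))
  if (length(p) != 1L || nchar(p) < 1L)
    stop("probe must be a single non-empty sequence")
  if (grepl("[^ACGT]", p))
    stop("probe contains non-ACGT characters")
  p
}

.revcompChar <- function(x) {
  as.character(reverseComplement(DNAString(x)))
}

# random ACGT string(s)
.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# sample from a vector without the base-R scalar surprise
.sampleVec <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]

# start positions of exact (possibly overlapping) occurrences of `pat`
.exactHits <- function(pat, subject) {
  out <- integer()
  from <- 1L
  n <- nchar(subject)
  k <- nchar(pat)
  repeat {
    p <- regexpr(pat, substr(subject, from, n), fixed = TRUE)
    if (p < 0L) break
    hit <- from + as.integer(p) - 1L
    out <- c(out, hit)
    from <- hit + 1L
    if (from + k - 1L > n) break
  }
  out
}

# empty GRanges with given seqlevels and typed metadata columns
.emptyGR <- function(seqnames = character(), ...) {
  gr <- GRanges()
  if (length(seqnames)) seqlevels(gr) <- seqnames
  cols <- list(...)
  if (length(cols)) mcols(gr) <- do.call(DataFrame, cols)
  gr
}
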
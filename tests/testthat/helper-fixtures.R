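# shared fixtures, built once per session and memoized

.fx <- new.env(parent = emptyenv())

fxModel <- function() {
  if (is.null(.fx$model)) .fx$model <- makeElementModel(seed = 101)
  .fx$model
}

fxQuerySet <- function() {
  if (is.null(.fx$qs)) .fx$qs <- makeQuerySet(fxModel(), n = 40, seed = 202)
  .fx$qs
}

fxDecoy <- function() {
  if (is.null(.fx$decoy))
    .fx$decoy <- plantElements(fxModel(), 0, 20000, seed = 303)$genome
  .fx$decoy
}

fxProbeSet <- function() {
  if (is.null(.fx$ps)) .fx$ps <- designProbes(fxQuerySet(), fxDecoy())
  .fx$ps
}

# 25 intact copies in 200 kb of background
fxSim <- function() {
  if (is.null(.fx$sim))
    .fx$sim <- plantElements(fxModel(), 25, backgroundLength = 2e5,
                             seed = 404)
  .fx$sim
}

fxSeeds <- function() {
  if (is.null(.fx$seeds))
    .fx$seeds <- mapProbeSet(fxSim()$genome, fxProbeSet(),
                             detectionParams())
  .fx$seeds
}

randomDnaString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# plant `pat` into `text` at 1-based position `at` (overwrite)
plantAt <- function(text, pat, at) {
  paste0(substr(text, 1, at - 1), pat,
         substr(text, at + nchar(pat), nchar(text)))
}

# mutate a sequence with `nSub` substitutions at random positions
mutateSeq <- function(x, nSub) {
  ch <- strsplit(x, "")[[1]]
  idx <- sample(seq_along(ch), nSub)
  bases <- c("A", "C", "G", "T")
  for (i in idx) ch[i] <- sample(setdiff(bases, ch[i]), 1)
  paste(ch, collapse = "")
}

revcompChr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
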
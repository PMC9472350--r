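# a ProbeSet with prescribed adjacent distances, for fabricated seed sets
toyProbeSet <- function(dists, k = 15) {
  n <- length(dists) + 1
  probes <- vapply(seq_len(n), function(i) randomDnaString(k), character(1))
  ProbeSet(probes, region = rep("ORF1", n),
           offsetElement = as.integer(c(0, cumsum(dists))),
           adjacentDistances = dists, avgTailLength = 10)
}

# GRanges seeds from plain vectors (positions are starts)
toySeeds <- function(pos, probe, strand = "+", chrom = "chr1", k = 15) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = k),
                         strand = strand, probe = as.integer(probe),
                         editDistance = 0L)
}

test_that("expected gaps telescope over adjacent distances", {
  set.seed(31)
  ps <- toyProbeSet(c(500, 300, 250))
  expect_equal(expectedGap(ps, 1, 2), 500)
  expect_equal(expectedGap(ps, 1, 3), 800)
  expect_equal(expectedGap(ps, 1, 4), 1050)
  expect_error(expectedGap(ps, 3, 3), "smaller")
  expect_error(expectedGap(ps, 2, 9), "out of range")
})

test_that("the three-seed pattern-match inequality is applied per link", {
  set.seed(32)
  ps <- toyProbeSet(c(500, 300))
  prm <- detectionParams(m = 3, t = 50, delta = 5)
  # observed gaps 520 and 290: |500-520| <= 50 and |300-290| <= 50
  ch <- chainSeeds(toySeeds(c(1000, 1520, 1810), 1:3), ps, prm)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$nSeeds, 3)
  expect_equal(ch[[1]]$totalDeviation, 30)
  # first observed gap 600 breaks the link; remaining chain of 2 < m
  ch2 <- chainSeeds(toySeeds(c(1000, 1600, 1890), 1:3), ps, prm)
  expect_length(ch2, 0)
})

test_that("chaining equals the brute-force maximal-chain oracle", {
  set.seed(33)
  for (i in 1:40) {
    nProbes <- sample(3:6, 1)
    dists <- sample(100:600, nProbes - 1, replace = TRUE)
    ps <- toyProbeSet(dists)
    n <- sample(4:12, 1)
    pos <- sort(sample(1:4000, n))
    probe <- sample(nProbes, n, replace = TRUE)
    t <- sample(c(25, 100, 300, 700), 1)
    m <- sample(2:4, 1)
    got <- chainSeeds(toySeeds(pos, probe), ps,
                      detectionParams(m = m, t = t, delta = 5))
    gotKeys <- chainKeys(lapply(got, function(ch) sort(ch$seedIdx)))
    want <- oracleChains(pos, probe, dists, t, m)
    wantKeys <- chainKeys(want)
    expect_equal(gotKeys, wantKeys, info = paste("instance", i))
  }
})

test_that("minus-strand chains run right to left with the same gaps", {
  set.seed(34)
  ps <- toyProbeSet(c(500, 300))
  prm <- detectionParams(m = 3, t = 50, delta = 5)
  # probe 3 leftmost, probe 1 rightmost; start gaps mirror the layout
  ch <- chainSeeds(toySeeds(c(1000, 1290, 1800), c(3, 2, 1), strand = "-"),
                   ps, prm)
  expect_length(ch, 1)
  expect_equal(ch[[1]]$strand, "-")
  expect_equal(ch[[1]]$probes, 1:3)
  # observed start gaps 510 and 290 against expected 500 and 300
  expect_equal(ch[[1]]$totalDeviation, 20)
})

test_that("overlap resolution prefers longer, tighter, leftmost chains", {
  mk <- function(n, dev, start, seeds, strand = "+") {
    list(seqname = "chr1", strand = strand, seedIdx = seeds,
         probes = seq_along(seeds), nSeeds = n, totalDeviation = dev,
         footprintStart = start, footprintEnd = start + 5000,
         elementStart = start, elementEnd = start + 6000)
  }
  # disjoint chains: both kept
  kept <- resolveOverlaps(list(mk(10, 5, 1000, 1:10),
                               mk(9, 5, 20000, 11:19)))
  expect_length(kept, 2)
  # shared seeds: the 10-seed chain wins over the 9-seed chain
  kept2 <- resolveOverlaps(list(mk(9, 1, 1000, 1:9), mk(10, 50, 1001, 2:11)))
  expect_equal(kept2[[1]]$nSeeds, 10)
  expect_length(kept2, 1)
  # equal seed counts: smaller deviation wins
  kept3 <- resolveOverlaps(list(mk(9, 40, 1000, 1:9), mk(9, 12, 1001, 1:9)))
  expect_length(kept3, 1)
  expect_equal(kept3[[1]]$totalDeviation, 12)
  # same-strand span overlap without shared seeds still conflicts
  kept4 <- resolveOverlaps(list(mk(9, 1, 1000, 1:9), mk(9, 2, 4000, 21:29)))
  expect_length(kept4, 1)
  # opposite strands do not conflict
  kept5 <- resolveOverlaps(list(mk(9, 1, 1000, 1:9),
                                mk(9, 2, 4000, 21:29, strand = "-")))
  expect_length(kept5, 2)
})

test_that("element bounds anchor on probe offsets and clamp to the sequence", {
  ps <- ProbeSet(c(paste0(strrep("A", 49), "C"), paste0(strrep("C", 49), "G")),
                 region = c("ORF1", "ORF2"),
                 offsetElement = c(908L, 5000L),
                 adjacentDistances = 4092, avgTailLength = 100)
  chain <- list(seqname = "chr1", strand = "+", probes = c(1L, 2L),
                nSeeds = 2L, footprintStart = 10001L,
                footprintEnd = 14142L)
  b <- inferElementBounds(chain, ps, seqlen = 100000L)
  # element start = first seed start - offset of probe 1
  expect_equal(b[["start"]], 10001L - 908L)
  # element end = last seed end + (L - offset_last - k)
  expect_equal(b[["end"]], 14142L + (5000 + 50 + 100) - 5000 - 50)
  # clamped at the left edge
  chain$footprintStart <- 100L
  chain$footprintEnd <- 4241L
  expect_equal(inferElementBounds(chain, ps, 100000L)[["start"]], 1L)
})

test_that("match counts are monotone in m and chains stay valid as t grows", {
  ps <- fxProbeSet()
  seeds <- fxSeeds()
  sim <- fxSim()
  counts <- vapply(c(2, 5, 9, 12, 14, 16), function(m) {
    length(detectElements(sim$genome, ps, detectionParams(m = m),
                          seeds = seeds))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[3], 25)   # defaults recover every planted copy

  # chain validity is preserved when t increases: every link of every chain
  # found at a small t still passes the inequality at larger t, and the
  # number of qualifying chains does not drop on this fixture
  cum <- c(0, cumsum(adjacentDistances(ps)))
  for (tLow in c(50, 200)) {
    chLow <- chainSeeds(seeds, ps, detectionParams(t = tLow))
    for (ch in chLow) {
      obs <- abs(diff(BiocGenerics::start(seeds[ch$seedIdx])))
      expg <- diff(cum[ch$probes])
      expect_true(all(abs(expg - obs) <= tLow))
      expect_true(all(abs(expg - obs) <= 700))
    }
    chHigh <- chainSeeds(seeds, ps, detectionParams(t = 700))
    expect_gte(length(chHigh), length(chLow))
  }
})

test_that("detection mirrors under reverse complement of the genome", {
  ps <- fxProbeSet()
  model <- fxModel()
  sim <- plantElements(model, 4, backgroundLength = 5e4, seed = 606)
  det <- detectElements(sim$genome, ps)
  rcGenome <- Biostrings::reverseComplement(sim$genome)
  names(rcGenome) <- names(sim$genome)
  detRC <- detectElements(rcGenome, ps)
  expect_equal(length(det), length(detRC))
  n <- Biostrings::width(sim$genome)[1]
  expect_equal(sort(n - BiocGenerics::end(detRC) + 1),
               sort(BiocGenerics::start(det)))
  expect_equal(sort(n - BiocGenerics::start(detRC) + 1),
               sort(BiocGenerics::end(det)))
  expect_equal(sum(BiocGenerics::strand(detRC) == "+"),
               sum(BiocGenerics::strand(det) == "-"))
})
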
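test_that("column conservation counts the modal base over all members", {
  # unanimous column, gap-containing column, N handling
  q <- AlignedQuerySet(c(rep("ACGT", 9), "AC-N"),
                       IRanges::IRanges(1, 4, names = "ORF1"))
  expect_equal(columnConservation(q), c(1, 1, 0.9, 0.9))

  # 19 C + 1 gap: gaps count in the denominator, never as the modal base
  q2 <- AlignedQuerySet(c(rep("C", 19), "-"),
                        IRanges::IRanges(1, 1, names = "ORF1"))
  expect_equal(columnConservation(q2), 0.95)

  expect_error(AlignedQuerySet("ACGT", IRanges::IRanges(1, 4, names = "ORF1")),
               "at least 2")
  expect_error(AlignedQuerySet(c("ACGT", "ACG"),
                               IRanges::IRanges(1, 3, names = "ORF1")),
               "same length")
})

test_that("column conservation equals a brute-force per-column tally", {
  set.seed(42)
  for (rep in 1:5) {
    mat <- matrix(sample(c("A", "C", "G", "T", "-", "N"), 4 * 30,
                         replace = TRUE, prob = c(rep(0.22, 4), 0.06, 0.06)),
                  nrow = 4)
    q <- AlignedQuerySet(apply(mat, 1, paste, collapse = ""),
                         IRanges::IRanges(1, 30, names = "ORF1"))
    expected <- apply(mat, 2, function(col) {
      max(table(factor(col, levels = c("A", "C", "G", "T")))) / length(col)
    })
    expect_equal(columnConservation(q), unname(expected))
  }
})

test_that("conserved blocks are maximal runs above an inclusive threshold", {
  expect_equal(IRanges::width(findConservedBlocks(rep(1, 120),
                                                  minBlockLen = 50)), 120)
  # 49 high columns flanked by low ones: below minimum length
  cons <- c(0.5, rep(1, 49), 0.5)
  expect_length(findConservedBlocks(cons, minBlockLen = 50), 0)
  # threshold exactly met is included ("at least 95%")
  expect_equal(IRanges::width(findConservedBlocks(rep(0.95, 60), 0.95, 50)),
               60)
  expect_error(findConservedBlocks(c(0.5, 1.2)), "in \\[0, 1\\]")
  # two separated runs stay separate and sorted
  cons2 <- c(rep(1, 55), rep(0.2, 10), rep(0.96, 70))
  bl <- findConservedBlocks(cons2, 0.95, 50)
  expect_equal(BiocGenerics::start(bl), c(1L, 66L))
  expect_equal(BiocGenerics::end(bl), c(55L, 135L))
})

test_that("candidate extraction windows blocks inside ORFs only", {
  set.seed(7)
  base <- randomDnaString(200)
  q <- AlignedQuerySet(c(a = base, b = base),
                       IRanges::IRanges(c(21, 121), c(100, 200),
                                        names = c("ORF1", "ORF2")))
  # block of exactly k inside ORF1 -> one candidate
  bl <- IRanges::IRanges(31, 80)
  cand <- extractCandidates(bl, q, k = 50)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$region, "ORF1")
  expect_equal(cand$sequence, substr(base, 31, 80))
  # 60-column block -> 11 candidates (60 - 50 + 1)
  cand2 <- extractCandidates(IRanges::IRanges(31, 90), q, k = 50)
  expect_equal(nrow(cand2), 11)
  expect_equal(cand2$column, 31:41)
  # block straddling the ORF1 boundary: only windows fully inside kept
  cand3 <- extractCandidates(IRanges::IRanges(41, 110), q, k = 50)
  expect_true(all(cand3$column + 49 <= 100))
  expect_equal(nrow(cand3), 11)   # starts 41..51
  # block in no ORF contributes nothing
  expect_equal(nrow(extractCandidates(IRanges::IRanges(101, 160), q, 50)), 0)
})

test_that("raising the conservation threshold never adds candidates", {
  qs <- fxQuerySet()
  cons <- columnConservation(qs)
  nCand <- vapply(c(0.9, 0.95, 0.975, 1.0), function(th) {
    nrow(extractCandidates(findConservedBlocks(cons, th, 50), qs, 50))
  }, numeric(1))
  expect_true(all(diff(nCand) <= 0))
})

test_that("refinement removes cross-ORF candidates and keeps min decoy hits", {
  set.seed(11)
  kmerA <- randomDnaString(50)
  kmerB <- randomDnaString(50)
  left <- randomDnaString(10)
  mid <- randomDnaString(20)
  right <- randomDnaString(10)
  # kmerA occurs in ORF1 AND ORF2 of every member; kmerB only in ORF2
  seqs <- paste0(left, kmerA, mid, kmerA, kmerB, right)
  q <- AlignedQuerySet(c(a = seqs, b = seqs),
                       IRanges::IRanges(c(11, 81), c(60, 180),
                                        names = c("ORF1", "ORF2")))
  cand <- data.frame(column = c(11, 81, 131),
                     region = c("ORF1", "ORF2", "ORF2"),
                     sequence = c(kmerA, kmerA, kmerB),
                     stringsAsFactors = FALSE)
  ps <- refineCandidates(cand, q, randomDnaString(5000))
  expect_equal(as.character(probeSequences(ps)), kmerB, ignore_attr = TRUE)

  # Step 2: candidate with 3 decoy hits loses to candidate with 0.
  # Members where kmerA and kmerB both live only in ORF2, so Step 1 keeps
  # both and Step 2 decides.
  seqs2 <- paste0(left, randomDnaString(50), mid, kmerA, kmerB, right)
  q2 <- AlignedQuerySet(c(a = seqs2, b = seqs2),
                        IRanges::IRanges(c(11, 81), c(60, 180),
                                         names = c("ORF1", "ORF2")))
  decoy <- randomDnaString(3000)
  for (at in c(100, 1000, 2000)) decoy <- plantAt(decoy, kmerB, at)
  cand2 <- data.frame(column = c(81, 131), region = c("ORF2", "ORF2"),
                      sequence = c(kmerA, kmerB), stringsAsFactors = FALSE)
  ps2 <- refineCandidates(cand2, q2, decoy)
  expect_equal(as.character(probeSequences(ps2)), kmerA, ignore_attr = TRUE)

  # Step 3: overlapping candidates at columns 100 and 130 -> left one kept
  cand3 <- data.frame(column = c(100, 130), region = "ORF2",
                      sequence = c(kmerA, kmerB), stringsAsFactors = FALSE)
  q3 <- AlignedQuerySet(
    c(a = paste0(randomDnaString(99), kmerA, randomDnaString(300)),
      b = paste0(randomDnaString(99), kmerA, randomDnaString(300))),
    IRanges::IRanges(c(1, 50), c(20, 449), names = c("ORF1", "ORF2")))
  ps3 <- refineCandidates(cand3, q3, randomDnaString(2000))
  expect_equal(length(ps3), 1)
  expect_equal(probeOffsets(ps3), 99L)

  expect_error(refineCandidates(cand[0, ], q, "ACGT"), "no candidates")
})

test_that("layout drops probes missing from most members, with a warning", {
  set.seed(17)
  p1 <- randomDnaString(50)
  ghost <- randomDnaString(50)   # never present in the members
  m <- paste0(randomDnaString(60), p1, randomDnaString(90))
  q <- AlignedQuerySet(c(a = m, b = m),
                       IRanges::IRanges(c(41, 150), c(140, 190),
                                        names = c("ORF1", "ORF2")))
  ps <- ProbeSet(c(p1, ghost), region = c("ORF1", "ORF2"),
                 offsetElement = c(60L, 150L))
  expect_warning(out <- computeLayout(ps, q), "dropping")
  expect_equal(length(out), 1)
  expect_equal(probeOffsets(out), 60L)
})

test_that("layout averages probe offsets and gaps across members", {
  set.seed(13)
  p1 <- randomDnaString(50)
  p2 <- randomDnaString(50)
  # member1: p1 at 101, p2 at 601 (gap 500); member2 identical but with a
  # 20-base deletion between the probes (gap 480)
  m1 <- paste0(randomDnaString(100), p1, randomDnaString(450), p2,
               randomDnaString(50))
  ch <- strsplit(m1, "")[[1]]
  ch[301:320] <- "-"
  m2 <- paste(ch, collapse = "")
  q <- AlignedQuerySet(c(a = m1, b = m2),
                       IRanges::IRanges(c(51, 401), c(250, 700),
                                        names = c("ORF1", "ORF2")))
  ps <- ProbeSet(c(p1, p2), region = c("ORF1", "ORF2"),
                 offsetElement = c(100L, 600L))
  out <- computeLayout(ps, q)
  expect_equal(adjacentDistances(out), 490)          # mean(500, 480)
  expect_equal(probeOffsets(out), c(100L, 590L))     # mean starts - 1
  expect_equal(avgTailLength(out), 50)               # both members end 50
                                                     # bases after the probe
})

test_that("the full pipeline recovers the planted probe layout", {
  ps <- fxProbeSet()
  model <- fxModel()
  expect_equal(length(ps), 16)
  expect_equal(sum(probeRegions(ps) == "ORF1"), 5)
  expect_equal(sum(probeRegions(ps) == "ORF2"), 11)
  # probes come from the planted conserved blocks: offsets close to block
  # starts (window 0 of each block; member deletions shift means slightly)
  # (single-base member deletions accumulate ~0.002 per free base, so
  # absolute offsets drift by up to ~12 at the 3' end; gaps barely move)
  blockStarts <- BiocGenerics::start(model@conservedBlocks)
  expect_true(all(abs(probeOffsets(ps) - (blockStarts - 1)) <= 25))
  consGaps <- diff(blockStarts)
  expect_true(all(abs(adjacentDistances(ps) - consGaps) <= 3))
  # ordering invariant
  expect_true(all(diff(probeOffsets(ps)) > 0))
  expect_true(all(adjacentDistances(ps) > 0))
})

test_that("probe sets validate their invariants", {
  expect_error(ProbeSet(c("ACGTN"), "ORF1", 0L), "only A, C, G, T")
  expect_error(ProbeSet(c("ACGTA", "ACGTC"), c("ORF1", "ORF1"),
                        c(10L, 5L)), "strictly increasing")
  expect_error(ProbeSet(c("ACGTA", "ACGT"), c("ORF1", "ORF1"),
                        c(1L, 5L)), "one length")
})
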
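#' @include AllClasses.R
NULL

# evenly place n blocks of width `w` inside [rs, re], optionally widening the
# gap after block `wideAfter` to `wideLen` bases
.placeBlocks <- function(rs, re, n, w, wideAfter = 0L, wideLen = 0L) {
  len <- re - rs + 1L
  totalGap <- len - n * w
  if (totalGap < 0) stop("blocks do not fit in the region")
  nGaps <- n + 1L
  if (wideAfter > 0L) {
    if (wideLen > totalGap) stop("wide gap larger than the gap budget")
    base <- (totalGap - wideLen) / (nGaps - 1L)
    gaps <- rep(base, nGaps)
    gaps[wideAfter + 1L] <- wideLen
  } else {
    gaps <- rep(totalGap / nGaps, nGaps)
  }
  starts <- integer(n)
  pos <- rs
  for (i in seq_len(n)) {
    pos <- pos + round(gaps[i])
    starts[i] <- pos
    pos <- pos + w
  }
  IRanges(starts, width = w)
}

# substitute the characters at idx with a uniformly chosen different base
.mutateChars <- function(chars, idx) {
  if (length(idx) == 0L) return(chars)
  bases <- c("A", "C", "G", "T")
  cur <- match(chars[idx], bases)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  chars
}

#' Build a synthetic element model
#'
#' Creates a LINE-1-like consensus (~6 kb) with the canonical region layout
#' (5'UTR, ORF1, inter-ORF, ORF2, 3'UTR) and a set of conserved blocks inside
#' the ORFs from which 50-mer probes can be recovered.  One inter-block gap
#' in ORF2 is kept wide (default 480 bases after the 9th ORF2 block, i.e.
#' between the 14th and 15th probes of the default 5+11 layout) so that
#' internal-deletion experiments can remove a segment strictly between two
#' probe loci.  Deterministic for a fixed seed.
#'
#' @param seed RNG seed (the consensus is random ACGT).
#' @param utr5Len,orf1Len,interLen,orf2Len,utr3Len Region lengths in bases;
#'   defaults mirror the human LINE-1 layout (908/1017/63/3828/206).
#' @param nBlocksOrf1,nBlocksOrf2 Conserved blocks per ORF (defaults 5 and
#'   11, so 16 probes).
#' @param blockLen Conserved block length in columns (default 60).
#' @param wideGapAfter ORF2 block after which the wide gap sits (default 9).
#' @param wideGapLen Width of that gap (default 480).
#' @param mutationRate Per-base substitution rate outside blocks
#'   (default 0.08; most columns outside blocks must fall below the 95%
#'   conservation threshold so that the conserved blocks are the only
#'   probe source, matching how a real query-class alignment behaves).
#' @param blockMutationRate Per-base substitution rate inside blocks
#'   (default 0.01; capped per column at 5% of members in [makeQuerySet()]).
#' @param deletionRate Per-base 1-bp deletion rate outside blocks
#'   (default 0.002).
#' @param polyALenRange Poly(A) tail length range (default 10-30).
#' @return An [ElementModel-class].
#' @export
makeElementModel <- function(seed = NULL, utr5Len = 908L, orf1Len = 1017L,
                             interLen = 63L, orf2Len = 3828L, utr3Len = 206L,
                             nBlocksOrf1 = 5L, nBlocksOrf2 = 11L,
                             blockLen = 60L, wideGapAfter = 9L,
                             wideGapLen = 480L, mutationRate = 0.08,
                             blockMutationRate = 0.01, deletionRate = 0.002,
                             polyALenRange = c(10L, 30L)) {
  lens <- c(UTR5 = utr5Len, ORF1 = orf1Len, interORF = interLen,
            ORF2 = orf2Len, UTR3 = utr3Len)
  if (any(lens <= 0)) stop("all region lengths must be positive")
  ends <- cumsum(lens)
  regions <- IRanges(c(1L, ends[-length(ends)] + 1L), ends,
                     names = names(lens))
  i1 <- match("ORF1", names(regions)); i2 <- match("ORF2", names(regions))
  b1 <- .placeBlocks(start(regions)[i1], end(regions)[i1],
                     nBlocksOrf1, blockLen)
  b2 <- .placeBlocks(start(regions)[i2], end(regions)[i2],
                     nBlocksOrf2, blockLen, wideGapAfter, wideGapLen)
  blocks <- c(b1, b2)
  names(blocks) <- c(rep("ORF1", nBlocksOrf1), rep("ORF2", nBlocksOrf2))
  consensus <- .withSeed(seed, .randomDna(sum(lens)))
  new("ElementModel", consensus = DNAString(consensus), regions = regions,
      conservedBlocks = blocks, mutationRate = mutationRate,
      blockMutationRate = blockMutationRate, deletionRate = deletionRate,
      polyALenRange = as.integer(polyALenRange))
}

# logical mask of consensus positions inside conserved blocks
.blockMask <- function(model) {
  L <- length(model@consensus)
  mask <- rep(FALSE, L)
  for (i in seq_along(model@conservedBlocks))
    mask[start(model@conservedBlocks)[i]:end(model@conservedBlocks)[i]] <- TRUE
  mask
}

#' Generate an aligned query set from an element model
#'
#' Members are copies of the consensus with substitutions at
#' \code{mutationRate} outside the conserved blocks, substitutions inside
#' blocks capped per column at 5% of members (so the blocks are guaranteed to
#' pass a 95% conservation scan), single-base deletions outside blocks, and a
#' variable-length poly(A) tail.  Because members never gain bases relative
#' to the consensus, alignment columns coincide with consensus coordinates
#' and the returned alignment is consistent by construction.
#'
#' @param model An [ElementModel-class].
#' @param n Number of members (>= 2; default 40).
#' @param seed RNG seed.
#' @return An [AlignedQuerySet-class] with ORF1/ORF2 column ranges.  The true
#'   planted probe-layout coordinates are available via
#'   \code{metadata: attr(x, "blockStarts")}.
#' @export
makeQuerySet <- function(model, n = 40L, seed = NULL) {
  stopifnot(is(model, "ElementModel"))
  if (n < 2L) stop("need at least 2 members")
  .withSeed(seed, {
    cons <- strsplit(as.character(model@consensus), "")[[1L]]
    L <- length(cons)
    inBlock <- .blockMask(model)
    blockCols <- which(inBlock)
    freeCols <- which(!inBlock)
    rows <- matrix(rep(cons, n), nrow = n, byrow = TRUE)

    # block columns: cap substitutions per column at floor(5% of members)
    cap <- floor(0.05 * n)
    for (col in blockCols) {
      cnt <- min(rbinom(1L, n, model@blockMutationRate), cap)
      if (cnt > 0L) {
        mem <- sample.int(n, cnt)
        rows[mem, col] <- .mutateChars(rows[mem, col], seq_len(cnt))
      }
    }
    # free columns: member-wise substitutions and deletions
    for (mi in seq_len(n)) {
      sub <- freeCols[runif(length(freeCols)) < model@mutationRate]
      rows[mi, ] <- .mutateChars(rows[mi, ], sub)
      del <- freeCols[runif(length(freeCols)) < model@deletionRate]
      rows[mi, del] <- "-"
    }
    # poly(A) tail columns, padded with gaps to the longest tail
    tailLens <- .sampleVec(seq(model@polyALenRange[1L],
                               model@polyALenRange[2L]), n)
    maxTail <- max(tailLens)
    tails <- t(vapply(tailLens, function(tl)
      c(rep("A", tl), rep("-", maxTail - tl)), character(maxTail)))
    rows <- cbind(rows, tails)

    aln <- apply(rows, 1L, paste, collapse = "")
    names(aln) <- paste0("member", seq_len(n))
    orf <- model@regions[c("ORF1", "ORF2")]
    qs <- AlignedQuerySet(aln, IRanges(start(orf), end(orf),
                                       names = names(orf)),
                          elementSpan = IRanges(1L, L + maxTail))
    attr(qs, "blockStarts") <- start(model@conservedBlocks)
    qs
  })
}

# one genome copy of the element; returns the sequence string.
# `class`: intact | truncated | deleted | decayed
.makeCopy <- function(model, class = "intact", deletionSize = 396L,
                      truncRange = c(0.1, 0.7), decayedRate = 0.6) {
  cons <- strsplit(as.character(model@consensus), "")[[1L]]
  L <- length(cons)
  inBlock <- .blockMask(model)
  rate <- if (class == "decayed") rep(decayedRate, L)
          else ifelse(inBlock, model@blockMutationRate, model@mutationRate)
  chars <- .mutateChars(cons, which(runif(L) < rate))
  kept <- !(runif(L) < model@deletionRate & !inBlock)
  map <- cumsum(kept)   # consensus coord -> copy coord
  chars <- chars[kept]

  if (class == "truncated") {
    cutCons <- round(runif(1L, truncRange[1L], truncRange[2L]) * L)
    chars <- chars[(map[cutCons] + 1L):length(chars)]
  } else if (class == "deleted") {
    # remove `deletionSize` bases strictly between the two probe loci that
    # flank the widest inter-block gap in ORF2
    b2 <- model@conservedBlocks[names(model@conservedBlocks) == "ORF2"]
    gaps <- start(b2)[-1L] - end(b2)[-length(b2)] - 1L
    gi <- which.max(gaps)
    delStartCons <- end(b2)[gi] + 41L
    if (gaps[gi] < deletionSize + 60L)
      stop("widest ORF2 inter-block gap too small for the requested deletion")
    a <- map[delStartCons - 1L] + 1L
    chars <- chars[-(a:(a + deletionSize - 1L))]
  }
  polyA <- .sampleVec(seq(model@polyALenRange[1L], model@polyALenRange[2L]))
  paste0(paste(chars, collapse = ""), strrep("A", polyA))
}

#' Plant element copies in a random background genome
#'
#' Builds a genome of i.i.d. uniform ACGT background with \code{nCopies}
#' element copies placed at non-overlapping positions (at least
#' \code{minGap} background bases apart), each on a random strand, with
#' integrity classes drawn from \code{classMix}.  Truth records every copy.
#'
#' @param model An [ElementModel-class].
#' @param nCopies Number of copies to plant.
#' @param backgroundLength Total background bases (over all chromosomes).
#' @param classMix Named probabilities over
#'   \code{c("intact","truncated","deleted","decayed")} (default all intact).
#' @param nChroms Number of chromosomes (copies spread round-robin).
#' @param seed RNG seed (fixed seed gives a byte-identical genome).
#' @param minGap Minimum background bases before/between/after copies.
#' @param deletionSize Internal deletion size for class \code{deleted}
#'   (default 396 bases, placed strictly between two consecutive probe loci).
#' @param truncRange Fraction range of the element removed 5' for class
#'   \code{truncated}.
#' @param decayedRate Substitution rate for class \code{decayed}.
#' @param repeatSeq,repeatCount Optionally embed \code{repeatCount} exact
#'   copies of a short decoy sequence in the background (exercises the
#'   minimal-background-hits probe filter).
#' @return List with \code{genome} (DNAStringSet) and \code{truth} (GRanges
#'   with metadata columns \code{class} and \code{copy}).
#' @export
plantElements <- function(model, nCopies, backgroundLength,
                          classMix = c(intact = 1), nChroms = 1L,
                          seed = NULL, minGap = 200L, deletionSize = 396L,
                          truncRange = c(0.1, 0.7), decayedRate = 0.6,
                          repeatSeq = NULL, repeatCount = 0L) {
  stopifnot(is(model, "ElementModel"))
  classes <- c("intact", "truncated", "deleted", "decayed")
  if (!all(names(classMix) %in% classes))
    stop("classMix names must be among: ", paste(classes, collapse = ", "))
  .withSeed(seed, {
    chromOf <- rep(seq_len(nChroms), length.out = nCopies)
    bgPer <- diff(round(seq(0, backgroundLength, length.out = nChroms + 1L)))
    cls <- if (nCopies > 0L)
      sample(names(classMix), nCopies, replace = TRUE, prob = classMix)
    else character()
    seqs <- character(nChroms)
    truthList <- list()
    copyID <- 0L
    for (ci in seq_len(nChroms)) {
      bgLen <- bgPer[ci]
      nC <- sum(chromOf == ci)
      if (bgLen < (nC + 1L) * minGap)
        stop("insufficient room: increase backgroundLength or lower minGap")
      bg <- .randomDna(bgLen)
      if (!is.null(repeatSeq) && repeatCount > 0L && ci == 1L) {
        # overwrite non-overlapping background stretches with the decoy
        rl <- nchar(repeatSeq)
        at <- round(seq(1L, bgLen - rl, length.out = repeatCount))
        for (p in at) substr(bg, p, p + rl - 1L) <- repeatSeq
      }
      if (nC == 0L) { seqs[ci] <- bg; next }
      slack <- bgLen - (nC + 1L) * minGap
      cuts <- sort(sample.int(slack + 1L, nC, replace = TRUE)) - 1L
      insAt <- seq_len(nC) * minGap + cuts   # background offsets, increasing
      strands <- sample(c("+", "-"), nC, replace = TRUE)
      idx <- which(chromOf == ci)
      pieces <- character(2L * nC + 1L)
      pos <- 0L   # genome position so far
      prevBg <- 0L
      for (j in seq_len(nC)) {
        copyID <- copyID + 1L
        cp <- .makeCopy(model, cls[idx[j]], deletionSize, truncRange,
                        decayedRate)
        if (strands[j] == "-") cp <- .revcompChar(cp)
        pieces[2L * j - 1L] <- substr(bg, prevBg + 1L, insAt[j])
        pieces[2L * j] <- cp
        pos <- pos + (insAt[j] - prevBg)
        truthList[[copyID]] <- data.frame(
          chrom = paste0("chr", ci), start = pos + 1L,
          end = pos + nchar(cp), strand = strands[j],
          class = cls[idx[j]], copy = paste0("copy", copyID),
          stringsAsFactors = FALSE)
        pos <- pos + nchar(cp)
        prevBg <- insAt[j]
      }
      pieces[2L * nC + 1L] <- substr(bg, prevBg + 1L, bgLen)
      seqs[ci] <- paste(pieces, collapse = "")
    }
    genome <- DNAStringSet(seqs)
    names(genome) <- paste0("chr", seq_len(nChroms))
    truth <- if (length(truthList)) {
      td <- do.call(rbind, truthList)
      GRanges(td$chrom, IRanges(td$start, td$end), strand = td$strand,
              class = td$class, copy = td$copy)
    } else .emptyGR(class = character(), copy = character())
    seqlevels(truth) <- names(genome)
    list(genome = genome, truth = truth)
  })
}

#' Insert or delete element copies in an existing genome
#'
#' Deletes whole planted spans and/or inserts fresh intact copies, updating
#' the truth annotation (coordinates are shifted accordingly).  The net
#' change in copy number is \code{nInsert - nDelete}.
#'
#' @param genome DNAStringSet genome (from [plantElements()]).
#' @param truth Truth GRanges for \code{genome}.
#' @param model The [ElementModel-class] used to generate fresh copies.
#' @param nInsert,nDelete Copies to add / remove.
#' @param seed RNG seed.
#' @param minGap Minimum distance of an insertion point from existing spans.
#' @return List with updated \code{genome} and \code{truth}.
#' @export
perturbGenome <- function(genome, truth, model, nInsert = 0L, nDelete = 0L,
                          seed = NULL, minGap = 200L) {
  stopifnot(is(genome, "DNAStringSet"), is(truth, "GRanges"))
  if (nDelete > length(truth))
    stop("cannot delete more copies than the genome contains")
  .withSeed(seed, {
    seqs <- setNames(as.character(genome), names(genome))
    td <- data.frame(chrom = as.character(seqnames(truth)),
                     start = start(truth), end = end(truth),
                     strand = as.character(strand(truth)),
                     class = mcols(truth)$class,
                     copy = mcols(truth)$copy, stringsAsFactors = FALSE)
    # deletions: remove whole spans, right to left per chromosome
    if (nDelete > 0L) {
      kill <- sample.int(nrow(td), nDelete)
      for (i in kill[order(-td$start[kill])]) {
        ch <- td$chrom[i]
        w <- td$end[i] - td$start[i] + 1L
        seqs[ch] <- paste0(substr(seqs[ch], 1L, td$start[i] - 1L),
                           substr(seqs[ch], td$end[i] + 1L,
                                  nchar(seqs[ch])))
        after <- td$chrom == ch & td$start > td$end[i]
        td$start[after] <- td$start[after] - w
        td$end[after] <- td$end[after] - w
      }
      td <- td[-kill, , drop = FALSE]
    }
    # insertions: fresh intact copies at points clear of existing spans
    if (nInsert > 0L) {
      for (j in seq_len(nInsert)) {
        ch <- sample(names(seqs), 1L)
        cp <- .makeCopy(model, "intact")
        strandJ <- sample(c("+", "-"), 1L)
        if (strandJ == "-") cp <- .revcompChar(cp)
        len <- nchar(seqs[ch])
        repeat {
          at <- sample.int(len - 1L, 1L)   # insert after position `at`
          near <- td$chrom == ch &
            td$start - minGap <= at & at <= td$end + minGap
          if (!any(near)) break
        }
        seqs[ch] <- paste0(substr(seqs[ch], 1L, at), cp,
                           substr(seqs[ch], at + 1L, len))
        w <- nchar(cp)
        after <- td$chrom == ch & td$start > at
        td$start[after] <- td$start[after] + w
        td$end[after] <- td$end[after] + w
        td <- rbind(td, data.frame(
          chrom = ch, start = at + 1L, end = at + w, strand = strandJ,
          class = "intact",
          copy = paste0("inserted", j), stringsAsFactors = FALSE))
      }
    }
    genome2 <- DNAStringSet(seqs)
    names(genome2) <- names(seqs)
    truth2 <- if (nrow(td)) {
      GRanges(td$chrom, IRanges(td$start, td$end), strand = td$strand,
              class = td$class, copy = td$copy)
    } else .emptyGR(class = character(), copy = character())
    seqlevels(truth2) <- names(genome2)
    list(genome = genome2, truth = truth2)
  })
}
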
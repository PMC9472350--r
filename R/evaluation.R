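#' @include AllClasses.R
NULL

#' Match predictions to truth intervals
#'
#' One-to-one assignment between predicted and true element intervals: a
#' prediction may claim at most one same-strand truth interval with positive
#' overlap, assigned greedily by descending overlap width (ties broken by
#' input order).  Optionally a reciprocal-overlap fraction can be required.
#'
#' @param predictions,truth Strand-annotated [GenomicRanges::GRanges].
#' @param minReciprocalOverlap Minimum overlap as a fraction of BOTH interval
#'   widths (default 0: any positive overlap qualifies).
#' @return Named integer vector \code{c(tp, fp, fn)} with
#'   \code{tp + fp = length(predictions)} and \code{tp + fn = length(truth)}.
#' @export
matchPredictions <- function(predictions, truth, minReciprocalOverlap = 0) {
  stopifnot(is(predictions, "GRanges"), is(truth, "GRanges"))
  if (length(predictions) == 0L || length(truth) == 0L)
    return(c(tp = 0L, fp = length(predictions), fn = length(truth)))
  ov <- suppressWarnings(findOverlaps(predictions, truth))
  if (length(ov) > 0L) {
    w <- width(pintersect(predictions[queryHits(ov)], truth[subjectHits(ov)]))
    if (minReciprocalOverlap > 0) {
      frac <- pmin(w / width(predictions[queryHits(ov)]),
                   w / width(truth[subjectHits(ov)]))
      keep <- frac >= minReciprocalOverlap
      ov <- ov[keep]; w <- w[keep]
    }
  }
  tp <- 0L
  if (length(ov) > 0L) {
    o <- order(-w, queryHits(ov), subjectHits(ov))
    usedP <- logical(length(predictions))
    usedT <- logical(length(truth))
    for (i in o) {
      q <- queryHits(ov)[i]; s <- subjectHits(ov)[i]
      if (!usedP[q] && !usedT[s]) {
        usedP[q] <- TRUE; usedT[s] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  c(tp = tp, fp = length(predictions) - tp, fn = length(truth) - tp)
}

#' Precision, recall and F1
#'
#' \eqn{P = tp/(tp+fp)}, \eqn{R = tp/(tp+fn)} and their harmonic mean
#' \eqn{F1 = 2PR/(P+R)}.  Zero denominators yield 0 so parameter sweeps stay
#' total.
#'
#' @param tp,fp,fn Non-negative counts, or \code{tp} may be the vector
#'   returned by [matchPredictions()].
#' @return Named numeric vector
#'   \code{c(tp, fp, fn, precision, recall, f1)}.
#' @examples
#' precisionRecallF1(1, 1, 1)  # P = R = F1 = 0.5
#' @export
precisionRecallF1 <- function(tp, fp = NULL, fn = NULL) {
  if (length(tp) == 3L && is.null(fp) && is.null(fn)) {
    fp <- tp[["fp"]]; fn <- tp[["fn"]]; tp <- tp[["tp"]]
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f1)
}

#' F1 from printed precision/recall values
#'
#' Convenience for recomputing F1 from already-rounded precision and recall
#' figures (e.g. to check a published table).
#'
#' @param precision,recall Fractions in \[0, 1\].
#' @return The harmonic mean.
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' Parameter sweep over (m, t, delta)
#'
#' Runs detection and evaluation on every grid point and reports precision,
#' recall and F1 per point, plus the F1-argmax (ties resolved toward smaller
#' m, then t, then delta).  The probe mapping is computed once per distinct
#' \code{delta} and reused across the (m, t) sub-grid.
#'
#' @param genome Target genome.
#' @param probeset A [ProbeSet-class].
#' @param truth Truth intervals (GRanges).
#' @param m,t,delta Numeric vectors defining the grid.
#' @param minReciprocalOverlap Passed to [matchPredictions()].
#' @return A data.frame with columns \code{delta, t, m, tp, fp, fn,
#'   precision, recall, f1}, ordered by (delta, t, m), with the argmax row
#'   index in \code{attr(, "best")}.
#' @export
parameterSweep <- function(genome, probeset, truth, m = 9L, t = 700L,
                           delta = 20L, minReciprocalOverlap = 0) {
  if (length(m) == 0L || length(t) == 0L || length(delta) == 0L)
    stop("empty parameter grid")
  genome <- .asGenome(genome)
  grid <- expand.grid(m = sort(unique(m)), t = sort(unique(t)),
                      delta = sort(unique(delta)))
  grid <- grid[order(grid$delta, grid$t, grid$m), , drop = FALSE]
  rows <- vector("list", nrow(grid))
  curDelta <- NA
  seeds <- NULL
  for (i in seq_len(nrow(grid))) {
    prm <- detectionParams(grid$m[i], grid$t[i], grid$delta[i])
    if (is.na(curDelta) || grid$delta[i] != curDelta) {
      seeds <- mapProbeSet(genome, probeset, prm)
      curDelta <- grid$delta[i]
    }
    pred <- detectElements(genome, probeset, prm, seeds = seeds)
    res <- precisionRecallF1(matchPredictions(pred, truth,
                                              minReciprocalOverlap))
    rows[[i]] <- data.frame(delta = grid$delta[i], t = grid$t[i],
                            m = grid$m[i], tp = res[["tp"]],
                            fp = res[["fp"]], fn = res[["fn"]],
                            precision = res[["precision"]],
                            recall = res[["recall"]], f1 = res[["f1"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  best <- order(-out$f1, out$m, out$t, out$delta)[1L]
  attr(out, "best") <- best
  out
}

#' Argmax record of a sweep
#'
#' @param records Sweep data.frame from [parameterSweep()].
#' @return The single best row (highest F1; ties toward smaller m, t, delta).
#' @export
sweepBest <- function(records) {
  if (nrow(records) == 0L) stop("empty sweep")
  records[order(-records$f1, records$m, records$t, records$delta)[1L], ,
          drop = FALSE]
}

#' Write a sweep table
#'
#' Tab-separated table with columns (delta, t, m, precision, recall, f1).
#'
#' @param records Sweep data.frame.
#' @param path Output path.
#' @export
writeSweep <- function(records, path) {
  write.table(records[, c("delta", "t", "m", "precision", "recall", "f1")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
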
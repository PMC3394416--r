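as_states <- function(x) {
  if (inherits(x, "labeled_structure")) return(x$states)
  if (inherits(x, "barrel_structure")) return(structure_states(x))
  if (is.character(x) && length(x) == 1L) {
    return(strsplit(x, "", fixed = TRUE)[[1L]])
  }
  x
}

as_strands <- function(x) {
  if (inherits(x, "labeled_structure")) return(x$strands)
  if (inherits(x, "barrel_structure")) {
    return(cbind(start = x$strands$nu, end = x$strands$kappa))
  }
  if (is.matrix(x)) return(x)
  strand_runs(as_states(x))
}

metrics_report <- function(tp, fp, fn, tn, level, mcc) {
  n <- tp + fp + fn + tn
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(
    q2 = if (n > 0) 100 * (tp + tn) / n else NA_real_,
    specificity = 100 * p, sensitivity = 100 * r,
    f_score = f, mcc = mcc, level = level,
    tp = tp, fp = fp, fn = fn, tn = tn
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %s: Q2=%.1f spec=%.1f sens=%.1f F=%.3f MCC=%.3f\n",
    x$level, x$q2, x$specificity, x$sensitivity, x$f_score, x$mcc))
  invisible(x)
}

#' Per-residue prediction metrics
#'
#' Two-state (strand vs other) confusion metrics with strand as the
#' positive class: Q2 is the percentage of correctly labeled residues,
#' specificity is precision TP/(TP+FP), sensitivity is recall TP/(TP+FN)
#' (both percentages), the F-score combines the two on the unit interval,
#' and MCC is the Matthews correlation with the zero-marginal convention
#' MCC = 0.
#'
#' @param pred,truth Labeled structures, state strings or state vectors of
#'   equal length.
#' @return A \code{metrics_report} (level \code{"residues"}).
#' @export
residue_metrics <- function(pred, truth) {
  p <- as_states(pred) == "S"
  t <- as_states(truth) == "S"
  if (length(p) != length(t)) {
    stop("prediction and truth lengths differ (", length(p), " vs ",
         length(t), ")")
  }
  tp <- sum(p & t); fp <- sum(p & !t); fn <- sum(!p & t); tn <- sum(!p & !t)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  metrics_report(tp, fp, fn, tn, "residues", mcc)
}

#' Per-strand prediction metrics
#'
#' A predicted strand counts as a true positive when it overlaps a not yet
#' matched true strand by at least the given fraction of the shorter of
#' the two (default 50%); matching is greedy in sequence order and each
#' true strand can be matched once. There are no true negatives at the
#' segment level, so the reported MCC is the TN-free limit
#' sqrt(precision * recall) (the Fowlkes-Mallows index).
#'
#' @param pred,truth Labeled structures, barrel structures or strand
#'   interval matrices.
#' @param overlap_rule Minimum overlap fraction of the shorter strand.
#' @return A \code{metrics_report} (level \code{"strands"}).
#' @export
strand_metrics <- function(pred, truth, overlap_rule = 0.5) {
  ps <- as_strands(pred)
  ts <- as_strands(truth)
  matched_t <- rep(FALSE, nrow(ts))
  tp <- 0L
  for (i in seq_len(nrow(ps))) {
    for (j in seq_len(nrow(ts))) {
      if (matched_t[j]) next
      ov <- min(ps[i, 2L], ts[j, 2L]) - max(ps[i, 1L], ts[j, 1L]) + 1L
      shorter <- min(ps[i, 2L] - ps[i, 1L], ts[j, 2L] - ts[j, 1L]) + 1L
      if (ov >= overlap_rule * shorter) {
        matched_t[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  fp <- nrow(ps) - tp
  fn <- nrow(ts) - tp
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  metrics_report(tp, fp, fn, 0L, "strands", sqrt(p * r))
}
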
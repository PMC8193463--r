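# Binary-classification metrics shared by edge-level and graphlet-level
# network comparison: P = TP/(TP+FP), R = TP/(TP+FN), F1 = 2PR/(P+R).

#' Precision, recall and F1 from classification counts
#'
#' Degenerate denominators (no positives predicted, no positives in the
#' gold standard, or P + R = 0) yield a metric value of 0 with the
#' corresponding `degenerate` flag set, rather than NaN.
#'
#' @param tp,fp,fn non-negative counts (vectorized).
#' @param tn optional true-negative count, carried through unchanged.
#' @return A `data.frame` with columns `TP`, `FP`, `FN`, `TN`, `P`, `R`,
#'   `F1`, `degenerate`.
#' @export
classification_metrics <- function(tp, fp, fn, tn = NA_real_) {
  if (any(c(tp, fp, fn) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  n <- max(length(tp), length(fp), length(fn))
  tp <- rep_len(as.numeric(tp), n)
  fp <- rep_len(as.numeric(fp), n)
  fn <- rep_len(as.numeric(fn), n)
  tn <- rep_len(as.numeric(tn), n)
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  degenerate <- (tp + fp == 0) | (tp + fn == 0) | (p + r == 0)
  data.frame(TP = tp, FP = fp, FN = fn, TN = tn,
             P = p, R = r, F1 = f1, degenerate = degenerate)
}

#' Round metrics for report output
#'
#' Three decimal places, round-half-even (the table convention); internal
#' values stay at full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 3).
#' @return Rounded numeric vector.
#' @export
round_metric <- function(x, digits = 3) round(x, digits)

#' Compare two networks edge by edge
#'
#' Edges are keyed by (regulator, target, kind). TP = edges in both
#' networks, FP = edges only in `predicted`, FN = edges only in `gold`. TN
#' is reported only when an explicit comparison universe (e.g. the reference
#' edge set) is supplied.
#'
#' @param predicted,gold `grn` objects.
#' @param universe optional `grn` whose edge set defines the negatives.
#' @return A one-row `data.frame` of counts and metrics
#'   (see [classification_metrics()]).
#' @export
compare_edges <- function(predicted, gold, universe = NULL) {
  stopifnot(is(predicted, "grn"), is(gold, "grn"))
  a <- edge_key(predicted$edges)
  b <- edge_key(gold$edges)
  tp <- length(intersect(a, b))
  fp <- length(setdiff(a, b))
  fn <- length(setdiff(b, a))
  tn <- NA_real_
  if (!is.null(universe)) {
    u <- unique(edge_key(universe$edges))
    tn <- length(setdiff(u, union(a, b)))
  }
  classification_metrics(tp, fp, fn, tn)
}
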
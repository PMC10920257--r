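## Residue-level evaluation statistics: confusion counts, sensitivity,
## precision, Matthews correlation, hypergeometric enrichment p-value, and a
## one-sided Wilcoxon signed-rank comparison between paired method metrics.

#' Confusion counts between a prediction and the true epitope
#'
#' @param prediction,epitope Character vectors of residue keys, both subsets
#'   of `universe`.
#' @param universe All residue keys of the evaluation universe (by default
#'   every residue of the selected antigen chains).
#' @return Named integer vector: tp, fp, fn, tn.
#' @export
confusion <- function(prediction, epitope, universe) {
  prediction <- unique(prediction)
  epitope <- unique(epitope)
  universe <- unique(universe)
  if (length(setdiff(prediction, universe)))
    stop("prediction contains residues outside the universe")
  if (length(setdiff(epitope, universe)))
    stop("epitope contains residues outside the universe")
  tp <- length(intersect(prediction, epitope))
  c(tp = tp,
    fp = length(prediction) - tp,
    fn = length(epitope) - tp,
    tn = length(universe) - length(union(prediction, epitope)))
}

.check_counts <- function(...) {
  v <- c(...)
  if (any(v < 0) || anyNA(v)) stop("counts must be non-negative")
  invisible(v)
}

#' Sensitivity (epitope coverage)
#'
#' TP / (TP + FN); 0 when the denominator is zero.
#' @param tp,fn Non-negative counts.
#' @export
sensitivity <- function(tp, fn) {
  .check_counts(tp, fn)
  if (tp + fn == 0) 0 else tp / (tp + fn)
}

#' Precision (prediction purity)
#'
#' TP / (TP + FP); 0 when the denominator is zero.
#' @param tp,fp Non-negative counts.
#' @export
precision <- function(tp, fp) {
  .check_counts(tp, fp)
  if (tp + fp == 0) 0 else tp / (tp + fp)
}

#' Matthews correlation coefficient
#'
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)); 0 when any marginal
#' factor is zero.
#' @param tp,fp,fn,tn Non-negative counts.
#' @export
mcc <- function(tp, fp, fn, tn) {
  .check_counts(tp, fp, fn, tn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Hypergeometric enrichment p-value
#'
#' Probability that a random residue set of the prediction's size overlaps
#' the epitope at least as well as observed: the upper tail P(X >= k) of a
#' hypergeometric distribution for k successes when n epitope residues are
#' drawn from a universe of N residues of which M are predicted (equivalently
#' by symmetry, M drawn with n marked).
#'
#' @param k Observed overlap (TP).
#' @param n Epitope size.
#' @param N Universe size.
#' @param M Prediction size.
#' @return P(X >= k), in (0, 1]; `k = 0` gives 1.
#' @export
hypergeom_pvalue <- function(k, n, N, M) {
  .check_counts(k, n, N, M)
  if (n > N || M > N) stop("n and M cannot exceed N")
  if (k > min(n, M)) stop("k cannot exceed min(n, M)")
  if (k == 0) return(1)
  stats::phyper(k - 1, m = M, n = N - M, k = n, lower.tail = FALSE)
}

#' One-sided Wilcoxon signed-rank test (a > b)
#'
#' Paired comparison of two methods' per-case metrics. Zero differences are
#' dropped; absolute differences are mid-ranked in case of ties. The exact
#' permutation distribution of the positive-rank sum is used for up to 25
#' non-zero pairs (a shift-algorithm convolution, valid with midranks); a
#' normal approximation with tie correction and continuity correction is
#' used beyond that.
#'
#' @param paired_a,paired_b Equal-length numeric vectors (length >= 5).
#' @return The one-sided p-value for the alternative `a > b`; 1 when all
#'   differences are zero.
#' @export
#' @examples
#' wilcoxon_one_sided(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))  # 1/32
wilcoxon_one_sided <- function(paired_a, paired_b) {
  if (length(paired_a) != length(paired_b))
    stop("paired vectors must have equal length")
  if (length(paired_a) < 5) stop("need at least 5 pairs")
  d <- paired_a - paired_b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= 25) {
    # exact distribution of the positive-rank sum; double the ranks so
    # midranks (x.5) become integers
    r2 <- round(2 * r)
    total <- sum(r2)
    cnt <- c(1, rep(0, total))              # cnt[s+1] = #subsets with sum s
    for (ri in r2) {
      shifted <- c(rep(0, ri), cnt[seq_len(total + 1 - ri)])
      cnt <- cnt + shifted
    }
    p <- sum(cnt[seq(round(2 * w) + 1, total + 1)]) / 2^n
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    p <- stats::pnorm((w - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
  }
  min(max(p, .Machine$double.xmin), 1)
}

#' Evaluate a prediction against the true epitope
#'
#' Computes the full statistics row reported for a prediction: confusion
#' counts, sensitivity, precision, MCC, hypergeometric p-value, prediction
#' size and density (size / universe size).
#'
#' @param prediction A `mimotree` fit, a prediction data frame with a `key`
#'   column, or a character vector of residue keys.
#' @param epitope A [true_epitope()] result or character vector of keys.
#' @param universe Character vector of universe keys; defaults to the
#'   epitope's recorded antigen universe when available.
#' @return Object of class `epitope_eval` (a list with fields tp, fp, fn,
#'   tn, sensitivity, precision, mcc, p_value, size, density, n_universe).
#' @export
evaluate_prediction <- function(prediction, epitope, universe = NULL) {
  pk <- if (inherits(prediction, "mimotree")) prediction$residues
        else if (is.data.frame(prediction)) prediction$key
        else prediction
  ek <- if (inherits(epitope, "true_epitope")) epitope$key
        else if (is.data.frame(epitope)) epitope$key
        else epitope
  if (is.null(universe) && inherits(epitope, "true_epitope"))
    universe <- attr(epitope, "universe")
  if (is.null(universe))
    stop("supply a universe (all antigen residue keys)")
  # predictions may cover chains outside the evaluation universe; clip
  pk <- intersect(unique(pk), universe)
  cf <- confusion(pk, ek, universe)
  out <- list(tp = cf[["tp"]], fp = cf[["fp"]], fn = cf[["fn"]],
              tn = cf[["tn"]],
              sensitivity = sensitivity(cf[["tp"]], cf[["fn"]]),
              precision = precision(cf[["tp"]], cf[["fp"]]),
              mcc = mcc(cf[["tp"]], cf[["fp"]], cf[["fn"]], cf[["tn"]]),
              p_value = hypergeom_pvalue(cf[["tp"]],
                                         n = cf[["tp"]] + cf[["fn"]],
                                         N = length(unique(universe)),
                                         M = cf[["tp"]] + cf[["fp"]]),
              size = cf[["tp"]] + cf[["fp"]],
              density = (cf[["tp"]] + cf[["fp"]]) / length(unique(universe)),
              n_universe = length(unique(universe)))
  class(out) <- "epitope_eval"
  out
}

#' @export
print.epitope_eval <- function(x, ...) {
  cat("Prediction evaluation (universe: ", x$n_universe, " residues)\n",
      sep = "")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  Sensitivity %.2f  Precision %.2f  MCC %.2f\n",
              x$sensitivity, x$precision, x$mcc))
  cat(sprintf("  p-value %.3g  Size %d  Density %.1f%%\n",
              x$p_value, x$size, 100 * x$density))
  invisible(x)
}

#' @export
as.data.frame.epitope_eval <- function(x, ...) {
  data.frame(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn,
             sensitivity = x$sensitivity, precision = x$precision,
             mcc = x$mcc, p_value = x$p_value, size = x$size,
             density = x$density)
}
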
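# Classifier and campaign evaluation: ROC AUC (Mann-Whitney identity),
# confusion metrics at a score threshold, hit-rate arithmetic, potency
# threshold counts and top-N hit-list overlap.

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity `AUC = U / (n1 * n0)` with ties
#' counted one half, where U is the number of (active, decoy) pairs the
#' active out-scores (higher score = more active-like).
#'
#' @param scores numeric vector
#' @param labels vector of 0/1, same length
#' @return AUC in [0, 1]
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  u <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' Confusion metrics at a score threshold
#'
#' A molecule is predicted active when `score >= threshold`. The default
#' threshold 0 is the no-information point of the Bayesian score (an empty
#' bin sum).
#'
#' @param scores numeric vector
#' @param labels 0/1 vector
#' @param threshold decision threshold (default 0)
#' @return object of class `eval_report`: `auc`, `sensitivity`,
#'   `specificity`, `accuracy`, `threshold`
#' @export
confusion_metrics <- function(scores, labels, threshold = 0) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L); fp <- sum(pred & labels == 0L)
  structure(list(auc = roc_auc(scores, labels),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(labels),
                 threshold = threshold),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> AUC %.3f | sensitivity %.3f | ",
                     "specificity %.3f | accuracy %.3f (threshold %g)\n"),
              x$auc, x$sensitivity, x$specificity, x$accuracy, x$threshold))
  invisible(x)
}

#' Hit rate of a screening campaign
#'
#' @param n_hits confirmed actives among the tested compounds
#' @param n_tested compounds experimentally tested (> 0)
#' @return percentage rounded to 2 decimals (e.g. `hit_rate(11, 38)` is
#'   28.95)
#' @export
hit_rate <- function(n_hits, n_tested) {
  stopifnot(n_tested > 0, n_hits >= 0, n_hits <= n_tested)
  round(100 * n_hits / n_tested, 2)
}

#' Count potency values strictly below a cutoff
#'
#' @param values finite positive potency values (e.g. IC50 in uM)
#' @param cutoff threshold in the same units
#' @return number of values strictly less than `cutoff`
#' @export
count_below_threshold <- function(values, cutoff) {
  stopifnot(all(is.finite(values)), all(values > 0))
  sum(values < cutoff)
}

#' Overlap of two hit lists
#'
#' Jaccard index of the top-N id sets of two rankings over the same library.
#' @param ranking_a,ranking_b character vectors of molecule ids, best first
#'   (or data.frames with a `molecule_id` column)
#' @param N list depth to compare (default 500)
#' @return Jaccard index in [0, 1]
#' @export
hitlist_similarity <- function(ranking_a, ranking_b, N = 500L) {
  ids_a <- if (is.data.frame(ranking_a)) ranking_a$molecule_id else ranking_a
  ids_b <- if (is.data.frame(ranking_b)) ranking_b$molecule_id else ranking_b
  stopifnot(N >= 1L, N <= length(ids_a), N <= length(ids_b))
  a <- ids_a[seq_len(N)]; b <- ids_b[seq_len(N)]
  length(intersect(a, b)) / length(union(a, b))
}
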
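# Receptor structure qualification: a candidate crystal structure enters the
# screening ensemble only if (a) redocking reproduces the crystallographic
# ligand pose within 2.0 A RMSD ("docking power") and (b) its docking scores
# separate known actives from decoys at p <= 1e-20 ("discrimination power").

#' One-sided Mann-Whitney test that actives score better than decoys
#'
#' Docking scores are better when more negative, so the alternative is that
#' active scores are stochastically smaller. The exact null distribution is
#' used when there are no ties and `n_a * n_d <= 1e4`; otherwise the normal
#' approximation with tie correction and continuity correction. Because the
#' interesting separations sit far below double underflow, the log10 p-value
#' is always reported alongside.
#'
#' @param active_scores,decoy_scores numeric vectors (more negative = better)
#' @return list with `p` (clamped to [1e-300, 1]), `log10_p`, `U` (number of
#'   (active, decoy) pairs where the active wins, ties counting 1/2) and
#'   `method`
#' @export
discrimination_power <- function(active_scores, decoy_scores) {
  stopifnot(length(active_scores) >= 1L, length(decoy_scores) >= 1L,
            all(is.finite(active_scores)), all(is.finite(decoy_scores)))
  na <- length(active_scores); nd <- length(decoy_scores)
  all_scores <- c(active_scores, decoy_scores)
  if (length(unique(all_scores)) == 1L) {
    warning("all scores identical across both groups; p = 1", call. = FALSE)
    return(list(p = 1, log10_p = 0, U = na * nd / 2, method = "degenerate"))
  }
  r <- rank(all_scores)                 # low score = low rank = better
  ra <- sum(r[seq_len(na)])
  # U counts (active, decoy) pairs with active ranked worse; we want actives
  # ranked LOWER, so the test statistic is U_wins = na*nd - U_worse
  u_worse <- ra - na * (na + 1) / 2
  u_wins <- na * nd - u_worse
  has_ties <- anyDuplicated(all_scores) > 0L
  if (!has_ties && na * nd <= 1e4) {
    # exact: P(U_wins >= observed) under the null
    p <- stats::pwilcox(u_wins - 1, na, nd, lower.tail = FALSE)
    p <- max(p, 1e-300)
    return(list(p = p, log10_p = log10(p), U = u_wins, method = "exact"))
  }
  n <- na + nd
  mu <- na * nd / 2
  tie_tab <- table(all_scores)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- na * nd / 12 * ((n + 1) - tie_term)
  z <- (u_wins - mu - 0.5) / sqrt(sigma2)
  logp <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  log10_p <- logp / log(10)
  p <- max(exp(logp), 1e-300)
  list(p = p, log10_p = log10_p, U = u_wins, method = "normal_approx")
}

#' Bundle the qualification evidence for one receptor structure
#'
#' @param structure_id text id
#' @param redock_rmsd redocking pose RMSD in Angstrom (>= 0)
#' @param log10_p log10 of the discrimination p-value (<= 0)
#' @return object of class `structure_qc_result`
#' @export
structure_qc_result <- function(structure_id, redock_rmsd, log10_p) {
  stopifnot(is.character(structure_id), length(structure_id) == 1L,
            is.numeric(redock_rmsd), redock_rmsd >= 0,
            is.numeric(log10_p), log10_p <= 0)
  structure(list(structure_id = structure_id,
                 redock_rmsd = redock_rmsd,
                 log10_p = log10_p),
            class = "structure_qc_result")
}

#' Qualify receptor structures for the screening ensemble
#'
#' A structure qualifies iff `redock_rmsd <= rmsd_threshold` and its
#' discrimination p-value is at or below `p_threshold`. Input order is
#' preserved. Thresholds default to the campaign settings (2.0 A, 1e-20).
#'
#' @param results list of [structure_qc_result] objects
#' @param rmsd_threshold maximum allowed redocking RMSD (Angstrom)
#' @param p_threshold maximum allowed discrimination p-value
#' @return data.frame with columns `structure_id`, `redock_rmsd`, `log10_p`,
#'   `qualified`
#' @export
qualify_structures <- function(results, rmsd_threshold = 2.0,
                               p_threshold = 1e-20) {
  stopifnot(rmsd_threshold > 0, p_threshold > 0, p_threshold <= 1)
  stopifnot(length(results) >= 1L)
  log10_thresh <- log10(p_threshold)
  df <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "structure_qc_result"))
    data.frame(structure_id = r$structure_id,
               redock_rmsd = r$redock_rmsd,
               log10_p = r$log10_p,
               stringsAsFactors = FALSE)
  }))
  df$qualified <- df$redock_rmsd <= rmsd_threshold & df$log10_p <= log10_thresh
  df
}
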
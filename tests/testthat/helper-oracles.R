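# Independent oracles kept deliberately naive: direct enumeration and
# from-scratch arithmetic, no shared code paths with the implementations
# they check (except the Kabsch primitive, which has its own tests).

# ROC AUC by exhaustive pair counting
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# one-sided Mann-Whitney p by enumeration of all group assignments
# (actives-lower alternative); feasible for tiny samples only
oracle_mw_exact <- function(a, d) {
  all_v <- c(a, d)
  n <- length(all_v); na <- length(a)
  stat <- function(av, dv) {
    s <- 0
    for (x in av) for (y in dv) s <- s + if (x < y) 1 else if (x == y) 0.5 else 0
    s
  }
  obs <- stat(a, d)
  combos <- utils::combn(n, na)
  cnt <- 0
  for (k in seq_len(ncol(combos))) {
    idx <- combos[, k]
    if (stat(all_v[idx], all_v[-idx]) >= obs) cnt <- cnt + 1
  }
  cnt / ncol(combos)
}

# normal-approximation Mann-Whitney log10 p (tie + continuity corrected),
# written from the textbook formulas
oracle_mw_normal <- function(a, d) {
  na <- length(a); nd <- length(d); n <- na + nd
  all_v <- c(a, d)
  r <- rank(all_v)
  u_worse <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  u_wins <- na * nd - u_worse
  tt <- table(all_v)
  sigma2 <- na * nd / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
  z <- (u_wins - na * nd / 2 - 0.5) / sqrt(sigma2)
  pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
}

# Laplacian-corrected Bayesian score from raw bin counts, computed with its
# own bin location (linear scan over edges, (-inf, e1], (e1, e2], ...)
oracle_nbc_score <- function(train_values, train_labels, edges_list, row) {
  locate <- function(x, edges) {
    b <- 1L
    for (e in edges) if (x > e) b <- b + 1L
    b
  }
  n_act <- sum(train_labels == 1L)
  prior <- n_act / length(train_labels)
  K <- 1 / prior
  s <- 0
  for (ch in names(edges_list)) {
    x <- row[[ch]]
    if (!is.finite(x)) next
    edges <- edges_list[[ch]]
    b <- locate(x, edges)
    v <- train_values[, ch]
    ok <- is.finite(v)
    bins_train <- vapply(v[ok], locate, integer(1), edges = edges)
    A <- sum(bins_train == b & train_labels[ok] == 1L)
    Tt <- sum(bins_train == b)
    s <- s + log((A + prior * K) / ((Tt + K) * prior))
  }
  s
}

# pharmacophore fit by exhaustive assignment enumeration over permutations
oracle_map_fit <- function(model, molecule) {
  mk <- vapply(model$features, `[[`, "", "kind")
  mc <- do.call(rbind, lapply(model$features, `[[`, "center"))
  tol <- vapply(model$features, `[[`, 0, "tolerance")
  wts <- vapply(model$features, `[[`, 0, "weight")
  best <- 0
  for (ci in seq_along(molecule$conformers)) {
    lf <- perceive_features(molecule, ci)
    if (length(lf) == 0L) next
    lk <- vapply(lf, `[[`, "", "kind")
    lc <- do.call(rbind, lapply(lf, `[[`, "center"))
    # enumerate every injective mapping via expand.grid + filters
    cand <- lapply(mk, function(k) which(lk == k))
    if (any(lengths(cand) == 0L)) next
    grid <- do.call(expand.grid, cand)
    for (g in seq_len(nrow(grid))) {
      asg <- as.integer(grid[g, ])
      if (anyDuplicated(asg)) next
      fitted <- kabsch(lc[asg, , drop = FALSE], mc)$fitted
      d <- sqrt(rowSums((fitted - mc)^2))
      if (any(d > 2 * tol)) next
      best <- max(best, sum(wts * pmax(0, 1 - (d / tol)^2)))
    }
  }
  best
}

# enumerate automorphisms of a tiny molecule by brute force over all
# permutations (used to cross-check symmetry-corrected RMSD)
oracle_automorphisms <- function(mol) {
  n <- nrow(mol$atoms)
  stopifnot(n <= 8L)
  perms <- .permutations(seq_len(n))
  adj <- matrix(0, n, n)
  for (k in seq_len(nrow(mol$bonds))) {
    key <- mol$bonds$order[k] + 10 * mol$bonds$aromatic[k]
    adj[mol$bonds$i[k], mol$bonds$j[k]] <- key
    adj[mol$bonds$j[k], mol$bonds$i[k]] <- key
  }
  keep <- list()
  for (p in perms) {
    if (any(mol$atoms$element[p] != mol$atoms$element)) next
    if (!identical(adj[p, p], adj)) next
    keep[[length(keep) + 1L]] <- p
  }
  keep
}

.permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
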
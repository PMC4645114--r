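# Training set assembly at the campaign's 20:1 decoy-to-active ratio, with
# greedy max-min fingerprint diversity picking over the decoy pool (the
# stand-in for a vendor "find diverse molecules" protocol).

#' Assemble a labeled training set
#'
#' Keeps every active and selects `ratio * n_actives` decoys from the pool.
#' When the pool is exactly the required size it is taken whole; otherwise
#' decoys are chosen by greedy max-min diversity on circular fingerprints
#' (folded to 256 bits for speed): the first pick is seeded-random, each
#' subsequent pick maximises the minimum Tanimoto distance to the already
#' picked set, ties broken by pool order. Deterministic given the seed.
#'
#' @param actives list of [molecule_record] (labels forced to `"active"`)
#' @param decoy_pool list of [molecule_record] to draw decoys from
#' @param ratio decoys per active (default 20)
#' @param seed integer seed for the first pick
#' @return list of [molecule_record]: actives first, then selected decoys
#'   (labels forced to `"decoy"`)
#' @export
build_training_set <- function(actives, decoy_pool, ratio = 20L, seed = 1L) {
  stopifnot(length(actives) >= 1L, ratio >= 1L)
  need <- length(actives) * as.integer(ratio)
  if (length(decoy_pool) < need)
    stop("decoy pool has ", length(decoy_pool), " molecules; ",
         need, " are required at ratio ", ratio)
  if (length(decoy_pool) == need) {
    picked <- seq_len(need)
  } else {
    fps <- fingerprint_matrix(decoy_pool, "ecfp", nbits = 256L)
    picked <- .maxmin_pick(fps, need, seed)
  }
  acts <- lapply(actives, function(m) { m$label <- "active"; m })
  decs <- lapply(decoy_pool[picked], function(m) { m$label <- "decoy"; m })
  c(acts, decs)
}

# greedy max-min picking on a logical fingerprint matrix
.maxmin_pick <- function(fps, k, seed) {
  n <- nrow(fps)
  fps_num <- fps * 1
  card <- rowSums(fps_num)
  first <- with_seed(seed, sample.int(n, 1L))
  picked <- integer(k)
  picked[1L] <- first
  # min distance (1 - tanimoto) of every pool molecule to the picked set
  min_dist <- rep(Inf, n)
  update <- function(min_dist, idx) {
    inter <- as.numeric(fps_num %*% fps_num[idx, ])
    uni <- card + card[idx] - inter
    sim <- ifelse(uni > 0, inter / uni, 0)
    pmin(min_dist, 1 - sim)
  }
  min_dist <- update(min_dist, first)
  for (t in 2L:k) {
    min_dist[picked[seq_len(t - 1L)]] <- -1
    nxt <- which.max(min_dist)            # ties: lowest index (pool order)
    picked[t] <- nxt
    min_dist <- update(min_dist, nxt)
  }
  sort(picked)
}
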
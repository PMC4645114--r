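# Structural clustering of hits: single-linkage connected components of the
# similarity graph with edges where Tanimoto exceeds the threshold
# (strictly), i.e. "similarity higher than 0.85 goes in the same group"
# taken literally as a transitive rule.

#' Cluster fingerprints by Tanimoto similarity
#'
#' @param fps list of [fingerprint] objects (same kind)
#' @param threshold similarity above which two molecules join one cluster
#'   (strict `>`; default 0.85)
#' @return integer cluster labels, numbered by first-seen order (cluster 1
#'   contains the first molecule)
#' @export
cluster_by_similarity <- function(fps, threshold = 0.85) {
  n <- length(fps)
  stopifnot(n >= 1L, threshold >= 0, threshold <= 1)
  if (n == 1L) return(1L)
  # union-find over above-threshold pairs
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (tanimoto(fps[[i]], fps[[j]]) > threshold) {
        ra <- find(i); rb <- find(j)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Pick one representative per cluster
#'
#' The highest-priority member (lowest value of `priority`, e.g. rank in the
#' scored hit list) represents each cluster; ties keep the earliest.
#' @param labels integer cluster labels from [cluster_by_similarity()]
#' @param priority numeric vector, lower = better (default: input order)
#' @return integer indices of the representatives, in cluster-label order
#' @export
cluster_representatives <- function(labels, priority = seq_along(labels)) {
  stopifnot(length(labels) == length(priority))
  vapply(seq_len(max(labels)), function(cl) {
    members <- which(labels == cl)
    members[which.min(priority[members])]
  }, integer(1))
}
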
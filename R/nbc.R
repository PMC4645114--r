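# Laplacian-corrected naive Bayesian classifier over binned channels.
#
# Each channel is discretized into B equal-frequency bins fit on training
# data. For a bin holding A actives among T molecules, with class prior
# p = n_active / n_total and smoothing constant K = 1/p, the bin's
# log-weight is
#
#     W = log[ (A + p K) / ((T + K) p) ] = log[ (A + 1) / (T p + 1) ]
#
# so a bin with no training data is exactly neutral (W = 0) and a bin whose
# active fraction equals the prior tends to 0 as T grows. A molecule's score
# is the sum of its bins' weights over non-missing channels; masked channels
# contribute nothing.

#' Fit an equal-frequency binning scheme
#'
#' Bin edges are the type-1 quantiles of the finite training values: for B
#' bins the edges sit at the sorted values with index `ceiling(n * i / B)`,
#' i = 1..B-1, deduplicated. Outer bins are open, so any screening value is
#' binnable. Channels with fewer distinct values than bins get fewer bins
#' (with a warning); an all-missing channel is dropped with a warning.
#'
#' @param matrix a [feature_matrix]
#' @param B target bin count per channel (default 10)
#' @return object of class `binning_scheme`: list of per-channel edge vectors
#' @export
fit_bins <- function(matrix, B = 10L) {
  stopifnot(inherits(matrix, "feature_matrix"), B >= 1L)
  edges <- list()
  for (ch in colnames(matrix$values)) {
    v <- matrix$values[, ch]
    v <- v[is.finite(v)]
    if (length(v) == 0L) {
      warning("channel '", ch, "' is all-missing and was dropped",
              call. = FALSE)
      next
    }
    dv <- sort(unique(v))
    if (length(dv) == 1L) {
      warning("channel '", ch, "' is constant; using a single bin",
              call. = FALSE)
      edges[[ch]] <- numeric(0)
      next
    }
    b_eff <- min(B, length(dv))
    if (b_eff < B)
      warning("channel '", ch, "' has only ", length(dv),
              " distinct values; using ", b_eff, " bins", call. = FALSE)
    sv <- sort(v)
    n <- length(sv)
    idx <- ceiling(n * seq_len(b_eff - 1L) / b_eff)
    edges[[ch]] <- unique(sv[idx])
  }
  if (length(edges) == 0L) stop("no usable channels")
  structure(list(edges = edges, bin_count = as.integer(B)),
            class = "binning_scheme")
}

# bin index of values under a channel's edges: (-inf, e1], (e1, e2], ...
.bin_index <- function(x, edges) {
  if (length(edges) == 0L) return(rep(1L, length(x)))
  findInterval(x, edges, left.open = TRUE) + 1L
}

#' Train the naive Bayesian classifier
#'
#' @param matrix a labeled [feature_matrix] (both classes present)
#' @param bins a [binning_scheme] from [fit_bins()]
#' @return object of class `bayes_model` with `prior`, `K`, per-channel
#'   per-bin `weights`, and the binning scheme
#' @export
train_nbc <- function(matrix, bins) {
  stopifnot(inherits(matrix, "feature_matrix"),
            inherits(bins, "binning_scheme"))
  y <- matrix$labels
  if (is.null(y) || anyNA(y)) stop("training requires complete 1/0 labels")
  n_act <- sum(y == 1L); n_tot <- length(y)
  if (n_act == 0L || n_act == n_tot)
    stop("training requires both classes present")
  prior <- n_act / n_tot
  K <- 1 / prior
  weights <- list()
  for (ch in names(bins$edges)) {
    e <- bins$edges[[ch]]
    nb <- length(e) + 1L
    v <- matrix$values[, ch]
    ok <- is.finite(v)
    b <- .bin_index(v[ok], e)
    A <- tabulate(b[y[ok] == 1L], nbins = nb)
    Tt <- tabulate(b, nbins = nb)
    weights[[ch]] <- log((A + prior * K) / ((Tt + K) * prior))
  }
  structure(list(prior = prior, K = K, weights = weights, binning = bins),
            class = "bayes_model")
}

#' @export
print.bayes_model <- function(x, ...) {
  cat(sprintf("<bayes_model> %d channels, prior P(active) = %.4f, K = %.2f\n",
              length(x$weights), x$prior, x$K))
  invisible(x)
}

#' Score molecules with a trained Bayesian model
#'
#' @param model a [bayes_model]
#' @param values either a single named numeric vector (one molecule; `NA` =
#'   masked) or a numeric matrix with channel columns
#' @return numeric score(s); a molecule with every channel missing scores 0
#' @export
score_nbc <- function(model, values) {
  stopifnot(inherits(model, "bayes_model"))
  if (is.matrix(values)) {
    missing_ch <- setdiff(names(model$weights), colnames(values))
    if (length(missing_ch) > 0L)
      stop("matrix lacks model channel(s): ", paste(missing_ch, collapse = ", "))
    out <- rep(0, nrow(values))
    for (ch in names(model$weights)) {
      v <- values[, ch]
      ok <- is.finite(v)
      b <- .bin_index(v[ok], model$binning$edges[[ch]])
      out[ok] <- out[ok] + model$weights[[ch]][b]
    }
    names(out) <- rownames(values)
    return(out)
  }
  unknown <- setdiff(names(values), names(model$weights))
  if (length(unknown) > 0L)
    stop("unknown channel(s): ", paste(unknown, collapse = ", "))
  s <- 0
  for (ch in names(values)) {
    v <- values[[ch]]
    if (!is.finite(v)) next
    b <- .bin_index(v, model$binning$edges[[ch]])
    s <- s + model$weights[[ch]][b]
  }
  s
}

#' Rank a library by fused Bayesian score
#'
#' Descending score; ties broken by molecule id in C-locale lexicographic
#' order (stable and platform independent).
#'
#' @param model a [bayes_model]
#' @param matrix a [feature_matrix] of the screening library
#' @param top_n number of hits to keep (>= 1; clipped to the library size)
#' @return data.frame of `screening_hit` rows: `rank`, `molecule_id`, `score`
#' @export
rank_library <- function(model, matrix, top_n) {
  stopifnot(inherits(matrix, "feature_matrix"), top_n >= 1L)
  s <- score_nbc(model, matrix$values)
  ids <- matrix$molecule_ids
  ord <- order(-s, ids, method = "radix")
  keep <- ord[seq_len(min(top_n, length(ids)))]
  data.frame(rank = seq_along(keep), molecule_id = ids[keep],
             score = unname(s[keep]), stringsAsFactors = FALSE)
}

#' Persist a Bayesian model as JSON
#' @param model a [bayes_model]
#' @param path output path
#' @export
write_bayes_model <- function(model, path) {
  # edges and weights are written as %.17g strings: values sitting exactly on
  # a bin edge must land in the same bin after a round trip, and JSON number
  # emission is not guaranteed bit-exact
  fmt <- function(x) sprintf("%.17g", x)
  doc <- list(prior = fmt(model$prior), K = fmt(model$K),
              bin_count = model$binning$bin_count,
              channels = lapply(names(model$weights), function(ch) {
                list(name = ch, edges = fmt(model$binning$edges[[ch]]),
                     weights = fmt(model$weights[[ch]]))
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load a Bayesian model from JSON
#' @param path file written by [write_bayes_model()]
#' @return a [bayes_model]
#' @export
read_bayes_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- stats::setNames(lapply(seq_len(nrow(doc$channels)), function(i) {
    e <- doc$channels$edges[[i]]
    if (is.null(e)) numeric(0) else as.numeric(e)
  }), doc$channels$name)
  weights <- stats::setNames(lapply(doc$channels$weights, as.numeric),
                             doc$channels$name)
  bins <- structure(list(edges = edges, bin_count = as.integer(doc$bin_count)),
                    class = "binning_scheme")
  structure(list(prior = as.numeric(doc$prior), K = as.numeric(doc$K),
                 weights = weights, binning = bins),
            class = "bayes_model")
}
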
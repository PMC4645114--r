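# The molecules x channels matrix fused by the Bayesian classifier: one
# docking-score channel and one fit-value channel per qualified structure.
# Missing policy: a molecule absent from a docking table is masked missing
# (contributes nothing to the fused score -- a crashed docking run carries no
# information); a molecule absent from a fit table is a non-mapper and gets
# the real observation 0.0.

#' Construct a feature matrix
#'
#' @param values numeric matrix, molecules x channels, with `NA` for masked
#'   entries; rownames are molecule ids, colnames are channel names
#' @param labels optional integer vector (1 active / 0 decoy) aligned with
#'   rows; `NA` for unlabeled molecules
#' @export
feature_matrix <- function(values, labels = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(values),
              all(labels %in% c(0L, 1L, NA)))
    labels <- as.integer(labels)
  }
  structure(list(values = values, labels = labels,
                 molecule_ids = rownames(values),
                 channels = colnames(values)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d molecules x %d channels, %d masked, %s\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              if (is.null(x$labels)) "unlabeled"
              else sprintf("%d active / %d decoy",
                           sum(x$labels == 1L, na.rm = TRUE),
                           sum(x$labels == 0L, na.rm = TRUE))))
  invisible(x)
}

#' Assemble the fused feature matrix from per-structure tables
#'
#' Builds channels `dock_<structure>` and `fit_<structure>` for every
#' structure present in `score_tables` / `fit_tables` (normally the
#' qualified subset).
#'
#' @param molecule_ids character vector defining row order
#' @param score_tables list of [score_table] objects
#' @param fit_tables named list (structure id -> named numeric fit vector)
#' @param labels optional 1/0 labels aligned with `molecule_ids`
#' @return a [feature_matrix]
#' @export
assemble_features <- function(molecule_ids, score_tables, fit_tables = NULL,
                              labels = NULL) {
  stopifnot(length(molecule_ids) >= 1L, !anyDuplicated(molecule_ids))
  cols <- list()
  for (st in score_tables) {
    stopifnot(inherits(st, "score_table"))
    v <- st$scores[molecule_ids]          # NA when absent -> masked missing
    cols[[paste0("dock_", st$structure_id)]] <- unname(v)
  }
  for (sid in names(fit_tables)) {
    v <- fit_tables[[sid]][molecule_ids]
    v[is.na(v)] <- 0                      # non-mapper: observed zero
    cols[[paste0("fit_", sid)]] <- unname(v)
  }
  if (length(cols) == 0L) stop("no channels supplied")
  m <- do.call(cbind, cols)
  rownames(m) <- molecule_ids
  feature_matrix(m, labels)
}
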
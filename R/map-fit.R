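# Pharmacophore fit mapping. For every conformer and every injective,
# kind-compatible assignment of model features to perceived ligand features,
# the matched ligand feature centers are rigidly superposed onto the model
# feature centers (Kabsch least squares) and scored with a quadratic
# displacement penalty:
#
#     fit = sum_f  w_f * max(0, 1 - (d_f / tol_f)^2)
#
# where d_f is the post-alignment displacement of feature f. An assignment is
# rejected outright if any feature lands beyond twice its tolerance. The fit
# value of the molecule is the best over all assignments and conformers, or 0
# when no assignment is valid.

.MAX_ASSIGNMENTS <- 1e5

# enumerate injective assignments: for model feature i, cands[[i]] lists
# usable ligand feature indices; returns matrix with one assignment per row
.enumerate_assignments <- function(cands, cap = .MAX_ASSIGNMENTS) {
  n <- length(cands)
  out <- list()
  rec <- function(i, chosen) {
    if (length(out) >= cap) return(invisible(NULL))
    if (i > n) { out[[length(out) + 1L]] <<- chosen; return(invisible(NULL)) }
    for (c in cands[[i]]) {
      if (c %in% chosen) next
      rec(i + 1L, c(chosen, c))
      if (length(out) >= cap) return(invisible(NULL))
    }
  }
  rec(1L, integer(0))
  truncated <- length(out) >= cap
  list(assignments = out, truncated = truncated)
}

#' Map a molecule onto a pharmacophore model
#'
#' @param model a [pharmacophore_model]
#' @param molecule a [molecule_record] with at least one conformer
#' @param features optional pre-perceived feature lists (one list per
#'   conformer) to skip re-perception
#' @param align superpose ligand feature centers onto the model by least
#'   squares before measuring displacements (default). With `align = FALSE`
#'   displacements are measured in the frame as given -- use this when the
#'   conformer is already posed in the receptor frame.
#' @return list of class `fit_result` with `molecule_id`, `model_id`,
#'   `fit_value` (0 when nothing maps), `best_conformer_index` (NA when
#'   nothing maps) and `feature_assignment` (two-column matrix pairing model
#'   feature index with ligand feature index)
#' @export
map_fit <- function(model, molecule, features = NULL, align = TRUE) {
  stopifnot(inherits(model, "pharmacophore_model"),
            inherits(molecule, "molecule_record"))
  if (length(model$features) == 0L) stop("model has no features")
  if (length(molecule$conformers) == 0L)
    stop("molecule '", molecule$id, "' has no conformers; run generate_conformers()")
  mk <- vapply(model$features, `[[`, "", "kind")
  mcenters <- do.call(rbind, lapply(model$features, `[[`, "center"))
  tol <- vapply(model$features, `[[`, 0, "tolerance")
  wts <- vapply(model$features, `[[`, 0, "weight")

  best <- list(fit = 0, conf = NA_integer_, assign = NULL)
  warned <- FALSE
  for (ci in seq_along(molecule$conformers)) {
    lf <- if (!is.null(features)) features[[ci]]
          else perceive_features(molecule, ci)
    if (length(lf) == 0L) next
    lk <- vapply(lf, `[[`, "", "kind")
    cands <- lapply(mk, function(k) which(lk == k))
    if (any(vapply(cands, length, 0L) == 0L)) next
    lcenters <- do.call(rbind, lapply(lf, `[[`, "center"))
    en <- .enumerate_assignments(cands)
    if (en$truncated && !warned) {
      warning("assignment enumeration capped at ", .MAX_ASSIGNMENTS,
              " for '", molecule$id, "'", call. = FALSE)
      warned <- TRUE
    }
    for (asg in en$assignments) {
      src <- lcenters[asg, , drop = FALSE]
      fitted <- if (align) kabsch(src, mcenters)$fitted else src
      d <- sqrt(rowSums((fitted - mcenters)^2))
      if (any(d > 2 * tol)) next
      val <- sum(wts * pmax(0, 1 - (d / tol)^2))
      if (val > best$fit) {
        best <- list(fit = val, conf = ci,
                     assign = cbind(model_feature = seq_along(mk),
                                    ligand_feature = asg))
      }
    }
  }
  structure(list(molecule_id = molecule$id, model_id = model$model_id,
                 fit_value = best$fit, best_conformer_index = best$conf,
                 feature_assignment = best$assign),
            class = "fit_result")
}

#' Fit a library of molecules against a set of models
#'
#' Convenience wrapper producing one named fit-value vector per model,
#' the shape consumed by [assemble_features()].
#' @param models list of [pharmacophore_model]
#' @param molecules list of [molecule_record] with conformers
#' @return named list: model_id -> named numeric vector of fit values
#' @export
map_fit_library <- function(models, molecules) {
  out <- lapply(models, function(m) {
    v <- vapply(molecules, function(mol) map_fit(m, mol)$fit_value, numeric(1))
    names(v) <- vapply(molecules, `[[`, "", "id")
    v
  })
  names(out) <- vapply(models, `[[`, "", "model_id")
  out
}
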
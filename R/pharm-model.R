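# Receptor-ligand pharmacophore models: subsets of the ligand features that
# match a receptor interaction, ranked by selectivity (empirical rarity of a
# non-zero fit against a reference library).

#' Construct a pharmacophore model
#'
#' @param model_id text id
#' @param source_complex_id id of the receptor-ligand complex the model was
#'   derived from
#' @param features list of [pharmacophore_feature] (length >= `min_features`)
#' @param selectivity non-negative selectivity score (NA until estimated)
#' @param min_features minimum feature count enforced (default 3)
#' @export
pharmacophore_model <- function(model_id, source_complex_id, features,
                                selectivity = NA_real_, min_features = 3L) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  if (length(features) < min_features)
    stop("pharmacophore model needs at least ", min_features, " features")
  for (f in features) stopifnot(inherits(f, "pharmacophore_feature"))
  if (!is.na(selectivity)) stopifnot(is.finite(selectivity), selectivity >= 0)
  structure(list(model_id = model_id,
                 source_complex_id = source_complex_id,
                 features = features, selectivity = selectivity),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  cat(sprintf("<pharmacophore_model> %s (from %s): %d features [%s], selectivity %s\n",
              x$model_id, x$source_complex_id, length(x$features),
              paste(vapply(x$features, `[[`, "", "kind"), collapse = ", "),
              if (is.na(x$selectivity)) "unrated" else
                sprintf("%.3f", x$selectivity)))
  invisible(x)
}

#' Tag ligand features that match a receptor interaction
#'
#' A polar feature (donor, acceptor, ionizable) matches when a receptor N or
#' O heavy atom lies within `polar_dist` of the feature center; an apolar
#' feature (hydrophobe, aromatic ring) matches when a receptor carbon lies
#' within `apolar_dist`. Hydrogens carry no coordinates here, so the H-bond
#' criterion is distance-only.
#'
#' @param ligand_features list of [pharmacophore_feature]
#' @param receptor_atoms data.frame with columns `element`, `x`, `y`, `z`
#' @param polar_dist,apolar_dist distance windows in Angstrom
#' @return logical vector, one flag per feature
#' @export
match_receptor_contacts <- function(ligand_features, receptor_atoms,
                                    polar_dist = 3.5, apolar_dist = 4.5) {
  stopifnot(is.data.frame(receptor_atoms),
            all(c("element", "x", "y", "z") %in% names(receptor_atoms)))
  rec <- as.matrix(receptor_atoms[, c("x", "y", "z")])
  polar_idx <- receptor_atoms$element %in% c("N", "O")
  apolar_idx <- receptor_atoms$element == "C"
  vapply(ligand_features, function(f) {
    d2 <- colSums((t(rec) - f$center)^2)
    if (f$kind %in% c("hydrophobe", "aromatic_ring"))
      any(d2[apolar_idx] <= apolar_dist^2)
    else
      any(d2[polar_idx] <= polar_dist^2)
  }, logical(1))
}

#' Derive candidate pharmacophore models from a receptor-ligand complex
#'
#' Models are subsets (size `min_features` up to all) of the
#' interaction-matched ligand features. Candidates are ranked by descending
#' selectivity -- estimated against `reference` when given, otherwise by the
#' feature count surrogate (larger models are rarer) -- and at most
#' `max_models` are returned.
#'
#' @param ligand_features list of [pharmacophore_feature] perceived on the
#'   bound ligand pose
#' @param receptor_contacts either a logical vector tagging each feature as
#'   interaction-matched, or a receptor-atom data.frame passed to
#'   [match_receptor_contacts()]
#' @param min_features minimum model size (default 3)
#' @param max_models maximum number of models returned (default 10)
#' @param source_complex_id id recorded on each model
#' @param reference optional list of [molecule_record] (with conformers) for
#'   selectivity estimation
#' @return list of [pharmacophore_model], best first; empty with a warning if
#'   fewer than `min_features` features are matched
#' @export
derive_models <- function(ligand_features, receptor_contacts,
                          min_features = 3L, max_models = 10L,
                          source_complex_id = "complex",
                          reference = NULL) {
  stopifnot(min_features >= 1L, max_models >= 1L)
  matched <- if (is.logical(receptor_contacts)) {
    stopifnot(length(receptor_contacts) == length(ligand_features))
    receptor_contacts
  } else {
    match_receptor_contacts(ligand_features, receptor_contacts)
  }
  pool <- ligand_features[matched]
  if (length(pool) < min_features) {
    warning("only ", length(pool), " interaction-matched feature(s); ",
            "no model derived", call. = FALSE)
    return(list())
  }
  subsets <- list()
  for (k in seq(min_features, length(pool))) {
    cmb <- utils::combn(length(pool), k, simplify = FALSE)
    subsets <- c(subsets, cmb)
    if (length(subsets) > 5000L) break    # bounded enumeration
  }
  models <- lapply(seq_along(subsets), function(s) {
    pharmacophore_model(sprintf("%s_m%02d", source_complex_id, s),
                        source_complex_id, pool[subsets[[s]]],
                        min_features = min_features)
  })
  sel <- if (!is.null(reference)) {
    vapply(models, function(m) estimate_selectivity(m, reference), numeric(1))
  } else {
    vapply(models, function(m) length(m$features), numeric(1))
  }
  ord <- order(-sel, vapply(models, `[[`, "", "model_id"), method = "radix")
  models <- models[ord][seq_len(min(max_models, length(models)))]
  for (i in seq_along(models)) {
    models[[i]]$selectivity <- if (!is.null(reference)) sel[ord][i] else NA_real_
    models[[i]]$model_id <- sprintf("%s_m%02d", source_complex_id, i)
  }
  models
}

#' Empirical selectivity of a pharmacophore model
#'
#' Fraction-based rarity: `-log10` of the fraction of reference molecules
#' that attain a non-zero fit value. A model matched by every reference
#' molecule scores 0; one matched by none is capped at `-log10(0.5 / N)`.
#'
#' @param model a [pharmacophore_model]
#' @param reference non-empty list of [molecule_record] with conformers
#' @return non-negative selectivity
#' @export
estimate_selectivity <- function(model, reference) {
  stopifnot(inherits(model, "pharmacophore_model"), length(reference) >= 1L)
  hits <- vapply(reference, function(mr) {
    map_fit(model, mr)$fit_value > 0
  }, logical(1))
  frac <- max(sum(hits), 0.5) / length(reference)
  -log10(frac)
}

#' Serialize pharmacophore models to JSON
#' @param models list of [pharmacophore_model]
#' @param path output path
#' @export
write_pharmacophore_models <- function(models, path) {
  doc <- lapply(models, function(m) {
    list(model_id = m$model_id, source_complex_id = m$source_complex_id,
         selectivity = m$selectivity,
         features = lapply(m$features, function(f) {
           list(kind = f$kind, center = f$center, tolerance = f$tolerance,
                weight = f$weight)
         }))
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read pharmacophore models from JSON
#' @param path file written by [write_pharmacophore_models()]
#' @return list of [pharmacophore_model]
#' @export
read_pharmacophore_models <- function(path) {
  doc <- jsonlite::read_json(path)
  lapply(doc, function(m) {
    feats <- lapply(m$features, function(f) {
      pharmacophore_feature(f$kind, unlist(f$center), f$tolerance, f$weight)
    })
    pharmacophore_model(m$model_id, m$source_complex_id, feats,
                        selectivity = if (is.null(m$selectivity)) NA_real_
                                      else m$selectivity,
                        min_features = 1L)
  })
}
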
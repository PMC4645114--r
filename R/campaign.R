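# Campaign orchestration: the full screening funnel from structure
# qualification to clustered candidate representatives, driven by one config
# and one seed, with per-stage counts logged so funnel audits are diff-able.

#' Campaign configuration
#'
#' @param rmsd_threshold docking-power cutoff in Angstrom (default 2.0)
#' @param p_threshold discrimination-power p-value cutoff (default 1e-20)
#' @param decoy_ratio decoys per active in the training set (default 20)
#' @param bin_count Bayesian bins per channel (default 10)
#' @param top_n hits kept from the ranked library (default 100)
#' @param cluster_threshold Tanimoto threshold for hit clustering
#'   (default 0.85)
#' @param max_confs conformers per molecule where conformers are generated
#'   (default 100; fixture campaigns take fit values from tables instead)
#' @param seed campaign seed; all stages derive their randomness from it
#' @return object of class `campaign_config`
#' @export
campaign_config <- function(rmsd_threshold = 2.0, p_threshold = 1e-20,
                            decoy_ratio = 20L, bin_count = 10L,
                            top_n = 100L, cluster_threshold = 0.85,
                            max_confs = 100L, seed = 1L) {
  stopifnot(rmsd_threshold > 0, p_threshold > 0, p_threshold <= 1,
            decoy_ratio >= 1L, bin_count >= 1L, top_n >= 1L,
            cluster_threshold >= 0, cluster_threshold <= 1, max_confs >= 1L)
  structure(list(rmsd_threshold = rmsd_threshold, p_threshold = p_threshold,
                 decoy_ratio = as.integer(decoy_ratio),
                 bin_count = as.integer(bin_count),
                 top_n = as.integer(top_n),
                 cluster_threshold = cluster_threshold,
                 max_confs = as.integer(max_confs),
                 seed = as.integer(seed)),
            class = "campaign_config")
}

#' Read a campaign configuration from a JSON file
#' @param path JSON file with any subset of the [campaign_config()] fields
#' @export
read_campaign_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(campaign_config, doc)
}

#' Run the integrated screening funnel
#'
#' Stages: qualify structures -> assemble the fused feature matrix over the
#' qualified channels -> build the 20:1 training set -> fit bins and train
#' the Bayesian classifier -> rank the library and keep the top N -> apply
#' the Rule-of-Five + REOS drug-likeness screen -> cluster the survivors on
#' structural keys -> keep one representative per cluster. Identical inputs
#' and seed give an identical report.
#'
#' @param config a [campaign_config]
#' @param molecules list of [molecule_record] (the screening library;
#'   labeled actives/decoys supply the training classes)
#' @param score_tables list of [score_table], one per candidate structure
#' @param fit_tables named list of fit-value vectors, one per structure
#' @param structure_qc list of [structure_qc_result] (redocking RMSD +
#'   discrimination log10 p per structure); when `NULL`, discrimination is
#'   computed from each score table against the molecule labels, and
#'   `redock_rmsds` must give the redocking RMSD per structure id
#' @param redock_rmsds named numeric vector (structure id -> RMSD, Angstrom)
#' @return list of class `campaign_report`; see Details
#' @details The report carries `qualified` (structure QC table), `stages`
#'   (named counts down the funnel), `training` (resubstitution
#'   [confusion_metrics()] of the trained classifier), `hits` (ranked top-N
#'   with filter flags and cluster labels) and `candidates` (cluster
#'   representatives).
#' @export
run_campaign <- function(config, molecules, score_tables, fit_tables,
                         structure_qc = NULL, redock_rmsds = NULL) {
  stopifnot(inherits(config, "campaign_config"))
  ids <- vapply(molecules, `[[`, "", "id")
  labels <- vapply(molecules, `[[`, "", "label")
  lab01 <- ifelse(labels == "active", 1L, ifelse(labels == "decoy", 0L, NA))
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  note("campaign seed %d: %d molecules (%d active, %d decoy), %d structures",
       config$seed, length(ids), sum(lab01 == 1L, na.rm = TRUE),
       sum(lab01 == 0L, na.rm = TRUE), length(score_tables))

  # --- stage 1: structure qualification ------------------------------------
  if (is.null(structure_qc)) {
    if (is.null(redock_rmsds)) stop("stage qualify: need structure_qc or redock_rmsds")
    structure_qc <- lapply(score_tables, function(st) {
      sc <- st$scores[ids]
      ok <- !is.na(sc) & !is.na(lab01)
      dp <- discrimination_power(sc[ok][lab01[ok] == 1L],
                                 sc[ok][lab01[ok] == 0L])
      structure_qc_result(st$structure_id,
                          redock_rmsds[[st$structure_id]],
                          min(dp$log10_p, 0))
    })
  }
  qc <- qualify_structures(structure_qc, config$rmsd_threshold,
                           config$p_threshold)
  qualified_ids <- qc$structure_id[qc$qualified]
  note("stage qualify: %d of %d structures qualified (%s)",
       length(qualified_ids), nrow(qc), paste(qualified_ids, collapse = ", "))
  if (length(qualified_ids) == 0L)
    stop("stage qualify: no structure passed; cannot screen")

  # --- stage 2: training set ----------------------------------------------
  actives <- molecules[labels == "active"]
  decoy_pool <- molecules[labels == "decoy"]
  training <- build_training_set(actives, decoy_pool,
                                 ratio = config$decoy_ratio,
                                 seed = config$seed)
  train_ids <- vapply(training, `[[`, "", "id")
  train_lab <- ifelse(vapply(training, `[[`, "", "label") == "active", 1L, 0L)
  note("stage training_set: %d actives + %d decoys (ratio %d)",
       sum(train_lab == 1L), sum(train_lab == 0L), config$decoy_ratio)

  # --- stage 3: features + classifier -------------------------------------
  st_q <- score_tables[vapply(score_tables, `[[`, "", "structure_id") %in%
                         qualified_ids]
  ft_q <- fit_tables[qualified_ids[qualified_ids %in% names(fit_tables)]]
  fm_train <- assemble_features(train_ids, st_q, ft_q, labels = train_lab)
  bins <- fit_bins(fm_train, config$bin_count)
  model <- train_nbc(fm_train, bins)
  train_scores <- score_nbc(model, fm_train$values)
  train_eval <- confusion_metrics(train_scores, train_lab)
  note("stage train_nbc: %d channels, prior %.4f, resubstitution AUC %.4f",
       length(model$weights), model$prior, train_eval$auc)

  # --- stage 4: rank ------------------------------------------------------
  fm_all <- assemble_features(ids, st_q, ft_q)
  hits <- rank_library(model, fm_all, config$top_n)
  note("stage rank: top %d of %d kept", nrow(hits), length(ids))

  # --- stage 5: drug-likeness filter --------------------------------------
  mol_by_id <- stats::setNames(molecules, ids)
  hits$druglike <- vapply(hits$molecule_id, function(id)
    as.logical(druglikeness_pass(mol_by_id[[id]])), logical(1))
  filtered <- hits[hits$druglike, , drop = FALSE]
  note("stage filter: %d of %d pass Ro5+REOS", nrow(filtered), nrow(hits))

  # --- stage 6: cluster + representatives ---------------------------------
  if (nrow(filtered) > 0L) {
    fps <- lapply(filtered$molecule_id,
                  function(id) fingerprint(mol_by_id[[id]], "maccs"))
    cl <- cluster_by_similarity(fps, config$cluster_threshold)
    filtered$cluster <- cl
    reps <- cluster_representatives(cl, priority = filtered$rank)
    candidates <- filtered[reps, , drop = FALSE]
  } else {
    filtered$cluster <- integer(0)
    candidates <- filtered
  }
  note("stage cluster: %d clusters at threshold %.2f -> %d representatives",
       if (nrow(filtered) > 0L) max(filtered$cluster) else 0L,
       config$cluster_threshold, nrow(candidates))

  structure(list(
    config = unclass(config),
    qualified = qc,
    stages = list(structures_total = nrow(qc),
                  structures_qualified = length(qualified_ids),
                  library = length(ids),
                  training_actives = sum(train_lab == 1L),
                  training_decoys = sum(train_lab == 0L),
                  ranked = nrow(hits),
                  filtered = nrow(filtered),
                  representatives = nrow(candidates)),
    training = unclass(train_eval),
    hits = hits,
    candidates = candidates,
    log = log_lines),
    class = "campaign_report")
}

#' @export
print.campaign_report <- function(x, ...) {
  cat("<campaign_report>\n")
  for (ln in x$log) cat(" ", ln, "\n")
  invisible(x)
}

#' Write a campaign report as canonical JSON
#'
#' Serialization is deterministic: the same report writes the same bytes.
#' @param report a `campaign_report`
#' @param path output path
#' @export
write_campaign_report <- function(report, path) {
  doc <- report
  doc$qualified <- as.list(report$qualified)
  doc$hits <- as.list(report$hits)
  doc$candidates <- as.list(report$candidates)
  class(doc) <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
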
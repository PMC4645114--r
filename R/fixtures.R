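# Deterministic synthetic fixtures emulating an ensemble screening campaign:
# a library of actives and decoys (20 decoys per active by default), one
# Gaussian docking-score channel per receptor structure with a shared latent
# factor inducing equicorrelation across structures, and zero-inflated
# pharmacophore fit-value channels. All randomness flows through one seed.

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

#' Specify a synthetic screening fixture
#'
#' Defaults mirror the campaign the toolkit is designed around: 350 actives,
#' a 20:1 decoy ratio (7000 decoys), 8 receptor structures, docking-score
#' class means -9 (active) and -6.5 (decoy) with sd 1.5 -- a class separation
#' whose single-channel ROC AUC has the closed form
#' pnorm(2.5 / (1.5 * sqrt(2))) ~ 0.881 -- and modest cross-structure score
#' correlation so different structures promote different top hits.
#'
#' @param n_actives number of active molecules
#' @param decoy_ratio decoys generated per active (>= 1)
#' @param n_structures number of receptor structure channels
#' @param active_score_mean,decoy_score_mean class-conditional docking score
#'   means (more negative = better)
#' @param score_sd docking score standard deviation (> 0)
#' @param cross_structure_correlation equicorrelation of a molecule's scores
#'   across structures, in [0, 1]
#' @param fit_nonmapper_prob probability that a decoy fails to map onto a
#'   pharmacophore model and gets fit value 0
#' @param active_fit_mean,decoy_fit_mean,fit_sd fit-value channel parameters
#' @param n_unqualified number of structures built to fail qualification
#'   (redock RMSD > 2 A and no class separation in their score channel)
#' @param seed integer seed; identical seed gives byte-identical fixtures
#' @return object of class `fixture_spec`
#' @export
fixture_spec <- function(n_actives = 350L, decoy_ratio = 20L,
                         n_structures = 8L,
                         active_score_mean = -9, decoy_score_mean = -6.5,
                         score_sd = 1.5, cross_structure_correlation = 0.3,
                         fit_nonmapper_prob = 0.5,
                         active_fit_mean = 3, decoy_fit_mean = 1.5,
                         fit_sd = 0.8,
                         n_unqualified = 0L, seed = 1L) {
  stopifnot(n_actives >= 1L, decoy_ratio >= 1L, n_structures >= 1L,
            score_sd > 0, fit_sd > 0,
            cross_structure_correlation >= 0, cross_structure_correlation <= 1,
            fit_nonmapper_prob >= 0, fit_nonmapper_prob <= 1,
            n_unqualified >= 0L, n_unqualified <= n_structures)
  structure(list(n_actives = as.integer(n_actives),
                 decoy_ratio = as.integer(decoy_ratio),
                 n_structures = as.integer(n_structures),
                 active_score_mean = active_score_mean,
                 decoy_score_mean = decoy_score_mean,
                 score_sd = score_sd,
                 cross_structure_correlation = cross_structure_correlation,
                 fit_nonmapper_prob = fit_nonmapper_prob,
                 active_fit_mean = active_fit_mean,
                 decoy_fit_mean = decoy_fit_mean,
                 fit_sd = fit_sd,
                 n_unqualified = as.integer(n_unqualified),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Simulate the score and fit channels of a fixture (no molecules)
#'
#' The statistics-only core of [generate_fixtures()], exposed for fast
#' classifier experiments. Scores for molecule i in structure j are
#' `mu_class + sd * (sqrt(rho) * z_i + sqrt(1 - rho) * e_ij)` with a shared
#' latent `z_i`, giving equicorrelated channels. Fit channels are truncated
#' Gaussians; decoys additionally drop to exactly 0 with probability
#' `fit_nonmapper_prob` (a non-mapping molecule is a real observation, not a
#' missing value). The last `n_unqualified` structures are generated with no
#' class separation and a redocking RMSD above 2 A.
#'
#' @param spec a [fixture_spec]
#' @return list with `ids`, `labels` (1 active / 0 decoy), `scores` and
#'   `fits` (molecule x structure matrices), and `structures` (data.frame
#'   with `structure_id`, `redock_rmsd`, `designed_qualified`)
#' @export
simulate_channels <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_act <- spec$n_actives
  n_dec <- spec$n_actives * spec$decoy_ratio
  n <- n_act + n_dec
  S <- spec$n_structures
  ids <- c(sprintf("act_%05d", seq_len(n_act)),
           sprintf("dec_%05d", seq_len(n_dec)))
  labels <- c(rep(1L, n_act), rep(0L, n_dec))
  rho <- spec$cross_structure_correlation
  good <- c(rep(TRUE, S - spec$n_unqualified),
            rep(FALSE, spec$n_unqualified))
  with_seed(spec$seed, {
    z <- stats::rnorm(n)
    mu <- ifelse(labels == 1L, spec$active_score_mean, spec$decoy_score_mean)
    scores <- matrix(NA_real_, n, S)
    fits <- matrix(NA_real_, n, S)
    fmu <- ifelse(labels == 1L, spec$active_fit_mean, spec$decoy_fit_mean)
    for (j in seq_len(S)) {
      e <- stats::rnorm(n)
      mu_j <- if (good[j]) mu else rep(spec$decoy_score_mean, n)
      scores[, j] <- mu_j + spec$score_sd *
        (sqrt(rho) * z + sqrt(1 - rho) * e)
      fmu_j <- if (good[j]) fmu else rep(spec$decoy_fit_mean, n)
      f <- pmax(0, stats::rnorm(n, fmu_j, spec$fit_sd))
      nonmap <- stats::runif(n) < spec$fit_nonmapper_prob & labels == 0L
      f[nonmap] <- 0
      fits[, j] <- f
    }
    rmsd_good <- stats::runif(S, 0.3, 1.5)
    rmsd <- ifelse(good, rmsd_good, stats::runif(S, 2.6, 4.0))
    rownames(scores) <- rownames(fits) <- ids
    sid <- sprintf("struct_%02d", seq_len(S))
    colnames(scores) <- colnames(fits) <- sid
    list(ids = ids, labels = labels, scores = scores, fits = fits,
         structures = data.frame(structure_id = sid,
                                 redock_rmsd = rmsd,
                                 designed_qualified = good,
                                 stringsAsFactors = FALSE))
  })
}

# -- synthetic molecule library ----------------------------------------------

# Core templates with two substitution slots. {R} slots are replaced by a
# parenthesised substituent or removed. Actives are biased toward fused
# azaindole-like (kinase-hinge) scaffolds; decoys draw from a broader pool.
.FIXTURE_CORES_ACTIVE <- c(
  "c1cc{R1}c2cc[nH]c2n1",                 # 7-azaindole core
  "c1cc{R1}c(-c2ccc{R2}cc2)c3cc[nH]c13",  # 4-aryl pyrrolopyridine
  "c1cc{R1}ncc1C(=O)NC{R2}C1CCNCC1",      # amide-piperidine
  "c1cc{R1}c2[nH]ncc2c1{R2}",             # indazole-like
  "c1cc{R1}nc(N{R2}C2CCNCC2)n1"           # aminopyrimidine-piperidine
)
.FIXTURE_CORES_DECOY <- c(
  "c1cc{R1}cc{R2}c1",
  "c1cc{R1}ccc1OCC(=O)N{R2}",
  "C1CC{R1}CCC1{R2}",
  "c1cc{R1}sc1C(=O)OC{R2}",
  "c1cc{R1}oc1C{R2}",
  "C{R1}C(=O)NC{R2}C(=O)O",
  "c1cc{R1}ccc1S(=O)(=O)NC{R2}",
  "c1cc{R1}cnc1N{R2}"
)
.FIXTURE_SUBS <- c("", "(C)", "(CC)", "(CCC)", "(C(C)C)", "(O)", "(OC)",
                   "(OCC)", "(N)", "(NC)", "(F)", "(Cl)", "(C(=O)OC)",
                   "(C(=O)N)", "(C(F)(F)F)")

.fixture_smiles <- function(core, sub1, sub2) {
  s <- sub("\\{R1\\}", sub1, core)
  sub("\\{R2\\}", sub2, s, fixed = FALSE)
}

#' Generate a complete synthetic screening fixture
#'
#' Builds the molecule library (fragment-combinatorial SMILES with computed
#' MW/HBD/HBA and synthetic logP/logS/Caco-2 properties), the per-structure
#' docking [score_table]s and fit-value tables of [simulate_channels()], and
#' the per-structure redocking RMSD table. Byte-identical output for the same
#' spec (including seed).
#'
#' @param spec a [fixture_spec]
#' @return list with `molecules` (list of [molecule_record]), `score_tables`
#'   (list of [score_table]), `fit_tables` (list of named numeric vectors per
#'   structure), `structures`, `ids`, `labels`
#' @export
generate_fixtures <- function(spec) {
  ch <- simulate_channels(spec)
  n <- length(ch$ids)
  graph_cache <- new.env(hash = TRUE)
  parse_cached <- function(smi) {
    if (!exists(smi, envir = graph_cache))
      assign(smi, parse_smiles(smi), envir = graph_cache)
    get(smi, envir = graph_cache)
  }
  molecules <- with_seed(spec$seed + 1L, {
    cores <- ifelse(ch$labels == 1L,
                    sample(.FIXTURE_CORES_ACTIVE, n, replace = TRUE),
                    sample(.FIXTURE_CORES_DECOY, n, replace = TRUE))
    s1 <- sample(.FIXTURE_SUBS, n, replace = TRUE)
    s2 <- sample(.FIXTURE_SUBS, n, replace = TRUE)
    logp <- round(stats::rnorm(n, 2.5, 1.0), 2)
    logs <- round(-stats::rnorm(n, 3.5, 0.8), 2)
    caco <- round(stats::rlnorm(n, log(200), 0.9), 2)
    out <- vector("list", n)
    for (k in seq_len(n)) {
      smi <- .fixture_smiles(cores[k], s1[k], s2[k])
      mol <- parse_cached(smi)
      out[[k]] <- molecule_record(
        ch$ids[k], mol,
        properties = list(MW = round(mol_mw(mol), 2),
                          logP = min(6, max(-2, logp[k])),
                          logS = logs[k], caco2 = caco[k],
                          HBD = count_hbd(mol), HBA = count_hba(mol)),
        label = if (ch$labels[k] == 1L) "active" else "decoy")
    }
    out
  })
  sids <- ch$structures$structure_id
  score_tables <- lapply(seq_along(sids), function(j) {
    v <- ch$scores[, j]
    names(v) <- ch$ids
    score_table(sids[j], v, "stand-in")
  })
  names(score_tables) <- sids
  fit_tables <- lapply(seq_along(sids), function(j) {
    v <- ch$fits[, j]
    names(v) <- ch$ids
    v
  })
  names(fit_tables) <- sids
  list(molecules = molecules, score_tables = score_tables,
       fit_tables = fit_tables, structures = ch$structures,
       ids = ch$ids, labels = ch$labels)
}
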
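test_that("training-set assembly enforces the ratio and pool size", {
  fx <- small_campaign_fixture()
  actives <- fx$molecules[fx$labels == 1L]
  decoys <- fx$molecules[fx$labels == 0L]
  ts <- build_training_set(actives[1:5], decoys, ratio = 20L, seed = 1L)
  expect_length(ts, 105L)
  expect_equal(sum(vapply(ts, `[[`, "", "label") == "decoy"), 100L)
  # pool exactly the required size is taken whole
  ts2 <- build_training_set(actives, decoys, ratio = 20L, seed = 1L)
  expect_length(ts2, 420L)
  # pool too small names the required count
  expect_error(build_training_set(actives[1:5], decoys[1:10], ratio = 20L),
               "100")
})

test_that("diversity picking is deterministic and spreads picks", {
  fx <- small_campaign_fixture()
  decoys <- fx$molecules[fx$labels == 0L]
  p1 <- build_training_set(fx$molecules[fx$labels == 1L][1:3], decoys,
                           ratio = 20L, seed = 9L)
  p2 <- build_training_set(fx$molecules[fx$labels == 1L][1:3], decoys,
                           ratio = 20L, seed = 9L)
  expect_identical(vapply(p1, `[[`, "", "id"), vapply(p2, `[[`, "", "id"))
  # a max-min pick of k from a redundant pool covers more unique structures
  # than the first k in pool order
  ids_picked <- vapply(p1[-(1:3)], `[[`, "", "id")
  smiles_of <- function(ids) {
    vapply(decoys[match(ids, vapply(decoys, `[[`, "", "id"))],
           function(m) m$structure$smiles, "")
  }
  first_k <- vapply(decoys[seq_along(ids_picked)],
                    function(m) m$structure$smiles, "")
  expect_gte(length(unique(smiles_of(ids_picked))),
             length(unique(first_k)))
})

test_that("equal-frequency binning follows the documented quantile rule", {
  fm <- feature_matrix(matrix(as.numeric(1:10), 10L, 1L,
                              dimnames = list(paste0("m", 1:10), "c")),
                       labels = rep(c(1L, 0L), 5L))
  bn <- fit_bins(fm, 4L)
  occ <- table(ensembleVS:::.bin_index(1:10, bn$edges$c))
  expect_equal(as.integer(occ), c(3L, 2L, 3L, 2L))
  fm100 <- feature_matrix(matrix(as.numeric(1:100), 100L, 1L,
                                 dimnames = list(paste0("m", 1:100), "c")),
                          labels = rep(c(1L, 0L), 50L))
  expect_equal(as.integer(table(ensembleVS:::.bin_index(
    1:100, fit_bins(fm100, 10L)$edges$c))), rep(10L, 10L))
  # constant channel degenerates to one bin with a warning
  fmc <- feature_matrix(matrix(5, 6L, 1L,
                               dimnames = list(paste0("m", 1:6), "c")),
                        labels = rep(c(1L, 0L), 3L))
  expect_warning(bc <- fit_bins(fmc, 10L), "constant")
  expect_length(bc$edges$c, 0L)
  # all-missing channel is dropped
  fmm <- feature_matrix(matrix(c(1:6, rep(NA_real_, 6L)), 6L, 2L,
                               dimnames = list(paste0("m", 1:6),
                                               c("ok", "gone"))),
                        labels = rep(c(1L, 0L), 3L))
  expect_warning(bm <- fit_bins(fmm, 3L), "all-missing")
  expect_named(bm$edges, "ok")
})

test_that("NBC weights follow the Laplacian-corrected formula", {
  # 2 actives in a bin holding only them, prior 0.1 (K = 10)
  vals <- matrix(c(5, 5, rep(1, 18)), 20L, 1L,
                 dimnames = list(paste0("m", 1:20), "c"))
  fm <- feature_matrix(vals, c(rep(1L, 2L), rep(0L, 18L)))
  bins <- structure(list(edges = list(c = 3), bin_count = 2L),
                    class = "binning_scheme")
  mod <- train_nbc(fm, bins)
  expect_equal(mod$prior, 0.1)
  expect_equal(mod$K, 10)
  expect_equal(mod$weights$c[2L], log(3 / 1.2), tolerance = 1e-12)
  # scoring puts a molecule in that bin
  expect_equal(score_nbc(mod, c(c = 5)), log(3 / 1.2), tolerance = 1e-12)
  expect_equal(score_nbc(mod, c(c = NA)), 0)
  expect_error(score_nbc(mod, c(zzz = 1)), "unknown channel")
  # empty bin is exactly neutral: no value ever lands above edge 3 in a
  # scheme with an extra edge
  bins3 <- structure(list(edges = list(c = c(3, 10)), bin_count = 3L),
                     class = "binning_scheme")
  mod3 <- train_nbc(fm, bins3)
  expect_identical(mod3$weights$c[3L], 0)
  # a bin with A/T equal to the prior tends to neutrality as T grows
  n <- 10000L
  vals_big <- matrix(1, n, 1L, dimnames = list(paste0("m", 1:n), "c"))
  fm_big <- feature_matrix(vals_big, c(rep(1L, n / 10L), rep(0L, 9L * n / 10L)))
  mod_big <- train_nbc(fm_big, structure(list(edges = list(c = numeric(0)),
                                              bin_count = 1L),
                                         class = "binning_scheme"))
  expect_lt(abs(mod_big$weights$c[1L]), 1e-3)
  # single-class labels are fatal
  fm_one <- feature_matrix(vals, rep(1L, 20L))
  expect_error(train_nbc(fm_one, bins), "both classes")
})

test_that("score_nbc equals the brute-force bin-count oracle", {
  with_seed(5L, {
    for (rep in 1:4) {
      n <- 30L
      n_ch <- sample(2:4, 1L)
      vals <- matrix(round(rnorm(n * n_ch), 1L), n, n_ch,
                     dimnames = list(sprintf("m%02d", 1:n),
                                     paste0("ch", seq_len(n_ch))))
      vals[sample(length(vals), 5L)] <- NA      # masked entries
      y <- sample(c(rep(1L, 10L), rep(0L, 20L)))
      fm <- feature_matrix(vals, y)
      bins <- suppressWarnings(fit_bins(fm, 3L))
      mod <- train_nbc(fm, bins)
      got <- score_nbc(mod, vals)
      for (i in seq_len(n)) {
        row <- as.list(vals[i, ])
        want <- oracle_nbc_score(vals, y, bins$edges, row)
        expect_equal(unname(got[i]), want, tolerance = 1e-12)
        expect_equal(score_nbc(mod, vals[i, ]), want, tolerance = 1e-12)
      }
    }
  })
})

test_that("scores are additive over independent channels", {
  vals <- matrix(c(5, 5, rep(1, 18), rep(c(2, 7), 10L)), 20L, 2L,
                 dimnames = list(paste0("m", 1:20), c("a", "b")))
  fm <- feature_matrix(vals, c(rep(1L, 2L), rep(0L, 18L)))
  bins <- fit_bins(fm, 2L)
  mod <- train_nbc(fm, bins)
  s_both <- score_nbc(mod, c(a = 5, b = 7))
  s_a <- score_nbc(mod, c(a = 5, b = NA))
  s_b <- score_nbc(mod, c(a = NA, b = 7))
  expect_equal(s_both, s_a + s_b, tolerance = 1e-12)
})

test_that("training separates classes whenever a channel does", {
  ch <- simulate_channels(fixture_spec(n_actives = 50L, decoy_ratio = 10L,
                                       n_structures = 2L, seed = 17L))
  fm <- feature_matrix(cbind(ch$scores, ch$fits), ch$labels)
  mod <- train_nbc(fm, fit_bins(fm, 10L))
  s <- score_nbc(mod, fm$values)
  expect_gt(mean(s[ch$labels == 1L]), mean(s[ch$labels == 0L]))
})

test_that("ranking is stable, id-tie-broken and permutation invariant", {
  vals <- matrix(c(1, 1, 3, 2, 9, 9, 9, 9), 4L, 2L,
                 dimnames = list(c("mB", "mA", "mD", "mC"), c("a", "b")))
  fm <- feature_matrix(vals, c(1L, 1L, 0L, 0L))
  mod <- train_nbc(fm, suppressWarnings(fit_bins(fm, 2L)))  # 'b' is constant
  r_all <- rank_library(mod, fm, 10L)
  expect_equal(nrow(r_all), 4L)                   # top_n > size: whole library
  expect_true(!is.unsorted(-r_all$score))
  # equal scores resolve by id
  ties <- which(duplicated(r_all$score) | duplicated(r_all$score, fromLast = TRUE))
  if (length(ties) > 1L)
    expect_true(!is.unsorted(r_all$molecule_id[ties]))
  # permuting rows changes nothing
  perm <- c(3L, 1L, 4L, 2L)
  fm_p <- feature_matrix(vals[perm, ], c(1L, 1L, 0L, 0L)[perm])
  r_p <- rank_library(mod, fm_p, 10L)
  expect_equal(r_p$molecule_id, r_all$molecule_id)
  expect_equal(r_p$score, r_all$score)
  expect_equal(nrow(rank_library(mod, fm, 2L)), 2L)
})

test_that("feature assembly applies the missing-value policy", {
  st <- list(score_table("s1", c(m1 = -9, m2 = -8)),
             score_table("s2", c(m1 = -7, m2 = -6, m3 = -5)))
  ft <- list(s1 = c(m1 = 2.5), s2 = c(m1 = 1.0, m3 = 0.5))
  fm <- assemble_features(c("m1", "m2", "m3"), st, ft)
  expect_equal(colnames(fm$values),
               c("dock_s1", "dock_s2", "fit_s1", "fit_s2"))
  expect_true(is.na(fm$values["m3", "dock_s1"]))   # failed docking: masked
  expect_equal(fm$values["m2", "fit_s1"], 0)        # non-mapper: observed 0
  expect_equal(fm$values["m1", "fit_s2"], 1.0)
})

test_that("dropping a structure's channels leaves the others untouched", {
  fx <- small_campaign_fixture()
  fm_all <- assemble_features(fx$ids, fx$score_tables, fx$fit_tables)
  fm_less <- assemble_features(fx$ids, fx$score_tables[-1L],
                               fx$fit_tables[-1L])
  shared <- colnames(fm_less$values)
  expect_identical(fm_all$values[, shared], fm_less$values[, shared])
})

test_that("bayes models survive a JSON round trip", {
  fx <- small_campaign_fixture()
  fm <- assemble_features(fx$ids, fx$score_tables, fx$fit_tables,
                          labels = fx$labels)
  mod <- train_nbc(fm, fit_bins(fm, 5L))
  f <- withr::local_tempfile(fileext = ".json")
  write_bayes_model(mod, f)
  back <- read_bayes_model(f)
  expect_equal(back$prior, mod$prior)
  expect_equal(back$weights, mod$weights, tolerance = 1e-12)
  expect_equal(back$binning$edges, mod$binning$edges, tolerance = 1e-12)
  expect_equal(score_nbc(back, fm$values), score_nbc(mod, fm$values),
               tolerance = 1e-12)
})
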
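test_that("feature perception applies the documented rule set", {
  fb <- perceive_features(benzene())
  expect_equal(vapply(fb, `[[`, "", "kind"), "aromatic_ring")
  # symmetry forces the centroid of the ring
  expect_equal(fb[[1L]]$center,
               colMeans(benzene()$conformers[[1L]]), tolerance = 1e-9)

  fm <- perceive_features(methanol())
  expect_setequal(vapply(fm, `[[`, "", "kind"), c("HB_donor", "HB_acceptor"))
  expect_length(fm, 2L)

  fba <- perceive_features(benzamidine())
  expect_setequal(vapply(fba, `[[`, "", "kind"),
                  c("pos_ionizable", "aromatic_ring"))
  expect_length(fba, 2L)

  fh <- perceive_features(hexane())
  expect_equal(vapply(fh, `[[`, "", "kind"), "hydrophobe")
  expect_error(perceive_features(toluene()), "no conformer")
})

test_that("conformer generation respects rigidity, caps and seeds", {
  expect_length(benzene()$conformers, 1L)          # no rotatable bonds
  hx1 <- generate_conformers(mk_mol("CCCCCC", confs = FALSE), max_confs = 1L)
  expect_length(hx1$conformers, 1L)
  hx <- generate_conformers(mk_mol("CCCCCC", confs = FALSE),
                            max_confs = 100L, seed = 2L)
  expect_gte(length(hx$conformers), 1L)
  expect_lte(length(hx$conformers), 100L)
  hx_again <- generate_conformers(mk_mol("CCCCCC", confs = FALSE),
                                  max_confs = 100L, seed = 2L)
  expect_identical(hx$conformers, hx_again$conformers)
  # ensemble members are mutually distinct at the 0.5 A dedup radius
  if (length(hx$conformers) > 1L) {
    r12 <- kabsch(hx$conformers[[1L]], hx$conformers[[2L]])$rmsd
    expect_gt(r12, 0.5)
  }
})

test_that("model derivation enumerates matched-feature subsets", {
  feats <- lapply(1:5, function(i)
    pharmacophore_feature(c("HB_donor", "HB_acceptor", "aromatic_ring",
                            "hydrophobe", "HB_donor")[i],
                          center = c(i, 0, 0)))
  # 3 matched -> exactly one model of size 3
  m3 <- derive_models(feats, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_length(m3, 1L)
  expect_length(m3[[1L]]$features, 3L)
  # 5 matched -> subsets of sizes 3..5 (16 candidates), capped at 10
  m5 <- derive_models(feats, rep(TRUE, 5L))
  expect_length(m5, 10L)
  sizes <- vapply(m5, function(m) length(m$features), 0L)
  expect_true(all(sizes >= 3L & sizes <= 5L))
  # default surrogate ranks larger (rarer) models first
  expect_equal(sizes[1L], 5L)
  # 2 matched -> empty with warning
  expect_warning(m2 <- derive_models(feats, c(TRUE, TRUE, rep(FALSE, 3L))),
                 "no model")
  expect_length(m2, 0L)
})

test_that("receptor contact matching uses the distance windows", {
  feats <- list(
    pharmacophore_feature("HB_donor", c(0, 0, 0)),
    pharmacophore_feature("hydrophobe", c(10, 0, 0)),
    pharmacophore_feature("HB_acceptor", c(20, 0, 0)))
  rec <- data.frame(element = c("O", "C", "N"),
                    x = c(3.0, 13.0, 24.5), y = 0, z = 0)
  # donor: O at 3.0 <= 3.5 ok; hydrophobe: C at 3.0 <= 4.5 ok;
  # acceptor: N at 4.5 > 3.5 fails
  expect_equal(match_receptor_contacts(feats, rec), c(TRUE, TRUE, FALSE))
})

test_that("selectivity is the capped -log10 match fraction", {
  donor_mol <- mk_mol("Nc1ccc(O)cc1", "aminophenol")
  model <- pharmacophore_model("m", "cx",
                               perceive_features(donor_mol)[1:3],
                               min_features = 3L)
  # aminophenols map the model they generated; benzenes lack the polar
  # features entirely and can never map
  mappers <- replicate(4, donor_mol, simplify = FALSE)
  expect_equal(estimate_selectivity(model, mappers), 0)
  nonmappers <- replicate(4, benzene(), simplify = FALSE)
  expect_equal(estimate_selectivity(model, nonmappers), -log10(0.5 / 4))
  mixed <- c(mappers[1L], nonmappers[1:3])
  expect_equal(estimate_selectivity(model, mixed), -log10(1 / 4))
})

test_that("selectivity never decreases when features are added", {
  base <- lapply(1:3, function(i)
    pharmacophore_feature("hydrophobe", c(1.2 * i, 0.3 * i, 0)))
  extra <- pharmacophore_feature("aromatic_ring", c(0, 3, 0))
  small <- pharmacophore_model("s", "cx", base, min_features = 3L)
  large <- pharmacophore_model("l", "cx", c(base, list(extra)),
                               min_features = 3L)
  ref <- list(hexane(), benzene(), mk_mol("CCCCC(C)C", "branched"),
              mk_mol("Cc1ccccc1C", "xylene"))
  expect_gte(estimate_selectivity(large, ref),
             estimate_selectivity(small, ref))
})

test_that("self-mapping attains the weight sum; motion leaves fit unchanged", {
  mol <- mk_mol("Nc1ccc(O)cc1", "aminophenol")
  f <- perceive_features(mol)
  expect_gte(length(f), 3L)
  model <- pharmacophore_model("m", "cx", f[1:3], min_features = 3L)
  r <- map_fit(model, mol)
  expect_equal(r$fit_value, 3.0, tolerance = 1e-9)
  expect_equal(r$best_conformer_index, 1L)
  expect_equal(nrow(r$feature_assignment), 3L)
  expect_false(anyDuplicated(r$feature_assignment[, 2L]) > 0L)
  # random rigid motions of the conformer
  with_seed(7L, {
    for (i in 1:5) {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2)); th <- runif(1, 0, pi)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3L, 3L, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      moved <- mol
      moved$conformers <- lapply(mol$conformers, function(x)
        t(R %*% t(x)) + matrix(rnorm(3, 0, 5), nrow(x), 3L, byrow = TRUE))
      expect_equal(map_fit(model, moved)$fit_value, 3.0, tolerance = 1e-9)
    }
  })
})

test_that("displacement penalty arithmetic matches the quadratic form", {
  # in the receptor frame (align = FALSE) displacements are taken literally
  mol <- mk_mol("Nc1ccc(O)cc1", "aminophenol")
  f <- perceive_features(mol)[1:3]
  tol <- f[[1L]]$tolerance
  exact <- pharmacophore_model("m0", "cx", f, min_features = 3L)
  expect_equal(map_fit(exact, mol, align = FALSE)$fit_value, 3.0,
               tolerance = 1e-9)
  # one feature displaced by exactly its tolerance: that term contributes 0
  f_tol <- f
  f_tol[[1L]]$center <- f_tol[[1L]]$center + c(0, 0, tol)
  m_tol <- pharmacophore_model("m1", "cx", f_tol, min_features = 3L)
  expect_equal(map_fit(m_tol, mol, align = FALSE)$fit_value, 2.0,
               tolerance = 1e-9)
  # displaced by tolerance/2: term contributes 1 - 0.25
  f_half <- f
  f_half[[1L]]$center <- f_half[[1L]]$center + c(0, 0, tol / 2)
  m_half <- pharmacophore_model("m2", "cx", f_half, min_features = 3L)
  expect_equal(map_fit(m_half, mol, align = FALSE)$fit_value, 2.75,
               tolerance = 1e-9)
  # beyond twice the tolerance the assignment is rejected outright
  f_far <- f
  f_far[[1L]]$center <- f_far[[1L]]$center + c(0, 0, 2.01 * tol)
  m_far <- pharmacophore_model("m3", "cx", f_far, min_features = 3L)
  expect_equal(map_fit(m_far, mol, align = FALSE)$fit_value, 0)
})

test_that("map_fit equals the exhaustive assignment oracle", {
  mols <- list(mk_mol("Nc1ccc(O)cc1", "aminophenol"),
               mk_mol("OCCN", "aminoethanol"),
               mk_mol("NC(=N)c1ccccc1", "benzamidine2"),
               mk_mol("OCC(O)CO", "glycerol"))
  with_seed(13L, {
    for (mol in mols) {
      f <- perceive_features(mol)
      if (length(f) < 3L) next
      # perturb the model slightly so fits are non-trivial
      feats <- lapply(f[seq_len(min(4L, length(f)))], function(ft) {
        ft$center <- ft$center + rnorm(3, 0, 0.4)
        ft
      })
      model <- pharmacophore_model(paste0("m_", mol$id), "cx", feats,
                                   min_features = 3L)
      got <- map_fit(model, mol)$fit_value
      want <- oracle_map_fit(model, mol)
      expect_equal(got, want, tolerance = 1e-9)
      expect_gte(got, 0)
      expect_lte(got, length(feats) + 1e-12)
    }
  })
})

test_that("models survive a JSON round trip", {
  feats <- lapply(1:3, function(i)
    pharmacophore_feature("HB_donor", c(i, 2 * i, 0), tolerance = 1.2,
                          weight = 0.5))
  m <- pharmacophore_model("m1", "cx", feats, selectivity = 1.25)
  f <- withr::local_tempfile(fileext = ".json")
  write_pharmacophore_models(list(m), f)
  back <- read_pharmacophore_models(f)
  expect_length(back, 1L)
  expect_equal(back[[1L]]$model_id, "m1")
  expect_equal(back[[1L]]$selectivity, 1.25)
  expect_equal(do.call(rbind, lapply(back[[1L]]$features, `[[`, "center")),
               do.call(rbind, lapply(feats, `[[`, "center")))
})
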
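test_that("fingerprints are deterministic and kind-checked", {
  f1 <- fingerprint(benzene(), "maccs")
  f2 <- fingerprint(benzene(), "maccs")
  expect_identical(as.logical(f1), as.logical(f2))
  expect_length(f1, 166L)
  e1 <- fingerprint(benzene(), "ecfp")
  expect_length(e1, 2048L)
  expect_error(tanimoto(f1, e1), "mismatch")
  expect_error(fingerprint(molgraph(
    data.frame(element = character(0), aromatic = logical(0),
               charge = integer(0), hcount = integer(0)),
    data.frame(i = integer(0), j = integer(0), order = numeric(0),
               aromatic = logical(0)))), "empty")
})

test_that("structural keys order similarity sensibly", {
  fp_bz <- fingerprint(benzene(), "maccs")
  fp_tol <- fingerprint(toluene(), "maccs")
  fp_met <- fingerprint(methane(), "maccs")
  expect_equal(tanimoto(fp_bz, fp_bz), 1.0)
  # methane shares strictly fewer keys with benzene than toluene does
  expect_lt(sum(as.logical(fp_met) & as.logical(fp_bz)),
            sum(as.logical(fp_tol) & as.logical(fp_bz)))
  expect_gt(tanimoto(fp_bz, fp_tol), tanimoto(fp_bz, fp_met))
})

test_that("tanimoto identities hold", {
  a <- fingerprint(benzene(), "ecfp")
  b <- fingerprint(toluene(), "ecfp")
  expect_equal(tanimoto(a, b), tanimoto(b, a))
  expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
  expect_lt(tanimoto(a, b), 1)
  # disjoint and both-empty conventions via hand-built fingerprints
  mk_fp <- function(bits) structure(bits, kind = "ecfp", nbits = length(bits),
                                    class = "fingerprint")
  expect_equal(tanimoto(mk_fp(c(TRUE, FALSE, FALSE)),
                        mk_fp(c(FALSE, TRUE, FALSE))), 0)
  expect_equal(tanimoto(mk_fp(rep(FALSE, 3L)), mk_fp(rep(FALSE, 3L))), 0)
  expect_equal(tanimoto(mk_fp(c(TRUE, TRUE, TRUE, FALSE)),
                        mk_fp(c(TRUE, TRUE, FALSE, TRUE))), 0.5)  # 2 / 4
})

test_that("single-linkage clustering is transitive and monotone", {
  mk_fp <- function(bits) structure(bits, kind = "x", nbits = length(bits),
                                    class = "fingerprint")
  same <- replicate(3, mk_fp(c(TRUE, TRUE, FALSE, TRUE)), simplify = FALSE)
  expect_equal(cluster_by_similarity(same, 0.85), rep(1L, 3L))
  # pairwise at exactly the threshold stays apart (strict >)
  a <- mk_fp(c(rep(TRUE, 17), rep(FALSE, 7)))
  b <- mk_fp(c(rep(TRUE, 20), rep(FALSE, 4)))       # sim(a, b) = 17/20 = 0.85
  expect_equal(cluster_by_similarity(list(a, b), 0.85), c(1L, 2L))
  # chain A~B, B~C, A!~C still collapses into one cluster
  fA <- mk_fp(c(rep(TRUE, 18), rep(FALSE, 4), rep(FALSE, 2)))
  fB <- mk_fp(c(rep(TRUE, 20), rep(FALSE, 2), rep(FALSE, 2)))
  fC <- mk_fp(c(rep(TRUE, 20), rep(TRUE, 2), rep(FALSE, 2)))
  expect_gt(tanimoto(fA, fB), 0.85)
  expect_gt(tanimoto(fB, fC), 0.85)
  expect_lt(tanimoto(fA, fC), 0.85 + 1e-9)
  expect_equal(cluster_by_similarity(list(fA, fB, fC), 0.85), rep(1L, 3L))
  # permutation invariance up to relabeling
  l1 <- cluster_by_similarity(list(fA, fB, fC, a, b), 0.85)
  l2 <- cluster_by_similarity(list(b, fC, fA, a, fB), 0.85)[c(3L, 5L, 2L, 4L, 1L)]
  expect_equal(length(unique(l1)), length(unique(l2)))
  expect_equal(outer(l1, l1, "=="), outer(l2, l2, "=="))
  # raising the threshold never merges clusters
  lo <- cluster_by_similarity(list(fA, fB, fC, a, b), 0.5)
  hi <- cluster_by_similarity(list(fA, fB, fC, a, b), 0.95)
  expect_gte(length(unique(hi)), length(unique(lo)))
})

test_that("Rule-of-Five verdicts match the assayed panel and hand cases", {
  panel <- rock1_inhibitor_panel()
  for (i in seq_len(nrow(panel))) {
    v <- lipinski_ro5(list(MW = panel$mw[i], logP = panel$logp[i]),
                      panel$compound[i])
    expect_true(v$passed)
    expect_length(v$violations, 0L)      # all panel rows are inside MW/logP
    expect_setequal(v$skipped, c("HBD", "HBA"))
  }
  bad <- lipinski_ro5(list(MW = 600, logP = 6, HBD = 6, HBA = 11), "bad")
  expect_false(bad$passed)
  expect_length(bad$violations, 4L)
  # exactly one violation still passes
  one <- lipinski_ro5(list(MW = 501, logP = 2, HBD = 1, HBA = 4), "one")
  expect_true(one$passed)
  expect_length(one$violations, 1L)
})

test_that("REOS windows and alerts fire as documented", {
  v_bz <- reos_filter(benzene())
  expect_false(v_bz$passed)
  expect_true(any(grepl("MW", v_bz$violations)))
  expect_true(any(grepl("heavy atoms", v_bz$violations)))
  # a constructed druglike molecule inside every window passes
  v_ok <- reos_filter(druglike_350())
  expect_true(v_ok$passed)
  expect_length(v_ok$violations, 0L)
  # acyl halide alert is named
  v_acyl <- reos_filter(mk_mol("c1ccc(cc1)C(=O)NC2CCN(CC2)C(=O)Cl", "acyl",
                               confs = FALSE,
                               properties = list(logP = 2.0)))
  expect_false(v_acyl$passed)
  expect_true(any(grepl("acyl_halide", v_acyl$violations)))
  # an aldehyde fails but the matching ketone analogue does not
  v_ald <- reos_filter(mk_mol("O=CCCc1ccc(cc1)C2CCNCC2c3ccccc3", "ald",
                              confs = FALSE, properties = list(logP = 3)))
  expect_true(any(grepl("aldehyde", v_ald$violations)))
  v_ket <- reos_filter(mk_mol("O=C(C)CCc1ccc(cc1)C2CCNCC2c3ccccc3", "ket",
                              confs = FALSE, properties = list(logP = 3)))
  expect_false(any(grepl("aldehyde", v_ket$violations)))
})

test_that("substructure search honors aromaticity and substitution", {
  scaffold <- parse_smiles(pyrrolopyridine_scaffold)
  lib <- list(
    mk_mol(pyrrolopyridine_scaffold, "self", confs = FALSE),
    mk_mol(pyrrolopyridine_analogue, "analogue", confs = FALSE),
    mk_mol("c1ccc(-c2ccccn2)cc1", "biarylpyridine", confs = FALSE),
    benzene())
  hits <- substructure_search(scaffold, lib)
  expect_equal(vapply(hits, `[[`, "", "id"), c("self", "analogue"))
  # benzene pattern: in pyridine every embedding hits the heteroatom
  expect_false(has_substructure(parse_smiles("c1ccccc1"),
                                parse_smiles("c1ccncc1")))
  expect_true(has_substructure(parse_smiles("c1ccccc1"),
                               parse_smiles("Cc1ccccc1")))
  # bond order matters: an ether pattern is absent from an ester's C=O
  expect_false(has_substructure(parse_smiles("C=C"), parse_smiles("CC")))
  expect_error(substructure_search("", lib))
})

test_that("substructure matcher agrees with the igraph LAD oracle", {
  cases <- list(
    c("c1ccccc1", pyrrolopyridine_scaffold),
    c("C(=O)N", "CC(=O)NC1CCNCC1"),
    c("c1cc[nH]c1", pyrrolopyridine_analogue),
    c("CCO", "c1ccccc1"),
    c(pyrrolopyridine_scaffold, pyrrolopyridine_analogue))
  for (cs in cases) {
    pat <- parse_smiles(cs[1L]); tgt <- parse_smiles(cs[2L])
    got <- has_substructure(pat, tgt)
    # oracle: LAD with compatibility domains, bond orders checked post hoc
    gp <- mol_igraph(pat); gt <- mol_igraph(tgt)
    domains <- lapply(seq_len(nrow(pat$atoms)), function(i) {
      which(tgt$atoms$element == pat$atoms$element[i] &
              tgt$atoms$aromatic == pat$atoms$aromatic[i])
    })
    want <- FALSE
    if (!any(lengths(domains) == 0L)) {
      maps <- igraph::subgraph_isomorphisms(gp, gt, method = "lad",
                                            induced = FALSE,
                                            domains = domains)
      for (mp in maps) {
        mp <- as.integer(mp)
        ok <- TRUE
        for (k in seq_len(nrow(pat$bonds))) {
          ti <- mp[pat$bonds$i[k]]; tj <- mp[pat$bonds$j[k]]
          eb <- which((tgt$bonds$i == ti & tgt$bonds$j == tj) |
                        (tgt$bonds$i == tj & tgt$bonds$j == ti))
          if (length(eb) == 0L) { ok <- FALSE; break }
          if (pat$bonds$aromatic[k]) {
            if (!tgt$bonds$aromatic[eb]) { ok <- FALSE; break }
          } else if (tgt$bonds$aromatic[eb] ||
                     tgt$bonds$order[eb] != pat$bonds$order[k]) {
            ok <- FALSE; break
          }
        }
        if (ok) { want <- TRUE; break }
      }
    }
    expect_identical(got, want)
  }
})

test_that("max similarity to a known set behaves as a maximum", {
  known <- list(benzene(), toluene())
  expect_equal(max_similarity_to_known(benzene(), known), 1.0)
  expect_lt(max_similarity_to_known(mk_mol("NCCO", "mea", confs = FALSE),
                                    known), 0.2)
  m <- mk_mol("Cc1ccccc1C", "xylene2", confs = FALSE)
  sims <- vapply(known, function(k)
    tanimoto(fingerprint(m, "ecfp"), fingerprint(k, "ecfp")), numeric(1))
  expect_equal(max_similarity_to_known(m, known), max(sims))
})
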
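---
title: "Ensemble virtual screening with Bayesian score fusion: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble virtual screening with Bayesian score fusion: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensembleVS)
```

## The problem and the model

Docking a compound library into a single rigid crystal structure of a target
ignores protein flexibility, and in practice the top-ranked hits from
different crystal structures of the same protein overlap very little. The
funnel implemented here treats each qualified structure as an information
channel and fuses the channels instead of choosing among them:

1. **Structure qualification.** A candidate receptor structure enters the
   ensemble only if redocking reproduces its co-crystallized ligand pose
   within 2.0 Å RMSD (*docking power*) and its docking scores separate known
   actives from decoys with a one-sided Mann–Whitney p ≤ 1e-20
   (*discrimination power*).
2. **Per-structure descriptors.** Every library molecule gets one docking
   score and one pharmacophore fit value per qualified structure (16
   channels for an 8-structure ensemble).
3. **Naive Bayesian fusion.** Each channel is discretized into B = 10
   equal-frequency bins. A bin holding A actives among T molecules, under
   class prior $p$ and smoothing constant $K = 1/p$, contributes the
   log-weight
   $$W = \log\frac{A + pK}{(T + K)\,p} = \log\frac{A + 1}{Tp + 1},$$
   so an empty bin is exactly neutral ($W = 0$) and a bin whose active
   fraction equals the prior tends to neutrality as it fills. A molecule's
   score is the sum of its bins' weights over non-missing channels. This is
   the classical Laplacian-corrected naive Bayes estimator; the choice
   $K = 1/p$ is what makes "no data" and "prior-consistent data" coincide at
   zero.
4. **Post-processing.** The top-N molecules are screened with Lipinski's
   Rule-of-Five (pass = at most one violation) and a REOS-style property +
   structural-alert filter (pass = zero violations), clustered at Tanimoto
   0.85 on structural keys (single linkage), and reduced to one
   representative per cluster. Selecting which representatives to purchase
   is a human decision and deliberately outside the pipeline.

The naive-independence assumption is knowingly wrong — channels from related
crystal structures are correlated — but binning makes the fusion
scale-free per channel, and the additive log-weight form degrades gracefully
under correlation: it over-counts shared evidence but preserves ranking
monotonicity in each channel.

## Statistical components

**Discrimination power.** Scores are better when more negative, so the
alternative hypothesis is that active scores are stochastically smaller. The
exact null distribution (`stats::pwilcox`) is used when there are no ties
and $n_a n_d \le 10^4$; otherwise a normal approximation with tie and
continuity corrections. Because interesting separations sit far below double
underflow ($10^{-100}$ and beyond), the log10 p-value is computed on the log
scale throughout and is the quantity compared against the −20 threshold.
A practical consequence worth knowing: the U statistic scales with
$n_a n_d$, so *no* small cohort can clear 1e-20 — with 20 actives and 400
decoys even perfect separation gives p ≈ 1e-14. The threshold is meaningful
at campaign scale (350/7000), and that is where the package tests it.

**Pose RMSD** is computed in the docking frame without superposition, heavy
atoms only, as is conventional for redocking checks. An optional symmetry
mode minimizes over graph automorphisms (element- and bond-colored), so a
benzene ring rotated by 60° correctly scores 0.

**ROC AUC** uses the Mann–Whitney identity with ties counted ½, making
`roc_auc` and `discrimination_power` two views of the same statistic.

## Pharmacophore machinery

Features are perceived from the molecular graph by a fixed rule set
(positive/negative ionizable groups claim their atoms first, then H-bond
donors/acceptors, aromatic ring centroids, and hydrophobic clusters of ≥ 3
carbons untouched by heteroatoms). Models are subsets (size ≥ 3) of the
ligand features that match a receptor interaction; matching is
distance-only — 3.5 Å to a receptor N/O for polar features, 4.5 Å to a
receptor carbon for apolar ones — because the toolkit stores heavy atoms
only and hydrogens have no coordinates to measure a donor angle from.

The fit value of a molecule against a model is the best over conformers and
over injective kind-compatible feature assignments of
$$\text{fit} = \sum_f w_f \max\!\left(0,\ 1 - (d_f/\text{tol}_f)^2\right),$$
where $d_f$ is the displacement of feature $f$ after least-squares (Kabsch)
superposition of the matched ligand feature centers onto the model centers,
and any feature landing beyond $2\,\text{tol}_f$ rejects the assignment.
Defaults: tolerance 1.6 Å (2.2 Å for hydrophobes), weight 1. With
`align = FALSE` the displacements are taken in the frame as given, which is
the right mode when conformers are already posed in the receptor frame; it
is also the mode in which boundary arithmetic is exact (a feature displaced
by its tolerance contributes 0; by half its tolerance, $1 - 0.25$).

Model **selectivity** is the empirical rarity $-\log_{10}$(fraction of a
reference library attaining non-zero fit), capped at $-\log_{10}(0.5/N)$
when nothing matches. The vendor estimator this stands in for is
regression-based and unpublished; empirical rarity is transparent and
directly testable. When no reference is supplied, candidate models are
ranked by feature count (more constraints ⇒ rarer), a deliberate surrogate.
Candidate models differ by feature subset only, not by tolerances.

**Conformers** come from an idealized-geometry builder: standard bond
lengths (covalent-radius sums shortened for bond order), 109.5°/120°/180°
angles by hybridization, planar polygon rings, and torsion-state sampling
at rotatable bonds ({60°, 180°, −60°} for sp3, {0°, 180°} for sp2), with
duplicates removed below 0.5 Å Kabsch RMSD. It is deterministic per seed,
exact for chains and isolated rings, approximate for fused ring systems,
and applies no force-field relaxation. In the campaign itself fit values
are ingested from tables; the builder exists so that the pharmacophore
operations are testable end to end without external software.

## The synthetic campaign generator

`fixture_spec()` states the world the tests run in, mirroring the campaign
the package is designed around:

| parameter | default | meaning |
|---|---|---|
| `n_actives` / `decoy_ratio` | 350 / 20 | 7000 decoys, the stated class imbalance |
| `active_score_mean` / `decoy_score_mean` | −9 / −6.5 | docking-score class means |
| `score_sd` | 1.5 | common within-class spread |
| `cross_structure_correlation` | 0.3 | equicorrelation of one molecule's scores across structures |
| `fit_nonmapper_prob` | 0.5 | chance a decoy fails to map a model (fit = 0) |
| `active_fit_mean` / `decoy_fit_mean` / `fit_sd` | 3 / 1.5 / 0.8 | truncated-Gaussian fit channels |
| `n_unqualified` | 0 | structures built to fail qualification |

The score model is a one-factor equicorrelated Gaussian:
$s_{ij} = \mu_{c(i)} + \sigma(\sqrt{\rho}\,z_i + \sqrt{1-\rho}\,e_{ij})$.
Two consequences are used as oracles. First, a single channel's ROC AUC has
the closed form $\Phi(\Delta\mu / (\sigma\sqrt{2}))$, which at the default
Δμ = 2.5, σ = 1.5 is $\Phi(1.1785) \approx 0.8807$; the empirical AUC at
350/7000 must sit within ±0.02 of it. Second, a low ρ makes per-structure
top-500 lists overlap weakly, reproducing qualitatively the observed
dispersion of single-structure hit lists. The correlation value 0.3 and the
fit-channel means were chosen once as plausible for kinase docking
campaigns and are not tuned to any test outcome.

Fixture molecules are fragment-combinatorial SMILES (active scaffolds
biased toward fused azaindole-like, kinase-hinge cores; decoys drawn from a
broader pool), with MW/HBD/HBA computed from the graph and logP/logS/Caco-2
drawn synthetically — in the real pipeline those are ingested predictions,
never computed. What the generator does **not** emulate: realistic
score–structure coupling (scores are independent of the molecular graph),
assay noise, activity cliffs, or tautomer/protonation effects. A green test
therefore establishes the *statistical* machinery, not chemical realism.

## Numerical choices

- Equal-frequency bin edges are type-1 quantiles (sorted values at indices
  $\lceil ni/B \rceil$), deduplicated; bins are $(-\infty, e_1], (e_1, e_2],
  \dots$ with open outer bins so any screening value is binnable. Values
  1..10 at B = 4 bin as {3, 2, 3, 2}.
- Missing policy: a molecule absent from a docking table is masked (a
  crashed run carries no information); a molecule absent from a fit table
  is a non-mapper and contributes a real 0.0 observation.
- Ranking ties break by molecule id in C-locale radix order — stable and
  platform independent, so reports are byte-reproducible.
- Persisted models write doubles as `%.17g` strings: JSON numeric emission
  is not bit-exact, and a training value sitting exactly on a bin edge must
  re-bin identically after a round trip.
- The assignment search in `map_fit` is exhaustive with kind-compatibility
  pruning, capped at 1e5 assignments per conformer (best-first truncation
  with a warning).
- p-values are clamped to $[10^{-300}, 1]$ on the natural scale; the log10
  value is exact.

## Known limitations

- The SMILES reader covers the common exchange subset (organic subset,
  brackets, branches, ring closures, aromatic lowercase); it performs no
  aromaticity perception, so Kekulé-form inputs stay alternating
  single/double and will not match aromatic-form patterns.
- Fingerprints are contract-stable within the toolkit but not
  bit-compatible with vendor MACCS/ECFP implementations; similarity values
  should only be compared to each other.
- Fused-ring conformer geometry is approximate (see above).
- The REOS alert list is compact (nine classical reactive groups); an
  in-house drug-likeness rule set can be attached through the
  `custom_rule` hook of `druglikeness_pass()`.

## A small worked run

```{r demo, eval = FALSE}
spec <- fixture_spec(n_structures = 9, n_unqualified = 1, seed = 1)
fx <- generate_fixtures(spec)
rpt <- run_campaign(campaign_config(seed = 1),
                    fx$molecules, fx$score_tables, fx$fit_tables,
                    redock_rmsds = setNames(fx$structures$redock_rmsd,
                                            fx$structures$structure_id))
print(rpt)
```

The report logs every stage count (structures qualified, training-set
sizes, ranked/filtered/representative counts) so two runs can be diffed;
identical config and seed give byte-identical JSON via
`write_campaign_report()`.
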
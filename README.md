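# ensembleVS

Ensemble virtual screening with naive Bayesian score fusion, for
computational chemists running structure-based campaigns against a target
with several crystal structures.

Docking a library into one rigid structure misses protein flexibility, and
the top hits produced by different crystal structures of the same protein
barely overlap. `ensembleVS` implements the integrated funnel that exploits
this instead of suffering from it:

1. **Qualify** candidate receptor structures: redocking pose RMSD ≤ 2.0 Å
   ("docking power") and one-sided Mann–Whitney separation of active vs
   decoy docking scores at p ≤ 1e-20 ("discrimination power").
2. **Describe** each library molecule by one docking-score channel and one
   pharmacophore fit-value channel per qualified structure.
3. **Fuse** the channels with a Laplacian-corrected naive Bayesian
   classifier over B = 10 equal-frequency bins per channel. A bin with A
   actives among T molecules, prior *p*, K = 1/*p*, contributes
   W = log[(A + pK) / ((T + K) p)] — an empty bin is exactly neutral, and a
   molecule's score is the sum of its bin weights over non-missing
   channels.
4. **Post-process** the top-N: Lipinski Rule-of-Five (≤ 1 violation) and a
   REOS-style property/alert filter (0 violations), single-linkage
   clustering at Tanimoto > 0.85 on structural keys, one representative per
   cluster.

The package also ships pharmacophore model derivation and fit mapping
(Catalyst-style quadratic displacement penalty), ROC/enrichment evaluation,
scaffold substructure search, and a deterministic synthetic campaign
generator so everything is testable offline. The chemistry layer (SMILES
subset, SDF V2000, fingerprints, substructure matching) is implemented
natively; fingerprints are contract-stable within the toolkit, not
bit-compatible with vendor keys.

## Worked example

A fully synthetic campaign at the stated scale — 350 actives, 7000 decoys
(20:1), nine candidate structures of which one is built to fail
qualification:

```r
library(ensembleVS)

spec <- fixture_spec(n_structures = 9, n_unqualified = 1, seed = 1)
fx <- generate_fixtures(spec)
rpt <- run_campaign(campaign_config(seed = 1),
                    fx$molecules, fx$score_tables, fx$fit_tables,
                    redock_rmsds = setNames(fx$structures$redock_rmsd,
                                            fx$structures$structure_id))
print(rpt)
#> <campaign_report>
#>   campaign seed 1: 7350 molecules (350 active, 7000 decoy), 9 structures
#>   stage qualify: 8 of 9 structures qualified (struct_01, struct_02, struct_03, struct_04, struct_05, struct_06, struct_07, struct_08)
#>   stage training_set: 350 actives + 7000 decoys (ratio 20)
#>   stage train_nbc: 16 channels, prior 0.0476, resubstitution AUC 1.0000
#>   stage rank: top 100 of 7350 kept
#>   stage filter: 24 of 100 pass Ro5+REOS
#>   stage cluster: 7 clusters at threshold 0.85 -> 7 representatives
```

Eight structures clear both thresholds (the ninth was generated with a bad
redock RMSD and no score separation); the classifier fuses the 16 channels,
the top 100 molecules are filtered to 24 drug-like ones, and clustering at
0.85 leaves 7 chemically distinct candidates:

```r
head(rpt$candidates)
#>    rank molecule_id    score druglike cluster
#> 3     3   act_00279 30.07438     TRUE       1
#> 9     9   act_00136 29.06406     TRUE       2
#> 23   23   act_00186 27.76640     TRUE       3
#> 25   25   act_00024 27.51329     TRUE       4
#> 49   49   act_00003 26.02612     TRUE       5
#> 60   60   act_00248 25.64946     TRUE       6
```

Campaign bookkeeping helpers reproduce the screening arithmetic — of 38
tested compounds, 11 confirmed actives is a 28.95% hit rate (a
single-structure campaign of 174 tested / 12 confirmed gives 6.90%), and 7
of the 11 assayed IC50 values in the bundled inhibitor panel fall below
10 μM:

```r
hit_rate(11, 38)                                      # 28.95
hit_rate(12, 174)                                     # 6.9
panel <- rock1_inhibitor_panel(hits_only = TRUE)
count_below_threshold(panel$ic50_um, 10)              # 7
```

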
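# Shared in-code fixtures: small molecules with conformers, and a compact
# synthetic campaign spec reused across files.

mk_mol <- function(smiles, id = "mol", confs = TRUE, ...) {
  m <- molecule_record(id, parse_smiles(smiles), ...)
  if (confs) m <- generate_conformers(m, max_confs = 20L, seed = 42L)
  m
}

benzene    <- function() mk_mol("c1ccccc1", "benzene")
methanol   <- function() mk_mol("CO", "methanol")
benzamidine <- function() mk_mol("NC(=N)c1ccccc1", "benzamidine")
hexane     <- function() mk_mol("CCCCCC", "hexane")
toluene    <- function() mk_mol("Cc1ccccc1", "toluene", confs = FALSE)
methane    <- function() mk_mol("C", "methane", confs = FALSE)

# the campaign's novelty scaffold and an analogue: N-methylated plus a ring
# substituent, which must still contain the scaffold
pyrrolopyridine_scaffold <- "c1ccc(-c2ccc3cc[nH]c3n2)cc1"
pyrrolopyridine_analogue <- "Cc1ccc(-c2ccc3cc(n(C)c3n2)C)cc1"

# a neutral, druglike molecule constructed inside every REOS window
# (MW ~350, 26 heavy atoms, logP supplied in range)
druglike_350 <- function() {
  mk_mol("CCOc1ccc(C(=O)NC2CCN(Cc3ccccc3)CC2)cc1", "druglike",
         confs = FALSE,
         properties = list(logP = 2.8))
}

small_campaign_fixture <- function(seed = 5L) {
  spec <- fixture_spec(n_actives = 20L, decoy_ratio = 20L,
                       n_structures = 4L, seed = seed)
  generate_fixtures(spec)
}
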
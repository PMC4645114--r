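# Molecular fingerprints: 166-position structural keys in the spirit of the
# public MACCS key set, and circular (Morgan-style, radius 3 = "diameter 6")
# hashed fingerprints. Definitions are contract-stable within this toolkit;
# they are NOT bit-compatible with any vendor implementation, so similarity
# values are comparable only to each other.

.MACCS_LEN <- 166L
.ECFP_LEN <- 2048L

#' Compute a molecular fingerprint
#'
#' @param molecule a [molecule_record] or [molgraph]
#' @param kind `"maccs"` (166 structural keys) or `"ecfp"` (circular,
#'   radius 3, folded to 2048 bits)
#' @param nbits fold length for the circular kind
#' @return object of class `fingerprint`: logical bit vector with attributes
#'   `kind` and `nbits`
#' @export
fingerprint <- function(molecule, kind = c("maccs", "ecfp"),
                        nbits = .ECFP_LEN) {
  kind <- match.arg(kind)
  mol <- if (inherits(molecule, "molecule_record")) molecule$structure
         else molecule
  stopifnot(inherits(mol, "molgraph"))
  if (nrow(mol$atoms) == 0L) stop("cannot fingerprint an empty molecule")
  bits <- if (kind == "maccs") .fp_maccs(mol) else .fp_ecfp(mol, nbits)
  structure(bits, kind = kind, nbits = length(bits), class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`; two all-zero fingerprints score 0 by convention.
#' @param a,b [fingerprint] objects of the same kind and length
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (!identical(attr(a, "kind"), attr(b, "kind")) || length(a) != length(b))
    stop("fingerprint kind/length mismatch")
  u <- sum(a | b)
  if (u == 0L) return(0)
  sum(a & b) / u
}

#' Highest similarity of a molecule to a known set
#'
#' @param molecule a [molecule_record]
#' @param known non-empty list of [molecule_record]
#' @param kind fingerprint kind (default circular radius 3, the novelty
#'   convention)
#' @return maximum pairwise Tanimoto in [0, 1]
#' @export
max_similarity_to_known <- function(molecule, known, kind = "ecfp") {
  stopifnot(length(known) >= 1L)
  fp <- fingerprint(molecule, kind)
  max(vapply(known, function(k) tanimoto(fp, fingerprint(k, kind)),
             numeric(1)))
}

# --- structural keys --------------------------------------------------------
# A documented subset of the 166 positions is populated: element presence and
# counts, ring statistics, aromaticity, charges, and a set of small
# substructure patterns matched on the graph. Unimplemented positions stay 0
# for every molecule, which leaves Tanimoto values well defined.

.MACCS_PATTERNS <- list(
  # slot, SMILES-subset pattern (matched with match_substructure)
  list(120L, "c1ccccc1"),        # benzene ring
  list(121L, "C=O"),             # carbonyl
  list(122L, "C(=O)N"),          # amide
  list(123L, "C(=O)O"),          # carboxyl/ester
  list(124L, "S(=O)(=O)"),       # sulfonyl
  list(125L, "C#N"),             # nitrile
  list(126L, "N=C"),             # imine/amidine
  list(127L, "COC"),             # ether
  list(128L, "CN"),              # C-N single
  list(129L, "CO"),              # C-O single
  list(130L, "c1ccncc1"),        # pyridine ring
  list(131L, "c1cc[nH]c1"),      # pyrrole ring
  list(132L, "c1ccoc1"),         # furan ring
  list(133L, "c1ccsc1"),         # thiophene ring
  list(134L, "C(F)(F)F"),        # trifluoromethyl
  list(135L, "NC(=O)N"),         # urea
  list(136L, "OCO"),             # acetal-like
  list(137L, "NCN"),             # aminal-like
  list(138L, "C=C"),             # olefin
  list(139L, "CC(C)C")           # isopropyl branch
)

.fp_maccs <- function(mol) {
  bits <- rep(FALSE, .MACCS_LEN)
  at <- mol$atoms
  set <- function(i, val = TRUE) bits[i] <<- bits[i] | val
  # element presence (slots 1-19)
  els <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B", "Si")
  for (e in seq_along(els)) set(e, els[e] %in% at$element)
  set(12L, any(at$charge > 0L)); set(13L, any(at$charge < 0L))
  set(14L, any(at$aromatic));    set(15L, any(!at$aromatic & at$element == "C"))
  set(16L, any(at$hcount > 0L & at$element == "N"))
  set(17L, any(at$hcount > 0L & at$element == "O"))
  set(18L, sum(at$element == "N") >= 2L)
  set(19L, sum(at$element == "O") >= 2L)
  # count thresholds (slots 20-59)
  thr <- function(x, cuts, base) {
    for (k in seq_along(cuts)) set(base + k - 1L, x >= cuts[k])
  }
  thr(nrow(at), c(5, 10, 15, 20, 25, 30, 40, 50), 20L)
  thr(sum(at$element == "N"), 1:4, 28L)
  thr(sum(at$element == "O"), 1:4, 32L)
  thr(sum(at$element %in% c("F", "Cl", "Br", "I")), 1:3, 36L)
  thr(sum(at$element == "S"), 1:2, 39L)
  rings <- mol_rings(mol)
  thr(length(rings), 1:4, 41L)
  for (r in rings) {
    if (length(r) == 5L) set(45L)
    if (length(r) == 6L) set(46L)
    if (length(r) >= 7L) set(47L)
    if (all(at$aromatic[r])) set(48L)
    if (any(at$element[r] == "N")) set(49L)
    if (any(at$element[r] == "O")) set(50L)
    if (any(at$element[r] == "S")) set(51L)
  }
  thr(count_hbd(mol), 1:3, 52L)
  thr(count_hba(mol), c(1, 2, 3, 5, 7), 55L)
  thr(count_rotatable_bonds(mol), c(1, 3, 5, 8), 60L)
  thr(sum(at$aromatic), c(5, 6, 10, 12), 64L)
  # bond-environment slots (70-119): hashed atom pairs at distance 1
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds$i[k]; b <- mol$bonds$j[k]
      key <- paste(sort(c(paste0(at$element[a], at$aromatic[a]),
                          paste0(at$element[b], at$aromatic[b]))),
                   mol$bonds$order[k], mol$bonds$aromatic[k], collapse = "|")
      slot <- 70L + (.str_hash(key) %% 50L)
      set(slot)
    }
  }
  # substructure pattern slots (120-139)
  for (p in .MACCS_PATTERNS) {
    pat <- .pattern_cache(p[[2L]])
    set(p[[1L]], has_substructure(pat, mol))
  }
  bits
}

# small deterministic string hash (djb2, 31-bit)
.str_hash <- function(s) {
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  as.integer(h)
}

.pattern_env <- new.env(hash = TRUE)
.pattern_cache <- function(smi) {
  if (!exists(smi, envir = .pattern_env))
    assign(smi, parse_smiles(smi), envir = .pattern_env)
  get(smi, envir = .pattern_env)
}

# --- circular fingerprint ---------------------------------------------------
# Morgan algorithm: initial atom invariants are hashed
# (element, aromatic, charge, hcount, degree); each iteration r = 1..3 hashes
# the atom invariant with the sorted (bond order, neighbour invariant) list.
# Every invariant from every radius sets one folded bit.

.fp_ecfp <- function(mol, nbits = .ECFP_LEN, radius = 3L) {
  at <- mol$atoms
  n <- nrow(at)
  nbrs <- mol_neighbors(mol)
  bond_key <- matrix(0, n, n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      o <- if (mol$bonds$aromatic[k]) 5L else mol$bonds$order[k]
      bond_key[mol$bonds$i[k], mol$bonds$j[k]] <- o
      bond_key[mol$bonds$j[k], mol$bonds$i[k]] <- o
    }
  }
  deg <- vapply(nbrs, length, 0L)
  inv <- vapply(seq_len(n), function(a) {
    .str_hash(paste(at$element[a], at$aromatic[a], at$charge[a],
                    at$hcount[a], deg[a], sep = ":"))
  }, integer(1))
  ids <- inv
  for (r in seq_len(radius)) {
    new_inv <- vapply(seq_len(n), function(a) {
      if (deg[a] == 0L) return(inv[a])
      parts <- sort(vapply(nbrs[[a]], function(b) {
        .str_hash(paste(bond_key[a, b], inv[b], sep = "_"))
      }, integer(1)))
      .str_hash(paste(c(r, inv[a], parts), collapse = ","))
    }, integer(1))
    inv <- new_inv
    ids <- c(ids, inv)
  }
  bits <- rep(FALSE, nbits)
  bits[(ids %% nbits) + 1L] <- TRUE
  bits
}

# fingerprint matrix helper used by diversity picking and clustering
fingerprint_matrix <- function(molecules, kind = "ecfp", nbits = .ECFP_LEN) {
  cache <- new.env(hash = TRUE)
  rows <- lapply(molecules, function(m) {
    key <- if (!is.na(m$structure$smiles)) m$structure$smiles
           else paste0("id:", m$id)
    if (!exists(key, envir = cache))
      assign(key, as.logical(fingerprint(m, kind, nbits)), envir = cache)
    get(key, envir = cache)
  })
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(molecules, `[[`, "", "id")
  mat
}
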
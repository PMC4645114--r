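# Pharmacophore feature perception. Features are located on a conformer by a
# fixed, documented rule set applied to the molecular graph:
#
#   pos_ionizable : formally positive atoms; amidine / guanidine groups
#                   (centroid of C and its N partners); aliphatic amines that
#                   are neither amide nor aniline nitrogens
#   neg_ionizable : formally negative atoms; carboxylic acid / carboxylate
#                   and sulfonic acid groups (centroid of the acid group)
#   HB_donor      : N or O bearing >= 1 hydrogen, not claimed by an
#                   ionizable group
#   HB_acceptor   : any O, and N with an available lone pair (not
#                   pyrrole-type aromatic NH, not amide N, not positively
#                   charged), not claimed by an ionizable group
#   aromatic_ring : centroid of each fully aromatic ring
#   hydrophobe    : centroid of each connected cluster of >= 3 non-aromatic
#                   carbons that touch no heteroatom
#
# Ionizable groups claim their atoms first, so e.g. benzamidine yields one
# aromatic ring plus one positive-ionizable feature and nothing else.
# Hydrogens carry no coordinates; donor features sit on the heavy atom.

.DEFAULT_TOLERANCE <- 1.6
.HYDROPHOBE_TOLERANCE <- 2.2

#' Construct a pharmacophore feature
#'
#' @param kind one of `"HB_donor"`, `"HB_acceptor"`, `"hydrophobe"`,
#'   `"aromatic_ring"`, `"pos_ionizable"`, `"neg_ionizable"`
#' @param center length-3 xyz in Angstrom
#' @param tolerance sphere radius in Angstrom (> 0)
#' @param weight non-negative contribution weight
#' @param atoms integer indices of the underlying ligand atoms (optional)
#' @export
pharmacophore_feature <- function(kind, center, tolerance = .DEFAULT_TOLERANCE,
                                  weight = 1, atoms = integer(0)) {
  kind <- match.arg(kind, c("HB_donor", "HB_acceptor", "hydrophobe",
                            "aromatic_ring", "pos_ionizable",
                            "neg_ionizable"))
  stopifnot(is.numeric(center), length(center) == 3L, all(is.finite(center)),
            tolerance > 0, weight >= 0)
  structure(list(kind = kind, center = as.numeric(center),
                 tolerance = tolerance, weight = weight,
                 atoms = as.integer(atoms)),
            class = "pharmacophore_feature")
}

#' Perceive pharmacophore features on a conformer
#'
#' @param molecule a [molecule_record] with at least one conformer
#' @param conformer_index which conformer to read coordinates from
#' @return list of [pharmacophore_feature] objects (deterministic order:
#'   ionizables, donors, acceptors, rings, hydrophobes; each by atom index)
#' @export
perceive_features <- function(molecule, conformer_index = 1L) {
  stopifnot(inherits(molecule, "molecule_record"))
  if (length(molecule$conformers) < conformer_index)
    stop("molecule '", molecule$id, "' has no conformer ", conformer_index)
  mol <- molecule$structure
  xyz <- molecule$conformers[[conformer_index]]
  at <- mol$atoms
  n <- nrow(at)
  nb <- mol_neighbors(mol)
  bond_order_to <- function(a, b) {
    k <- which((mol$bonds$i == a & mol$bonds$j == b) |
                 (mol$bonds$i == b & mol$bonds$j == a))
    if (length(k) == 0L) return(0)
    if (mol$bonds$aromatic[k[1L]]) 1.5 else mol$bonds$order[k[1L]]
  }
  claimed <- rep(FALSE, n)
  feats <- list()
  add <- function(kind, atoms, tol = .DEFAULT_TOLERANCE) {
    ctr <- colMeans(xyz[atoms, , drop = FALSE])
    feats[[length(feats) + 1L]] <<-
      pharmacophore_feature(kind, ctr, tolerance = tol, atoms = atoms)
  }

  is_carbonyl_c <- vapply(seq_len(n), function(a) {
    at$element[a] == "C" &&
      any(vapply(nb[[a]], function(b)
        at$element[b] == "O" && bond_order_to(a, b) == 2, logical(1)))
  }, logical(1))

  # --- positive ionizable -------------------------------------------------
  for (a in seq_len(n)) {
    if (at$charge[a] > 0L && !claimed[a]) { add("pos_ionizable", a); claimed[a] <- TRUE }
  }
  # amidine / guanidine: non-aromatic C double-bonded to N, single to >= 1 N
  for (a in seq_len(n)) {
    if (claimed[a] || at$element[a] != "C" || at$aromatic[a]) next
    ns <- nb[[a]][at$element[nb[[a]]] == "N" & !at$aromatic[nb[[a]]]]
    if (length(ns) < 2L) next
    dbl <- any(vapply(ns, function(b) bond_order_to(a, b) == 2, logical(1)))
    if (dbl) {
      grp <- c(a, ns)
      if (!any(claimed[grp])) { add("pos_ionizable", grp); claimed[grp] <- TRUE }
    }
  }
  # aliphatic amine: sp3 N, H-bearing or tertiary, not amide / aniline
  for (a in seq_len(n)) {
    if (claimed[a] || at$element[a] != "N" || at$aromatic[a]) next
    if (at$charge[a] != 0L) next
    orders <- vapply(nb[[a]], function(b) bond_order_to(a, b), numeric(1))
    if (any(orders > 1)) next                       # imine / nitrile N
    if (any(is_carbonyl_c[nb[[a]]])) next           # amide N
    if (any(at$aromatic[nb[[a]]])) next             # aniline-type N
    add("pos_ionizable", a); claimed[a] <- TRUE
  }
  # --- negative ionizable -------------------------------------------------
  for (a in seq_len(n)) {
    if (at$charge[a] < 0L && !claimed[a]) { add("neg_ionizable", a); claimed[a] <- TRUE }
  }
  # carboxyl / sulfonate: C or S with =O and -O(H/-)
  for (a in seq_len(n)) {
    if (claimed[a] || !(at$element[a] %in% c("C", "S")) || at$aromatic[a]) next
    os <- nb[[a]][at$element[nb[[a]]] == "O"]
    if (length(os) < 2L) next
    dbl <- os[vapply(os, function(b) bond_order_to(a, b) == 2, logical(1))]
    sgl <- os[vapply(os, function(b) bond_order_to(a, b) == 1, logical(1))]
    sgl <- sgl[vapply(sgl, function(b) length(nb[[b]]) == 1L, logical(1))]  # terminal O(H)
    if (length(dbl) >= 1L && length(sgl) >= 1L) {
      grp <- c(a, dbl, sgl)
      if (!any(claimed[grp])) { add("neg_ionizable", grp); claimed[grp] <- TRUE }
    }
  }
  # --- donors and acceptors ----------------------------------------------
  for (a in seq_len(n)) {
    if (claimed[a] || !(at$element[a] %in% c("N", "O"))) next
    if (at$hcount[a] >= 1L) add("HB_donor", a)
  }
  for (a in seq_len(n)) {
    if (claimed[a]) next
    el <- at$element[a]
    if (el == "O") { add("HB_acceptor", a); next }
    if (el != "N" || at$charge[a] > 0L) next
    if (at$aromatic[a] && at$hcount[a] > 0L) next   # pyrrole-type NH
    if (any(is_carbonyl_c[nb[[a]]])) next           # amide N
    orders <- vapply(nb[[a]], function(b) bond_order_to(a, b), numeric(1))
    if (sum(orders) + at$hcount[a] < 4) add("HB_acceptor", a)
  }
  # --- aromatic rings -----------------------------------------------------
  for (r in mol_rings(mol)) {
    if (all(at$aromatic[r])) add("aromatic_ring", r)
  }
  # --- hydrophobes --------------------------------------------------------
  hetero_adjacent <- vapply(seq_len(n), function(a)
    any(!(at$element[nb[[a]]] %in% c("C", "H"))), logical(1))
  hp_ok <- at$element == "C" & !at$aromatic & at$charge == 0L & !hetero_adjacent
  if (any(hp_ok)) {
    g <- mol_igraph(mol)
    sub <- igraph::induced_subgraph(g, which(hp_ok))
    comp <- igraph::components(sub)
    orig <- which(hp_ok)
    for (ci in seq_len(comp$no)) {
      members <- orig[comp$membership == ci]
      if (length(members) >= 3L)
        add("hydrophobe", members, tol = .HYDROPHOBE_TOLERANCE)
    }
  }
  feats
}
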
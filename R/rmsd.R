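# Pose RMSD in the docking frame (no superposition) with optional
# graph-automorphism symmetry correction, plus the Kabsch least-squares
# superposition used by pharmacophore mapping.

#' Root-mean-square deviation between two poses
#'
#' RMSD over paired heavy atoms in a common (receptor) frame -- no
#' superposition is applied, matching docking-pose convention. With
#' `symmetry = TRUE` and the molecule's graph supplied, the minimum RMSD over
#' all graph automorphisms is returned, so e.g. a benzene ring rotated by 60
#' degrees scores 0.
#'
#' @param pose_a,pose_b n x 3 coordinate matrices (Angstrom)
#' @param atom_map two-column integer matrix pairing rows of `pose_a` (col 1)
#'   with rows of `pose_b` (col 2); default pairs identical indices
#' @param symmetry if `TRUE`, minimise over automorphisms of `mol`
#' @param mol a [molgraph] (required when `symmetry = TRUE`); atom order must
#'   match the pose rows
#' @return RMSD in Angstrom
#' @export
pose_rmsd <- function(pose_a, pose_b, atom_map = NULL,
                      symmetry = FALSE, mol = NULL) {
  stopifnot(is.matrix(pose_a), is.matrix(pose_b),
            ncol(pose_a) == 3L, ncol(pose_b) == 3L)
  if (is.null(atom_map)) {
    if (nrow(pose_a) != nrow(pose_b))
      stop("poses have different atom counts and no atom_map was given")
    atom_map <- cbind(seq_len(nrow(pose_a)), seq_len(nrow(pose_a)))
  }
  atom_map <- as.matrix(atom_map)
  if (ncol(atom_map) != 2L) stop("atom_map must have two columns")
  if (max(atom_map[, 1L]) > nrow(pose_a) || max(atom_map[, 2L]) > nrow(pose_b))
    stop("atom_map indexes beyond the pose atom count")
  if (!symmetry) return(.rmsd_mapped(pose_a, pose_b, atom_map))
  if (is.null(mol)) stop("symmetry mode needs the molecular graph")
  autos <- mol_automorphisms(mol)
  best <- Inf
  for (perm in autos) {
    m <- cbind(perm[atom_map[, 1L]], atom_map[, 2L])
    best <- min(best, .rmsd_mapped(pose_a, pose_b, m))
  }
  best
}

.rmsd_mapped <- function(a, b, map) {
  d <- a[map[, 1L], , drop = FALSE] - b[map[, 2L], , drop = FALSE]
  sqrt(mean(rowSums(d * d)))
}

#' Enumerate graph automorphisms of a molecule
#'
#' Element- and bond-order-preserving permutations of the atom indices,
#' found with VF2 on the coloured graph.
#' @param mol a [molgraph]
#' @return list of integer permutations (each maps atom i to its image)
#' @export
mol_automorphisms <- function(mol) {
  g <- mol_igraph(mol)
  vcol <- as.integer(factor(paste(mol$atoms$element, mol$atoms$aromatic)))
  ecol <- if (nrow(mol$bonds) > 0L)
    as.integer(factor(paste(mol$bonds$order, mol$bonds$aromatic)))
  else integer(0)
  maps <- igraph::subgraph_isomorphisms(
    pattern = g, target = g, method = "vf2",
    vertex.color1 = vcol, vertex.color2 = vcol,
    edge.color1 = ecol, edge.color2 = ecol)
  lapply(maps, as.integer)
}

#' Kabsch least-squares rigid superposition
#'
#' Finds rotation `R` and translation `t` minimising
#' `sum(w || R x_i + t - y_i ||^2)` (proper rotation; reflections are
#' corrected away). Degenerate cases (1 or 2 points, collinear sets) are
#' handled by the SVD construction.
#'
#' @param x,y n x 3 matrices of source and target points
#' @param w optional non-negative weights
#' @return list with `R` (3 x 3), `t` (length 3) and `rmsd` after fit
#' @export
kabsch <- function(x, y, w = NULL) {
  stopifnot(is.matrix(x), is.matrix(y), ncol(x) == 3L, ncol(y) == 3L,
            nrow(x) == nrow(y), nrow(x) >= 1L)
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cx <- colSums(x * w); cy <- colSums(y * w)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  H <- t(xc * w) %*% yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- cy - as.numeric(R %*% cx)
  fitted <- t(R %*% t(x)) + matrix(t_vec, n, 3L, byrow = TRUE)
  rmsd <- sqrt(sum(w * rowSums((fitted - y)^2)))
  list(R = R, t = t_vec, rmsd = rmsd, fitted = fitted)
}

# apply a kabsch fit to new points
apply_rigid <- function(fit, pts) {
  t(fit$R %*% t(pts)) + matrix(fit$t, nrow(pts), 3L, byrow = TRUE)
}
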
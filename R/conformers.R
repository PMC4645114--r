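# Idealized-geometry conformer generator. Coordinates are built atom by atom
# along a depth-first spanning tree with standard bond lengths (covalent
# radii sums, shortened for higher bond orders), hybridization-dependent bond
# angles (109.47 / 120 / 180 degrees) and ring-interior angles for ring
# bonds, so isolated planar rings close exactly. Conformational diversity
# comes from sampling staggered (sp3) or planar (sp2) torsion states at each
# rotatable bond; duplicates are removed at 0.5 A heavy-atom RMSD after
# Kabsch alignment. This is a geometry sketcher, not a force field: fused
# ring systems are laid out approximately, and no steric relaxation is done.

.COV_RADIUS <- c(H = 0.31, B = 0.85, C = 0.77, N = 0.70, O = 0.66, F = 0.64,
                 Si = 1.11, P = 1.10, S = 1.04, Cl = 0.99, Br = 1.14,
                 I = 1.33)

.bond_length <- function(el_a, el_b, order, aromatic) {
  base <- .COV_RADIUS[[el_a]] + .COV_RADIUS[[el_b]]
  f <- if (aromatic) 0.93 else switch(as.character(order),
                                      "1" = 1.0, "2" = 0.87, "3" = 0.78, 1.0)
  base * f
}

# sp classification per atom: 1 = sp, 2 = sp2, 3 = sp3
.hybridization <- function(mol) {
  n <- nrow(mol$atoms)
  hyb <- rep(3L, n)
  if (nrow(mol$bonds) == 0L) return(hyb)
  for (a in seq_len(n)) {
    k <- mol$bonds$i == a | mol$bonds$j == a
    ord <- mol$bonds$order[k]; arom <- mol$bonds$aromatic[k]
    if (any(ord == 3) || sum(ord == 2) >= 2L) hyb[a] <- 1L
    else if (any(ord == 2) || any(arom)) hyb[a] <- 2L
  }
  hyb
}

# NERF placement of point D given A (parent), B, C references
.place_atom <- function(A, B, C, r, theta, phi) {
  bc <- A - B
  nb <- sqrt(sum(bc^2)); bc <- bc / nb
  ab <- B - C
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) {                       # collinear references: any normal
    ref <- if (abs(bc[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- c(ref[2] * bc[3] - ref[3] * bc[2],
           ref[3] * bc[1] - ref[1] * bc[3],
           ref[1] * bc[2] - ref[2] * bc[1])
    nn <- sqrt(sum(n^2))
  }
  n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(phi), r * sin(theta) * sin(phi))
  A + d[1] * bc + d[2] * m + d[3] * n
}

# one coordinate build for a given assignment of torsion states
.build_coords <- function(mol, torsion_state) {
  n <- nrow(mol$atoms)
  xyz <- matrix(NA_real_, n, 3L)
  if (n == 0L) return(xyz)
  nb <- mol_neighbors(mol)
  hyb <- .hybridization(mol)
  rings <- mol_rings(mol)
  ring_of <- function(a, b) {
    for (r in rings) {
      cyc <- c(r, r[1L])
      for (t in seq_len(length(r)))
        if ((cyc[t] == a && cyc[t + 1L] == b) ||
            (cyc[t] == b && cyc[t + 1L] == a)) return(length(r))
    }
    0L
  }
  border_of <- function(a, b) {
    k <- which((mol$bonds$i == a & mol$bonds$j == b) |
                 (mol$bonds$i == b & mol$bonds$j == a))[1L]
    list(order = mol$bonds$order[k], aromatic = mol$bonds$aromatic[k])
  }

  parent <- rep(NA_integer_, n)
  placed <- rep(FALSE, n)
  sibling_rank <- rep(0L, n)

  for (root in seq_len(n)) {
    if (placed[root]) next
    offset <- sum(placed)                # translate disconnected components
    xyz[root, ] <- c(offset * 6, 0, 0)
    placed[root] <- TRUE
    # iterative DFS so rings are traversed sequentially
    stack <- root
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      kids <- nb[[v]][!placed[nb[[v]]]]
      kids <- sort(kids)
      rank <- 0L
      for (w in kids) {
        if (placed[w]) next
        rank <- rank + 1L
        parent[w] <- v
        sibling_rank[w] <- rank
        b <- border_of(v, w)
        r_len <- .bond_length(mol$atoms$element[v], mol$atoms$element[w],
                              b$order, b$aromatic)
        A <- xyz[v, ]
        gp <- parent[v]
        if (is.na(gp)) {
          # v is a root: place w along +x, or in the xy-plane for rank > 1
          ang <- switch(hyb[v], 2.0944, 2.0944, 1.9106)  # unused for rank 1
          if (rank == 1L && !any(placed & seq_len(n) != v & seq_len(n) != w)) {
            xyz[w, ] <- A + c(r_len, 0, 0)
          } else {
            ref <- A + c(1, 0, 0)
            phi0 <- (rank - 1L) * 2 * pi / 3
            xyz[w, ] <- .place_atom(A, ref, A + c(0, 1, 0),
                                    r_len, pi - ang, phi0)
          }
          placed[w] <- TRUE
          stack <- c(stack, w)
          next
        }
        B <- xyz[gp, ]
        ggp <- parent[gp]
        C <- if (!is.na(ggp)) xyz[ggp, ] else {
          alt <- nb[[gp]][placed[nb[[gp]]] & nb[[gp]] != v]
          if (length(alt) > 0L) xyz[alt[1L], ] else B + c(0.3, 1.1, 0.2)
        }
        rs <- ring_of(v, w)
        rs_parent <- ring_of(gp, v)
        if (rs > 0L && rs_parent > 0L) {
          # ring interior: polygon angle, cis torsion keeps the ring planar
          theta <- pi - 2 * pi / rs
          phi <- 0
        } else {
          theta <- switch(hyb[v], pi, 2 * pi / 3, 1.9106332)  # 180/120/109.47
          tstate <- torsion_state[v]
          base_phi <- if (hyb[v] >= 3L) tstate else round(tstate / pi) * pi
          extra <- if (rs_parent > 0L) pi else 0   # substituent on a ring: exo
          phi <- base_phi + extra + (sibling_rank[w] - 1L) * 2 * pi / 3
        }
        if (abs(theta - pi) < 1e-6) theta <- pi - 1e-3  # avoid exact collinearity
        xyz[w, ] <- .place_atom(A, B, C, r_len, theta, phi)
        placed[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  xyz
}

# rotatable-bond atoms: atoms whose outgoing torsion state matters
.torsion_atoms <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(integer(0))
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = nrow(mol$atoms))
  ring <- mol_ring_bonds(mol)
  k <- which(mol$bonds$order == 1 & !mol$bonds$aromatic & !ring &
               deg[mol$bonds$i] >= 2L & deg[mol$bonds$j] >= 2L)
  unique(c(mol$bonds$i[k], mol$bonds$j[k]))
}

#' Generate an idealized conformer ensemble
#'
#' Builds up to `max_confs` heavy-atom conformers by sampling torsion states
#' at rotatable bonds over an idealized covalent geometry, then removes
#' near-duplicates (Kabsch-aligned RMSD below 0.5 A). Rigid molecules yield
#' exactly one conformer. The ensemble is deterministic for a given seed.
#'
#' @param molecule a [molecule_record]
#' @param max_confs maximum ensemble size (default 100)
#' @param seed integer seed for torsion sampling
#' @return the molecule record with `conformers` replaced by the ensemble
#' @export
generate_conformers <- function(molecule, max_confs = 100L, seed = 1L) {
  stopifnot(inherits(molecule, "molecule_record"), max_confs >= 1L)
  mol <- molecule$structure
  n <- nrow(mol$atoms)
  tors <- .torsion_atoms(mol)
  base_state <- rep(pi, n)               # anti everywhere
  first <- .build_coords(mol, base_state)
  if (anyNA(first)) stop("coordinate embedding failed for '", molecule$id, "'")
  confs <- list(first)
  if (length(tors) > 0L && max_confs > 1L) {
    n_try <- min(3L * max_confs, 3L^min(length(tors), 6L) * 4L)
    states <- with_seed(seed, {
      lapply(seq_len(n_try), function(i) {
        st <- base_state
        st[tors] <- sample(c(pi / 3, pi, -pi / 3), length(tors),
                           replace = TRUE)
        st
      })
    })
    for (st in states) {
      if (length(confs) >= max_confs) break
      cand <- .build_coords(mol, st)
      dup <- FALSE
      for (cf in confs) {
        r <- if (n >= 2L) kabsch(cand, cf)$rmsd else 0
        if (r < 0.5) { dup <- TRUE; break }
      }
      if (!dup) confs[[length(confs) + 1L]] <- cand
    }
  }
  molecule$conformers <- confs[seq_len(min(length(confs), max_confs))]
  molecule
}
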
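# Molecular graph container used by every chemistry-aware operation.
#
# A `molgraph` stores heavy atoms only. Hydrogens are kept as per-atom counts
# (explicit bracket counts from SMILES, or implicit counts filled from default
# valences); they carry no coordinates. Aromaticity is taken as written
# (lowercase SMILES atoms / SDF bond type 4) -- the toolkit performs no
# aromaticity perception or kekulization.

#' Construct a molecular graph
#'
#' Low-level constructor; most users obtain `molgraph` objects from
#' [parse_smiles()] or [read_library()].
#'
#' @param atoms data.frame with columns `element` (character), `aromatic`
#'   (logical), `charge` (integer formal charge), `hcount` (integer attached
#'   hydrogens).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2, 3) and `aromatic` (logical; aromatic bonds have
#'   `order = 1` and `aromatic = TRUE`).
#' @param smiles optional source string, kept for caching and reporting.
#' @return object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds, smiles = NA_character_) {
  stopifnot(is.data.frame(atoms), is.data.frame(bonds))
  if (nrow(bonds) > 0L) {
    stopifnot(all(bonds$i >= 1L), all(bonds$j >= 1L),
              all(bonds$i <= nrow(atoms)), all(bonds$j <= nrow(atoms)))
  }
  structure(list(atoms = atoms, bonds = bonds, smiles = smiles),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d heavy atoms, %d bonds%s\n",
              nrow(x$atoms), nrow(x$bonds),
              if (is.na(x$smiles)) "" else paste0("  [", x$smiles, "]")))
  invisible(x)
}

# monoisotopic-free average atomic masses (g/mol) for MW computation
.ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453, Br = 79.904, I = 126.904
)

#' Heavy atom count of a molecule
#' @param mol a `molgraph`
#' @return integer count of non-hydrogen atoms
#' @export
heavy_atom_count <- function(mol) nrow(mol$atoms)

#' Molecular weight from the graph
#'
#' Average-mass MW in g/mol including implicit/explicit hydrogens.
#' @param mol a `molgraph`
#' @export
mol_mw <- function(mol) {
  m <- .ATOMIC_MASS[mol$atoms$element]
  if (anyNA(m)) {
    bad <- unique(mol$atoms$element[is.na(m)])
    stop("no mass tabulated for element(s): ", paste(bad, collapse = ", "))
  }
  sum(m) + sum(mol$atoms$hcount) * .ATOMIC_MASS[["H"]]
}

#' Lipinski hydrogen-bond donor count (N-H and O-H hydrogens)
#' @param mol a `molgraph`
#' @export
count_hbd <- function(mol) {
  idx <- mol$atoms$element %in% c("N", "O")
  sum(mol$atoms$hcount[idx] > 0L)
}

#' Lipinski hydrogen-bond acceptor count (all N and O atoms)
#' @param mol a `molgraph`
#' @export
count_hba <- function(mol) sum(mol$atoms$element %in% c("N", "O"))

#' Net formal charge
#' @param mol a `molgraph`
#' @export
formal_charge <- function(mol) sum(mol$atoms$charge)

# adjacency list: integer vector of neighbours per atom
mol_neighbors <- function(mol) {
  n <- nrow(mol$atoms)
  nb <- vector("list", n)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
  }
  nb
}

#' Convert a molecule to an igraph object
#'
#' Vertices carry `element`, `aromatic`, `charge`, `hcount`; edges carry
#' `order` and `aromatic`. Used for ring perception, automorphism
#' enumeration and substructure matching.
#' @param mol a `molgraph`
#' @return an [igraph::graph] object
#' @export
mol_igraph <- function(mol) {
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "element", value = mol$atoms$element)
  g <- igraph::set_vertex_attr(g, "aromatic", value = mol$atoms$aromatic)
  g <- igraph::set_vertex_attr(g, "charge", value = mol$atoms$charge)
  g <- igraph::set_vertex_attr(g, "hcount", value = mol$atoms$hcount)
  if (nrow(mol$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(mol$bonds$i, mol$bonds$j))
    g <- igraph::set_edge_attr(g, "order", value = mol$bonds$order)
    g <- igraph::set_edge_attr(g, "aromatic", value = mol$bonds$aromatic)
  }
  g
}

# Smallest-ring perception from the fundamental cycle basis of a spanning
# forest. For each non-tree bond the shortest cycle through it is recovered
# with a BFS that avoids the bond itself. Adequate for the ring sizes this
# toolkit meets (isolated and ortho-fused rings); not a full SSSR solver.
mol_rings <- function(mol) {
  nb <- mol_neighbors(mol)
  n <- nrow(mol$atoms)
  if (n == 0L || nrow(mol$bonds) == 0L) return(list())
  in_tree <- rep(FALSE, nrow(mol$bonds))
  parent <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  edge_id <- new.env(hash = TRUE)
  for (k in seq_len(nrow(mol$bonds))) {
    key <- paste(sort(c(mol$bonds$i[k], mol$bonds$j[k])), collapse = "-")
    assign(key, k, envir = edge_id)
  }
  for (root in seq_len(n)) {
    if (seen[root]) next
    seen[root] <- TRUE
    queue <- root
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in nb[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          parent[w] <- v
          key <- paste(sort(c(v, w)), collapse = "-")
          in_tree[get(key, envir = edge_id)] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
  }
  rings <- list()
  for (k in which(!in_tree)) {
    a <- mol$bonds$i[k]; b <- mol$bonds$j[k]
    # shortest path a..b avoiding the chord itself
    path <- .bfs_path(nb, a, b, forbid = k, bonds = mol$bonds)
    if (!is.null(path)) rings[[length(rings) + 1L]] <- path
  }
  rings
}

.bfs_path <- function(nb, from, to, forbid, bonds) {
  n <- length(nb)
  prev <- rep(NA_integer_, n)
  seen <- rep(FALSE, n)
  seen[from] <- TRUE
  queue <- from
  fi <- bonds$i[forbid]; fj <- bonds$j[forbid]
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in nb[[v]]) {
      if ((v == fi && w == fj) || (v == fj && w == fi)) next
      if (!seen[w]) {
        seen[w] <- TRUE
        prev[w] <- v
        if (w == to) {
          path <- w
          while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  NULL
}

# logical vector: atom participates in any ring
mol_ring_membership <- function(mol) {
  member <- rep(FALSE, nrow(mol$atoms))
  for (r in mol_rings(mol)) member[r] <- TRUE
  member
}

# logical vector over bonds: bond is in a ring (both ends on one ring and
# consecutive within it)
mol_ring_bonds <- function(mol) {
  rb <- rep(FALSE, nrow(mol$bonds))
  rings <- mol_rings(mol)
  if (length(rings) == 0L) return(rb)
  ring_pairs <- new.env(hash = TRUE)
  for (r in rings) {
    cyc <- c(r, r[1L])
    for (t in seq_len(length(r))) {
      key <- paste(sort(c(cyc[t], cyc[t + 1L])), collapse = "-")
      assign(key, TRUE, envir = ring_pairs)
    }
  }
  for (k in seq_len(nrow(mol$bonds))) {
    key <- paste(sort(c(mol$bonds$i[k], mol$bonds$j[k])), collapse = "-")
    rb[k] <- exists(key, envir = ring_pairs)
  }
  rb
}

#' Rotatable bond count
#'
#' Acyclic single (non-aromatic) bonds between two heavy atoms that each have
#' at least one further heavy neighbour. A deliberately simple definition;
#' amide bonds are not excluded.
#' @param mol a `molgraph`
#' @export
count_rotatable_bonds <- function(mol) {
  if (nrow(mol$bonds) == 0L) return(0L)
  deg <- tabulate(c(mol$bonds$i, mol$bonds$j), nbins = nrow(mol$atoms))
  ring <- mol_ring_bonds(mol)
  sum(mol$bonds$order == 1 & !mol$bonds$aromatic & !ring &
        deg[mol$bonds$i] >= 2L & deg[mol$bonds$j] >= 2L)
}
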
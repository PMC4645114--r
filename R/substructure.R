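# Substructure matching: subgraph (monomorphism, not induced) search with a
# backtracking matcher. Atom compatibility is element + aromaticity; bond
# compatibility is aromatic-vs-aromatic or equal order. Hydrogen counts
# constrain a match only when the pattern atom wrote them explicitly in
# brackets (e.g. the [CH1] of an aldehyde alert requires >= 1 H on the
# target carbon); implicit pattern hydrogens and charges of 0 do not
# constrain, so an N-methylated analogue still matches an [nH]-containing
# scaffold. Patterns are ordinary SMILES parsed with parse_smiles();
# aromaticity must be written as such (lowercase), since no perception is
# done.

.atoms_compatible <- function(pat, tgt, pi, ti) {
  if (pat$atoms$element[pi] != tgt$atoms$element[ti]) return(FALSE)
  if (pat$atoms$aromatic[pi] != tgt$atoms$aromatic[ti]) return(FALSE)
  # [nH]-style brackets are syntactic necessity on aromatic atoms, not an
  # intentional constraint, so only non-aromatic explicit H counts bind
  hx <- pat$atoms$h_explicit
  if (!is.null(hx) && isTRUE(hx[pi]) && !pat$atoms$aromatic[pi] &&
      tgt$atoms$hcount[ti] < pat$atoms$hcount[pi]) return(FALSE)
  if (pat$atoms$charge[pi] != 0L &&
      pat$atoms$charge[pi] != tgt$atoms$charge[ti]) return(FALSE)
  TRUE
}

.bond_lookup <- function(mol) {
  env <- new.env(hash = TRUE)
  if (nrow(mol$bonds) > 0L) {
    for (k in seq_len(nrow(mol$bonds))) {
      key <- paste(sort(c(mol$bonds$i[k], mol$bonds$j[k])), collapse = "-")
      assign(key, c(order = mol$bonds$order[k],
                    aromatic = as.numeric(mol$bonds$aromatic[k])), envir = env)
    }
  }
  env
}

.bonds_compatible <- function(pb, tb) {
  if (is.null(tb)) return(FALSE)
  if (pb[["aromatic"]] == 1) return(tb[["aromatic"]] == 1)
  tb[["aromatic"]] == 0 && pb[["order"]] == tb[["order"]]
}

#' Test whether a pattern occurs as a substructure of a molecule
#'
#' @param pattern a [molgraph] (the query; parse with [parse_smiles()])
#' @param mol a [molgraph] (the target)
#' @return `TRUE` if at least one subgraph embedding exists
#' @export
has_substructure <- function(pattern, mol) {
  length(match_substructure(pattern, mol, first_only = TRUE)) > 0L
}

#' Enumerate substructure embeddings
#'
#' @param pattern,mol [molgraph] objects (query, target)
#' @param first_only stop after the first embedding
#' @return list of integer vectors mapping pattern atom i to a target atom
#' @export
match_substructure <- function(pattern, mol, first_only = FALSE) {
  stopifnot(inherits(pattern, "molgraph"), inherits(mol, "molgraph"))
  np <- nrow(pattern$atoms); nt <- nrow(mol$atoms)
  if (np == 0L) stop("empty substructure pattern")
  if (np > nt) return(list())
  pnb <- mol_neighbors(pattern)
  tnb <- mol_neighbors(mol)
  pbonds <- .bond_lookup(pattern)
  tbonds <- .bond_lookup(mol)
  # visit pattern atoms in BFS order so each (after the first per component)
  # has a previously-mapped neighbour
  order_p <- integer(0)
  seen <- rep(FALSE, np)
  for (root in seq_len(np)) {
    if (seen[root]) next
    queue <- root; seen[root] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      order_p <- c(order_p, v)
      for (w in pnb[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
  }
  results <- list()
  map <- rep(NA_integer_, np)
  used <- rep(FALSE, nt)
  rec <- function(step) {
    if (first_only && length(results) > 0L) return(invisible(NULL))
    if (step > np) {
      results[[length(results) + 1L]] <<- map
      return(invisible(NULL))
    }
    pi <- order_p[step]
    mapped_nbrs <- pnb[[pi]][!is.na(map[pnb[[pi]]])]
    cand <- if (length(mapped_nbrs) == 0L) {
      which(!used)
    } else {
      anchor <- map[mapped_nbrs[1L]]
      tnb[[anchor]][!used[tnb[[anchor]]]]
    }
    for (ti in cand) {
      if (!.atoms_compatible(pattern, mol, pi, ti)) next
      ok <- TRUE
      for (pn in mapped_nbrs) {
        pkey <- paste(sort(c(pi, pn)), collapse = "-")
        tkey <- paste(sort(c(ti, map[pn])), collapse = "-")
        pb <- get(pkey, envir = pbonds)
        tb <- if (exists(tkey, envir = tbonds)) get(tkey, envir = tbonds) else NULL
        if (!.bonds_compatible(pb, tb)) { ok <- FALSE; break }
      }
      if (!ok) next
      map[pi] <<- ti; used[ti] <<- TRUE
      rec(step + 1L)
      map[pi] <<- NA_integer_; used[ti] <<- FALSE
      if (first_only && length(results) > 0L) return(invisible(NULL))
    }
  }
  rec(1L)
  results
}

#' Scaffold substructure search over a library
#'
#' Returns the order-preserved subset of molecules containing the scaffold.
#' @param scaffold SMILES string or [molgraph] of the query substructure
#' @param library list of [molecule_record]
#' @return list of matching [molecule_record]
#' @export
substructure_search <- function(scaffold, library) {
  pat <- if (is.character(scaffold)) parse_smiles(scaffold) else scaffold
  stopifnot(inherits(pat, "molgraph"))
  keep <- vapply(library, function(m) has_substructure(pat, m$structure),
                 logical(1))
  library[keep]
}
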
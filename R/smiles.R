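# SMILES reader covering the exchange subset this toolkit needs:
# organic-subset atoms, bracket atoms with charge/H-count, branches, ring
# closures (including %nn), explicit bond orders and aromatic (lowercase)
# notation. Stereo marks (/ \ @) are accepted and ignored. Aromaticity is
# taken from the input; no perception is attempted, so Kekule-form inputs
# stay as alternating single/double bonds.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")
# allowed valences used to fill implicit hydrogens
.DEFAULT_VALENCE <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1, Si = 4
)

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single SMILES string (heavy atoms only are stored;
#'   hydrogens become per-atom counts).
#' @return a [molgraph] object
#' @examples
#' benzene <- parse_smiles("c1ccccc1")
#' heavy_atom_count(benzene)  # 6
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, !is.na(smiles))
  s <- trimws(smiles)
  if (nchar(s) == 0L) stop("empty SMILES string")

  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n_guess <- nchar(s)
  element  <- character(0); aromatic <- logical(0)
  charge   <- integer(0);   hexpl    <- integer(0)   # bracket H count, NA if organic subset
  bi <- integer(0); bj <- integer(0); border <- numeric(0); barom <- logical(0)

  prev <- NA_integer_          # atom the next bond attaches to
  stack <- integer(0)          # branch stack
  pending <- NA_character_     # explicit bond symbol awaiting next atom
  ring_open <- list()          # closure number -> list(atom, bond)

  add_atom <- function(el, arom, chg, hx) {
    element  <<- c(element, el)
    aromatic <<- c(aromatic, arom)
    charge   <<- c(charge, chg)
    hexpl    <<- c(hexpl, hx)
    length(element)
  }
  add_bond <- function(a, b, sym, arom_pair) {
    if (is.na(sym)) {
      if (arom_pair) { o <- 1; ar <- TRUE } else { o <- 1; ar <- FALSE }
    } else if (sym == "=") { o <- 2; ar <- FALSE
    } else if (sym == "#") { o <- 3; ar <- FALSE
    } else if (sym == ":") { o <- 1; ar <- TRUE
    } else { o <- 1; ar <- FALSE }                 # '-', '/', '\\'
    bi <<- c(bi, a); bj <<- c(bj, b)
    border <<- c(border, o); barom <<- c(barom, ar)
  }
  connect <- function(idx) {
    if (!is.na(prev)) {
      arom_pair <- aromatic[prev] && aromatic[idx]
      add_bond(prev, idx, pending, arom_pair)
    }
    pending <<- NA_character_
    prev <<- idx
  }
  handle_ring <- function(num) {
    key <- as.character(num)
    if (!is.null(ring_open[[key]])) {
      op <- ring_open[[key]]
      sym <- if (!is.na(pending)) pending else op$sym
      arom_pair <- aromatic[op$atom] && aromatic[prev]
      add_bond(op$atom, prev, sym, arom_pair)
      ring_open[[key]] <<- NULL
    } else {
      ring_open[[key]] <<- list(atom = prev, sym = pending)
    }
    pending <<- NA_character_
  }

  i <- 1L
  while (i <= n_guess) {
    ch <- chars[i]
    if (ch == "[") {
      close <- i
      while (close <= n_guess && chars[close] != "]") close <- close + 1L
      if (close > n_guess) stop("unclosed bracket atom in SMILES: ", smiles)
      body <- substr(s, i + 1L, close - 1L)
      m <- regmatches(body,
        regexec("^([0-9]*)([A-Za-z][a-z]?)(@{1,2})?(H[0-9]*)?([+-][0-9]*|\\++|-+)?$",
                body))[[1L]]
      if (length(m) == 0L) stop("cannot parse bracket atom [", body, "]")
      el_raw <- m[3L]
      arom <- el_raw == tolower(el_raw) && nchar(el_raw) <= 2L &&
        substr(el_raw, 1L, 1L) %in% c("b", "c", "n", "o", "p", "s")
      el <- paste0(toupper(substr(el_raw, 1L, 1L)),
                   substring(el_raw, 2L))
      hx <- 0L
      if (nzchar(m[5L])) {
        hx <- if (m[5L] == "H") 1L else as.integer(substring(m[5L], 2L))
      }
      chg <- 0L
      if (nzchar(m[6L])) {
        cs <- m[6L]
        if (grepl("^[+-][0-9]+$", cs)) {
          chg <- as.integer(cs)
        } else {
          chg <- (nchar(cs)) * (if (substr(cs, 1L, 1L) == "+") 1L else -1L)
        }
      }
      idx <- add_atom(el, arom, chg, hx)
      connect(idx)
      i <- close + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- ch
      i <- i + 1L
    } else if (ch == "(") {
      stack <- c(stack, prev)
      i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0L) stop("unbalanced ')' in SMILES: ", smiles)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      handle_ring(as.integer(ch))
      i <- i + 1L
    } else if (ch == "%") {
      num <- as.integer(substr(s, i + 1L, i + 2L))
      if (is.na(num)) stop("bad %% ring closure in SMILES: ", smiles)
      handle_ring(num)
      i <- i + 3L
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NA_character_
      i <- i + 1L
    } else {
      two <- substr(s, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE, 0L, NA_integer_)
        connect(idx); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        idx <- add_atom(ch, FALSE, 0L, NA_integer_)
        connect(idx); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        idx <- add_atom(toupper(ch), TRUE, 0L, NA_integer_)
        connect(idx); i <- i + 1L
      } else {
        stop("unsupported SMILES token '", ch, "' in: ", smiles)
      }
    }
  }
  if (length(ring_open) > 0L) stop("unclosed ring bond in SMILES: ", smiles)
  if (length(element) == 0L) stop("SMILES parsed to zero atoms: ", smiles)

  atoms <- data.frame(element = element, aromatic = aromatic,
                      charge = charge, hcount = 0L,
                      h_explicit = !is.na(hexpl),
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = bi, j = bj, order = border, aromatic = barom)
  atoms$hcount <- .fill_implicit_h(atoms, bonds, hexpl)
  molgraph(atoms, bonds, smiles = s)
}

# Implicit hydrogen filling. Bracket atoms use their explicit H count.
# Organic-subset atoms get max(0, v - ceiling(sum of bond orders)) where v is
# the smallest allowed valence not below the bond-order sum and aromatic
# bonds count 1.5 (so an aromatic CH in benzene gets exactly one H).
.fill_implicit_h <- function(atoms, bonds, hexpl) {
  n <- nrow(atoms)
  used <- rep(0, n)
  if (nrow(bonds) > 0L) {
    o <- ifelse(bonds$aromatic, 1.5, bonds$order)
    for (k in seq_len(nrow(bonds))) {
      used[bonds$i[k]] <- used[bonds$i[k]] + o[k]
      used[bonds$j[k]] <- used[bonds$j[k]] + o[k]
    }
  }
  h <- integer(n)
  for (a in seq_len(n)) {
    if (!is.na(hexpl[a])) { h[a] <- hexpl[a]; next }
    vals <- .DEFAULT_VALENCE[[atoms$element[a]]]
    if (is.null(vals)) { h[a] <- 0L; next }
    need <- ceiling(used[a] - 1e-9)
    v <- vals[vals >= need]
    h[a] <- if (length(v) == 0L) 0L else as.integer(min(v) - need)
  }
  h
}
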
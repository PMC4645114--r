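# SDF (MDL V2000) reader and writer. Coordinates in the atom block become
# the molecule's first conformer; data fields (`> <name>`) are parsed into
# numeric properties where possible.

.read_sdf_blocks <- function(lines) {
  ends <- grep("^\\$\\$\\$\\$", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) + 1L }
  Map(function(s, e) lines[s:(e - 1L)], starts,
      if (length(ends) > 0 && ends[1] <= length(lines)) ends else length(lines))
}

.parse_sdf_block <- function(blk) {
  blk <- blk[blk != "$$$$"]
  if (length(blk) < 4L) stop("truncated SDF record")
  name <- trimws(blk[1L])
  counts <- blk[4L]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(natoms) || is.na(nbonds)) stop("bad counts line in SDF record")
  at <- blk[5L:(4L + natoms)]
  xyz <- matrix(0, natoms, 3L)
  element <- character(natoms)
  for (k in seq_len(natoms)) {
    xyz[k, 1L] <- as.numeric(substr(at[k], 1L, 10L))
    xyz[k, 2L] <- as.numeric(substr(at[k], 11L, 20L))
    xyz[k, 3L] <- as.numeric(substr(at[k], 21L, 30L))
    element[k] <- trimws(substr(at[k], 32L, 34L))
  }
  bi <- integer(nbonds); bj <- integer(nbonds); bt <- integer(nbonds)
  if (nbonds > 0L) {
    bl <- blk[(5L + natoms):(4L + natoms + nbonds)]
    for (k in seq_len(nbonds)) {
      bi[k] <- as.integer(substr(bl[k], 1L, 3L))
      bj[k] <- as.integer(substr(bl[k], 4L, 6L))
      bt[k] <- as.integer(substr(bl[k], 7L, 9L))
    }
  }
  charge <- integer(natoms)
  for (ln in grep("^M  CHG", blk, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substring(ln, 7L)), "[[:space:]]+")[[1L]])
    cnt <- f[1L]
    for (p in seq_len(cnt)) charge[f[2L * p]] <- f[2L * p + 1L]
  }
  # properties
  props <- list()
  tag_lines <- grep("^>", blk)
  for (t in tag_lines) {
    nm <- sub("^>\\s*<([^>]+)>.*$", "\\1", blk[t])
    val <- if (t + 1L <= length(blk)) trimws(blk[t + 1L]) else ""
    num <- suppressWarnings(as.numeric(val))
    props[[nm]] <- if (!is.na(num)) num else val
  }

  keep <- element != "H"
  hcount_expl <- integer(sum(keep))
  idx_map <- cumsum(keep)
  arom_bond <- bt == 4L
  order <- ifelse(arom_bond, 1L, bt)
  # count explicit hydrogens onto their heavy partner, then drop them
  for (k in seq_len(nbonds)) {
    a <- bi[k]; b <- bj[k]
    if (!keep[a] && keep[b]) hcount_expl[idx_map[b]] <- hcount_expl[idx_map[b]] + 1L
    if (!keep[b] && keep[a]) hcount_expl[idx_map[a]] <- hcount_expl[idx_map[a]] + 1L
  }
  bkeep <- keep[bi] & keep[bj]
  atoms <- data.frame(element = element[keep],
                      aromatic = FALSE, charge = charge[keep],
                      hcount = 0L, h_explicit = FALSE,
                      stringsAsFactors = FALSE)
  bonds <- data.frame(i = idx_map[bi[bkeep]], j = idx_map[bj[bkeep]],
                      order = order[bkeep], aromatic = arom_bond[bkeep])
  if (nrow(bonds) > 0L) {
    arom_atoms <- unique(c(bonds$i[bonds$aromatic], bonds$j[bonds$aromatic]))
    atoms$aromatic[arom_atoms] <- TRUE
  }
  hx <- ifelse(hcount_expl > 0L, hcount_expl, NA_integer_)
  atoms$hcount <- .fill_implicit_h(atoms, bonds, hx)
  list(name = name, mol = molgraph(atoms, bonds),
       conformer = xyz[keep, , drop = FALSE], properties = props)
}

#' Write molecule records to an SDF (V2000) file
#'
#' Each record's first conformer (heavy atoms) is written; molecules without
#' conformers get zero coordinates. Numeric properties are emitted as data
#' fields.
#' @param records list of [molecule_record] objects
#' @param path output file path
#' @export
write_sdf <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    mol <- rec$structure
    n <- nrow(mol$atoms); nb <- nrow(mol$bonds)
    xyz <- if (length(rec$conformers) > 0L) rec$conformers[[1L]]
           else matrix(0, n, 3L)
    writeLines(c(rec$id, "  ensembleVS", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (k in seq_len(n)) {
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         xyz[k, 1L], xyz[k, 2L], xyz[k, 3L],
                         mol$atoms$element[k]), con)
    }
    if (nb > 0L) {
      bt <- ifelse(mol$bonds$aromatic, 4L, mol$bonds$order)
      for (k in seq_len(nb)) {
        writeLines(sprintf("%3d%3d%3d  0", mol$bonds$i[k], mol$bonds$j[k],
                           bt[k]), con)
      }
    }
    chg <- which(mol$atoms$charge != 0L)
    if (length(chg) > 0L) {
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]),
                               collapse = "")), con)
    }
    writeLines("M  END", con)
    for (nm in names(rec$properties)) {
      writeLines(c(sprintf(">  <%s>", nm),
                   as.character(rec$properties[[nm]]), ""), con)
    }
    writeLines("$$$$", con)
  }
  invisible(path)
}
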
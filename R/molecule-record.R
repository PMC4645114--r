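# MoleculeRecord: the library entry every module consumes. Carries the
# molecular graph, optional 3D conformers (heavy-atom coordinate matrices in
# Angstrom), named scalar properties, and an activity label.

#' Construct a molecule record
#'
#' @param id unique text identifier within a library
#' @param structure a [molgraph]
#' @param conformers list of n_atoms x 3 numeric matrices (Angstrom); may be
#'   empty
#' @param properties named list of finite scalars (e.g. `MW`, `logP`, `logS`,
#'   `caco2`, `HBD`, `HBA`, `IC50_uM`)
#' @param label one of `"active"`, `"decoy"`, `"unknown"`
#' @return object of class `molecule_record`
#' @export
molecule_record <- function(id, structure, conformers = list(),
                            properties = list(), label = "unknown") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(inherits(structure, "molgraph"))
  label <- match.arg(label, c("active", "decoy", "unknown"))
  n <- nrow(structure$atoms)
  for (cf in conformers) {
    if (!is.matrix(cf) || nrow(cf) != n || ncol(cf) != 3L)
      stop("conformer of '", id, "' must be a ", n, " x 3 coordinate matrix")
  }
  for (nm in names(properties)) {
    v <- properties[[nm]]
    if (is.numeric(v) && length(v) == 1L && !is.finite(v))
      stop("property '", nm, "' of '", id, "' is not finite")
  }
  structure(list(id = id, structure = structure, conformers = conformers,
                 properties = properties, label = label),
            class = "molecule_record")
}

#' @export
print.molecule_record <- function(x, ...) {
  cat(sprintf("<molecule_record> %s (%s): %d heavy atoms, %d conformer(s), %d propertie(s)\n",
              x$id, x$label, nrow(x$structure$atoms),
              length(x$conformers), length(x$properties)))
  invisible(x)
}

#' Read a compound library from SMILES or SDF
#'
#' SMILES files hold one molecule per line as `"SMILES<whitespace>id"`; a
#' missing id becomes `mol_<line>`. SDF files must be V2000. Records that fail
#' to parse are skipped with a warning naming the line/record index; input
#' order is preserved for the rest.
#'
#' @param path file path
#' @param format `"smiles"` or `"sdf"`; default guesses from the extension
#' @return list of [molecule_record] objects
#' @export
read_library <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("library file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  if (format == "smiles") .read_smiles_library(path) else .read_sdf_library(path)
}

.read_smiles_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  records <- list()
  ids_seen <- character(0)
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (!nzchar(raw) || startsWith(raw, "#")) next
    parts <- strsplit(raw, "[[:space:]]+")[[1L]]
    smi <- parts[1L]
    id <- if (length(parts) >= 2L) parts[2L] else sprintf("mol_%d", ln)
    mol <- tryCatch(parse_smiles(smi), error = function(e) e)
    if (inherits(mol, "error")) {
      warning("line ", ln, ": unparsable SMILES skipped (",
              conditionMessage(mol), ")", call. = FALSE)
      next
    }
    if (id %in% ids_seen) {
      warning("line ", ln, ": duplicate id '", id, "' skipped", call. = FALSE)
      next
    }
    ids_seen <- c(ids_seen, id)
    records[[length(records) + 1L]] <- molecule_record(id, mol)
  }
  if (length(records) == 0L) stop("no parsable records in ", path)
  records
}

.read_sdf_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blocks <- .read_sdf_blocks(lines)
  records <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    if (all(!nzchar(trimws(blk)))) next
    parsed <- tryCatch(.parse_sdf_block(blk), error = function(e) e)
    if (inherits(parsed, "error")) {
      warning("SDF record ", b, ": skipped (", conditionMessage(parsed), ")",
              call. = FALSE)
      next
    }
    id <- if (nzchar(parsed$name)) parsed$name else sprintf("mol_%d", b)
    records[[length(records) + 1L]] <-
      molecule_record(id, parsed$mol, conformers = list(parsed$conformer),
                      properties = parsed$properties)
  }
  if (length(records) == 0L) stop("no parsable records in ", path)
  records
}
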
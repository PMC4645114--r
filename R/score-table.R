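# Per-structure docking score tables. Scores follow the docking convention:
# more negative = better. The classifier downstream is orientation-agnostic
# (binning), so scores are stored raw.

#' Construct a score table
#'
#' @param structure_id receptor structure identifier
#' @param scores named numeric vector, names are molecule ids
#' @param score_mode `"SP"`, `"XP"` or `"stand-in"` (synthetic fixtures)
#' @export
score_table <- function(structure_id, scores,
                        score_mode = c("stand-in", "SP", "XP")) {
  score_mode <- match.arg(score_mode)
  stopifnot(is.character(structure_id), length(structure_id) == 1L)
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (any(!is.finite(scores))) stop("score table contains non-finite scores")
  if (anyDuplicated(names(scores)))
    stop("duplicate molecule ids; resolve with the best-kept rule first")
  structure(list(structure_id = structure_id, scores = scores,
                 score_mode = score_mode),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %s (%s): %d molecules, score range [%.2f, %.2f]\n",
              x$structure_id, x$score_mode, length(x$scores),
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' Read a docking score table from CSV
#'
#' Expects a header `molecule_id,score`. Rows with a non-numeric score are
#' rejected with a warning; duplicated molecule ids keep the best (most
#' negative) score, mirroring best-pose reporting.
#'
#' @param path CSV file path
#' @param structure_id receptor structure id; default is the file stem
#' @param score_mode scoring mode tag (metadata only)
#' @return a [score_table]
#' @export
read_score_table <- function(path, structure_id = NULL,
                             score_mode = c("stand-in", "SP", "XP")) {
  score_mode <- match.arg(score_mode)
  if (!file.exists(path)) stop("score table not found: ", path)
  if (is.null(structure_id))
    structure_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  if (!all(c("molecule_id", "score") %in% names(df)))
    stop("score table must have header 'molecule_id,score': ", path)
  val <- suppressWarnings(as.numeric(df$score))
  bad <- !is.finite(val)
  if (any(bad)) {
    warning(sum(bad), " row(s) with non-numeric score rejected in ",
            basename(path), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    val <- val[!bad]
  }
  if (nrow(df) == 0L) stop("score table has no valid rows: ", path)
  if (anyDuplicated(df$molecule_id)) {
    warning("duplicate molecule id(s) in ", basename(path),
            ": keeping most negative score", call. = FALSE)
    best <- tapply(val, df$molecule_id, min)
    # preserve first-seen order of ids
    ids <- df$molecule_id[!duplicated(df$molecule_id)]
    val <- as.numeric(best[ids])
  } else {
    ids <- df$molecule_id
  }
  names(val) <- ids
  score_table(structure_id, val, score_mode)
}

#' Write a score table to CSV
#' @param tab a [score_table]
#' @param path output path
#' @export
write_score_table <- function(tab, path) {
  stopifnot(inherits(tab, "score_table"))
  utils::write.csv(data.frame(molecule_id = names(tab$scores),
                              score = unname(tab$scores)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
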
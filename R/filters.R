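# Drug-likeness filters used to post-process the ranked hit list: Lipinski's
# Rule-of-Five (pass = at most one violation) and a REOS-style "rapid
# elimination of swill" screen (property windows plus reactive-group alerts;
# pass = zero violations).

#' Lipinski Rule-of-Five verdict
#'
#' Violations among MW > 500, logP > 5, HBD > 5, HBA > 10; a molecule passes
#' with at most one violation. Rules whose property is absent are skipped and
#' recorded in `skipped`.
#'
#' @param props named list/vector with any of `MW`, `logP`, `HBD`, `HBA`
#' @param molecule_id id recorded on the verdict
#' @return object of class `filter_verdict`
#' @export
lipinski_ro5 <- function(props, molecule_id = NA_character_) {
  p <- as.list(props)
  violations <- character(0)
  skipped <- character(0)
  check <- function(name, limit) {
    if (is.null(p[[name]]) || is.na(p[[name]])) {
      skipped <<- c(skipped, name)
    } else if (p[[name]] > limit) {
      violations <<- c(violations, sprintf("%s > %g", name, limit))
    }
  }
  check("MW", 500); check("logP", 5); check("HBD", 5); check("HBA", 10)
  structure(list(molecule_id = molecule_id, rule_set = "Ro5",
                 passed = length(violations) <= 1L,
                 violations = violations, skipped = skipped),
            class = "filter_verdict")
}

#' @export
print.filter_verdict <- function(x, ...) {
  cat(sprintf("<filter_verdict> %s [%s]: %s%s\n",
              x$molecule_id, x$rule_set,
              if (x$passed) "PASS" else "FAIL",
              if (length(x$violations) > 0L)
                paste0(" (", paste(x$violations, collapse = "; "), ")")
              else ""))
  invisible(x)
}

# REOS structural alerts, matched as substructures. A deliberately compact,
# documented list of classically reactive groups.
.REOS_ALERTS <- list(
  acyl_halide      = "C(=O)Cl",
  acyl_bromide     = "C(=O)Br",
  sulfonyl_halide  = "S(=O)(=O)Cl",
  aldehyde         = "[CH1](=O)C",
  isocyanate       = "N=C=O",
  thiol            = "[SH1]C",
  epoxide          = "C1OC1",
  aziridine        = "C1NC1",
  anhydride        = "C(=O)OC(=O)"
)

#' REOS-style filter verdict
#'
#' Property windows: MW in [200, 500], logP in [-5, 5], HBD <= 5, HBA <= 10,
#' formal charge in [-2, 2], rotatable bonds <= 8, heavy atoms in [20, 70];
#' plus structural alerts for reactive groups (acyl/sulfonyl halides,
#' aldehyde, isocyanate, thiol, epoxide, aziridine, anhydride). Passing
#' requires zero violations. HBD/HBA, charge, rotatable bonds and heavy atoms
#' are computed from the structure; MW falls back to the graph when absent
#' from `props`; logP must be supplied (skipped when absent).
#'
#' @param molecule a [molecule_record]
#' @param props optional property overrides (defaults to the record's)
#' @return object of class `filter_verdict`
#' @export
reos_filter <- function(molecule, props = NULL) {
  stopifnot(inherits(molecule, "molecule_record"))
  mol <- molecule$structure
  p <- if (is.null(props)) molecule$properties else as.list(props)
  violations <- character(0)
  skipped <- character(0)
  mw <- if (!is.null(p$MW)) p$MW else mol_mw(mol)
  if (mw < 200 || mw > 500)
    violations <- c(violations, sprintf("MW %.1f outside [200, 500]", mw))
  if (!is.null(p$logP)) {
    if (p$logP < -5 || p$logP > 5)
      violations <- c(violations, sprintf("logP %.2f outside [-5, 5]", p$logP))
  } else skipped <- c(skipped, "logP")
  hbd <- count_hbd(mol); hba <- count_hba(mol)
  if (hbd > 5) violations <- c(violations, sprintf("HBD %d > 5", hbd))
  if (hba > 10) violations <- c(violations, sprintf("HBA %d > 10", hba))
  fc <- formal_charge(mol)
  if (fc < -2 || fc > 2)
    violations <- c(violations, sprintf("formal charge %d outside [-2, 2]", fc))
  rot <- count_rotatable_bonds(mol)
  if (rot > 8) violations <- c(violations, sprintf("rotatable bonds %d > 8", rot))
  ha <- heavy_atom_count(mol)
  if (ha < 20 || ha > 70)
    violations <- c(violations, sprintf("heavy atoms %d outside [20, 70]", ha))
  for (alert in names(.REOS_ALERTS)) {
    pat <- .pattern_cache(.REOS_ALERTS[[alert]])
    if (has_substructure(pat, mol))
      violations <- c(violations, paste0("alert: ", alert))
  }
  structure(list(molecule_id = molecule$id, rule_set = "REOS",
                 passed = length(violations) == 0L,
                 violations = violations, skipped = skipped),
            class = "filter_verdict")
}

#' Combined drug-likeness screen
#'
#' The conjunction used by the campaign funnel: Rule-of-Five (<= 1
#' violation) AND REOS (0 violations). A hook for a custom in-house rule
#' function is provided; it must accept a [molecule_record] and return a
#' `filter_verdict`-like list with a `passed` flag.
#'
#' @param molecule a [molecule_record]
#' @param custom_rule optional extra filter function
#' @return logical pass/fail with verdicts in attributes
#' @export
druglikeness_pass <- function(molecule, custom_rule = NULL) {
  props <- molecule$properties
  if (is.null(props$HBD)) props$HBD <- count_hbd(molecule$structure)
  if (is.null(props$HBA)) props$HBA <- count_hba(molecule$structure)
  if (is.null(props$MW)) props$MW <- mol_mw(molecule$structure)
  ro5 <- lipinski_ro5(props, molecule$id)
  reos <- reos_filter(molecule)
  ok <- ro5$passed && reos$passed
  if (!is.null(custom_rule)) ok <- ok && isTRUE(custom_rule(molecule)$passed)
  structure(ok, ro5 = ro5, reos = reos)
}
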
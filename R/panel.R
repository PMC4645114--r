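# Bundled reference data: the experimentally characterized ROCK1 inhibitor
# panel from the ensemble screening campaign this toolkit re-implements.
# Assayed IC50 values (uM, mean +/- sd over triplicate 8-point dilutions) and
# QikProp-style predicted properties for the reference inhibitor Y27632 and
# the 11 confirmed screening hits; `max_known_similarity` is each hit's
# highest circular-fingerprint Tanimoto against previously known ROCK1
# inhibitors (a novelty measure).

#' Load the ROCK1 inhibitor reference panel
#'
#' The assayed hit panel of the campaign: 11 confirmed inhibitors plus the
#' reference compound Y27632, with IC50 (uM), MW, logP, logS, Caco-2
#' permeability (nm/s) and each hit's maximum similarity to previously known
#' inhibitors. Properties here are ingested assay/prediction results --
#' nothing in this table is computed by the toolkit.
#'
#' @param hits_only drop the reference compound row (default `FALSE`)
#' @return data.frame, one row per compound
#' @export
rock1_inhibitor_panel <- function(hits_only = FALSE) {
  path <- system.file("extdata", "rock1_inhibitor_panel.csv",
                      package = "ensembleVS")
  if (!nzchar(path))
    path <- file.path("inst", "extdata", "rock1_inhibitor_panel.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (hits_only) df <- df[df$role == "hit", , drop = FALSE]
  df
}
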
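#' Filtering configuration for tetramer assembly
#'
#' The five evidence presets combine the disease-evidence classes with
#' the two disease-level filters:
#' * `v1`: marker/mechanism only; disease tissue filter on; disease
#'   species filter on (most stringent)
#' * `v2`: marker/mechanism + therapeutic; tissue on; species on
#' * `v3`: marker/mechanism + therapeutic; tissue on; species off
#' * `v4`: marker/mechanism + therapeutic; tissue off; species on
#' * `v5`: marker/mechanism + therapeutic; both off (most relaxed)
#'
#' The organism filter on chemical-gene/chemical-phenotype interactions
#' and the anatomy-based tissue filter (active when `tissue_group` is not
#' `"all"`) apply in every preset; the preset toggles only the
#' disease-edge filters. Relaxing the preset can therefore only grow the
#' tetramer set for a fixed organism and tissue group.
#'
#' @param organism_taxon NCBI taxon (9606 human, 10090 mouse, 10116 rat
#'   in the defaults).
#' @param tissue_group Tissue-group identifier or `"all"` (disables
#'   anatomy filtering and PubMed-based indirect tissue filtering).
#' @param preset One of `"v1"` to `"v5"`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(organism_taxon, tissue_group = "all",
                          preset = c("v1", "v2", "v3", "v4", "v5")) {
  preset <- match.arg(preset)
  stopifnot(is.numeric(organism_taxon), organism_taxon > 0,
            is.character(tissue_group), length(tissue_group) == 1)
  spec <- list(
    v1 = list(ev = "marker_mechanism", tissue = TRUE, species = TRUE),
    v2 = list(ev = c("marker_mechanism", "therapeutic"), tissue = TRUE,
              species = TRUE),
    v3 = list(ev = c("marker_mechanism", "therapeutic"), tissue = TRUE,
              species = FALSE),
    v4 = list(ev = c("marker_mechanism", "therapeutic"), tissue = FALSE,
              species = TRUE),
    v5 = list(ev = c("marker_mechanism", "therapeutic"), tissue = FALSE,
              species = FALSE)
  )[[preset]]
  out <- list(
    organism_taxon = as.integer(organism_taxon),
    tissue_group = tissue_group,
    evidence_preset = preset,
    allowed_evidence = spec$ev,
    disease_tissue_filter = spec$tissue,
    disease_species_filter = spec$species
  )
  class(out) <- "filter_config"
  out
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config> taxon ", x$organism_taxon, ", tissue '",
      x$tissue_group, "', preset ", x$evidence_preset, " (evidence: ",
      paste(x$allowed_evidence, collapse = "+"),
      "; disease tissue filter ", x$disease_tissue_filter,
      ", disease species filter ", x$disease_species_filter, ")\n",
      sep = "")
  invisible(x)
}
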
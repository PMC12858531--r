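#' Load a tissue-group map
#'
#' A tissue-group map places MeSH anatomy terms and MeSH diseases onto 28
#' coarse tissue groups (25 groups from the foundational cumulative-
#' assessment report plus breast, fat tissue and pluripotent stem cells).
#' Group names are case-normalized identifiers; the display name is the
#' identifier with underscores replaced by spaces. The packaged default
#' is a synthetic stand-in that reproduces the documented structure of
#' the published mapping (28 groups covering 506 anatomy terms, plus
#' category expansions such as Endocrine system to the four glands); the
#' disease mapping is precomputed, the runtime performs lookups only.
#'
#' @param anatomy_path,disease_path TSV files with columns
#'   `anatomy_id`/`disease_id`, `*_name`, `tissue_groups` (pipe-delimited
#'   group identifiers). Defaults are the packaged synthetic maps.
#' @return An object of class `tissue_group_map`: a list with `groups`
#'   (character vector of 28 identifiers), `anatomy` and `disease`
#'   tibbles.
#' @export
tissue_group_map <- function(
    anatomy_path = system.file("extdata",
                               "anatomy_tissue_groups_synthetic.tsv",
                               package = "cgpdgroup"),
    disease_path = system.file("extdata",
                               "disease_tissue_groups_synthetic.tsv",
                               package = "cgpdgroup")) {
  am <- tibble::as_tibble(utils::read.delim(anatomy_path,
                                            colClasses = "character"))
  dm <- tibble::as_tibble(utils::read.delim(disease_path,
                                            colClasses = "character"))
  groups <- sort(unique(unlist(split_set(c(am$tissue_groups,
                                           dm$tissue_groups)))))
  out <- list(groups = groups, anatomy = am, disease = dm)
  class(out) <- "tissue_group_map"
  out
}

#' @export
print.tissue_group_map <- function(x, ...) {
  cat("<tissue_group_map> ", length(x$groups), " groups, ",
      nrow(x$anatomy), " anatomy terms, ", nrow(x$disease),
      " mapped diseases\n", sep = "")
  invisible(x)
}

#' Tissue groups reached by a set of anatomy terms
#'
#' Unmapped terms contribute nothing; lookups try the MeSH ID first and
#' fall back to the term name (CTD dumps may carry either).
#'
#' @param terms Character vector of MeSH anatomy IDs or term names.
#' @param map A [tissue_group_map()].
#' @return Character vector: the union of mapped group identifiers
#'   (possibly empty).
#' @export
anatomy_groups <- function(terms, map) {
  if (length(terms) == 0) return(character(0))
  hit <- map$anatomy$anatomy_id %in% terms |
    map$anatomy$anatomy_name %in% setdiff(terms, map$anatomy$anatomy_id)
  groups <- unlist(split_set(map$anatomy$tissue_groups[hit]))
  sort(unique(as.character(groups)))
}

#' Tissue groups assigned to a disease
#'
#' Returns the precomputed group set for a mapped disease; diseases
#' absent from the mapping default to all 28 tissue groups (a disease
#' with no anatomical localization is not excluded by tissue filtering),
#' so the result is never empty.
#'
#' @param disease_id MeSH disease ID (single string).
#' @param map A [tissue_group_map()].
#' @return Character vector of group identifiers.
#' @export
disease_groups <- function(disease_id, map) {
  stopifnot(length(disease_id) == 1)
  hit <- which(map$disease$disease_id == disease_id)
  if (length(hit) == 0) return(map$groups)
  sort(unique(unlist(split_set(map$disease$tissue_groups[hit]))))
}
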
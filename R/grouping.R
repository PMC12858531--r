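#' Group chemicals by shared (gene, phenotype, disease) trimers
#'
#' One group per distinct GPD key occurring in the tetramer set; a
#' group's chemicals are all chemicals with a tetramer on that key.
#' Grouping is performed within one (organism, tissue group) run;
#' singleton groups are kept.
#'
#' @param tetramers Tibble from [cgpd_tetramers()].
#' @return Tibble with key columns `speciesgeneid`, `phenotypeid`,
#'   `diseaseid`, a `chemicals` list-column (sorted unique IDs),
#'   `n_chemicals`, `n_tetramers`, `organismid`, `tissue_group`.
#' @export
group_gpd <- function(tetramers) {
  out <- dplyr::summarise(
    dplyr::group_by(tetramers, .data$speciesgeneid, .data$phenotypeid,
                    .data$diseaseid, .data$organismid, .data$tissue_group),
    chemicals = list(sort(unique(.data$chemicalid))),
    n_chemicals = length(unique(.data$chemicalid)),
    n_tetramers = dplyr::n(),
    .groups = "drop")
  out$group_id <- paste("gpd", out$speciesgeneid, out$phenotypeid,
                        out$diseaseid, sep = ":")
  out
}

#' Group chemicals by shared (phenotype, disease) dimers
#'
#' As [group_gpd()] but the key omits the gene, so chemicals acting on
#' different genes that share a phenotype and disease fall into one
#' group; the genes behind each group are retained as a list-column.
#'
#' @param tetramers Tibble from [cgpd_tetramers()].
#' @return Tibble with key columns `phenotypeid`, `diseaseid`, list-
#'   columns `chemicals` and `genes`, counts, `organismid`,
#'   `tissue_group`.
#' @export
group_pd <- function(tetramers) {
  out <- dplyr::summarise(
    dplyr::group_by(tetramers, .data$phenotypeid, .data$diseaseid,
                    .data$organismid, .data$tissue_group),
    chemicals = list(sort(unique(.data$chemicalid))),
    genes = list(sort(unique(.data$speciesgeneid))),
    n_chemicals = length(unique(.data$chemicalid)),
    n_tetramers = dplyr::n(),
    .groups = "drop")
  out$group_id <- paste("pd", out$phenotypeid, out$diseaseid, sep = ":")
  out
}

#' Write chemical groups as TSV
#'
#' List-columns are flattened to pipe-delimited cells.
#'
#' @param groups Tibble from [group_gpd()] or [group_pd()].
#' @param path Output TSV path.
#' @return `groups`, invisibly.
#' @export
write_groups <- function(groups, path) {
  flat <- groups
  for (col in names(flat)) {
    if (is.list(flat[[col]])) {
      flat[[col]] <- vapply(flat[[col]], function(v)
        paste(v, collapse = "|"), character(1))
    }
  }
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(groups)
}
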
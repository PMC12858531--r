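#' Remap primary gene IDs to species-specific gene IDs
#'
#' CTD identifies genes in chemical-gene interactions by a *primary*
#' Entrez ID assigned irrespective of the organism in which the
#' interaction was curated; an interaction curated in mouse may carry the
#' human ortholog's ID. This adds a `speciesgeneid` column: when the
#' primary gene's own taxon equals the record's `organismid` the primary
#' ID is kept; otherwise the ortholog of the primary gene in the curated
#' organism is looked up in an NCBI `gene_orthologs`-format table.
#' Records whose primary gene has no ortholog in the curated organism are
#' excluded, as are records whose primary gene is absent from the
#' gene-info lookup (unknown taxon). A gene with several orthologs in the
#' target taxon yields one record per ortholog.
#'
#' @param interactions Tibble of chemical-gene interactions with at least
#'   `geneid` and `organismid` (see [load_ctd_table()] kind `chem_gene`).
#' @param orthologs Tibble in `gene_orthologs` format (`tax_id`, `geneid`,
#'   `other_tax_id`, `other_geneid`); pairs are treated symmetrically.
#' @param gene_info Tibble with `geneid` and `tax_id` giving each primary
#'   gene's own taxon.
#' @return The retained interactions with a `speciesgeneid` column.
#'   Attribute `remap_report` is a named integer vector with counts
#'   `input`, `retained_input_rows`, `emitted`, `excluded_no_ortholog`,
#'   `excluded_unknown_taxon`; a summary message is emitted when records
#'   are excluded.
#' @export
remap_gene_ids <- function(interactions, orthologs, gene_info) {
  stopifnot(all(c("geneid", "organismid") %in% names(interactions)),
            !any(is.na(interactions$organismid)))
  n_input <- nrow(interactions)

  taxon_of <- dplyr::distinct(gene_info[, c("geneid", "tax_id")])
  x <- dplyr::left_join(interactions, taxon_of, by = "geneid")

  unknown <- is.na(x$tax_id)
  same <- !unknown & x$tax_id == x$organismid
  needs_map <- !unknown & !same

  kept_same <- x[same, , drop = FALSE]
  kept_same$speciesgeneid <- kept_same$geneid

  # symmetric ortholog lookup: (gene, target taxon) -> ortholog gene
  orth <- dplyr::bind_rows(
    tibble::tibble(geneid = orthologs$geneid,
                   target_taxon = orthologs$other_tax_id,
                   ortholog = orthologs$other_geneid),
    tibble::tibble(geneid = orthologs$other_geneid,
                   target_taxon = orthologs$tax_id,
                   ortholog = orthologs$geneid)
  )
  orth <- dplyr::distinct(orth)

  to_map <- x[needs_map, , drop = FALSE]
  mapped <- dplyr::inner_join(
    to_map, orth,
    by = c(geneid = "geneid", organismid = "target_taxon"),
    relationship = "many-to-many"
  )
  mapped$speciesgeneid <- mapped$ortholog
  mapped$ortholog <- NULL
  unmapped <- dplyr::anti_join(
    to_map, orth, by = c(geneid = "geneid", organismid = "target_taxon")
  )

  out <- dplyr::bind_rows(kept_same, mapped)
  out$tax_id <- NULL
  out <- dplyr::distinct(out)

  n_retained_input <- sum(same) + (nrow(to_map) - nrow(unmapped))
  report <- c(
    input = n_input,
    retained_input_rows = n_retained_input,
    emitted = nrow(out),
    excluded_no_ortholog = nrow(unmapped),
    excluded_unknown_taxon = sum(unknown)
  )
  if (report[["excluded_no_ortholog"]] + report[["excluded_unknown_taxon"]] > 0) {
    message("remap_gene_ids: excluded ", report[["excluded_no_ortholog"]],
            " record(s) without ortholog and ",
            report[["excluded_unknown_taxon"]],
            " record(s) with unknown gene taxon")
  }
  attr(out, "remap_report") <- report
  out
}
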
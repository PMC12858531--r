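#' Canonical table names of the relational store
#'
#' Sixteen tables mirror the CTD dump files they are loaded from (four
#' interaction tables carry the evidence the tetramer pipeline uses; the
#' vocabulary and auxiliary tables are stored verbatim); two further
#' tables hold compound descriptions and external identifiers keyed by
#' the MeSH-to-CID mapping. Names are lowercase, as are all column names.
#'
#' @export
ctd_store_tables <- c(
  "ctd_chem_gene_ixns",
  "ctd_pheno_term_ixns",
  "ctd_chemicals_diseases",
  "ctd_genes_diseases",
  "ctd_chemicals",
  "ctd_diseases",
  "ctd_genes",
  "ctd_anatomy",
  "ctd_chem_go_enriched_associations",
  "ctd_chem_pathways_enriched",
  "ctd_genes_pathways",
  "ctd_diseases_pathways",
  "ctd_pheno_disease_biological_processes",
  "ctd_pheno_disease_cellular_components",
  "ctd_exposure_studies",
  "ctd_exposure_events"
)

pubchem_store_tables <- c("pubchem_descriptions", "pubchem_identifiers")

#' Build the single-file SQLite store
#'
#' Writes the 16 ingested CTD-format tables plus the two compound tables
#' into one SQLite database. Table names must match [ctd_store_tables]
#' exactly (a missing table aborts the build naming it); reopening the
#' store yields identical record counts and field values.
#'
#' @param tables Named list of tibbles covering all of [ctd_store_tables].
#' @param chemical_descriptions,chemical_identifiers Tibbles for the two
#'   compound tables (MeSH-to-CID mapping plus per-compound properties).
#' @param out_path Path of the SQLite file to create (overwritten).
#' @return `out_path`, invisibly.
#' @seealso [open_store()], [store_counts()]
#' @export
build_store <- function(tables, chemical_descriptions, chemical_identifiers,
                        out_path) {
  if (anyDuplicated(names(tables)) > 0) {
    stop("duplicate table name(s): ",
         paste(unique(names(tables)[duplicated(names(tables))]),
               collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(ctd_store_tables, names(tables))
  if (length(missing) > 0) {
    stop("missing CTD table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(tables), ctd_store_tables)
  if (length(extra) > 0) {
    stop("unexpected table(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (file.exists(out_path)) file.remove(out_path)
  con <- DBI::dbConnect(RSQLite::SQLite(), out_path)
  on.exit(DBI::dbDisconnect(con))
  for (nm in ctd_store_tables) {
    DBI::dbWriteTable(con, nm, as.data.frame(tables[[nm]]))
  }
  DBI::dbWriteTable(con, "pubchem_descriptions",
                    as.data.frame(chemical_descriptions))
  DBI::dbWriteTable(con, "pubchem_identifiers",
                    as.data.frame(chemical_identifiers))
  invisible(out_path)
}

#' Open an existing store
#'
#' @param path SQLite file written by [build_store()].
#' @return A DBI connection; caller must disconnect.
#' @export
open_store <- function(path) {
  if (!file.exists(path)) stop("no store at '", path, "'", call. = FALSE)
  DBI::dbConnect(RSQLite::SQLite(), path)
}

#' Per-table record counts of a store
#'
#' @param path SQLite file written by [build_store()].
#' @return Named integer vector over all store tables.
#' @export
store_counts <- function(path) {
  con <- open_store(path)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  vapply(stats::setNames(tabs, tabs), function(t) {
    DBI::dbGetQuery(con, paste0("SELECT COUNT(*) AS n FROM ", t))$n
  }, numeric(1))
}

#' Read one table back from a store
#'
#' @param path SQLite file.
#' @param name Table name (see [ctd_store_tables]).
#' @return A tibble.
#' @export
read_store_table <- function(path, name) {
  con <- open_store(path)
  on.exit(DBI::dbDisconnect(con))
  tibble::as_tibble(DBI::dbReadTable(con, name))
}
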
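#' Table kinds understood by the CTD-dialect loader
#'
#' Each kind declares the columns that must be present after header
#' normalization. `generic` accepts any header (used for vocabulary and
#' auxiliary tables that are stored verbatim).
#'
#' @format A named list mapping kind to required column names.
#' @keywords internal
ctd_table_schemas <- list(
  chem_gene      = c("chemicalid", "geneid", "organismid", "pubmedids"),
  chem_pheno     = c("chemicalid", "phenotypeid", "organismid", "anatomyterms",
                     "pubmedids"),
  chem_disease   = c("chemicalid", "diseaseid", "directevidence", "pubmedids"),
  gene_disease   = c("geneid", "diseaseid", "directevidence", "pubmedids"),
  gene2go        = c("tax_id", "geneid", "go_id", "evidence"),
  gene_orthologs = c("tax_id", "geneid", "other_tax_id", "other_geneid"),
  gene_info      = c("tax_id", "geneid"),
  chemicals      = c("chemicalid"),
  generic        = character(0)
)

normalize_header <- function(x) {
  x <- tolower(trimws(x))
  gsub("[^a-z0-9_]", "", x)
}

strip_mesh_prefix <- function(x) {
  # also strips inside pipe-delimited multi-valued cells
  gsub("(^|\\|)MESH:", "\\1", x)
}

#' Load a CTD-dialect TSV table
#'
#' Reads a tab-separated dump (optionally gzipped) whose header may be
#' embedded in a leading comment block of lines beginning with `#` (the
#' last comment line is taken as the header, as in CTD dumps). Column
#' names are lowercased and stripped of punctuation; every leading
#' `MESH:` prefix is removed from cell values, including inside
#' pipe-delimited multi-valued cells. Rows whose field count does not
#' match the header are counted and reported through the `malformed`
#' attribute (and a message), never silently dropped without notice.
#'
#' @param path Path to a `.tsv` or `.tsv.gz` file.
#' @param table_kind One of `names(ctd_table_schemas)`; selects the
#'   required-column check. Defaults to `"generic"` (no check).
#' @return A tibble with normalized column names. Attributes:
#'   `malformed` (number of skipped rows), `malformed_lines` (their line
#'   numbers in the file).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("# ChemicalName\tChemicalID", "aspirin\tMESH:D001241"), tf)
#' load_ctd_table(tf)
#' @export
load_ctd_table <- function(path, table_kind = "generic") {
  table_kind <- match.arg(table_kind, names(ctd_table_schemas))
  if (!file.exists(path)) {
    stop("cannot read CTD table: no such file '", path, "'", call. = FALSE)
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  is_comment <- grepl("^#", lines)
  n_lead <- if (all(is_comment)) length(lines) else which(!is_comment)[1] - 1L
  if (n_lead > 0L) {
    header_line <- sub("^#\\s*", "", lines[n_lead])
    body <- lines[-seq_len(n_lead)]
    body_lineno <- seq_along(body) + n_lead
  } else {
    if (length(lines) == 0L) {
      stop("cannot read CTD table: '", path, "' is empty", call. = FALSE)
    }
    header_line <- lines[1]
    body <- lines[-1]
    body_lineno <- seq_along(body) + 1L
  }
  # drop stray comment lines inside the body (CTD dumps end with none, but
  # be permissive) and blank lines
  keep <- !grepl("^#", body) & nzchar(body)
  body <- body[keep]
  body_lineno <- body_lineno[keep]

  cols <- normalize_header(strsplit(header_line, "\t", fixed = TRUE)[[1]])
  required <- ctd_table_schemas[[table_kind]]
  missing <- setdiff(required, cols)
  if (length(missing) > 0L) {
    stop("CTD table '", path, "' (kind '", table_kind,
         "') is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; the true field count is
  # tabs + 1. A row is malformed iff that count differs from the header.
  nf_true <- nchar(gsub("[^\t]", "", body)) + 1L
  bad <- nf_true != length(cols)
  fields <- lapply(fields, function(f) {
    if (length(f) < length(cols)) c(f, rep("", length(cols) - length(f)))
    else f[seq_len(length(cols))]
  })
  if (any(bad)) {
    message(sum(bad), " malformed row(s) skipped in '", basename(path), "'")
  }
  good <- fields[!bad]
  mat <- if (length(good) > 0L) {
    do.call(rbind, good)
  } else {
    matrix(character(0), ncol = length(cols))
  }
  out <- tibble::as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                           .name_repair = "minimal")
  names(out) <- cols
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(),
                                          strip_mesh_prefix))
  out <- parse_typed_columns(out, table_kind)
  out <- dplyr::distinct(out)
  attr(out, "malformed") <- sum(bad)
  attr(out, "malformed_lines") <- body_lineno[bad]
  out
}

# integer coercion for known ID columns; evidence label canonicalization
parse_typed_columns <- function(tbl, table_kind) {
  int_cols <- intersect(
    c("geneid", "organismid", "tax_id", "other_tax_id", "other_geneid"),
    names(tbl)
  )
  for (col in int_cols) tbl[[col]] <- suppressWarnings(as.integer(tbl[[col]]))
  if ("directevidence" %in% names(tbl)) {
    tbl$evidence <- parse_evidence(tbl$directevidence)
  }
  tbl
}

#' Canonicalize CTD direct-evidence labels
#'
#' CTD marks manually curated disease associations as `marker/mechanism`
#' and/or `therapeutic`; rows with an empty label are inferred
#' associations (derived via shared genes or chemicals, not curated).
#'
#' @param x Character vector of raw `directevidence` cells (possibly
#'   pipe-delimited when a row carries both labels).
#' @return Character vector over `marker_mechanism`, `therapeutic`,
#'   `inferred`; multi-labelled rows stay pipe-delimited.
#' @export
parse_evidence <- function(x) {
  vapply(split_set(x), function(v) {
    if (length(v) == 0L) return("inferred")
    v <- ifelse(v == "marker/mechanism", "marker_mechanism", v)
    bad <- setdiff(v, c("marker_mechanism", "therapeutic"))
    if (length(bad) > 0L) {
      stop("unknown direct-evidence label: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    paste(sort(unique(v)), collapse = "|")
  }, character(1))
}
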
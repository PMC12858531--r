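#' Chemical class dictionary
#'
#' Rules for tagging chemicals with regulatory classes. Three rule types
#' are supported: `pattern` (case-insensitive substring over name and
#' synonyms, e.g. "bisphenol"), `mesh_list` (explicit MeSH ID list, as
#' for pesticide and pharmaceutical dictionaries) and `parent`
#' (membership via the vocabulary's parent MeSH ID, e.g. Fluorocarbons
#' D005466 for PFAS). Chemicals tagged `pesticide` are excluded from the
#' `pharmaceutical` class.
#'
#' @param rules Tibble with columns `class`, `rule_type`, `value`
#'   (`mesh_list` values pipe-delimited). Defaults to the three
#'   industrial-chemical rules (bisphenol/phthalate patterns, PFAS
#'   parent ID).
#' @return Object of class `chemical_class_dictionary`.
#' @export
chemical_class_dictionary <- function(rules = NULL) {
  if (is.null(rules)) {
    rules <- tibble::tibble(
      class = c("bisphenol", "phthalate", "pfas"),
      rule_type = c("pattern", "pattern", "parent"),
      value = c("bisphenol", "phthalate", "D005466")
    )
  }
  stopifnot(all(c("class", "rule_type", "value") %in% names(rules)),
            all(rules$rule_type %in% c("pattern", "mesh_list", "parent")))
  out <- tibble::as_tibble(rules)
  class(out) <- c("chemical_class_dictionary", class(out))
  out
}

#' Tag chemicals with regulatory classes
#'
#' Deterministic and idempotent; a chemical may match several classes.
#'
#' @param records Tibble with columns `chemicalid`, `chemicalname`, and
#'   optionally `synonyms` and `parentids` (pipe-delimited).
#' @param dict A [chemical_class_dictionary()].
#' @return Long tibble (`chemicalid`, `class`), one row per assignment.
#' @export
tag_chemicals <- function(records, dict) {
  syn <- if ("synonyms" %in% names(records)) records$synonyms else ""
  par <- if ("parentids" %in% names(records)) records$parentids else ""
  text <- tolower(paste(records$chemicalname, syn, sep = "|"))
  parents <- split_set(par)
  hits <- lapply(seq_len(nrow(dict)), function(r) {
    rule <- dict[r, ]
    match <- switch(
      rule$rule_type,
      pattern = grepl(tolower(rule$value), text, fixed = TRUE),
      mesh_list = records$chemicalid %in% split_set(rule$value)[[1]],
      parent = vapply(parents, function(p) rule$value %in% p, logical(1))
    )
    tibble::tibble(chemicalid = records$chemicalid[match],
                   class = rule$class)
  })
  out <- dplyr::distinct(dplyr::bind_rows(hits))
  if (all(c("pesticide", "pharmaceutical") %in% dict$class)) {
    pest <- out$chemicalid[out$class == "pesticide"]
    out <- out[!(out$class == "pharmaceutical" &
                   out$chemicalid %in% pest), , drop = FALSE]
  }
  out
}

#' Hypergeometric over-representation of a category in a cluster
#'
#' Upper-tail probability `P(X >= k)` of drawing at least
#' `k = |cluster intersect category|` category members when drawing
#' `n = |cluster|` items from a background of `N` items containing
#' `K = |category|`; the classic one-tailed ORA test. `gene_ratio` is
#' `k / n` (so a cluster whose genes are all inside the category scores
#' a gene ratio of 1).
#'
#' @param cluster_members,category_members,background Character vectors;
#'   both member sets must be subsets of the background.
#' @param cluster_id,category Optional labels carried into the result.
#' @return One-row tibble: `cluster_id`, `category`, `k`, `n`, `K`, `N`,
#'   `gene_ratio`, `p_value`.
#' @export
overrepresentation <- function(cluster_members, category_members,
                               background, cluster_id = NA_character_,
                               category = NA_character_) {
  background <- unique(background)
  if (length(background) == 0) stop("empty background", call. = FALSE)
  cluster_members <- unique(cluster_members)
  category_members <- unique(category_members)
  stopifnot(all(cluster_members %in% background),
            all(category_members %in% background))
  k <- length(intersect(cluster_members, category_members))
  n <- length(cluster_members)
  K <- length(category_members)
  N <- length(background)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(cluster_id = cluster_id, category = category,
                 k = k, n = n, K = K, N = N,
                 gene_ratio = if (n > 0) k / n else NA_real_,
                 p_value = p)
}

#' Benjamini-Hochberg adjustment of ORA results
#'
#' Step-up FDR adjustment applied within each batch (e.g. one batch per
#' cluster-by-category-family combination); adjusted values are monotone
#' in the raw p-values, bounded by 1, and independent of input order.
#'
#' @param results Tibble with a `p_value` column.
#' @param batch Optional factor/character vector defining adjustment
#'   batches (default: one batch).
#' @return `results` with an `adjusted_p` column.
#' @export
adjust_pvalues <- function(results, batch = NULL) {
  stopifnot("p_value" %in% names(results))
  if (is.null(batch)) batch <- rep(1L, nrow(results))
  stopifnot(length(batch) == nrow(results))
  adjusted <- numeric(nrow(results))
  for (b in unique(batch)) {
    i <- which(batch == b)
    adjusted[i] <- stats::p.adjust(results$p_value[i], method = "BH")
  }
  results$adjusted_p <- adjusted
  results
}

#' Compare derived and reference chemical-tissue profiles
#'
#' Reports, per chemical, the number of tissues in the derived map, the
#' reference map and their intersection; and, per tissue, which
#' chemicals are linked only in the derived map, only in the reference,
#' or in both. Both maps must use the same tissue-group vocabulary.
#'
#' @param derived,reference Named lists: chemical -> character vector of
#'   tissue groups.
#' @return List with tibbles `per_chemical` (`chemical`, `n_derived`,
#'   `n_reference`, `n_intersection`) and `per_tissue` (`tissue`,
#'   list-columns `only_derived`, `only_reference`, `both`, and counts).
#' @export
compare_tissue_profiles <- function(derived, reference) {
  chems <- sort(union(names(derived), names(reference)))
  per_chemical <- dplyr::bind_rows(lapply(chems, function(ch) {
    d <- unique(derived[[ch]] %||% character(0))
    r <- unique(reference[[ch]] %||% character(0))
    tibble::tibble(chemical = ch, n_derived = length(d),
                   n_reference = length(r),
                   n_intersection = length(intersect(d, r)))
  }))
  tissues <- sort(unique(c(unlist(derived), unlist(reference))))
  per_tissue <- dplyr::bind_rows(lapply(tissues, function(ts) {
    d <- names(derived)[vapply(derived, function(v) ts %in% v, logical(1))]
    r <- names(reference)[vapply(reference, function(v) ts %in% v,
                                 logical(1))]
    tibble::tibble(
      tissue = ts,
      only_derived = list(sort(setdiff(d, r))),
      only_reference = list(sort(setdiff(r, d))),
      both = list(sort(intersect(d, r))),
      n_only_derived = length(setdiff(d, r)),
      n_only_reference = length(setdiff(r, d)),
      n_both = length(intersect(d, r))
    )
  }))
  list(per_chemical = per_chemical, per_tissue = per_tissue)
}
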
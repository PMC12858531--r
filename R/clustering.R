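# Aggregate groups (or clusters) into clusters given a membership vector
# over rows. Chemical sets are unioned; key fields become set-valued
# list-columns, so the result can be re-clustered.
aggregate_clusters <- function(groups, membership) {
  stopifnot(length(membership) == nrow(groups))
  col <- function(nm) if (nm %in% names(groups)) groups[[nm]] else NULL
  get_set <- function(col_list, col_scalar) {
    if (!is.null(col_list)) col_list
    else if (!is.null(col_scalar)) as.list(col_scalar)
    else rep(list(character(0)), length(membership))
  }
  genes <- get_set(col("genes"), col("speciesgeneid"))
  phens <- get_set(col("phenotypes"), col("phenotypeid"))
  dis <- get_set(col("diseases"), col("diseaseid"))
  member_src <- col("member_groups") %||% as.list(col("group_id") %||%
    sprintf("group_%d", seq_len(nrow(groups))))
  idx <- split(seq_along(membership), membership)
  rows <- lapply(idx, function(i) {
    tibble::tibble(
      member_groups = list(sort(unique(unlist(member_src[i])))),
      chemicals = list(sort(unique(unlist(groups$chemicals[i])))),
      genes = list(sort(unique(unlist(genes[i])))),
      phenotypes = list(sort(unique(unlist(phens[i])))),
      diseases = list(sort(unique(unlist(dis[i])))),
      organismid = groups$organismid[i][1],
      tissue_group = groups$tissue_group[i][1]
    )
  })
  out <- dplyr::bind_rows(rows)
  out$n_groups <- lengths(out$member_groups)
  out$n_chemicals <- lengths(out$chemicals)
  out$n_phenotypes <- lengths(out$phenotypes)
  out$cluster_id <- sprintf("cluster_%03d", seq_len(nrow(out)))
  out
}

#' Merge chemical groups by phenotype similarity
#'
#' Groups whose phenotypes fall in the same similarity component (from
#' [threshold_components()] over a Lin similarity matrix) are merged iff
#' they additionally share a common gene AND disease (mode `"gpd"`) or a
#' common disease (mode `"pd"`). The merge constraint is evaluated
#' pairwise and closed transitively within a phenotype component
#' (connected components of the constraint graph). Groups whose
#' phenotype is absent from the similarity matrix (undefined IC) form
#' their own singleton components.
#'
#' @param groups Tibble from [group_gpd()] or [group_pd()].
#' @param components Output of [threshold_components()] on the phenotype
#'   similarity matrix.
#' @param mode `"gpd"` or `"pd"`, matching how `groups` was built.
#' @return Cluster tibble: `cluster_id`, list-columns `member_groups`,
#'   `chemicals`, `genes`, `phenotypes`, `diseases`, counts.
#' @export
merge_by_phenotype <- function(groups, components, mode = c("gpd", "pd")) {
  mode <- match.arg(mode)
  if (nrow(groups) == 0) return(aggregate_clusters(groups, integer(0)))
  comp_of <- components$membership
  pheno_comp <- unname(comp_of[groups$phenotypeid])
  # unmatched phenotypes -> unique negative component ids (singletons)
  miss <- is.na(pheno_comp)
  pheno_comp[miss] <- -seq_len(sum(miss))

  n <- nrow(groups)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    ok <- logical(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (pheno_comp[i] != pheno_comp[j]) next
      share_d <- groups$diseaseid[i] == groups$diseaseid[j]
      if (mode == "gpd") {
        ok[k] <- share_d &&
          groups$speciesgeneid[i] == groups$speciesgeneid[j]
      } else {
        ok[k] <- share_d
      }
    }
    if (any(ok)) {
      g <- igraph::add_edges(g, as.vector(pairs[, ok, drop = FALSE]))
    }
  }
  membership <- igraph::components(g)$membership
  aggregate_clusters(groups, membership)
}

#' Cluster groups by Tanimoto similarity of their chemical lists
#'
#' Builds the pairwise Tanimoto matrix over member chemical sets,
#' thresholds it ([threshold_components()]) and merges each connected
#' component into one cluster. Accepts either raw groups or clusters
#' from [merge_by_phenotype()], so both clustering routes compose.
#'
#' @param x Tibble with a `chemicals` list-column (groups or clusters).
#' @param threshold Numeric in `[0, 1]`.
#' @return Cluster tibble as in [merge_by_phenotype()].
#' @export
cluster_by_chemicals <- function(x, threshold) {
  if (nrow(x) == 0) return(aggregate_clusters(x, integer(0)))
  sets <- x$chemicals
  names(sets) <- sprintf("row_%d", seq_along(sets))
  comp <- threshold_components(tanimoto_matrix(sets), threshold)
  aggregate_clusters(x, unname(comp$membership))
}

#' Enumerate the run-configuration grid
#'
#' The full evaluation grid crosses the evidence presets with the two
#' grouping strategies and the clustering options; clustering options
#' are phenotype-only (one per threshold), chemical-only (one per
#' threshold) and both combined (each threshold pair). With 5 presets,
#' 2 groupings and thresholds {0.5, 0.75, 0.9} this yields
#' 5 x 2 x (3 + 3 + 9) = 150 configurations per organism.
#'
#' @param presets Character vector of evidence presets.
#' @param groupings Character vector over `"gpd"`, `"pd"`.
#' @param thresholds Numeric vector of clustering thresholds.
#' @return Tibble with columns `preset`, `grouping`, `pheno_threshold`,
#'   `chem_threshold` (NA where a clustering route is unused).
#' @export
enumerate_configs <- function(presets = paste0("v", 1:5),
                              groupings = c("gpd", "pd"),
                              thresholds = c(0.5, 0.75, 0.9)) {
  if (length(thresholds) == 0) {
    stop("at least one clustering threshold is required", call. = FALSE)
  }
  stopifnot(all(thresholds >= 0 & thresholds <= 1),
            length(presets) > 0, length(groupings) > 0)
  opts <- dplyr::bind_rows(
    tibble::tibble(pheno_threshold = thresholds, chem_threshold = NA_real_),
    tibble::tibble(pheno_threshold = NA_real_, chem_threshold = thresholds),
    tidyr::expand_grid(pheno_threshold = thresholds,
                       chem_threshold = thresholds)
  )
  out <- tidyr::expand_grid(preset = presets, grouping = groupings,
                            opts)
  tibble::as_tibble(out)
}

#' Write clusters as JSON and a TSV summary
#'
#' @param clusters Cluster tibble.
#' @param path_json,path_tsv Output paths (`NULL` to skip either).
#' @return `clusters`, invisibly.
#' @export
write_clusters <- function(clusters, path_json = NULL, path_tsv = NULL) {
  if (!is.null(path_json)) {
    jsonlite::write_json(clusters, path_json, auto_unbox = FALSE,
                         digits = NA)
  }
  if (!is.null(path_tsv)) {
    smry <- tibble::tibble(
      cluster_id = clusters$cluster_id,
      n_groups = clusters$n_groups,
      n_chemicals = clusters$n_chemicals,
      n_phenotypes = clusters$n_phenotypes,
      n_genes = lengths(clusters$genes)
    )
    utils::write.table(smry, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(clusters)
}
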
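#' Read a YAML run configuration
#'
#' @param path YAML file. Recognized keys: `input_dir` (directory with
#'   the CTD-dialect files, gene2go, gene_orthologs, gene_info,
#'   ontology.obo, chemical_descriptions/identifiers), `store`
#'   (SQLite path), `out_dir`, `organisms`, `tissue_groups`, `presets`,
#'   `groupings`, `pheno_thresholds`, `chem_thresholds`,
#'   `anatomy_map`/`disease_map` (optional tissue-map overrides),
#'   `seed`.
#' @return The configuration as a named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  cfg$organisms <- as.integer(cfg$organisms %||% c(9606L, 10090L, 10116L))
  cfg$tissue_groups <- cfg$tissue_groups %||% "all"
  cfg$presets <- cfg$presets %||% paste0("v", 1:5)
  cfg$groupings <- cfg$groupings %||% c("gpd", "pd")
  cfg$pheno_thresholds <- cfg$pheno_thresholds %||% numeric(0)
  cfg$chem_thresholds <- cfg$chem_thresholds %||% numeric(0)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  thr <- c(cfg$pheno_thresholds, cfg$chem_thresholds)
  if (length(thr) == 0) {
    stop("config error: at least one clustering threshold ",
         "(pheno_thresholds or chem_thresholds) is required",
         call. = FALSE)
  }
  if (any(thr < 0 | thr > 1)) {
    stop("config error: thresholds must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$groupings) == 0 ||
      !all(cfg$groupings %in% c("gpd", "pd"))) {
    stop("config error: groupings must be a non-empty subset of ",
         "{gpd, pd}", call. = FALSE)
  }
  if (!all(cfg$presets %in% paste0("v", 1:5))) {
    stop("config error: presets must be among v1..v5", call. = FALSE)
  }
  cfg
}

run_config_tmap <- function(cfg) {
  if (!is.null(cfg$anatomy_map) || !is.null(cfg$disease_map)) {
    tissue_group_map(cfg$anatomy_map, cfg$disease_map)
  } else {
    tissue_group_map()
  }
}

#' Ingest local dumps and build the relational store
#'
#' The local-file counterpart of the tool's download step: loads the 16
#' CTD-dialect tables plus the two compound tables from `input_dir`,
#' normalizes them (lowercase headers, MeSH prefix stripping,
#' deduplication), remaps chemical-gene primary gene IDs to
#' species-specific IDs via the ortholog table, and writes the SQLite
#' store. Rerunning on the same inputs produces an identical store.
#'
#' @param cfg Configuration list (see [read_run_config()]) or a YAML
#'   path; `input_dir` and `store` are required.
#' @return The store path, invisibly; logs per-table sizes.
#' @export
run_download <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (is.null(cfg$input_dir) || !dir.exists(cfg$input_dir)) {
    stop("config error: input_dir missing or not a directory",
         call. = FALSE)
  }
  if (is.null(cfg$store)) stop("config error: store path required",
                               call. = FALSE)
  find_file <- function(name) {
    for (cand in file.path(cfg$input_dir, c(name, paste0(name, ".gz")))) {
      if (file.exists(cand)) return(cand)
    }
    stop("config error: required input '", name, "' not found in ",
         cfg$input_dir, call. = FALSE)
  }
  kinds <- c(ctd_chem_gene_ixns = "chem_gene",
             ctd_pheno_term_ixns = "chem_pheno",
             ctd_chemicals_diseases = "chem_disease",
             ctd_genes_diseases = "gene_disease",
             ctd_chemicals = "chemicals")
  tables <- lapply(stats::setNames(ctd_store_tables, ctd_store_tables),
                   function(nm) {
    kind <- if (nm %in% names(kinds)) kinds[[nm]] else "generic"
    load_ctd_table(find_file(paste0(nm, ".tsv")), kind)
  })
  orthologs <- load_ctd_table(find_file("gene_orthologs.tsv"),
                              "gene_orthologs")
  gene_info <- load_ctd_table(find_file("gene_info.tsv"), "gene_info")
  tables$ctd_chem_gene_ixns <- remap_gene_ids(
    tables$ctd_chem_gene_ixns, orthologs, gene_info)
  descriptions <- load_ctd_table(find_file("chemical_descriptions.tsv"))
  identifiers <- load_ctd_table(find_file("chemical_identifiers.tsv"))
  build_store(tables, descriptions, identifiers, cfg$store)
  counts <- store_counts(cfg$store)
  message("store built at ", cfg$store, " (",
          paste(names(counts), counts, sep = "=", collapse = ", "), ")")
  invisible(cfg$store)
}

#' Run grouping and clustering over a configuration grid
#'
#' For every organism x tissue group x (preset, grouping, clustering
#' option) combination, assembles CGPD tetramers, forms chemical groups,
#' clusters them by phenotype semantic similarity and/or Tanimoto
#' similarity of chemical lists, and writes tetramer/group/cluster
#' tables plus a JSON run manifest with the resolved configuration and
#' all counts. An empty tetramer set yields valid empty outputs and a
#' warning in the manifest.
#'
#' @param cfg Configuration list or YAML path. Requires `store` (or
#'   `input_dir` to read the dumps directly), `ontology` (OBO path,
#'   defaults to `input_dir/ontology.obo`), `gene2go` (defaults to
#'   `input_dir/gene2go.tsv`) and `out_dir`.
#' @return The run manifest (list), invisibly; files under `out_dir`.
#' @export
run_grouping <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- validate_run_config(cfg)
  if (is.null(cfg$out_dir)) stop("config error: out_dir required",
                                 call. = FALSE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  tmap <- run_config_tmap(cfg)

  if (!is.null(cfg$store) && file.exists(cfg$store)) {
    cg <- read_store_table(cfg$store, "ctd_chem_gene_ixns")
    cp <- read_store_table(cfg$store, "ctd_pheno_term_ixns")
    cd <- read_store_table(cfg$store, "ctd_chemicals_diseases")
    gd <- read_store_table(cfg$store, "ctd_genes_diseases")
  } else if (!is.null(cfg$input_dir)) {
    tabs <- load_fixture_tables(cfg$input_dir)
    cg <- tabs$cg; cp <- tabs$cp; cd <- tabs$cd; gd <- tabs$gd
  } else {
    stop("config error: either store or input_dir required",
         call. = FALSE)
  }
  gp_path <- cfg$gene2go %||% file.path(cfg$input_dir %||% "", "gene2go.tsv")
  obo_path <- cfg$ontology %||% file.path(cfg$input_dir %||% "",
                                          "ontology.obo")
  gp <- load_ctd_table(gp_path, "gene2go")
  dag <- compute_ic(read_obo(obo_path), gp)
  tables <- list(cg = cg, cp = cp, cd = cd, gd = gd, gp = gp)

  grid <- enumerate_configs(
    presets = cfg$presets, groupings = cfg$groupings,
    thresholds = sort(unique(c(cfg$pheno_thresholds,
                               cfg$chem_thresholds))))
  grid <- grid[
    (is.na(grid$pheno_threshold) |
       grid$pheno_threshold %in% cfg$pheno_thresholds) &
    (is.na(grid$chem_threshold) |
       grid$chem_threshold %in% cfg$chem_thresholds), , drop = FALSE]

  runs <- list()
  for (org in cfg$organisms) {
    for (tg in cfg$tissue_groups) {
      tet_cache <- list()
      for (r in seq_len(nrow(grid))) {
        row <- grid[r, ]
        fc <- filter_config(org, tg, row$preset)
        key <- row$preset
        if (is.null(tet_cache[[key]])) {
          tet_cache[[key]] <- cgpd_tetramers(tables, fc, tmap)
        }
        tets <- tet_cache[[key]]
        groups <- if (row$grouping == "gpd") group_gpd(tets)
                  else group_pd(tets)
        clusters <- groups
        if (!is.na(row$pheno_threshold) && nrow(groups) > 0) {
          simm <- lin_sim_matrix(unique(groups$phenotypeid), dag)
          comp <- threshold_components(simm, row$pheno_threshold)
          clusters <- merge_by_phenotype(groups, comp, row$grouping)
        }
        if (!is.na(row$chem_threshold) && nrow(clusters) > 0) {
          clusters <- cluster_by_chemicals(clusters, row$chem_threshold)
        }
        tag <- sprintf("org%s_%s_%s_%s_p%s_c%s", org, tg, row$preset,
                       row$grouping,
                       ifelse(is.na(row$pheno_threshold), "NA",
                              row$pheno_threshold),
                       ifelse(is.na(row$chem_threshold), "NA",
                              row$chem_threshold))
        write_tetramers(tets, file.path(cfg$out_dir,
                                        paste0(tag, "_tetramers.tsv")))
        write_groups(groups, file.path(cfg$out_dir,
                                       paste0(tag, "_groups.tsv")))
        write_clusters(clusters,
                       path_tsv = file.path(cfg$out_dir,
                                            paste0(tag, "_clusters.tsv")))
        if (nrow(tets) == 0) {
          warning("empty tetramer set for ", tag, call. = FALSE)
        }
        runs[[tag]] <- list(
          organism = org, tissue_group = tg, preset = row$preset,
          grouping = row$grouping,
          pheno_threshold = row$pheno_threshold,
          chem_threshold = row$chem_threshold,
          n_tetramers = nrow(tets), n_groups = nrow(groups),
          n_clusters = nrow(clusters))
      }
    }
  }
  manifest <- list(config = cfg, n_runs = length(runs), runs = runs)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
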
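#' Step 1: initial chemical set from chemical-phenotype interactions
#'
#' Retains chemical-phenotype records curated for the configured organism
#' and, when a specific tissue group is requested, whose anatomy terms
#' map into that group. Returns the distinct chemicals, the union of
#' their PubMed IDs (used downstream for indirect tissue filtering of
#' chemical-gene records), and the retained table itself.
#'
#' @param cp Chemical-phenotype tibble (kind `chem_pheno`).
#' @param cfg A [filter_config()].
#' @param tmap A [tissue_group_map()].
#' @return List with `chemicals`, `pubmeds`, `cp` (retained records).
#' @export
select_chemicals <- function(cp, cfg, tmap) {
  keep <- cp$organismid == cfg$organism_taxon
  if (cfg$tissue_group != "all") {
    in_tissue <- vapply(split_set(cp$anatomyterms), function(terms) {
      cfg$tissue_group %in% anatomy_groups(terms, tmap)
    }, logical(1))
    keep <- keep & in_tissue
  }
  retained <- cp[keep, , drop = FALSE]
  list(
    chemicals = unique(retained$chemicalid),
    pubmeds = set_union(retained$pubmedids),
    cp = retained
  )
}

#' Step 2: chemical-gene interactions for the selected chemicals
#'
#' Chemical-gene records lack anatomy terms; when tissue filtering is
#' active their PubMed IDs must intersect those collected in Step 1,
#' which ties the interaction to a publication reporting a phenotype in
#' the requested tissue. A record with no PubMed IDs fails an active
#' intersection filter.
#'
#' @param cg Remapped chemical-gene tibble (must carry `speciesgeneid`).
#' @param chemicals,pubmeds Step 1 output.
#' @param cfg A [filter_config()].
#' @return Retained chemical-gene tibble.
#' @export
collect_cg <- function(cg, chemicals, pubmeds, cfg) {
  stopifnot("speciesgeneid" %in% names(cg))
  keep <- cg$chemicalid %in% chemicals &
    cg$organismid == cfg$organism_taxon
  if (cfg$tissue_group != "all") {
    keep <- keep & set_intersects(cg$pubmedids, pubmeds)
  }
  cg[keep, , drop = FALSE]
}

#' Steps 3-4: disease edges under evidence, tissue and species filters
#'
#' Chemical-disease and gene-disease associations carry no organism or
#' anatomy annotation. Evidence filtering keeps records whose direct-
#' evidence class is allowed by the preset (rows with several labels pass
#' if any is allowed; unlabelled rows are `inferred`). The disease tissue
#' filter requires [disease_groups()] of the disease to contain the
#' configured tissue group (unmapped diseases default to all groups and
#' always pass). The disease species filter cross-references PubMed IDs
#' with chemical-gene interactions curated for the configured organism.
#'
#' @param cd,gd Chemical-disease / gene-disease tibbles.
#' @param cfg A [filter_config()].
#' @param tmap A [tissue_group_map()].
#' @param organism_cg_pubmeds PubMed IDs of all chemical-gene records
#'   curated for `cfg$organism_taxon` (whole table, not the Step 2
#'   subset).
#' @param chemicals,genes Restrict to chemicals from Step 1 and primary
#'   gene IDs seen in Step 2 (`NULL` = no restriction).
#' @return List with filtered `cd` and `gd` tibbles.
#' @export
collect_disease_edges <- function(cd, gd, cfg, tmap, organism_cg_pubmeds,
                                  chemicals = NULL, genes = NULL) {
  filter_one <- function(tbl) {
    keep <- vapply(split_set(tbl$evidence), function(ev) {
      any(ev %in% cfg$allowed_evidence) ||
        (length(ev) == 1 && ev == "inferred" &&
           "inferred" %in% cfg$allowed_evidence)
    }, logical(1))
    if (cfg$disease_tissue_filter && cfg$tissue_group != "all") {
      in_tissue <- vapply(tbl$diseaseid, function(d) {
        cfg$tissue_group %in% disease_groups(d, tmap)
      }, logical(1))
      keep <- keep & in_tissue
    }
    if (cfg$disease_species_filter) {
      keep <- keep & set_intersects(tbl$pubmedids, organism_cg_pubmeds)
    }
    tbl[keep, , drop = FALSE]
  }
  if (!is.null(chemicals)) cd <- cd[cd$chemicalid %in% chemicals, ,
                                    drop = FALSE]
  if (!is.null(genes)) gd <- gd[gd$geneid %in% genes, , drop = FALSE]
  list(cd = filter_one(cd), gd = filter_one(gd))
}

#' Step 5: chemical-gene-disease triplets
#'
#' A pure three-way join: one triplet per (chemical, gene, disease) for
#' which a chemical-gene, a chemical-disease and a gene-disease edge all
#' survived their filters. Gene-disease edges are joined on the primary
#' Entrez ID (the identifier CTD uses in that table); the species-
#' specific gene ID from the remapping travels along for Steps 6-7.
#' PubMed IDs supporting each edge are merged per triplet.
#'
#' @param cg,cd,gd Filtered tables from the previous steps.
#' @return Tibble of triplets with per-edge PubMed columns.
#' @export
build_triplets <- function(cg, cd, gd) {
  cg_k <- dplyr::summarise(
    dplyr::group_by(cg, .data$chemicalid, .data$geneid, .data$speciesgeneid),
    cg_pubmeds = join_set(set_union(.data$pubmedids)), .groups = "drop")
  cd_k <- dplyr::summarise(
    dplyr::group_by(cd, .data$chemicalid, .data$diseaseid),
    cd_pubmeds = join_set(set_union(.data$pubmedids)), .groups = "drop")
  gd_k <- dplyr::summarise(
    dplyr::group_by(gd, .data$geneid, .data$diseaseid),
    gd_pubmeds = join_set(set_union(.data$pubmedids)), .groups = "drop")
  out <- dplyr::inner_join(cg_k, cd_k, by = "chemicalid",
                           relationship = "many-to-many")
  out <- dplyr::inner_join(out, gd_k, by = c("geneid", "diseaseid"))
  dplyr::distinct(out)
}

#' Steps 6-7: attach phenotypes and assemble tetramers
#'
#' Gene-phenotype annotations (gene2go format, species-specific Entrez
#' IDs) are restricted to genes present in the triplets; a phenotype is
#' attached to a triplet only if it is linked to both the chemical (a
#' retained chemical-phenotype record) and the gene (a gene2go record).
#' The output is deduplicated on (chemical, gene, phenotype, disease)
#' with PubMed unions merged, and carries the five evidence statements of
#' every tetramer: C-G, C-P, C-D, G-D PubMed support plus the G-P
#' annotation evidence code.
#'
#' @param triplets Output of [build_triplets()].
#' @param cp_retained Retained chemical-phenotype records from Step 1.
#' @param gp gene2go tibble (`tax_id`, `geneid`, `go_id`, `evidence`).
#' @param cfg A [filter_config()].
#' @return Tibble of tetramers; one row per (C, G, P, D).
#' @export
assemble_tetramers <- function(triplets, cp_retained, gp, cfg) {
  empty <- tibble::tibble(
    chemicalid = character(0), speciesgeneid = integer(0),
    phenotypeid = character(0), diseaseid = character(0),
    organismid = integer(0), tissue_group = character(0),
    cg_pubmeds = character(0), cp_pubmeds = character(0),
    cd_pubmeds = character(0), gd_pubmeds = character(0),
    gp_evidence = character(0)
  )
  if (nrow(triplets) == 0) return(empty)
  gp_use <- gp[gp$tax_id == cfg$organism_taxon &
                 gp$geneid %in% triplets$speciesgeneid, , drop = FALSE]
  gp_k <- dplyr::summarise(
    dplyr::group_by(gp_use, speciesgeneid = .data$geneid,
                    phenotypeid = .data$go_id),
    gp_evidence = join_set(.data$evidence), .groups = "drop")
  cp_k <- dplyr::summarise(
    dplyr::group_by(cp_retained, .data$chemicalid,
                    .data$phenotypeid),
    cp_pubmeds = join_set(set_union(.data$pubmedids)), .groups = "drop")
  out <- dplyr::inner_join(triplets, cp_k, by = "chemicalid",
                           relationship = "many-to-many")
  out <- dplyr::inner_join(out, gp_k, by = c("speciesgeneid", "phenotypeid"))
  if (nrow(out) == 0) return(empty)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$chemicalid, .data$speciesgeneid,
                    .data$phenotypeid, .data$diseaseid),
    cg_pubmeds = join_set(set_union(.data$cg_pubmeds)),
    cp_pubmeds = join_set(set_union(.data$cp_pubmeds)),
    cd_pubmeds = join_set(set_union(.data$cd_pubmeds)),
    gd_pubmeds = join_set(set_union(.data$gd_pubmeds)),
    gp_evidence = join_set(set_union(.data$gp_evidence)),
    .groups = "drop")
  out$organismid <- cfg$organism_taxon
  out$tissue_group <- cfg$tissue_group
  out[, names(empty)]
}

#' Assemble CGPD tetramers for one organism and tissue group
#'
#' Runs the full Step 1-7 workflow: select chemicals from chemical-
#' phenotype interactions, collect chemical-gene interactions, filter
#' chemical-disease and gene-disease edges by evidence/tissue/species,
#' join into chemical-gene-disease triplets, and attach phenotypes
#' linked to both chemical and gene.
#'
#' @param tables Named list with tibbles `cg` (remapped chemical-gene),
#'   `cp`, `cd`, `gd`, `gp` (gene2go).
#' @param cfg A [filter_config()].
#' @param tmap A [tissue_group_map()].
#' @return Tetramer tibble (see [assemble_tetramers()]).
#' @examples
#' \dontrun{
#' fx <- generate_fixtures(fixture_spec(seed = 1), tempdir())
#' tabs <- load_fixture_tables(fx$dir)
#' cfg <- filter_config(10116, "all", "v1")
#' cgpd_tetramers(tabs, cfg, tissue_group_map())
#' }
#' @export
cgpd_tetramers <- function(tables, cfg, tmap) {
  step1 <- select_chemicals(tables$cp, cfg, tmap)
  cg <- collect_cg(tables$cg, step1$chemicals, step1$pubmeds, cfg)
  organism_cg_pubmeds <- set_union(
    tables$cg$pubmedids[tables$cg$organismid == cfg$organism_taxon])
  edges <- collect_disease_edges(
    tables$cd, tables$gd, cfg, tmap, organism_cg_pubmeds,
    chemicals = step1$chemicals, genes = unique(cg$geneid))
  triplets <- build_triplets(cg, edges$cd, edges$gd)
  assemble_tetramers(triplets, step1$cp, tables$gp, cfg)
}

#' Write tetramers as TSV and JSON-lines
#'
#' @param tetramers Tibble from [cgpd_tetramers()].
#' @param path_tsv,path_jsonl Output paths (`NULL` to skip either).
#' @return `tetramers`, invisibly.
#' @export
write_tetramers <- function(tetramers, path_tsv = NULL, path_jsonl = NULL) {
  if (!is.null(path_tsv)) {
    utils::write.table(tetramers, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(path_jsonl)) {
    con <- file(path_jsonl, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(tetramers))) {
      row <- as.list(tetramers[i, ])
      row$provenance <- list(
        chem_gene = row$cg_pubmeds, chem_phenotype = row$cp_pubmeds,
        chem_disease = row$cd_pubmeds, gene_disease = row$gd_pubmeds,
        gene_phenotype = row$gp_evidence)
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE), con)
    }
  }
  invisible(tetramers)
}
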
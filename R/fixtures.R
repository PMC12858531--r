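#' Specification for a synthetic CTD-format fixture set
#'
#' The generator plants disjoint evidence blocks: block `b` ties a set
#' of chemicals to a set of genes, one phenotype family (sibling leaf
#' terms under a family node of a toy GO DAG) and one disease, all
#' curated for one organism and supported by one block-level PubMed ID
#' shared across the C-G, C-P, C-D and G-D rows (so the species and
#' tissue cross-reference filters pass by construction). Blocks are
#' pairwise disjoint in chemicals, genes and diseases, which makes the
#' expected tetramers, groups and clusters derivable in closed form.
#' Noise edges draw from disjoint noise-chemical/noise-disease pools and
#' can therefore never complete a tetramer.
#'
#' @param n_blocks Number of planted blocks (default 3, one per default
#'   organism, round-robin).
#' @param chemicals_per_block,genes_per_block Block sizes.
#' @param n_phenotype_families Number of leaf families in the toy DAG;
#'   blocks take families round-robin.
#' @param leaves_per_family Sibling leaves per family.
#' @param dag_depth Root-to-leaf depth of the toy DAG (>= 3: root,
#'   family chain, leaves).
#' @param organisms NCBI taxa; blocks take organisms round-robin.
#' @param evidence_mix Fraction of blocks whose disease edges are
#'   labelled `therapeutic` instead of `marker/mechanism` (those blocks
#'   drop out of preset v1 but stay in v2-v5).
#' @param noise_edges Number of decoy rows spread over the four
#'   interaction tables.
#' @param seed Integer; fully determines the output.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_blocks = 3, chemicals_per_block = 3,
                         genes_per_block = 2, n_phenotype_families = n_blocks,
                         leaves_per_family = 2, dag_depth = 3,
                         organisms = c(9606L, 10090L, 10116L),
                         evidence_mix = 0, noise_edges = 0, seed = 1L) {
  stopifnot(n_blocks >= 1, chemicals_per_block >= 1, genes_per_block >= 1,
            n_phenotype_families >= 1, leaves_per_family >= 2,
            dag_depth >= 3, length(organisms) >= 1,
            evidence_mix >= 0, evidence_mix <= 1, noise_edges >= 0)
  out <- list(n_blocks = as.integer(n_blocks),
              chemicals_per_block = as.integer(chemicals_per_block),
              genes_per_block = as.integer(genes_per_block),
              n_phenotype_families = as.integer(n_phenotype_families),
              leaves_per_family = as.integer(leaves_per_family),
              dag_depth = as.integer(dag_depth),
              organisms = as.integer(organisms),
              evidence_mix = evidence_mix,
              noise_edges = as.integer(noise_edges),
              seed = as.integer(seed))
  class(out) <- "fixture_spec"
  out
}

# deterministic identifier builders
fx_chem <- function(i) sprintf("C%06d", i)
fx_disease <- function(i) sprintf("D8%05d", i)
fx_noise_disease <- function(i) sprintf("D7%05d", i)
fx_leaf <- function(f, l) sprintf("GO:%07d", 200000L + f * 100L + l)
fx_family <- function(f) sprintf("GO:%07d", 100000L + f)
fx_chain <- function(f, d) sprintf("GO:%07d", 300000L + f * 10L + d)
fx_root <- "GO:0000001"

# closed-form planted blocks for a spec
fixture_blocks <- function(spec) {
  lapply(seq_len(spec$n_blocks), function(b) {
    org_i <- (b - 1L) %% length(spec$organisms) + 1L
    org <- spec$organisms[org_i]
    fam <- (b - 1L) %% spec$n_phenotype_families + 1L
    chem0 <- (b - 1L) * spec$chemicals_per_block
    gene0 <- (b - 1L) * spec$genes_per_block
    sgid <- as.integer(org_i * 100000L + gene0 + seq_len(spec$genes_per_block))
    # even-indexed genes of non-human blocks carry a human primary ID
    use_ortholog <- (seq_len(spec$genes_per_block) %% 2L == 0L) &
      org != 9606L & 9606L %in% spec$organisms
    primary <- ifelse(use_ortholog, sgid + 500000L, sgid)
    list(
      id = b, organism = org, family = fam,
      chemicals = fx_chem(chem0 + seq_len(spec$chemicals_per_block)),
      species_genes = sgid, primary_genes = as.integer(primary),
      use_ortholog = use_ortholog,
      leaves = fx_leaf(fam, seq_len(spec$leaves_per_family)),
      disease = fx_disease(b),
      pubmed = 700000L + b,
      anatomy = c("D008099", "D007668", "D001921")[(b - 1L) %% 3L + 1L]
    )
  })
}

# Lin similarity between two leaves of family f, from planted counts
planted_family_lin <- function(spec) {
  blocks <- fixture_blocks(spec)
  leaf_count <- stats::setNames(
    numeric(spec$n_phenotype_families * spec$leaves_per_family),
    unlist(lapply(seq_len(spec$n_phenotype_families), function(f)
      fx_leaf(f, seq_len(spec$leaves_per_family)))))
  for (b in blocks) {
    leaf_count[b$leaves] <- leaf_count[b$leaves] + length(b$species_genes)
  }
  total <- sum(leaf_count)
  vapply(seq_len(spec$n_phenotype_families), function(f) {
    c12 <- leaf_count[fx_leaf(f, 1:2)]
    c_fam <- sum(leaf_count[fx_leaf(f, seq_len(spec$leaves_per_family))])
    if (any(c12 == 0)) return(NA_real_)
    2 * log(total / c_fam) / sum(log(total / c12))
  }, numeric(1))
}

write_ctd_file <- function(df, header, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(header, collapse = "\t")), con)
  if (nrow(df) > 0) {
    lines <- do.call(paste, c(unname(as.list(df)), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Generate a CTD-format fixture set with planted structure
#'
#' Writes the 16 CTD-dialect TSVs (four populated interaction tables,
#' the chemical vocabulary, and header-only files for the rest), a toy
#' OBO ontology with one subtree per phenotype family, gene2go-format
#' annotations, an NCBI gene_orthologs file, a gene-info taxon lookup,
#' the two compound tables, and a JSON ground-truth manifest listing
#' every expected tetramer, GPD/PD group and planted cluster. Chemical
#' and disease IDs are written with their `MESH:` prefix, as in real
#' dumps. Output is byte-identical for a fixed seed.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return List with `dir`, `files` and the `manifest` (also written to
#'   `manifest.json`).
#' @export
generate_fixtures <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  lin <- planted_family_lin(spec)
  if (any(!is.na(lin) & lin <= 0.5)) {
    stop("phenotype families too shallow to separate at threshold 0.5 ",
         "(within-family Lin = ",
         paste(round(lin, 3), collapse = ", "),
         "); add families or reduce leaves per family", call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- fixture_blocks(spec)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  therapeutic_block <- stats::runif(spec$n_blocks) < spec$evidence_mix

  mesh <- function(x) paste0("MESH:", x)
  cg <- cp <- cd <- gd <- list()
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    ev <- if (therapeutic_block[i]) "therapeutic" else "marker/mechanism"
    grid_cg <- expand.grid(chem = b$chemicals, g = seq_along(b$species_genes),
                           stringsAsFactors = FALSE)
    cg[[i]] <- data.frame(
      chemicalname = paste("chemical", grid_cg$chem),
      chemicalid = mesh(grid_cg$chem),
      geneid = b$primary_genes[grid_cg$g],
      organismid = b$organism,
      pubmedids = b$pubmed,
      interactionactions = "increases^expression",
      stringsAsFactors = FALSE)
    grid_cp <- expand.grid(chem = b$chemicals, p = b$leaves,
                           stringsAsFactors = FALSE)
    cp[[i]] <- data.frame(
      chemicalname = paste("chemical", grid_cp$chem),
      chemicalid = mesh(grid_cp$chem),
      phenotypeid = grid_cp$p,
      organismid = b$organism,
      anatomyterms = mesh(b$anatomy),
      pubmedids = b$pubmed,
      stringsAsFactors = FALSE)
    cd[[i]] <- data.frame(
      chemicalname = paste("chemical", b$chemicals),
      chemicalid = mesh(b$chemicals),
      diseaseid = mesh(b$disease),
      directevidence = ev,
      pubmedids = b$pubmed,
      stringsAsFactors = FALSE)
    gd[[i]] <- data.frame(
      geneid = b$primary_genes,
      diseaseid = mesh(b$disease),
      directevidence = ev,
      pubmedids = b$pubmed,
      stringsAsFactors = FALSE)
  }
  cg <- dplyr::bind_rows(cg); cp <- dplyr::bind_rows(cp)
  cd <- dplyr::bind_rows(cd); gd <- dplyr::bind_rows(gd)

  # noise edges over disjoint pools; round-robin over the four tables
  if (spec$noise_edges > 0) {
    all_genes <- unlist(lapply(blocks, `[[`, "primary_genes"))
    all_leaves <- unique(unlist(lapply(blocks, `[[`, "leaves")))
    for (k in seq_len(spec$noise_edges)) {
      org <- spec$organisms[sample.int(length(spec$organisms), 1)]
      pm <- 800000L + k
      nc <- fx_chem(900000L + k)
      switch((k - 1L) %% 4L + 1L,
        { cg <- dplyr::bind_rows(cg, data.frame(
            chemicalname = paste("noise chemical", nc),
            chemicalid = mesh(nc),
            geneid = all_genes[sample.int(length(all_genes), 1)],
            organismid = org, pubmedids = pm,
            interactionactions = "decreases^expression")) },
        { cp <- dplyr::bind_rows(cp, data.frame(
            chemicalname = paste("noise chemical", nc),
            chemicalid = mesh(nc),
            phenotypeid = all_leaves[sample.int(length(all_leaves), 1)],
            organismid = org, anatomyterms = "",
            pubmedids = pm)) },
        { cd <- dplyr::bind_rows(cd, data.frame(
            chemicalname = paste("noise chemical", nc),
            chemicalid = mesh(nc),
            diseaseid = mesh(fx_noise_disease(k)),
            directevidence = "marker/mechanism", pubmedids = pm)) },
        { gd <- dplyr::bind_rows(gd, data.frame(
            geneid = all_genes[sample.int(length(all_genes), 1)],
            diseaseid = mesh(fx_noise_disease(100000L + k)),
            directevidence = "marker/mechanism", pubmedids = pm)) }
      )
    }
  }

  # auxiliary gene files
  orth <- gi <- list()
  for (b in blocks) {
    gi[[length(gi) + 1]] <- data.frame(tax_id = b$organism,
                                       geneid = b$species_genes)
    if (any(b$use_ortholog)) {
      h <- b$primary_genes[b$use_ortholog]
      s <- b$species_genes[b$use_ortholog]
      gi[[length(gi) + 1]] <- data.frame(tax_id = 9606L, geneid = h)
      orth[[length(orth) + 1]] <- data.frame(
        tax_id = 9606L, geneid = h, relationship = "Ortholog",
        other_tax_id = b$organism, other_geneid = s)
    }
  }
  gene_info <- dplyr::distinct(dplyr::bind_rows(gi))
  gene_orthologs <- if (length(orth) > 0) {
    dplyr::distinct(dplyr::bind_rows(orth))
  } else {
    data.frame(tax_id = integer(0), geneid = integer(0),
               relationship = character(0), other_tax_id = integer(0),
               other_geneid = integer(0))
  }

  gene2go <- dplyr::bind_rows(lapply(blocks, function(b) {
    grid <- expand.grid(g = b$species_genes, p = b$leaves,
                        stringsAsFactors = FALSE)
    data.frame(tax_id = b$organism, geneid = grid$g, go_id = grid$p,
               evidence = "IEA", stringsAsFactors = FALSE)
  }))

  # toy OBO: root -> (chain nodes) -> family -> leaves, one namespace
  obo <- c("format-version: 1.2", "",
           "[Term]", paste0("id: ", fx_root), "name: biological_process",
           "namespace: biological_process", "")
  for (f in seq_len(spec$n_phenotype_families)) {
    chain_len <- spec$dag_depth - 3L
    above <- fx_root
    for (d in seq_len(chain_len)) {
      node <- fx_chain(f, d)
      obo <- c(obo, "[Term]", paste0("id: ", node),
               paste0("name: chain ", f, ".", d),
               "namespace: biological_process",
               paste0("is_a: ", above), "")
      above <- node
    }
    obo <- c(obo, "[Term]", paste0("id: ", fx_family(f)),
             paste0("name: phenotype family ", f),
             "namespace: biological_process",
             paste0("is_a: ", above), "")
    for (l in seq_len(spec$leaves_per_family)) {
      obo <- c(obo, "[Term]", paste0("id: ", fx_leaf(f, l)),
               paste0("name: phenotype ", f, ".", l),
               "namespace: biological_process",
               paste0("is_a: ", fx_family(f)), "")
    }
  }

  # chemical vocabulary + compound tables
  all_chems <- sort(unique(sub("^MESH:", "", c(cg$chemicalid,
                                               cp$chemicalid))))
  chemicals <- data.frame(
    chemicalname = paste("chemical", all_chems),
    chemicalid = mesh(all_chems),
    parentids = "MESH:D900000",
    synonyms = paste0("syn-", tolower(all_chems)),
    stringsAsFactors = FALSE)
  descriptions <- data.frame(
    chemicalid = all_chems,
    cid = 10000L + seq_along(all_chems),
    molecularformula = "C6H6",
    stringsAsFactors = FALSE)
  identifiers <- data.frame(
    chemicalid = all_chems,
    cid = 10000L + seq_along(all_chems),
    registry = "CAS", registryid = sprintf("50-%02d-0",
                                           seq_along(all_chems) %% 100),
    stringsAsFactors = FALSE)

  files <- character(0)
  emit <- function(df, header, name) {
    p <- file.path(out_dir, name)
    write_ctd_file(df, header, p)
    files[[length(files) + 1]] <<- p
  }
  emit(cg, c("ChemicalName", "ChemicalID", "GeneID", "OrganismID",
             "PubMedIDs", "InteractionActions"), "ctd_chem_gene_ixns.tsv")
  emit(cp, c("ChemicalName", "ChemicalID", "PhenotypeID", "OrganismID",
             "AnatomyTerms", "PubMedIDs"), "ctd_pheno_term_ixns.tsv")
  emit(cd, c("ChemicalName", "ChemicalID", "DiseaseID", "DirectEvidence",
             "PubMedIDs"), "ctd_chemicals_diseases.tsv")
  emit(gd, c("GeneID", "DiseaseID", "DirectEvidence", "PubMedIDs"),
       "ctd_genes_diseases.tsv")
  emit(chemicals, c("ChemicalName", "ChemicalID", "ParentIDs", "Synonyms"),
       "ctd_chemicals.tsv")
  empty_tables <- setdiff(ctd_store_tables,
                          c("ctd_chem_gene_ixns", "ctd_pheno_term_ixns",
                            "ctd_chemicals_diseases", "ctd_genes_diseases",
                            "ctd_chemicals"))
  for (nm in empty_tables) {
    emit(data.frame(id = character(0), name = character(0)),
         c("ID", "Name"), paste0(nm, ".tsv"))
  }
  emit(gene2go, c("tax_id", "GeneID", "GO_ID", "Evidence"), "gene2go.tsv")
  emit(gene_orthologs, c("tax_id", "GeneID", "relationship",
                         "Other_tax_id", "Other_GeneID"),
       "gene_orthologs.tsv")
  emit(gene_info, c("tax_id", "GeneID"), "gene_info.tsv")
  emit(descriptions, c("ChemicalID", "CID", "MolecularFormula"),
       "chemical_descriptions.tsv")
  emit(identifiers, c("ChemicalID", "CID", "Registry", "RegistryID"),
       "chemical_identifiers.tsv")
  obo_path <- file.path(out_dir, "ontology.obo")
  writeLines(obo, obo_path)
  files <- c(files, obo_path)

  manifest <- fixture_manifest(spec, blocks, therapeutic_block)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(dir = out_dir, files = c(files, manifest_path),
       manifest = manifest)
}

# ground truth by construction: blocks are disjoint, so tetramers,
# groups and clusters factorize per block
fixture_manifest <- function(spec, blocks, therapeutic_block) {
  tet_rows <- function(b) {
    grid <- expand.grid(chemicalid = b$chemicals,
                        speciesgeneid = b$species_genes,
                        phenotypeid = b$leaves,
                        diseaseid = b$disease,
                        stringsAsFactors = FALSE)
    grid$organismid <- b$organism
    grid
  }
  empty_tets <- data.frame(chemicalid = character(0),
                           speciesgeneid = integer(0),
                           phenotypeid = character(0),
                           diseaseid = character(0),
                           organismid = integer(0))
  pad <- function(df, empty) if (nrow(df) == 0) empty else df
  per_org <- lapply(stats::setNames(spec$organisms,
                                    as.character(spec$organisms)),
                    function(org) {
    ob <- blocks[vapply(blocks, function(b) b$organism == org, logical(1))]
    ther <- therapeutic_block[vapply(blocks, function(b) b$organism == org,
                                     logical(1))]
    tets_all <- pad(dplyr::bind_rows(lapply(ob, tet_rows)), empty_tets)
    tets_v1 <- pad(dplyr::bind_rows(lapply(ob[!ther], tet_rows)),
                   empty_tets)
    empty_groups <- tibble::tibble(speciesgeneid = integer(0),
                                   phenotypeid = character(0),
                                   diseaseid = character(0),
                                   chemicals = list())
    gpd_groups <- function(bl) {
      if (length(bl) == 0) return(empty_groups)
      dplyr::bind_rows(lapply(bl, function(b) {
        grid <- expand.grid(speciesgeneid = b$species_genes,
                            phenotypeid = b$leaves,
                            diseaseid = b$disease,
                            stringsAsFactors = FALSE)
        grid$chemicals <- rep(list(sort(b$chemicals)), nrow(grid))
        grid
      }))
    }
    pd_groups <- function(bl) {
      if (length(bl) == 0) return(empty_groups[, -1])
      dplyr::bind_rows(lapply(bl, function(b) {
        grid <- expand.grid(phenotypeid = b$leaves, diseaseid = b$disease,
                            stringsAsFactors = FALSE)
        grid$chemicals <- rep(list(sort(b$chemicals)), nrow(grid))
        grid
      }))
    }
    clusters <- function(bl, per_gene) {
      out <- list()
      for (b in bl) {
        if (per_gene) {
          for (g in b$species_genes) out[[length(out) + 1]] <-
              sort(b$chemicals)
        } else {
          out[[length(out) + 1]] <- sort(b$chemicals)
        }
      }
      out
    }
    list(
      n_blocks = length(ob),
      tetramers_v1 = tets_v1,
      tetramers_v2plus = tets_all,
      gpd_groups_v1 = gpd_groups(ob[!ther]),
      pd_groups_v1 = pd_groups(ob[!ther]),
      gpd_groups_v2plus = gpd_groups(ob),
      pd_groups_v2plus = pd_groups(ob),
      gpd_pheno_clusters_v1 = clusters(ob[!ther], per_gene = TRUE),
      pd_pheno_clusters_v1 = clusters(ob[!ther], per_gene = FALSE),
      chem_clusters_v1 = clusters(ob[!ther], per_gene = FALSE)
    )
  })
  list(
    spec = unclass(spec),
    family_lin = planted_family_lin(spec),
    therapeutic_blocks = which(therapeutic_block),
    organisms = per_org
  )
}

#' Load the populated fixture tables for the tetramer pipeline
#'
#' Reads the four interaction tables plus gene2go, gene_orthologs and
#' gene_info from a fixture directory, remaps gene IDs and returns the
#' list expected by [cgpd_tetramers()].
#'
#' @param dir Directory written by [generate_fixtures()] (or any
#'   directory following the same layout).
#' @return Named list: `cg` (remapped), `cp`, `cd`, `gd`, `gp`,
#'   `chemicals`, plus `orthologs` and `gene_info`.
#' @export
load_fixture_tables <- function(dir) {
  f <- function(name, kind) load_ctd_table(file.path(dir, name), kind)
  cg_raw <- f("ctd_chem_gene_ixns.tsv", "chem_gene")
  orthologs <- f("gene_orthologs.tsv", "gene_orthologs")
  gene_info <- f("gene_info.tsv", "gene_info")
  list(
    cg = remap_gene_ids(cg_raw, orthologs, gene_info),
    cp = f("ctd_pheno_term_ixns.tsv", "chem_pheno"),
    cd = f("ctd_chemicals_diseases.tsv", "chem_disease"),
    gd = f("ctd_genes_diseases.tsv", "gene_disease"),
    gp = f("gene2go.tsv", "gene2go"),
    chemicals = f("ctd_chemicals.tsv", "chemicals"),
    orthologs = orthologs,
    gene_info = gene_info
  )
}
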
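# Independent oracles and small in-code fixtures.
#
# oracle_tetramers() is a literal five-table nested-loop join that
# re-states the filtering semantics row by row; it shares no code with
# the package's join pipeline.

oracle_tetramers <- function(tabs, org, preset, tissue, tmap) {
  allowed <- if (preset == "v1") "marker_mechanism" else
    c("marker_mechanism", "therapeutic")
  tissue_on <- preset %in% c("v1", "v2", "v3")
  species_on <- preset %in% c("v1", "v2", "v4")

  split1 <- function(x) strsplit(ifelse(is.na(x), "", x), "|",
                                 fixed = TRUE)[[1]]
  # Step 1
  cp_keep <- integer(0)
  for (i in seq_len(nrow(tabs$cp))) {
    r <- tabs$cp[i, ]
    if (r$organismid != org) next
    if (tissue != "all") {
      terms <- split1(r$anatomyterms)
      if (!(tissue %in% anatomy_groups(terms, tmap))) next
    }
    cp_keep <- c(cp_keep, i)
  }
  chems <- unique(tabs$cp$chemicalid[cp_keep])
  pm1 <- unique(unlist(lapply(cp_keep, function(i)
    split1(tabs$cp$pubmedids[i]))))
  # Step 2
  cg_keep <- integer(0)
  for (i in seq_len(nrow(tabs$cg))) {
    r <- tabs$cg[i, ]
    if (!(r$chemicalid %in% chems) || r$organismid != org) next
    if (tissue != "all" && !any(split1(r$pubmedids) %in% pm1)) next
    cg_keep <- c(cg_keep, i)
  }
  org_pm <- unique(unlist(lapply(
    which(tabs$cg$organismid == org),
    function(i) split1(tabs$cg$pubmedids[i]))))
  ev_ok <- function(ev) any(split1(ev) %in% allowed)
  dis_ok <- function(r) {
    if (tissue_on && tissue != "all" &&
        !(tissue %in% disease_groups(r$diseaseid, tmap))) return(FALSE)
    if (species_on && !any(split1(r$pubmedids) %in% org_pm)) return(FALSE)
    TRUE
  }
  cd_keep <- which(vapply(seq_len(nrow(tabs$cd)), function(i) {
    r <- tabs$cd[i, ]
    r$chemicalid %in% chems && ev_ok(r$evidence) && dis_ok(r)
  }, logical(1)))
  genes2 <- unique(tabs$cg$geneid[cg_keep])
  gd_keep <- which(vapply(seq_len(nrow(tabs$gd)), function(i) {
    r <- tabs$gd[i, ]
    r$geneid %in% genes2 && ev_ok(r$evidence) && dis_ok(r)
  }, logical(1)))

  out <- list()
  for (i in cg_keep) for (j in cd_keep) for (k in gd_keep) {
    if (tabs$cg$chemicalid[i] != tabs$cd$chemicalid[j]) next
    if (tabs$cg$geneid[i] != tabs$gd$geneid[k]) next
    if (tabs$cd$diseaseid[j] != tabs$gd$diseaseid[k]) next
    for (l in cp_keep) {
      if (tabs$cp$chemicalid[l] != tabs$cg$chemicalid[i]) next
      for (m in seq_len(nrow(tabs$gp))) {
        if (tabs$gp$tax_id[m] != org) next
        if (tabs$gp$geneid[m] != tabs$cg$speciesgeneid[i]) next
        if (tabs$gp$go_id[m] != tabs$cp$phenotypeid[l]) next
        out[[length(out) + 1]] <- data.frame(
          chemicalid = tabs$cg$chemicalid[i],
          speciesgeneid = tabs$cg$speciesgeneid[i],
          phenotypeid = tabs$cp$phenotypeid[l],
          diseaseid = tabs$cd$diseaseid[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chemicalid = character(0),
                      speciesgeneid = integer(0),
                      phenotypeid = character(0),
                      diseaseid = character(0)))
  }
  unique(do.call(rbind, out))
}

# canonical sortable key for a tetramer table
tetramer_keys <- function(df) {
  sort(paste(df$chemicalid, df$speciesgeneid, df$phenotypeid,
             df$diseaseid, sep = "/"))
}

# canonical representation of a collection of chemical sets
set_of_sets <- function(sets) {
  sort(vapply(sets, function(v) paste(sort(unique(v)), collapse = "|"),
              character(1)))
}

# toy DAG used across clustering tests: R <- A <- A1, R <- B
toy_dag <- function() {
  ontology_from_edges(child = c("A", "A1", "B"),
                      parent = c("R", "A", "R"))
}

toy_dag_ic <- function() {
  compute_ic(toy_dag(),
             tibble::tibble(go_id = c("A1", "A1", "A", "B")))
}

# generate fixtures into a fresh temp dir
make_fixtures <- function(...) {
  dir <- tempfile("fx")
  generate_fixtures(fixture_spec(...), dir)
}

run_pipeline <- function(dir, org, preset, tissue = "all",
                         tmap = tissue_group_map(),
                         tabs = load_fixture_tables(dir)) {
  cgpd_tetramers(tabs, filter_config(org, tissue, preset), tmap)
}
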
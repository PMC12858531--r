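write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("loader strips MESH: prefixes, lowercases headers, dedupes", {
  p <- write_tsv_fixture(c(
    "# ChemicalName\tChemicalID\tDiseaseID\tDirectEvidence\tPubMedIDs",
    "bisphenol A\tMESH:C006780\tMESH:D009845\tmarker/mechanism\t111|222",
    "bisphenol A\tMESH:C006780\tMESH:D009845\tmarker/mechanism\t111|222",
    "aspirin\tD001241\tMESH:D006943\ttherapeutic\t"
  ))
  tbl <- load_ctd_table(p, "chem_disease")
  expect_named(tbl, c("chemicalname", "chemicalid", "diseaseid",
                      "directevidence", "pubmedids", "evidence"))
  expect_equal(nrow(tbl), 2)  # duplicate row collapsed
  expect_equal(tbl$chemicalid, c("C006780", "D001241"))
  expect_equal(tbl$diseaseid, c("D009845", "D006943"))
  expect_equal(tbl$evidence, c("marker_mechanism", "therapeutic"))
})

test_that("prefix stripping is idempotent and reaches multi-valued cells", {
  p1 <- write_tsv_fixture(c("# ChemicalID\tAnatomyTerms",
                            "MESH:C1\tMESH:D1|MESH:D2"))
  t1 <- load_ctd_table(p1)
  expect_equal(t1$anatomyterms, "D1|D2")
  # write the stripped table back and reload: nothing changes
  p2 <- write_tsv_fixture(c("# ChemicalID\tAnatomyTerms",
                            paste(t1$chemicalid, t1$anatomyterms,
                                  sep = "\t")))
  expect_equal(load_ctd_table(p2), t1, ignore_attr = TRUE)
})

test_that("empty body, gzip input, and malformed rows are handled", {
  p <- write_tsv_fixture("# ChemicalID\tDiseaseID")
  expect_equal(nrow(load_ctd_table(p)), 0)

  gz <- tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w")
  writeLines(c("# ChemicalID\tGeneID\tOrganismID\tPubMedIDs",
               "MESH:C1\t10\t9606\t1"), con)
  close(con)
  expect_equal(load_ctd_table(gz, "chem_gene")$chemicalid, "C1")

  # 5 data rows, one missing its disease field entirely
  p <- write_tsv_fixture(c(
    "# ChemicalID\tDiseaseID\tDirectEvidence\tPubMedIDs",
    "C1\tD1\tmarker/mechanism\t1",
    "C2\tD2\tmarker/mechanism\t1",
    "C3\tmarker/mechanism\t1",
    "C4\tD4\ttherapeutic\t2",
    "C5\tD5\ttherapeutic\t2"
  ))
  expect_message(tbl <- load_ctd_table(p, "chem_disease"), "malformed")
  expect_equal(nrow(tbl), 4)
  expect_equal(attr(tbl, "malformed"), 1)
})

test_that("schema violations and unreadable files raise named errors", {
  p <- write_tsv_fixture(c("# ChemicalID\tGeneID", "C1\t10"))
  expect_error(load_ctd_table(p, "chem_gene"), "organismid")
  expect_error(load_ctd_table(tempfile(), "chem_gene"), "no such file")
  expect_error(parse_evidence("speculative"), "unknown direct-evidence")
})

make_cg <- function(geneid, organismid, chem = "C1") {
  tibble::tibble(chemicalid = chem, geneid = as.integer(geneid),
                 organismid = as.integer(organismid), pubmedids = "1")
}

orth_tbl <- tibble::tibble(
  tax_id = 9606L, geneid = 2099L, relationship = "Ortholog",
  other_tax_id = 10090L, other_geneid = 13982L)
ginfo <- tibble::tibble(geneid = c(2099L, 13982L, 24890L),
                        tax_id = c(9606L, 10090L, 10116L))

test_that("remapping keeps same-taxon genes and maps orthologs", {
  # human-curated, human primary gene: identity
  r <- remap_gene_ids(make_cg(2099, 9606), orth_tbl, ginfo)
  expect_equal(r$speciesgeneid, 2099L)
  # mouse-curated, human primary 2099 -> mouse 13982 via ortholog pair
  r <- remap_gene_ids(make_cg(2099, 10090), orth_tbl, ginfo)
  expect_equal(r$speciesgeneid, 13982L)
  # symmetric lookup: mouse primary, human organism
  r <- remap_gene_ids(make_cg(13982, 9606), orth_tbl, ginfo)
  expect_equal(r$speciesgeneid, 2099L)
})

test_that("remapping excludes missing orthologs and unknown taxa", {
  # rat-curated with no rat ortholog -> excluded
  expect_message(
    r <- remap_gene_ids(make_cg(2099, 10116), orth_tbl, ginfo),
    "without ortholog")
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "remap_report")[["excluded_no_ortholog"]], 1)
  # gene absent from gene_info -> excluded with its own reason
  expect_message(
    r <- remap_gene_ids(make_cg(999, 9606), orth_tbl, ginfo),
    "unknown gene taxon")
  expect_equal(attr(r, "remap_report")[["excluded_unknown_taxon"]], 1)
})

test_that("one-to-many orthology emits one record per target ortholog", {
  orth2 <- dplyr::bind_rows(orth_tbl, tibble::tibble(
    tax_id = 9606L, geneid = 2099L, relationship = "Ortholog",
    other_tax_id = 10090L, other_geneid = 13983L))
  r <- remap_gene_ids(make_cg(2099, 10090), orth2, ginfo)
  expect_setequal(r$speciesgeneid, c(13982L, 13983L))
})

test_that("remapping conserves records and is a no-op on own-taxon input", {
  x <- dplyr::bind_rows(make_cg(2099, 9606, "C1"),
                        make_cg(2099, 10090, "C2"),
                        make_cg(2099, 10116, "C3"),
                        make_cg(999, 9606, "C4"))
  r <- suppressMessages(remap_gene_ids(x, orth_tbl, ginfo))
  rep <- attr(r, "remap_report")
  expect_equal(rep[["retained_input_rows"]] +
                 rep[["excluded_no_ortholog"]] +
                 rep[["excluded_unknown_taxon"]], rep[["input"]])
  # all primary genes already in the curated organism: identity
  own <- dplyr::bind_rows(make_cg(2099, 9606), make_cg(24890, 10116))
  r <- remap_gene_ids(own, orth_tbl, ginfo)
  expect_equal(r$speciesgeneid, r$geneid)
})

test_that("store build requires the full table set and round-trips", {
  fx <- make_fixtures(seed = 11)
  tabs <- lapply(
    stats::setNames(ctd_store_tables, ctd_store_tables),
    function(nm) load_ctd_table(file.path(fx$dir, paste0(nm, ".tsv"))))
  desc <- load_ctd_table(file.path(fx$dir, "chemical_descriptions.tsv"))
  idnt <- load_ctd_table(file.path(fx$dir, "chemical_identifiers.tsv"))
  db <- tempfile(fileext = ".sqlite")
  build_store(tabs, desc, idnt, db)

  counts <- store_counts(db)
  expect_length(counts, 18)
  for (nm in ctd_store_tables) {
    expect_equal(unname(counts[nm]), nrow(tabs[[nm]]))
  }
  # field-level round trip on a populated table
  back <- read_store_table(db, "ctd_chem_gene_ixns")
  expect_equal(as.data.frame(back),
               as.data.frame(tabs$ctd_chem_gene_ixns),
               ignore_attr = TRUE)
  # missing table -> error naming it
  expect_error(
    build_store(tabs[-1], desc, idnt, tempfile()),
    names(tabs)[1])
})
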
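tmap <- tissue_group_map()

# minimal hand-built tables: chemical C1 completes a tetramer on
# (G10/species G10, P GO:0000002, D1); C2 lacks a gene-disease edge
hand_tables <- function() {
  list(
    cg = tibble::tibble(
      chemicalid = c("C1", "C2"), geneid = c(10L, 20L),
      speciesgeneid = c(10L, 20L), organismid = 9606L,
      pubmedids = c("100", "200")),
    cp = tibble::tibble(
      chemicalid = c("C1", "C2"),
      phenotypeid = c("GO:0000002", "GO:0000002"),
      organismid = 9606L, anatomyterms = c("D008099", "D007668"),
      pubmedids = c("100", "200")),
    cd = tibble::tibble(
      chemicalid = c("C1", "C2"), diseaseid = c("D1", "D1"),
      evidence = c("marker_mechanism", "marker_mechanism"),
      pubmedids = c("100", "200")),
    gd = tibble::tibble(
      geneid = 10L, diseaseid = "D1",
      evidence = "marker_mechanism", pubmedids = "100"),
    gp = tibble::tibble(
      tax_id = 9606L, geneid = c(10L, 20L), go_id = "GO:0000002",
      evidence = "IEA")
  )
}

test_that("step 1 selects chemicals by organism and tissue", {
  tabs <- hand_tables()
  s <- select_chemicals(tabs$cp, filter_config(9606, "all", "v1"), tmap)
  expect_setequal(s$chemicals, c("C1", "C2"))
  expect_setequal(s$pubmeds, c("100", "200"))
  # organism filter excluding everything
  s <- select_chemicals(tabs$cp, filter_config(10090, "all", "v1"), tmap)
  expect_length(s$chemicals, 0)
  # tissue filter: C1 is annotated in liver (D008099), C2 in kidney
  s <- select_chemicals(tabs$cp, filter_config(9606, "liver", "v1"), tmap)
  expect_equal(s$chemicals, "C1")
})

test_that("step 2 applies the indirect PubMed tissue filter", {
  tabs <- hand_tables()
  cfg <- filter_config(9606, "liver", "v1")
  s <- select_chemicals(tabs$cp, cfg, tmap)
  # C1's record shares PubMed 100 with step 1 -> retained
  cg <- collect_cg(tabs$cg, c("C1", "C2"), s$pubmeds, cfg)
  expect_equal(cg$chemicalid, "C1")
  # disjoint PubMed IDs under tissue filtering -> dropped
  cg2 <- collect_cg(tabs$cg, c("C1", "C2"), "999", cfg)
  expect_equal(nrow(cg2), 0)
  # tissue "all": no PubMed intersection required
  cfg_all <- filter_config(9606, "all", "v1")
  cg3 <- collect_cg(tabs$cg, c("C1", "C2"), character(0), cfg_all)
  expect_equal(nrow(cg3), 2)
})

test_that("disease edges honour evidence preset, tissue and species filters", {
  tabs <- hand_tables()
  cd_ther <- tibble::tibble(chemicalid = "C1", diseaseid = "D1",
                            evidence = "therapeutic", pubmedids = "100")
  gd <- tabs$gd
  # therapeutic under v1 -> dropped; under v2 -> retained
  e1 <- collect_disease_edges(cd_ther, gd, filter_config(9606, "all", "v1"),
                              tmap, organism_cg_pubmeds = "100")
  expect_equal(nrow(e1$cd), 0)
  e2 <- collect_disease_edges(cd_ther, gd, filter_config(9606, "all", "v2"),
                              tmap, organism_cg_pubmeds = "100")
  expect_equal(nrow(e2$cd), 1)
  # species filter: PubMed IDs must intersect organism C-G PubMed IDs
  e3 <- collect_disease_edges(tabs$cd, gd, filter_config(9606, "all", "v1"),
                              tmap, organism_cg_pubmeds = "999")
  expect_equal(nrow(e3$cd), 0)
  # unmapped disease with tissue filter on -> retained for any tissue
  e4 <- collect_disease_edges(tabs$cd, gd,
                              filter_config(9606, "liver", "v1"),
                              tmap, organism_cg_pubmeds = c("100", "200"))
  expect_equal(nrow(e4$cd), 2)
  # mapped disease restricted to its tissue group
  cd_liver <- tibble::tibble(chemicalid = "C1", diseaseid = "D008107",
                             evidence = "marker_mechanism",
                             pubmedids = "100")
  e5 <- collect_disease_edges(cd_liver, gd,
                              filter_config(9606, "kidney", "v1"),
                              tmap, organism_cg_pubmeds = "100")
  expect_equal(nrow(e5$cd), 0)
})

test_that("triplets are a pure three-way join", {
  tabs <- hand_tables()
  tr <- build_triplets(tabs$cg, tabs$cd, tabs$gd)
  # C1 has all three edges; C2's gene 20 lacks a G-D edge
  expect_equal(nrow(tr), 1)
  expect_equal(tr$chemicalid, "C1")
  expect_equal(tr$diseaseid, "D1")
  # empty gene-disease table -> empty output
  expect_equal(nrow(build_triplets(tabs$cg, tabs$cd, tabs$gd[0, ])), 0)
})

test_that("tetramers need the phenotype on both chemical and gene sides", {
  tabs <- hand_tables()
  cfg <- filter_config(9606, "all", "v1")
  tets <- cgpd_tetramers(tabs, cfg, tmap)
  expect_equal(nrow(tets), 1)
  expect_equal(tets$chemicalid, "C1")
  expect_equal(tets$phenotypeid, "GO:0000002")
  # remove the gene-phenotype annotation: phenotype only on the
  # chemical side, no tetramer
  tabs2 <- tabs
  tabs2$gp <- tabs$gp[0, ]
  expect_equal(nrow(cgpd_tetramers(tabs2, cfg, tmap)), 0)
  # provenance: all five evidence statements populated
  expect_true(all(nzchar(tets$cg_pubmeds)))
  expect_true(all(nzchar(tets$cp_pubmeds)))
  expect_true(all(nzchar(tets$cd_pubmeds)))
  expect_true(all(nzchar(tets$gd_pubmeds)))
  expect_true(all(nzchar(tets$gp_evidence)))
})

test_that("pipeline equals the nested-loop oracle on generated fixtures", {
  fx <- make_fixtures(seed = 21, evidence_mix = 0.5, noise_edges = 6)
  tabs <- load_fixture_tables(fx$dir)
  for (org in c(9606, 10116)) {
    for (preset in c("v1", "v3")) {
      got <- run_pipeline(fx$dir, org, preset, tabs = tabs, tmap = tmap)
      want <- oracle_tetramers(tabs, org, preset, "all", tmap)
      expect_equal(tetramer_keys(got), tetramer_keys(want),
                   info = paste(org, preset))
    }
  }
  # and for a specific tissue group
  got <- run_pipeline(fx$dir, 9606, "v1", "liver", tabs = tabs,
                      tmap = tmap)
  want <- oracle_tetramers(tabs, 9606, "v1", "liver", tmap)
  expect_equal(tetramer_keys(got), tetramer_keys(want))
})

test_that("tetramer sets grow monotonically from v1 to v5", {
  fx <- make_fixtures(seed = 22, evidence_mix = 0.6, noise_edges = 4)
  tabs <- load_fixture_tables(fx$dir)
  keys <- lapply(stats::setNames(paste0("v", 1:5), paste0("v", 1:5)),
                 function(p) tetramer_keys(
                   run_pipeline(fx$dir, 9606, p, tabs = tabs, tmap = tmap)))
  expect_true(all(keys$v1 %in% keys$v2))
  expect_true(all(keys$v2 %in% keys$v3))
  expect_true(all(keys$v2 %in% keys$v4))
  expect_true(all(keys$v3 %in% keys$v5))
  expect_true(all(keys$v4 %in% keys$v5))
})
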
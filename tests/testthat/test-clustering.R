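test_that("annotation counts propagate through ancestor sets", {
  dag <- toy_dag_ic()
  expect_equal(unname(dag$counts[c("R", "A", "A1", "B")]),
               c(4, 3, 2, 1))
  expect_equal(unname(dag$ic["R"]), 0)
  expect_equal(unname(dag$ic["B"]), -log(0.25), tolerance = 1e-12)
  expect_equal(unname(dag$ic["A1"]), -log(0.5), tolerance = 1e-12)
  # annotation to unknown term is reported and skipped
  expect_message(
    d2 <- compute_ic(toy_dag(), tibble::tibble(go_id = c("A", "ZZZ"))),
    "unknown term")
  expect_equal(unname(d2$counts["A"]), 1)
})

test_that("IC propagation counts each annotation once per ancestor (diamond)", {
  # A1 has two paths to R via A and B; R must still count each
  # annotation exactly once
  dag <- ontology_from_edges(child = c("A", "B", "A1", "A1"),
                             parent = c("R", "R", "A", "B"))
  dag <- compute_ic(dag, tibble::tibble(go_id = c("A1", "A1", "A")))
  expect_equal(unname(dag$counts["R"]), 3)
  expect_equal(unname(dag$counts["A"]), 3)
  expect_equal(unname(dag$counts["B"]), 2)
})

test_that("obo reader builds the DAG and rejects cycles", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "name: child",
    "namespace: biological_process",
    "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000009", "name: gone", "is_obsolete: true", "",
    "[Typedef]", "id: part_of"), obo)
  dag <- read_obo(obo)
  expect_setequal(dag$terms, c("GO:0000001", "GO:0000002"))
  expect_equal(dag$parents[["GO:0000002"]], "GO:0000001")
  expect_error(
    ontology_from_edges(child = c("A", "B"), parent = c("B", "A")),
    "cycle")
})

test_that("Lin similarity matches its closed forms on the toy DAG", {
  dag <- toy_dag_ic()
  expect_equal(lin_similarity("A1", "A1", dag), 1)
  expect_equal(lin_similarity("B", "B", dag), 1)
  # MICA of A1 and B is the root: similarity 0
  expect_equal(lin_similarity("A1", "B", dag), 0)
  # closed form 2*ic(A)/(ic(A1)+ic(A))
  want <- 2 * (-log(3 / 4)) / ((-log(2 / 4)) + (-log(3 / 4)))
  expect_equal(lin_similarity("A1", "A", dag), want, tolerance = 1e-12)
  expect_equal(want, 0.5866, tolerance = 1e-3)
  # symmetry + root-pair convention
  expect_equal(lin_similarity("A", "A1", dag),
               lin_similarity("A1", "A", dag))
  expect_equal(lin_similarity("R", "R", dag), 0)
  # cross-namespace pairs score 0
  dag2 <- ontology_from_edges(child = c("A", "B"), parent = c("R", "S"),
                              namespace = c(R = "bp", A = "bp",
                                            S = "mf", B = "mf"))
  dag2 <- compute_ic(dag2, tibble::tibble(go_id = c("A", "B")))
  expect_equal(lin_similarity("A", "B", dag2), 0)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  fx <- make_fixtures(seed = 41)
  tabs <- load_fixture_tables(fx$dir)
  dag <- compute_ic(read_obo(file.path(fx$dir, "ontology.obo")), tabs$gp)
  terms <- unique(tabs$gp$go_id)
  m <- lin_sim_matrix(terms, dag)
  expect_true(isSymmetric(m))
  expect_true(all(m >= 0 & m <= 1))
  expect_true(all(diag(m) == 1))
})

test_that("threshold components follow union-find semantics", {
  m <- matrix(c(1, .8, .1,
                .8, 1, .8,
                .1, .8, 1), 3, 3,
              dimnames = list(1:3, 1:3))
  comp <- threshold_components(m, 0.75)
  expect_length(comp$components, 1)
  expect_setequal(comp$components[[1]], c("1", "2", "3"))
  comp <- threshold_components(m, 0.9)
  expect_length(comp$components, 3)
  comp <- threshold_components(m, 0)
  expect_length(comp$components, 1)
  # monotone: raising the threshold never merges components
  for (pair in list(c(0, .5), c(.5, .8), c(.8, .9))) {
    lo <- threshold_components(m, pair[1])$membership
    hi <- threshold_components(m, pair[2])$membership
    # components at hi refine components at lo
    for (cmp in split(names(hi), hi)) {
      expect_length(unique(lo[cmp]), 1)
    }
  }
})

test_that("tanimoto matches intersection over union", {
  expect_equal(tanimoto(c("a", "b"), c("a", "b")), 1)
  expect_equal(tanimoto(c("a"), c("b")), 0)
  expect_equal(tanimoto(c("a", "b"), c("b", "c")), 1 / 3)
  expect_error(tanimoto(character(0), character(0)), "undefined")
})

test_that("chemical-list clustering merges by thresholded Tanimoto", {
  groups <- tibble::tibble(
    group_id = c("g1", "g2", "g3"),
    chemicals = list(c("a", "b"), c("b", "c"), c("x", "y")),
    organismid = 9606L, tissue_group = "all")
  cl <- cluster_by_chemicals(groups, 0.3)
  expect_equal(nrow(cl), 2)
  expect_equal(set_of_sets(cl$chemicals), c("a|b|c", "x|y"))
  # conservation: cluster chemicals are unions of member group sets
  expect_setequal(unlist(cl$chemicals), unlist(groups$chemicals))
  # threshold 1 with distinct sets: nothing merges
  expect_equal(nrow(cluster_by_chemicals(groups, 1)), 3)
  # identical chemical sets merge at any threshold
  twin <- groups[c(1, 1), ]
  expect_equal(nrow(cluster_by_chemicals(twin, 1)), 1)
})

test_that("phenotype merging requires shared keys within a component", {
  dag <- toy_dag_ic()
  simm <- lin_sim_matrix(c("A", "A1", "B"), dag)
  comp <- threshold_components(simm, 0.5)  # {A, A1} together, {B} alone
  base <- tibble::tibble(
    speciesgeneid = c(1L, 1L), phenotypeid = c("A", "A1"),
    diseaseid = c("D1", "D1"), organismid = 9606L, tissue_group = "all",
    chemicals = list("C1", "C2"), group_id = c("g1", "g2"))
  # same gene and disease, phenotypes in one component -> one cluster
  cl <- merge_by_phenotype(base, comp, "gpd")
  expect_equal(nrow(cl), 1)
  expect_setequal(cl$chemicals[[1]], c("C1", "C2"))
  expect_setequal(cl$phenotypes[[1]], c("A", "A1"))
  # different diseases -> not merged
  diff_d <- base
  diff_d$diseaseid <- c("D1", "D2")
  expect_equal(nrow(merge_by_phenotype(diff_d, comp, "gpd")), 2)
  # different genes -> not merged in gpd mode, merged in pd mode
  diff_g <- base
  diff_g$speciesgeneid <- c(1L, 2L)
  expect_equal(nrow(merge_by_phenotype(diff_g, comp, "gpd")), 2)
  pd <- diff_g
  pd$genes <- pd$chemicals  # pd-style groups carry gene list-columns
  pd$speciesgeneid <- NULL
  expect_equal(nrow(merge_by_phenotype(pd, comp, "pd")), 1)
  # phenotypes in different components -> never merged
  far <- base
  far$phenotypeid <- c("A1", "B")
  expect_equal(nrow(merge_by_phenotype(far, comp, "gpd")), 2)
})

test_that("configuration grid enumerates presets x groupings x clusterings", {
  grid <- enumerate_configs()
  expect_equal(nrow(grid), 150)
  expect_equal(nrow(enumerate_configs(presets = "v1")), 30)
  # 15 clustering options: 3 phenotype-only + 3 chemical-only + 9 both
  opts <- unique(grid[, c("pheno_threshold", "chem_threshold")])
  expect_equal(nrow(opts), 15)
  expect_equal(sum(is.na(opts$chem_threshold)), 3)
  expect_equal(sum(is.na(opts$pheno_threshold)), 3)
  expect_error(enumerate_configs(thresholds = numeric(0)),
               "at least one")
})
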
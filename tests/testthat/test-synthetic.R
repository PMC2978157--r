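test_that("generators are pure functions of the spec", {
  spec <- synthetic_spec(n_genes = 50, n_edges = 100, seed = 17)
  g1 <- generate_pin(spec); g2 <- generate_pin(spec)
  e1 <- igraph::as_edgelist(g1); e2 <- igraph::as_edgelist(g2)
  expect_identical(e1, e2)
  x1 <- generate_expression(spec); x2 <- generate_expression(spec)
  expect_identical(x1$expr, x2$expr)
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture(spec, d1)
  generate_fixture(spec, d2)
  f1 <- sort(list.files(d1, full.names = TRUE))
  f2 <- sort(list.files(d2, full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_length(f1, 6)   # 5 inputs + manifest
  expect_error(generate_fixture(spec, d1), "overwrite")
})

test_that("the PIN is connected with planted members induced connected", {
  spec <- synthetic_spec(n_genes = 50, n_edges = 100, seed = 23)
  pin <- generate_pin(spec)
  expect_equal(igraph::ecount(pin), 100)
  expect_equal(igraph::vcount(pin), 50)
  expect_true(igraph::is_connected(pin))
  for (members in cepin:::spec_members(spec)) {
    sub <- igraph::induced_subgraph(pin, members)
    expect_true(igraph::is_connected(sub))
  }
  # complete-graph saturation
  tiny <- synthetic_spec(n_genes = 6, n_edges = 15,
                         planted_terms = list(planted_term("t", 3, 0.5, 0)),
                         samples_per_condition = c(3, 3), decoy_size = 3)
  expect_equal(igraph::ecount(generate_pin(tiny)), 15)
  expect_error(synthetic_spec(n_genes = 6, n_edges = 16,
                              planted_terms = list()), "complete graph")
})

test_that("the generated ontology places terms at their levels", {
  spec <- synthetic_spec(n_genes = 50, n_edges = 100, seed = 29)
  oa <- generate_annotations(spec)
  expect_equal(term_level(oa$dag, "GO:9100001"), 6L)
  expect_equal(term_level(oa$dag, "GO:9100002"), 6L)
  # planted members are directly annotated; propagation reaches the root
  members <- cepin:::spec_members(spec)[["GO:9100001"]]
  expect_true(all(vapply(oa$ann$direct[members],
                         function(ts) "GO:9100001" %in% ts, logical(1))))
  expect_true(all(vapply(oa$ann$propagated[members],
                         function(ts) "GO:0000001" %in% ts, logical(1))))
  # every gene annotated; decoy terms have the configured size
  expect_setequal(names(oa$ann$direct), cepin:::spec_genes(spec))
})

test_that("the one-factor model calibrates within-module correlation", {
  for (rho in c(0.3, 0.6, 0.8)) {
    means <- vapply(1:50, function(seed) {
      spec <- synthetic_spec(
        n_genes = 20, n_edges = 25, samples_per_condition = c(15, 15),
        planted_terms = list(planted_term("t", 10, rho, 0, shift = 0)),
        decoy_size = 10, seed = seed)
      x <- generate_expression(spec)
      C <- cor(t(x$expr[1:10, 1:15]))
      mean(C[upper.tri(C)])
    }, numeric(1))
    expect_lt(abs(mean(means) - rho), 0.05)
  }
})

test_that("rho = 0 and shift = 0 give a calibrated null", {
  # planted pairs at rho 0: mean |PCC| stays within the sampling bound
  absr <- vapply(1:10, function(seed) {
    spec <- synthetic_spec(
      n_genes = 20, n_edges = 25, samples_per_condition = c(15, 15),
      planted_terms = list(planted_term("t", 10, 0, 0, shift = 0)),
      decoy_size = 10, seed = seed)
    x <- generate_expression(spec)
    C <- cor(t(x$expr[1:10, 1:15]))
    mean(abs(C[upper.tri(C)]))
  }, numeric(1))
  expect_lt(mean(absr), 2 / sqrt(15))

  # shift = 0: rank-sum p-values are uniform, ~5% below 0.05
  spec <- synthetic_spec(n_genes = 500, n_edges = 600,
                         planted_terms = list(), seed = 77)
  x <- generate_expression(spec)
  s <- call_sdegs(x$expr, x$design)
  expect_lt(abs(mean(s$p_value <= 0.05) - 0.05), 0.03)
})

test_that("fixture manifests round-trip the spec", {
  spec <- synthetic_spec(n_genes = 40, n_edges = 80, seed = 31)
  dir <- tempfile()
  paths <- generate_fixture(spec, dir)
  spec2 <- read_fixture_manifest(paths["manifest"])
  dir2 <- tempfile()
  paths2 <- generate_fixture(spec2, dir2)
  expect_identical(unname(tools::md5sum(sort(unname(paths)))),
                   unname(tools::md5sum(sort(unname(paths2)))))
})

test_that("fixture files re-read into the generated objects", {
  spec <- synthetic_spec(n_genes = 40, n_edges = 80, seed = 37)
  d <- generate_fixture_data(spec)
  dir <- tempfile()
  paths <- generate_fixture(spec, dir)
  expr <- read_expression_table(paths["expression"])
  expect_equal(expr, d$expr, tolerance = 1e-12)
  des <- read_sample_design(paths["design"])
  expect_identical(des$sample, d$design$sample)
  pin <- read_edge_list(paths["edges"], quiet = TRUE)
  expect_equal(igraph::ecount(pin), igraph::ecount(d$pin))
  dag <- read_ontology_obo(paths["ontology"])
  expect_setequal(dag$terms$id, d$dag$terms$id)
  expect_identical(term_level(dag, d$dag$terms$id),
                   term_level(d$dag, d$dag$terms$id))
  ann <- read_annotations(paths["annotations"], dag = dag)
  expect_identical(lapply(ann$direct, sort),
                   lapply(d$ann$direct[names(ann$direct)], sort))
})
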
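test_that("topology matches hand-worked values on path, triangle, star", {
  path <- read_edge_list(write_tmp(c("A\tB", "B\tC")))
  t <- compute_topology(path)
  expect_equal(t$degree[t$node == "B"], 2L)
  expect_equal(t$betweenness[t$node == "B"], 1 / 3)
  expect_equal(t$closeness[t$node == "B"], 1)
  expect_equal(t$closeness[t$node == "A"], 2 / 3)
  expect_equal(t$clustering[t$node == "B"], 0)
  expect_false(t$clustering_defined[t$node == "A"])

  tri <- read_edge_list(write_tmp(c("A\tB", "B\tC", "A\tC")))
  tt <- compute_topology(tri)
  expect_equal(tt$betweenness, rep(0, 3))
  expect_equal(tt$closeness, rep(1, 3))
  expect_equal(tt$clustering, rep(1, 3))

  star <- read_edge_list(write_tmp(c("X\tL1", "X\tL2", "X\tL3")))
  st <- compute_topology(star)
  expect_equal(st$degree[st$node == "X"], 3L)
  expect_equal(st$betweenness[st$node == "X"], 0.5)
  expect_equal(st$clustering[st$node == "X"], 0)
})

test_that("all four measures match brute-force oracles on random graphs", {
  set.seed(21)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    g <- rand_connected_graph(n)
    t <- compute_topology(g)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    o <- oracle_topology(adj)
    idx <- match(rownames(adj), t$node)
    expect_identical(t$degree[idx], as.integer(o$degree))
    expect_equal(t$clustering[idx], o$clustering)
    expect_equal(t$betweenness[idx], o$betweenness, tolerance = 1e-9)
    expect_equal(t$closeness[idx], o$closeness, tolerance = 1e-9)
  }
})

test_that("wilcoxon_exact matches full enumeration, incl. ties", {
  expect_equal(wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_exact(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_exact(c(4, 5, 6), c(1, 2, 3)),
               wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)))
  set.seed(31)
  for (rep in 1:60) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    vals <- sample(1:6, nx + ny, replace = TRUE)  # plenty of ties
    x <- vals[seq_len(nx)]; y <- vals[-seq_len(nx)]
    if (length(unique(vals)) == 1) next
    expect_equal(wilcoxon_exact(x, y), oracle_wilcox_enum(x, y))
  }
  # approximate branch stays close to the exact answer
  set.seed(32)
  x <- rnorm(12); y <- rnorm(12, 1)
  exact <- wilcoxon_exact(x, y)
  approx <- wilcoxon_exact(x, y, exact_limit = 1)
  expect_lt(abs(exact - approx), 0.02)
})

test_that("SDEG calling flags genes by rank-sum p and directions by means", {
  expr <- rbind(up = c(4, 5, 6, 1, 2, 3),
                flat = c(1, 2, 3, 1, 2, 3),
                down = c(1, 2, 3, 4, 5, 6))
  colnames(expr) <- c(paste0("a", 1:3), paste0("b", 1:3))
  design <- sample_design(colnames(expr), rep(c("A", "B"), each = 3))
  s <- call_sdegs(expr, design, alpha = 0.1)
  expect_true(s$sdeg[s$gene == "up"])
  expect_identical(s$direction[s$gene == "up"], "up")
  expect_identical(s$direction[s$gene == "down"], "down")
  expect_false(s$sdeg[s$gene == "flat"])
  expect_equal(s$p_value[s$gene == "up"], 0.1)
  # stricter alpha flags nothing
  expect_equal(sum(call_sdegs(expr, design, alpha = 0.05)$sdeg), 0)
})

test_that("group topology comparison reports means and rank-sum p", {
  topo <- tibble::tibble(node = letters[1:6],
                         degree = c(5, 6, 7, 1, 2, 3),
                         betweenness = rep(0.5, 6),
                         closeness = c(5, 6, 7, 1, 2, 3) / 10,
                         clustering = rep(0.2, 6))
  cmp <- compare_topology_by_group(topo, letters[1:3])
  deg <- cmp[cmp$property == "degree", ]
  expect_equal(deg[[2]], 6)
  expect_equal(deg[[3]], 2)
  expect_equal(deg$p_value, 0.1)
  expect_equal(cmp$p_value[cmp$property == "betweenness"], 1)
  expect_error(compare_topology_by_group(topo, character()), "non-empty")
})

test_that("hub calling is strict above the percentile threshold", {
  gg <- read_edge_list(write_tmp(c("a\tb", "a\tc", "a\td", "b\tc")))
  # degrees: a=3, b=2, c=2, d=1
  hubs <- call_hubs(gg, percentile = 25)
  expect_identical(as.character(hubs), "a")
  all_eq <- read_edge_list(write_tmp(c("a\tb", "c\td")))
  expect_length(suppressMessages(call_hubs(all_eq, percentile = 1)), 0)
  # linear-interpolation quantile: degrees 1..4, percentile 50 -> {3,4}
  chain <- read_edge_list(write_tmp(c(
    "n1\tn4", "n2\tn4", "n2\tn3", "n3\tn4", "n3\tx1", "n4\tx2")))
  # degrees: n1=1, n2=2, n3=3, n4=4, x1=1, x2=1 -- use explicit subset
  deg <- igraph::degree(chain)[c("n1", "n2", "n3", "n4")]
  thr <- unname(quantile(deg, 0.5, type = 7))
  expect_equal(thr, 2.5)
})

test_that("degree/SDEG association reproduces Fisher enumeration", {
  # clique of 10 high-degree nodes + 10 degree-1 pairs
  hi <- sprintf("H%02d", 1:10)
  lo <- sprintf("L%02d", 1:10)
  edges <- c(apply(utils::combn(hi, 2), 2, paste, collapse = "\t"),
             paste(lo[c(1, 3, 5, 7, 9)], lo[c(2, 4, 6, 8, 10)], sep = "\t"))
  g <- read_edge_list(write_tmp(edges))
  sdegs <- tibble::tibble(gene = c(hi, lo),
                          p_value = 0.01,
                          sdeg = c(rep(TRUE, 8), rep(FALSE, 2),
                                   rep(TRUE, 2), rep(FALSE, 8)),
                          direction = "up")
  assoc <- sdeg_degree_association(g, sdegs)
  expect_equal(unname(assoc$table[1, 1]), 8)
  expect_equal(assoc$p_value, oracle_fisher2x2(assoc$table), tolerance = 1e-10)
  expect_equal(assoc$p_value, 0.0230141, tolerance = 1e-4)
  expect_gt(assoc$proportions["high"], assoc$proportions["low"])

  # extreme 10/0 vs 0/10 association
  sdegs2 <- dplyr::mutate(sdegs, sdeg = gene %in% hi)
  assoc2 <- sdeg_degree_association(g, sdegs2)
  expect_lt(assoc2$p_value, 1e-4)
  expect_equal(assoc2$p_value, oracle_fisher2x2(assoc2$table), tolerance = 1e-10)
})

test_that("planted differential co-expression concentrates SDEGs at high degree", {
  hits <- 0L
  for (seed in 1:20) {
    spec <- synthetic_spec(seed = seed)
    d <- generate_fixture_data(spec)
    s <- score_network_edges(d$pin, d$expr, d$design, "A")
    cp <- build_cepin(s)
    sdegs <- call_sdegs(d$expr, d$design)
    assoc <- sdeg_degree_association(cp, sdegs)
    if (assoc$proportions["high"] > assoc$proportions["low"]) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
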
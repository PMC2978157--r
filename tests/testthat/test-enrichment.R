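test_that("hypergeometric tail matches enumeration on worked examples", {
  expect_equal(hypergeometric_tail(10, 4, 5, 0), 1)
  expect_equal(hypergeometric_tail(10, 4, 5, 2), 186 / 252, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(10, 4, 5, 4), 6 / 252, tolerance = 1e-12)
  expect_equal(hypergeometric_tail(10, 4, 5, 4, mode = "point"), 6 / 252,
               tolerance = 1e-12)
  expect_error(hypergeometric_tail(10, 4, 5, 6), "require")
  expect_error(hypergeometric_tail(10, 11, 5, 2), "require")
})

test_that("hypergeometric tail equals exhaustive enumeration for all N <= 25", {
  worst <- 0
  for (N in 1:25) {
    for (n in 0:N) {
      for (m in 0:N) {
        for (k in 0:min(m, n)) {
          err <- abs(hypergeometric_tail(N, m, n, k) -
                       oracle_hyper_tail(N, m, n, k))
          worst <- max(worst, err)
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("hypergeometric tail is non-increasing in k", {
  for (case in list(c(20, 8, 10), c(15, 15, 3), c(25, 5, 20))) {
    N <- case[1]; m <- case[2]; n <- case[3]
    p <- vapply(0:min(m, n), function(k) hypergeometric_tail(N, m, n, k),
                numeric(1))
    expect_true(all(diff(p) <= 1e-12))
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(41)
  ok <- TRUE; worst <- 0
  for (i in 1:1000) {
    p <- runif(sample(1:100, 1))
    q <- bh_adjust(p)
    worst <- max(worst, abs(q - oracle_bh(p)))
    o <- order(p)
    ok <- ok && all(diff(q[o]) >= -1e-15) && all(q >= p - 1e-15)
  }
  expect_lt(worst, 1e-15)
  expect_true(ok)
})

test_that("gene enrichment counts (N, m, n, k) against the background", {
  dag <- toy_dag()
  bg <- sprintf("G%02d", 1:10)
  # 4 genes annotated to t1, all of them in the 5-gene selection
  direct <- setNames(as.list(rep("t1", 4)), bg[1:4])
  direct <- c(direct, setNames(as.list(rep("c6", 6)), bg[5:10]))
  ann <- propagate_annotations(annotation_map(direct), dag)
  sel <- bg[1:5]
  enr <- gene_enrichment(sel, ann, background = bg, dag = dag)
  t1 <- enr[enr$term == "t1", ]
  expect_equal(t1$N, 10); expect_equal(t1$m, 5)
  expect_equal(t1$n, 4); expect_equal(t1$k, 4)
  expect_equal(t1$p_raw, 5 / 210, tolerance = 1e-12)
  # the root covers every gene: no enrichment possible
  expect_equal(enr$p_raw[enr$term == "r"], 1)
  # a term with no selected gene has k = 0 -> p 1
  direct2 <- c(direct[1:4], setNames(as.list(rep("c6", 5)), bg[6:10]),
               list(G05 = "a"))
  ann2 <- propagate_annotations(annotation_map(direct2), dag)
  enr2 <- gene_enrichment(bg[1:4], ann2, background = bg)
  expect_equal(enr2$p_raw[enr2$term == "c6"], 1)
  expect_error(gene_enrichment(sel, ann, background = character()), "empty")
})

test_that("dyad enrichment counts functional dyads among CePPIs", {
  dag <- toy_dag()
  bg <- sprintf("G%02d", 1:12)
  # static PIN: a 10-edge ring over G01..G10
  ring <- paste(bg[1:10], bg[c(2:10, 1)], sep = "\t")
  static <- read_edge_list(write_tmp(ring))
  # term t1 annotates G01..G05: ring edges 1-2,2-3,3-4,4-5 are its dyads (ne=4)
  direct <- c(setNames(as.list(rep("t1", 5)), bg[1:5]),
              setNames(as.list(rep("c6", 7)), bg[6:12]))
  ann <- propagate_annotations(annotation_map(direct), dag)
  # CePPIs: those same 4 dyads plus edge 6-7 (me=5)
  sc <- tibble::tibble(u = bg[c(1:4, 6)], v = bg[c(2:5, 7)], condition = "A",
                       pcc = 0.9, n_used = 10L, p_value = 0.01)
  cp <- build_cepin(sc)
  de <- dyad_enrichment(cp, ann, static, terms = c("t1", "c6"), background = bg)
  t1 <- de[de$term == "t1", ]
  expect_equal(t1$Ne, 10); expect_equal(t1$me, 5)
  expect_equal(t1$ne, 4); expect_equal(t1$ke, 4)
  expect_equal(t1$p_raw, oracle_hyper_tail(10, 5, 4, 4), tolerance = 1e-12)
  expect_equal(t1$p_raw, 5 / 210, tolerance = 1e-12)

  # saturated: every static edge a CePPI -> p = 1 for every term
  sc_all <- tibble::tibble(u = bg[1:10], v = bg[c(2:10, 1)], condition = "A",
                           pcc = 0.9, n_used = 10L, p_value = 0.01)
  de_all <- dyad_enrichment(build_cepin(sc_all), ann, static,
                            terms = "t1", background = bg)
  expect_equal(de_all$p_raw, 1)

  # term annotating a single gene: no dyad possible, flagged
  ann1 <- propagate_annotations(
    annotation_map(c(direct, list(G12 = c("c6", "a")))), dag)
  de1 <- dyad_enrichment(cp, ann1, static, terms = "a", background = bg,
                         use = "direct")
  expect_true(de1$no_dyad)
  expect_equal(de1$p_raw, 1)
})
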
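toy_design <- function(n = 4) {
  sample_design(c(paste0("p", 1:n), paste0("q", 1:n)),
                rep(c("P", "Q"), each = n), positive = "P")
}

test_that("module activity is the (masked) mean member expression", {
  expr <- rbind(g1 = c(1, 2, 3, 4), g2 = c(3, 2, 1, NA))
  colnames(expr) <- paste0("s", 1:4)
  one <- module_activity("g1", expr)
  expect_equal(one$score, c(1, 2, 3, 4))
  both <- module_activity(c("g1", "g2"), expr)
  expect_equal(both$score[1], 2)
  expect_equal(both$score[4], 4)       # masked mean over remaining member
  expect_false(both$complete[4])
  expect_error(module_activity("absent", expr), "no member gene")
})

test_that("root-split classification satisfies the count identities", {
  set.seed(51)
  n <- 7
  expr <- cbind(matrix(rnorm(20 * n, 3, 0.3), 20),
                matrix(rnorm(20 * n, 0, 0.3), 20))
  rownames(expr) <- paste0("g", 1:20)
  colnames(expr) <- c(paste0("p", 1:n), paste0("q", 1:n))
  design <- sample_design(colnames(expr), rep(c("P", "Q"), each = n),
                          positive = "P")
  cr <- classify_by_clustering(paste0("g", 1:20), expr, design)
  expect_equal(cr$accuracy, 1)
  expect_equal(cr$tp + cr$fn, n)
  expect_equal(cr$tn + cr$fp, n)
  expect_equal(cr$sensitivity, cr$tp / (cr$tp + cr$fn))
  expect_equal(cr$specificity, cr$tn / (cr$fp + cr$tn))
  expect_equal(cr$accuracy, (cr$tp + cr$tn) / (2 * n))

  # imperfect separation: move two positive samples into the negative block
  expr2 <- expr
  expr2[, c("p1", "p2")] <- matrix(rnorm(40, 0, 0.3), 20)
  cr2 <- classify_by_clustering(paste0("g", 1:20), expr2, design)
  expect_equal(cr2$tp, 5); expect_equal(cr2$fn, 2)
  expect_equal(cr2$accuracy, (cr2$tp + cr2$tn) / (2 * n))
  expect_equal(cr2$sensitivity, 5 / 7, tolerance = 1e-12)
  g <- glance(cr2)
  expect_equal(g$accuracy, cr2$accuracy)

  const <- matrix(1, 5, 8, dimnames = list(paste0("g", 1:5),
                                           toy_design()$sample))
  expect_error(classify_by_clustering(paste0("g", 1:5), const, toy_design()),
               "degenerate")
})

test_that("ROC/AUC equals the pairwise-concordance oracle", {
  d <- toy_design(4)
  r <- roc_auc(setNames(c(0.9, 0.8, 0.85, 0.95, 0.2, 0.1, 0.15, 0.05),
                        d$sample), d)
  expect_equal(r$auc, 1)
  r2 <- roc_auc(setNames(rep(1, 8), d$sample), d)
  expect_equal(r2$auc, 0.5)
  # duplicating each class of {0.8, 0.4} vs {0.6, 0.2} keeps AUC = 3/4
  r3 <- roc_auc(setNames(c(0.8, 0.8, 0.4, 0.4, 0.6, 0.6, 0.2, 0.2),
                         d$sample), d)
  expect_equal(r3$auc, 0.75)
  # curve starts at (0,0), ends at (1,1), is monotone
  expect_equal(unlist(r3$points[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r3$points[nrow(r3$points), c("fpr", "tpr")]),
               c(fpr = 1, tpr = 1))
  expect_true(all(diff(r3$points$fpr) >= 0) && all(diff(r3$points$tpr) >= 0))

  set.seed(52)
  for (i in 1:1000) {
    n <- sample(4:25, 1)
    sam <- paste0("s", 1:(2 * n))
    des <- sample_design(sam, rep(c("P", "Q"), each = n), positive = "P")
    sc <- setNames(sample(seq_len(8), 2 * n, replace = TRUE) / 8, sam)
    r <- roc_auc(sc, des)
    expect_equal(r$auc, oracle_auc(sc, rep(c(TRUE, FALSE), each = n)))
  }
})

test_that("random subnetwork nulls are seeded, sized and degenerate-safe", {
  pool <- paste0("g", 1:30)
  n1 <- random_subnetwork_null(pool, 5, 20, function(g) length(g), seed = 7)
  expect_true(all(n1 == 5))
  n2 <- random_subnetwork_null(pool, 5, 20, function(g) sum(match(g, pool)),
                               seed = 7)
  n3 <- random_subnetwork_null(pool, 5, 20, function(g) sum(match(g, pool)),
                               seed = 7)
  expect_identical(n2, n3)
  n4 <- random_subnetwork_null(pool, 30, 5, function(g) sum(match(g, pool)))
  expect_equal(sd(n4), 0)
  expect_error(random_subnetwork_null(pool, 31, 5, length), "exceeds")
})

test_that("dynamics Z-scores and empirical p follow their definitions", {
  set.seed(53)
  spec <- synthetic_spec(n_genes = 60, n_edges = 120, seed = 53)
  d <- generate_fixture_data(spec)
  members <- sprintf("G%04d", 1:20)    # the planted rho_A = 0.8 term
  dyn <- module_dynamics_zscores(members, d$expr, d$design,
                                 n_null = 99, seed = 3)
  expect_equal(dyn$z, (dyn$observed - dyn$null_mean) / dyn$null_sd)
  expect_true(all(dyn$p_empirical >= 1 / 100 & dyn$p_empirical <= 1))
  pa <- dyn[dyn$statistic == "mean_abs_pcc_a", ]
  expect_gt(pa$observed, pa$null_mean)   # planted co-expression
  expect_equal(pa$p_empirical, 1 / 100)  # above every null draw
  # reproducible under the same seed
  dyn2 <- module_dynamics_zscores(members, d$expr, d$design,
                                  n_null = 99, seed = 3)
  expect_equal(dyn$null_mean, dyn2$null_mean)
  expect_error(module_dynamics_zscores("G0001", d$expr, d$design, n_null = 9),
               "at least 2")
})

test_that("edge dynamics classes follow the absolute-PCC threshold", {
  mk <- function(pcc, cond) tibble::tibble(
    u = c("a", "b", "c"), v = c("b", "c", "d"), condition = cond,
    pcc = pcc, n_used = 10L, p_value = 0.01)
  ed <- classify_edge_dynamics(mk(c(0.6, 0.55, 0.1), "A"),
                               mk(c(0.1, -0.72, 0.2), "B"))
  expect_identical(ed$class, c("A-specific", "both", "neither"))
  ed0 <- classify_edge_dynamics(mk(c(0.6, 0.55, 0.1), "A"),
                                mk(c(0.1, -0.72, 0.2), "B"), threshold = 0)
  expect_true(all(ed0$class == "both"))
  # missing score in one condition -> neither + flagged
  ed_na <- classify_edge_dynamics(mk(c(0.6, 0.55, 0.1), "A")[1:2, ],
                                  mk(c(0.1, -0.72, 0.2), "B"))
  expect_identical(ed_na$class[3], "neither")
  expect_true(ed_na$flagged[3])
})

test_that("resampling at full size recovers everything, reproducibly", {
  spec <- synthetic_spec(n_genes = 80, n_edges = 160,
                         samples_per_condition = c(8, 8), seed = 11)
  d <- generate_fixture_data(spec)
  rb <- resample_robustness(d$expr, d$design, d$pin, d$dag, d$ann,
                            sizes = 8, n_repeat = 2, seed = 2)
  expect_true(all(rb$recovery_A == 1))
  expect_true(all(rb$recovery_B == 1))
  expect_true(all(is.na(rb$identification_rate) | rb$identification_rate == 1))
  rb2 <- resample_robustness(d$expr, d$design, d$pin, d$dag, d$ann,
                             sizes = c(8, 5), n_repeat = 2, seed = 2)
  expect_identical(rb$recovery_A, rb2$recovery_A[rb2$size == 8])
  expect_error(resample_robustness(d$expr, d$design, d$pin, d$dag, d$ann,
                                   sizes = 2), ">= 3")
})
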
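#' Module activity score per sample
#'
#' The mean expression of the module's member genes in each sample; samples in
#' which some member is missing use the mean over the remaining members and
#' are flagged.
#'
#' @param module A `functional_module` or a character vector of genes.
#' @param expr Expression matrix (genes x samples).
#' @return A tibble `sample`, `score`, `n_members`, `complete`.
#' @export
module_activity <- function(module, expr) {
  genes <- if (inherits(module, "functional_module")) module$genes else module
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) abort("no member gene measured")
  M <- expr[genes, , drop = FALSE]
  used <- colSums(is.finite(M))
  if (any(used == 0L)) abort("sample(s) with no measured member gene")
  tibble(sample = colnames(expr),
         score = unname(colMeans(M, na.rm = TRUE)),
         n_members = unname(used),
         complete = unname(used == length(genes)))
}

#' Classify samples by hierarchical clustering on module expression
#'
#' Samples are clustered on the member genes' expression with Euclidean
#' distance, the tree is cut at the root into two groups, and the group with
#' more positive-condition samples is called positive (ties broken toward the
#' group holding the lexicographically smallest sample id, with a message).
#' Sensitivity = TP/(TP+FN), specificity = TN/(FP+TN), and accuracy =
#' (TP+TN)/N. `accuracy_mode = "printed"` instead reports
#' (sensitivity+specificity)/N, a historical formula kept for forensic
#' comparison only.
#'
#' @param module A `functional_module` or character vector of genes.
#' @param expr Expression matrix.
#' @param design A [sample_design()].
#' @param linkage Agglomeration method (default `"average"`, i.e. UPGMA).
#' @param accuracy_mode `"standard"` (default) or `"printed"`.
#' @return A `module_classification` object with counts, rates, and the
#'   per-sample group assignment tibble.
#' @export
classify_by_clustering <- function(module, expr, design,
                                   linkage = c("average", "single", "complete",
                                               "ward.D2"),
                                   accuracy_mode = c("standard", "printed")) {
  linkage <- match.arg(linkage)
  accuracy_mode <- match.arg(accuracy_mode)
  genes <- if (inherits(module, "functional_module")) module$genes else module
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) abort("no member gene measured")
  samples <- intersect(design$sample, colnames(expr))
  M <- t(expr[genes, samples, drop = FALSE])
  d <- dist(M)
  if (all(d < .Machine$double.eps^0.5)) abort("degenerate clustering: all samples identical")
  hc <- hclust(d, method = linkage)
  grp <- cutree(hc, k = 2)
  pos_label <- design_positive(design)
  is_pos <- setNames(design$condition == pos_label, design$sample)[samples]
  pos_in <- vapply(1:2, function(k) sum(is_pos[grp == k]), numeric(1))
  pos_grp <- if (pos_in[1] != pos_in[2]) which.max(pos_in) else {
    firsts <- vapply(1:2, function(k) min(names(grp)[grp == k]), character(1))
    inform("root-split tie: positive group chosen by smallest sample id")
    order(firsts)[1]
  }
  predicted_pos <- grp == pos_grp
  tp <- sum(predicted_pos & is_pos); fp <- sum(predicted_pos & !is_pos)
  tn <- sum(!predicted_pos & !is_pos); fn <- sum(!predicted_pos & is_pos)
  sens <- tp / (tp + fn); spec <- tn / (fp + tn)
  acc <- if (accuracy_mode == "standard") (tp + tn) / length(samples) else
    (sens + spec) / length(samples)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec, accuracy = acc,
    accuracy_mode = accuracy_mode, linkage = linkage,
    assignment = tibble(sample = samples, group = unname(grp),
                        predicted_positive = unname(predicted_pos),
                        positive = unname(is_pos))
  ), class = "module_classification")
}

#' @export
print.module_classification <- function(x, ...) {
  cat(sprintf(
    "Root-split classification: TP=%d FP=%d TN=%d FN=%d | sens %.3f spec %.3f acc %.3f\n",
    x$tp, x$fp, x$tn, x$fn, x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' ROC curve and AUC from per-sample scores
#'
#' Threshold sweep over the unique scores; AUC equals the Mann-Whitney
#' pairwise-concordance probability with half-credit for ties. Orientation is
#' auto-selected so that AUC >= 0.5 and recorded.
#'
#' @param scores Tibble `sample`,`score` (e.g. [module_activity()]) or a named
#'   numeric vector.
#' @param design A [sample_design()].
#' @return A `roc_result`: list with `points` (tibble `threshold`,`fpr`,`tpr`),
#'   `auc`, `orientation` (+1 high score = positive, -1 flipped).
#' @export
roc_auc <- function(scores, design) {
  if (is.numeric(scores)) scores <- tibble(sample = names(scores), score = scores)
  lab <- setNames(design$condition, design$sample)[scores$sample]
  pos <- lab == design_positive(design)
  if (!any(pos) || all(pos)) abort("both conditions must be represented")
  s <- scores$score
  np <- sum(pos); nn <- sum(!pos)
  auc_of <- function(v) (sum(rank(v)[pos]) - np * (np + 1) / 2) / (np * nn)
  a <- auc_of(s)
  orientation <- if (a >= 0.5) 1 else -1
  if (orientation < 0) { s <- -s; a <- auc_of(s) }
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  pts <- tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(s[!pos] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
  )
  structure(list(points = pts, auc = a, orientation = orientation),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d points, orientation %+d)\n",
              x$auc, nrow(x$points), x$orientation))
  invisible(x)
}

#' Null distribution of a statistic over random gene sets of equal size
#'
#' Draws `n_null` uniform random gene sets of the stated size from the pool of
#' measured network genes and evaluates `statistic` on each; reproducible
#' under a fixed seed.
#'
#' @param pool Character vector of genes to draw from (or an igraph, whose
#'   node names are used).
#' @param size Genes per draw.
#' @param n_null Number of draws (>= 100 recommended).
#' @param statistic Function taking a character vector of genes and returning
#'   a numeric scalar or fixed-length named vector.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A matrix (`n_null` rows) of statistic values.
#' @export
random_subnetwork_null <- function(pool, size, n_null, statistic, seed = NULL) {
  if (igraph::is_igraph(pool)) pool <- igraph::V(pool)$name
  if (size > length(pool)) abort("size exceeds the available gene pool")
  with_rng(seed, {
    draws <- lapply(seq_len(n_null), function(i) sample(pool, size))
    vals <- lapply(draws, statistic)
    out <- do.call(rbind, vals)
    if (is.null(colnames(out)) && ncol(out) == 1L) colnames(out) <- "statistic"
    out
  })
}

# Dynamics statistics of a gene set: mean |pairwise PCC| within each
# condition, mean |per-gene condition-mean difference|, and mean |PCC change|
# over `edges` (all pairs when edges is NULL).
dynamics_statistics <- function(genes, expr, design, edges = NULL) {
  conds <- design_conditions(design)
  sa <- intersect(design_samples(design, conds[1]), colnames(expr))
  sb <- intersect(design_samples(design, conds[2]), colnames(expr))
  A <- t(expr[genes, sa, drop = FALSE]); B <- t(expr[genes, sb, drop = FALSE])
  Ca <- suppressWarnings(cor(A, use = "pairwise.complete.obs"))
  Cb <- suppressWarnings(cor(B, use = "pairwise.complete.obs"))
  up <- upper.tri(Ca)
  if (is.null(edges)) {
    d_idx <- which(up)
  } else {
    i <- match(edges$u, genes); j <- match(edges$v, genes)
    d_idx <- (pmax(i, j) - 1L) * length(genes) + pmin(i, j)
  }
  c(mean_abs_pcc_a = mean(abs(Ca[up]), na.rm = TRUE),
    mean_abs_pcc_b = mean(abs(Cb[up]), na.rm = TRUE),
    mean_expr_diff = mean(abs(colMeans(A, na.rm = TRUE) -
                                colMeans(B, na.rm = TRUE))),
    mean_abs_dpcc = if (length(d_idx)) mean(abs(Ca[d_idx] - Cb[d_idx]),
                                            na.rm = TRUE) else NA_real_)
}

#' Module dynamics against a random-subnetwork null
#'
#' Compares the module's expression dynamics with random gene sets of equal
#' size: (a) mean absolute pairwise correlation of member genes within each
#' condition, (b) mean absolute per-gene condition-mean difference, and
#' (c) mean absolute correlation change over member interactions. Each
#' statistic gets the null mean/sd, a Z-score and an add-one empirical
#' upper-tail p-value, `p = (1 + #(null >= observed)) / (1 + n_null)`.
#'
#' @param module A `functional_module` (its edges feed statistic (c); null
#'   sets use all within-set pairs).
#' @param expr Expression matrix.
#' @param design A [sample_design()].
#' @param n_null Null draws (default 1000).
#' @param seed Integer seed for the null sampler.
#' @param pool Gene pool for null draws (default: all measured genes).
#' @return A `module_dynamics` object: tibble `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_empirical`, with `n_null`/`seed` attrs.
#' @export
module_dynamics_zscores <- function(module, expr, design, n_null = 1000,
                                    seed = 1L, pool = NULL) {
  genes <- if (inherits(module, "functional_module")) module$genes else module
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2L) abort("module needs at least 2 measured genes")
  edges <- if (inherits(module, "functional_module") && nrow(module$edges)) {
    filter(module$edges, .data$u %in% genes & .data$v %in% genes)
  } else NULL
  pool <- pool %||% rownames(expr)
  observed <- dynamics_statistics(genes, expr, design, edges = edges)
  null <- random_subnetwork_null(pool, length(genes), n_null,
    function(g) dynamics_statistics(g, expr, design), seed = seed)
  null_mean <- colMeans(null, na.rm = TRUE)
  null_sd <- apply(null, 2, sd, na.rm = TRUE)
  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd, NA_real_)
  p_emp <- vapply(seq_along(observed), function(i)
    (1 + sum(null[, i] >= observed[i], na.rm = TRUE)) / (1 + n_null),
    numeric(1))
  out <- tibble(statistic = names(observed), observed = unname(observed),
                null_mean = unname(null_mean), null_sd = unname(null_sd),
                z = unname(z), p_empirical = p_emp)
  structure(out, n_null = n_null, seed = seed,
            class = c("module_dynamics", class(out)))
}

#' @export
print.module_dynamics <- function(x, ...) {
  cat(sprintf("Module dynamics vs %d random subnetworks (seed %s):\n",
              attr(x, "n_null"), attr(x, "seed")))
  NextMethod()
}

#' Classify edge co-expression dynamics between two conditions
#'
#' Each edge is labelled by where its correlation magnitude reaches the
#' threshold: specific to one condition, `"both"`, or `"neither"`. Edges
#' missing a score in a condition are `"neither"` and flagged.
#'
#' @param scores_a,scores_b Edge-score tibbles ([score_network_edges()]) of
#'   the two conditions.
#' @param threshold Absolute-PCC cutoff (default 0.5).
#' @return An `edge_dynamics` tibble: `u`, `v`, `pcc_a`, `pcc_b`, `class`,
#'   `flagged`.
#' @export
classify_edge_dynamics <- function(scores_a, scores_b, threshold = 0.5) {
  la <- scores_a$condition[1] %||% "A"
  lb <- scores_b$condition[1] %||% "B"
  a <- select(scores_a, "u", "v", pcc_a = "pcc")
  b <- select(scores_b, "u", "v", pcc_b = "pcc")
  m <- full_join(a, b, by = c("u", "v"))
  sig_a <- !is.na(m$pcc_a) & abs(m$pcc_a) >= threshold
  sig_b <- !is.na(m$pcc_b) & abs(m$pcc_b) >= threshold
  cls <- dplyr::case_when(
    sig_a & sig_b ~ "both",
    sig_a ~ paste0(la, "-specific"),
    sig_b ~ paste0(lb, "-specific"),
    TRUE ~ "neither")
  out <- mutate(m, class = cls, flagged = is.na(.data$pcc_a) | is.na(.data$pcc_b))
  structure(out, threshold = threshold, conditions = c(la, lb),
            class = c("edge_dynamics", class(out)))
}
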
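#' Pearson correlation coefficient of two expression profiles
#'
#' Direct implementation of the sample correlation as the mean standardized
#' cross-product, `sum(z_x * z_y) / (n - 1)`, over pairwise-finite entries,
#' clipped to `[-1, 1]` against rounding. Undefined scores (fewer than 3
#' pairwise-finite entries, or a constant profile) return `NA` rather than
#' raising: ineligible edges are flagged and excluded downstream, not errors.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A correlation in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- sum((x - mean(x)) / sx * (y - mean(y)) / sy) / (n - 1)
  max(-1, min(1, r))
}

#' Two-sided significance of a Pearson correlation
#'
#' Standard r-to-t transform: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` with
#' `n - 2` degrees of freedom. `|r| = 1` is reported as `p = 0` (degenerate).
#'
#' @param pcc Correlation(s) in `[-1, 1]` (NA allowed).
#' @param n_used Number(s) of samples used (>= 3).
#' @return Two-sided p-value(s) in `[0, 1]`; `NA` where `pcc` is `NA`.
#' @export
pearson_pvalue <- function(pcc, n_used) {
  if (any(n_used < 3L, na.rm = TRUE)) abort("n_used must be >= 3")
  r2 <- pmin(pcc^2, 1)
  t <- abs(pcc) * sqrt((n_used - 2) / pmax(1 - r2, 0))
  p <- 2 * pt(-t, df = n_used - 2)
  p[is.finite(pcc) & r2 >= 1] <- 0
  p
}

#' Score every network edge with condition-specific co-expression
#'
#' Assigns each static-PIN edge the Pearson correlation of its two genes'
#' expression across the samples of one condition, with its two-sided
#' p-value. Edges with an unmeasured endpoint are excluded and reported in the
#' `"unscored"` attribute.
#'
#' @param net The static PIN, an undirected [igraph::igraph].
#' @param expr Expression matrix (genes x samples).
#' @param design A [sample_design()].
#' @param condition Condition label whose samples are used.
#' @return A tibble with columns `u`, `v`, `condition`, `pcc`, `n_used`,
#'   `p_value`, one row per scorable edge; attribute `"unscored"` holds the
#'   remaining edges.
#' @export
score_network_edges <- function(net, expr, design, condition) {
  if (!condition %in% design$condition) abort("unknown condition label")
  samples <- intersect(design_samples(design, condition), colnames(expr))
  if (length(samples) < 3L) abort("fewer than 3 measured samples in condition")
  el <- igraph::as_edgelist(net)
  edges <- canonical_edges(el[, 1], el[, 2])
  measured <- edges$u %in% rownames(expr) & edges$v %in% rownames(expr)
  unscored <- edges[!measured, , drop = FALSE]
  edges <- edges[measured, , drop = FALSE]
  X <- expr[, samples, drop = FALSE]
  n_s <- length(samples)
  used_genes <- unique(c(edges$u, edges$v))
  Xu <- X[used_genes, , drop = FALSE]
  fin <- is.finite(Xu)
  clean <- rowSums(fin) == n_s
  pcc <- rep(NA_real_, nrow(edges))
  n_used <- integer(nrow(edges))
  fast <- clean[edges$u] & clean[edges$v]
  if (any(fast)) {
    Z <- Xu[clean, , drop = FALSE]
    mu <- rowMeans(Z)
    sdv <- sqrt(rowSums((Z - mu)^2) / (n_s - 1))
    ok <- sdv > 0
    Z <- (Z - mu) / ifelse(sdv > 0, sdv, 1)
    iu <- edges$u[fast]; iv <- edges$v[fast]
    r <- rowSums(Z[iu, , drop = FALSE] * Z[iv, , drop = FALSE]) / (n_s - 1)
    r[!(ok[iu] & ok[iv])] <- NA_real_
    pcc[fast] <- pmax(-1, pmin(1, r))
    n_used[fast] <- n_s
  }
  slow <- which(!fast)
  for (i in slow) {
    xi <- Xu[edges$u[i], ]; yi <- Xu[edges$v[i], ]
    pcc[i] <- pearson_cc(xi, yi)
    n_used[i] <- sum(is.finite(xi) & is.finite(yi))
  }
  p <- rep(NA_real_, nrow(edges))
  def <- !is.na(pcc)
  p[def] <- pearson_pvalue(pcc[def], pmax(n_used[def], 3L))
  out <- tibble(u = edges$u, v = edges$v, condition = condition,
                pcc = pcc, n_used = n_used, p_value = p)
  attr(out, "unscored") <- unscored
  out
}

#' Build a co-expressed protein interaction network (CePIN)
#'
#' Retains edges whose co-expression p-value is at or below `alpha`
#' (inclusive threshold); the node set is the endpoints of retained edges.
#' Raising `alpha` can only grow the edge set (threshold monotonicity).
#'
#' @param scores Edge-score tibble from [score_network_edges()].
#' @param alpha Significance threshold in (0, 1); default 0.05.
#' @return A `cepin` object: list with `condition`, `alpha`, `graph`
#'   (igraph of retained edges) and `scores` (input plus `retained` flag).
#' @export
build_cepin <- function(scores, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  scores <- mutate(scores, retained = !is.na(.data$p_value) &
                     .data$p_value <= alpha)
  kept <- filter(scores, .data$retained)
  graph <- if (nrow(kept)) {
    igraph::graph_from_data_frame(select(kept, "u", "v"), directed = FALSE)
  } else igraph::make_empty_graph(directed = FALSE)
  structure(list(condition = scores$condition[1] %||% NA_character_,
                 alpha = alpha, graph = graph, scores = scores),
            class = "cepin")
}

#' @export
print.cepin <- function(x, ...) {
  cat(sprintf(
    "CePIN ('%s', alpha = %g): %d nodes, %d co-expressed edges of %d scored\n",
    x$condition, x$alpha, igraph::vcount(x$graph), igraph::ecount(x$graph),
    nrow(x$scores)))
  invisible(x)
}

cepin_nodes <- function(cepin) igraph::V(cepin$graph)$name %||% character()

cepin_edges <- function(cepin) {
  filter(cepin$scores, .data$retained) |> select("u", "v", "pcc", "p_value")
}

#' Structural overlap of two CePINs
#'
#' Mirrors the usual structural summary of condition-specific networks: per
#' condition the protein count, the scored static-PPI count and the CePPI
#' count, plus the pairwise overlaps.
#'
#' @param a,b `cepin` objects built from the same static PIN.
#' @return A tibble with rows for each condition and the overlap.
#' @export
network_overlap <- function(a, b) {
  ek <- function(s) edge_key(s$u, s$v)
  sa <- a$scores; sb <- b$scores
  ca <- filter(sa, .data$retained); cb <- filter(sb, .data$retained)
  na_ <- cepin_nodes(a); nb_ <- cepin_nodes(b)
  tibble(
    network = c(a$condition, b$condition, "overlap"),
    proteins = c(length(na_), length(nb_), length(intersect(na_, nb_))),
    ppis_scored = c(nrow(sa), nrow(sb), length(intersect(ek(sa), ek(sb)))),
    ceppis = c(nrow(ca), nrow(cb), length(intersect(ek(ca), ek(cb))))
  )
}
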
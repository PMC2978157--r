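#' Node-level topological measures
#'
#' Degree and local clustering coefficient are computed on the whole graph;
#' betweenness and closeness centrality are computed within the largest
#' connected component (nodes outside it carry `NA`). Conventions follow the
#' usual definitions: betweenness counts shortest paths fractionally (each
#' shortest path between a pair contributes `1/#shortest-paths`) and is
#' normalized by `choose(N, 2)`; closeness is the reciprocal of the mean
#' shortest-path length; clustering is the realized fraction of links among a
#' node's neighbours, reported as 0 (flagged) for degree < 2.
#'
#' @param net A non-empty undirected [igraph::igraph].
#' @return A tibble with columns `node`, `degree`, `betweenness`, `closeness`,
#'   `clustering`, `clustering_defined`, `in_lcc`.
#' @export
compute_topology <- function(net) {
  if (igraph::vcount(net) == 0L) abort("empty graph")
  nm <- igraph::V(net)$name
  deg <- unname(igraph::degree(net))
  cl <- unname(igraph::transitivity(net, type = "local", isolates = "zero"))
  cl_def <- deg >= 2L
  cl[!cl_def] <- 0
  lcc <- largest_connected_component(net)
  lnm <- igraph::V(lcc)$name
  N <- length(lnm)
  bc <- rep(NA_real_, length(nm))
  cc <- rep(NA_real_, length(nm))
  i <- match(lnm, nm)
  bc[i] <- if (N >= 3) unname(igraph::betweenness(lcc)) / choose(N, 2) else 0
  if (N >= 2) {
    dists <- igraph::distances(lcc)
    cc[i] <- (N - 1) / unname(rowSums(dists))
  }
  tibble(node = nm, degree = as.integer(deg), betweenness = bc,
         closeness = cc, clustering = cl, clustering_defined = cl_def,
         in_lcc = nm %in% lnm)
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Two-sided p-value for the rank-sum statistic under the permutation null,
#' `P(|W - mu| >= |w_obs - mu|)`, with midranks for ties. The exact
#' distribution is computed by a subset-sum dynamic program whenever
#' `choose(nx + ny, nx) <= exact_limit`; otherwise a normal approximation
#' with tie-corrected variance and continuity correction is used.
#'
#' @param x,y Numeric vectors (non-empty after removing NA).
#' @param exact_limit Enumeration-size cap for the exact branch.
#' @return A p-value in `[0, 1]` (1 when every value is tied across groups).
#' @export
wilcoxon_exact <- function(x, y, exact_limit = 1e6) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) abort("both groups must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  if (length(unique(c(x, y))) == 1L) return(1)
  w <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  if (choose(N, nx) <= exact_limit) {
    # distribution of the rank sum over all size-nx subsets (DP over 2*ranks,
    # which are integers even with midranks)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- matrix(0, nrow = nx + 1L, ncol = total + 1L)
    counts[1L, 1L] <- 1
    for (item in r2) {
      kmax <- nx
      for (k in seq(min(kmax, nx), 1L)) {
        shifted <- c(rep(0, item), counts[k, seq_len(total + 1L - item)])
        counts[k + 1L, ] <- counts[k + 1L, ] + shifted
      }
    }
    sums <- (seq_len(total + 1L) - 1L) / 2
    dist_w <- counts[nx + 1L, ]
    extreme <- abs(sums - mu) >= abs(w - mu) - 1e-9
    sum(dist_w[extreme]) / choose(N, nx)
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
    min(1, 2 * pnorm(-max(z, 0)))
  }
}

#' Call significantly differentially expressed genes (SDEGs)
#'
#' Per-gene two-sided Wilcoxon rank-sum test of the positive condition against
#' the other; genes at `p <= alpha` are flagged, with direction from the
#' comparison of condition means (up = higher in the positive condition).
#'
#' @param expr Expression matrix (genes x samples).
#' @param design A [sample_design()].
#' @param alpha Significance threshold (default 0.05).
#' @return A tibble `gene`, `p_value`, `sdeg`, `direction`; genes lacking a
#'   finite value in either condition are skipped and listed in the
#'   `"skipped"` attribute.
#' @export
call_sdegs <- function(expr, design, alpha = 0.05) {
  conds <- design_conditions(design)
  sa <- intersect(design_samples(design, conds[1]), colnames(expr))
  sb <- intersect(design_samples(design, conds[2]), colnames(expr))
  A <- expr[, sa, drop = FALSE]; B <- expr[, sb, drop = FALSE]
  ok <- rowSums(is.finite(A)) >= 1L & rowSums(is.finite(B)) >= 1L
  skipped <- rownames(expr)[!ok]
  genes <- rownames(expr)[ok]
  p <- vapply(genes, function(g) wilcoxon_exact(A[g, ], B[g, ]), numeric(1))
  flag <- p <= alpha
  dirn <- ifelse(flag,
                 ifelse(rowMeans(A[genes, , drop = FALSE], na.rm = TRUE) >
                          rowMeans(B[genes, , drop = FALSE], na.rm = TRUE),
                        "up", "down"),
                 NA_character_)
  out <- tibble(gene = genes, p_value = unname(p), sdeg = unname(flag),
                direction = unname(dirn))
  attr(out, "skipped") <- skipped
  out
}

#' Compare topological properties between two node groups
#'
#' For each topological measure, reports the group means and a two-sided
#' rank-sum p-value -- the usual SDEG vs non-SDEG comparison table.
#'
#' @param topo Output of [compute_topology()].
#' @param groups Named logical vector (or character vector of member nodes)
#'   defining group membership over `topo$node`.
#' @param group_labels Length-2 labels for members / non-members.
#' @return A tibble `property`, `mean_<g1>`, `mean_<g2>`, `p_value`.
#' @export
compare_topology_by_group <- function(topo, groups,
                                      group_labels = c("in_group", "out_group")) {
  member <- if (is.character(groups)) topo$node %in% groups else
    as.logical(groups[topo$node])
  member[is.na(member)] <- FALSE
  if (!any(member) || all(member)) abort("both groups must be non-empty")
  props <- c("degree", "betweenness", "closeness", "clustering")
  rows <- lapply(props, function(pr) {
    a <- topo[[pr]][member]; b <- topo[[pr]][!member]
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    # a property can be undefined for a whole group (e.g. centralities of
    # nodes outside the LCC); report NA rather than fail
    p <- if (length(a) && length(b)) wilcoxon_exact(a, b) else NA_real_
    tibble(property = pr,
           m1 = if (length(a)) mean(a) else NA_real_,
           m2 = if (length(b)) mean(b) else NA_real_,
           p_value = p)
  })
  out <- bind_rows(rows)
  names(out)[2:3] <- paste0("mean_", group_labels)
  out
}

#' Call hub nodes of a CePIN
#'
#' Hubs are nodes whose degree is strictly greater than the
#' `(100 - percentile)`-th degree quantile (type-7 linear interpolation); the
#' realized threshold is attached as an attribute. With all degrees equal the
#' hub set is empty (strict inequality).
#'
#' @param cepin A `cepin` object or an [igraph::igraph].
#' @param percentile Top percentage of the degree distribution (default 1).
#' @return Character vector of hub nodes, with attribute `"threshold"`.
#' @export
call_hubs <- function(cepin, percentile = 1) {
  if (!(percentile > 0 && percentile < 100)) abort("percentile must be in (0, 100)")
  g <- if (inherits(cepin, "cepin")) cepin$graph else cepin
  deg <- igraph::degree(g)
  thr <- unname(quantile(deg, 1 - percentile / 100, type = 7))
  hubs <- names(deg)[deg > thr]
  if (!length(hubs) && length(unique(deg)) == 1L) {
    inform("all degrees equal; hub set is empty under the strict rule")
  }
  structure(hubs, threshold = thr)
}

#' Association between CePIN degree and differential expression
#'
#' Splits nodes into high- (top 50%) and low-degree halves at the median,
#' reports the SDEG proportion in each half, and tests the 2x2 association
#' with a two-sided Fisher exact test; also returns a binned degree-vs-SDEG
#' proportion curve.
#'
#' @param cepin A `cepin` object (or igraph).
#' @param sdegs SDEG table from [call_sdegs()].
#' @param breaks Bin edges for the degree curve (default
#'   `c(0, 1, 2, 3, 5, 10, 20, 50, Inf)`).
#' @return An `sdeg_association` object: list with `table` (2x2), `p_value`,
#'   `proportions`, and `curve` tibble.
#' @export
sdeg_degree_association <- function(cepin, sdegs,
                                    breaks = c(0, 1, 2, 3, 5, 10, 20, 50, Inf)) {
  g <- if (inherits(cepin, "cepin")) cepin$graph else cepin
  deg <- igraph::degree(g)
  if (length(unique(deg)) < 2L) abort("fewer than 2 distinct degrees")
  flag <- setNames(sdegs$sdeg, sdegs$gene)[names(deg)]
  keep <- !is.na(flag)
  deg <- deg[keep]; flag <- flag[keep]
  high <- deg > median(deg)
  if (!any(high) || all(high)) {
    high <- rank(deg, ties.method = "first") > length(deg) / 2
  }
  tab <- table(degree = factor(ifelse(high, "high", "low"), c("high", "low")),
               sdeg = factor(flag, c(TRUE, FALSE)))
  p <- fisher.test(tab)$p.value
  props <- c(high = mean(flag[high]), low = mean(flag[!high]))
  bin <- cut(deg, breaks = breaks, include.lowest = FALSE)
  curve <- tibble(bin = bin, deg = deg, sdeg = flag) |>
    group_by(.data$bin) |>
    summarise(n = dplyr::n(), mean_degree = mean(.data$deg),
              sdeg_prop = mean(.data$sdeg), .groups = "drop")
  structure(list(table = tab, p_value = p, proportions = props, curve = curve),
            class = "sdeg_association")
}

#' @export
print.sdeg_association <- function(x, ...) {
  cat(sprintf(
    "SDEG proportion: high-degree %.3f vs low-degree %.3f (Fisher p = %.3g)\n",
    x$proportions["high"], x$proportions["low"], x$p_value))
  invisible(x)
}
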
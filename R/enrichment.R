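#' Hypergeometric enrichment probability
#'
#' Probability of observing `k` or more annotated members in a size-`m`
#' draw, where the background holds `N` items of which `n` carry the
#' annotation: `P(X >= k)` with `P(X = j) = C(m,j) C(N-m, n-j) / C(N,n)`.
#' Computed exactly in log space (log-gamma binomials), never by normal
#' approximation. `mode = "point"` returns the single term `P(X = k)`.
#'
#' @param N Background size.
#' @param m Selected-set size (e.g. CePIN genes) in the background.
#' @param n Annotated count in the background.
#' @param k Annotated count in the selected set.
#' @param mode `"tail"` (default, enrichment direction) or `"point"`.
#' @return A probability in `[0, 1]`.
#' @export
hypergeometric_tail <- function(N, m, n, k, mode = c("tail", "point")) {
  mode <- match.arg(mode)
  if (any(c(N, m, n, k) < 0) || k > n || n > N || m > N || k > m) {
    abort("require 0 <= k <= min(m, n) and m, n <= N")
  }
  j <- if (mode == "tail") seq(k, min(m, n)) else k
  lg <- lchoose(m, j) + lchoose(N - m, n - j) - lchoose(N, n)
  lg <- lg[is.finite(lg)]
  if (!length(lg)) return(0)
  mx <- max(lg)
  min(1, exp(mx) * sum(exp(lg - mx)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, `q_(i) = min_{j >= i} p_(j) * M / j` capped at 1,
#' returned in input order (delegates to [stats::p.adjust()]).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Gene-level functional enrichment of a CePIN
#'
#' For each ontology term with at least one background gene, tests whether the
#' CePIN's genes are enriched for the term against the background (annotated
#' genes present in both the expression data and the static PIN), with BH
#' adjustment across all tested terms.
#'
#' @param cepin A `cepin` object (or a character vector of selected genes).
#' @param ann A propagated [annotation_map()].
#' @param background Character vector of background genes.
#' @param dag Optional [ontology_dag()] used to attach term names and levels.
#' @param use Use `"propagated"` (default) or `"direct"` annotations.
#' @return A tibble `term`, (`name`, `level`,) `N`, `m`, `n`, `k`, `p_raw`,
#'   `p_adj`, sorted by `p_raw`.
#' @export
gene_enrichment <- function(cepin, ann, background, dag = NULL,
                            use = c("propagated", "direct")) {
  use <- match.arg(use)
  if (!length(background)) abort("empty background")
  sel_genes <- if (inherits(cepin, "cepin")) cepin_nodes(cepin) else cepin
  sel <- intersect(sel_genes, background)
  by_term <- genes_per_term(ann, background, use = use)
  N <- length(background); m <- length(sel)
  n <- lengths(by_term)
  k <- vapply(by_term, function(g) length(intersect(g, sel)), integer(1))
  p_raw <- vapply(seq_along(n), function(i)
    hypergeometric_tail(N, m, n[[i]], k[[i]]), numeric(1))
  out <- tibble(term = names(by_term), N = N, m = m,
                n = unname(n), k = unname(k),
                p_raw = p_raw, p_adj = bh_adjust(p_raw))
  if (!is.null(dag)) {
    out <- left_join(out, dplyr::rename(dag$terms, term = "id"), by = "term") |>
      select("term", "name", "level", dplyr::everything(), -"namespace")
  }
  arrange(out, .data$p_raw)
}

#' Dyad-level (edge) functional enrichment of a CePIN
#'
#' A functional dyad is a co-expressed interaction whose two proteins share
#' the annotation under test. For each term, counts dyads among the CePPIs
#' (`ke`) and among the static-PIN edges restricted to the annotated
#' background (`ne`), and tests `P(X >= ke)` for a draw of `me` CePPIs out of
#' `Ne` background edges; BH adjustment across the tested terms. Terms with no
#' background dyad get `p_raw = 1` and `no_dyad = TRUE`.
#'
#' @param cepin A `cepin` object.
#' @param ann A propagated [annotation_map()].
#' @param static The static PIN ([igraph::igraph]).
#' @param terms Terms to test (typically the gene-level significant ones).
#' @param background Background gene set (as in [gene_enrichment()]).
#' @inheritParams gene_enrichment
#' @return A tibble `term`, (`name`, `level`,) `Ne`, `me`, `ne`, `ke`,
#'   `p_raw`, `p_adj`, `no_dyad`, sorted by `p_raw`.
#' @export
dyad_enrichment <- function(cepin, ann, static, terms, background, dag = NULL,
                            use = c("propagated", "direct")) {
  use <- match.arg(use)
  el <- igraph::as_edgelist(static)
  st <- canonical_edges(el[, 1], el[, 2]) |>
    filter(.data$u %in% background & .data$v %in% background)
  ce <- cepin_edges(cepin) |>
    filter(.data$u %in% background & .data$v %in% background)
  Ne <- nrow(st); me <- nrow(ce)
  by_term <- genes_per_term(ann, background, use = use)
  rows <- lapply(terms, function(t) {
    gs <- by_term[[t]] %||% character()
    ne <- sum(st$u %in% gs & st$v %in% gs)
    ke <- sum(ce$u %in% gs & ce$v %in% gs)
    if (ne == 0L) {
      tibble(term = t, Ne = Ne, me = me, ne = 0L, ke = 0L,
             p_raw = 1, no_dyad = TRUE)
    } else {
      tibble(term = t, Ne = Ne, me = me, ne = ne, ke = ke,
             p_raw = hypergeometric_tail(Ne, me, ne, ke), no_dyad = FALSE)
    }
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(term = character(), Ne = integer(), me = integer(),
                  ne = integer(), ke = integer(), p_raw = numeric(),
                  p_adj = numeric(), no_dyad = logical()))
  }
  out$p_adj <- bh_adjust(out$p_raw)
  if (!is.null(dag)) {
    out <- left_join(out, dplyr::rename(dag$terms, term = "id"), by = "term") |>
      select("term", "name", "level", dplyr::everything(), -"namespace")
  }
  arrange(out, .data$p_raw)
}
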
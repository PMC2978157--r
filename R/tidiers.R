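#' Tidy a CePIN into its edge-score table
#' @param x A `cepin` object.
#' @param ... Unused.
#' @return The edge-score tibble with the `retained` flag.
#' @export
tidy.cepin <- function(x, ...) as_tibble(x$scores)

#' One-row summary of a CePIN
#' @inheritParams tidy.cepin
#' @return Tibble `condition`, `alpha`, `n_nodes`, `n_ceppis`, `n_scored`.
#' @export
glance.cepin <- function(x, ...) {
  tibble(condition = x$condition, alpha = x$alpha,
         n_nodes = igraph::vcount(x$graph),
         n_ceppis = igraph::ecount(x$graph),
         n_scored = nrow(x$scores))
}

#' Tidy a functional module into its CePPI table
#' @param x A `functional_module`.
#' @param ... Unused.
#' @export
tidy.functional_module <- function(x, ...) as_tibble(x$edges)

#' One-row summary of a functional module
#' @inheritParams tidy.functional_module
#' @export
glance.functional_module <- function(x, ...) {
  tibble(term = x$term, name = x$name, level = x$level,
         condition = x$condition, n_genes = length(x$genes),
         n_ceppis = nrow(x$edges), gene_p_adj = x$gene_p_adj,
         dyad_p_adj = x$dyad_p_adj)
}

#' One-row summary of a root-split classification
#' @param x A `module_classification`.
#' @param ... Unused.
#' @export
glance.module_classification <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
         sensitivity = x$sensitivity, specificity = x$specificity,
         accuracy = x$accuracy)
}

#' ROC points of a `roc_result`
#' @param x A `roc_result`.
#' @param ... Unused.
#' @export
tidy.roc_result <- function(x, ...) x$points

#' One-row AUC summary of a `roc_result`
#' @inheritParams tidy.roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, orientation = x$orientation,
         n_points = nrow(x$points))
}

#' Dynamics statistics of a module as a tibble
#' @param x A `module_dynamics`.
#' @param ... Unused.
#' @export
tidy.module_dynamics <- function(x, ...) as_tibble(unclass(x))

#' Per-module summary of a comparative run
#' @param x A `cepin_comparison`.
#' @param ... Unused.
#' @return One row per exclusive module with counts, enrichment p-values and
#'   (when evaluated) accuracy/AUC.
#' @export
tidy.cepin_comparison <- function(x, ...) {
  rows <- list()
  for (cc in x$conditions) {
    for (i in seq_along(x$modules[[cc]])) {
      g <- glance(x$modules[[cc]][[i]])
      if (!is.null(x$evaluations)) {
        ev <- x$evaluations[[cc]][[i]]
        g$accuracy <- ev$classification$accuracy
        g$auc <- ev$roc$auc
      }
      rows[[length(rows) + 1L]] <- g
    }
  }
  if (!length(rows)) {
    return(tibble(term = character(), name = character(), level = integer(),
                  condition = character(), n_genes = integer(),
                  n_ceppis = integer(), gene_p_adj = numeric(),
                  dyad_p_adj = numeric()))
  }
  bind_rows(rows)
}

#' Stage counters of a comparative run
#' @inheritParams tidy.cepin_comparison
#' @export
glance.cepin_comparison <- function(x, ...) {
  ca <- x$conditions[1]; cb <- x$conditions[2]
  tibble(
    condition_a = ca, condition_b = cb,
    edges_scored_a = nrow(x$scores[[ca]]),
    edges_scored_b = nrow(x$scores[[cb]]),
    ceppis_a = igraph::ecount(x$cepins[[ca]]$graph),
    ceppis_b = igraph::ecount(x$cepins[[cb]]$graph),
    sdegs = sum(x$sdegs$sdeg),
    terms_tested_a = nrow(x$gene_enrichment[[ca]]),
    terms_tested_b = nrow(x$gene_enrichment[[cb]]),
    candidates_a = length(x$candidates[[ca]]),
    candidates_b = length(x$candidates[[cb]]),
    exclusive_a = length(x$exclusive[[ca]]),
    exclusive_b = length(x$exclusive[[cb]])
  )
}
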
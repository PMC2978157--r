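#' Candidate functional terms of one condition
#'
#' A term is a candidate when it is significant in both the gene-level and the
#' dyad-level enrichment (BH-adjusted p at or below `alpha` in each family):
#' only subnetworks functionally homogeneous in genes *and* interactions are
#' kept.
#'
#' @param gene_enr Tibble from [gene_enrichment()].
#' @param dyad_enr Tibble from [dyad_enrichment()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Character vector of candidate term ids.
#' @export
candidate_functions <- function(gene_enr, dyad_enr, alpha = 0.05) {
  g <- gene_enr$term[gene_enr$p_adj <= alpha]
  d <- dyad_enr$term[dyad_enr$p_adj <= alpha]
  intersect(g, d)
}

#' Condition-exclusive functional terms
#'
#' The set difference `cand_a \ cand_b`: terms that are candidates in
#' condition A but not in condition B.
#'
#' @param cand_a,cand_b Candidate term sets ([candidate_functions()]).
#' @return Character vector of terms exclusive to A.
#' @export
exclusive_functions <- function(cand_a, cand_b) setdiff(cand_a, cand_b)

#' Keep terms at or below a functional-specificity depth
#'
#' Retains terms whose ontology level is at least `min_level` (root = level 1);
#' shallow, unspecific terms are dropped.
#'
#' @param terms Character vector of term ids.
#' @param dag An [ontology_dag()].
#' @param min_level Minimum level kept, inclusive (default 5).
#' @return The filtered term vector.
#' @export
filter_by_level <- function(terms, dag, min_level = 5) {
  lv <- term_level(dag, terms)
  if (anyNA(lv)) {
    abort(paste0("term(s) not in ontology: ",
                 paste(terms[is.na(lv)], collapse = ", ")))
  }
  terms[lv >= min_level]
}

#' Assemble a functional module from a CePIN
#'
#' Member genes are the term-annotated genes among the CePIN's nodes; member
#' CePPIs are the retained edges with both endpoints annotated.
#'
#' @param term Ontology term id.
#' @param cepin A `cepin` object.
#' @param ann A propagated [annotation_map()].
#' @param dag Optional [ontology_dag()] for name/level.
#' @param gene_enr,dyad_enr Optional enrichment tibbles; the term's adjusted
#'   p-values are copied into the module when supplied.
#' @inheritParams gene_enrichment
#' @return A `functional_module` object: list with `term`, `name`, `level`,
#'   `condition`, `genes`, `edges` (tibble `u`,`v`,`pcc`,`p_value`),
#'   `gene_p_adj`, `dyad_p_adj`.
#' @export
assemble_module <- function(term, cepin, ann, dag = NULL,
                            gene_enr = NULL, dyad_enr = NULL,
                            use = c("propagated", "direct")) {
  use <- match.arg(use)
  src <- if (use == "propagated") ann$propagated else ann$direct
  if (is.null(src)) abort("annotations not propagated")
  annotated <- names(src)[vapply(src, function(ts) term %in% ts, logical(1))]
  genes <- intersect(cepin_nodes(cepin), annotated)
  if (!length(genes)) abort(sprintf("term '%s' annotates no CePIN gene", term))
  edges <- cepin_edges(cepin) |>
    filter(.data$u %in% genes & .data$v %in% genes)
  if (!nrow(edges)) inform(sprintf("module '%s' has no internal CePPI", term))
  pick <- function(enr) {
    if (is.null(enr)) return(NA_real_)
    i <- match(term, enr$term)
    if (is.na(i)) NA_real_ else enr$p_adj[i]
  }
  structure(list(
    term = term,
    name = if (!is.null(dag)) dag$terms$name[match(term, dag$terms$id)] else NA_character_,
    level = if (!is.null(dag)) term_level(dag, term) else NA_integer_,
    condition = cepin$condition,
    genes = genes,
    edges = edges,
    gene_p_adj = pick(gene_enr),
    dyad_p_adj = pick(dyad_enr)
  ), class = "functional_module")
}

#' @export
print.functional_module <- function(x, ...) {
  cat(sprintf(
    "Functional module %s ('%s', level %s, condition '%s'): %d genes, %d CePPIs\n",
    x$term, x$name, x$level, x$condition, length(x$genes), nrow(x$edges)))
  if (is.finite(x$gene_p_adj)) {
    cat(sprintf("  gene p_adj = %.3g, dyad p_adj = %.3g\n",
                x$gene_p_adj, x$dyad_p_adj))
  }
  invisible(x)
}
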
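#' Run the full two-condition comparative analysis in memory
#'
#' Executes the complete workflow: per-condition edge scoring, CePIN
#' construction, structural overlap, SDEG and topology analyses, gene- and
#' dyad-level enrichment, candidate and exclusive functional sets (both
#' directions), the ontology-level filter, module assembly, and (optionally)
#' per-module classification, ROC/AUC, dynamics Z-scores and the edge-dynamics
#' classification.
#'
#' @param expr Expression matrix (genes x samples).
#' @param design A [sample_design()]; its positive condition is "condition A".
#' @param pin Static PIN ([igraph::igraph]).
#' @param dag An [ontology_dag()].
#' @param ann An [annotation_map()] (propagated on the fly if needed).
#' @param alpha_edge Edge co-expression significance threshold (default 0.05).
#' @param alpha_sdeg SDEG threshold (default 0.05).
#' @param alpha_enrich BH-adjusted enrichment threshold (default 0.05).
#' @param min_go_level Minimum ontology level of a module (default 5).
#' @param hub_percentile Top degree percentage for hub calling (default 1).
#' @param edge_dyn_threshold |PCC| cutoff for edge-dynamics classes (0.5).
#' @param n_null Null draws for module dynamics (default 1000).
#' @param seed Seed for the dynamics null sampler.
#' @param topology Compute topology/hub/SDEG-association analyses.
#' @param evaluate Evaluate assembled modules (classification, ROC, dynamics).
#' @param use_annotations `"propagated"` or `"direct"` for enrichment counts.
#' @return A `cepin_comparison` list; see the elements' own accessors and
#'   [glance.cepin_comparison()].
#' @export
run_comparison <- function(expr, design, pin, dag, ann,
                           alpha_edge = 0.05, alpha_sdeg = 0.05,
                           alpha_enrich = 0.05, min_go_level = 5,
                           hub_percentile = 1, edge_dyn_threshold = 0.5,
                           n_null = 1000, seed = 1L,
                           topology = TRUE, evaluate = TRUE,
                           use_annotations = c("propagated", "direct")) {
  use_annotations <- match.arg(use_annotations)
  if (is.null(ann$propagated)) ann <- propagate_annotations(ann, dag)
  conds <- design_conditions(design)
  scores <- lapply(conds, function(cc) score_network_edges(pin, expr, design, cc))
  names(scores) <- conds
  cepins <- lapply(scores, build_cepin, alpha = alpha_edge)
  overlap <- network_overlap(cepins[[1]], cepins[[2]])
  sdegs <- call_sdegs(expr, design, alpha = alpha_sdeg)
  topo <- hubs <- topo_compare <- assoc <- NULL
  if (topology) {
    topo <- lapply(cepins, function(cp) {
      if (igraph::ecount(cp$graph) == 0L) return(NULL)
      compute_topology(cp$graph)
    })
    hubs <- lapply(cepins, function(cp) {
      if (igraph::vcount(cp$graph) == 0L) return(character())
      call_hubs(cp, percentile = hub_percentile)
    })
    sdeg_genes <- sdegs$gene[sdegs$sdeg]
    topo_compare <- lapply(topo, function(tt) {
      if (is.null(tt)) return(NULL)
      memb <- tt$node %in% sdeg_genes
      if (!any(memb) || all(memb)) return(NULL)
      compare_topology_by_group(tt, sdeg_genes,
                                group_labels = c("sdeg", "non_sdeg"))
    })
    assoc <- lapply(cepins, function(cp) {
      deg <- igraph::degree(cp$graph)
      if (length(unique(deg)) < 2L) return(NULL)
      sdeg_degree_association(cp, sdegs)
    })
  }
  annotated <- names(if (use_annotations == "propagated") ann$propagated else ann$direct)
  background <- Reduce(intersect,
                       list(annotated, rownames(expr), igraph::V(pin)$name))
  gene_enr <- lapply(cepins, gene_enrichment, ann = ann,
                     background = background, dag = dag, use = use_annotations)
  dyad_enr <- lapply(conds, function(cc) {
    sig <- gene_enr[[cc]]$term[gene_enr[[cc]]$p_adj <= alpha_enrich]
    dyad_enrichment(cepins[[cc]], ann, pin, sig, background, dag = dag,
                    use = use_annotations)
  })
  names(dyad_enr) <- conds
  candidates <- lapply(conds, function(cc)
    candidate_functions(gene_enr[[cc]], dyad_enr[[cc]], alpha = alpha_enrich))
  names(candidates) <- conds
  exclusive <- list(
    exclusive_functions(candidates[[1]], candidates[[2]]),
    exclusive_functions(candidates[[2]], candidates[[1]]))
  names(exclusive) <- conds
  exclusive <- lapply(exclusive, filter_by_level, dag = dag,
                      min_level = min_go_level)
  modules <- lapply(conds, function(cc) {
    lapply(exclusive[[cc]], function(t)
      assemble_module(t, cepins[[cc]], ann, dag = dag,
                      gene_enr = gene_enr[[cc]], dyad_enr = dyad_enr[[cc]],
                      use = use_annotations))
  })
  names(modules) <- conds
  evaluations <- NULL
  if (evaluate) {
    pool <- intersect(rownames(expr), igraph::V(pin)$name)
    evaluations <- lapply(conds, function(cc) {
      lapply(modules[[cc]], function(mod) {
        act <- module_activity(mod, expr)
        list(module = mod$term,
             activity = act,
             classification = classify_by_clustering(mod, expr, design),
             roc = roc_auc(act, design),
             dynamics = if (length(mod$genes) >= 2L)
               module_dynamics_zscores(mod, expr, design, n_null = n_null,
                                       seed = seed, pool = pool) else NULL)
      })
    })
    names(evaluations) <- conds
  }
  edge_dyn <- classify_edge_dynamics(scores[[1]], scores[[2]],
                                     threshold = edge_dyn_threshold)
  structure(list(
    conditions = conds, scores = scores, cepins = cepins, overlap = overlap,
    sdegs = sdegs, topology = topo, hubs = hubs, topo_compare = topo_compare,
    sdeg_association = assoc, background = background,
    gene_enrichment = gene_enr, dyad_enrichment = dyad_enr,
    candidates = candidates, exclusive = exclusive, modules = modules,
    evaluations = evaluations, edge_dynamics = edge_dyn,
    params = list(alpha_edge = alpha_edge, alpha_sdeg = alpha_sdeg,
                  alpha_enrich = alpha_enrich, min_go_level = min_go_level,
                  hub_percentile = hub_percentile,
                  edge_dyn_threshold = edge_dyn_threshold,
                  n_null = n_null, seed = seed)
  ), class = "cepin_comparison")
}

#' @export
print.cepin_comparison <- function(x, ...) {
  ca <- x$conditions[1]; cb <- x$conditions[2]
  cat(sprintf("Comparative CePIN analysis: '%s' (positive) vs '%s'\n", ca, cb))
  print(x$overlap)
  cat(sprintf("Candidate terms: %d (%s), %d (%s); exclusive modules: %d / %d\n",
              length(x$candidates[[ca]]), ca, length(x$candidates[[cb]]), cb,
              length(x$exclusive[[ca]]), length(x$exclusive[[cb]])))
  invisible(x)
}

#' Pipeline configuration for file-based runs
#'
#' @param expression,design,edges,ontology,annotations Input file paths
#'   (expression TSV, design TSV, edge-list TSV, OBO, annotation TSV).
#' @param out_dir Output directory for stage results.
#' @param annotation_format `"tsv"` or `"gaf"`.
#' @param positive Positive condition label (default: first seen in design).
#' @inheritParams run_comparison
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(expression, design, edges, ontology, annotations,
                            out_dir, annotation_format = "tsv",
                            positive = NULL,
                            alpha_edge = 0.05, alpha_sdeg = 0.05,
                            alpha_enrich = 0.05, min_go_level = 5,
                            hub_percentile = 1, edge_dyn_threshold = 0.5,
                            n_null = 1000, seed = 1L) {
  stopifnot(alpha_edge > 0, alpha_edge < 1, alpha_sdeg > 0, alpha_sdeg < 1,
            alpha_enrich > 0, alpha_enrich < 1, min_go_level >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the comparative analysis from input files and write all stage outputs
#'
#' File-based orchestration of [run_comparison()]: reads the five inputs,
#' runs every stage, and writes per-stage TSV/JSON outputs plus a run manifest
#' (configuration and seed) into `out_dir`. Any stage failure aborts with a
#' stage-named error and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config A [pipeline_config()].
#' @return The `cepin_comparison` result, invisibly.
#' @export
run_full_comparison <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(out, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  inputs <- stage("read_inputs", {
    expr <- read_expression_table(config$expression)
    design <- read_sample_design(config$design, positive = config$positive)
    pin <- read_edge_list(config$edges, quiet = TRUE)
    dag <- read_ontology_obo(config$ontology)
    ann <- read_annotations(config$annotations, dag = dag,
                            format = config$annotation_format)
    list(expr = expr, design = design, pin = pin, dag = dag, ann = ann)
  })
  res <- stage("run_comparison", with(inputs, run_comparison(
    expr, design, pin, dag, ann,
    alpha_edge = config$alpha_edge, alpha_sdeg = config$alpha_sdeg,
    alpha_enrich = config$alpha_enrich, min_go_level = config$min_go_level,
    hub_percentile = config$hub_percentile,
    edge_dyn_threshold = config$edge_dyn_threshold,
    n_null = config$n_null, seed = config$seed)))
  stage("write_outputs", write_comparison_outputs(res, out, config))
  invisible(res)
}

fmt_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 12, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_comparison_outputs <- function(res, out, config) {
  conds <- res$conditions
  for (cc in conds) {
    fmt_tsv(res$cepins[[cc]]$scores, file.path(out, sprintf("edge_scores_%s.tsv", cc)))
    if (!is.null(res$topology[[cc]])) {
      tt <- res$topology[[cc]]
      tt$is_hub <- tt$node %in% res$hubs[[cc]]
      fmt_tsv(tt, file.path(out, sprintf("topology_%s.tsv", cc)))
    }
    fmt_tsv(res$gene_enrichment[[cc]],
            file.path(out, sprintf("gene_enrichment_%s.tsv", cc)))
    fmt_tsv(res$dyad_enrichment[[cc]],
            file.path(out, sprintf("dyad_enrichment_%s.tsv", cc)))
    cp <- res$cepins[[cc]]
    if (igraph::ecount(cp$graph) > 0L) {
      write_network(cp$graph, file.path(out, sprintf("cepin_%s.tsv", cc)),
                    format = "tsv", edge_attrs = cepin_edges(cp))
    }
  }
  fmt_tsv(res$overlap, file.path(out, "overlap.tsv"))
  fmt_tsv(res$sdegs, file.path(out, "sdeg.tsv"))
  fmt_tsv(res$edge_dynamics, file.path(out, "edge_dynamics.tsv"))
  mods <- lapply(conds, function(cc) lapply(res$modules[[cc]], function(m)
    list(term = m$term, name = m$name, level = m$level, condition = m$condition,
         n_genes = length(m$genes), n_ceppis = nrow(m$edges),
         gene_p_adj = m$gene_p_adj, dyad_p_adj = m$dyad_p_adj,
         genes = m$genes)))
  names(mods) <- conds
  jsonlite::write_json(mods, file.path(out, "modules.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(res$evaluations)) {
    ev <- lapply(conds, function(cc) lapply(res$evaluations[[cc]], function(e)
      list(module = e$module,
           classification = glance(e$classification),
           auc = e$roc$auc,
           dynamics = if (!is.null(e$dynamics)) as.data.frame(e$dynamics))))
    names(ev) <- conds
    jsonlite::write_json(ev, file.path(out, "evaluation.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  cfg <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(
    list(config = cfg, counters = as.list(glance(res))),
    file.path(out, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA, force = TRUE)
  invisible(out)
}
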
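#' Describe a planted functional term for the synthetic generator
#'
#' @param id Term id.
#' @param size Number of member genes.
#' @param rho_a,rho_b Target within-condition pairwise expression correlation
#'   of the members in each condition, in `[0, 1)` (one-factor model).
#' @param shift Mean expression shift added to members in the positive
#'   condition (planted differential expression).
#' @param level Ontology level at which the term is placed (default 6).
#' @return A `planted_term` list.
#' @export
planted_term <- function(id, size, rho_a, rho_b, shift = 0, level = 6L) {
  stopifnot(rho_a >= 0, rho_a < 1, rho_b >= 0, rho_b < 1, size >= 2, level >= 2)
  structure(list(id = id, size = as.integer(size), rho_a = rho_a,
                 rho_b = rho_b, shift = shift, level = as.integer(level)),
            class = "planted_term")
}

#' Specification of a synthetic two-condition study
#'
#' Defines the synthetic study conditions: a random static PIN, a small
#' ontology with decoy terms, and a two-condition expression matrix in which
#' each planted term's members follow a one-factor Gaussian model
#' `x = sqrt(rho_c) * f_sample + sqrt(1 - rho_c) * eps` per condition, so the
#' expected within-condition pairwise correlation is `rho_c`. The defaults are
#' a desk-scale study: 300 genes, 800 interactions, 15 + 15 samples, one
#' condition-A-exclusive co-expression term (rho 0.8 vs 0, with a 1.5 mean
#' shift) and one both-condition term (rho 0.8 in each condition, with
#' independent per-condition factors, i.e. rewired co-expression).
#'
#' @param n_genes,n_edges Size of the static PIN (`n_edges >= n_genes - 1`; a
#'   random spanning tree guarantees a connected network).
#' @param samples_per_condition Integer pair, samples in conditions A and B
#'   (each >= 3).
#' @param planted_terms List of [planted_term()]s (possibly empty for a null
#'   study); member sets are disjoint, assigned in order.
#' @param sdeg_shift Default mean shift used by the default planted terms.
#' @param noise_sd Standard deviation scaling of the idiosyncratic noise.
#' @param ontology_depth Depth of the generated ontology (>= max planted
#'   level).
#' @param decoy_size Genes per decoy term (matched to planted sizes by
#'   default).
#' @param seed Integer seed; every generator output is a pure function of the
#'   spec, including this seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_genes = 300L, n_edges = 800L,
                           samples_per_condition = c(15L, 15L),
                           planted_terms = NULL,
                           sdeg_shift = 1.5, noise_sd = 1,
                           ontology_depth = 6L, decoy_size = 20L,
                           seed = 1L) {
  if (is.null(planted_terms)) {
    planted_terms <- list(
      planted_term("GO:9100001", 20L, rho_a = 0.8, rho_b = 0,
                   shift = sdeg_shift, level = 6L),
      planted_term("GO:9100002", 20L, rho_a = 0.8, rho_b = 0.8,
                   shift = 0, level = 6L))
  }
  sizes <- vapply(planted_terms, `[[`, integer(1), "size")
  if (sum(sizes) > n_genes) abort("planted members exceed n_genes")
  if (n_edges < n_genes - 1L) abort("n_edges too small for a connected PIN")
  if (n_edges > choose(n_genes, 2)) abort("n_edges exceeds the complete graph")
  if (any(samples_per_condition < 3L)) abort("need >= 3 samples per condition")
  lv <- vapply(planted_terms, `[[`, integer(1), "level")
  if (length(lv) && max(lv) > ontology_depth) {
    abort("ontology_depth smaller than a planted term's level")
  }
  structure(list(n_genes = as.integer(n_genes), n_edges = as.integer(n_edges),
                 samples_per_condition = as.integer(samples_per_condition),
                 planted_terms = planted_terms, sdeg_shift = sdeg_shift,
                 noise_sd = noise_sd, ontology_depth = as.integer(ontology_depth),
                 decoy_size = as.integer(decoy_size), seed = as.integer(seed)),
            class = "synthetic_spec")
}

spec_genes <- function(spec) sprintf("G%04d", seq_len(spec$n_genes))

spec_members <- function(spec) {
  genes <- spec_genes(spec)
  offset <- 0L
  out <- list()
  for (t in spec$planted_terms) {
    out[[t$id]] <- genes[(offset + 1L):(offset + t$size)]
    offset <- offset + t$size
  }
  out
}

# Random recursive tree over `nodes` (connected, uniform parent choice).
random_tree_edges <- function(nodes) {
  n <- length(nodes)
  if (n < 2L) return(tibble(u = character(), v = character()))
  p <- sample(nodes)
  parent <- vapply(2:n, function(i) p[sample.int(i - 1L, 1L)], character(1))
  canonical_edges(parent, p[2:n])
}

#' Generate the synthetic static PIN
#'
#' A random simple connected graph: a random spanning tree over all genes
#' (so the largest connected component covers every node), plus a random
#' spanning tree within each planted term's members (so each planted module is
#' an induced connected subgraph), topped up with uniform random edges to the
#' edge budget.
#'
#' @param spec A [synthetic_spec()].
#' @return An undirected [igraph::igraph] with `n_genes` nodes and `n_edges`
#'   edges.
#' @export
generate_pin <- function(spec) {
  with_rng(derive_seed(spec$seed, 1L), {
    genes <- spec_genes(spec)
    e <- random_tree_edges(genes)
    for (members in spec_members(spec)) {
      e <- bind_rows(e, random_tree_edges(members))
    }
    e <- dplyr::distinct(e)
    need <- spec$n_edges - nrow(e)
    if (need < 0) abort("edge budget below the connectivity skeleton")
    have <- edge_key(e$u, e$v)
    while (need > 0) {
      i <- sample.int(spec$n_genes, 2L * need, replace = TRUE)
      j <- sample.int(spec$n_genes, 2L * need, replace = TRUE)
      ok <- i != j
      cand <- canonical_edges(genes[i[ok]], genes[j[ok]])
      cand <- cand[!edge_key(cand$u, cand$v) %in% have, , drop = FALSE]
      take <- head(seq_len(nrow(cand)), need)
      e <- bind_rows(e, cand[take, ])
      have <- c(have, edge_key(cand$u[take], cand$v[take]))
      need <- spec$n_edges - nrow(e)
    }
    igraph::graph_from_data_frame(e, directed = FALSE,
                                  vertices = tibble(name = genes))
  })
}

#' Generate the synthetic ontology and annotations
#'
#' Builds a DAG with one namespace root and a private parent chain under the
#' root for every leaf term, placing each planted term at its configured level
#' and decoy terms at the ontology depth. Planted members are directly
#' annotated to their term; every gene is annotated to at least one decoy term
#' (decoy memberships are uniform random sets of `decoy_size` genes, matching
#' the planted set sizes).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dag` (an [ontology_dag()]) and `ann` (a propagated
#'   [annotation_map()]).
#' @export
generate_annotations <- function(spec) {
  with_rng(derive_seed(spec$seed, 2L), {
    genes <- spec_genes(spec)
    members <- spec_members(spec)
    n_decoys <- max(1L, ceiling(spec$n_genes / spec$decoy_size))
    decoy_ids <- sprintf("GO:8%06d", seq_len(n_decoys))
    root <- "GO:0000001"
    terms <- tibble(id = root, name = "biological_process",
                    namespace = "biological_process")
    parents <- list()
    parents[[root]] <- character()
    add_chain <- function(leaf_id, leaf_name, level) {
      # ancestors at levels 2..(level-1), private to this leaf
      chain <- if (level > 2L) {
        sprintf("%s:a%02d", leaf_id, 2:(level - 1L))
      } else character()
      ids <- c(chain, leaf_id)
      up <- c(root, chain)
      for (i in seq_along(ids)) {
        terms <<- bind_rows(terms, tibble(
          id = ids[i],
          name = if (i == length(ids)) leaf_name else
            sprintf("%s (ancestor level %d)", leaf_name, i + 1L),
          namespace = "biological_process"))
        parents[[ids[i]]] <<- up[i]
      }
    }
    for (t in spec$planted_terms) {
      add_chain(t$id, sprintf("planted process %s", t$id), t$level)
    }
    for (i in seq_len(n_decoys)) {
      add_chain(decoy_ids[i], sprintf("decoy process %d", i),
                spec$ontology_depth)
    }
    dag <- ontology_dag(terms, parents)
    gene_terms <- setNames(vector("list", length(genes)), genes)
    for (id in names(members)) {
      for (g in members[[id]]) gene_terms[[g]] <- c(gene_terms[[g]], id)
    }
    for (d in decoy_ids) {
      for (g in sample(genes, min(spec$decoy_size, length(genes)))) {
        gene_terms[[g]] <- c(gene_terms[[g]], d)
      }
    }
    bare <- names(gene_terms)[lengths(gene_terms) == 0L]
    for (g in bare) gene_terms[[g]] <- sample(decoy_ids, 1L)
    ann <- propagate_annotations(annotation_map(gene_terms), dag)
    list(dag = dag, ann = ann)
  })
}

#' Generate the synthetic two-condition expression matrix
#'
#' Background genes are i.i.d. standard normal across samples. For each
#' planted term and condition, member genes follow a one-factor model
#' `x = sqrt(rho_c) * f_sample + sqrt(1 - rho_c) * noise_sd * eps`; members
#' with a planted shift get it added in the positive condition (A).
#'
#' @param spec A [synthetic_spec()].
#' @param pin Optional PIN from [generate_pin()] (membership comes from the
#'   spec; the network itself does not alter expression).
#' @return List with `expr` (matrix) and `design` (a [sample_design()] with
#'   conditions `"A"` and `"B"`, positive `"A"`).
#' @export
generate_expression <- function(spec, pin = NULL) {
  with_rng(derive_seed(spec$seed, 3L), {
    genes <- spec_genes(spec)
    na <- spec$samples_per_condition[1]; nb <- spec$samples_per_condition[2]
    samples <- c(sprintf("A%02d", seq_len(na)), sprintf("B%02d", seq_len(nb)))
    cond <- rep(c("A", "B"), c(na, nb))
    expr <- matrix(rnorm(length(genes) * length(samples)),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
    members <- spec_members(spec)
    for (t in spec$planted_terms) {
      g <- members[[t$id]]
      for (cc in c("A", "B")) {
        rho <- if (cc == "A") t$rho_a else t$rho_b
        idx <- which(cond == cc)
        f <- rnorm(length(idx))
        eps <- matrix(rnorm(length(g) * length(idx)), length(g))
        expr[g, idx] <- sqrt(rho) * rep(f, each = length(g)) +
          sqrt(1 - rho) * spec$noise_sd * eps
      }
      if (t$shift != 0) {
        expr[g, cond == "A"] <- expr[g, cond == "A"] + t$shift
      }
    }
    list(expr = expr, design = sample_design(samples, cond, positive = "A"))
  })
}

#' Generate all pipeline inputs in memory
#'
#' @param spec A [synthetic_spec()].
#' @return List `expr`, `design`, `pin`, `dag`, `ann`, `spec`.
#' @export
generate_fixture_data <- function(spec) {
  pin <- generate_pin(spec)
  onto <- generate_annotations(spec)
  ed <- generate_expression(spec, pin)
  list(expr = ed$expr, design = ed$design, pin = pin,
       dag = onto$dag, ann = onto$ann, spec = spec)
}

# Minimal OBO 1.2 writer for generated ontologies.
write_ontology_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2",
               "default-namespace: biological_process", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 paste0("is_a: ", dag$parents[[id]]),
                 ""), con)
  }
  invisible(path)
}

#' Write a complete synthetic input bundle to disk
#'
#' Writes `expression.tsv`, `design.tsv`, `edges.tsv`, `ontology.obo`,
#' `annotations.tsv` and a `manifest.json` recording the spec (including the
#' seed). Identical specs yield byte-identical bundles.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if missing).
#' @param overwrite Allow overwriting existing files.
#' @return Invisibly, a named character vector of the file paths.
#' @export
generate_fixture <- function(spec, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c(expression = "expression.tsv",
                            design = "design.tsv", edges = "edges.tsv",
                            ontology = "ontology.obo",
                            annotations = "annotations.tsv",
                            manifest = "manifest.json"))
  names(paths) <- c("expression", "design", "edges", "ontology",
                    "annotations", "manifest")
  if (!overwrite && any(file.exists(paths))) {
    abort("output files exist; use overwrite = TRUE")
  }
  d <- generate_fixture_data(spec)
  expr_df <- data.frame(gene = rownames(d$expr),
                        format(d$expr, digits = 15, trim = TRUE,
                               scientific = FALSE),
                        check.names = FALSE)
  write.table(expr_df, paths["expression"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample = d$design$sample,
                         condition = d$design$condition),
              paths["design"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_network(d$pin, paths["edges"], format = "tsv")
  write_ontology_obo(d$dag, paths["ontology"])
  ann_df <- tibble(gene = rep(names(d$ann$direct), lengths(d$ann$direct)),
                   term = unlist(d$ann$direct, use.names = FALSE))
  write.table(ann_df, paths["annotations"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  manifest <- list(
    generator = "cepin::generate_fixture",
    spec = list(n_genes = spec$n_genes, n_edges = spec$n_edges,
                samples_per_condition = spec$samples_per_condition,
                planted_terms = lapply(spec$planted_terms, unclass),
                sdeg_shift = spec$sdeg_shift, noise_sd = spec$noise_sd,
                ontology_depth = spec$ontology_depth,
                decoy_size = spec$decoy_size, seed = spec$seed),
    files = as.list(setNames(basename(paths), names(paths))))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Rebuild a synthetic spec from a fixture manifest
#'
#' @param path Path to a `manifest.json` written by [generate_fixture()].
#' @return The [synthetic_spec()] it records.
#' @export
read_fixture_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  s <- m$spec
  synthetic_spec(
    n_genes = s$n_genes, n_edges = s$n_edges,
    samples_per_condition = unlist(s$samples_per_condition),
    planted_terms = lapply(s$planted_terms, function(t)
      planted_term(t$id, t$size, t$rho_a, t$rho_b, shift = t$shift,
                   level = t$level)),
    sdeg_shift = s$sdeg_shift, noise_sd = s$noise_sd,
    ontology_depth = s$ontology_depth, decoy_size = s$decoy_size,
    seed = s$seed)
}
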
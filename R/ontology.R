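#' Construct an ontology DAG
#'
#' Internal constructor shared by the OBO reader and the synthetic generator.
#' Levels follow the BiNGO-style convention: the namespace root is level 1 and
#' `level(t) = 1 + min (or max) over parents of level(parent)`.
#'
#' @param terms Tibble with columns `id`, `name`, `namespace`.
#' @param parents Named list: term id -> character vector of parent ids
#'   (is_a/part_of).
#' @param level_rule `"shortest"` (default) or `"longest"` path from the root.
#' @return An `ontology_dag` object: list with `terms` (tibble incl. `level`),
#'   `parents`, and `ancestors` (transitive closure, named list).
#' @export
ontology_dag <- function(terms, parents, level_rule = c("shortest", "longest")) {
  level_rule <- match.arg(level_rule)
  terms <- as_tibble(terms)
  ids <- terms$id
  parents <- lapply(parents[ids], function(p) intersect(p, ids))
  names(parents) <- ids
  # topological order via igraph (parent -> child edges)
  pe <- tibble(
    from = unlist(parents, use.names = FALSE),
    to = rep(ids, lengths(parents))
  )
  g <- igraph::graph_from_data_frame(pe, directed = TRUE,
                                     vertices = tibble(name = ids))
  if (!igraph::is_dag(g)) {
    sc <- igraph::components(g, mode = "strong")
    wit <- igraph::V(g)$name[sc$membership == which(sc$csize > 1)[1]]
    abort(paste0("ontology contains a cycle involving: ",
                 paste(wit, collapse = " -> ")))
  }
  ord <- igraph::V(g)$name[as.integer(igraph::topo_sort(g, mode = "out"))]
  lvl <- setNames(rep(NA_real_, length(ids)), ids)
  anc <- setNames(vector("list", length(ids)), ids)
  agg <- if (level_rule == "shortest") min else max
  for (t in ord) {
    p <- parents[[t]]
    if (!length(p)) {
      lvl[t] <- 1
      anc[[t]] <- character()
    } else {
      lvl[t] <- 1 + agg(lvl[p])
      anc[[t]] <- unique(c(p, unlist(anc[p], use.names = FALSE)))
    }
  }
  terms$level <- as.integer(lvl[terms$id])
  structure(list(terms = terms, parents = parents, ancestors = anc,
                 level_rule = level_rule),
            class = "ontology_dag")
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("Ontology DAG: %d terms (levels 1-%d, %s-path rule)\n",
              nrow(x$terms), max(x$terms$level), x$level_rule))
  invisible(x)
}

#' Look up term levels
#' @param dag An [ontology_dag()].
#' @param ids Term ids.
#' @return Integer levels (NA for unknown terms).
#' @export
term_level <- function(dag, ids) {
  x <- setNames(dag$terms$level, dag$terms$id)
  unname(x[ids])
}

#' Ancestors of terms (transitive is_a/part_of closure)
#' @inheritParams term_level
#' @return Named list of character vectors.
#' @export
term_ancestors <- function(dag, ids) dag$ancestors[ids]

#' Read an ontology from an OBO file
#'
#' Parses `[Term]` stanzas (OBO 1.2/1.4), restricted to one namespace;
#' obsolete terms are dropped, and `is_a` plus `relationship: part_of` links
#' define parenthood.
#'
#' @param path OBO file path.
#' @param namespace Namespace to keep (default `"biological_process"`). Terms
#'   without a namespace field inherit the file's `default-namespace`, if any.
#' @inheritParams ontology_dag
#' @return An [ontology_dag()].
#' @export
read_ontology_obo <- function(path, namespace = "biological_process",
                              level_rule = c("shortest", "longest")) {
  lines <- readLines(path)
  default_ns <- sub("^default-namespace: *", "",
                    grep("^default-namespace:", lines, value = TRUE)[1])
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  ends <- c(starts[-1] - 1L, length(lines))
  recs <- lapply(term_starts, function(s) {
    e <- ends[match(s, starts)]
    lines[(s + 1L):e]
  })
  parse_one <- function(block) {
    val <- function(key) {
      hit <- grep(paste0("^", key, ": *"), block, value = TRUE)
      if (!length(hit)) return(NA_character_)
      sub(" *!.*$", "", sub(paste0("^", key, ": *"), "", hit[1]))
    }
    isa <- sub(" *!.*$", "", sub("^is_a: *", "",
               grep("^is_a: *", block, value = TRUE)))
    po <- grep("^relationship: *part_of ", block, value = TRUE)
    po <- sub(" *!.*$", "", sub("^relationship: *part_of *", "", po))
    list(id = val("id"), name = val("name"),
         namespace = val("namespace"),
         obsolete = identical(val("is_obsolete"), "true"),
         parents = trimws(c(isa, po)))
  }
  parsed <- lapply(recs, parse_one)
  ns <- vapply(parsed, function(r)
    if (is.na(r$namespace)) default_ns %||% NA_character_ else r$namespace,
    character(1))
  keep <- !vapply(parsed, `[[`, logical(1), "obsolete") &
    (is.na(ns) | ns == namespace)
  parsed <- parsed[keep]
  if (!length(parsed)) abort(sprintf("no terms in namespace '%s'", namespace))
  terms <- tibble(
    id = vapply(parsed, `[[`, character(1), "id"),
    name = vapply(parsed, `[[`, character(1), "name"),
    namespace = namespace
  )
  parents <- setNames(lapply(parsed, `[[`, "parents"), terms$id)
  ontology_dag(terms, parents, level_rule = level_rule)
}

#' Construct an annotation map
#'
#' @param direct Named list: gene -> character vector of directly annotated
#'   term ids.
#' @param propagated Optional named list closed under ancestors (filled by
#'   [propagate_annotations()]).
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(direct, propagated = NULL) {
  structure(list(direct = direct, propagated = propagated),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("Annotation map: %d genes, %d direct annotations%s\n",
              length(x$direct), sum(lengths(x$direct)),
              if (is.null(x$propagated)) " (not propagated)" else " (propagated)"))
  invisible(x)
}

#' Read gene-to-term annotations
#'
#' @param path Annotation file.
#' @param dag Optional [ontology_dag()]; annotations to terms absent from the
#'   DAG are dropped with a warning count.
#' @param format `"tsv"` (two columns: gene, term; `#` lines skipped) or
#'   `"gaf"` (GAF 2.x; `!` header lines skipped, `NOT`-qualified records
#'   excluded, malformed lines skipped with a logged count).
#' @param gene_column For GAF input, which column supplies the gene id
#'   (default 3, the DB object symbol).
#' @param exclude_evidence GAF evidence codes to drop (default none).
#' @return An [annotation_map()] with direct annotations only.
#' @export
read_annotations <- function(path, dag = NULL, format = c("tsv", "gaf"),
                             gene_column = 3L, exclude_evidence = character()) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "tsv") {
    lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) != 2L
    if (any(bad)) inform(sprintf("skipped %d malformed annotation line(s)", sum(bad)))
    m <- do.call(rbind, fields[!bad])
    genes <- m[, 1]; terms <- m[, 2]
  } else {
    lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- lengths(fields) < 15L
    if (any(bad)) inform(sprintf("skipped %d malformed GAF line(s)", sum(bad)))
    fields <- fields[!bad]
    qual <- vapply(fields, `[[`, character(1), 4L)
    ev <- vapply(fields, `[[`, character(1), 7L)
    keep <- !grepl("(^|\\|)NOT($|\\|)", qual) & !(ev %in% exclude_evidence)
    genes <- vapply(fields[keep], `[[`, character(1), gene_column)
    terms <- vapply(fields[keep], `[[`, character(1), 5L)
  }
  if (!is.null(dag)) {
    known <- terms %in% dag$terms$id
    if (any(!known)) {
      warn(sprintf("dropped %d annotation(s) to term(s) absent from the DAG",
                   sum(!known)))
    }
    genes <- genes[known]; terms <- terms[known]
  }
  direct <- lapply(split(terms, genes), unique)
  annotation_map(direct)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' Each gene inherits every ancestor of each of its direct terms; the result
#' is closed under ancestors and the operation is idempotent.
#'
#' @param ann An [annotation_map()].
#' @param dag An [ontology_dag()].
#' @return The annotation map with `propagated` filled.
#' @export
propagate_annotations <- function(ann, dag) {
  anc <- dag$ancestors
  ids <- dag$terms$id
  prop <- lapply(ann$direct, function(ts) {
    ts <- intersect(ts, ids)
    unique(c(ts, unlist(anc[ts], use.names = FALSE)))
  })
  annotation_map(ann$direct, propagated = prop)
}

# Inverse map term -> genes over a background set.
genes_per_term <- function(ann, background,
                           use = c("propagated", "direct")) {
  use <- match.arg(use)
  src <- if (use == "propagated") {
    if (is.null(ann$propagated)) abort("annotations not propagated")
    ann$propagated
  } else ann$direct
  src <- src[intersect(names(src), background)]
  g <- rep(names(src), lengths(src))
  t <- unlist(src, use.names = FALSE)
  lapply(split(g, t), unique)
}
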
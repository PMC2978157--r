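#' Read a protein-protein interaction edge list
#'
#' Reads a two-column whitespace/tab-delimited edge list into a simple
#' undirected graph: self-loops are removed, duplicate and reversed-duplicate
#' edges are merged, and the counts of removed records are reported.
#'
#' @param path Path to the edge-list file. Lines starting with `#` are
#'   skipped.
#' @param quiet Suppress the removed-record message.
#' @return An [igraph::igraph] undirected simple graph.
#' @export
read_edge_list <- function(path, quiet = FALSE) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (!length(idx)) return(igraph::make_empty_graph(directed = FALSE))
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad)) {
    abort(sprintf("edge-list line %d does not have 2 fields", idx[bad[1]]))
  }
  m <- do.call(rbind, fields)
  self <- m[, 1] == m[, 2]
  e <- canonical_edges(m[!self, 1], m[!self, 2])
  n_dup <- sum(!self) - nrow(e)
  if (!quiet && (any(self) || n_dup > 0)) {
    inform(sprintf("removed %d self-loop(s) and %d duplicate edge(s)",
                   sum(self), n_dup))
  }
  igraph::graph_from_data_frame(e, directed = FALSE)
}

#' Largest connected component of a network
#'
#' Ties in component size are broken deterministically: the component
#' containing the lexicographically smallest node name wins.
#'
#' @param net An undirected [igraph::igraph].
#' @return The induced subgraph on the largest component (the empty graph for
#'   empty input).
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) return(net)
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    nm <- igraph::V(net)$name
    firsts <- vapply(big, function(k) min(nm[comp$membership == k]), character(1))
    big <- big[order(firsts)[1]]
  }
  igraph::induced_subgraph(net, which(comp$membership == big))
}

#' Export a network with attributes
#'
#' @param net An undirected [igraph::igraph].
#' @param path Output file.
#' @param format `"tsv"` (two-column edge list; extra edge attributes add a
#'   commented header line so [read_edge_list()] round-trips), `"sif"`
#'   (Cytoscape simple interaction format, relation `pp`), or `"graphml"`.
#' @param node_attrs Optional data frame with a `node` column plus attribute
#'   columns; every node must exist in `net`.
#' @param edge_attrs Optional data frame with `u`,`v` columns plus attribute
#'   columns; every edge must exist in `net`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml"),
                          node_attrs = NULL, edge_attrs = NULL) {
  format <- match.arg(format)
  nm <- igraph::V(net)$name
  if (!is.null(node_attrs)) {
    missing <- setdiff(node_attrs$node, nm)
    if (length(missing)) {
      abort(paste0("node attribute(s) for unknown node(s): ",
                   paste(missing, collapse = ", ")))
    }
    for (col in setdiff(names(node_attrs), "node")) {
      net <- igraph::set_vertex_attr(net, col,
        index = match(node_attrs$node, nm), value = node_attrs[[col]])
    }
  }
  el <- igraph::as_edgelist(net)
  etab <- if (nrow(el)) canonical_edges(el[, 1], el[, 2]) else
    tibble(u = character(), v = character())
  if (!is.null(edge_attrs)) {
    ek <- edge_key(edge_attrs$u, edge_attrs$v)
    missing <- setdiff(ek, edge_key(etab$u, etab$v))
    if (length(missing)) abort("edge attribute(s) for unknown edge(s)")
    ea <- edge_attrs
    lo <- pmin(ea$u, ea$v); hi <- pmax(ea$u, ea$v)
    ea$u <- lo; ea$v <- hi
    etab <- left_join(etab, ea, by = c("u", "v"))
  }
  switch(format,
    tsv = {
      con <- file(path, "w")
      on.exit(close(con))
      if (ncol(etab) > 2L) {
        writeLines(paste0("#", paste(names(etab), collapse = "\t")), con)
      }
      if (nrow(etab)) {
        write.table(etab, con, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE)
      }
    },
    sif = {
      iso <- setdiff(nm, c(etab$u, etab$v))
      writeLines(c(if (nrow(etab)) paste(etab$u, "pp", etab$v), iso), path)
    },
    graphml = {
      if (!is.null(edge_attrs)) {
        el_keys <- edge_key(el[, 1], el[, 2])
        at <- mutate(edge_attrs, .k = edge_key(.data$u, .data$v))
        for (col in setdiff(names(edge_attrs), c("u", "v"))) {
          net <- igraph::set_edge_attr(net, col,
            index = match(at$.k, el_keys), value = at[[col]])
        }
      }
      igraph::write_graph(net, path, format = "graphml")
    })
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Input file.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return An undirected [igraph::igraph].
#' @export
read_network <- function(path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  switch(format,
    tsv = {
      lines <- readLines(path)
      lines <- trimws(lines)
      lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
      if (!length(lines)) return(igraph::make_empty_graph(directed = FALSE))
      fields <- strsplit(lines, "[ \t]+")
      e <- t(vapply(fields, function(f) f[1:2], character(2)))
      igraph::graph_from_data_frame(canonical_edges(e[, 1], e[, 2]),
                                    directed = FALSE)
    },
    sif = {
      lines <- readLines(path)
      lines <- lines[nzchar(trimws(lines))]
      fields <- strsplit(trimws(lines), "[ \t]+")
      singles <- vapply(fields, length, 1L) == 1L
      e <- do.call(rbind, fields[!singles])
      g <- if (is.null(e)) igraph::make_empty_graph(directed = FALSE) else
        igraph::graph_from_data_frame(canonical_edges(e[, 1], e[, 3]),
                                      directed = FALSE)
      iso <- setdiff(unlist(fields[singles]), igraph::V(g)$name)
      igraph::add_vertices(g, length(iso), name = iso)
    },
    graphml = {
      g <- igraph::read_graph(path, format = "graphml")
      igraph::as_undirected(igraph::simplify(g), mode = "collapse")
    })
}
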
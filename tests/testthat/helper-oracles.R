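# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct formulas, BFS.

# Upper-tail hypergeometric by exhaustive summation with exact binomials
# (choose() is exact in double precision for N <= 25).
oracle_hyper_tail <- function(N, m, n, k) {
  js <- k:min(m, n)
  terms <- vapply(js, function(j) choose(m, j) * choose(N - m, n - j),
                  numeric(1))
  sum(terms) / choose(N, n)
}

# Textbook BH step-up: q_(i) = min_{j >= i} p_(j) * M / j, capped at 1.
oracle_bh <- function(p) {
  M <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * M / seq_len(M)))))
  q <- numeric(M)
  q[o] <- q_sorted
  q
}

# Two-sided rank-sum p by explicit enumeration of all size-nx subsets.
oracle_wilcox_enum <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (length(r) + 1) / 2
  subs <- utils::combn(length(r), nx)
  ws <- colSums(matrix(r[subs], nrow = nx))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum of all table probabilities <= the observed one.
oracle_fisher2x2 <- function(tab) {
  a <- tab[1, 1]
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  prob <- function(x) choose(cs[1], x) * choose(cs[2], rs[1] - x) / choose(N, rs[1])
  xs <- max(0, rs[1] - cs[2]):min(rs[1], cs[1])
  ps <- vapply(xs, prob, numeric(1))
  sum(ps[ps <= prob(a) * (1 + 1e-7)])
}

# Brute-force node topology from an adjacency matrix: BFS distances and
# shortest-path counts from every source, fractional betweenness, closeness
# as reciprocal mean distance, clustering by neighbour-edge counting.
oracle_topology <- function(adj) {
  N <- nrow(adj)
  dist <- matrix(Inf, N, N)
  sigma <- matrix(0, N, N)
  for (s in seq_len(N)) {
    dist[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (u in frontier) {
        for (v in which(adj[u, ] == 1)) {
          if (is.infinite(dist[s, v])) {
            dist[s, v] <- d
            nxt <- c(nxt, v)
          }
          if (dist[s, v] == d) sigma[s, v] <- sigma[s, v] + sigma[s, u]
        }
      }
      frontier <- unique(nxt)
    }
  }
  bc <- numeric(N)
  for (v in seq_len(N)) {
    for (s in seq_len(N - 1)) {
      for (t in (s + 1):N) {
        if (s == v || t == v || is.infinite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
  }
  bc <- bc / choose(N, 2)
  cc <- vapply(seq_len(N), function(i) (N - 1) / sum(dist[i, -i]), numeric(1))
  deg <- rowSums(adj)
  cl <- vapply(seq_len(N), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    sum(adj[nb, nb]) / 2 / choose(length(nb), 2)
  }, numeric(1))
  list(degree = deg, betweenness = bc, closeness = cc, clustering = cl)
}

# AUC as the pairwise-concordance probability with tie half-credit.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  max(x <- tot / (length(sp) * length(sn)), 1 - x)
}

# Random connected labelled graph as an igraph (tree + extra edges).
rand_connected_graph <- function(n, extra = n) {
  nodes <- sprintf("N%02d", seq_len(n))
  p <- sample(nodes)
  e <- cbind(vapply(2:n, function(i) p[sample.int(i - 1, 1)], character(1)),
             p[2:n])
  more <- cbind(sample(nodes, extra, replace = TRUE),
                sample(nodes, extra, replace = TRUE))
  e <- rbind(e, more[more[, 1] != more[, 2], , drop = FALSE])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[!duplicated(key), , drop = FALSE]
  igraph::graph_from_data_frame(as.data.frame(e), directed = FALSE,
                                vertices = data.frame(name = nodes))
}

# Small ontology: root -> a -> t1, root -> b, b -> t1 alternative path,
# plus a deep chain for level filtering.
toy_dag <- function() {
  terms <- tibble::tibble(
    id = c("r", "a", "b", "t1", "c2", "c3", "c4", "c5", "c6"),
    name = paste("term", id),
    namespace = "biological_process")
  parents <- list(r = character(), a = "r", b = "r", t1 = c("a", "b"),
                  c2 = "r", c3 = "c2", c4 = "c3", c5 = "c4", c6 = "c5")
  ontology_dag(terms, parents)
}

write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}
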
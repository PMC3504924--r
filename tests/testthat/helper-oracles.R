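# Independent oracles used to cross-check the package's implementations.
# These deliberately use naive loop-based arithmetic, not the package's
# code paths.

oracle_entropy <- function(x) {
  h <- 0
  for (v in unique(x)) {
    p <- sum(x == v) / length(x)
    h <- h - p * log2(p)
  }
  h
}

oracle_mi <- function(x, y) {
  mi <- 0
  for (vx in unique(x)) {
    px <- mean(x == vx)
    for (vy in unique(y)) {
      py <- mean(y == vy)
      pxy <- mean(x == vx & y == vy)
      if (pxy > 0) mi <- mi + pxy * log2(pxy / (px * py))
    }
  }
  mi
}

# Cover sets straight from the definition, as sample-name sets.
oracle_cover_sets <- function(Q, C) {
  out <- list()
  for (g in rownames(Q)) {
    for (t in C$classes) {
      in_t <- names(C$labels)[C$labels == t]
      out[[paste(g, t, "P", sep = ".")]] <-
        sort(in_t[Q[g, in_t] == 1L])
      out[[paste(g, t, "N", sep = ".")]] <-
        sort(in_t[Q[g, in_t] == -1L])
    }
  }
  out
}

# Exhaustive minimum set cover: smallest number of genes whose positive
# covers union to the whole universe. Returns Inf if infeasible.
oracle_min_cover <- function(cover_list, universe) {
  n <- length(cover_list)
  for (k in 1:n) {
    for (combo in utils::combn(n, k, simplify = FALSE)) {
      if (setequal(Reduce(union, cover_list[combo]), universe))
        return(k)
    }
  }
  Inf
}

# Naive induced subgraph as a sorted edge-list data frame.
oracle_induced_edges <- function(edges, keep) {
  sel <- edges[, 1] %in% keep & edges[, 2] %in% keep
  e <- edges[sel, , drop = FALSE]
  e <- t(apply(e, 1, sort))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  unique(e)
}

# All-pairs shortest hop counts by Floyd-Warshall on an adjacency matrix.
oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n, dimnames = dimnames(adj))
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# BFS depths from a source over an adjacency list.
oracle_bfs_depths <- function(adj_list, src) {
  depth <- stats::setNames(rep(Inf, length(adj_list)), names(adj_list))
  depth[src] <- 0
  frontier <- src
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(adj_list[frontier])),
                   names(depth)[is.finite(depth)])
    depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("a", "b")
  m
}
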
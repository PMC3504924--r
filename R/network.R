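#' Build an interaction network from an edge list
#'
#' Constructs an undirected simple graph: self-loops are dropped,
#' duplicate and reversed edges are collapsed. Nodes only ever enter
#' through edges, so isolated proteins are absent by construction.
#'
#' @param edges two-column character matrix or data frame of endpoint
#'   identifiers (extra columns ignored).
#' @return An [igraph::igraph] object.
#' @export
interaction_network <- function(edges) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2L)
    stop("edge list needs two endpoint columns", call. = FALSE)
  ep <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  ep <- ep[ep[, 1L] != ep[, 2L], , drop = FALSE]
  if (nrow(ep) == 0L)
    stop("no edges remain after dropping self-loops", call. = FALSE)
  g <- igraph::graph_from_edgelist(ep, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

network_nodes <- function(G) igraph::V(G)$name

assert_node <- function(G, g) {
  if (!all(g %in% network_nodes(G)))
    stop("unknown network node(s): ",
         paste(setdiff(g, network_nodes(G)), collapse = ", "), call. = FALSE)
}

#' Restrict a network to the measured gene universe
#'
#' Induces the subgraph on the intersection of the network's nodes with
#' the supplied gene identifiers, then removes nodes left without any
#' interaction.
#'
#' @param G interaction network (igraph).
#' @param genes character vector of gene identifiers (typically the
#'   expression matrix rows).
#' @return Restricted igraph object.
#' @export
restrict_to_expression <- function(G, genes) {
  keep <- intersect(network_nodes(G), genes)
  if (length(keep) == 0L)
    stop("network and expression matrix share no genes", call. = FALSE)
  g <- igraph::induced_subgraph(G, keep)
  deg <- igraph::degree(g)
  igraph::delete_vertices(g, names(deg)[deg == 0])
}

#' Hop distance between two genes
#'
#' Unweighted shortest-path length; 0 for a node to itself, `Inf` when
#' unreachable.
#'
#' @param G interaction network.
#' @param gi,gj node identifiers.
#' @return Non-negative number, possibly `Inf`.
#' @export
hop_distance <- function(G, gi, gj) {
  assert_node(G, c(gi, gj))
  as.numeric(igraph::distances(G, v = gi, to = gj)[1L, 1L])
}

#' l-hop neighborhood of a gene
#'
#' All other genes within `ell` hops of `gi`. `ell = Inf` gives the
#' network-free neighborhood: every other node of the graph.
#'
#' @param G interaction network.
#' @param gi node identifier.
#' @param ell positive integer or `Inf`.
#' @return Character vector of node identifiers (excludes `gi`).
#' @export
lhop_neighbors <- function(G, gi, ell = 3) {
  assert_node(G, gi)
  if (is.infinite(ell))
    return(setdiff(network_nodes(G), gi))
  if (!is.numeric(ell) || length(ell) != 1L || ell < 1 || ell != floor(ell))
    stop("`ell` must be a positive integer or Inf", call. = FALSE)
  nb <- igraph::ego(G, order = ell, nodes = gi, mindist = 1L)[[1L]]
  nb$name
}

# Precompute the l-hop neighborhood of every node once; the greedy
# searches query these sets repeatedly.
all_lhop_neighborhoods <- function(G, ell) {
  nodes <- network_nodes(G)
  if (is.infinite(ell)) {
    out <- lapply(nodes, function(v) setdiff(nodes, v))
  } else {
    eg <- igraph::ego(G, order = ell, nodes = nodes, mindist = 1L)
    out <- lapply(eg, function(x) x$name)
  }
  names(out) <- nodes
  out
}
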
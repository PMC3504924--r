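#' Grow a subnetwork by greedy mutual-information maximization
#'
#' The additive greedy of the subnetwork-marker literature: start from a
#' seed gene and repeatedly add the neighborhood gene that most improves
#' the objective (one-vs-all or all-vs-all discriminative power of the
#' subnetwork activity), stopping when the neighborhood is empty or the
#' best improvement does not exceed `min_improvement`.
#'
#' For the one-vs-all objective the target class is fixed when the seed
#' is scored: the class maximizing the seed's own one-vs-all power
#' (ties to the lexicographically smallest label).
#'
#' @param seed seed gene identifier.
#' @param E expression matrix.
#' @param C [phenotype()] vector.
#' @param G interaction network or `NULL` (network-free).
#' @param objective `"one_vs_all"` or `"all_vs_all"`.
#' @param target optional fixed target class for one-vs-all.
#' @param min_improvement minimum improvement in bits for a gene to be
#'   accepted (default 0.01).
#' @param ell hop-distance bound (default 3; `Inf` = network-free).
#' @param bins activity bin count (default [default_bins()]).
#' @param nbrs optional precomputed neighborhood list (internal use).
#' @return A `scored_subnetwork` with the trajectory's final score.
#' @export
grow_additive <- function(seed, E, C, G = NULL,
                          objective = c("one_vs_all", "all_vs_all"),
                          target = NULL, min_improvement = 0.01,
                          ell = 3, bins = NULL, nbrs = NULL) {
  objective <- match.arg(objective)
  stopifnot(inherits(C, "phenotype"))
  if (!seed %in% rownames(E))
    stop("unknown seed gene: ", seed, call. = FALSE)
  if (min_improvement < 0)
    stop("`min_improvement` must be non-negative", call. = FALSE)
  if (is.null(bins)) bins <- default_bins(length(C))

  score <- if (objective == "all_vs_all") {
    function(S) delta_all_vs_all(E, C, S, bins)
  } else {
    if (is.null(target)) {
      seed_scores <- vapply(sort(C$classes),
                            function(t) delta_one_vs_all(E, C, seed, t, bins),
                            numeric(1))
      target <- names(seed_scores)[which.max(seed_scores)]
    } else if (!target %in% C$classes) {
      stop("unknown target class: ", target, call. = FALSE)
    }
    function(S) delta_one_vs_all(E, C, S, target, bins)
  }

  neighborhood <- function(g) {
    if (!is.null(nbrs)) return(nbrs[[g]])
    if (is.null(G)) return(setdiff(rownames(E), g))
    if (!g %in% network_nodes(G)) return(character(0))
    lhop_neighbors(G, g, ell)
  }

  S <- seed
  current <- score(S)
  Q <- sort(setdiff(intersect(neighborhood(seed), rownames(E)), S))
  while (length(Q) > 0L) {
    scores <- vapply(Q, function(g) score(c(S, g)), numeric(1))
    best <- max(scores)
    if (best - current <= min_improvement) break
    gk <- Q[which.max(scores)]      # Q sorted: argmax ties go to smallest id
    S <- c(S, gk)
    current <- best
    Q <- sort(setdiff(union(Q, intersect(neighborhood(gk), rownames(E))), S))
  }

  new_scored_subnetwork(S, seed, direction = "additive",
                        target = if (objective == "one_vs_all") target else NULL,
                        covered = character(0), delta = current,
                        mode = objective)
}

#' Run the additive greedy from every seed and rank the results
#'
#' One growth per seed gene (the network's nodes when a network is
#' supplied, otherwise every gene), ranked by final score descending
#' with ties broken by seed identifier.
#'
#' @inheritParams grow_additive
#' @return List of `scored_subnetwork`, ranked.
#' @export
discover_additive_all <- function(E, C, G = NULL,
                                  objective = c("one_vs_all", "all_vs_all"),
                                  min_improvement = 0.01, ell = 3,
                                  bins = NULL) {
  objective <- match.arg(objective)
  validate_expression_matrix(E)
  if (!is.null(G)) {
    G <- restrict_to_expression(G, rownames(E))
    seeds <- network_nodes(G)
    nbrs <- all_lhop_neighborhoods(G, ell)
  } else {
    seeds <- rownames(E)
    nbrs <- NULL
  }
  out <- lapply(seeds, function(g)
    grow_additive(g, E, C, G = G, objective = objective,
                  min_improvement = min_improvement, ell = ell,
                  bins = bins, nbrs = nbrs))
  ord <- order(-vapply(out, function(s) s$delta, numeric(1)),
               vapply(out, function(s) s$seed, character(1)))
  out[ord]
}
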
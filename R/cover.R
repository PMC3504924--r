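#' Build positive and negative cover sets
#'
#' A gene positively covers a sample when its quantized expression there
#' is +1, negatively when it is -1. For each gene i and class t the
#' positive cover set P_i^(t) holds the class-t samples positively
#' covered by i; N_i^(t) the negatively covered ones.
#'
#' @param Q quantized matrix from [quantize()].
#' @param C [phenotype()] vector over the same samples.
#' @return Object of class `cover_index` with logical cover matrices and
#'   the class partition (as column indices into `Q`).
#' @export
build_cover_index <- function(Q, C) {
  stopifnot(inherits(C, "phenotype"))
  samples <- names(C$labels)
  if (!setequal(colnames(Q), samples))
    stop("quantized matrix and phenotype vector cover different samples",
         call. = FALSE)
  Q <- Q[, samples, drop = FALSE]
  part <- lapply(class_partition(C), function(s) match(s, samples))
  storage.mode(Q) <- "double"   # ternary matrix doubles as the gain kernel
  structure(list(pos = Q == 1, neg = Q == -1, ternary = unname(Q),
                 classes = C$classes, partition = part,
                 samples = samples, genes = rownames(Q)),
            class = "cover_index")
}

#' @export
print.cover_index <- function(x, ...) {
  cat("<cover_index> ", length(x$genes), " genes x ", length(x$samples),
      " samples, classes: ", paste(names(x$partition), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Extract one cover set
#'
#' @param idx a `cover_index`.
#' @param gene gene identifier.
#' @param t class label.
#' @param direction `"positive"` or `"negative"`.
#' @return Character vector of covered sample identifiers.
#' @export
cover_set <- function(idx, gene, t, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  m <- if (direction == "positive") idx$pos else idx$neg
  cols <- idx$partition[[t]]
  idx$samples[cols[m[gene, cols]]]
}

#' Select the target class for a seed gene
#'
#' The class with the maximum fraction of its samples covered by the
#' gene in the requested direction; ties go to the lexicographically
#' smallest class label. When no class has any coverage the gene seeds
#' no subnetwork and `NULL` is returned.
#'
#' @inheritParams cover_set
#' @return Class label, or `NULL` when every fraction is zero.
#' @export
select_target_class <- function(idx, gene, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (!gene %in% idx$genes)
    stop("unknown gene: ", gene, call. = FALSE)
  m <- if (direction == "positive") idx$pos else idx$neg
  frac <- vapply(idx$partition,
                 function(cols) sum(m[gene, cols]) / length(cols),
                 numeric(1))
  if (all(frac == 0)) return(NULL)
  cand <- names(frac)[frac == max(frac)]
  sort(cand)[1L]
}

#' Marginal covering gain of a candidate gene
#'
#' For target class t and the current uncovered set M, the gain of gene
#' j is |P_j^(t) ∩ M| - |N_j^(t) ∩ M| (cover sets swapped in the
#' negative direction): samples newly covered in the subnetwork's
#' direction, penalized by samples the gene covers in the opposite
#' direction.
#'
#' @param idx a `cover_index`.
#' @param gene candidate gene.
#' @param t target class.
#' @param M character vector of currently uncovered class-t samples.
#' @inheritParams cover_set
#' @return Integer gain.
#' @export
marginal_gain <- function(idx, gene, t, M, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  cols <- match(M, idx$samples)
  cov <- if (direction == "positive") idx$pos else idx$neg
  anti <- if (direction == "positive") idx$neg else idx$pos
  sum(cov[gene, cols]) - sum(anti[gene, cols])
}

new_scored_subnetwork <- function(genes, seed, direction, target, covered,
                                  delta = NA_real_, mode = "one_vs_all") {
  structure(list(genes = genes, seed = seed, direction = direction,
                 target = target, covered = covered, delta = delta,
                 mode = mode, p_label = NA_real_, p_profile = NA_real_,
                 significant = NA),
            class = "scored_subnetwork")
}

#' @export
print.scored_subnetwork <- function(x, ...) {
  cat("<subnetwork> seed=", x$seed,
      " target=", if (is.null(x$target)) "-" else x$target,
      " dir=", x$direction,
      " size=", length(x$genes),
      " delta=", formatC(x$delta, digits = 4, format = "g"), "\n", sep = "")
  cat("  genes: ", paste(x$genes, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Grow a minimal covering subnetwork from a seed gene
#'
#' Greedy set-cover growth: pick the seed's target class (largest
#' covered fraction), then repeatedly add, from the l-hop network
#' neighborhood of the current subnetwork, the gene with maximum
#' marginal gain on the uncovered samples. Ties are broken by minimum
#' positive background coverage (covers of the subnetwork's direction
#' in the other classes), then by gene identifier. Growth stops when
#' the target class is fully covered, the neighborhood is exhausted,
#' the best gain is non-positive (unless `early_stop = FALSE`), or
#' `max_size` is reached.
#'
#' @param seed seed gene identifier.
#' @param direction `"positive"` or `"negative"`.
#' @param idx a `cover_index`.
#' @param G interaction network, or `NULL` for network-free search
#'   (every gene of the index is a neighbor).
#' @param ell hop-distance bound (default 3; `Inf` = network-free).
#' @param max_size subnetwork size cap (default 20; `Inf` disables).
#' @param early_stop stop when the best gain is <= 0 (default TRUE);
#'   `FALSE` reproduces the covering-only stopping rule.
#' @param nbrs optional precomputed neighborhood list (internal use).
#' @return A `scored_subnetwork` (delta unset), or `NULL` when the seed
#'   covers no class in the requested direction.
#' @export
grow_cover_subnetwork <- function(seed, direction, idx, G = NULL, ell = 3,
                                  max_size = 20, early_stop = TRUE,
                                  nbrs = NULL) {
  direction <- match.arg(direction, c("positive", "negative"))
  genes <- idx$genes
  n <- length(genes)
  seed_i <- match(seed, genes)
  if (is.na(seed_i))
    stop("unknown seed gene: ", seed, call. = FALSE)
  t <- select_target_class(idx, seed, direction)
  if (is.null(t)) return(NULL)

  # ternary kernel: +1 where the gene covers in the search direction,
  # -1 where it covers in the opposite direction
  D <- if (direction == "positive") idx$ternary else -idx$ternary
  cov <- if (direction == "positive") idx$pos else idx$neg
  Ut <- idx$partition[[t]]
  other_cols <- setdiff(seq_along(idx$samples), Ut)
  # direction-specific coverage of the non-target classes (tie-break)
  bg_cover <- rowSums(cov[, other_cols, drop = FALSE])

  # neighborhoods as integer gene indices; network-free mode treats
  # every other gene as a neighbor
  free <- is.null(G) && is.null(nbrs)
  nbr_idx <- if (free) {
    NULL
  } else if (!is.null(nbrs)) {
    if (is.null(attr(nbrs, "indexed")))
      nbrs <- lapply(nbrs, match, genes)
    nbrs
  } else {
    NULL
  }
  get_nbr <- function(i) {
    if (!is.null(nbr_idx)) {
      nb <- nbr_idx[[genes[i]]]
      return(nb[!is.na(nb)])
    }
    match(intersect(lhop_neighbors(G, genes[i], ell), genes), genes)
  }

  S <- seed_i
  M <- Ut[!cov[seed_i, Ut]]
  gains <- .rowSums(D[, M, drop = FALSE], n, length(M))
  inQ <- logical(n)
  if (free) inQ[] <- TRUE else inQ[get_nbr(seed_i)] <- TRUE
  inQ[seed_i] <- FALSE

  while (length(M) > 0L && any(inQ) && length(S) < max_size) {
    Qi <- which(inQ)
    best <- max(gains[Qi])
    if (early_stop && best <= 0) break
    cand <- Qi[gains[Qi] == best]
    if (length(cand) > 1L) {
      b <- bg_cover[cand]
      cand <- cand[b == min(b)]
      if (length(cand) > 1L) cand <- cand[order(genes[cand])]
    }
    gk <- cand[1L]
    S <- c(S, gk)
    removed <- M[cov[gk, M]]
    if (length(removed) > 0L) {
      gains <- gains - .rowSums(D[, removed, drop = FALSE], n,
                                length(removed))
      M <- setdiff(M, removed)
    }
    if (!free) inQ[get_nbr(gk)] <- TRUE
    inQ[S] <- FALSE
  }

  covered <- idx$samples[setdiff(Ut, M)]
  new_scored_subnetwork(genes[S], seed, direction, t, covered)
}

#' Discover covering subnetworks for every seed gene
#'
#' Runs the greedy cover growth for every gene (both directions by
#' default) and scores each resulting subnetwork by its one-vs-all
#' discriminative power with respect to its own target class. Seeds are
#' the network's nodes when a network is supplied, otherwise all genes.
#' Output order is deterministic: gene order, positive before negative.
#'
#' @param E expression matrix.
#' @param C [phenotype()] vector.
#' @param G interaction network or `NULL` (network-free).
#' @param ell hop-distance bound.
#' @param alpha quantization threshold (default 2).
#' @param bins activity bin count (default [default_bins()]).
#' @param max_size subnetwork size cap.
#' @param directions directions to search.
#' @param early_stop see [grow_cover_subnetwork()].
#' @param zscore z-score expression rows before activity scoring.
#' @return List of `scored_subnetwork` objects.
#' @export
discover_all <- function(E, C, G = NULL, ell = 3, alpha = 2, bins = NULL,
                         max_size = 20,
                         directions = c("positive", "negative"),
                         early_stop = TRUE, zscore = FALSE) {
  validate_expression_matrix(E)
  stopifnot(inherits(C, "phenotype"))
  if (!setequal(colnames(E), names(C$labels)))
    stop("expression matrix and phenotype vector cover different samples",
         call. = FALSE)
  if (is.null(bins)) bins <- default_bins(length(C))
  Escore <- if (zscore) zscore_rows(E) else E
  Q <- quantize(E, alpha)
  idx <- build_cover_index(Q, C)
  if (!is.null(G)) {
    G <- restrict_to_expression(G, rownames(E))
    seeds <- network_nodes(G)
    nbrs <- lapply(all_lhop_neighborhoods(G, ell), match, rownames(E))
    attr(nbrs, "indexed") <- TRUE
  } else {
    seeds <- rownames(E)
    nbrs <- NULL
  }
  out <- list()
  for (g in seeds) {
    for (d in directions) {
      sn <- grow_cover_subnetwork(g, d, idx, G = G, ell = ell,
                                  max_size = max_size,
                                  early_stop = early_stop, nbrs = nbrs)
      if (is.null(sn)) next
      sn$delta <- delta_one_vs_all(Escore, C, sn$genes, sn$target, bins)
      out[[length(out) + 1L]] <- sn
    }
  }
  out
}

#' Tabulate a list of subnetworks
#'
#' @param subnets list of `scored_subnetwork` objects.
#' @return A data frame with one row per subnetwork.
#' @export
subnetworks_table <- function(subnets) {
  data.frame(
    seed = vapply(subnets, function(s) s$seed, character(1)),
    target = vapply(subnets, function(s) s$target %||% NA_character_, character(1)),
    direction = vapply(subnets, function(s) s$direction, character(1)),
    size = vapply(subnets, function(s) length(s$genes), integer(1)),
    delta = vapply(subnets, function(s) s$delta, numeric(1)),
    p_label = vapply(subnets, function(s) s$p_label, numeric(1)),
    p_profile = vapply(subnets, function(s) s$p_profile, numeric(1)),
    significant = vapply(subnets, function(s) as.logical(s$significant), logical(1)),
    genes = vapply(subnets, function(s) paste(s$genes, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
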
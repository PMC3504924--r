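# Run `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched. A NULL seed uses (and advances) the
# session RNG.
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Randomly permute class labels
#'
#' Uniform permutation of the phenotype vector over samples; the class
#' multiset (and hence every class size) is preserved.
#'
#' @param C [phenotype()] vector.
#' @param rng_seed optional integer seed for reproducibility.
#' @return A new `phenotype` object.
#' @export
permute_class_labels <- function(C, rng_seed = NULL) {
  stopifnot(inherits(C, "phenotype"))
  lab <- with_rng(rng_seed, sample(C$labels))
  ph <- phenotype(unname(lab), samples = names(C$labels))
  ph$classes <- C$classes
  ph
}

#' Randomly permute gene expression profiles
#'
#' Reassigns the rows of the expression matrix to gene identifiers at
#' random, breaking the correspondence between expression profiles and
#' network nodes while keeping every profile intact.
#'
#' @param E expression matrix.
#' @param rng_seed optional integer seed.
#' @return Permuted expression matrix with the original row names.
#' @export
permute_gene_profiles <- function(E, rng_seed = NULL) {
  validate_expression_matrix(E)
  if (nrow(E) < 2L)
    stop("at least 2 genes are required to permute profiles", call. = FALSE)
  perm <- with_rng(rng_seed, sample(nrow(E)))
  E2 <- E[perm, , drop = FALSE]
  rownames(E2) <- rownames(E)
  E2
}

#' Build a permutation background distribution of subnetwork scores
#'
#' Repeatedly randomizes the dataset (permuting class labels or gene
#' profiles), reruns the full covering-subnetwork discovery on each
#' randomized dataset, and pools the (size, score) pairs of every
#' subnetwork found. Because each null dataset contributes its own most
#' discriminative subnetworks, comparing against this background
#' implicitly corrects for the multiplicity of the search.
#'
#' @param E,C,G,ell,alpha,bins,max_size,early_stop as in [discover_all()].
#' @param n_perms number of randomized datasets (default 100).
#' @param mode `"label"` (permute class labels) or `"profile"` (permute
#'   gene expression profiles).
#' @param rng_seed optional integer master seed for the permutations.
#' @return Object of class `background_dist` with vectors `size` and
#'   `delta` plus the run metadata.
#' @export
build_background <- function(E, C, G = NULL, n_perms = 100,
                             mode = c("label", "profile"),
                             rng_seed = NULL, ell = 3, alpha = 2,
                             bins = NULL, max_size = 20,
                             early_stop = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(n_perms) || n_perms < 1)
    stop("`n_perms` must be >= 1", call. = FALSE)
  run_one <- function() {
    if (mode == "label") {
      discover_all(E, permute_class_labels(C), G = G, ell = ell,
                   alpha = alpha, bins = bins, max_size = max_size,
                   early_stop = early_stop)
    } else {
      discover_all(permute_gene_profiles(E), C, G = G, ell = ell,
                   alpha = alpha, bins = bins, max_size = max_size,
                   early_stop = early_stop)
    }
  }
  runs <- with_rng(rng_seed, replicate(n_perms, run_one(), simplify = FALSE))
  pooled <- unlist(runs, recursive = FALSE)
  structure(list(mode = mode,
                 size = vapply(pooled, function(s) length(s$genes), integer(1)),
                 delta = vapply(pooled, function(s) s$delta, numeric(1)),
                 n_perms = as.integer(n_perms),
                 rng_seed = rng_seed),
            class = "background_dist")
}

#' @export
print.background_dist <- function(x, ...) {
  cat("<background_dist> mode=", x$mode, ", ", x$n_perms,
      " permutations, ", length(x$delta), " subnetworks pooled\n", sep = "")
  invisible(x)
}

#' Size-stratified empirical p-value
#'
#' The fraction of background subnetworks with score strictly greater
#' than the observed subnetwork's, among background subnetworks of
#' equal size. Thin strata are widened symmetrically to the nearest
#' sizes until at least `min_stratum` background values are available
#' (random covers of similar size have similar score distributions).
#'
#' @param S a `scored_subnetwork` with its `delta` set.
#' @param bg a `background_dist`.
#' @param min_stratum minimum background values per stratum (default 20).
#' @return p-value in \[0, 1\].
#' @export
size_stratified_pvalue <- function(S, bg, min_stratum = 20) {
  stopifnot(inherits(S, "scored_subnetwork"), inherits(bg, "background_dist"))
  if (length(bg$delta) == 0L)
    stop("background distribution is empty", call. = FALSE)
  if (is.na(S$delta))
    stop("subnetwork has no score; run discovery scoring first", call. = FALSE)
  k <- length(S$genes)
  w <- 0L
  repeat {
    sel <- abs(bg$size - k) <= w
    if (sum(sel) >= min(min_stratum, length(bg$delta))) break
    w <- w + 1L
  }
  mean(bg$delta[sel] > S$delta)
}

#' Assess significance of subnetworks against two permutation nulls
#'
#' A subnetwork is statistically significant when its size-stratified
#' empirical p-value is below `threshold` under both the label- and the
#' profile-permutation backgrounds.
#'
#' @param subnets list of scored subnetworks.
#' @param bg_label label-permutation `background_dist`.
#' @param bg_profile profile-permutation `background_dist`.
#' @param threshold significance threshold (default 0.05).
#' @param min_stratum see [size_stratified_pvalue()].
#' @return The subnetwork list with `p_label`, `p_profile` and
#'   `significant` filled in, with a `data.frame` summary attached as
#'   attribute `"summary"` (also via [subnetworks_table()]).
#' @export
assess_significance <- function(subnets, bg_label, bg_profile,
                                threshold = 0.05, min_stratum = 20) {
  if (bg_label$mode != "label" || bg_profile$mode != "profile")
    stop("backgrounds must be built with modes 'label' and 'profile'",
         call. = FALSE)
  out <- lapply(subnets, function(s) {
    s$p_label <- size_stratified_pvalue(s, bg_label, min_stratum)
    s$p_profile <- size_stratified_pvalue(s, bg_profile, min_stratum)
    s$significant <- (s$p_label < threshold) && (s$p_profile < threshold)
    s
  })
  attr(out, "summary") <- subnetworks_table(out)
  attr(out, "threshold") <- threshold
  out
}
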
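#' Subnetwork activity
#'
#' The aggregate expression profile of a gene set: the unweighted mean
#' of the member genes' expression in each sample,
#' E_S(j) = sum_{i in S} E_i(j) / |S|.
#'
#' @param E expression matrix.
#' @param S non-empty character vector of member genes.
#' @return Numeric vector named by sample.
#' @export
subnetwork_activity <- function(E, S) {
  if (length(S) == 0L)
    stop("subnetwork is empty", call. = FALSE)
  missing <- setdiff(S, rownames(E))
  if (length(missing) > 0L)
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  colMeans(E[S, , drop = FALSE])
}

#' Default number of activity bins
#'
#' `ceiling(log2(n)) + 1` for n samples, a Sturges-style rule.
#'
#' @param n number of samples.
#' @return Integer bin count (at least 2).
#' @export
default_bins <- function(n) max(2L, as.integer(ceiling(log2(n)) + 1))

#' Equal-frequency discretization of an activity vector
#'
#' Bin edges are placed at empirical quantiles so that bins hold
#' near-equal numbers of samples; tied values always share a bin, so
#' fewer than `bins` symbols may be occupied.
#'
#' @param v numeric vector.
#' @param bins integer >= 2 and <= `length(v)`.
#' @return Integer vector of bin symbols (same names as `v`).
#' @export
discretize_activity <- function(v, bins) {
  if (!is.numeric(bins) || length(bins) != 1L || bins < 2L)
    stop("`bins` must be an integer >= 2", call. = FALSE)
  if (bins > length(v))
    stop("`bins` exceeds the number of samples", call. = FALSE)
  inner <- stats::quantile(v, probs = seq_len(bins - 1L) / bins,
                           names = FALSE, type = 7)
  sym <- findInterval(v, unique(inner), left.open = TRUE)
  stats::setNames(as.integer(sym), names(v))
}

#' Plug-in Shannon entropy in bits
#'
#' Empirical entropy H(X) = -sum p(x) log2 p(x) with 0*log 0 := 0.
#'
#' @param x vector of discrete symbols.
#' @return Entropy in bits.
#' @export
entropy_bits <- function(x) {
  if (length(x) == 0L)
    stop("empty vector", call. = FALSE)
  p <- tabulate(match(x, unique(x)))
  p <- p / length(x)
  -sum(p * log2(p))
}

#' Plug-in mutual information in bits
#'
#' I(X;Y) = H(X) + H(Y) - H(X,Y) from the empirical joint distribution.
#'
#' @param x,y equal-length vectors of discrete symbols.
#' @return Mutual information in bits (non-negative up to rounding).
#' @export
mutual_information_bits <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` lengths differ", call. = FALSE)
  joint <- paste(x, y, sep = "\r")
  mi <- entropy_bits(x) + entropy_bits(y) - entropy_bits(joint)
  max(mi, 0)
}

#' All-vs-all discriminative power
#'
#' Mutual information between the discretized subnetwork activity and
#' the full multi-class phenotype vector:
#' Delta_all-vs-all(S) = I(E_S, C) = H(C) - H(C | E_S).
#'
#' @param E expression matrix.
#' @param C [phenotype()] vector.
#' @param S member gene set.
#' @param bins activity bin count; default [default_bins()] of the
#'   sample count.
#' @return Score in bits.
#' @export
delta_all_vs_all <- function(E, C, S, bins = NULL) {
  stopifnot(inherits(C, "phenotype"))
  if (is.null(bins)) bins <- default_bins(length(C))
  act <- subnetwork_activity(E, S)[names(C$labels)]
  mutual_information_bits(discretize_activity(act, bins), C$labels)
}

#' One-vs-all discriminative power
#'
#' Mutual information between the discretized subnetwork activity and
#' the binary indicator of a single class:
#' Delta_one-vs-all^(t)(S) = I(E_S, C^(t)).
#'
#' @inheritParams delta_all_vs_all
#' @param t target class label.
#' @return Score in bits.
#' @export
delta_one_vs_all <- function(E, C, S, t, bins = NULL) {
  stopifnot(inherits(C, "phenotype"))
  if (is.null(bins)) bins <- default_bins(length(C))
  act <- subnetwork_activity(E, S)[names(C$labels)]
  mutual_information_bits(discretize_activity(act, bins), class_indicator(C, t))
}
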
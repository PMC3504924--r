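#' Validate a gene expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique gene
#' identifiers as row names and unique sample identifiers as column names.
#' Values must be finite: missing values are not supported and raise an
#' error rather than being silently handled.
#'
#' @param E numeric matrix, genes in rows, samples in columns.
#' @return `E`, invisibly classed checks passed; the matrix itself.
#' @export
validate_expression_matrix <- function(E) {
  if (!is.matrix(E) || !is.numeric(E))
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(E)) || is.null(colnames(E)))
    stop("expression matrix must have gene row names and sample column names",
         call. = FALSE)
  if (anyDuplicated(rownames(E)))
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(E)))
    stop("duplicate sample identifiers in expression matrix", call. = FALSE)
  if (!all(is.finite(E)))
    stop("expression matrix contains non-finite values (NA/NaN/Inf are not supported)",
         call. = FALSE)
  invisible(E)
}

#' Construct a phenotype vector
#'
#' Annotates each sample with one phenotype class. The class set is
#' recorded in order of first appearance; reporting functions order
#' classes lexicographically for reproducibility.
#'
#' @param labels character vector of class labels, one per sample.
#' @param samples sample identifiers; defaults to `names(labels)`.
#' @return An object of class `phenotype` with elements `labels`
#'   (named character vector) and `classes`.
#' @export
phenotype <- function(labels, samples = names(labels)) {
  labels <- as.character(labels)
  if (is.null(samples))
    stop("sample identifiers are required (name the labels or pass `samples`)",
         call. = FALSE)
  samples <- as.character(samples)
  if (length(samples) != length(labels))
    stop("`labels` and `samples` lengths differ", call. = FALSE)
  if (length(labels) == 0L)
    stop("phenotype vector is empty", call. = FALSE)
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers in phenotype vector", call. = FALSE)
  if (anyNA(labels) || any(labels == ""))
    stop("empty or missing class labels", call. = FALSE)
  structure(list(labels = stats::setNames(labels, samples),
                 classes = unique(labels)),
            class = "phenotype")
}

#' @export
print.phenotype <- function(x, ...) {
  cat("<phenotype> ", length(x$labels), " samples, ",
      length(x$classes), " classes\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @export
length.phenotype <- function(x) length(x$labels)

#' Per-class sample partition
#'
#' @param C a [phenotype()] object.
#' @return Named list mapping each class label t to the sample
#'   identifiers of U(t).
#' @export
class_partition <- function(C) {
  stopifnot(inherits(C, "phenotype"))
  split(names(C$labels), factor(C$labels, levels = C$classes))
}

#' Binary one-vs-all class indicator
#'
#' Returns the indicator vector whose j-th entry is 1 iff sample j
#' belongs to class `t`.
#'
#' @param C a [phenotype()] object.
#' @param t a class label present in `C`.
#' @return Integer 0/1 vector named by sample.
#' @export
class_indicator <- function(C, t) {
  stopifnot(inherits(C, "phenotype"))
  if (!t %in% C$classes)
    stop("unknown class label: ", t, call. = FALSE)
  stats::setNames(as.integer(C$labels == t), names(C$labels))
}

#' Per-gene mean and standard deviation
#'
#' Computes, for every gene, the mean and the population standard
#' deviation of its expression across all samples:
#' mu_i = sum_j E_i(j)/|U| and sigma_i = sqrt(sum_j (E_i(j)-mu_i)^2/|U|).
#' These pooled statistics define the dysregulation thresholds used by
#' [quantize()].
#'
#' @param E expression matrix (genes x samples).
#' @return Object of class `gene_stats`: list with numeric vectors
#'   `mu` and `sigma`, named by gene.
#' @export
compute_gene_stats <- function(E) {
  validate_expression_matrix(E)
  if (ncol(E) < 2L)
    stop("at least 2 samples are required to compute gene statistics",
         call. = FALSE)
  mu <- rowMeans(E)
  sigma <- sqrt(rowMeans((E - mu)^2))
  structure(list(mu = mu, sigma = sigma), class = "gene_stats")
}

#' Ternary quantization of expression
#'
#' A gene's expression in a sample is quantized to +1 if it exceeds
#' mu_i + alpha*sigma_i, to -1 if it is below mu_i - alpha*sigma_i, and
#' to 0 otherwise (strict inequalities; boundary values quantize to 0).
#' Genes with zero variance quantize to all zeros.
#'
#' @param E expression matrix.
#' @param alpha non-negative dysregulation threshold in units of the
#'   per-gene standard deviation. Default 2.
#' @return Integer matrix in \{-1, 0, +1\} with the same dimnames as
#'   `E` and attribute `alpha`.
#' @export
quantize <- function(E, alpha = 2) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  st <- compute_gene_stats(E)
  up <- st$mu + alpha * st$sigma
  lo <- st$mu - alpha * st$sigma
  Q <- matrix(0L, nrow(E), ncol(E), dimnames = dimnames(E))
  Q[E > up] <- 1L
  Q[E < lo] <- -1L
  # sigma == 0 rows: with alpha = 0 the strict inequalities are never met
  # anyway, so no special-casing is needed; kept explicit for clarity.
  attr(Q, "alpha") <- alpha
  Q
}

#' Z-score expression rows
#'
#' Optional preprocessing: centers and scales each gene's row to zero
#' mean and unit (population) standard deviation. Constant rows are
#' centered only.
#'
#' @param E expression matrix.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(E) {
  validate_expression_matrix(E)
  st <- compute_gene_stats(E)
  s <- ifelse(st$sigma > 0, st$sigma, 1)
  (E - st$mu) / s
}
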
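#' Select the top-k subnetworks per class and direction
#'
#' For every phenotype class and search direction, keeps the `k`
#' highest-scoring subnetworks (ties broken by seed identifier), giving
#' up to 2k|T| features for the covering searches.
#'
#' @param subnets list of scored subnetworks.
#' @param k features per class/direction (default 1).
#' @param classes class labels to cover; defaults to the sorted targets
#'   present.
#' @return Flat list of selected subnetworks.
#' @export
select_top_k <- function(subnets, k = 1, classes = NULL) {
  if (length(subnets) == 0L)
    stop("no subnetworks to select from", call. = FALSE)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  targets <- vapply(subnets, function(s) s$target %||% NA_character_, character(1))
  dirs <- vapply(subnets, function(s) s$direction, character(1))
  if (all(is.na(targets))) {
    # all-vs-all subnetworks have no class axis: take the top k overall
    ord <- order(-vapply(subnets, function(s) s$delta, numeric(1)),
                 vapply(subnets, function(s) s$seed, character(1)))
    return(subnets[utils::head(ord, k)])
  }
  if (is.null(classes)) classes <- sort(unique(targets[!is.na(targets)]))
  out <- list()
  for (t in classes) {
    for (d in sort(unique(dirs))) {
      pool <- subnets[which(targets == t & dirs == d)]
      if (length(pool) == 0L) next
      ord <- order(-vapply(pool, function(s) s$delta, numeric(1)),
                   vapply(pool, function(s) s$seed, character(1)))
      out <- c(out, pool[utils::head(ord, k)])
    }
  }
  expected <- k * length(classes) * length(unique(dirs))
  if (length(out) < expected)
    warning("only ", length(out), " of ", expected,
            " requested features available", call. = FALSE)
  out
}

#' Select the significant subnetworks
#'
#' Keeps exactly the subnetworks flagged significant by the dual
#' permutation test of [assess_significance()].
#'
#' @param subnets list of subnetworks with significance flags filled.
#' @return Flat list (possibly empty, with a warning).
#' @export
select_significant <- function(subnets) {
  flags <- vapply(subnets, function(s) isTRUE(s$significant), logical(1))
  if (!any(flags))
    warning("no subnetwork passed both significance tests", call. = FALSE)
  subnets[flags]
}

#' Subnetwork-activity feature matrix
#'
#' One column per selected subnetwork holding its aggregate expression
#' E_S(j); one row per sample.
#'
#' @param E expression matrix.
#' @param features non-empty list of subnetworks.
#' @return Numeric matrix (samples x features) with feature names
#'   `seed|class|direction`.
#' @export
feature_matrix <- function(E, features) {
  if (length(features) == 0L)
    stop("feature list is empty", call. = FALSE)
  X <- vapply(features, function(s) subnetwork_activity(E, s$genes),
              numeric(ncol(E)))
  dim(X) <- c(ncol(E), length(features))
  rownames(X) <- colnames(E)
  colnames(X) <- make.unique(vapply(features, function(s)
    paste(s$seed, s$target %||% "all", s$direction, sep = "|"), character(1)))
  X
}

#' Fit a Gaussian naive Bayes classifier
#'
#' Per-class, per-feature Gaussian densities with maximum-likelihood
#' means and variances (variances floored at 1e-9) and class priors
#' equal to training frequencies.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y class labels, one per row of `X`.
#' @return Object of class `gnb_model`.
#' @export
gnb_fit <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (nrow(X) != length(y))
    stop("rows of `X` and length of `y` differ", call. = FALSE)
  classes <- sort(unique(y))
  counts <- table(factor(y, levels = classes))
  if (any(counts < 2L))
    stop("every class needs >= 2 training samples (",
         paste(names(counts)[counts < 2L], collapse = ", "), ")",
         call. = FALSE)
  mu <- t(vapply(classes, function(cl) colMeans(X[y == cl, , drop = FALSE]),
                 numeric(ncol(X))))
  va <- t(vapply(classes, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    pmax(colMeans(sweep(Xi, 2L, colMeans(Xi))^2), 1e-9)
  }, numeric(ncol(X))))
  dim(mu) <- dim(va) <- c(length(classes), ncol(X))
  structure(list(classes = classes, prior = as.numeric(counts) / length(y),
                 mu = mu, var = va, n_features = ncol(X)),
            class = "gnb_model")
}

#' Predict classes with a Gaussian naive Bayes model
#'
#' Argmax of the log posterior; exact ties go to the lexicographically
#' smallest class label (classes are stored sorted).
#'
#' @param model a `gnb_model`.
#' @param X feature matrix with the training feature count.
#' @return Character vector of predicted labels.
#' @export
gnb_predict <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$n_features)
    stop("feature count differs from the fitted model", call. = FALSE)
  logpost <- vapply(seq_along(model$classes), function(ci) {
    ll <- rep(log(model$prior[ci]), nrow(X))
    for (f in seq_len(ncol(X)))
      ll <- ll + stats::dnorm(X[, f], model$mu[ci, f],
                              sqrt(model$var[ci, f]), log = TRUE)
    ll
  }, numeric(nrow(X)))
  dim(logpost) <- c(nrow(X), length(model$classes))
  model$classes[apply(logpost, 1L, which.max)]
}

confusion_from <- function(actual, predicted, classes) {
  tab <- table(factor(actual, levels = classes),
               factor(predicted, levels = classes))
  M <- matrix(as.integer(tab), length(classes), length(classes),
              dimnames = list(classes, classes))
  M
}

#' Stratified k-fold cross-validation of subnetwork features
#'
#' Samples of each class are randomly split into `folds` near-equal
#' groups (sizes differing by at most one). Each fold is predicted by a
#' Gaussian naive Bayes classifier trained on the remaining folds, and
#' the held-out predictions are aggregated into one confusion matrix.
#'
#' By default the features are fixed before cross-validation,
#' replicating the discover-once-then-validate protocol (which leaks
#' feature-selection information across folds); pass `discover_fun` to
#' rediscover features inside every training fold instead.
#'
#' @param E expression matrix.
#' @param C [phenotype()] vector.
#' @param features list of subnetworks used as features.
#' @param folds number of folds (default 10).
#' @param rng_seed optional integer seed for the fold assignment.
#' @param discover_fun optional `function(E_train, C_train)` returning a
#'   feature list, enabling nested (leakage-free) feature discovery.
#' @return Confusion matrix (rows = actual, columns = predicted) over
#'   lexicographically ordered classes.
#' @export
stratified_kfold_cv <- function(E, C, features, folds = 10, rng_seed = NULL,
                                discover_fun = NULL) {
  stopifnot(inherits(C, "phenotype"))
  if (folds < 2) stop("`folds` must be >= 2", call. = FALSE)
  classes <- sort(C$classes)
  part <- class_partition(C)
  if (any(lengths(part) < folds))
    warning("class(es) smaller than the fold count: some folds will lack them",
            call. = FALSE)
  assignment <- with_rng(rng_seed, {
    a <- integer(length(C)); names(a) <- names(C$labels)
    for (t in names(part)) {
      ids <- sample(part[[t]])
      a[ids] <- rep_len(seq_len(folds), length(ids))
    }
    a
  })
  actual <- character(0); predicted <- character(0)
  for (f in seq_len(folds)) {
    test_ids <- names(assignment)[assignment == f]
    train_ids <- names(assignment)[assignment != f]
    if (length(test_ids) == 0L) next
    feats <- if (is.null(discover_fun)) features else
      discover_fun(E[, train_ids, drop = FALSE],
                   phenotype(C$labels[train_ids]))
    X <- feature_matrix(E, feats)
    model <- gnb_fit(X[train_ids, , drop = FALSE], C$labels[train_ids])
    pred <- gnb_predict(model, X[test_ids, , drop = FALSE])
    actual <- c(actual, unname(C$labels[test_ids]))
    predicted <- c(predicted, pred)
  }
  confusion_from(actual, predicted, classes)
}

#' Cross-dataset classification
#'
#' Trains on the whole training bundle and predicts the whole test
#' bundle using features discovered on the training data.
#'
#' @param E_train,C_train training expression and phenotype.
#' @param E_test,C_test test expression and phenotype.
#' @param features subnetwork feature list (genes must be measured in
#'   both datasets).
#' @return Confusion matrix over the union of class labels.
#' @export
cross_classify <- function(E_train, C_train, E_test, C_test, features) {
  genes <- unique(unlist(lapply(features, function(s) s$genes)))
  missing <- setdiff(genes, rownames(E_test))
  if (length(missing) > 0L)
    stop("feature gene(s) absent from test data: ",
         paste(missing, collapse = ", "), call. = FALSE)
  classes <- sort(union(C_train$classes, C_test$classes))
  Xtr <- feature_matrix(E_train, features)
  Xte <- feature_matrix(E_test, features)
  model <- gnb_fit(Xtr[names(C_train$labels), , drop = FALSE], C_train$labels)
  pred <- gnb_predict(model, Xte[names(C_test$labels), , drop = FALSE])
  confusion_from(unname(C_test$labels), pred, classes)
}

# Two-decimal truncated (floored) display, matching how the per-class
# metrics are conventionally printed in the staging tables.
truncate2 <- function(x) sprintf("%.2f", floor(x * 100 + 1e-9) / 100)

#' Per-class precision and recall from a confusion matrix
#'
#' Precision for class t is the fraction of samples predicted as t that
#' truly are t (diagonal over column sum); recall is the fraction of
#' true-t samples predicted as t (diagonal over row sum). Weighted
#' averages weight the per-class values by actual class sizes, so the
#' weighted recall equals overall accuracy (trace/total). Display
#' strings are truncated (not rounded) to two decimals.
#'
#' @param M square confusion matrix, rows = actual, columns = predicted,
#'   identical dimnames.
#' @return Object of class `class_metrics`: exact per-class values,
#'   weighted averages, and two-decimal display strings.
#' @export
precision_recall <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M) || is.null(rownames(M)) ||
      !identical(rownames(M), colnames(M)))
    stop("confusion matrix must be square with matching class dimnames",
         call. = FALSE)
  if (sum(M) == 0) stop("confusion matrix is all zero", call. = FALSE)
  d <- diag(M)
  col_tot <- colSums(M)
  row_tot <- rowSums(M)
  zero_col <- col_tot == 0
  zero_row <- row_tot == 0
  if (any(zero_col))
    warning("no samples predicted for class(es): ",
            paste(rownames(M)[zero_col], collapse = ", "),
            "; precision reported as 0", call. = FALSE)
  precision <- ifelse(zero_col, 0, d / pmax(col_tot, 1L))
  recall <- ifelse(zero_row, 0, d / pmax(row_tot, 1L))
  w <- row_tot / sum(M)
  structure(list(
    precision = precision, recall = recall,
    weighted_precision = sum(w * precision),
    weighted_recall = sum(w * recall),
    accuracy = sum(d) / sum(M),
    display = list(precision = truncate2(precision),
                   recall = truncate2(recall),
                   weighted_precision = truncate2(sum(w * precision)),
                   weighted_recall = truncate2(sum(w * recall))),
    confusion = M), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  M <- x$confusion
  cat("Confusion matrix (rows = actual, columns = predicted)\n")
  disp <- cbind(M, recall = x$display$recall)
  print(disp, quote = FALSE)
  cat("precision:", paste(x$display$precision, collapse = "  "), "\n")
  cat("weighted precision:", x$display$weighted_precision,
      " weighted recall:", x$display$weighted_recall, "\n")
  invisible(x)
}
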
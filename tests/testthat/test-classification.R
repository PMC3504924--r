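feature_stub <- function(seed, target, direction, delta, genes = seed) {
  covernet:::new_scored_subnetwork(genes = genes, seed = seed,
                                   direction = direction, target = target,
                                   covered = character(0), delta = delta)
}

test_that("top-k selection is a per-class, per-direction sort and slice", {
  set.seed(101)
  subs <- list()
  for (t in c("A", "B", "C", "D"))
    for (d in c("positive", "negative"))
      for (i in 1:3)
        subs <- c(subs, list(feature_stub(sprintf("g%s%s%d", t, d, i),
                                          t, d, runif(1))))
  sel <- select_top_k(subs, k = 1)
  expect_lte(length(sel), 8)
  expect_length(sel, 8)
  # sort-then-slice oracle per (class, direction)
  for (t in c("A", "B", "C", "D")) {
    for (d in c("positive", "negative")) {
      pool <- Filter(function(s) s$target == t && s$direction == d, subs)
      best <- pool[[which.max(vapply(pool, function(s) s$delta, numeric(1)))]]
      hit <- Filter(function(s) s$target == t && s$direction == d, sel)
      expect_identical(hit[[1]]$seed, best$seed)
    }
  }
  expect_warning(sel_all <- select_top_k(subs, k = 10), "available")
  expect_length(sel_all, length(subs))
  expect_error(select_top_k(list(), 1), "no subnetworks")
})

test_that("significant-feature selection respects the flags exactly", {
  subs <- lapply(1:10, function(i) {
    s <- feature_stub(sprintf("g%02d", i), "A", "positive", i / 10)
    s$significant <- i %% 3 == 0
    s
  })
  sel <- select_significant(subs)
  expect_identical(vapply(sel, function(s) s$seed, character(1)),
                   sprintf("g%02d", c(3, 6, 9)))
  none <- lapply(subs, function(s) { s$significant <- FALSE; s })
  expect_warning(empty <- select_significant(none), "no subnetwork")
  expect_length(empty, 0)
})

test_that("feature matrices recompute subnetwork activities column-wise", {
  E <- toy_expression(6, 8)
  f1 <- feature_stub("g01", "A", "positive", 0.5)
  f2 <- feature_stub("g02", "B", "negative", 0.4, genes = c("g02", "g04"))
  X <- feature_matrix(E, list(f1, f2))
  expect_equal(dim(X), c(8L, 2L))
  expect_equal(unname(X[, 1]), unname(E["g01", ]))
  expect_equal(unname(X[, 2]), unname(subnetwork_activity(E, c("g02", "g04"))))
  expect_error(feature_matrix(E, list()), "empty")
})

test_that("Gaussian naive Bayes separates well-separated classes", {
  set.seed(8)
  X <- matrix(c(rnorm(20, -10), rnorm(20, 10)), ncol = 1)
  y <- rep(c("A", "B"), each = 20)
  m <- gnb_fit(X, y)
  expect_identical(gnb_predict(m, X), y)
  expect_error(gnb_fit(X[1:21, , drop = FALSE], y[1:21]), ">= 2")
})

test_that("posterior ties resolve to the lexicographically smallest class", {
  X <- matrix(c(-1, -1, 1, 1), ncol = 1)
  y <- c("B", "B", "A", "A")   # deliberately reversed
  m <- gnb_fit(X, y)
  expect_identical(gnb_predict(m, matrix(0, 1, 1)), "A")
})

test_that("posteriors match hand-computed density products", {
  X <- matrix(c(0, 2, 0, 2,   1, 1, 3, 3), ncol = 2)
  y <- c("A", "A", "B", "B")
  m <- gnb_fit(X, y)
  xq <- matrix(c(0.4, 1.8), 1, 2)
  ll <- function(cl) {
    mu <- colMeans(X[y == cl, ]); va <- pmax(colMeans(
      sweep(X[y == cl, ], 2, colMeans(X[y == cl, ]))^2), 1e-9)
    log(0.5) + sum(dnorm(xq, mu, sqrt(va), log = TRUE))
  }
  expect_identical(gnb_predict(m, xq),
                   c("A", "B")[which.max(c(ll("A"), ll("B")))])
})

test_that("naive Bayes predictions agree with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(12)
  X <- matrix(rnorm(120), ncol = 3)
  y <- sample(c("A", "B"), 40, replace = TRUE)
  m <- gnb_fit(X, y)
  ref <- e1071::naiveBayes(data.frame(X), y)
  mine <- gnb_predict(m, X)
  theirs <- as.character(predict(ref, data.frame(X)))
  # the reference uses the unbiased variance, ours the ML variance, so
  # compare only where the posterior margin is decisive
  post <- predict(ref, data.frame(X), type = "raw")
  margin <- abs(post[, 1] - post[, 2])
  expect_gt(sum(margin > 0.1), 25)
  expect_identical(mine[margin > 0.1], theirs[margin > 0.1])
})

test_that("stratified folds conserve samples and separate planted classes", {
  set.seed(44)
  n <- c(A = 12, B = 20, C = 15)
  E <- matrix(rnorm(3 * sum(n), sd = 0.1), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"),
                              sprintf("s%02d", seq_len(sum(n)))))
  C <- phenotype(rep(names(n), times = n), colnames(E))
  # make gene i the indicator of class i => perfectly separable features
  for (i in seq_along(n))
    E[i, C$labels == names(n)[i]] <- E[i, C$labels == names(n)[i]] + 10
  feats <- list(feature_stub("g1", "A", "positive", 1),
                feature_stub("g2", "B", "positive", 1),
                feature_stub("g3", "C", "positive", 1))
  M <- stratified_kfold_cv(E, C, feats, folds = 5, rng_seed = 7)
  expect_equal(unname(rowSums(M)), unname(as.numeric(n)))
  expect_equal(unname(diag(M)), unname(as.numeric(n)))
  expect_warning(stratified_kfold_cv(E, C, feats, folds = 14, rng_seed = 7),
                 "smaller than the fold count")
})

test_that("cross-classification equals fit-then-predict composition", {
  set.seed(52)
  E <- toy_expression(4, 12, seed = 52)
  C <- phenotype(rep(c("A", "B"), each = 6), colnames(E))
  feats <- list(feature_stub("g01", "A", "positive", 1),
                feature_stub("g02", "B", "positive", 1))
  M <- cross_classify(E, C, E, C, feats)
  expect_equal(unname(rowSums(M)), c(6, 6))
  X <- feature_matrix(E, feats)
  model <- gnb_fit(X, C$labels)
  pred <- gnb_predict(model, X)
  Mo <- table(factor(unname(C$labels), c("A", "B")), factor(pred, c("A", "B")))
  expect_equal(unname(as.matrix(M)), unname(unclass(Mo))[, ])
  bad <- list(feature_stub("gZZ", "A", "positive", 1))
  expect_error(cross_classify(E, C, E, C, bad), "gZZ")
})

test_that("precision and recall reproduce a staging table under truncation", {
  M <- matrix(c(9, 2, 1, 0, 3, 18, 8, 3, 5, 3, 20, 5, 4, 3, 6, 8),
              4, 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  pm <- precision_recall(M)
  expect_identical(unname(pm$display$precision), c("0.42", "0.69", "0.57", "0.50"))
  expect_identical(unname(pm$display$recall), c("0.75", "0.56", "0.60", "0.38"))
  expect_equal(pm$weighted_recall, 55 / 98)

  I4 <- diag(4L); dimnames(I4) <- list(LETTERS[1:4], LETTERS[1:4])
  pmI <- precision_recall(I4)
  expect_true(all(pmI$precision == 1) && all(pmI$recall == 1))

  Z <- matrix(0L, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(precision_recall(Z), "all zero")
  M2 <- matrix(c(2L, 1L, 0L, 0L), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(pm2 <- precision_recall(M2), "precision reported as 0")
  expect_equal(unname(pm2$precision[2]), 0)
})
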
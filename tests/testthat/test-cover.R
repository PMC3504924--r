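test_that("cover sets follow the quantized-matrix definition", {
  Q <- scripted_quantized(list(g1 = c(1, 1, 0, 0)), sprintf("s%d", 1:4))
  C <- phenotype(c("A", "A", "B", "B"), sprintf("s%d", 1:4))
  idx <- build_cover_index(Q, C)
  expect_setequal(cover_set(idx, "g1", "A", "positive"), c("s1", "s2"))
  expect_length(cover_set(idx, "g1", "B", "positive"), 0)
  expect_length(cover_set(idx, "g1", "A", "negative"), 0)

  Q0 <- scripted_quantized(list(g1 = c(0, 0, 0, 0)), sprintf("s%d", 1:4))
  idx0 <- build_cover_index(Q0, C)
  for (t in c("A", "B")) {
    expect_length(cover_set(idx0, "g1", t, "positive"), 0)
    expect_length(cover_set(idx0, "g1", t, "negative"), 0)
  }
})

test_that("cover index equals the brute-force definition on random matrices", {
  for (rep in 1:20) {
    Q <- random_quantized(6, 10, seed = 100 + rep)
    C <- random_phenotype(10, n_classes = 3, seed = 200 + rep)
    idx <- build_cover_index(Q, C)
    oracle <- oracle_cover_sets(Q, C)
    for (g in rownames(Q)) {
      pos_total <- 0L
      for (t in C$classes) {
        P <- sort(cover_set(idx, g, t, "positive"))
        N <- sort(cover_set(idx, g, t, "negative"))
        expect_identical(P, oracle[[paste(g, t, "P", sep = ".")]])
        expect_identical(N, oracle[[paste(g, t, "N", sep = ".")]])
        expect_length(intersect(P, N), 0)
        pos_total <- pos_total + length(P)
      }
      # partition identity: class-wise positive covers sum to the +1 count
      expect_equal(pos_total, sum(Q[g, ] == 1L))
    }
  }
})

test_that("target class is the argmax covered fraction with lexicographic ties", {
  Q <- scripted_quantized(list(g1 = c(1, 1, 0, 0),
                               g2 = c(1, 0, 1, 0),
                               g3 = c(0, 0, 0, 0)),
                          sprintf("s%d", 1:4))
  C <- phenotype(c("A", "A", "B", "B"), sprintf("s%d", 1:4))
  idx <- build_cover_index(Q, C)
  expect_identical(select_target_class(idx, "g1", "positive"), "A")
  expect_identical(select_target_class(idx, "g2", "positive"), "A")  # tie 0.5/0.5
  expect_null(select_target_class(idx, "g3", "positive"))
  expect_error(select_target_class(idx, "zz", "positive"), "unknown gene")
})

test_that("marginal gain is |P' | minus |N'| and shrinks with M", {
  Q <- scripted_quantized(list(gj = c(1, 1, -1, 0)), sprintf("s%d", 1:4))
  C <- phenotype(rep("A", 4), sprintf("s%d", 1:4))
  idx <- build_cover_index(Q, C)
  expect_equal(marginal_gain(idx, "gj", "A", c("s1", "s2", "s3"), "positive"), 1)
  expect_equal(marginal_gain(idx, "gj", "A", "s4", "positive"), 0)

  set.seed(55)
  for (rep in 1:10) {
    Q <- random_quantized(4, 8, seed = 300 + rep)
    C <- phenotype(rep("A", 8), sprintf("s%02d", 1:8))
    idx <- build_cover_index(Q, C)
    M <- sprintf("s%02d", 1:8)
    g <- sample(rownames(Q), 1)
    while (length(M) > 1) {
      M2 <- sample(M, length(M) - 1)
      gain_full <- marginal_gain(idx, g, "A", M, "positive")
      # positive-part monotonicity: |P ∩ M| is monotone; the signed gain
      # can move either way, so compare the positive cover counts
      p_full <- length(intersect(cover_set(idx, g, "A", "positive"), M))
      p_sub <- length(intersect(cover_set(idx, g, "A", "positive"), M2))
      expect_lte(p_sub, p_full)
      expect_true(is.finite(gain_full))
      M <- M2
    }
  }
})

test_that("growth stops immediately when the seed covers its whole class", {
  Q <- scripted_quantized(list(g1 = c(1, 1, 0), g2 = c(0, 1, 0)),
                          sprintf("s%d", 1:3))
  C <- phenotype(c("A", "A", "B"), sprintf("s%d", 1:3))
  idx <- build_cover_index(Q, C)
  G <- path_graph(c("g1", "g2"))
  sn <- grow_cover_subnetwork("g1", "positive", idx, G, ell = 1)
  expect_identical(sn$genes, "g1")
  expect_setequal(sn$covered, c("s1", "s2"))
})

test_that("growth completes a two-gene cover along a path", {
  Q <- scripted_quantized(list(g1 = c(1, 0), g2 = c(0, 1)), c("s1", "s2"))
  C <- phenotype(c("A", "A"), c("s1", "s2"))
  idx <- build_cover_index(Q, C)
  G <- path_graph(c("g1", "g2"))
  sn <- grow_cover_subnetwork("g1", "positive", idx, G, ell = 1)
  expect_identical(sn$genes, c("g1", "g2"))
  expect_setequal(sn$covered, c("s1", "s2"))
  expect_identical(sn$target, "A")
})

test_that("equal gains break toward minimum positive background coverage", {
  # g2 and g3 both cover the one uncovered A sample; g2 also covers a B
  # sample positively, so g3 must win the tie
  Q <- scripted_quantized(list(g1 = c(1, 0, 0),
                               g2 = c(0, 1, 1),
                               g3 = c(0, 1, 0)),
                          sprintf("s%d", 1:3))
  C <- phenotype(c("A", "A", "B"), sprintf("s%d", 1:3))
  idx <- build_cover_index(Q, C)
  G <- interaction_network(edge_df("g1", "g2", "g1", "g3"))
  sn <- grow_cover_subnetwork("g1", "positive", idx, G, ell = 1)
  expect_identical(sn$genes, c("g1", "g3"))
})

test_that("negative-direction growth swaps the cover-set roles", {
  Q <- scripted_quantized(list(g1 = c(-1, 0), g2 = c(0, -1)), c("s1", "s2"))
  C <- phenotype(c("A", "A"), c("s1", "s2"))
  idx <- build_cover_index(Q, C)
  G <- path_graph(c("g1", "g2"))
  expect_null(grow_cover_subnetwork("g1", "positive", idx, G, ell = 1))
  sn <- grow_cover_subnetwork("g1", "negative", idx, G, ell = 1)
  expect_identical(sn$genes, c("g1", "g2"))
})

test_that("discovery output is deterministic and bounded by 2|V|", {
  cfg <- synthetic_config(n_genes = 40, class_sizes = c(A = 8, B = 8),
                          planted_size = 3, rng_seed = 9)
  G <- generate_network(cfg)
  plants <- plant_class_subnetworks(G, cfg)
  dat <- generate_expression(G, plants, cfg)
  a <- discover_all(dat$expression, dat$labels, G = G, ell = 2)
  b <- discover_all(dat$expression, dat$labels, G = G, ell = 2)
  expect_identical(subnetworks_table(a), subnetworks_table(b))
  expect_lte(length(a), 2 * igraph::vcount(G))
  # with early stopping every accepted gene covers >= 1 new sample
  for (s in a) expect_gte(length(s$covered), length(s$genes))
})

test_that("a dataset with no dysregulated entries yields no subnetworks", {
  E <- matrix(rep(c(1, 2), each = 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), sprintf("s%d", 1:4)))
  C <- phenotype(c("A", "A", "B", "B"), colnames(E))
  expect_length(discover_all(E, C, G = path_graph(c("g1", "g2"))), 0)
})

test_that("the candidate pool grows with the hop bound", {
  cfg <- synthetic_config(n_genes = 30, class_sizes = c(A = 6, B = 6),
                          planted_size = 3, rng_seed = 4)
  G <- generate_network(cfg)
  dat <- generate_expression(G, plant_class_subnetworks(G, cfg), cfg)
  Q <- quantize(dat$expression, 1)
  idx <- build_cover_index(Q, dat$labels)
  for (v in sample(igraph::V(G)$name, 5)) {
    nb <- lapply(c(1, 2, 3, Inf), function(l) lhop_neighbors(G, v, l))
    for (i in 1:3) expect_true(all(nb[[i]] %in% nb[[i + 1]]))
  }
  # for any fixed member set, the candidate pool under ell+1 contains the
  # pool under ell (union of member neighborhoods minus members)
  nbs <- lapply(c(1, 2, 3),
                function(l) covernet:::all_lhop_neighborhoods(G, l))
  for (rep in 1:5) {
    S <- sample(igraph::V(G)$name, 3)
    pools <- lapply(nbs, function(nb)
      setdiff(unique(unlist(nb[S])), S))
    expect_true(all(pools[[1]] %in% pools[[2]]))
    expect_true(all(pools[[2]] %in% pools[[3]]))
  }
})
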
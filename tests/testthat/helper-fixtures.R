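# Small in-code fixtures shared across tests.

toy_expression <- function(n_genes = 6, n_samples = 8, seed = 42) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples))))
}

toy_phenotype <- function(labels = c("A", "A", "A", "A", "B", "B", "B", "B"),
                          samples = sprintf("s%02d", seq_along(labels))) {
  phenotype(labels, samples)
}

# A quantized matrix built directly (bypassing quantize()) so cover
# structure can be scripted exactly. `rows` is a list of -1/0/1 vectors.
scripted_quantized <- function(rows, samples) {
  Q <- do.call(rbind, lapply(rows, as.integer))
  rownames(Q) <- names(rows)
  colnames(Q) <- samples
  attr(Q, "alpha") <- 2
  Q
}

random_quantized <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  Q <- matrix(sample(c(-1L, 0L, 1L), n_genes * n_samples, replace = TRUE,
                     prob = c(0.2, 0.6, 0.2)),
              n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  attr(Q, "alpha") <- 2
  Q
}

random_phenotype <- function(n, n_classes = 2, seed = 1) {
  set.seed(seed)
  phenotype(sample(LETTERS[seq_len(n_classes)], n, replace = TRUE),
            sprintf("s%02d", seq_len(n)))
}

path_graph <- function(nodes) {
  interaction_network(cbind(nodes[-length(nodes)], nodes[-1]))
}

complete_graph <- function(nodes) {
  interaction_network(t(utils::combn(nodes, 2)))
}
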
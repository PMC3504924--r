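#' Configuration for the synthetic dysregulation generator
#'
#' Defines a PPI-like random network, a multi-class sample population,
#' and planted connected gene modules shifted up or down in exactly one
#' class. Defaults emulate a four-stage dataset with class sizes
#' 44/94/91/61 and a module of five genes shifted by two noise standard
#' deviations.
#'
#' @param n_genes number of genes/nodes (default 300).
#' @param attachment preferential-attachment parameter: edges added per
#'   new node (default 2).
#' @param class_sizes named integer vector of samples per class
#'   (default `c(A = 44, B = 94, C = 91, D = 61)`).
#' @param planted_size genes per planted module (default 5).
#' @param effect_size shift applied to planted genes in their class, in
#'   multiples of `noise_sd` (default 2).
#' @param noise_sd baseline expression standard deviation (default 1).
#' @param directions per-class shift directions, `"positive"` or
#'   `"negative"`; recycled (default alternating).
#' @param disjoint require planted modules to be gene-disjoint across
#'   classes (default TRUE).
#' @param rng_seed integer seed (default 1).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_genes = 300, attachment = 2,
                             class_sizes = c(A = 44, B = 94, C = 91, D = 61),
                             planted_size = 5, effect_size = 2,
                             noise_sd = 1,
                             directions = c("positive", "negative"),
                             disjoint = TRUE, rng_seed = 1) {
  if (is.null(names(class_sizes)))
    names(class_sizes) <- LETTERS[seq_along(class_sizes)]
  if (any(class_sizes < 1)) stop("class sizes must be >= 1", call. = FALSE)
  if (planted_size < 1) stop("`planted_size` must be >= 1", call. = FALSE)
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (n_genes < attachment + 1)
    stop("`n_genes` must exceed the attachment parameter", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 attachment = as.integer(attachment),
                 class_sizes = class_sizes,
                 planted_size = as.integer(planted_size),
                 effect_size = effect_size, noise_sd = noise_sd,
                 directions = rep_len(directions, length(class_sizes)),
                 disjoint = isTRUE(disjoint),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_config")
}

#' Generate a PPI-like random network
#'
#' Preferential attachment (Barabasi-Albert) graph: connected, simple,
#' with the heavy-tailed degree distribution typical of protein
#' interaction networks. Nodes are named `g001`, `g002`, ...
#'
#' @param cfg a [synthetic_config()].
#' @return An igraph object.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_rng(cfg$rng_seed, {
    g <- igraph::sample_pa(cfg$n_genes, m = cfg$attachment, directed = FALSE)
    igraph::V(g)$name <- sprintf("g%03d", seq_len(cfg$n_genes))
    igraph::simplify(g)
  })
}

# Connected gene set grown by randomized BFS from a random root,
# avoiding `exclude`.
sample_connected_set <- function(G, size, exclude = character(0)) {
  nodes <- setdiff(network_nodes(G), exclude)
  if (length(nodes) == 0L) return(NULL)
  root <- sample(nodes, 1L)
  set <- root
  frontier <- setdiff(names(igraph::neighbors(G, root)), exclude)
  while (length(set) < size) {
    frontier <- setdiff(frontier, set)
    if (length(frontier) == 0L) return(NULL)
    nxt <- if (length(frontier) == 1L) frontier else sample(frontier, 1L)
    set <- c(set, nxt)
    frontier <- union(frontier,
                      setdiff(names(igraph::neighbors(G, nxt)), exclude))
  }
  set
}

#' Plant connected dysregulated modules, one per class
#'
#' Samples, for every phenotype class, a connected gene set of the
#' configured size by randomized breadth-first growth from a random
#' root. Modules are gene-disjoint across classes when `cfg$disjoint`.
#'
#' @param G interaction network.
#' @param cfg a [synthetic_config()].
#' @return List of plant records: `class`, `direction`, `genes`.
#' @export
plant_class_subnetworks <- function(G, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$planted_size > length(network_nodes(G)))
    stop("planted module larger than the network", call. = FALSE)
  classes <- names(cfg$class_sizes)
  with_rng(cfg$rng_seed + 1L, {
    used <- character(0)
    plants <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      set <- NULL
      for (try in 1:50) {
        set <- sample_connected_set(G, cfg$planted_size,
                                    exclude = if (cfg$disjoint) used else character(0))
        if (!is.null(set)) break
      }
      if (is.null(set))
        stop("could not plant a disjoint connected module for class ",
             classes[i], call. = FALSE)
      used <- c(used, set)
      plants[[i]] <- list(class = classes[i],
                          direction = cfg$directions[i], genes = set)
    }
    plants
  })
}

#' Generate expression data with planted class-specific shifts
#'
#' Baseline expression is i.i.d. Normal(0, noise_sd^2). For every plant
#' record, `effect_size * noise_sd` is added to (or subtracted from,
#' for negative plants) the planted genes in the samples of the plant's
#' class only.
#'
#' @param G interaction network supplying the gene universe.
#' @param plants list from [plant_class_subnetworks()].
#' @param cfg a [synthetic_config()].
#' @return List with `expression` (matrix) and `labels`
#'   ([phenotype()]).
#' @export
generate_expression <- function(G, plants, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  genes <- network_nodes(G)
  classes <- names(cfg$class_sizes)
  labels <- rep(classes, times = cfg$class_sizes)
  samples <- sprintf("s%03d", seq_along(labels))
  C <- phenotype(labels, samples)
  E <- with_rng(cfg$rng_seed + 2L, {
    E <- matrix(stats::rnorm(length(genes) * length(samples),
                             sd = cfg$noise_sd),
                nrow = length(genes),
                dimnames = list(genes, samples))
    for (p in plants) {
      shift <- cfg$effect_size * cfg$noise_sd *
        if (p$direction == "positive") 1 else -1
      cols <- samples[labels == p$class]
      E[p$genes, cols] <- E[p$genes, cols] + shift
    }
    E
  })
  list(expression = E, labels = C)
}

#' Generate and write a complete synthetic dataset
#'
#' Writes the expression TSV, labels TSV, network edge-list TSV and a
#' ground-truth plants JSON into `outdir`. Regeneration with the same
#' configuration is byte-identical.
#'
#' @param cfg a [synthetic_config()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list with the in-memory bundle and file paths.
#' @export
generate_dataset <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  G <- generate_network(cfg)
  plants <- plant_class_subnetworks(G, cfg)
  dat <- generate_expression(G, plants, cfg)
  paths <- list(expression = file.path(outdir, "expression.tsv"),
                labels = file.path(outdir, "labels.tsv"),
                network = file.path(outdir, "network.tsv"),
                plants = file.path(outdir, "plants.json"))
  write_expression_matrix(dat$expression, paths$expression)
  write_phenotype_labels(dat$labels, paths$labels)
  write_ppi_edgelist(G, paths$network)
  jsonlite::write_json(lapply(plants, function(p)
    list(class = p$class, direction = p$direction, genes = p$genes)),
    paths$plants, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(network = G, plants = plants,
                 expression = dat$expression, labels = dat$labels,
                 paths = paths))
}

#' Jaccard index between two gene sets
#'
#' @param a,b character vectors.
#' @return |a ∩ b| / |a ∪ b|.
#' @export
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
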
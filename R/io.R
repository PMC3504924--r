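split_tsv_lines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample identifiers (with or without a
#' leading label for the gene-identifier column) and one row per gene:
#' gene identifier followed by one finite numeric value per sample.
#'
#' @param path file path.
#' @return Numeric matrix, genes x samples, rows in file order.
#' @export
read_expression_matrix <- function(path) {
  tok <- split_tsv_lines(path)
  if (length(tok) < 2L)
    stop("expression file needs a header and at least one gene row",
         call. = FALSE)
  width <- length(tok[[2L]])
  n_samp <- width - 1L
  header <- tok[[1L]]
  if (length(header) == n_samp) {
    samples <- header
  } else if (length(header) == width) {
    samples <- header[-1L]
  } else {
    stop("format error at line 1: header has ", length(header),
         " fields, expected ", n_samp, " or ", width, call. = FALSE)
  }
  rows <- tok[-1L]
  bad <- which(lengths(rows) != width)
  if (length(bad) > 0L)
    stop("format error at line ", bad[1L] + 1L, ": ",
         lengths(rows)[bad[1L]], " fields, expected ", width, call. = FALSE)
  genes <- vapply(rows, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(rows, function(r) as.numeric(r[-1L]), numeric(n_samp)))
  E <- matrix(vals, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  if (anyNA(E) || !all(is.finite(E))) {
    bad_row <- which(apply(E, 1L, function(r) any(!is.finite(r))))[1L]
    stop("parse error at line ", bad_row + 1L,
         ": non-numeric or non-finite expression value", call. = FALSE)
  }
  validate_expression_matrix(E)
  E
}

#' Write a gene expression matrix to TSV
#'
#' @param E expression matrix.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(E, path) {
  validate_expression_matrix(E)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", colnames(E)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(E)), function(i)
    paste(c(rownames(E)[i], sprintf("%.17g", E[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read sample phenotype labels from TSV
#'
#' Two columns: sample identifier and class label. A header line
#' `sample<TAB>class` is auto-detected by its first token.
#'
#' @param path file path.
#' @return A [phenotype()] object; classes in order of first appearance.
#' @export
read_phenotype_labels <- function(path) {
  tok <- split_tsv_lines(path)
  if (length(tok) == 0L)
    stop("labels file is empty", call. = FALSE)
  if (identical(tok[[1L]][1L], "sample")) tok <- tok[-1L]
  if (length(tok) == 0L)
    stop("labels file has a header but no samples", call. = FALSE)
  bad <- which(lengths(tok) < 2L)
  if (length(bad) > 0L)
    stop("format error at line ", bad[1L], ": expected 2 tab-separated fields",
         call. = FALSE)
  samples <- vapply(tok, `[[`, character(1), 1L)
  labels <- vapply(tok, `[[`, character(1), 2L)
  if (anyDuplicated(samples))
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  phenotype(labels, samples)
}

#' Write phenotype labels to TSV
#'
#' @param C [phenotype()] object.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_phenotype_labels <- function(C, path) {
  stopifnot(inherits(C, "phenotype"))
  writeLines(c("sample\tclass",
               paste(names(C$labels), C$labels, sep = "\t")), path)
  invisible(path)
}

#' Read a protein-protein interaction network
#'
#' Accepts a tab-separated edge list (two identifier columns, extra
#' columns ignored) or, for paths ending in `.sif`, the SIF dialect
#' `nodeA relation nodeB`. Self-loops are dropped, duplicate and
#' reversed edges collapsed, and isolated nodes are absent.
#'
#' @param path file path.
#' @return An igraph object.
#' @export
read_ppi_edgelist <- function(path) {
  sif <- grepl("\\.sif$", path, ignore.case = TRUE)
  tok <- if (sif) {
    lapply(strsplit(readLines(path), "[ \t]+"), function(x) x[nzchar(x)])
  } else {
    split_tsv_lines(path)
  }
  tok <- tok[lengths(tok) > 0L]
  need <- if (sif) 3L else 2L
  bad <- which(lengths(tok) < need)
  if (length(bad) > 0L)
    stop("format error at line ", bad[1L], ": expected at least ", need,
         " fields", call. = FALSE)
  a <- vapply(tok, `[[`, character(1), 1L)
  b <- vapply(tok, `[[`, character(1), if (sif) 3L else 2L)
  interaction_network(cbind(a, b))
}

#' Write a network as a two-column edge list TSV
#'
#' Edges are written with lexicographically ordered endpoints and rows
#' sorted, so identical graphs serialize identically.
#'
#' @param G igraph object.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_ppi_edgelist <- function(G, path) {
  el <- igraph::as_edgelist(G)
  el <- t(apply(el, 1L, sort))
  ord <- order(el[, 1L], el[, 2L])
  writeLines(paste(el[ord, 1L], el[ord, 2L], sep = "\t"), path)
  invisible(path)
}

subnet_id <- function(s)
  paste(s$seed, s$target %||% "all", s$direction, sep = "|")

#' Write subnetworks as a GMT file with a JSON sidecar
#'
#' Each GMT line holds the identifier `seed|class|direction`, a
#' description with the score and p-values, then the member genes, all
#' tab-separated. The JSON sidecar (same path with extension `.json`)
#' carries the full numeric records and is what [read_subnetwork_sets()]
#' restores.
#'
#' @param path GMT file path.
#' @param subnets list of scored subnetworks.
#' @return Invisibly, the sidecar path.
#' @export
write_subnetwork_sets <- function(path, subnets) {
  json_path <- paste0(sub("\\.gmt$", "", path), ".json")
  if (length(subnets) == 0L) {
    warning("no subnetworks to write; emitting empty files", call. = FALSE)
    writeLines(character(0), path)
    jsonlite::write_json(list(), json_path, auto_unbox = TRUE, digits = NA)
    return(invisible(json_path))
  }
  for (s in subnets) {
    if (length(s$genes) == 0L)
      stop("empty subnetwork cannot be written", call. = FALSE)
    fields <- c(s$genes, s$seed, s$target, s$direction)
    if (any(grepl("\t", fields, fixed = TRUE)))
      stop("identifier containing a tab cannot be written to GMT",
           call. = FALSE)
  }
  lines <- vapply(subnets, function(s) {
    desc <- sprintf("delta=%.12g;p_label=%s;p_profile=%s",
                    s$delta, format(s$p_label), format(s$p_profile))
    paste(c(subnet_id(s), desc, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  recs <- lapply(subnets, function(s)
    list(id = subnet_id(s), seed = s$seed, target = s$target,
         direction = s$direction, mode = s$mode, genes = s$genes,
         covered = s$covered, delta = s$delta,
         p_label = s$p_label, p_profile = s$p_profile,
         significant = s$significant))
  jsonlite::write_json(recs, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(json_path)
}

#' Read subnetworks back from a JSON sidecar
#'
#' @param json_path path written by [write_subnetwork_sets()].
#' @return List of `scored_subnetwork` objects.
#' @export
read_subnetwork_sets <- function(json_path) {
  recs <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    s <- new_scored_subnetwork(genes = as.character(r$genes),
                               seed = r$seed, direction = r$direction,
                               target = r$target,
                               covered = as.character(r$covered %||% character(0)),
                               delta = as.numeric(r$delta %||% NA_real_),
                               mode = r$mode %||% "one_vs_all")
    s$p_label <- as.numeric(r$p_label %||% NA_real_)
    s$p_profile <- as.numeric(r$p_profile %||% NA_real_)
    s$significant <- r$significant %||% NA
    s
  })
}

#' Read a dataset bundle from disk
#'
#' Reads and cross-validates expression, labels and (optionally) a
#' network: expression and labels must cover identical sample sets, and
#' the network is restricted to the measured genes.
#'
#' @param expression,labels file paths.
#' @param network optional network file path.
#' @return List with `expression`, `labels`, `network` (or NULL).
#' @export
read_dataset_bundle <- function(expression, labels, network = NULL) {
  E <- read_expression_matrix(expression)
  C <- read_phenotype_labels(labels)
  if (!setequal(colnames(E), names(C$labels)))
    stop("expression matrix and labels cover different sample sets",
         call. = FALSE)
  G <- NULL
  if (!is.null(network)) {
    G <- read_ppi_edgelist(network)
    G <- restrict_to_expression(G, rownames(E))
  }
  list(expression = E, labels = C, network = G)
}

#' Write a confusion matrix as TSV with class-labeled header
#'
#' @param M confusion matrix.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_confusion_matrix <- function(M, path) {
  lines <- c(paste(c("class", colnames(M)), collapse = "\t"),
             vapply(seq_len(nrow(M)), function(i)
               paste(c(rownames(M)[i], M[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a confusion matrix written by [write_confusion_matrix()]
#'
#' @param path file path.
#' @return Integer matrix with class dimnames.
#' @export
read_confusion_matrix <- function(path) {
  tok <- split_tsv_lines(path)
  classes <- tok[[1L]][-1L]
  rows <- tok[-1L]
  M <- t(vapply(rows, function(r) as.integer(r[-1L]),
                integer(length(classes))))
  dim(M) <- c(length(rows), length(classes))
  rownames(M) <- vapply(rows, `[[`, character(1), 1L)
  colnames(M) <- classes
  if (!identical(rownames(M), colnames(M)))
    stop("confusion matrix rows and columns disagree", call. = FALSE)
  M
}
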
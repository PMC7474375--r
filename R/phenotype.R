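## Phenotype space: similarity matrix over phenotypes plus known
## phenotype-gene associations.

#' Construct a phenotype space
#'
#' A phenotype space couples a symmetric phenotype-similarity matrix (unit
#' diagonal, values in \[0, 1\]) with the known gene associations of each
#' phenotype. It is the input to phenotype-driven gene prioritization.
#'
#' @param similarity square numeric matrix with identical row and column
#'   names (phenotype ids); must be symmetric within `1e-9`, have diagonal
#'   exactly 1, and values in \[0, 1\].
#' @param known_genes named list mapping phenotype id to a [gene_set] or
#'   character vector of associated genes.
#' @param network optional network; if given, known genes absent from it
#'   are flagged in the `missing_genes` field (they are kept, but contribute
#'   nothing to closeness profiles).
#' @return An object of class `phenotype_space` with fields `ids`,
#'   `similarity`, `known_genes`, `missing_genes`.
#' @export
phenotype_space <- function(similarity, known_genes, network = NULL) {
  similarity <- as.matrix(similarity)
  if (nrow(similarity) != ncol(similarity)) stop("similarity must be square")
  ids <- rownames(similarity)
  if (is.null(ids) || is.null(colnames(similarity)) ||
      !identical(ids, colnames(similarity))) {
    stop("similarity must carry identical row and column phenotype ids")
  }
  if (any(similarity < 0 | similarity > 1)) stop("similarities must lie in [0, 1]")
  if (max(abs(similarity - t(similarity))) > 1e-9) {
    stop("similarity matrix is not symmetric (tolerance 1e-9)")
  }
  if (any(diag(similarity) != 1)) stop("similarity diagonal must be exactly 1")
  known_genes <- lapply(known_genes, as_members)
  if (is.null(names(known_genes)) || !all(names(known_genes) %in% ids)) {
    stop("known_genes must be named by phenotype ids present in the similarity matrix")
  }
  missing_genes <- character(0)
  if (!is.null(network)) {
    all_known <- unique(unlist(known_genes, use.names = FALSE))
    missing_genes <- setdiff(all_known, igraph::V(network)$name)
  }
  structure(
    list(ids = ids, similarity = similarity, known_genes = known_genes,
         missing_genes = missing_genes),
    class = "phenotype_space"
  )
}

#' @export
print.phenotype_space <- function(x, ...) {
  cat(sprintf("<phenotype_space> %d phenotypes, %d with known genes\n",
              length(x$ids), length(x$known_genes)))
  if (length(x$missing_genes) > 0) {
    cat(sprintf("  %d known genes absent from companion network\n",
                length(x$missing_genes)))
  }
  invisible(x)
}

#' Read/write a phenotype similarity matrix (CSV with header and index column)
#'
#' @param path path to the CSV file.
#' @return For `read_similarity_csv`, a numeric matrix with phenotype ids as
#'   dimnames.
#' @export
read_similarity_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, sep = ",", row.names = 1, check.names = FALSE)
  as.matrix(df)
}

#' @rdname read_similarity_csv
#' @param m numeric matrix with dimnames.
#' @export
write_similarity_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write known phenotype-gene associations (two-column TSV)
#'
#' Each line is `phenotype <tab> gene`.
#'
#' @param path path to the TSV file.
#' @return For `read_known_genes`, a named list of character vectors.
#' @export
read_known_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, col.names = c("phenotype", "gene"),
                   colClasses = "character")
  split(df$gene, factor(df$phenotype, levels = unique(df$phenotype)))
}

#' @rdname read_known_genes
#' @param known named list mapping phenotype id to gene identifiers.
#' @export
write_known_genes <- function(known, path) {
  df <- data.frame(
    phenotype = rep(names(known), lengths(known)),
    gene = unlist(known, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
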
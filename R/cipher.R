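## Phenotype-driven gene prioritization.
##
## Each gene is scored by the Pearson concordance between the query
## phenotype's similarity profile over reference phenotypes and the gene's
## network-closeness profile to each reference phenotype's known genes.
## The closeness kernel is Gaussian in the unweighted shortest-path length:
## a known gene at distance L contributes exp(-L^2), so a gene that is
## itself a known gene contributes exp(0) = 1 and unreachable known genes
## contribute 0.

# Reference phenotypes for a query: every phenotype with at least one known
# gene, excluding the query itself (its associations are what is predicted).
reference_phenotypes <- function(space, query) {
  refs <- names(space$known_genes)[lengths(space$known_genes) > 0]
  setdiff(refs, query)
}

closeness_kernel <- function(L) exp(-L^2)

#' Network-closeness profile of one gene
#'
#' For each reference phenotype, sums the Gaussian shortest-path kernel
#' `exp(-L^2)` over that phenotype's known genes, where `L` is the
#' unweighted shortest-path length from `gene`. Known genes unreachable
#' from `gene` (or absent from the network) contribute 0.
#'
#' @param net an undirected simple `igraph` network.
#' @param gene a node name in `net`.
#' @param space a [phenotype_space].
#' @param refs reference phenotype ids; defaults to every phenotype with
#'   known genes.
#' @return A named numeric vector (one value per reference phenotype) with
#'   attribute `gene`.
#' @export
closeness_profile <- function(net, gene, space, refs = NULL) {
  assert_network(net)
  if (!gene %in% igraph::V(net)$name) stop("gene not in network: ", gene)
  if (is.null(refs)) refs <- names(space$known_genes)[lengths(space$known_genes) > 0]
  if (length(refs) == 0) stop("no reference phenotype has known genes")
  d <- shortest_path_lengths(net, gene)
  vals <- vapply(refs, function(ph) {
    g <- intersect(space$known_genes[[ph]], names(d))
    if (length(g) == 0) return(0)
    sum(closeness_kernel(d[g]))
  }, numeric(1))
  structure(vals, gene = gene)
}

# Closeness profiles for every network gene at once: a (genes x refs)
# matrix, computed from one BFS per known gene.
closeness_matrix <- function(net, space, refs) {
  nodes <- igraph::V(net)$name
  knowns <- lapply(space$known_genes[refs], intersect, nodes)
  all_known <- unique(unlist(knowns, use.names = FALSE))
  M <- matrix(0, nrow = length(nodes), ncol = length(refs),
              dimnames = list(nodes, refs))
  if (length(all_known) > 0) {
    D <- igraph::distances(net, v = all_known, to = igraph::V(net), weights = NA)
    K <- closeness_kernel(D) # exp(-Inf) = 0 handles unreachable pairs
    for (j in seq_along(refs)) {
      g <- knowns[[j]]
      if (length(g) > 0) M[, j] <- colSums(K[g, , drop = FALSE])
    }
  }
  M
}

#' Concordance score of one gene for a query phenotype
#'
#' Pearson correlation between the query phenotype's similarity row over
#' the reference phenotypes and the gene's closeness profile on the same
#' index. Returns `NA` (gene excluded from ranking) when either vector has
#' zero variance.
#'
#' @param profile a closeness profile from [closeness_profile()], named by
#'   reference phenotype.
#' @param query the query phenotype id.
#' @param space a [phenotype_space].
#' @return A number in \[-1, 1\], or `NA` if undefined.
#' @export
cipher_score <- function(profile, query, space) {
  refs <- names(profile)
  if (is.null(refs) || !all(refs %in% space$ids)) {
    stop("profile names must be phenotype ids of the space")
  }
  if (!query %in% space$ids) stop("unknown query phenotype: ", query)
  if (length(refs) < 3) stop("at least 3 reference phenotypes are required")
  s <- space$similarity[query, refs]
  if (stats::sd(s) == 0 || stats::sd(profile) == 0) return(NA_real_)
  stats::cor(as.numeric(profile), as.numeric(s))
}

#' Rank network genes for a query phenotype
#'
#' Scores every network gene by [cipher_score()] and selects the top
#' `top_n` as the syndrome-related biomolecule list. Genes whose closeness
#' profile has zero variance are excluded (their correlation is undefined).
#' Ties are broken lexicographically by gene id (C collation), so output is
#' platform-independent.
#'
#' @param net an undirected simple `igraph` network.
#' @param space a [phenotype_space]; every phenotype other than the query
#'   that has known genes serves as a reference phenotype (at least 3
#'   required).
#' @param query the query phenotype id.
#' @param top_n number of genes to select (default 500).
#' @return An object of class `cipher_result`: list with `query`, `ranking`
#'   (data.frame `gene`, `score`, `rank`), `selected` ([gene_set] of the
#'   top `top_n`), `n_scoreable`, `top_n`.
#' @export
cipher_rank <- function(net, space, query, top_n = 500) {
  assert_network(net)
  if (!query %in% space$ids) stop("unknown query phenotype: ", query)
  stopifnot(top_n >= 1)
  refs <- reference_phenotypes(space, query)
  if (length(refs) < 3) stop("at least 3 reference phenotypes with known genes are required")
  M <- closeness_matrix(net, space, refs)
  s <- as.numeric(space$similarity[query, refs])
  if (stats::sd(s) == 0) stop("query similarity profile has zero variance; no gene is scoreable")
  scores <- suppressWarnings(as.numeric(stats::cor(t(M), s)))
  names(scores) <- rownames(M)
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no scoreable gene (all closeness profiles have zero variance)")
  ord <- order(-scores, names(scores), method = "radix")
  ranking <- data.frame(
    gene = names(scores)[ord],
    score = unname(scores[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  n_sel <- min(top_n, nrow(ranking))
  structure(
    list(query = query,
         ranking = ranking,
         selected = gene_set(paste0(query, "_top", n_sel), ranking$gene[seq_len(n_sel)],
                             description = "top-ranked genes"),
         n_scoreable = nrow(ranking),
         top_n = top_n),
    class = "cipher_result"
  )
}

#' @export
print.cipher_result <- function(x, ...) {
  cat(sprintf("<cipher_result> query '%s': %d scoreable genes, %d selected\n",
              x$query, x$n_scoreable, length(x$selected$members)))
  print(head(x$ranking, 5))
  invisible(x)
}

#' @export
summary.cipher_result <- function(object, ...) {
  cat(sprintf("Gene prioritization for query phenotype '%s'\n", object$query))
  cat(sprintf("  scoreable genes : %d\n", object$n_scoreable))
  cat(sprintf("  selected (top %d): %d genes\n", object$top_n,
              length(object$selected$members)))
  cat(sprintf("  score range     : [%.4f, %.4f]\n",
              min(object$ranking$score), max(object$ranking$score)))
  invisible(object)
}

#' Degree-preserving network shuffle
#'
#' Randomizes the network by double edge swaps that keep every node's
#' degree fixed; no self-loops or duplicate edges are introduced. This is
#' the standard null model for network prioritization: naive rewiring would
#' conflate degree effects with the signal under test. `10 * ecount(net)`
#' swap attempts are made. Deterministic given `seed`.
#'
#' @param net an undirected simple `igraph` network with at least 2 edges;
#'   smaller graphs are returned unchanged with attribute
#'   `shuffle_warning = TRUE`.
#' @param seed integer seed (`NULL`: use the current RNG stream).
#' @param n_swaps number of swap attempts.
#' @return A shuffled network with the same node set and degree sequence.
#' @export
shuffle_network <- function(net, seed = NULL, n_swaps = 10 * igraph::ecount(net)) {
  assert_network(net)
  if (igraph::ecount(net) < 2) {
    warning("network has fewer than 2 edges; returning it unshuffled")
    attr(net, "shuffle_warning") <- TRUE
    return(net)
  }
  with_seed(seed,
    igraph::rewire(net, with = igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
  )
}

#' Precision and recall of a predicted gene set
#'
#' `precision = 100 * |predicted intersect reported| / |predicted|` and
#' `recall = 100 * |predicted intersect reported| / |reported|`.
#'
#' @param predicted,reported gene sets ([gene_set] or character vectors);
#'   both must be non-empty.
#' @return Named numeric vector `c(precision, recall)` in percent.
#' @export
precision_recall <- function(predicted, reported) {
  p <- as_members(predicted)
  r <- as_members(reported)
  if (length(p) == 0) stop("predicted set is empty; precision undefined")
  if (length(r) == 0) stop("reported set is empty; recall undefined")
  i <- length(intersect(p, r))
  c(precision = 100 * i / length(p), recall = 100 * i / length(r))
}

#' Permutation validation of gene prioritization
#'
#' Computes precision and recall of the top-`top_n` prediction against a
#' reported gene list, then rebuilds the prediction on `n_perm`
#' degree-preserving shuffles of the network to obtain null distributions.
#' Empirical p-values use the add-one (permutation-inclusive) estimator
#' `(1 + #\{null >= observed\}) / (1 + n_perm)`, which never returns 0.
#'
#' @inheritParams cipher_rank
#' @param reported gene set of literature-reported genes.
#' @param n_perm number of network shuffles (default 1000). `n_perm = 0`
#'   returns the observed values with empty nulls and `NA` p-values.
#' @param seed integer seed for the shuffle ensemble.
#' @return An object of class `cipher_validation`: list with `precision`,
#'   `recall` (percent), `null_precision`, `null_recall` (length `n_perm`),
#'   `p_precision`, `p_recall`, `n_perm`, `top_n`.
#' @export
permutation_validation <- function(net, space, query, reported,
                                   n_perm = 1000, top_n = 500, seed = NULL) {
  real <- cipher_rank(net, space, query, top_n = top_n)
  obs <- precision_recall(real$selected, reported)
  null_p <- numeric(0)
  null_r <- numeric(0)
  if (n_perm > 0) {
    seeds <- with_seed(seed, sample.int(2147483646L, n_perm))
    null_p <- numeric(n_perm)
    null_r <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      g <- shuffle_network(net, seed = seeds[i])
      res <- cipher_rank(g, space, query, top_n = top_n)
      pr <- precision_recall(res$selected, reported)
      null_p[i] <- pr[["precision"]]
      null_r[i] <- pr[["recall"]]
    }
  }
  emp_p <- function(null, x) {
    if (length(null) == 0) return(NA_real_)
    (1 + sum(null >= x)) / (1 + length(null))
  }
  structure(
    list(precision = obs[["precision"]], recall = obs[["recall"]],
         null_precision = null_p, null_recall = null_r,
         p_precision = emp_p(null_p, obs[["precision"]]),
         p_recall = emp_p(null_r, obs[["recall"]]),
         n_perm = n_perm, top_n = top_n, query = query),
    class = "cipher_validation"
  )
}

#' @export
print.cipher_validation <- function(x, ...) {
  cat(sprintf("<cipher_validation> query '%s' (top %d, %d permutations)\n",
              x$query, x$top_n, x$n_perm))
  cat(sprintf("  precision: %6.2f%%  (null mean %6.2f%%, p = %s)\n",
              x$precision, if (x$n_perm > 0) mean(x$null_precision) else NA,
              format(x$p_precision, digits = 3)))
  cat(sprintf("  recall   : %6.2f%%  (null mean %6.2f%%, p = %s)\n",
              x$recall, if (x$n_perm > 0) mean(x$null_recall) else NA,
              format(x$p_recall, digits = 3)))
  invisible(x)
}
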
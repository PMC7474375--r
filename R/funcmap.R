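## Functional characterization of a gene network: set enrichment,
## differential-expression overlay, topological proximity of target sets,
## and hub-degree ranking.

#' Fisher's exact test enrichment of a gene set in term collections
#'
#' One-sided (over-representation) Fisher's exact test of the query set
#' against each term, restricted to the background universe, with
#' Benjamini-Hochberg adjustment across all tested terms. Terms are
#' intersected with the background before testing; terms empty after
#' intersection are dropped.
#'
#' @param query a [gene_set] or character vector; must lie within
#'   `background`.
#' @param terms list of [gene_set] objects (e.g. from [read_gmt()]).
#' @param background character vector (or [gene_set]) defining the gene
#'   universe; defaults should be all network genes.
#' @param alpha adjusted-p significance cutoff for the `flagged` column.
#' @return A data.frame with columns `term`, `overlap`, `query_size`,
#'   `term_size`, `background_size`, `p`, `p_adjusted`, `flagged`, sorted
#'   by `p`.
#' @export
fisher_enrichment <- function(query, terms, background, alpha = 0.05) {
  q <- as_members(query)
  bg <- as_members(background)
  if (length(q) == 0) stop("query set is empty")
  if (!all(q %in% bg)) stop("query genes must all lie within the background universe")
  N <- length(bg)
  rows <- lapply(terms, function(tm) {
    t_bg <- intersect(as_members(tm), bg)
    if (length(t_bg) == 0) return(NULL)
    a <- length(intersect(q, t_bg))
    mat <- matrix(c(a, length(q) - a,
                    length(t_bg) - a, N - length(q) - length(t_bg) + a),
                  nrow = 2)
    p <- stats::fisher.test(mat, alternative = "greater")$p.value
    name <- if (inherits(tm, "gene_set")) tm$name else NA_character_
    data.frame(term = name, overlap = a, query_size = length(q),
               term_size = length(t_bg), background_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no term overlaps the background universe")
  out <- do.call(rbind, rows)
  if (anyNA(out$term)) out$term[is.na(out$term)] <- names(terms)[is.na(out$term)]
  out$p_adjusted <- benjamini_hochberg(out$p)
  out$flagged <- out$p_adjusted < alpha
  out <- out[order(out$p, out$term, method = "radix"), ]
  rownames(out) <- NULL
  out
}

#' Overlay differentially expressed genes onto a network module
#'
#' Partitions the DEGs mapped to the network into `direct` members of the
#' module and `indirect` genes one PPI hop from a module member (the two
#' sets are disjoint and exhaustive over module-linked DEGs); the module
#' coverage p-value is the hypergeometric upper tail of the direct overlap
#' given the background universe.
#'
#' @param degs a data.frame with at least a `gene` column (see
#'   [call_degs()] for the full table: `gene`, `direction`, `effect`, `p`).
#' @param network an undirected simple `igraph` network.
#' @param module a [gene_set] or character vector, contained in the
#'   network's nodes.
#' @param background_size gene universe size for the hypergeometric test;
#'   defaults to the network's node count.
#' @param extra_edges optional list of gene sets; genes co-occurring in a
#'   set are treated as adjacent (a pathway-derived edge layer extending
#'   PPI adjacency).
#' @return An object of class `overlay_result`: list with `direct`,
#'   `indirect`, `unlinked` (character vectors), `coverage_p`,
#'   `module_size`, `n_degs_mapped`, `background_size`.
#' @export
overlay_degs <- function(degs, network, module, background_size = NULL,
                         extra_edges = NULL) {
  assert_network(network)
  if (is.null(degs) || nrow(degs) == 0) stop("DEG table is empty")
  if (!"gene" %in% names(degs)) stop("DEG table must have a 'gene' column")
  mod <- as_members(module)
  nodes <- igraph::V(network)$name
  if (!all(mod %in% nodes)) stop("module genes must all lie in the network")
  if (is.null(background_size)) background_size <- length(nodes)
  dg <- unique(as.character(degs$gene))
  mapped <- intersect(dg, nodes)
  direct <- intersect(mapped, mod)
  neigh <- unique(unlist(lapply(
    igraph::adjacent_vertices(network, mod), function(v) v$name)))
  if (!is.null(extra_edges)) {
    for (s in extra_edges) {
      s <- as_members(s)
      if (length(intersect(s, mod)) > 0) neigh <- union(neigh, s)
    }
  }
  indirect <- setdiff(intersect(mapped, neigh), mod)
  unlinked <- setdiff(mapped, union(direct, indirect))
  coverage_p <- stats::phyper(length(direct) - 1, length(mod),
                              background_size - length(mod),
                              length(mapped), lower.tail = FALSE)
  structure(
    list(direct = direct, indirect = indirect, unlinked = unlinked,
         coverage_p = coverage_p, module_size = length(mod),
         n_degs_mapped = length(mapped), background_size = background_size),
    class = "overlay_result"
  )
}

#' @export
print.overlay_result <- function(x, ...) {
  cat(sprintf("<overlay_result> %d DEGs on network: %d in module, %d one hop away, %d unlinked\n",
              x$n_degs_mapped, length(x$direct), length(x$indirect),
              length(x$unlinked)))
  cat(sprintf("  module coverage p = %s (module %d / background %d)\n",
              format(x$coverage_p, digits = 3), x$module_size, x$background_size))
  invisible(x)
}

#' Topological proximity of a target set to a network module
#'
#' Observed statistic: mean over target genes of the shortest-path distance
#' to the nearest module gene (0 when the target is itself in the module);
#' targets unreachable from every module gene are excluded and counted.
#' The null distribution re-draws, `n_null` times, a random gene set of the
#' same size matched on degree (log2 degree bins), and the z-score and
#' add-one empirical p-value (lower tail: closer than random) are reported.
#' Deterministic given `seed`.
#'
#' @param targets,module gene sets ([gene_set] or character vectors); both
#'   must intersect the network.
#' @param network an undirected simple `igraph` network.
#' @param n_null number of degree-matched null sets (default 1000).
#' @param seed integer seed.
#' @param bin_width width of the degree bins on the log2 scale (default 1).
#' @return An object of class `proximity_result`: list with `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_empirical`, `n_null`, `n_targets_used`,
#'   `n_unreachable`, `null_values`.
#' @export
nims_proximity <- function(targets, module, network, n_null = 1000,
                           seed = NULL, bin_width = 1) {
  assert_network(network)
  tg <- intersect(as_members(targets), igraph::V(network)$name)
  mod <- intersect(as_members(module), igraph::V(network)$name)
  if (length(tg) == 0) stop("no target gene lies on the network")
  if (length(mod) == 0) stop("no module gene lies on the network")
  nodes <- igraph::V(network)$name
  D <- igraph::distances(network, v = mod, to = igraph::V(network), weights = NA)
  min_dist <- apply(D, 2, min)
  names(min_dist) <- nodes
  set_stat <- function(genes) {
    d <- min_dist[genes]
    d <- d[is.finite(d)]
    if (length(d) == 0) return(NA_real_)
    mean(d)
  }
  obs_d <- min_dist[tg]
  n_unreachable <- sum(!is.finite(obs_d))
  observed <- set_stat(tg)
  if (is.na(observed)) stop("every target is unreachable from the module")
  deg <- igraph::degree(network)
  bin <- ifelse(deg == 0, -1, floor(log2(pmax(deg, 1)) / bin_width))
  names(bin) <- nodes
  by_bin <- split(nodes, bin)
  target_bins <- as.character(bin[tg])
  null_values <- with_seed(seed, vapply(seq_len(n_null), function(i) {
    draw <- vapply(target_bins, function(b) {
      pool <- by_bin[[b]]
      pool[sample.int(length(pool), 1)]
    }, "")
    set_stat(draw)
  }, numeric(1)))
  null_values <- null_values[!is.na(null_values)]
  null_mean <- mean(null_values)
  null_sd <- stats::sd(null_values)
  z <- if (isTRUE(null_sd > 0)) (observed - null_mean) / null_sd else NA_real_
  p_emp <- (1 + sum(null_values <= observed)) / (1 + length(null_values))
  structure(
    list(observed = observed, null_mean = null_mean, null_sd = null_sd,
         z = z, p_empirical = p_emp, n_null = length(null_values),
         n_targets_used = length(tg) - n_unreachable,
         n_unreachable = n_unreachable, null_values = null_values),
    class = "proximity_result"
  )
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf("<proximity_result> observed mean distance %.3f vs null %.3f +/- %.3f\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  z = %.2f, empirical p = %s (%d null sets, %d targets, %d unreachable)\n",
              x$z, format(x$p_empirical, digits = 3), x$n_null,
              x$n_targets_used, x$n_unreachable))
  invisible(x)
}

#' Hub-degree ranking of a subnetwork
#'
#' Nodes sorted by degree descending (ties broken lexicographically), with
#' an optional annotation column, mirroring the usual "top hubs" table of a
#' disease subnetwork.
#'
#' @param subnetwork an undirected simple `igraph` network.
#' @param top_n number of rows to keep (default 20).
#' @param annotations optional named character vector or list mapping gene
#'   to an annotation term.
#' @return A data.frame with columns `gene`, `degree`, `term`.
#' @export
hub_ranking <- function(subnetwork, top_n = 20, annotations = NULL) {
  assert_network(subnetwork)
  deg <- igraph::degree(subnetwork)
  ord <- order(-deg, names(deg), method = "radix")
  out <- data.frame(
    gene = names(deg)[ord],
    degree = unname(deg[ord]),
    term = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations)) {
    hit <- out$gene %in% names(annotations)
    out$term[hit] <- unlist(annotations[out$gene[hit]], use.names = FALSE)
  }
  head(out, top_n)
}
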
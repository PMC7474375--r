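## Network data model and file readers/writers.
##
## Networks are undirected simple igraph graphs with character node names.
## Gene identifiers are case-sensitive opaque strings; edge weights present
## in input files are parsed but ignored by every kernel downstream.

#' Build a validated undirected gene network
#'
#' Constructs a simple undirected network from a two-column edge table.
#' Self-loops and duplicate edges (in either orientation) are dropped and
#' counted in the attached load report.
#'
#' @param from,to character vectors of equal length naming edge endpoints.
#' @param nodes optional character vector of additional (possibly isolated)
#'   nodes to register.
#' @return An undirected simple `igraph` graph with a `load_report` graph
#'   attribute: a list with `n_self_loops` and `n_duplicate_edges` dropped.
#' @examples
#' net <- make_network(c("A", "B", "A"), c("B", "C", "A"))
#' network_load_report(net)
#' @export
make_network <- function(from, to, nodes = NULL) {
  stopifnot(length(from) == length(to))
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) == 0 && length(nodes) == 0) {
    stop("network must contain at least one node")
  }
  self <- from == to
  n_self <- sum(self)
  from2 <- from[!self]
  to2 <- to[!self]
  key <- paste(pmin(from2, to2), pmax(from2, to2), sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  all_nodes <- unique(c(from, to, as.character(nodes)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from2[!dup], to = to2[!dup], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  igraph::graph_attr(g, "load_report") <-
    list(n_self_loops = n_self, n_duplicate_edges = n_dup)
  g
}

#' @rdname make_network
#' @param net a network built by [make_network()] or [read_network()].
#' @export
network_load_report <- function(net) {
  rep <- igraph::graph_attr(net, "load_report")
  if (is.null(rep)) list(n_self_loops = 0L, n_duplicate_edges = 0L) else rep
}

assert_network <- function(net) {
  if (!igraph::is_igraph(net)) stop("expected an igraph network")
  if (igraph::is_directed(net)) stop("network must be undirected")
  if (igraph::vcount(net) < 1) stop("network must contain at least one node")
  if (igraph::any_multiple(net) || any(igraph::which_loop(net))) {
    stop("network must be simple (no self-loops or duplicate edges)")
  }
  invisible(net)
}

#' Read a network from a TSV edge list or SIF file
#'
#' `tsv-edgelist` files have two tab- or space-separated node columns and an
#' optional third weight column (parsed and ignored: all downstream kernels
#' are unweighted). SIF lines are `node <tab> relation <tab> node`.
#' Self-loops and duplicate (including reversed) edges are dropped and
#' counted in the load report.
#'
#' @param path path to the file.
#' @param format `"tsv-edgelist"` or `"sif"`.
#' @return An undirected simple `igraph` graph; see [make_network()].
#' @seealso [write_network()], [network_load_report()]
#' @export
read_network <- function(path, format = c("tsv-edgelist", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty network file: ", path)
  parts <- strsplit(lines, "[\t ]+")
  need <- if (format == "sif") 3L else 2L
  bad <- which(vapply(parts, length, 1L) < need)
  if (length(bad) > 0) {
    stop(sprintf("malformed line %d in %s: %s", bad[1], path, lines[bad[1]]))
  }
  if (format == "sif") {
    from <- vapply(parts, `[[`, "", 1L)
    to <- vapply(parts, `[[`, "", 3L)
  } else {
    from <- vapply(parts, `[[`, "", 1L)
    to <- vapply(parts, `[[`, "", 2L)
  }
  make_network(from, to)
}

#' Write a network to a TSV edge list or SIF file
#'
#' @inheritParams read_network
#' @param net an undirected simple `igraph` network.
#' @param relation relation label used for SIF output.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv-edgelist", "sif"),
                          relation = "pp") {
  format <- match.arg(format)
  assert_network(net)
  el <- igraph::as_edgelist(net, names = TRUE)
  lines <- if (format == "sif") {
    paste(el[, 1], relation, el[, 2], sep = "\t")
  } else {
    paste(el[, 1], el[, 2], sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Unweighted shortest-path lengths from one node
#'
#' Breadth-first distances from `source` to every node; unreachable nodes
#' get `Inf`. Edge weights, if any, are ignored.
#'
#' @param net an undirected simple `igraph` network.
#' @param source a node name present in `net`.
#' @return A named numeric vector over all nodes.
#' @export
shortest_path_lengths <- function(net, source) {
  assert_network(net)
  if (!source %in% igraph::V(net)$name) {
    stop("source node not in network: ", source)
  }
  d <- igraph::distances(net, v = source, weights = NA)[1, ]
  d
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validation wrapper around `stats::p.adjust(method = "BH")`: inputs
#' outside \[0, 1\] are an error rather than silently clamped.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
benjamini_hochberg <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}
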
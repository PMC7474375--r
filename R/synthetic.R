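## Seeded synthetic-world generators.
##
## Every generator is a pure function of (arguments, seed): repeated calls
## with the same seed give identical output, and each generator draws from
## its own sub-stream so adding one never perturbs another. Planted truth
## labels are returned alongside the data, so downstream recovery tests are
## self-contained.

#' Generate a random gene network
#'
#' `"scale-free"` grows a preferential-attachment graph (heavy-tailed
#' degrees, connected, simple); `"configuration"` realizes a requested
#' degree sequence exactly as a connected simple graph.
#'
#' @param n_nodes number of genes (at least 10).
#' @param model `"scale-free"` or `"configuration"`.
#' @param seed integer seed.
#' @param m edges attached per step in scale-free mode.
#' @param degree_seq degree sequence for configuration mode; defaults to a
#'   seeded draw with mean about 3 adjusted to be graphical.
#' @return An undirected simple `igraph` network with node names `G...`.
#' @export
generate_network <- function(n_nodes, model = c("scale-free", "configuration"),
                             seed = NULL, m = 2, degree_seq = NULL) {
  model <- match.arg(model)
  if (n_nodes < 10) stop("n_nodes must be at least 10")
  with_seed(seed, {
    if (model == "scale-free") {
      g <- igraph::sample_pa(n_nodes, power = 1, m = m, directed = FALSE)
    } else {
      if (is.null(degree_seq)) {
        repeat {
          degree_seq <- pmax(1L, stats::rpois(n_nodes, 2)) + 1L
          if (sum(degree_seq) %% 2 == 1) degree_seq[1] <- degree_seq[1] + 1L
          if (igraph::is_graphical(degree_seq)) break
        }
      }
      if (length(degree_seq) != n_nodes) stop("degree_seq must have length n_nodes")
      g <- igraph::sample_degseq(degree_seq, method = "vl")
    }
    igraph::V(g)$name <- paste0("G", formatC(seq_len(n_nodes),
                                             width = nchar(n_nodes), flag = "0"))
    g
  })
}

# internal: number of edges among a node set
internal_edges <- function(net, nodes) {
  igraph::ecount(igraph::induced_subgraph(net, nodes))
}

#' Plant a cohesive disease module in a network
#'
#' Selects `size` genes whose within-set edge density is at least
#' `cohesion` times the global density: with `cohesion <= 1` a uniform
#' random set; otherwise a greedy dense core grown around a seeded
#' high-degree node. If the greedy set cannot reach the requested density
#' an error reports the density actually achieved.
#'
#' @param net an undirected simple `igraph` network.
#' @param size module size (< node count).
#' @param cohesion required within-module edge-density enrichment over the
#'   global density.
#' @param seed integer seed.
#' @return A [gene_set] named `"module"` with attributes `density` and
#'   `global_density`.
#' @export
plant_disease_module <- function(net, size, cohesion = 5, seed = NULL) {
  assert_network(net)
  nodes <- igraph::V(net)$name
  n <- length(nodes)
  if (size >= n) stop("module size must be smaller than the network")
  global_density <- igraph::ecount(net) / choose(n, 2)
  members <- with_seed(seed, {
    if (cohesion <= 1) {
      sample(nodes, size)
    } else {
      deg <- igraph::degree(net)
      top <- names(sort(deg, decreasing = TRUE))[seq_len(max(1, ceiling(n * 0.05)))]
      start <- sample(top, 1)
      mod <- start
      # cnt[v]: edges from candidate v into the current module
      cnt <- integer(0)
      add_neighbors <- function(v, cnt, mod) {
        nb <- igraph::neighbors(net, v)$name
        nb <- setdiff(nb, mod)
        for (u in nb) cnt[u] <- if (u %in% names(cnt)) cnt[[u]] + 1L else 1L
        cnt
      }
      cnt <- add_neighbors(start, cnt, mod)
      while (length(mod) < size && length(cnt) > 0) {
        best <- names(cnt)[order(-unlist(cnt), names(cnt), method = "radix")][1]
        mod <- c(mod, best)
        cnt <- cnt[setdiff(names(cnt), best)]
        cnt <- add_neighbors(best, cnt, mod)
      }
      if (length(mod) < size) {
        mod <- c(mod, sample(setdiff(nodes, mod), size - length(mod)))
      }
      mod
    }
  })
  density <- internal_edges(net, members) / choose(size, 2)
  if (cohesion > 1 && density < cohesion * global_density) {
    stop(sprintf(
      "cannot plant module at cohesion %.1f: achieved density %.4g vs required %.4g",
      cohesion, density, cohesion * global_density))
  }
  out <- gene_set("module", members, description = "planted disease module")
  attr(out, "density") <- density
  attr(out, "global_density") <- global_density
  out
}

#' Generate a phenotype space around a planted module
#'
#' Builds a query phenotype plus `n_phenotypes` reference phenotypes with a
#' symmetric unit-diagonal similarity matrix (latent 1-D positions, the
#' query at one end, plus symmetric jitter). Each reference phenotype's
#' known genes are drawn from the planted module's network neighborhood
#' with probability `signal * similarity(query, phenotype)`, and uniformly
#' from all genes otherwise: at `signal = 1` the phenotypes most similar to
#' the query carry module-proximal known genes; at `signal = 0` known genes
#' are uniform and prioritization carries no information. A neighborhood
#' draw picks a module gene with probability 0.7 and a one-hop neighbor
#' otherwise (in a scale-free graph the full one-hop neighborhood of a
#' hub-containing module covers much of the graph, so drawing it uniformly
#' would dilute the planted signal to near-uniform).
#'
#' @param net an undirected simple `igraph` network.
#' @param planted a [gene_set] of planted module genes (non-empty).
#' @param n_phenotypes number of reference phenotypes (at least 4).
#' @param signal signal strength in \[0, 1\].
#' @param seed integer seed.
#' @param n_known known genes drawn per reference phenotype.
#' @param query query phenotype id (default `"SQD"`).
#' @param sim_jitter half-width of the symmetric similarity jitter.
#' @return A [phenotype_space]; the query phenotype has no known genes.
#' @export
generate_phenotype_space <- function(net, planted, n_phenotypes = 14,
                                     signal = 1, seed = NULL, n_known = 5,
                                     query = "SQD", sim_jitter = 0.05) {
  assert_network(net)
  members <- as_members(planted)
  if (length(members) == 0) stop("planted module is empty")
  if (n_phenotypes < 4) stop("at least 4 reference phenotypes are required")
  if (signal < 0 || signal > 1) stop("signal must lie in [0, 1]")
  nodes <- igraph::V(net)$name
  one_hop <- setdiff(unlist(lapply(
    igraph::adjacent_vertices(net, intersect(members, nodes)),
    function(v) v$name)), members)
  with_seed(seed, {
    ids <- c(query, paste0("PH", formatC(seq_len(n_phenotypes), width = 2, flag = "0")))
    # bimodal latent positions: reference diseases either share much of the
    # query syndrome's phenotype profile or little of it
    t_pos <- c(1, stats::rbeta(n_phenotypes, 0.4, 0.4))
    S <- 1 - abs(outer(t_pos, t_pos, "-"))
    E <- matrix(stats::runif(length(ids)^2, -sim_jitter, sim_jitter), length(ids))
    S <- pmin(pmax(S + (E + t(E)) / 2, 0), 1)
    diag(S) <- 1
    dimnames(S) <- list(ids, ids)
    known <- lapply(seq_len(n_phenotypes), function(j) {
      w <- signal * S[query, j + 1]
      picks <- vapply(seq_len(n_known), function(i) {
        if (stats::runif(1) < w) {
          if (stats::runif(1) < 0.7 || length(one_hop) == 0) {
            sample(members, 1)
          } else {
            sample(one_hop, 1)
          }
        } else {
          sample(nodes, 1)
        }
      }, "")
      unique(picks)
    })
    names(known) <- ids[-1]
    phenotype_space(S, known, network = net)
  })
}

#' Generate a drug-target gold standard and compound set
#'
#' Builds `n_drugs` reference drugs with random target sets, a drug-drug
#' similarity matrix (unit diagonal, exchangeable off-diagonal background),
#' and `n_compounds` synthetic compounds. Each compound carries a true
#' target: its similarity vector is elevated by `kappa` on the drugs known
#' to bind that target, so at `kappa = 0` similarities are exchangeable
#' across drugs and the true target is unrecoverable, while large `kappa`
#' makes it recoverable. Compound desirability vectors are drawn so that a
#' minority of compounds fail the default druglikeness filter.
#'
#' @param n_drugs number of reference drugs (at least 5).
#' @param proteome character vector of candidate proteins.
#' @param targets_per_drug known targets per drug.
#' @param n_compounds number of synthetic compounds.
#' @param kappa similarity concentration on true-target binders, in
#'   \[0, 1\].
#' @param seed integer seed.
#' @return List with `gold` (a [drug_target_gold]), `compounds` (list of
#'   [compound_record]), and `truth` (data.frame `compound`, `true_target`).
#' @export
generate_drug_target_gold <- function(n_drugs = 50, proteome,
                                      targets_per_drug = 5, n_compounds = 30,
                                      kappa = 0.6, seed = NULL) {
  if (n_drugs < 5) stop("at least 5 reference drugs are required")
  proteome <- unique(as.character(proteome))
  if (targets_per_drug > length(proteome)) {
    stop("targets_per_drug exceeds the proteome size")
  }
  with_seed(seed, {
    drugs <- paste0("D", formatC(seq_len(n_drugs), width = 2, flag = "0"))
    targets <- lapply(drugs, function(d) sample(proteome, targets_per_drug))
    names(targets) <- drugs
    DS <- matrix(stats::runif(n_drugs^2, 0, 0.3), n_drugs)
    DS <- (DS + t(DS)) / 2
    diag(DS) <- 1
    dimnames(DS) <- list(drugs, drugs)
    gold <- drug_target_gold(targets, DS)
    targetable <- names(gold$binders)
    compounds <- vector("list", n_compounds)
    truth <- character(n_compounds)
    for (i in seq_len(n_compounds)) {
      tt <- sample(targetable, 1)
      cs <- stats::runif(n_drugs, 0, 0.4)
      hits <- drugs %in% gold$binders[[tt]]
      cs[hits] <- pmin(1, cs[hits] + kappa * (0.6 + 0.4 * stats::runif(sum(hits))))
      names(cs) <- drugs
      d <- if (stats::runif(1) < 0.2) {
        stats::runif(8, 0.001, 0.2)   # deliberately undruglike
      } else {
        stats::runif(8, 0.2, 1)
      }
      compounds[[i]] <- compound_record(paste0("C", formatC(i, width = 3, flag = "0")),
                                        cs, desirabilities = d)
      truth[i] <- tt
    }
    list(gold = gold, compounds = compounds,
         truth = data.frame(compound = vapply(compounds, `[[`, "", "id"),
                            true_target = truth, stringsAsFactors = FALSE))
  })
}

#' Generate an expression matrix with planted differential expression
#'
#' Gaussian noise model: all genes are null except the module genes, which
#' are shifted by `effect` (log2-scale units) in the case group, downward
#' by default.
#'
#' @param net an undirected simple `igraph` network; its nodes are the gene
#'   universe.
#' @param module a [gene_set] of genes to perturb (must lie in the network).
#' @param n_per_group samples per group (at least 3).
#' @param effect absolute shift of module genes in the case group.
#' @param noise_sd Gaussian noise standard deviation.
#' @param direction `"down"` or `"up"` regulation in cases.
#' @param seed integer seed.
#' @return List with `expr` (genes x samples matrix), `groups` (factor
#'   `case`/`control`), `truth` (character vector of perturbed genes),
#'   `direction`.
#' @export
generate_expression <- function(net, module, n_per_group = 10, effect = 2,
                                noise_sd = 1, direction = c("down", "up"),
                                seed = NULL) {
  direction <- match.arg(direction)
  assert_network(net)
  genes <- igraph::V(net)$name
  mod <- as_members(module)
  if (!all(mod %in% genes)) stop("module genes must all lie in the gene universe")
  if (n_per_group < 3) stop("at least 3 samples per group are required")
  with_seed(seed, {
    n_s <- 2 * n_per_group
    X <- matrix(stats::rnorm(length(genes) * n_s, 0, noise_sd),
                nrow = length(genes),
                dimnames = list(genes, c(paste0("case", seq_len(n_per_group)),
                                         paste0("ctrl", seq_len(n_per_group)))))
    shift <- if (direction == "down") -effect else effect
    X[mod, seq_len(n_per_group)] <- X[mod, seq_len(n_per_group)] + shift
    list(expr = X,
         groups = factor(rep(c("case", "control"), each = n_per_group),
                         levels = c("case", "control")),
         truth = mod, direction = direction)
  })
}

#' Call differentially expressed genes by Welch's t-test
#'
#' Row-wise two-sample Welch t-tests of case versus control; the effect is
#' the case-minus-control mean difference and the direction its sign.
#'
#' @param expr genes x samples numeric matrix.
#' @param groups factor with levels `case`, `control` over the columns.
#' @param alpha p-value cutoff; only significant rows are returned unless
#'   `all = TRUE`.
#' @param all return the full table with a `significant` column.
#' @return A data.frame with columns `gene`, `direction` (`"up"`/`"down"`),
#'   `effect`, `p` (and `significant` when `all = TRUE`).
#' @export
call_degs <- function(expr, groups, alpha = 0.05, all = FALSE) {
  groups <- factor(groups)
  stopifnot(ncol(expr) == length(groups), nlevels(groups) == 2)
  a <- expr[, groups == levels(groups)[1], drop = FALSE]
  b <- expr[, groups == levels(groups)[2], drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(
    gene = rownames(expr),
    direction = ifelse(m1 - m2 >= 0, "up", "down"),
    effect = m1 - m2,
    p = p,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (all) {
    out$significant <- out$p < alpha
    out
  } else {
    out[out$p < alpha, , drop = FALSE]
  }
}

#' Generate a complete synthetic world
#'
#' Assembles every pipeline input with planted ground truth: a scale-free
#' network with a cohesive planted module, a phenotype space whose
#' query-similar phenotypes carry module-proximal known genes, a
#' drug-target gold standard with compounds concentrated on their true
#' targets, and an expression matrix with the module genes differentially
#' expressed. One global seed fans out to independent per-generator
#' streams.
#'
#' Default sizes: 2000-gene network with a 20-gene planted module, 14
#' reference phenotypes with 20 known genes each, 50 reference drugs,
#' 500-protein proteome (containing the module), 30 compounds, 10 samples
#' per expression group.
#'
#' @param seed integer seed.
#' @param n_nodes,model,m network controls, see [generate_network()].
#' @param module_size,cohesion module controls, see
#'   [plant_disease_module()].
#' @param n_phenotypes,signal,n_known,query phenotype-space controls, see
#'   [generate_phenotype_space()].
#' @param n_drugs,proteome_size,targets_per_drug,n_compounds,kappa
#'   drug-target controls, see [generate_drug_target_gold()].
#' @param n_per_group,effect,noise_sd,direction expression controls, see
#'   [generate_expression()].
#' @return An object of class `synthetic_world`: list with `network`,
#'   `module`, `space`, `query`, `proteome`, `gold`, `compounds`,
#'   `compound_truth`, `expression`, `seed`.
#' @export
generate_world <- function(seed = 1, n_nodes = 2000, model = "scale-free",
                           m = 2, module_size = 20, cohesion = 5,
                           n_phenotypes = 14, signal = 1, n_known = 20,
                           query = "SQD", n_drugs = 50, proteome_size = 500,
                           targets_per_drug = 5, n_compounds = 30,
                           kappa = 0.6, n_per_group = 10, effect = 2,
                           noise_sd = 1, direction = "down") {
  net <- generate_network(n_nodes, model = model, seed = sub_seed(seed, 1), m = m)
  module <- plant_disease_module(net, module_size, cohesion = cohesion,
                                 seed = sub_seed(seed, 2))
  space <- generate_phenotype_space(net, module, n_phenotypes = n_phenotypes,
                                    signal = signal, seed = sub_seed(seed, 3),
                                    n_known = n_known, query = query)
  nodes <- igraph::V(net)$name
  proteome <- with_seed(sub_seed(seed, 4), {
    pool <- setdiff(nodes, module$members)
    extra <- sample(pool, min(length(pool),
                              max(0, proteome_size - length(module$members))))
    sort(c(module$members, extra))
  })
  dt <- generate_drug_target_gold(n_drugs, proteome,
                                  targets_per_drug = targets_per_drug,
                                  n_compounds = n_compounds, kappa = kappa,
                                  seed = sub_seed(seed, 5))
  expr <- generate_expression(net, module, n_per_group = n_per_group,
                              effect = effect, noise_sd = noise_sd,
                              direction = direction, seed = sub_seed(seed, 6))
  structure(
    list(network = net, module = module, space = space, query = query,
         proteome = proteome, gold = dt$gold, compounds = dt$compounds,
         compound_truth = dt$truth, expression = expr, seed = seed),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> seed %d\n", x$seed))
  cat(sprintf("  network   : %d genes, %d interactions\n",
              igraph::vcount(x$network), igraph::ecount(x$network)))
  cat(sprintf("  module    : %d planted genes (density %.3f)\n",
              length(x$module$members), attr(x$module, "density")))
  cat(sprintf("  phenotypes: query '%s' + %d references\n", x$query,
              length(x$space$ids) - 1))
  cat(sprintf("  drugs     : %d reference drugs, %d proteins, %d compounds\n",
              length(x$gold$drugs), length(x$proteome), length(x$compounds)))
  cat(sprintf("  expression: %d x %d, %d planted DEGs (%s)\n",
              nrow(x$expression$expr), ncol(x$expression$expr),
              length(x$expression$truth), x$expression$direction))
  invisible(x)
}

#' Write a synthetic world to pipeline input files
#'
#' Emits the world as the plain-text files the readers consume: `ppi.tsv`,
#' `phenotypes.csv`, `known.tsv`, `gold.tsv`, `drug_similarity.csv`,
#' `cs.csv`, `compounds.csv`, `expr.csv`, and truth files under `truth/`.
#'
#' @param world a [generate_world()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_network(world$network, file.path(dir, "ppi.tsv"))
  write_similarity_csv(world$space$similarity, file.path(dir, "phenotypes.csv"))
  write_known_genes(world$space$known_genes, file.path(dir, "known.tsv"))
  write_drug_targets(world$gold$targets, file.path(dir, "gold.tsv"))
  write_similarity_csv(world$gold$similarity, file.path(dir, "drug_similarity.csv"))
  cs <- t(vapply(world$compounds, `[[`, numeric(length(world$gold$drugs)), "cs"))
  rownames(cs) <- vapply(world$compounds, `[[`, "", "id")
  write_similarity_csv(cs, file.path(dir, "cs.csv"))
  comp <- data.frame(id = rownames(cs),
                     wqed = vapply(world$compounds, `[[`, 1, "wqed"))
  write.table(comp, file.path(dir, "compounds.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  expr <- data.frame(gene = rownames(world$expression$expr),
                     world$expression$expr, check.names = FALSE)
  write.table(expr, file.path(dir, "expr.csv"), sep = ",", quote = FALSE,
              row.names = FALSE)
  writeLines(world$module$members, file.path(dir, "truth", "module.txt"))
  writeLines(world$proteome, file.path(dir, "truth", "proteome.txt"))
  write.table(world$compound_truth, file.path(dir, "truth", "compound_targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative (ties count 1/2).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical (or 0/1) truth labels, same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
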
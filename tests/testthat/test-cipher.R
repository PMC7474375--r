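test_that("closeness profile applies the Gaussian shortest-path kernel", {
  net <- path_graph(c("A", "B", "C"))
  S <- diag(1, 4)
  ids <- c("Q", "P1", "P2", "P3")
  dimnames(S) <- list(ids, ids)
  sp <- phenotype_space(S, list(P1 = "A", P2 = "B", P3 = "C"))

  expect_equal(unname(closeness_profile(net, "A", sp)["P1"]), 1.0)   # L = 0
  expect_equal(unname(closeness_profile(net, "C", sp)["P1"]), exp(-4)) # L = 2
  # two known genes sum their kernels
  sp2 <- phenotype_space(S, list(P1 = c("A", "B"), P2 = "B", P3 = "C"))
  expect_equal(unname(closeness_profile(net, "A", sp2)["P1"]), 1 + exp(-1))

  # disconnected gene contributes zero everywhere
  net2 <- make_network("A", "B", nodes = c("C", "D"))
  sp3 <- phenotype_space(S, list(P1 = "A", P2 = "B", P3 = "C"))
  expect_equal(as.numeric(closeness_profile(net2, "D", sp3)), c(0, 0, 0))
  expect_error(closeness_profile(net, "Z", sp), "not in network")
})

test_that("kernel contribution decreases monotonically with distance", {
  L <- 0:6
  k <- exp(-L^2)
  expect_true(all(diff(k) < 0))
})

test_that("concordance score is the Pearson correlation on the phenotype index", {
  sp <- toy_space()
  sim_row <- sp$similarity["Q", c("P1", "P2", "P3", "P4")]
  prof <- structure(2 * sim_row, names = names(sim_row))
  expect_equal(cipher_score(prof, "Q", sp), 1.0)
  prof_neg <- structure(1 - sim_row, names = names(sim_row))
  expect_equal(cipher_score(prof_neg, "Q", sp), -1.0)

  # hand-computed Pearson on 4 points
  x <- c(1, 0, 0, 0)
  y <- c(0.9, 0.1, 0.1, 0.1)
  prof4 <- structure(x, names = c("P1", "P2", "P3", "P4"))
  sp4 <- local({
    ids <- c("Q", "P1", "P2", "P3", "P4")
    S <- diag(1, 5); dimnames(S) <- list(ids, ids)
    S["Q", ids[-1]] <- y; S[ids[-1], "Q"] <- y
    phenotype_space(S, list(P1 = "A", P2 = "A", P3 = "A", P4 = "A"))
  })
  expect_equal(cipher_score(prof4, "Q", sp4), cor(x, y))
  expect_equal(cipher_score(prof4, "Q", sp4), 1.0) # affine relation

  # zero-variance profile is undefined
  prof_const <- structure(rep(0.5, 4), names = c("P1", "P2", "P3", "P4"))
  expect_true(is.na(cipher_score(prof_const, "Q", sp)))
})

test_that("ranking selects top-N with lexicographic tie-breaking", {
  w <- generate_world(seed = 3, n_nodes = 300, proteome_size = 100)
  res <- cipher_rank(w$network, w$space, w$query, top_n = 50)
  expect_equal(length(res$selected$members), 50)
  expect_equal(res$ranking$score, sort(res$ranking$score, decreasing = TRUE))
  # ties are ordered lexicographically
  tied <- split(res$ranking$gene, res$ranking$score)
  for (grp in tied) expect_equal(grp, sort(grp, method = "radix"))
  # top_n larger than gene count selects everything scoreable
  res_all <- cipher_rank(w$network, w$space, w$query, top_n = 10000)
  expect_equal(length(res_all$selected$members), res_all$n_scoreable)
})

test_that("ranking is invariant under gene relabeling", {
  w <- generate_world(seed = 5, n_nodes = 200)
  res <- cipher_rank(w$network, w$space, w$query, top_n = 20)
  # apply a permutation to node ids everywhere
  nodes <- igraph::V(w$network)$name
  perm <- with_seed(42, setNames(sample(nodes), nodes))
  net2 <- w$network
  igraph::V(net2)$name <- unname(perm[nodes])
  known2 <- lapply(w$space$known_genes, function(g) unname(perm[g]))
  sp2 <- phenotype_space(w$space$similarity, known2)
  res2 <- cipher_rank(net2, sp2, w$query, top_n = 20)
  sc1 <- setNames(res$ranking$score, unname(perm[res$ranking$gene]))
  sc2 <- setNames(res2$ranking$score, res2$ranking$gene)
  expect_equal(sc1[names(sc2)], sc2, tolerance = 1e-12)
})

test_that("planted module genes rank above background", {
  ranks <- sapply(1:5, function(s) {
    w <- generate_world(seed = s, n_nodes = 600, proteome_size = 200)
    res <- cipher_rank(w$network, w$space, w$query)
    r <- res$ranking$rank[res$ranking$gene %in% w$module$members]
    r_other <- res$ranking$rank[!res$ranking$gene %in% w$module$members]
    median(r) < median(r_other)
  })
  expect_true(all(ranks))
})

test_that("degree-preserving shuffle keeps node set, edge count and degrees", {
  g <- random_gnp(50, 0.12, seed = 2)
  for (s in c(1, 17, 33)) {
    sh <- shuffle_network(g, seed = s)
    expect_setequal(igraph::V(sh)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(sh), igraph::ecount(g))
    expect_equal(igraph::degree(sh)[igraph::V(g)$name],
                 igraph::degree(g)[igraph::V(g)$name])
    expect_false(igraph::any_multiple(sh))
    expect_false(any(igraph::which_loop(sh)))
  }
  # determinism
  expect_true(igraph::identical_graphs(shuffle_network(g, seed = 4),
                                       shuffle_network(g, seed = 4)))
})

test_that("shuffling genuinely perturbs the edge set", {
  g <- random_gnp(50, 0.12, seed = 5)
  ekey <- function(x) {
    el <- igraph::as_edgelist(x)
    paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  }
  e0 <- ekey(g)
  jac <- sapply(1:100, function(s) {
    e1 <- ekey(shuffle_network(g, seed = s))
    length(intersect(e0, e1)) / length(union(e0, e1))
  })
  expect_gte(sum(jac < 1), 95)
})

test_that("tiny graphs are returned unshuffled with a warning", {
  g <- make_network("A", "B")
  expect_warning(sh <- shuffle_network(g, seed = 1), "unshuffled")
  expect_true(attr(sh, "shuffle_warning"))
})

test_that("precision and recall follow the percentage set formulas", {
  expect_equal(precision_recall(c("A", "B"), c("A", "B")),
               c(precision = 100, recall = 100))
  pr <- precision_recall(c("A", "B", "C", "D"), c("C", "D", "E"))
  expect_equal(pr[["precision"]], 50)
  expect_equal(pr[["recall"]], 200 / 3)
  expect_equal(precision_recall(c("A", "B"), c("X", "Y")),
               c(precision = 0, recall = 0))
  expect_error(precision_recall(character(0), "A"), "predicted")
  expect_error(precision_recall("A", character(0)), "reported")
})

test_that("permutation validation recovers planted signal and calibrates under the null", {
  w <- generate_world(seed = 11, n_nodes = 400, proteome_size = 150)
  v <- permutation_validation(w$network, w$space, w$query, w$module,
                              n_perm = 200, top_n = 100, seed = 7)
  expect_length(v$null_recall, 200)
  expect_gt(v$recall, mean(v$null_recall))
  expect_lte(v$p_recall, 0.05)

  # random reported sets: p should rarely be small
  ps <- sapply(1:25, function(s) {
    rep_set <- with_seed(s + 500, sample(igraph::V(w$network)$name, 20))
    permutation_validation(w$network, w$space, w$query, rep_set,
                           n_perm = 39, top_n = 100, seed = s)$p_recall
  })
  expect_gte(mean(ps > 0.05), 0.8)
})

test_that("zero permutations give empty nulls and undefined p", {
  w <- generate_world(seed = 2, n_nodes = 200)
  v <- permutation_validation(w$network, w$space, w$query, w$module,
                              n_perm = 0, top_n = 50)
  expect_length(v$null_recall, 0)
  expect_true(is.na(v$p_recall))
})
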
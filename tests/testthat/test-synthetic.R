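test_that("generated networks are simple, connected and deterministic", {
  g1 <- generate_network(200, seed = 5)
  g2 <- generate_network(200, seed = 5)
  expect_true(igraph::identical_graphs(g1, g2))
  expect_false(igraph::any_multiple(g1))
  expect_false(any(igraph::which_loop(g1)))
  expect_true(igraph::is_connected(g1))
  # heavy-tailed degrees in scale-free mode
  deg <- igraph::degree(g1)
  expect_gte(max(deg), 3 * median(deg))
  expect_error(generate_network(5), "at least 10")
  expect_error(generate_network(50, model = "smallworld"), "arg")
})

test_that("configuration mode realizes the requested degree sequence exactly", {
  ds <- rep(c(2L, 3L, 4L), c(20, 14, 6))
  g <- generate_network(40, model = "configuration", seed = 3, degree_seq = ds)
  expect_equal(sort(unname(igraph::degree(g))), sort(ds))
  expect_true(igraph::is_connected(g))
})

test_that("planted modules reach the required density enrichment", {
  g <- generate_network(500, seed = 9)
  mod <- plant_disease_module(g, 20, cohesion = 5, seed = 2)
  expect_length(mod$members, 20)
  expect_gte(attr(mod, "density"), 5 * attr(mod, "global_density"))
  # determinism
  mod2 <- plant_disease_module(g, 20, cohesion = 5, seed = 2)
  expect_equal(mod$members, mod2$members)
  # cohesion 1 gives an unconstrained random set
  modr <- plant_disease_module(g, 20, cohesion = 1, seed = 2)
  expect_length(modr$members, 20)
  # infeasible cohesion reports the achieved density
  expect_error(plant_disease_module(g, 20, cohesion = 500, seed = 2),
               "achieved density")
})

test_that("phenotype spaces are valid and carry signal-dependent known genes", {
  g <- generate_network(300, seed = 1)
  mod <- plant_disease_module(g, 15, seed = 1)
  sp <- generate_phenotype_space(g, mod, n_phenotypes = 10, signal = 1,
                                 seed = 4, n_known = 10)
  S <- sp$similarity
  expect_equal(S, t(S))
  expect_equal(unname(diag(S)), rep(1, nrow(S)))
  expect_true(all(S >= 0 & S <= 1))
  expect_false("SQD" %in% names(sp$known_genes))
  # at full signal, query-similar phenotypes hold more module genes than
  # dissimilar ones
  sim <- S["SQD", names(sp$known_genes)]
  in_mod <- vapply(sp$known_genes, function(x) mean(x %in% mod$members), 1)
  expect_gt(mean(in_mod[sim > median(sim)]), mean(in_mod[sim <= median(sim)]))
  expect_error(generate_phenotype_space(g, gene_set("m", "X")[c()],
                                        n_phenotypes = 10), "empty|members")
  expect_error(generate_phenotype_space(g, mod, n_phenotypes = 3), "at least 4")
})

test_that("prioritization recovers the planted module at full signal but not at zero", {
  auc1 <- sapply(1:10, function(s) {
    w <- generate_world(seed = s)
    res <- cipher_rank(w$network, w$space, w$query)
    auroc(res$ranking$score, res$ranking$gene %in% w$module$members)
  })
  expect_gte(mean(auc1), 0.8)
  auc0 <- sapply(1:10, function(s) {
    w <- generate_world(seed = s, signal = 0, n_nodes = 500)
    res <- cipher_rank(w$network, w$space, w$query)
    auroc(res$ranking$score, res$ranking$gene %in% w$module$members)
  })
  expect_lt(abs(mean(auc0) - 0.5), 0.1)
})

test_that("drug-target gold standards are deterministic with valid similarities", {
  pro <- paste0("P", 1:100)
  d1 <- generate_drug_target_gold(10, pro, 3, 5, kappa = 0.5, seed = 8)
  d2 <- generate_drug_target_gold(10, pro, 3, 5, kappa = 0.5, seed = 8)
  expect_equal(d1$truth, d2$truth)
  expect_equal(d1$gold$similarity, d2$gold$similarity)
  cs <- d1$compounds[[1]]$cs
  expect_true(all(cs >= 0 & cs <= 1))
  expect_error(generate_drug_target_gold(3, pro, 3, 5), "at least 5")
  expect_error(generate_drug_target_gold(10, pro, 200, 5), "exceeds")
})

test_that("expression matrices plant differential expression with Gaussian noise", {
  g <- generate_network(400, seed = 2)
  mod <- plant_disease_module(g, 15, seed = 2)
  ex <- generate_expression(g, mod, n_per_group = 10, effect = 2,
                            noise_sd = 1, seed = 6)
  expect_equal(dim(ex$expr), c(400, 20))
  ex2 <- generate_expression(g, mod, n_per_group = 10, effect = 2,
                             noise_sd = 1, seed = 6)
  expect_equal(ex$expr, ex2$expr)
  # power: most module genes flagged at p < 0.05
  power <- sapply(1:10, function(s) {
    e <- generate_expression(g, mod, n_per_group = 10, effect = 2,
                             noise_sd = 1, seed = s)
    degs <- call_degs(e$expr, e$groups, alpha = 0.05)
    mean(mod$members %in% degs$gene)
  })
  expect_gte(mean(power), 0.8)
  # null calibration: with zero effect, about alpha of genes are flagged
  fpr <- sapply(1:10, function(s) {
    e <- generate_expression(g, mod, n_per_group = 10, effect = 0,
                             noise_sd = 1, seed = s + 50)
    nrow(call_degs(e$expr, e$groups, alpha = 0.05)) / 400
  })
  expect_lt(mean(fpr), 0.1) # within 2x of alpha
  expect_gt(mean(fpr), 0.025)
  # planted direction is respected
  degs <- call_degs(ex$expr, ex$groups, alpha = 0.05)
  planted <- degs[degs$gene %in% mod$members, ]
  expect_true(all(planted$direction == "down"))
  expect_error(generate_expression(g, gene_set("x", "NOT_A_NODE"), 5), "universe")
})

test_that("whole worlds are reproducible and round-trip through the readers", {
  w1 <- generate_world(seed = 42, n_nodes = 150, proteome_size = 60,
                       n_compounds = 5)
  w2 <- generate_world(seed = 42, n_nodes = 150, proteome_size = 60,
                       n_compounds = 5)
  expect_true(igraph::identical_graphs(w1$network, w2$network))
  expect_equal(w1$space$similarity, w2$space$similarity)
  expect_equal(w1$compound_truth, w2$compound_truth)

  dir <- withr::local_tempdir()
  write_world(w1, dir)
  net <- read_network(file.path(dir, "ppi.tsv"))
  expect_equal(igraph::ecount(net), igraph::ecount(w1$network))
  expect_setequal(igraph::V(net)$name, igraph::V(w1$network)$name)
  S <- read_similarity_csv(file.path(dir, "phenotypes.csv"))
  expect_equal(S, w1$space$similarity)
  known <- read_known_genes(file.path(dir, "known.tsv"))
  expect_equal(known[sort(names(known))],
               w1$space$known_genes[sort(names(w1$space$known_genes))])
  gold <- read_drug_targets(file.path(dir, "gold.tsv"))
  expect_equal(gold, w1$gold$targets)
})

test_that("AUROC matches the closed form on a tiny example", {
  # scores 1..4, positives at ranks 3,4 -> perfect separation
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # positives at score ranks 2 and 4: 3 of 4 positive-negative pairs ordered
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, TRUE, FALSE, TRUE)), 0.75)
  # full ties: every comparison counts one half
  expect_equal(auroc(c(1, 1, 1, 1), c(TRUE, FALSE, TRUE, FALSE)), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})
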
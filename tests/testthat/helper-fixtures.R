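# Small deterministic fixtures shared across test files.

path_graph <- function(nodes = c("A", "B", "C")) {
  make_network(nodes[-length(nodes)], nodes[-1])
}

# random simple undirected graph on n named nodes, edge probability p
random_gnp <- function(n, p, seed) {
  with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- paste0("N", formatC(seq_len(n), width = 2, flag = "0"))
    g
  })
}

with_seed <- netpharm:::with_seed

# 4-phenotype toy space on a path graph A-B-C-D
toy_space <- function() {
  ids <- c("Q", "P1", "P2", "P3", "P4")
  S <- diag(1, 5)
  dimnames(S) <- list(ids, ids)
  S["Q", c("P1", "P2", "P3", "P4")] <- c(0.9, 0.6, 0.3, 0.1)
  S[c("P1", "P2", "P3", "P4"), "Q"] <- c(0.9, 0.6, 0.3, 0.1)
  S["P1", "P2"] <- S["P2", "P1"] <- 0.5
  phenotype_space(S, list(P1 = "A", P2 = "B", P3 = "C", P4 = "D"))
}

# brute-force Poisson-binomial pmf by literal subset enumeration
enumerate_pois_binom <- function(p, k) {
  m <- length(p)
  if (k == 0) return(prod(1 - p))
  sets <- utils::combn(m, k)
  sum(apply(sets, 2, function(A) prod(p[A]) * prod(1 - p[-A])))
}
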
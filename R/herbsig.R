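## Herb-level target significance.
##
## Under the null, whether ingredient i's predicted target list contains a
## given protein is an independent Bernoulli draw with probability
## p_i = (size of the ingredient's target list) / (number of candidate
## proteins). The number K of lists containing the protein then follows a
## Poisson binomial distribution; its pmf is computed exactly by a dynamic
## programming convolution (equivalent to the sum over all subsets, without
## enumerating them), and a Monte Carlo tail estimate is kept as a
## validation mode mirroring the 1000-random-case procedure.

#' Exact Poisson-binomial probability mass
#'
#' `Pr(K = k)` for the number of successes among independent Bernoulli
#' trials with probabilities `p`, computed by the O(m^2) convolution
#' recurrence. Equals the sum over all k-subsets A of
#' `prod(p[A]) * prod(1 - p[-A])`.
#'
#' @param p numeric vector of success probabilities in \[0, 1\].
#' @param k integer count in `0..length(p)`; `NULL` returns the full pmf
#'   vector over `0..length(p)`.
#' @return `Pr(K = k)`, or the full pmf (length `length(p) + 1`).
#' @export
poisson_binomial_pmf <- function(p, k = NULL) {
  p <- as.numeric(p)
  if (length(p) == 0) stop("probability vector is empty")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  v <- 1
  for (pi in p) {
    v <- c(v * (1 - pi), 0) + c(0, v * pi)
  }
  if (is.null(k)) return(v)
  if (k != round(k) || k < 0 || k > length(p)) {
    stop("k must be an integer in 0..", length(p))
  }
  v[k + 1]
}

#' Poisson-binomial tail probability
#'
#' Upper-tail probability of the Poisson binomial count: by default the
#' inclusive tail `Pr(K >= k)`; `convention = "gt"` gives the strict tail
#' `Pr(K > k)`. The inclusive tail is the significance default so that an
#' observation equal to the maximum possible count is never assigned
#' probability 0.
#'
#' @inheritParams poisson_binomial_pmf
#' @param k integer; for the strict convention `k = length(p)` gives 0 and
#'   the inclusive tail at `k = 0` is 1.
#' @param convention `"geq"` for `Pr(K >= k)`, `"gt"` for `Pr(K > k)`.
#' @return A probability in \[0, 1\].
#' @export
poisson_binomial_tail <- function(p, k, convention = c("geq", "gt")) {
  convention <- match.arg(convention)
  pmf <- poisson_binomial_pmf(p)
  m <- length(p)
  if (k != round(k) || k < 0 || k > m + 1) stop("k must be an integer in 0..", m + 1)
  lo <- if (convention == "geq") k else k + 1
  if (lo > m) return(0)
  # 1 - sum of lower pmf; clamp tiny negative rounding
  max(0, min(1, 1 - sum(pmf[seq_len(lo)])))
}

#' Monte Carlo estimate of the Poisson-binomial tail
#'
#' Simulates `n_rep` random cases of the independent Bernoulli trials and
#' reports the fraction of replicates whose count reaches `k`, with the
#' binomial standard error of that fraction. Deterministic given `seed`.
#'
#' @inheritParams poisson_binomial_tail
#' @param n_rep number of random cases (default 1000).
#' @param seed integer seed.
#' @return List with `estimate`, `se`, `n_rep`, `convention`.
#' @export
monte_carlo_tail <- function(p, k, n_rep = 1000, seed = NULL,
                             convention = c("geq", "gt")) {
  convention <- match.arg(convention)
  p <- as.numeric(p)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  stopifnot(n_rep >= 1)
  counts <- with_seed(seed, {
    sim <- matrix(stats::rbinom(n_rep * length(p), 1, rep(p, each = n_rep)),
                  nrow = n_rep)
    rowSums(sim)
  })
  hit <- if (convention == "geq") counts >= k else counts > k
  est <- mean(hit)
  list(estimate = est, se = sqrt(est * (1 - est) / n_rep), n_rep = n_rep,
       convention = convention)
}

#' Significantly frequently occurring targets of an herb
#'
#' Counts, for each protein, the number k of ingredient target lists that
#' contain it, and tests k against the Poisson binomial background in which
#' ingredient i includes the protein with probability
#' `p_i = length(selected_i) / proteome_size`. Proteins never predicted by
#' any ingredient are omitted. Exact dynamic-programming tails are the
#' default inference path; `mode = "mc"` adds the Monte Carlo tail of the
#' 1000-random-case procedure alongside the exact one.
#'
#' @param rankings list of [target_ranking] objects (or character vectors
#'   of selected proteins), one per ingredient.
#' @param proteome_size number of candidate proteins.
#' @param alpha significance level (default 0.05, uncorrected; set
#'   `adjust = "BH"` for Benjamini-Hochberg flagging).
#' @param mode `"exact"` or `"mc"`.
#' @param convention tail convention, see [poisson_binomial_tail()].
#' @param p_i optional explicit per-ingredient inclusion probabilities
#'   (heterogeneous probabilities are supported).
#' @param n_rep,seed Monte Carlo controls (used when `mode = "mc"`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return An object of class `herb_targets`: a data.frame with columns
#'   `protein`, `k`, `m`, `p_tail` (exact), `mc_tail` (or `NA`),
#'   `p_adjusted`, `flagged`, sorted by `p_tail`; attributes `alpha`,
#'   `convention`, `p_i`.
#' @export
herb_significant_targets <- function(rankings, proteome_size, alpha = 0.05,
                                     mode = c("exact", "mc"),
                                     convention = c("geq", "gt"),
                                     p_i = NULL, n_rep = 1000, seed = NULL,
                                     adjust = c("none", "BH")) {
  mode <- match.arg(mode)
  convention <- match.arg(convention)
  adjust <- match.arg(adjust)
  if (length(rankings) == 0) stop("no ingredient rankings supplied")
  lists <- lapply(rankings, function(r) {
    if (inherits(r, "target_ranking")) r$selected else unique(as.character(r))
  })
  m <- length(lists)
  if (is.null(p_i)) {
    p_i <- vapply(lists, length, 1L) / proteome_size
  }
  if (length(p_i) == 1) p_i <- rep(p_i, m)
  if (length(p_i) != m || any(p_i < 0 | p_i > 1)) {
    stop("p_i must give one probability in [0, 1] per ingredient")
  }
  tab <- table(unlist(lapply(lists, unique), use.names = FALSE))
  if (length(tab) == 0) stop("ingredient target lists are all empty")
  prot <- names(tab)
  k <- as.integer(tab)
  # one pmf serves every protein when p_i is shared; tails by cumulative sum
  pmf <- poisson_binomial_pmf(p_i)
  upper <- rev(cumsum(rev(pmf)))   # upper[j] = Pr(K >= j - 1)
  tail_at <- function(kk) {
    lo <- if (convention == "geq") kk else kk + 1
    if (lo > m) 0 else upper[lo + 1]
  }
  p_tail <- vapply(k, tail_at, numeric(1))
  mc_tail <- rep(NA_real_, length(prot))
  if (mode == "mc") {
    seeds <- with_seed(seed, sample.int(2147483646L, length(prot)))
    mc_tail <- vapply(seq_along(prot), function(i) {
      monte_carlo_tail(p_i, k[i], n_rep = n_rep, seed = seeds[i],
                       convention = convention)$estimate
    }, numeric(1))
  }
  p_adj <- if (adjust == "BH") benjamini_hochberg(p_tail) else p_tail
  out <- data.frame(
    protein = prot, k = k, m = m,
    p_tail = p_tail, mc_tail = mc_tail, p_adjusted = p_adj,
    flagged = p_adj < alpha,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_tail, out$protein, method = "radix"), ]
  rownames(out) <- NULL
  structure(out, class = c("herb_targets", "data.frame"),
            alpha = alpha, convention = convention, p_i = p_i)
}

#' @export
print.herb_targets <- function(x, ...) {
  cat(sprintf("<herb_targets> %d proteins over %d ingredient lists; %d flagged at alpha = %g\n",
              nrow(x), x$m[1], sum(x$flagged), attr(x, "alpha")))
  print.data.frame(head(x, 10))
  invisible(x)
}
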
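## Compound-target prediction.
##
## A compound is represented by its similarity vector CS_d to a panel of
## reference drugs. A protein p is represented by a drug-relevance profile
## Phi_p = beta_p + sum over drugs d_j known to bind p of alpha_pj * (row of
## d_j in the drug-drug similarity matrix). Candidate targets are ranked by
## the Pearson concordance rho between CS_d and Phi_p. The published model
## leaves beta and alpha unspecified; the default beta = 0, alpha = 1 is the
## simplest member of the linear family, and `coef_fun` lets callers plug in
## fitted coefficients.

#' Weighted quantitative estimate of druglikeness (wQED)
#'
#' The weighted geometric mean of descriptor desirabilities:
#' `exp( sum(w * log(d)) / sum(w) )`. Any zero desirability gives 0 (the
#' continuous limit of the formula). Scale-invariant in the weights.
#'
#' @param d numeric vector of desirabilities in \[0, 1\].
#' @param w positive weights, same length as `d` (default: equal weights,
#'   i.e. the unweighted geometric mean).
#' @return A number in \[0, 1\].
#' @examples
#' wqed(c(0.1, 0.9)) # sqrt(0.09) = 0.3
#' @export
wqed <- function(d, w = rep(1, length(d))) {
  d <- as.numeric(d)
  w <- as.numeric(w)
  if (length(d) == 0) stop("desirability vector is empty")
  if (length(w) != length(d)) stop("weights and desirabilities differ in length")
  if (any(d < 0 | d > 1)) stop("desirabilities must lie in [0, 1]")
  if (any(w <= 0)) stop("weights must be positive")
  if (any(d == 0)) return(0)
  exp(sum(w * log(d)) / sum(w))
}

#' Construct a compound record
#'
#' @param id compound identifier.
#' @param cs numeric similarity vector to the reference drugs, named by
#'   drug id, values in \[0, 1\].
#' @param desirabilities optional descriptor desirabilities in \[0, 1\]
#'   used to compute the druglikeness score when `wqed_value` is missing.
#' @param weights optional desirability weights.
#' @param wqed_value precomputed druglikeness; if `NULL`, computed from
#'   `desirabilities` via [wqed()].
#' @return An object of class `compound_record` with fields `id`, `cs`,
#'   `wqed`, `desirabilities`.
#' @export
compound_record <- function(id, cs, desirabilities = NULL, weights = NULL,
                            wqed_value = NULL) {
  cs <- unlist(cs)
  if (is.null(names(cs))) stop("similarity vector must be named by reference drug")
  if (any(cs < 0 | cs > 1)) stop("similarities must lie in [0, 1]")
  if (is.null(wqed_value)) {
    if (is.null(desirabilities)) stop("either wqed_value or desirabilities must be given")
    if (is.null(weights)) weights <- rep(1, length(desirabilities))
    wqed_value <- wqed(desirabilities, weights)
  }
  if (wqed_value < 0 || wqed_value > 1) stop("wqed must lie in [0, 1]")
  structure(
    list(id = as.character(id), cs = cs, wqed = wqed_value,
         desirabilities = desirabilities),
    class = "compound_record"
  )
}

#' @export
print.compound_record <- function(x, ...) {
  cat(sprintf("<compound_record> %s: wQED = %.3f, %d reference drugs\n",
              x$id, x$wqed, length(x$cs)))
  invisible(x)
}

#' Filter compounds by druglikeness
#'
#' Keeps compounds with `wqed > threshold` (strict inequality, so a value
#' exactly at the threshold is excluded); input order is preserved.
#'
#' @param compounds list of [compound_record] objects.
#' @param threshold druglikeness cutoff (default 0.05).
#' @return The retained sublist.
#' @export
druglikeness_filter <- function(compounds, threshold = 0.05) {
  keep <- vapply(compounds, function(cp) cp$wqed > threshold, logical(1))
  compounds[keep]
}

#' Construct a drug-target gold standard
#'
#' @param targets named list mapping each reference drug to a [gene_set]
#'   (or character vector) of its known target proteins.
#' @param similarity square drug-drug similarity matrix with the reference
#'   drugs as dimnames (used to build protein profiles).
#' @return An object of class `drug_target_gold` with fields `drugs`,
#'   `targets`, `similarity`, and `binders` (protein -> drugs binding it).
#' @export
drug_target_gold <- function(targets, similarity) {
  similarity <- as.matrix(similarity)
  drugs <- rownames(similarity)
  if (is.null(drugs) || !identical(drugs, colnames(similarity))) {
    stop("similarity must carry identical drug row and column names")
  }
  targets <- lapply(targets, as_members)
  if (is.null(names(targets)) || !all(names(targets) %in% drugs)) {
    stop("every drug in targets must appear in the similarity matrix")
  }
  prot <- unique(unlist(targets, use.names = FALSE))
  binders <- lapply(stats::setNames(prot, prot), function(p) {
    names(targets)[vapply(targets, function(tg) p %in% tg, logical(1))]
  })
  structure(
    list(drugs = drugs, targets = targets, similarity = similarity,
         binders = binders),
    class = "drug_target_gold"
  )
}

#' @export
print.drug_target_gold <- function(x, ...) {
  cat(sprintf("<drug_target_gold> %d drugs, %d proteins with known binders\n",
              length(x$drugs), length(x$binders)))
  invisible(x)
}

#' Drug-relevance profile of a protein
#'
#' Builds `Phi_p = beta_p + sum over binding drugs of alpha * (similarity
#' row of the drug)`, a vector over the reference drugs. With the default
#' coefficients (`beta = 0`, `alpha = 1`) this is the unweighted sum of the
#' binder similarity rows.
#'
#' @param protein protein id.
#' @param gold a [drug_target_gold].
#' @param coef_fun optional `function(protein, binders)` returning
#'   `list(beta = <number>, alpha = <named numeric over binders>)` to
#'   replace the default coefficients.
#' @return Named numeric vector over the reference drugs, or `NULL` when no
#'   reference drug is known to bind the protein (protein not scoreable).
#' @export
fit_protein_profile <- function(protein, gold, coef_fun = NULL) {
  b <- gold$binders[[protein]]
  if (is.null(b) || length(b) == 0) return(NULL)
  beta <- 0
  alpha <- stats::setNames(rep(1, length(b)), b)
  if (!is.null(coef_fun)) {
    cf <- coef_fun(protein, b)
    if (!is.null(cf$beta)) beta <- cf$beta
    if (!is.null(cf$alpha)) alpha <- cf$alpha[b]
  }
  rows <- gold$similarity[b, , drop = FALSE]
  drop(beta + crossprod(rows, alpha[b]))[gold$drugs]
}

#' Concordance score between a compound and a protein profile
#'
#' Pearson correlation between the compound's similarity vector to the
#' reference drugs and the protein's drug-relevance profile, both indexed
#' by the same drug panel. Returns `NA` when either vector is constant.
#'
#' @param compound a [compound_record].
#' @param profile a protein profile from [fit_protein_profile()].
#' @return A number in \[-1, 1\], or `NA` if undefined.
#' @export
drugcipher_score <- function(compound, profile) {
  cs <- compound$cs
  if (length(cs) != length(profile)) stop("compound and profile cover different drug panels")
  if (!is.null(names(profile))) {
    if (!setequal(names(cs), names(profile))) {
      stop("compound and profile cover different drug panels")
    }
    profile <- profile[names(cs)]
  }
  if (length(cs) < 3) stop("at least 3 reference drugs are required")
  if (stats::sd(cs) == 0 || stats::sd(profile) == 0) return(NA_real_)
  stats::cor(as.numeric(cs), as.numeric(profile))
}

#' Rank candidate target proteins for a compound
#'
#' Scores every protein in the proteome that has at least one known binding
#' drug, ranks by concordance descending (ties broken lexicographically by
#' protein id) and selects the top `top_n` as the compound's potential
#' targets.
#'
#' @param compound a [compound_record].
#' @param gold a [drug_target_gold].
#' @param proteome character vector of candidate proteins.
#' @param top_n number of targets to select (default 100).
#' @param coef_fun passed to [fit_protein_profile()].
#' @return An object of class `target_ranking`: list with `compound`,
#'   `ranking` (data.frame `protein`, `score`, `rank`), `selected`
#'   (character vector of top proteins), `n_scoreable`, `top_n`.
#' @export
predict_targets <- function(compound, gold, proteome, top_n = 100,
                            coef_fun = NULL) {
  if (length(proteome) == 0) stop("proteome is empty")
  scores <- vapply(proteome, function(p) {
    prof <- fit_protein_profile(p, gold, coef_fun = coef_fun)
    if (is.null(prof)) return(NA_real_)
    drugcipher_score(compound, prof)
  }, numeric(1))
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("no scoreable protein for compound ", compound$id)
  ord <- order(-scores, names(scores), method = "radix")
  ranking <- data.frame(
    protein = names(scores)[ord],
    score = unname(scores[ord]),
    rank = seq_along(ord),
    stringsAsFactors = FALSE
  )
  n_sel <- min(top_n, nrow(ranking))
  structure(
    list(compound = compound$id,
         ranking = ranking,
         selected = ranking$protein[seq_len(n_sel)],
         n_scoreable = nrow(ranking),
         top_n = top_n),
    class = "target_ranking"
  )
}

#' @export
print.target_ranking <- function(x, ...) {
  cat(sprintf("<target_ranking> compound %s: %d scoreable proteins, %d selected\n",
              x$compound, x$n_scoreable, length(x$selected)))
  print(head(x$ranking, 5))
  invisible(x)
}

#' Tanimoto similarity of binary fingerprints
#'
#' Fixture helper for building compound-drug similarity matrices from
#' binary fingerprints: `|a & b| / |a | b|` (1 when both are all-zero).
#'
#' @param a,b logical or 0/1 vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) stop("fingerprints differ in length")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Read a drug-target interaction table (two-column TSV)
#'
#' Each line is `drug <tab> protein`.
#'
#' @param path path to the TSV file.
#' @return Named list mapping drug to character vector of targets.
#' @export
read_drug_targets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = FALSE, col.names = c("drug", "protein"),
                   colClasses = "character")
  split(df$protein, factor(df$drug, levels = unique(df$drug)))
}

#' @rdname read_drug_targets
#' @param targets named list mapping drug to targets.
#' @export
write_drug_targets <- function(targets, path) {
  df <- data.frame(
    drug = rep(names(targets), lengths(targets)),
    protein = unlist(targets, use.names = FALSE)
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
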
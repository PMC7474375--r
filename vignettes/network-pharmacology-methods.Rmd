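---
title: "Methods: syndrome networks, compound targets, and their null models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: syndrome networks, compound targets, and their null models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

This vignette documents the models behind `netpharm`, the choices we made
where the methods family leaves room, and what the synthetic benchmarks do
and do not demonstrate.

## Phenotype-driven gene prioritization

A traditional-medicine syndrome such as Spleen Qi Deficiency is treated as
a query phenotype embedded in a space of reference phenotypes (OMIM-style
diseases and syndromes) with a similarity matrix in [0, 1]. The working
assumption is phenotype–gene modularity: phenotypically similar disorders
tend to involve genes that are close in the protein–protein interaction
(PPI) network. A gene's closeness profile assigns to each reference
phenotype the sum of `exp(-L^2)` over that phenotype's known genes, where
`L` is the unweighted shortest-path distance; `cipher_score()` is the
Pearson correlation between this profile and the query's similarity row
over the same reference phenotypes.

Choices worth stating explicitly:

* **Kernel.** The Gaussian kernel of shortest-path length, `exp(-L^2)`,
  is the published closeness kernel of this prioritization family. It is
  sharp: contributions fall 1, 0.368, 0.018, 1.2e-4 at distances 0–3, so
  in practice only a gene's two-hop surroundings matter. Unreachable
  known genes contribute exactly 0 (`exp(-Inf) = 0`), which also settles
  the disconnected-network case without a special rule. The kernel is an
  internal function with a single definition, so a variant kernel is a
  one-line change.
* **Undefined correlations.** A gene whose profile has zero variance
  (typically: zero everywhere, i.e. disconnected from all known genes)
  has no defined correlation. Such genes are excluded from the ranking
  rather than scored 0 — silent zeros would pile mass into the middle of
  the ranking and distort both tails.
* **Reference set.** Every phenotype with at least one known gene serves
  as a reference, except the query itself: the query's associations are
  the quantity being predicted, and at least 3 references are required
  for a meaningful correlation.
* **Ties.** Equal scores are ordered lexicographically by gene id using C
  collation, so rankings are identical across platforms and locales.
* **Top-N.** The default `top_n = 500` matches the standard operating
  point of this analysis; it is a plain argument everywhere.

## Permutation validation

Precision and recall of the top-N list against a user-supplied reported
gene list are compared with the same quantities on shuffled networks. We
shuffle by degree-preserving double edge swaps (default `10 * |E|`
attempts per permutation, 1000 permutations): degree preservation is the
standard null for network prioritization, because naive rewiring would
let hub effects masquerade as signal. Even so, the null is informative
rather than flat — hubs stay hubs under the null, and hub genes are easy
to recall — so observed recall must beat a fairly high null mean, which
is exactly the comparison the empirical p-value makes. We use the add-one
estimator `(1 + #{null >= observed}) / (1 + n_perm)`, which cannot return
0 at finite permutation counts.

## Druglikeness and compound–target prediction

`wqed()` is the weighted geometric mean of descriptor desirabilities.
Numerically, any zero desirability yields 0 by the continuous limit
(`ln 0 = -Inf`, `exp(-Inf) = 0`) instead of an error; weights are only
required positive, since the value is invariant to their scale. The
filter keeps compounds with wQED strictly above 0.05. Descriptor-to-
desirability transforms and weights are the caller's responsibility —
the package treats desirabilities (or a precomputed wQED) as inputs, and
compound–drug similarities as a precomputed matrix, with a Tanimoto
helper for building fixture fingerprints. Filtering precedes target
prediction, following the narrative order of the procedure; both counts
are visible to the caller.

The protein profile is the linear family
`Phi_p = beta'_p + sum over binders alpha'_pj * CS_dj`. The literature
leaves the coefficients unspecified, so the default is the simplest
member, `beta' = 0`, `alpha' = 1` — an unweighted sum of binder
similarity rows — declared rather than silently assumed, with a
`coef_fun` hook for fitted coefficients. The concordance `rho_pd` is a
Pearson correlation, undefined (protein excluded for that compound) when
either vector is constant. Proteins with no known binding drug are not
scoreable and are excluded with their count available from the ranking
object. Top-100 selection and lexicographic tie-breaks mirror the
gene-ranking conventions. A consequence of the default coefficients worth
knowing: all proteins bound by exactly the same single drug share a
profile, hence a score — their relative order is purely lexicographic.

## Herb-level target significance

Whether ingredient *i*'s top-`top_n` list contains a given protein is
modelled as an independent Bernoulli draw with
`p_i = top_n / |candidate proteins|` (heterogeneous `p_i` are supported,
including per-ingredient list sizes). The count K over the herb's *m*
ingredients is Poisson binomial. The pmf is computed by the O(m²)
convolution recurrence, which is algebraically identical to the
subset-enumeration definition but exact at any *m*; the test suite checks
equality against literal enumeration to 1e-12 for all m ≤ 12 and against
the binomial closed form for equal probabilities.

Two conventions coexist in this family's descriptions: `Pr(K = k)` and a
strict tail `Pr(K > k)` estimated from 1000 random cases. Significance
here defaults to the inclusive tail `Pr(K >= k_obs)`, so an observation
at the maximum possible count is never assigned probability 0; the strict
tail is available via `convention = "gt"`, and the 1000-replicate Monte
Carlo estimator is retained as a validation mode (`mode = "mc"`), not the
inference path — exactness is available at negligible cost. No
multiplicity correction is applied by default, matching the plain
`P < 0.05` rule; `adjust = "BH"` is available. The independence
assumption is a genuine approximation: concordance-based lists of related
compounds overlap systematically, so on correlated ingredient sets the
model is anti-conservative — visible in the end-to-end synthetic run,
where most repeatedly-predicted proteins are flagged.

## Enrichment, overlay, proximity, hubs

* **Enrichment** is one-sided (over-representation only) Fisher's exact
  test against a user-chosen background, defaulting to all network genes
  (the universe is otherwise a silent degree of freedom), with BH
  adjustment across the tested terms.
* **Overlay**: differentially expressed genes are linked to a module
  either by direct membership or by one-hop PPI adjacency — our
  operationalization of a "direct or indirect relationship"; an optional
  gene-set-derived edge layer extends adjacency by pathway co-membership.
  The two classes are disjoint and exhaustive over module-linked DEGs.
  The coverage p-value is the hypergeometric upper tail of the direct
  overlap only, so indirect linkage never inflates significance.
* **Proximity** of a target set to a module is the mean over targets of
  the nearest-module shortest-path distance (0 iff every reachable target
  is in the module), compared with `n_null` random sets matched on degree
  (log2-degree bins, width configurable; isolated nodes form their own
  bin). The z-score and a lower-tail add-one empirical p quantify
  closer-than-random placement. Node-level degree-matched permutation was
  chosen over edge permutation so that observed and null statistics live
  on the identical network.
* **Hub ranking** is plain degree sorting with lexicographic ties and an
  annotation column, mirroring the usual top-20 hub table of a disease
  subnetwork.

## The synthetic world

`generate_world()` emulates the study conditions at desk scale: a
2000-gene connected scale-free PPI (preferential attachment, m = 2), a
20-gene planted module grown greedily as a dense core (within-module
density at least 5× global), 14 reference phenotypes mirroring the
14-phenotype clinical description of the query syndrome, 50 reference
drugs over a 500-protein candidate proteome containing the module, 30
compounds, and a 20-sample expression matrix with the module genes
down-regulated (effect 2 on log2 scale, noise sd 1 — a moderate, clearly
detectable microarray effect at n = 10 per group).

Generator design points:

* **Phenotype similarity** comes from 1-D latent positions with the query
  at one end; reference positions are drawn Beta(0.4, 0.4), i.e. bimodal
  — reference disorders either share much of the query's phenotype
  profile or little of it, which is how disease-similarity rows around a
  focused query actually look. Symmetric jitter (±0.05) keeps the matrix
  noisy but exactly symmetric with unit diagonal.
* **Known genes**: each reference phenotype draws 20 known genes; each
  draw comes from the planted module's neighborhood with probability
  `signal × similarity(query, phenotype)` and uniformly otherwise. A
  neighborhood draw picks a module gene with probability 0.7 and a
  one-hop neighbor otherwise: in a scale-free graph the raw one-hop
  neighborhood of a hub-containing module covers a third of the genome,
  and drawing it uniformly would dilute the planted signal to
  near-uniform. At `signal = 0` the construction collapses to uniform
  draws, giving the chance-level negative control. Twenty genes per
  phenotype is the scale at which the sharp closeness kernel yields
  stable profiles over 14 reference points; with ~5 the profiles are too
  sparse for any correlation-based method to read.
* **Compound similarities**: each compound has a true target; its
  similarity to the drugs binding that target is elevated by `kappa`
  (default 0.6) over a Uniform(0, 0.4) background, so `kappa = 0` is
  exchangeable by construction.
* **Determinism**: one global seed fans out through a fixed affine map to
  per-generator streams, so adding a generator never perturbs existing
  fixtures; every generator restores the caller's RNG state.

What passing the synthetic benchmarks does **not** show: real PPIs have
confidence-weighted, biased-ascertainment edges (the generator's graph is
clean and uniform-by-construction); real phenotype similarity matrices
are built from text-mined term vectors with structured noise; real
expression data have batch effects, correlated genes and heavier tails
than the Gaussian model; and compound–drug similarities from real
fingerprints are far from exchangeable even for unrelated molecules.
Recovery here demonstrates internal correctness and calibration of the
statistics, not field performance.

## Problem sizes and runtime posture

The test suite runs each stage at the default 2000-node world where the
check concerns the default configuration (selection sizes, the
1000-shuffle ensemble, AUROC recovery, proximity calibration) and at
200–1000-node worlds for repeated-replicate property checks; the
acceptance script uses the default world throughout, with 10 extra worlds
for the AUROC average and 20 uniform-null replicates for the herb
flagging rate. Exhaustive oracle comparisons (all-pairs distances, subset
enumeration, all 2×2 Fisher configurations) run at the sizes where
enumeration is exact and cheap: 15 nodes, m ≤ 12, backgrounds ≤ 25.

## Known limitations

* Gene identifiers are opaque case-sensitive strings; no symbol
  normalization or orthology mapping is attempted.
* All graph kernels ignore edge weights and directions by design.
* The Poisson-binomial background assumes independent ingredient lists
  (see above).
* One query phenotype is scored at a time; scoring several query
  phenotypes and merging (e.g. by max score) is left to the caller, and
  no claim is made that either matches any published multi-phenotype
  procedure.
* The Eq.-style linear coefficients of the protein profile are not
  fitted; the hook exists, a fitting scheme does not.
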
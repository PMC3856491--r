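---
title: "Evolving symbolic essentiality classifiers over PPI-network features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving symbolic essentiality classifiers over PPI-network features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(gepess)
library(dplyr)
```

## The problem and the model

Essential proteins are those whose loss is lethal to the cell. In yeast,
essentiality correlates with many partly redundant signals: a protein's
connectivity and embedding in the protein--protein interaction (PPI) network,
its co-expression with interaction partners (protein complexes are
co-expressed), its evolutionary conservation, and its subcellular compartment
(nuclear proteins are enriched in essentials, cytoplasmic and vacuolar ones
depleted). No single feature is decisive, and black-box learners that combine
them do not explain *how* they combine.

`gepess` takes the symbolic route: gene expression programming (GEP)
evolves a population of fixed-length linear genotypes (Karva strings) that
decode into arithmetic expression trees over the protein features. The
fittest evolved expression *is* the classifier — a human-readable formula
such as `Min(lysosome, WDC - 0.5) + (ION - 0.9) + ...` — scored on each
protein and thresholded by rank.

The feature set has three blocks, all max-normalized into $[-1, 1]$ by
dividing each feature by its maximum absolute value:

* **Topology** — degree (DC), betweenness (BC), closeness (CC), subgraph
  (SC), eigenvector (EC), information (IC) centrality, and NC, the sum of
  edge clustering coefficients (ECC) over a protein's edges. For an edge
  $(u,v)$, $\mathrm{ECC}(u,v) = z_{uv} / \min(d_u - 1, d_v - 1)$ with
  $z_{uv}$ the number of common neighbours; a pendant edge scores 0.
* **Composites** — PeC ($\sum_j \mathrm{ECC}\cdot\max(\mathrm{PCC},0)$ over
  neighbours), WDC ($\sum_j \lambda\,\mathrm{ECC} + (1-\lambda)\,
  \mathrm{PCC}$), and ION, the fixed point of
  $S_i = (1-\alpha) O_i + \alpha \sum_{j \in N(i)} W_{ji} S_j$, which
  propagates a max-normalized orthology conservation score $O$ over the
  network with ECC-proportional edge weights (uniform $1/d_j$ where a
  protein's incident ECCs are all zero).
* **Localization** — sixteen 0/1 compartment indicators
  (`yeast_compartments`).

Four constant terminals (0.1, 0.2, 0.5, 1.0) join the feature terminals so
that evolution can assemble free coefficients by arithmetic.

## The genotype and the fitness

A chromosome is one gene (configurably more, linked by addition) of head
length $h = 20$: the head holds functions or terminals, the tail — of length
$h + 1$, since the maximum function arity is 2 — holds terminals only. This
structural law makes *every* random string decode: level-order (Karva)
expansion closes before the gene ends, and trailing symbols are simply
non-coding. The derived gene length is therefore $2h + 1 = 41$ symbols.

Evaluation is protected so every score is finite: division returns 1 when
the divisor's magnitude is below $10^{-12}$; `sqrt` and `log` act on
magnitudes (with a $10^{-12}$ floor inside the logarithm); `exp` clips its
argument at 30; `=` is an approximate-equality indicator at tolerance
$10^{-9}$. These conventions are exposed in one place
(`evaluate_tree()`), and the textual form produced by `render_expression()`
round-trips through `parse_expression()`.

Fitness of a chromosome is **SSPN**: score all training proteins, call the
top $k$ positive where $k$ is the number of essential training proteins
(ties broken by protein ID so the procedure is deterministic), and take

$$\mathrm{SSPN} = \mathrm{SN} \cdot \mathrm{SP} \cdot \mathrm{PPV} \cdot
\mathrm{NPV},$$

each factor defined as 0 on an empty denominator. Cutting at the true
positive count forces $TP + FP = TP + FN$, hence SN = PPV and SP = NPV —
the identity our metric suite checks on random draws. Binarizing by rank
rather than by a fixed score threshold matches the top-$k$ evaluation
protocol used throughout and makes fitness invariant to monotone rescaling
of an expression.

## The generational loop

Each generation: evaluate the population, carry the single best chromosome
over unchanged (elitism, which guarantees that best-so-far fitness is
non-decreasing), keep the top 30% as parents, and refill by one-point
recombination (rate 0.1), per-position point mutation (rate 0.25), and
IS/RIS transposition (rates 0.1) — all domain-preserving, so offspring
always decode. Parents are consumed in fitness-rank order, continuing past
the elites, rather than resampled: with the parent fraction at 1 and all
operator rates 0 the population then passes through generations unchanged,
a useful invariant for testing, and all stochasticity lives in the
operators themselves.

Two published parameter readings were genuinely open and are resolved as
follows (both reachable through `gep_config()`):

* Rates labelled with a percent sign are read as probabilities (0.25
  per-position mutation, 0.1 per-pair crossover). The literal percent
  reading (0.0025, 0.001) mutates on average a tenth of a symbol per
  41-symbol chromosome — too little to search the space in 500 generations
  — so we treat the label as cosmetic. Either reading can be configured.
* A configured "chromosome length 60" is inconsistent with the structural
  Karva length 41 for one gene of head 20 at maximum arity 2 (a possible
  unstated constant-domain extension). Chromosome length here is always
  *derived* from head length and gene count, never set directly.

Defaults in `gep_config()` are the desk scale used by the tests and
examples: population 200, 50 generations. The full-scale study setting is
population 12000 over 500 generations with the same structural parameters;
it is a straight parameter change but hours of compute.

The published full-scale classifier is shipped as
`published_expression_text` and applied with `published_score()`. The
printed original contains a malformed term (a two-argument `Abs` with
unbalanced parentheses); we canonicalize it as `- Abs(Min(cytoplasm -
vacuole, 0.1) - 1)`, which evaluates to $-2.0$ on an all-zero feature
vector and is strictly increasing in ION — both properties are asserted in
the test suite. This canonical form is an interpretation, not a quotation.

## Evaluation machinery

`stratified_kfold()` shuffles each class independently and deals proteins
round-robin, so per-class fold sizes differ by at most one and every fold
preserves the global essential:nonessential ratio up to rounding. A class
smaller than $k$ leaves some folds without it; we warn rather than refuse,
since the round-robin contract stays meaningful. `roc_auc()` sweeps every
distinct score as a cutoff — equal scores form a single ROC step, which is
exactly the 0.5 tie credit of the rank-sum formulation, and the test suite
checks the trapezoidal integral against the Mann–Whitney oracle to
$10^{-12}$. `topk_metrics()` reports the SN/SP/FPR/PPV/NPV/F/ACC/MCC row at
a rank cutoff. `cross_validate()` evolves one classifier per fold and, for
whole-set scoring, selects the fold classifier whose held-out AUC is
closest to the mean (ties to the lower fold index) — a concrete reading of
"the classifier with average AUC".

## The synthetic study

Real inputs (DIP network, essentiality lists, expression compendia,
InParanoid orthology, eSLDB localization) require downloads and licenses,
so the package ships a generator that emulates their statistical structure
at desk scale. `synthetic_spec()` defaults are the study conditions used
throughout: 500 proteins (scale model of 5093), preferential-attachment
growth with 3 edges per new protein (scale-free, connected), 36 expression
samples in 20 co-expression modules with a shared-factor loading of 0.65
(within-module correlations near 0.65, between near 0), 5% of proteins
missing expression rows, essential fraction $1167/5093 \approx 0.229$, and
labels planted on `0.6*ION + 0.3*NC + 0.4*nucleus + noise` with Gaussian
noise of sd 0.2.

Circularity — ION reads orthology, which should be enriched in essentials,
which are defined through ION — is broken by two passes: a provisional
essential set (top fraction by NC, ties by degree then ID) drives the
biology tables (nucleus membership 0.60 vs 0.25, endoplasmic reticulum
0.40 vs 0.20, ortholog counts Binomial(99, 0.5) vs Binomial(99, 0.25) —
enrichments of the size reported for real yeast compartments and
conservation), then final features are computed and final labels planted on
them. Everything is a deterministic function of `rng_seed`.

What the generator does *not* emulate: the real degree distribution's exact
exponent, expression dynamics (cell-cycle periodicity), correlated
compartment memberships, and noise in the interaction network itself.
Passing the recovery experiment therefore shows the pipeline can find a
planted signal of realistic shape and strength — not that it reproduces
full-scale yeast accuracies.

```{r study, message = FALSE, warning = FALSE}
study <- simulate_ppi_study(synthetic_spec(rng_seed = 42))
glimpse(study$features[1:8])
count(study$labels, essential)
```

## The recovery experiment

`recovery_experiment()` is the desk-scale stand-in for the full-scale
cross-validation figures: five repetitions of (stratified 80/20 split,
evolve on the training side, AUC on the held-out side), compared with the
held-out AUC of the single centralities DC, BC and CC. The acceptance
checks require the median held-out AUC to exceed 0.85 and to beat the best
single-feature baseline — the desk-scale analogue of the claim that the
evolved combination outperforms individual features — and verify that
best-so-far fitness is non-decreasing in every run. A small version:

```{r evolve, message = FALSE}
labels <- study$labels[c("protein", "essential")]
split <- train_test_split(labels, test_frac = 0.2, seed = 101)
fit <- gep_evolve(
  study$features[study$features$protein %in% split$train$protein, ],
  split$train,
  gep_config(population_size = 100, generation_count = 20, rng_seed = 201)
)
fit
preds <- predict(fit, study$features[study$features$protein %in% split$test$protein, ])
roc_auc(preds, split$test)
tail(tidy(fit), 3)
```

Problem sizes in the shipped tests and the acceptance script were chosen as
the smallest at which every checked property is stable: oracle comparisons
on graphs of up to 25 nodes, operator checks on $10^4$ random applications,
and the recovery experiment at the generator's default 500 proteins with
population 200 over 50 generations.

## Numerical choices and known limitations

* ION iterates from $S = O$ to an L1 tolerance of $10^{-6}$ (cap 100
  iterations, warning on hitting it); $\alpha = 0.85$ and the WDC blend
  $\lambda = 0.5$ are conventional propagation/blend values, configurable,
  since no published setting exists for them.
* Closeness is component-restricted (the real network is not guaranteed
  connected); isolated proteins score 0 for CC, IC and EC (EC is the unit
  Euclidean-norm principal eigenvector of the largest component only).
* PeC floors negative co-expression at 0; WDC keeps it signed. Both are
  flags.
* All ranking ties (top-$k$ cutoff, eugenic selection, label planting)
  break lexicographically, so every pipeline stage is deterministic under
  its seed.
* SSPN is a coarse, plateau-heavy fitness: many expressions share a value,
  and search quality depends on the mutation-heavy operator mix. At desk
  scale occasional runs stall on a plateau; the recovery experiment uses
  the median over seeds for exactly that reason.
* The evolved expression is only rank-meaningful: its absolute scale is
  arbitrary, which is why evaluation is AUC- and rank-based throughout.
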
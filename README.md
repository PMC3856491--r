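# gepess

Essential proteins are those a cell cannot survive without; finding them
computationally from a protein–protein interaction (PPI) network is a
long-standing problem in systems biology, with applications from minimal
genomes to drug-target triage. Individual predictors — degree and other
centralities, co-expression-weighted scores, conservation — each capture a
slice of the signal. `gepess` combines them with **gene expression
programming (GEP)**: an evolutionary algorithm whose individuals are
fixed-length linear genotypes (Karva strings) that decode into arithmetic
expression trees over protein features. The evolved classifier is an
explicit, human-readable formula, not a black box.

The package is aimed at computational biologists who want to

* compute the standard essentiality feature panel from a PPI edge list —
  centralities DC, BC, CC, SC, EC, IC and NC (the per-node sum of edge
  clustering coefficients), the composites PeC, WDC (co-expression-weighted)
  and ION (orthology propagation), and subcellular-localization indicators —
  max-normalized into [-1, 1];
* evolve a symbolic classifier under the **SSPN** fitness
  `SN * SP * PPV * NPV`, computed by ranking training proteins and cutting
  at the number of known essentials;
* evaluate ranked predictions with stratified k-fold cross-validation,
  ROC/AUC (trapezoidal, tie-aware) and the full SN/SP/FPR/PPV/NPV/F/ACC/MCC
  metric row at a top-k cutoff.

A seeded synthetic-data module generates complete desk-scale studies
(scale-free network, module-structured expression, biology tables enriched
in essentials, labels planted through a known expression), so the entire
pipeline is testable without any downloads.

## Worked example

Simulate a 500-protein study, hold out a stratified 20%, evolve a
classifier (population 200, 50 generations), and evaluate it:

```r
library(gepess)

study  <- simulate_ppi_study(synthetic_spec(rng_seed = 42))
labels <- study$labels[c("protein", "essential")]
split  <- train_test_split(labels, test_frac = 0.2, seed = 101)

fit <- gep_evolve(
  study$features[study$features$protein %in% split$train$protein, ],
  split$train,
  gep_config(rng_seed = 201)
)
fit
#> <gep_fit> SSPN fitness 0.3999 after 50 generations
#>   score = Min(1,((nucleus+DC)-DC))

preds <- predict(fit, study$features[study$features$protein %in% split$test$protein, ])
roc_auc(preds, split$test)
#> <gep_roc> AUC = 0.8478 over 3 cutoffs

full <- predict(fit, study$features)
topk_metrics(full, labels, k = sum(labels$essential))
#> # A tibble: 1 × 13
#>      tp    tn    fp    fn     k    SN    SP    FPR   PPV   NPV F_measure   ACC   MCC
#>   <int> <int> <int> <int> <int> <dbl> <dbl>  <dbl> <dbl> <dbl>     <dbl> <dbl> <dbl>
#> 1    78   348    37    37   115 0.678 0.904 0.0961 0.678 0.904     0.678 0.852 0.582
```

The evolved expression here collapsed to the nuclear-localization indicator
(the `+DC-DC` is evolutionary dead code), capped at 1 — a readable statement
that, in this run, nuclear membership dominated. The held-out AUC of 0.85
and the metric row (note SN = PPV and SP = NPV: a consequence of cutting at
the true number of essentials) quantify the ranking. `tidy(fit)` exposes
the per-generation fitness history, `autoplot(fit)` plots it, and
`render_expression()`/`parse_expression()` serialize classifiers as text —
including the published full-scale classifier, shipped as
`published_expression_text` and applied with `published_score()`.

For file-based work, `write_synthetic_inputs()` writes the five standard
inputs (edge list, essential-protein list, expression/localization/orthology
TSVs) and `run_gep_pipeline()` drives read → featurize → cross-validate →
predict → report from those files.

## Documentation

The methods vignette (`vignettes/gep-essentiality.Rmd`) describes the
model, the protected evaluation semantics, the fitness and the generational
loop, what the synthetic generator does and does not emulate, and the
numerical conventions and known limitations.
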
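test_that("the preferential-attachment network is deterministic and scale-free", {
  spec <- synthetic_spec(rng_seed = 101)
  g1 <- generate_network(spec)
  g2 <- generate_network(spec)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  m <- spec$edges_per_new_node
  expect_equal(igraph::ecount(g1),
               (spec$n_proteins - m - 1) * m + m * (m + 1) / 2)
  expect_equal(igraph::vcount(g1), spec$n_proteins)
  expect_equal(igraph::components(g1)$no, 1)
  deg <- igraph::degree(g1)
  expect_gt(max(deg), 5 * median(deg)) # heavy tail

  tree_spec <- synthetic_spec(n_proteins = 10, edges_per_new_node = 1,
                              rng_seed = 4)
  gt <- generate_network(tree_spec)
  expect_equal(igraph::ecount(gt), 9) # (10 - 2) * 1 + 1: a tree
})

test_that("expression profiles are module-correlated with partial coverage", {
  spec <- synthetic_spec(n_proteins = 200, rng_seed = 55)
  g <- generate_network(spec)
  e <- generate_expression(spec, g)
  expect_equal(ncol(e) - 1, spec$n_samples)
  expect_equal(nrow(e), round(0.95 * 200)) # 5% of proteins omitted
  z <- gepess:::expression_zmatrix(e)
  cm <- tcrossprod(z)
  # recover module identity from the generator's seed stream
  set.seed(spec$rng_seed + 1)
  ids <- igraph::V(g)$name
  module <- sample.int(spec$n_modules, length(ids), replace = TRUE)
  mod <- module[match(rownames(z), ids)]
  same <- outer(mod, mod, "==") & upper.tri(cm)
  diff_ <- (!outer(mod, mod, "==")) & upper.tri(cm)
  expect_gt(mean(cm[same]) - mean(cm[diff_]), 0.3)
})

test_that("biology tables are enriched in the provisional essential set", {
  spec <- synthetic_spec(n_proteins = 300, rng_seed = 9)
  g <- generate_network(spec)
  ids <- igraph::V(g)$name
  prov <- ids[1:70]
  bio <- generate_localization_orthology(spec, g, prov)
  ess <- bio$localization$protein %in% prov
  expect_gt(mean(bio$localization$nucleus[ess]),
            mean(bio$localization$nucleus[!ess]))
  expect_gt(mean(bio$orthology$orthology[ess]),
            mean(bio$orthology$orthology[!ess]))
  expect_true(all(bio$orthology$orthology >= 0))
  expect_setequal(names(bio$localization), c("protein", yeast_compartments))
  expect_true(all(unlist(bio$localization[yeast_compartments]) %in% 0:1))
})

test_that("labels are planted on the requested score with the right prevalence", {
  feats <- tibble::tibble(protein = sprintf("P%04d", 1:100), DC = runif(100))
  spec <- synthetic_spec(n_proteins = 100, planting_expression = "DC",
                         noise_sd = 0, essential_fraction = 0.2, rng_seed = 3)
  labs <- plant_labels(spec, feats)
  expect_equal(sum(labs$essential), 20)
  expect_setequal(labs$protein[labs$essential],
                  feats$protein[order(-feats$DC)[1:20]])
  expect_error(plant_labels(synthetic_spec(planting_expression = "nope"),
                            feats), "unknown identifier")
})

test_that("the full study is deterministic and internally consistent", {
  spec <- synthetic_spec(rng_seed = 42)
  s1 <- simulate_ppi_study(spec)
  s2 <- simulate_ppi_study(spec)
  expect_identical(s1$features, s2$features)
  expect_identical(s1$labels, s2$labels)
  expect_equal(sum(s1$labels$essential),
               round(spec$essential_fraction * spec$n_proteins))
  # the planting score separates the planted classes by construction
  r <- roc_auc(tibble::tibble(protein = s1$labels$protein,
                              score = s1$labels$score),
               s1$labels[c("protein", "essential")])
  expect_gt(r$auc, 0.9)
  # features behave as a normalized table
  num <- s1$features[setdiff(names(s1$features), "protein")]
  expect_true(all(vapply(num, function(x) all(x >= -1 & x <= 1), logical(1))))
})

test_that("written study inputs read back through the data readers", {
  spec <- synthetic_spec(n_proteins = 80, rng_seed = 12)
  study <- simulate_ppi_study(spec)
  dir <- withr::local_tempdir()
  write_synthetic_inputs(study, dir)
  g <- suppressMessages(read_ppi_network(file.path(dir, "ppi_edges.tsv")))
  expect_equal(igraph::ecount(g), igraph::ecount(study$network))
  labs <- suppressMessages(read_essential_proteins(
    file.path(dir, "essential_proteins.txt"), g))
  expect_equal(sum(labs$essential), sum(study$labels$essential))
  expr <- read_expression_matrix(file.path(dir, "expression.tsv"))
  expect_equal(dim(expr), dim(study$expression))
  loc <- read_localization_matrix(file.path(dir, "localization.tsv"))
  expect_equal(loc, study$localization |>
                 dplyr::mutate(dplyr::across(-protein, as.integer)))
  orth <- read_orthology_scores(file.path(dir, "orthology.tsv"))
  expect_equal(orth, study$orthology)
})
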
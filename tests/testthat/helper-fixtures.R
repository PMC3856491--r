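# In-code fixtures shared across test files.

# two explanatory features with labels planted on x1 + 0.5 * x2
planted_tabular_fixture <- function(n = 120, seed = 7, frac = 0.25) {
  set.seed(seed)
  features <- tibble::tibble(
    protein = sprintf("T%03d", seq_len(n)),
    x1 = runif(n), x2 = runif(n)
  )
  score <- features$x1 + 0.5 * features$x2
  k <- round(frac * n)
  essential <- logical(n)
  essential[order(-score)[seq_len(k)]] <- TRUE
  list(features = features,
       labels = tibble::tibble(protein = features$protein,
                               essential = essential),
       plant_score = score)
}

# random expression tree over the given terminals (grown with a depth cap)
random_tree <- function(terminals, depth = 3) {
  if (depth == 0 || runif(1) < 0.3) {
    sym <- sample(c(terminals, gep_coefficients), 1)
    return(list(sym = sym, arity = 0L, children = list()))
  }
  fn <- sample(names(gep_function_set), 1)
  a <- gep_function_set[[fn]]
  kids <- lapply(seq_len(a), function(i) random_tree(terminals, depth - 1))
  list(sym = fn, arity = as.integer(a), children = kids)
}

tiny_gep_config <- function(...) {
  gep_config(population_size = 40, generation_count = 8, head_length = 6, ...)
}
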
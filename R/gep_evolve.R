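#' Evolve a GEP essentiality classifier
#'
#' Runs the generational loop: a random initial population of Karva
#' chromosomes is scored with the SSPN fitness, the best chromosome is
#' carried over unchanged (elitism), the top `eugenic_fraction` are kept as
#' parents, and the population is refilled by recombination, point mutation
#' and IS/RIS transposition of uniformly sampled parent pairs. All
#' stochastic steps run under `config$rng_seed`, so a rerun with the same
#' inputs is bit-identical.
#'
#' @param features Feature tibble: `protein` column plus numeric feature
#'   columns (normalized; see [assemble_feature_table()]). Every non-protein
#'   column becomes a terminal symbol, alongside the four coefficient
#'   constants in [gep_coefficients].
#' @param labels Tibble with `protein` and logical `essential`; both classes
#'   must be present.
#' @param config A [gep_config()].
#' @return A `gep_fit` object: `best_chromosome`, `best_fitness`,
#'   `expression` (rendered text), `history` (tibble of generation,
#'   best_fitness, mean_fitness), `config`, and the terminal/feature sets.
#'   Supports [predict()][predict.gep_fit], [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
gep_evolve <- function(features, labels, config = gep_config()) {
  labels <- labels[match(features$protein, labels$protein), ]
  essential <- labels$essential
  if (anyNA(essential)) stop("labels missing for some proteins", call. = FALSE)
  if (all(essential) || !any(essential))
    stop("training labels are degenerate: both classes are required",
         call. = FALSE)
  proteins <- features$protein
  feature_data <- as.list(features[setdiff(names(features), "protein")])
  terminals <- c(names(feature_data), gep_coefficients)

  set.seed(config$rng_seed)
  pop <- replicate(config$population_size,
                   random_chromosome(config, terminals), simplify = FALSE)
  cache <- new.env(parent = emptyenv())
  fit_of <- function(chr) {
    key <- chromosome_string(chr)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- chromosome_fitness(chr, feature_data, essential, proteins)
    cache[[key]] <- f
    f
  }

  best_chr <- NULL
  best_fit <- -Inf
  history <- vector("list", config$generation_count)
  for (gen in seq_len(config$generation_count)) {
    fitness <- vapply(pop, fit_of, numeric(1))
    gen_best <- max(fitness)
    if (gen_best > best_fit) {
      best_fit <- gen_best
      best_chr <- pop[[which.max(fitness)]]
    }
    history[[gen]] <- tibble::tibble(
      generation = gen, best_fitness = best_fit,
      generation_best = gen_best, mean_fitness = mean(fitness)
    )
    if (gen == config$generation_count) break

    parents <- select_eugenic(pop, fitness, config$eugenic_fraction)
    strs <- vapply(pop, chromosome_string, character(1))
    elite_ord <- order(-fitness, strs, method = "radix")
    next_pop <- pop[elite_ord[seq_len(min(config$elitism_count,
                                          length(pop)))]]
    # parents are consumed in fitness-rank order, continuing past the elites,
    # so that with eugenic_fraction = 1 and all operator rates 0 the
    # population is carried over unchanged
    np <- length(parents)
    idx <- length(next_pop)
    while (length(next_pop) < config$population_size) {
      i1 <- (idx %% np) + 1L
      i2 <- ((idx + 1L) %% np) + 1L
      idx <- idx + 2L
      kids <- recombine_chromosomes(parents[[i1]], parents[[i2]],
                                    config$crossover_rate, config)
      for (kid in kids) {
        if (length(next_pop) >= config$population_size) break
        kid <- mutate_chromosome(kid, config$mutation_rate, config)
        kid <- transpose_chromosome(kid, config$is_transposition_rate,
                                    config$ris_transposition_rate, config)
        next_pop[[length(next_pop) + 1L]] <- kid
      }
    }
    pop <- next_pop
  }

  structure(list(
    best_chromosome = best_chr,
    best_fitness = best_fit,
    expression = render_expression(decode(best_chr)),
    history = dplyr::bind_rows(history),
    config = config,
    terminals = terminals,
    feature_names = names(feature_data)
  ), class = "gep_fit")
}

#' @export
print.gep_fit <- function(x, ...) {
  cat("<gep_fit> SSPN fitness", format(x$best_fitness, digits = 4), "after",
      nrow(x$history), "generations\n  score =", x$expression, "\n")
  invisible(x)
}

#' Score proteins with a fitted GEP classifier
#'
#' @param object A `gep_fit`.
#' @param features Feature tibble with the columns the fit was trained on.
#' @param ... Unused.
#' @return A tibble with `protein` and `score`.
#' @export
predict.gep_fit <- function(object, features, ...) {
  tree <- decode(object$best_chromosome)
  tibble::tibble(protein = features$protein,
                 score = evaluate_tree(tree, features))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the evolution history of a GEP fit
#'
#' @param x A `gep_fit`.
#' @param ... Unused.
#' @return The per-generation history tibble (generation, best_fitness,
#'   generation_best, mean_fitness).
#' @method tidy gep_fit
#' @export
tidy.gep_fit <- function(x, ...) x$history

#' One-row summary of a GEP fit
#'
#' @param x A `gep_fit`.
#' @param ... Unused.
#' @return Tibble with `best_fitness`, `generations`, `population_size`,
#'   `expression`.
#' @method glance gep_fit
#' @export
glance.gep_fit <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    generations = nrow(x$history),
    population_size = x$config$population_size,
    expression = x$expression
  )
}

#' Plot the fitness trajectory of a GEP run
#'
#' @param object A `gep_fit`.
#' @param ... Unused.
#' @return A ggplot: best-so-far and mean SSPN fitness per generation.
#' @method autoplot gep_fit
#' @export
autoplot.gep_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            c("best_fitness", "mean_fitness"),
                            names_to = "series", values_to = "fitness")
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$fitness,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "SSPN fitness", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
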
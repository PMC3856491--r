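# Symbol tables for the GEP genotype. Functions carry an arity; terminals are
# feature-column names plus the four contribution coefficients, which enter
# the genotype as constant terminal symbols so evolved expressions can build
# free constants (0.4 = 0.5 - 0.1, 0.9 = 1.0 - 0.1, ...) by arithmetic.

#' GEP function set: arities by function name
#'
#' Binary: `add`, `sub`, `mul`, `div` (protected), `eq` (approximate-equality
#' indicator), `max`, `min`. Unary: `sqrt`, `log`, `exp`, `abs` (all
#' protected; see [evaluate_tree()]).
#'
#' @format Named integer vector mapping function name to arity.
#' @export
gep_function_set <- c(
  add = 2L, sub = 2L, mul = 2L, div = 2L, eq = 2L, max = 2L, min = 2L,
  sqrt = 1L, log = 1L, exp = 1L, abs = 1L
)

#' The four coefficient terminals
#'
#' Constant terminal symbols available to evolution alongside the feature
#' terminals, used to scale feature contributions.
#'
#' @format Character vector `c("0.1", "0.2", "0.5", "1.0")`.
#' @export
gep_coefficients <- c("0.1", "0.2", "0.5", "1.0")

is_function_symbol <- function(sym) sym %in% names(gep_function_set)

symbol_arity <- function(sym) unname(gep_function_set[sym])

#' GEP evolution configuration
#'
#' All evolution parameters in one validated list. Defaults are the desk
#' scale used throughout the examples and tests (population 200, 50
#' generations); the full-scale study setting is population 12000 over 500
#' generations with the same structural parameters (1 gene, head length 20,
#' mutation 0.25, crossover 0.1).
#'
#' @param population_size Number of chromosomes per generation.
#' @param gene_count Genes per chromosome; multiple genes are linked by
#'   addition.
#' @param head_length Karva head length h. The tail length is `h + 1` (max
#'   arity 2), so each gene spans `2h + 1` symbols.
#' @param mutation_rate Per-position replacement probability.
#' @param crossover_rate Per-pair one-point recombination probability.
#' @param is_transposition_rate,ris_transposition_rate Probabilities of
#'   insertion-sequence / root-insertion-sequence transposition per
#'   chromosome.
#' @param generation_count Number of generations.
#' @param function_set Function names drawn in heads; subset of
#'   `names(gep_function_set)`.
#' @param fitness_name Fitness label; only `"SSPN"` is implemented.
#' @param eugenic_fraction Fraction of the population kept as parents
#'   (truncation selection). Default 0.30.
#' @param elitism_count Best chromosomes carried unchanged. Default 1.
#' @param rng_seed Seed for all stochastic steps. Default 42.
#' @return A `gep_config` list.
#' @export
gep_config <- function(population_size = 200, gene_count = 1,
                       head_length = 20, mutation_rate = 0.25,
                       crossover_rate = 0.1, is_transposition_rate = 0.1,
                       ris_transposition_rate = 0.1, generation_count = 50,
                       function_set = names(gep_function_set),
                       fitness_name = "SSPN", eugenic_fraction = 0.30,
                       elitism_count = 1, rng_seed = 42) {
  stopifnot(
    head_length >= 1, gene_count >= 1, population_size >= 2,
    mutation_rate >= 0, mutation_rate <= 1,
    crossover_rate >= 0, crossover_rate <= 1,
    is_transposition_rate >= 0, is_transposition_rate <= 1,
    ris_transposition_rate >= 0, ris_transposition_rate <= 1,
    eugenic_fraction > 0, eugenic_fraction <= 1,
    all(function_set %in% names(gep_function_set)),
    identical(fitness_name, "SSPN")
  )
  structure(list(
    population_size = as.integer(population_size),
    gene_count = as.integer(gene_count),
    head_length = as.integer(head_length),
    mutation_rate = mutation_rate,
    crossover_rate = crossover_rate,
    is_transposition_rate = is_transposition_rate,
    ris_transposition_rate = ris_transposition_rate,
    generation_count = as.integer(generation_count),
    function_set = function_set,
    fitness_name = fitness_name,
    eugenic_fraction = eugenic_fraction,
    elitism_count = as.integer(elitism_count),
    rng_seed = as.integer(rng_seed)
  ), class = "gep_config")
}

gene_length <- function(config) 2L * config$head_length + 1L

chromosome_length <- function(config) config$gene_count * gene_length(config)
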
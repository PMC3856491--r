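# Rank-based binarization and the SSPN fitness. Scores are turned into hard
# labels by taking the top-k proteins (k = number of training positives),
# which makes TP + FP = TP + FN and hence SN = PPV and SP = NPV -- the
# identity pattern visible in every row of the full-scale comparison table.

#' Label the top-k scored proteins as predicted positives
#'
#' The `positive_count` highest-scoring proteins are labeled 1, the rest 0.
#' Ties at the cutoff are broken by protein-ID lexicographic order, so the
#' result is deterministic.
#'
#' @param scores Named numeric vector (names = protein IDs).
#' @param positive_count Number of proteins to call positive.
#' @return Named integer 0/1 vector in the input order.
#' @export
classify_by_rank <- function(scores, positive_count) {
  stopifnot(positive_count <= length(scores))
  ord <- order(-scores, names(scores), method = "radix")
  out <- setNames(integer(length(scores)), names(scores))
  out[ord[seq_len(positive_count)]] <- 1L
  out
}

#' Confusion counts of a hard prediction
#'
#' @param predicted Named 0/1 integer vector.
#' @param actual Named logical (or 0/1) vector over the same proteins.
#' @return One-row tibble with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(predicted, actual) {
  actual <- as.logical(actual[names(predicted)])
  pred <- predicted == 1L
  tibble::tibble(
    tp = sum(pred & actual), tn = sum(!pred & !actual),
    fp = sum(pred & !actual), fn = sum(!pred & actual)
  )
}

#' SSPN fitness of confusion counts
#'
#' The product SN * SP * PPV * NPV of sensitivity, specificity, positive and
#' negative predictive value; each factor is 0 when its denominator is 0.
#' Always in \[0, 1\], and 1 exactly when FP = FN = 0 with both classes
#' present.
#'
#' @param counts One-row tibble or list with `tp`, `tn`, `fp`, `fn`.
#' @return Fitness in \[0, 1\].
#' @export
fitness_sspn <- function(counts) {
  frac <- function(num, den) if (den > 0) num / den else 0
  sn <- frac(counts$tp, counts$tp + counts$fn)
  sp <- frac(counts$tn, counts$tn + counts$fp)
  ppv <- frac(counts$tp, counts$tp + counts$fp)
  npv <- frac(counts$tn, counts$tn + counts$fn)
  sn * sp * ppv * npv
}

#' SSPN fitness of one chromosome on labeled training data
#'
#' Decodes the chromosome, scores every training protein, binarizes by rank
#' at k = number of essential training proteins, and returns the SSPN of the
#' resulting confusion counts.
#'
#' @param chromosome A `gep_chromosome`.
#' @param feature_data Named list of feature vectors (or feature tibble).
#' @param essential Logical vector aligned with the feature rows.
#' @param proteins Protein IDs aligned with the feature rows (used for the
#'   deterministic tie-break).
#' @return Fitness in \[0, 1\].
#' @export
chromosome_fitness <- function(chromosome, feature_data, essential, proteins) {
  tree <- decode(chromosome)
  scores <- setNames(evaluate_tree(tree, feature_data), proteins)
  pred <- classify_by_rank(scores, sum(essential))
  fitness_sspn(confusion_counts(pred, setNames(essential, proteins)))
}

#' Truncation ("eugenic") selection
#'
#' Keeps the `ceiling(fraction * n)` highest-fitness chromosomes; fitness
#' ties are broken by chromosome-string lexicographic order.
#'
#' @param population List of chromosomes.
#' @param fitness Numeric vector of their fitnesses.
#' @param fraction Fraction to keep (default 0.30).
#' @return List of selected chromosomes, best first.
#' @export
select_eugenic <- function(population, fitness, fraction = 0.30) {
  keep <- ceiling(fraction * length(population))
  strs <- vapply(population, chromosome_string, character(1))
  ord <- order(-fitness, strs, method = "radix")
  population[ord[seq_len(keep)]]
}
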
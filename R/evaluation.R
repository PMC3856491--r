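# Stratified cross-validation and ranked-prediction evaluation: ROC/AUC by
# cutoff sweep (equal scores grouped into one step) and the confusion-metric
# suite at a top-k cutoff.

#' Stratified k-fold assignment
#'
#' Shuffles each class independently, then deals proteins round-robin to
#' folds, so per-class fold sizes differ by at most one and every fold
#' matches the global essential:nonessential ratio up to rounding.
#'
#' @param labels Tibble with `protein` and logical `essential`.
#' @param k Number of folds (>= 2); each class must have at least k members.
#' @param seed RNG seed for the per-class shuffles.
#' @return A tibble with `protein`, `essential`, and `fold` (integer 1..k).
#' @export
stratified_kfold <- function(labels, k = 10, seed = 42) {
  stopifnot(k >= 2, k <= nrow(labels))
  counts <- table(labels$essential)
  if (length(counts) < 2)
    stop("both classes must be present to stratify", call. = FALSE)
  if (any(counts < k))
    warning("a class has fewer than k = ", k,
            " members; some folds will lack it", call. = FALSE)
  set.seed(seed)
  out <- labels
  out$fold <- NA_integer_
  for (cls in c(TRUE, FALSE)) {
    idx <- which(labels$essential == cls)
    idx <- idx[sample.int(length(idx))]
    out$fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  out
}

#' Stratified train/test split
#'
#' Convenience wrapper over [stratified_kfold()]: one fold (of `1/test_frac`)
#' held out, the rest for training.
#'
#' @param labels Tibble with `protein` and `essential`.
#' @param test_frac Held-out fraction (1/k for integer k). Default 0.2.
#' @param seed RNG seed.
#' @return List with `train` and `test` label tibbles.
#' @export
train_test_split <- function(labels, test_frac = 0.2, seed = 42) {
  k <- max(2L, as.integer(round(1 / test_frac)))
  folds <- stratified_kfold(labels, k = k, seed = seed)
  list(train = folds[folds$fold != 1L, c("protein", "essential")],
       test = folds[folds$fold == 1L, c("protein", "essential")])
}

#' ROC curve and AUC of a ranked prediction
#'
#' Sweeps every distinct score value as a cutoff (equal scores form a single
#' step, giving the 0.5 tie credit of the rank-sum formulation) and
#' integrates the curve by the trapezoidal rule. The curve starts at (0, 0)
#' and ends at (1, 1) and is monotone in both coordinates.
#'
#' @param scores Tibble with `protein` and `score` (or a named numeric
#'   vector).
#' @param labels Tibble with `protein` and logical `essential`; both classes
#'   must be present.
#' @return A `gep_roc` list: `auc` (scalar) and `roc` (tibble of `cutoff`,
#'   `fpr`, `tpr`). Supports `autoplot()`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.numeric(scores)) {
    scores <- tibble::tibble(protein = names(scores), score = unname(scores))
  }
  m <- dplyr::inner_join(scores, labels, by = "protein")
  pos_total <- sum(m$essential)
  neg_total <- sum(!m$essential)
  if (pos_total == 0 || neg_total == 0)
    stop("ROC needs both classes present", call. = FALSE)
  grp <- m |>
    dplyr::group_by(.data$score) |>
    dplyr::summarise(pos = sum(.data$essential), neg = sum(!.data$essential),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$score))
  roc <- tibble::tibble(
    cutoff = c(Inf, grp$score),
    tpr = c(0, cumsum(grp$pos) / pos_total),
    fpr = c(0, cumsum(grp$neg) / neg_total)
  )
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  structure(list(auc = auc, roc = roc), class = "gep_roc")
}

#' @export
print.gep_roc <- function(x, ...) {
  cat("<gep_roc> AUC =", format(x$auc, digits = 4), "over",
      nrow(x$roc) - 1, "cutoffs\n")
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param object A `gep_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the chance diagonal.
#' @method autoplot gep_roc
#' @export
autoplot.gep_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("AUC = %.4f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Confusion-metric suite at a top-k cutoff
#'
#' Labels the top `k` scored proteins as predicted essential (ties broken by
#' protein ID) and reports the full metric row: SN, SP, FPR, PPV, NPV,
#' F-measure, ACC and MCC. When `k` equals the number of actual positives the
#' counting identities SN = PPV, SP = NPV and FPR = 1 - SP hold.
#'
#' @param scores Tibble with `protein` and `score` (or named numeric vector).
#' @param labels Tibble with `protein` and logical `essential`.
#' @param k Number of top-ranked proteins predicted positive.
#' @return One-row tibble with the counts and metrics.
#' @export
topk_metrics <- function(scores, labels, k) {
  if (is.numeric(scores)) {
    scores <- tibble::tibble(protein = names(scores), score = unname(scores))
  }
  m <- dplyr::inner_join(scores, labels, by = "protein")
  stopifnot(k > 0, k < nrow(m))
  s <- setNames(m$score, m$protein)
  pred <- classify_by_rank(s, k)
  cc <- confusion_counts(pred, setNames(m$essential, m$protein))
  n <- nrow(m)
  frac <- function(num, den) if (den > 0) num / den else 0
  sn <- frac(cc$tp, cc$tp + cc$fn)
  sp <- frac(cc$tn, cc$tn + cc$fp)
  ppv <- frac(cc$tp, cc$tp + cc$fp)
  npv <- frac(cc$tn, cc$tn + cc$fn)
  f <- if (ppv + sn > 0) 2 * ppv * sn / (ppv + sn) else 0
  mcc_den <- sqrt(prod(c(cc$tp + cc$fp, cc$tp + cc$fn,
                         cc$tn + cc$fp, cc$tn + cc$fn)))
  mcc <- if (mcc_den > 0) (cc$tp * cc$tn - cc$fp * cc$fn) / mcc_den else 0
  dplyr::bind_cols(cc, tibble::tibble(
    k = as.integer(k), SN = sn, SP = sp, FPR = frac(cc$fp, cc$fp + cc$tn),
    PPV = ppv, NPV = npv, F_measure = f, ACC = (cc$tp + cc$tn) / n, MCC = mcc
  ))
}

#' Stratified k-fold cross-validation of the GEP classifier
#'
#' For each fold, evolves a classifier on the other k - 1 folds and evaluates
#' it on the held-out fold (AUC plus the top-k metric row at k = number of
#' held-out positives). Fold f is evolved with seed `config$rng_seed + f` so
#' folds differ but the whole procedure is reproducible.
#'
#' @param features Feature tibble (`protein` + feature columns).
#' @param labels Tibble with `protein` and `essential`.
#' @param config A [gep_config()].
#' @param k Number of folds. Default 10.
#' @return A `gep_cv` list: `summary` (tibble of fold, train/test sizes,
#'   best training fitness, held-out AUC), `fits` (list of `gep_fit`),
#'   `mean_auc`, and `selected_fold` (the fold whose held-out AUC is closest
#'   to the mean, ties to the lower fold index -- the model-selection rule
#'   used before scoring the full protein set).
#' @export
cross_validate <- function(features, labels, config = gep_config(), k = 10) {
  folds <- stratified_kfold(labels, k = k, seed = config$rng_seed)
  fits <- vector("list", k)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    train_ids <- folds$protein[folds$fold != f]
    test_ids <- folds$protein[folds$fold == f]
    cfg <- config
    cfg$rng_seed <- config$rng_seed + f
    fit <- gep_evolve(features[features$protein %in% train_ids, ],
                      labels[labels$protein %in% train_ids, ], cfg)
    fits[[f]] <- fit
    test_feat <- features[features$protein %in% test_ids, ]
    test_lab <- labels[labels$protein %in% test_ids, ]
    preds <- predict(fit, test_feat)
    roc <- roc_auc(preds, test_lab)
    rows[[f]] <- tibble::tibble(
      fold = f, n_train = length(train_ids), n_test = length(test_ids),
      train_fitness = fit$best_fitness, auc = roc$auc
    )
  }
  summary <- dplyr::bind_rows(rows)
  mean_auc <- mean(summary$auc)
  sel <- order(abs(summary$auc - mean_auc), summary$fold)[1]
  structure(list(summary = summary, fits = fits, mean_auc = mean_auc,
                 selected_fold = summary$fold[sel]),
            class = "gep_cv")
}

#' @export
print.gep_cv <- function(x, ...) {
  cat("<gep_cv>", nrow(x$summary), "folds, mean held-out AUC =",
      format(x$mean_auc, digits = 4), "\n")
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `gep_cv`.
#' @param ... Unused.
#' @method tidy gep_cv
#' @export
tidy.gep_cv <- function(x, ...) x$summary

#' @rdname cross_validate
#' @method glance gep_cv
#' @export
glance.gep_cv <- function(x, ...) {
  tibble::tibble(folds = nrow(x$summary), mean_auc = x$mean_auc,
                 min_auc = min(x$summary$auc), max_auc = max(x$summary$auc),
                 selected_fold = x$selected_fold)
}
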
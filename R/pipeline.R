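#' Run the full study pipeline from input files
#'
#' Ties the stages together the way the full-scale study runs: read the five
#' inputs, assemble the normalized feature table, cross-validate the GEP
#' classifier with stratified k-fold, select the fold classifier whose
#' held-out AUC is closest to the mean, score the full protein set with it,
#' and report the ROC/AUC plus the confusion-metric row at
#' k = number of essential proteins.
#'
#' @param network_file Two-column edge-list TSV.
#' @param essential_file Essential-protein list (one ID per line).
#' @param expression_file,localization_file,orthology_file Feature input TSVs
#'   (any may be `NULL`; the corresponding feature contribution is 0).
#' @param config A [gep_config()].
#' @param k Cross-validation folds. Default 5.
#' @param lambda,alpha Feature parameters (see [assemble_feature_table()]).
#' @param out_dir If non-`NULL`, writes `feature_table.tsv`,
#'   `predictions.tsv`, `history.tsv` (selected fold), `roc_points.tsv` and
#'   `classifier.txt` there.
#' @param quiet Suppress progress messages.
#' @return List: `features`, `labels`, `cv` (a `gep_cv`), `fit` (selected
#'   `gep_fit`), `predictions`, `roc` (full-set `gep_roc`), `metrics`
#'   (top-k row at k = number of essentials).
#' @export
run_gep_pipeline <- function(network_file, essential_file,
                             expression_file = NULL,
                             localization_file = NULL,
                             orthology_file = NULL,
                             config = gep_config(), k = 5,
                             lambda = 0.5, alpha = 0.85,
                             out_dir = NULL, quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  network <- read_ppi_network(network_file, quiet = quiet)
  labels <- read_essential_proteins(essential_file, network, quiet = quiet)
  expression <- if (!is.null(expression_file))
    read_expression_matrix(expression_file)
  localization <- if (!is.null(localization_file))
    read_localization_matrix(localization_file)
  orthology <- if (!is.null(orthology_file))
    read_orthology_scores(orthology_file)
  say("assembling feature table for ", igraph::vcount(network), " proteins")
  features <- assemble_feature_table(network, expression = expression,
                                     localization = localization,
                                     orthology = orthology,
                                     lambda = lambda, alpha = alpha)
  labels <- labels[, c("protein", "essential")]
  say("cross-validating (", k, " folds, population ",
      config$population_size, ", ", config$generation_count, " generations)")
  cv <- cross_validate(features, labels, config, k = k)
  fit <- cv$fits[[cv$selected_fold]]
  say("selected fold ", cv$selected_fold, " (held-out AUC closest to mean ",
      format(cv$mean_auc, digits = 4), ")")
  predictions <- predict(fit, features)
  roc <- roc_auc(predictions, labels)
  metrics <- topk_metrics(predictions, labels, k = sum(labels$essential))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(features, file.path(out_dir, "feature_table.tsv"))
    write_predictions(predictions, file.path(out_dir, "predictions.tsv"))
    readr::write_tsv(fit$history, file.path(out_dir, "history.tsv"),
                     progress = FALSE)
    readr::write_tsv(roc$roc, file.path(out_dir, "roc_points.tsv"),
                     progress = FALSE)
    writeLines(fit$expression, file.path(out_dir, "classifier.txt"))
  }
  list(features = features, labels = labels, cv = cv, fit = fit,
       predictions = predictions, roc = roc, metrics = metrics)
}
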
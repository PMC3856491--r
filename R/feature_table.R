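#' Assemble the normalized per-protein feature table
#'
#' Computes the seven centralities (DC, BC, CC, SC, EC, IC, NC), the three
#' composite scores (PeC, WDC, ION) and the localization indicator columns for
#' every protein in the network, then max-normalizes: each numeric feature is
#' divided by its maximum absolute value so every value lies in \[-1, 1\] and
#' at least one protein attains magnitude 1 per non-constant feature.
#' Localization indicators are already 0/1 and pass through unchanged.
#' Missing biological data (no expression row, no orthology score, no
#' localization row) contributes 0 before normalization.
#'
#' @param network An igraph graph with named vertices.
#' @param expression Expression tibble (`protein` + sample columns), or `NULL`
#'   to set PeC/WDC's co-expression part to 0.
#' @param localization Localization tibble (`protein` + compartment 0/1
#'   columns), or `NULL` for all-zero indicators.
#' @param orthology Orthology tibble (`protein`, `orthology`), or `NULL` for
#'   all-zero conservation.
#' @param lambda WDC topology weight; see [wdc_score()].
#' @param alpha,tol,max_iter ION propagation parameters; see [ion_score()].
#' @param compartments Compartment column set for the localization block.
#' @return A tibble with `protein` plus one column per feature: `DC`, `BC`,
#'   `CC`, `SC`, `EC`, `IC`, `NC`, `PeC`, `WDC`, `ION` and the compartments.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::V(g)$name <- c("A", "B", "C")
#' assemble_feature_table(g)
#' @export
assemble_feature_table <- function(network, expression = NULL,
                                   localization = NULL, orthology = NULL,
                                   lambda = 0.5, alpha = 0.85, tol = 1e-6,
                                   max_iter = 100,
                                   compartments = yeast_compartments) {
  nodes <- igraph::V(network)$name
  if (is.null(expression)) {
    expression <- tibble::tibble(protein = character(0), s1 = numeric(0),
                                 s2 = numeric(0))
  }
  if (is.null(orthology)) {
    orthology <- tibble::tibble(protein = character(0), orthology = numeric(0))
  }
  tbl <- tibble::tibble(
    protein = nodes,
    DC  = unname(degree_centrality(network)),
    BC  = unname(betweenness_centrality(network)),
    CC  = unname(closeness_centrality(network)),
    SC  = unname(subgraph_centrality(network)),
    EC  = unname(eigenvector_centrality(network)),
    IC  = unname(information_centrality(network)),
    NC  = unname(nc_centrality(network)),
    PeC = unname(pec_score(network, expression)),
    WDC = unname(wdc_score(network, expression, lambda = lambda)),
    ION = unname(ion_score(network, orthology, alpha = alpha, tol = tol,
                           max_iter = max_iter))
  )
  loc <- matrix(0L, nrow = length(nodes), ncol = length(compartments),
                dimnames = list(NULL, compartments))
  if (!is.null(localization)) {
    idx <- match(nodes, localization$protein)
    for (cmp in intersect(compartments, names(localization))) {
      v <- localization[[cmp]][idx]
      loc[, cmp] <- ifelse(is.na(v), 0L, as.integer(v))
    }
  }
  tbl <- dplyr::bind_cols(tbl, tibble::as_tibble(loc))
  normalize_features(tbl, skip = compartments)
}

#' Max-normalize feature columns into \[-1, 1\]
#'
#' Divides every numeric feature column by its maximum absolute value;
#' constant-zero columns are left as 0 with a warning. Columns named in
#' `skip` (e.g. 0/1 indicators) pass through unchanged.
#'
#' @param features Feature tibble with a `protein` column.
#' @param skip Column names exempt from normalization.
#' @return The normalized tibble.
#' @export
normalize_features <- function(features, skip = yeast_compartments) {
  for (nm in setdiff(names(features), c("protein", skip))) {
    mx <- max(abs(features[[nm]]))
    if (mx == 0) {
      warning("feature '", nm, "' is identically zero", call. = FALSE)
    } else {
      features[[nm]] <- features[[nm]] / mx
    }
  }
  features
}
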
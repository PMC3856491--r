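# Co-expression weights and the three composite essentiality scores.

# Row-standardize an expression tibble into a matrix keyed by protein, so a
# pairwise Pearson correlation is an inner product / (m - 1). Zero-variance
# profiles get an all-zero row (correlation 0 by convention).
expression_zmatrix <- function(expression) {
  m <- as.matrix(expression[, -1, drop = FALSE])
  rownames(m) <- expression$protein
  mu <- rowMeans(m)
  cen <- m - mu
  sdv <- sqrt(rowSums(cen^2) / (ncol(m) - 1))
  z <- cen / ifelse(sdv > 0, sdv, Inf) # zero-variance rows -> 0
  z / sqrt(ncol(m) - 1)
}

#' Pearson co-expression of two proteins
#'
#' Pearson correlation of the two proteins' expression profiles across
#' samples. If either protein has no expression row, or a zero-variance
#' profile, the correlation is 0 (a neutral contribution).
#'
#' @param expression Expression tibble (`protein` + sample columns).
#' @param u,v Protein IDs.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_coexpression <- function(expression, u, v) {
  if (!(u %in% expression$protein) || !(v %in% expression$protein)) return(0)
  xu <- as.numeric(expression[expression$protein == u, -1][1, ])
  xv <- as.numeric(expression[expression$protein == v, -1][1, ])
  if (stats::sd(xu) == 0 || stats::sd(xv) == 0) return(0)
  cor(xu, xv)
}

# Per-edge ECC and PCC in one pass; the workhorse behind PeC / WDC / NC.
edge_weights <- function(network, expression) {
  ew <- ecc_all_edges(network)
  z <- expression_zmatrix(expression)
  iu <- match(ew$from, rownames(z))
  iv <- match(ew$to, rownames(z))
  pcc <- numeric(nrow(ew))
  ok <- !is.na(iu) & !is.na(iv)
  if (any(ok)) pcc[ok] <- rowSums(z[iu[ok], , drop = FALSE] * z[iv[ok], , drop = FALSE])
  ew$pcc <- pmin(pmax(pcc, -1), 1)
  ew
}

# Sum per-edge values into per-node totals over both endpoints.
sum_incident <- function(network, ew, values) {
  nodes <- igraph::V(network)$name
  out <- setNames(numeric(length(nodes)), nodes)
  if (nrow(ew) == 0) return(out)
  acc <- rowsum(c(values, values), c(ew$from, ew$to))
  out[rownames(acc)] <- acc[, 1]
  out
}

#' PeC: co-expression-weighted edge clustering
#'
#' For each protein, the sum over its edges of `ECC * max(PCC, 0)`: edges that
#' are both inside a dense neighbourhood and co-expressed count most. Negative
#' correlations contribute 0 by default.
#'
#' @param network An igraph graph with named vertices.
#' @param expression Expression tibble (`protein` + sample columns).
#' @param floor_pcc Floor negative correlations at 0 (default `TRUE`).
#' @return Named numeric vector, one value per protein.
#' @export
pec_score <- function(network, expression, floor_pcc = TRUE) {
  ew <- edge_weights(network, expression)
  pcc <- if (floor_pcc) pmax(ew$pcc, 0) else ew$pcc
  sum_incident(network, ew, ew$ecc * pcc)
}

#' WDC: weighted-degree centrality blending topology and co-expression
#'
#' For each protein, the sum over its edges of
#' `lambda * ECC + (1 - lambda) * PCC`. At `lambda = 1` this is NC; at
#' `lambda = 0` with all correlations 1 it is the degree.
#'
#' @inheritParams pec_score
#' @param lambda Topology weight in \[0, 1\]. Default 0.5.
#' @param floor_pcc Floor negative correlations at 0 (default `FALSE`: the
#'   signed correlation is kept).
#' @return Named numeric vector.
#' @export
wdc_score <- function(network, expression, lambda = 0.5, floor_pcc = FALSE) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  ew <- edge_weights(network, expression)
  pcc <- if (floor_pcc) pmax(ew$pcc, 0) else ew$pcc
  sum_incident(network, ew, lambda * ew$ecc + (1 - lambda) * pcc)
}

#' ION: orthology-seeded score propagation over the PPI network
#'
#' Iterates `S(i) = (1 - alpha) * O(i) + alpha * sum_j W(j, i) S(j)` to a
#' fixed point, where `O` is the orthology conservation score max-normalized
#' to \[0, 1\] and `W(j, i)` distributes protein j's score over its neighbours
#' proportionally to edge clustering coefficients (uniformly, `1/d_j`, when
#' all of j's incident ECCs are 0). Conserved proteins in clustered
#' neighbourhoods reinforce each other.
#'
#' @param network An igraph graph with named vertices.
#' @param orthology Tibble with columns `protein`, `orthology` (score >= 0);
#'   proteins absent from the table get score 0.
#' @param alpha Propagation weight in \[0, 1). Default 0.85.
#' @param tol L1 convergence tolerance. Default 1e-6.
#' @param max_iter Iteration cap. Default 100; on hitting it, the last iterate
#'   is returned with a warning.
#' @return Named numeric vector, one value per protein.
#' @export
ion_score <- function(network, orthology, alpha = 0.85, tol = 1e-6,
                      max_iter = 100) {
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)", call. = FALSE)
  nodes <- igraph::V(network)$name
  o <- setNames(numeric(length(nodes)), nodes)
  hit <- intersect(orthology$protein, nodes)
  o[hit] <- orthology$orthology[match(hit, orthology$protein)]
  if (max(o) > 0) o <- o / max(o)
  ew <- ecc_all_edges(network)
  deg <- degree_centrality(network)
  # out-weight of j toward i: ecc(j,i) / sum_k ecc(j,k), or 1/deg(j) uniform
  ecc_sum <- sum_incident(network, ew, ew$ecc)
  # sparse weight triplets: each edge contributes j->i and i->j
  src <- c(ew$from, ew$to)
  dst <- c(ew$to, ew$from)
  ecc2 <- c(ew$ecc, ew$ecc)
  w <- ifelse(ecc_sum[src] > 0, ecc2 / ecc_sum[src], 1 / deg[src])
  si <- match(src, nodes); di <- match(dst, nodes)
  s <- o
  for (it in seq_len(max_iter)) {
    inflow <- numeric(length(nodes))
    if (length(w) > 0) {
      acc <- rowsum(w * s[si], di)
      inflow[as.integer(rownames(acc))] <- acc[, 1]
    }
    s_new <- (1 - alpha) * o + alpha * inflow
    if (sum(abs(s_new - s)) < tol) return(setNames(s_new, nodes))
    s <- s_new
  }
  warning("ion_score did not converge within ", max_iter,
          " iterations; returning last iterate", call. = FALSE)
  setNames(s, nodes)
}
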
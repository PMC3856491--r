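# Node centralities. DC/BC/CC/SC delegate to igraph, whose conventions match
# the definitions used here (unnormalized betweenness over unordered pairs;
# component-restricted closeness (n_comp - 1) / sum of distances; subgraph
# centrality as the diagonal of the adjacency matrix exponential). EC and IC
# are computed directly: EC as the unit-Euclidean-norm principal eigenvector
# of the largest component, IC from the inverse of (Laplacian + all-ones).

as_named <- function(x, nodes) setNames(as.numeric(x), nodes)

#' Degree centrality (DC)
#'
#' Number of interaction partners of each protein.
#'
#' @param network An igraph graph with named vertices.
#' @return Named numeric vector, one value per protein.
#' @export
degree_centrality <- function(network) {
  as_named(igraph::degree(network), igraph::V(network)$name)
}

#' Betweenness centrality (BC)
#'
#' Sum over unordered protein pairs (s, t) of the fraction of shortest s-t
#' paths passing through the protein; disconnected pairs contribute 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(network) {
  as_named(igraph::betweenness(network, directed = FALSE, normalized = FALSE),
           igraph::V(network)$name)
}

#' Closeness centrality (CC)
#'
#' Component-restricted closeness: (n_comp - 1) divided by the sum of
#' shortest-path distances to the other proteins in the same connected
#' component. Isolated proteins score 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(network) {
  nodes <- igraph::V(network)$name
  if (length(nodes) == 0) return(setNames(numeric(0), character(0)))
  cc <- suppressWarnings(igraph::closeness(network, normalized = TRUE))
  cc[!is.finite(cc)] <- 0 # isolated vertices
  as_named(cc, nodes)
}

#' Subgraph centrality (SC)
#'
#' Diagonal of the matrix exponential of the adjacency matrix: a
#' factorial-weighted count of closed walks through each protein.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
subgraph_centrality <- function(network) {
  as_named(igraph::subgraph_centrality(network, diag = FALSE),
           igraph::V(network)$name)
}

#' Eigenvector centrality (EC)
#'
#' Nonnegative principal eigenvector of the adjacency matrix of the largest
#' connected component, scaled to unit Euclidean norm; proteins outside that
#' component score 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
eigenvector_centrality <- function(network) {
  nodes <- igraph::V(network)$name
  n <- length(nodes)
  if (n == 0) stop("eigenvector centrality of an empty network", call. = FALSE)
  comp <- igraph::components(network)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  out <- setNames(numeric(n), nodes)
  if (length(members) == 1) {
    out[members] <- 1
    return(out)
  }
  sub <- igraph::induced_subgraph(network, members)
  A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
  ev <- eigen(A, symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (sum(v) < 0) v <- -v # Perron vector is sign-fixable to nonnegative
  v <- pmax(v, 0)
  v <- v / sqrt(sum(v^2))
  out[members] <- v[match(igraph::V(network)$name[members], igraph::V(sub)$name)]
  out
}

#' Information centrality (IC)
#'
#' Within each connected component of size n >= 2, let C = (L + J)^-1 with L
#' the component Laplacian and J the all-ones matrix. The pairwise information
#' I_ij = 1 / (c_ii + c_jj - 2 c_ij), and IC(i) is the harmonic-style average
#' n / sum_j (1 / I_ij) with the self term taken as 0. Isolated proteins
#' score 0.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
information_centrality <- function(network) {
  nodes <- igraph::V(network)$name
  out <- setNames(numeric(length(nodes)), nodes)
  comp <- igraph::components(network)
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    n <- length(members)
    if (n < 2) next
    sub <- igraph::induced_subgraph(network, members)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
    L <- diag(rowSums(A)) - A
    C <- solve(L + matrix(1, n, n))
    d <- diag(C)
    M <- outer(d, rep(1, n)) + outer(rep(1, n), d) - 2 * C
    diag(M) <- 0 # 1 / I_ii := 0
    ic <- n / rowSums(M)
    out[members] <- ic[match(igraph::V(network)$name[members],
                             igraph::V(sub)$name)]
  }
  out
}

#' Edge clustering coefficient (ECC)
#'
#' For an edge (u, v): the number of triangles it participates in divided by
#' the maximum possible, `min(d_u - 1, d_v - 1)`. A pendant edge (either
#' endpoint of degree 1) scores 0.
#'
#' @inheritParams degree_centrality
#' @param u,v Protein IDs of an existing edge.
#' @return A single ECC value in \[0, 1\].
#' @export
edge_clustering_coefficient <- function(network, u, v) {
  eid <- igraph::get_edge_ids(network, c(u, v), error = FALSE)
  if (eid == 0) stop("edge ", u, "--", v, " is not in the network", call. = FALSE)
  ecc_all_edges(network)$ecc[eid]
}

#' ECC for every edge of a network
#'
#' Vectorized edge clustering coefficients, in igraph edge order.
#'
#' @inheritParams degree_centrality
#' @return A tibble with columns `from`, `to`, `ecc`.
#' @export
ecc_all_edges <- function(network) {
  el <- igraph::as_edgelist(network, names = FALSE)
  nodes <- igraph::V(network)$name
  if (nrow(el) == 0) {
    return(tibble::tibble(from = character(0), to = character(0), ecc = numeric(0)))
  }
  A <- igraph::as_adjacency_matrix(network, sparse = TRUE)
  deg <- igraph::degree(network)
  # common-neighbour count of the endpoints = (A %*% A)[u, v]
  A2 <- A %*% A
  z <- A2[cbind(el[, 1], el[, 2])]
  denom <- unname(pmin(deg[el[, 1]], deg[el[, 2]])) - 1
  ecc <- ifelse(denom > 0, as.numeric(z) / denom, 0)
  tibble::tibble(from = nodes[el[, 1]], to = nodes[el[, 2]], ecc = ecc)
}

#' Edge-clustering-coefficient centrality (NC)
#'
#' Sum of the ECC values of a protein's incident edges: proteins inside
#' densely clustered (complex-like) neighbourhoods score high.
#'
#' @inheritParams degree_centrality
#' @return Named numeric vector.
#' @export
nc_centrality <- function(network) {
  nodes <- igraph::V(network)$name
  out <- setNames(numeric(length(nodes)), nodes)
  ew <- ecc_all_edges(network)
  if (nrow(ew) == 0) return(out)
  half <- rowsum(c(ew$ecc, ew$ecc), c(ew$from, ew$to))
  out[rownames(half)] <- half[, 1]
  out
}
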
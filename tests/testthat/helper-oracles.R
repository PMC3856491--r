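# Brute-force oracles, independent of the package implementations: breadth-
# first searches over adjacency lists for distances and shortest-path counts,
# dense eigendecompositions, explicit matrix formulas, and literal triangle
# counting. All take a plain 0/1 adjacency matrix.

random_adjacency <- function(n, p = 0.25) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- rbinom(n * (n - 1) / 2, 1L, p)
  a <- a + t(a)
  dimnames(a) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  a
}

graph_from_adjacency <- function(a) {
  igraph::graph_from_adjacency_matrix(a, mode = "undirected")
}

# distances and shortest-path counts from source s by BFS levels
bfs_paths <- function(a, s) {
  n <- nrow(a)
  d <- rep(Inf, n); sig <- numeric(n)
  d[s] <- 0; sig[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(a[u, ] == 1)) {
        if (is.infinite(d[v])) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
        if (d[v] == d[u] + 1) sig[v] <- sig[v] + sig[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(d = d, sigma = sig)
}

oracle_dc <- function(a) rowSums(a)

oracle_bc <- function(a) {
  n <- nrow(a)
  paths <- lapply(1:n, function(s) bfs_paths(a, s))
  bc <- numeric(n)
  for (v in 1:n) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v) next
      st <- paths[[s]]
      if (is.infinite(st$d[t]) || st$sigma[t] == 0) next
      through <- if (st$d[v] + paths[[v]]$d[t] == st$d[t])
        st$sigma[v] * paths[[v]]$sigma[t] else 0
      bc[v] <- bc[v] + through / st$sigma[t]
    }
  }
  setNames(bc, rownames(a))
}

oracle_cc <- function(a) {
  n <- nrow(a)
  cc <- numeric(n)
  for (v in 1:n) {
    d <- bfs_paths(a, v)$d
    comp <- which(is.finite(d))
    cc[v] <- if (length(comp) > 1) (length(comp) - 1) / sum(d[comp]) else 0
  }
  setNames(cc, rownames(a))
}

oracle_sc <- function(a) {
  e <- eigen(a, symmetric = TRUE)
  setNames(rowSums(e$vectors^2 %*% diag(exp(e$values), nrow(a))), rownames(a))
}

# power iteration on the largest component, unit Euclidean norm
oracle_ec <- function(a, iters = 5000) {
  n <- nrow(a)
  d0 <- bfs_paths(a, 1)$d
  comps <- list()
  seen <- rep(FALSE, n)
  for (v in 1:n) {
    if (seen[v]) next
    members <- which(is.finite(bfs_paths(a, v)$d))
    seen[members] <- TRUE
    comps[[length(comps) + 1]] <- members
  }
  big <- comps[[which.max(lengths(comps))]]
  out <- setNames(numeric(n), rownames(a))
  if (length(big) == 1) { out[big] <- 1; return(out) }
  # shift by +I so the dominant eigenvalue is strictly dominant even on
  # bipartite components (spectrum symmetric about 0); eigenvectors unchanged
  sub <- a[big, big] + diag(length(big))
  x <- rep(1, length(big))
  for (i in 1:iters) {
    x2 <- as.numeric(sub %*% x)
    nrm <- sqrt(sum(x2^2))
    if (nrm == 0) break
    x2 <- x2 / nrm
    if (max(abs(x2 - x)) < 1e-13) { x <- x2; break }
    x <- x2
  }
  out[big] <- x
  out
}

oracle_ic <- function(a) {
  n <- nrow(a)
  out <- setNames(numeric(n), rownames(a))
  seen <- rep(FALSE, n)
  for (v in 1:n) {
    if (seen[v]) next
    members <- which(is.finite(bfs_paths(a, v)$d))
    seen[members] <- TRUE
    m <- length(members)
    if (m < 2) next
    sub <- a[members, members, drop = FALSE]
    L <- diag(rowSums(sub)) - sub
    C <- solve(L + matrix(1, m, m))
    for (ii in 1:m) {
      acc <- 0
      for (jj in 1:m) {
        if (ii == jj) next
        acc <- acc + (C[ii, ii] + C[jj, jj] - 2 * C[ii, jj])
      }
      out[members[ii]] <- m / acc
    }
  }
  out
}

oracle_ecc <- function(a, u, v) {
  z <- length(intersect(which(a[u, ] == 1), which(a[v, ] == 1)))
  denom <- min(sum(a[u, ]), sum(a[v, ])) - 1
  if (denom <= 0) 0 else z / denom
}

oracle_nc <- function(a) {
  n <- nrow(a)
  out <- setNames(numeric(n), rownames(a))
  for (u in 1:n) {
    for (v in which(a[u, ] == 1)) out[u] <- out[u] + oracle_ecc(a, u, v)
  }
  out
}

# AUC as the rank-sum (Mann-Whitney) probability with 0.5 tie credit
oracle_auc_ranksum <- function(score, positive) {
  r <- rank(score)
  p <- sum(positive); n <- sum(!positive)
  (sum(r[positive]) - p * (p + 1) / 2) / (p * n)
}

named_graph <- function(edges_text) {
  # edges_text like c("A B", "B C")
  parts <- do.call(rbind, strsplit(edges_text, " "))
  igraph::graph_from_data_frame(data.frame(from = parts[, 1], to = parts[, 2]),
                                directed = FALSE)
}
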
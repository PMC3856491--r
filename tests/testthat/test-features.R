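expr_tbl <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(r) r[-1]))
  colnames(m) <- paste0("s", seq_len(ncol(m)))
  out <- tibble::as_tibble(m)
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.numeric))
  dplyr::bind_cols(
    tibble::tibble(protein = vapply(rows, `[[`, character(1), 1)), out)
}

test_that("pairwise co-expression follows the Pearson formula with conventions", {
  e <- expr_tbl(c("A", 1, 2, 3, 4), c("B", 2, 4, 6, 9), c("C", 5, 5, 5, 5))
  expect_equal(pearson_coexpression(e, "A", "A"), 1)
  neg <- expr_tbl(c("A", 1, 2, 3), c("B", -1, -2, -3))
  expect_equal(pearson_coexpression(neg, "A", "B"), -1)
  # textbook formula oracle
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_coexpression(e, "A", "B"), oracle)
  expect_equal(pearson_coexpression(e, "A", "C"), 0) # zero variance
  expect_equal(pearson_coexpression(e, "A", "missing"), 0)
})

test_that("PeC combines ECC with floored co-expression", {
  k3 <- named_graph(c("A B", "B C", "A C"))
  same <- expr_tbl(c("A", 1, 2, 3), c("B", 1, 2, 3), c("C", 1, 2, 3))
  expect_equal(pec_score(k3, same), c(A = 2, B = 2, C = 2))
  # anti-correlated profiles are floored at 0
  anti <- expr_tbl(c("A", 1, 2, 3), c("B", 3, 2, 1), c("C", 3, 2, 1))
  expect_equal(pec_score(k3, anti)[["A"]], 0)
  # star: every edge has ECC 0, so PeC vanishes regardless of expression
  star <- named_graph(c("H L1", "H L2", "H L3"))
  expect_equal(unname(pec_score(star, same)), rep(0, 4))
  # no expression data at all -> 0 by the PCC = 0 rule
  expect_equal(unname(pec_score(k3, expr_tbl(c("Z", 1, 2, 3)))),
               rep(0, 3))
})

test_that("WDC reduces to NC and DC at the lambda limits", {
  set.seed(23)
  a <- random_adjacency(15, 0.3)
  g <- graph_from_adjacency(a)
  nodes <- rownames(a)
  same <- do.call(expr_tbl, lapply(nodes, function(p) c(p, 1, 2, 3, 7)))
  expect_equal(wdc_score(g, same, lambda = 1), nc_centrality(g))
  expect_equal(wdc_score(g, same, lambda = 0), degree_centrality(g))
  k3 <- named_graph(c("A B", "B C", "A C"))
  same3 <- expr_tbl(c("A", 1, 2, 3), c("B", 1, 2, 3), c("C", 1, 2, 3))
  expect_equal(wdc_score(k3, same3, lambda = 0.5), c(A = 2, B = 2, C = 2))
  expect_error(wdc_score(k3, same3, lambda = 1.2), "lambda")
})

test_that("ION propagation hits its fixed point and limits", {
  p3 <- named_graph(c("A B", "B C"))
  orth <- tibble::tibble(protein = c("A", "B", "C"), orthology = c(1, 0, 0))
  # alpha = 0: the normalized orthology itself
  expect_equal(ion_score(p3, orth, alpha = 0), c(A = 1, B = 0, C = 0))
  # vertex-transitive graph with equal scores -> all equal
  k3 <- named_graph(c("A B", "B C", "A C"))
  eq <- tibble::tibble(protein = c("A", "B", "C"), orthology = c(2, 2, 2))
  s <- ion_score(k3, eq)
  expect_equal(diff(range(s)), 0, tolerance = 1e-12)

  # long-run iteration oracle on the path
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- 1; w["C", "B"] <- 1 # all ECC are 0 -> uniform 1/deg
  w["B", "A"] <- 0.5; w["B", "C"] <- 0.5
  o <- c(A = 1, B = 0, C = 0)
  s_oracle <- o
  for (i in 1:1000) s_oracle <- (1 - 0.5) * o + 0.5 * as.numeric(t(w) %*% s_oracle)
  got <- ion_score(p3, orth, alpha = 0.5, tol = 1e-12, max_iter = 5000)
  expect_equal(got, setNames(s_oracle, c("A", "B", "C")), tolerance = 1e-9)
})

test_that("ION is equivariant under protein relabeling", {
  set.seed(41)
  a <- random_adjacency(12, 0.3)
  g <- graph_from_adjacency(a)
  orth <- tibble::tibble(protein = rownames(a),
                         orthology = runif(12, 0, 10))
  s1 <- ion_score(g, orth)
  perm <- sample(rownames(a))
  map <- setNames(sprintf("Q%02d", seq_along(perm)), perm)
  g2 <- g
  igraph::V(g2)$name <- unname(map[igraph::V(g)$name])
  orth2 <- tibble::tibble(protein = unname(map[orth$protein]),
                          orthology = orth$orthology)
  s2 <- ion_score(g2, orth2)
  expect_equal(unname(s2[map[names(s1)]]), unname(s1), tolerance = 1e-12)
})

test_that("feature assembly max-normalizes into [-1, 1]", {
  raw <- tibble::tibble(protein = c("A", "B", "C"), DC = c(2, 4, 8))
  norm <- normalize_features(raw)
  expect_equal(norm$DC, c(0.25, 0.5, 1.0))
  expect_warning(normalize_features(
    tibble::tibble(protein = "A", dead = 0)), "identically zero")

  set.seed(13)
  a <- random_adjacency(30, 0.2)
  g <- graph_from_adjacency(a)
  nodes <- rownames(a)
  e <- do.call(expr_tbl,
               lapply(nodes[1:25], function(p) c(p, round(runif(6), 2))))
  loc <- tibble::tibble(protein = nodes)
  for (cmp in yeast_compartments) loc[[cmp]] <- rbinom(30, 1, 0.3)
  orth <- tibble::tibble(protein = nodes, orthology = rpois(30, 5))
  ft <- suppressWarnings(
    assemble_feature_table(g, e, loc, orth))
  num <- ft[setdiff(names(ft), "protein")]
  expect_true(all(vapply(num, function(x) all(x >= -1 & x <= 1), logical(1))))
  for (nm in setdiff(names(num), yeast_compartments)) {
    if (diff(range(num[[nm]])) > 0) {
      expect_equal(max(abs(num[[nm]])), 1, tolerance = 1e-12)
    }
  }
  expect_false(anyNA(num))
})
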
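terms2 <- c("a", "b", gep_coefficients)

chromosome_ok <- function(chr, config) {
  syms <- unclass(chr)
  hp <- gepess:::head_positions(chr)
  tailp <- setdiff(seq_along(syms), hp)
  length(syms) == gepess:::chromosome_length(config) &&
    all(syms[hp] %in% c(config$function_set, attr(chr, "terminals"))) &&
    all(syms[tailp] %in% attr(chr, "terminals"))
}

test_that("chromosome structure follows the Karva head/tail law", {
  cfg <- gep_config(head_length = 3)
  chr <- random_chromosome(cfg, terms2)
  expect_length(unclass(chr), 7) # t = h + 1 for max arity 2
  expect_error(random_chromosome(cfg, character(0)), "empty terminal")

  set.seed(99)
  cfg20 <- gep_config()
  ok <- vapply(1:500, function(i) chromosome_ok(random_chromosome(cfg20, terms2), cfg20),
               logical(1))
  expect_true(all(ok))

  set.seed(123); c1 <- random_chromosome(cfg20, terms2)
  set.seed(123); c2 <- random_chromosome(cfg20, terms2)
  expect_identical(c1, c2)
})

test_that("level-order decoding matches hand expansion", {
  cfg <- gep_config(head_length = 3)
  mk <- function(syms) gepess:::new_chromosome(syms, cfg, terms2)
  expect_equal(render_expression(decode(mk(c("add", "a", "b", "a", "a", "b", "b")))),
               "(a+b)")
  expect_equal(render_expression(decode(mk(c("add", "mul", "a", "b", "b", "a", "a")))),
               "((b*b)+a)")
  # all-terminal head: single-leaf tree, everything else non-coding
  expect_equal(render_expression(decode(mk(c("0.5", "add", "a", "b", "b", "a", "a")))),
               "0.5")
  # multigenic chromosomes link genes by addition
  cfg2 <- gep_config(head_length = 1, gene_count = 2)
  chr2 <- gepess:::new_chromosome(c("a", "b", "b", "mul", "a", "b"), cfg2, terms2)
  expect_equal(render_expression(decode(chr2)), "(a+(a*b))")
})

test_that("point mutation preserves domains and matches its expected intensity", {
  cfg <- gep_config()
  set.seed(3)
  chr <- random_chromosome(cfg, terms2)
  expect_identical(mutate_chromosome(chr, 0, cfg), chr)
  full <- mutate_chromosome(chr, 1, cfg)
  expect_true(chromosome_ok(full, cfg))
  hp <- gepess:::head_positions(chr)
  expect_true(all(unclass(full)[-hp] %in% terms2)) # tail still terminal-only

  # mean number of replaced positions ~ Binomial(41, 0.25)
  set.seed(11)
  base <- random_chromosome(cfg, c("a", "b")) # no constants: changes visible
  nmut <- vapply(1:2000, function(i) {
    m <- mutate_chromosome(base, 0.25, cfg)
    sum(unclass(m) != unclass(base)) # count differing sites
  }, numeric(1))
  # a resample can redraw the same symbol, so the observed rate is slightly
  # below 0.25 * 41; bound it loosely from both sides
  expect_gt(mean(nmut), 0.25 * 41 * 0.6)
  expect_lt(mean(nmut), 0.25 * 41 * 1.1)
})

test_that("transposition rearranges heads only and is seed-reproducible", {
  cfg <- gep_config()
  set.seed(8)
  chr <- random_chromosome(cfg, terms2)
  expect_identical(transpose_chromosome(chr, 0, 0, cfg), chr)
  set.seed(21); t1 <- transpose_chromosome(chr, 1, 1, cfg)
  set.seed(21); t2 <- transpose_chromosome(chr, 1, 1, cfg)
  expect_identical(t1, t2)
  hp <- gepess:::head_positions(chr)
  for (i in 1:200) {
    tr <- transpose_chromosome(chr, 0.8, 0.8, cfg)
    expect_true(chromosome_ok(tr, cfg))
    expect_identical(unclass(tr)[-hp], unclass(chr)[-hp]) # tail untouched
  }
})

test_that("one-point recombination exchanges aligned suffixes", {
  cfg <- gep_config()
  set.seed(14)
  p1 <- random_chromosome(cfg, terms2)
  p2 <- random_chromosome(cfg, terms2)
  expect_identical(recombine_chromosomes(p1, p2, 0, cfg), list(p1, p2))
  self <- recombine_chromosomes(p1, p1, 1, cfg)
  expect_identical(unclass(self[[1]]), unclass(p1))
  for (i in 1:200) {
    kids <- recombine_chromosomes(p1, p2, 1, cfg)
    expect_true(chromosome_ok(kids[[1]], cfg))
    expect_true(chromosome_ok(kids[[2]], cfg))
    # symbols are conserved position-wise across the pair (order may swap)
    pairkey <- function(u, v) paste(pmin(u, v), pmax(u, v))
    expect_identical(pairkey(unclass(kids[[1]]), unclass(kids[[2]])),
                     pairkey(unclass(p1), unclass(p2)))
  }
  short <- gepess:::new_chromosome(c("a", "b", "b"), gep_config(head_length = 1),
                                   terms2)
  expect_error(recombine_chromosomes(p1, short, 1, cfg), "equal length")
})
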
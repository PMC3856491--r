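# Karva-encoded chromosomes: fixed-length symbol strings whose head may hold
# functions or terminals and whose tail holds terminals only. With maximum
# arity 2 a tail of h + 1 symbols guarantees that level-order decoding always
# closes into a valid expression tree, whatever the head contains.

new_chromosome <- function(symbols, config, terminals) {
  structure(symbols,
            head_length = config$head_length,
            gene_count = config$gene_count,
            terminals = terminals,
            class = "gep_chromosome")
}

chromosome_string <- function(chr) paste(unclass(chr), collapse = " ")

# head positions (relative to the full chromosome) across all genes
head_positions <- function(chr) {
  h <- attr(chr, "head_length")
  g <- attr(chr, "gene_count")
  glen <- 2L * h + 1L
  as.vector(outer(seq_len(h), (seq_len(g) - 1L) * glen, `+`))
}

#' Generate a random chromosome
#'
#' Head positions are sampled uniformly from functions and terminals, tail
#' positions from terminals only, so every generated chromosome decodes.
#'
#' @param config A [gep_config()].
#' @param terminals Character vector of terminal symbols (feature names and
#'   constants).
#' @return A `gep_chromosome`.
#' @export
random_chromosome <- function(config, terminals) {
  if (length(terminals) == 0) stop("empty terminal set", call. = FALSE)
  h <- config$head_length
  head_pool <- c(config$function_set, terminals)
  genes <- replicate(config$gene_count, c(
    sample(head_pool, h, replace = TRUE),
    sample(terminals, h + 1L, replace = TRUE)
  ), simplify = FALSE)
  new_chromosome(unlist(genes), config, terminals)
}

#' @export
print.gep_chromosome <- function(x, ...) {
  cat("<gep_chromosome> head", attr(x, "head_length"), "x",
      attr(x, "gene_count"), "gene(s)\n ", chromosome_string(x), "\n")
  invisible(x)
}

# level-order (breadth-first) Karva expansion of one gene
karva_decode_gene <- function(symbols) {
  make_node <- function(sym) {
    a <- if (is_function_symbol(sym)) symbol_arity(sym) else 0L
    list(sym = sym, arity = a, children = vector("list", a))
  }
  nodes <- list(make_node(symbols[1]))
  consume <- 2L
  frontier <- 1L # indices into nodes still awaiting children
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      a <- nodes[[i]]$arity
      if (a == 0L) next
      for (c in seq_len(a)) {
        if (consume > length(symbols))
          stop("chromosome decoding read past the gene end", call. = FALSE)
        nodes[[length(nodes) + 1L]] <- make_node(symbols[consume])
        nodes[[i]]$children[[c]] <- length(nodes)
        consume <- consume + 1L
        nxt <- c(nxt, length(nodes))
      }
    }
    frontier <- nxt
  }
  # resolve child indices into nested lists, leaves first
  build <- function(i) {
    nd <- nodes[[i]]
    if (nd$arity > 0) nd$children <- lapply(nd$children, build)
    nd
  }
  build(1L)
}

#' Decode a chromosome into its expression tree
#'
#' Level-order Karva expansion; symbols beyond the tree's closure are
#' non-coding and ignored. Genes of a multigenic chromosome are linked by
#' addition.
#'
#' @param chromosome A `gep_chromosome`.
#' @return A `gep_tree` (nested list with `sym`, `arity`, `children`).
#' @export
decode <- function(chromosome) {
  h <- attr(chromosome, "head_length")
  g <- attr(chromosome, "gene_count")
  glen <- 2L * h + 1L
  trees <- lapply(seq_len(g), function(k) {
    karva_decode_gene(unclass(chromosome)[((k - 1L) * glen + 1L):(k * glen)])
  })
  tree <- trees[[1]]
  for (k in seq_len(g)[-1]) {
    tree <- list(sym = "add", arity = 2L, children = list(tree, trees[[k]]))
  }
  structure(tree, class = "gep_tree")
}

#' Point mutation
#'
#' Each position is independently replaced with probability `rate`; head
#' positions draw from functions and terminals, tail positions from terminals
#' only, preserving the Karva domain invariant.
#'
#' @param chromosome A `gep_chromosome`.
#' @param rate Per-position mutation probability.
#' @param config A [gep_config()].
#' @return The mutated chromosome.
#' @export
mutate_chromosome <- function(chromosome, rate, config) {
  if (rate <= 0) return(chromosome)
  syms <- unclass(chromosome)
  terminals <- attr(chromosome, "terminals")
  head_pool <- c(config$function_set, terminals)
  hp <- head_positions(chromosome)
  flip <- runif(length(syms)) < rate
  idx <- which(flip)
  for (i in idx) {
    pool <- if (i %in% hp) head_pool else terminals
    syms[i] <- sample(pool, 1L)
  }
  new_chromosome(syms, config, terminals)
}

# insert segment seg into gene head at position pos (>= 2), shifting right and
# truncating at the head end; tail untouched
head_insert <- function(gene, h, seg, pos) {
  head <- gene[seq_len(h)]
  new_head <- append(head, seg, after = pos - 1L)[seq_len(h)]
  c(new_head, gene[(h + 1L):length(gene)])
}

#' Transposition operators
#'
#' Insertion-sequence (IS) transposition copies a random 1-3 symbol segment
#' of a gene into a random non-root head position, shifting the head right
#' and truncating at the head boundary. Root-insertion-sequence (RIS)
#' transposition copies a segment starting at a function symbol to the head
#' start. Each fires with its own probability; the tail is never altered.
#'
#' @param chromosome A `gep_chromosome`.
#' @param is_rate,ris_rate Event probabilities.
#' @param config A [gep_config()].
#' @return The (possibly) transposed chromosome.
#' @export
transpose_chromosome <- function(chromosome, is_rate, ris_rate, config) {
  syms <- unclass(chromosome)
  terminals <- attr(chromosome, "terminals")
  h <- config$head_length
  glen <- 2L * h + 1L
  for (k in seq_len(config$gene_count)) {
    rng <- ((k - 1L) * glen + 1L):(k * glen)
    gene <- syms[rng]
    if (h >= 2 && runif(1) < is_rate) {
      len <- sample(1:3, 1L)
      start <- sample(glen - len + 1L, 1L)
      pos <- sample(2:h, 1L)
      gene <- head_insert(gene, h, gene[start:(start + len - 1L)], pos)
    }
    if (runif(1) < ris_rate) {
      scan_from <- sample(h, 1L)
      fpos <- which(is_function_symbol(gene[seq_len(h)]))
      fpos <- fpos[fpos >= scan_from]
      if (length(fpos) > 0) {
        start <- fpos[1]
        len <- sample(1:3, 1L)
        len <- min(len, glen - start + 1L)
        seg <- gene[start:(start + len - 1L)]
        gene <- c(seg, gene[seq_len(h)])[seq_len(h)] |>
          c(gene[(h + 1L):glen])
      }
    }
    syms[rng] <- gene
  }
  new_chromosome(syms, config, terminals)
}

#' One-point recombination
#'
#' With probability `rate`, exchanges the suffixes of two equal-length
#' chromosomes past a uniform random cut. Because head/tail structure is
#' aligned between parents, both children keep the Karva domain invariant.
#'
#' @param parent1,parent2 `gep_chromosome`s of equal length.
#' @param rate Crossover probability.
#' @param config A [gep_config()].
#' @return List of two chromosomes.
#' @export
recombine_chromosomes <- function(parent1, parent2, rate, config) {
  if (length(parent1) != length(parent2))
    stop("parents must have equal length", call. = FALSE)
  if (runif(1) >= rate || length(parent1) < 2)
    return(list(parent1, parent2))
  cut <- sample(length(parent1) - 1L, 1L)
  s1 <- unclass(parent1); s2 <- unclass(parent2)
  tail_idx <- (cut + 1L):length(s1)
  tmp <- s1[tail_idx]
  s1[tail_idx] <- s2[tail_idx]
  s2[tail_idx] <- tmp
  terminals <- attr(parent1, "terminals")
  list(new_chromosome(s1, config, terminals),
       new_chromosome(s2, config, terminals))
}
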
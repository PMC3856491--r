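# Protected evaluation of expression trees, plus the textual round-trip
# (render to infix, parse from infix) used to serialize classifiers.

#' Evaluate an expression tree over protein feature vectors
#'
#' Evaluates a decoded `gep_tree` with protected semantics so every score is
#' finite:
#' \itemize{
#'   \item `div(a, b)` = `a / b` when `|b| > 1e-12`, else 1
#'   \item `sqrt(x)` = `sqrt(|x|)`; `log(x)` = `log(|x| + 1e-12)`
#'   \item `exp(x)` = `exp(min(x, 30))`
#'   \item `eq(a, b)` = 1 when `|a - b| <= 1e-9`, else 0
#' }
#' Any residual non-finite result is mapped to 0.
#'
#' @param tree A `gep_tree` from [decode()] or [parse_expression()].
#' @param features A feature tibble (`protein` + numeric columns) or a named
#'   list of equal-length numeric vectors; a single protein's named vector
#'   also works.
#' @return Numeric vector of scores, one per row of `features`.
#' @export
evaluate_tree <- function(tree, features) {
  if (is.numeric(features) && !is.list(features)) features <- as.list(features)
  if (is.data.frame(features)) {
    features <- as.list(features[setdiff(names(features), "protein")])
  }
  n <- if (length(features) > 0) length(features[[1]]) else 1L
  out <- eval_node(tree, features, n)
  out[!is.finite(out)] <- 0
  out
}

eval_node <- function(node, data, n) {
  if (node$arity == 0L) {
    v <- data[[node$sym]]
    if (is.null(v)) {
      num <- suppressWarnings(as.numeric(node$sym))
      if (is.na(num))
        stop("unknown terminal '", node$sym, "'", call. = FALSE)
      return(rep.int(num, n))
    }
    return(v)
  }
  a <- eval_node(node$children[[1]], data, n)
  if (node$arity == 1L) {
    return(switch(node$sym,
      sqrt = sqrt(abs(a)),
      log = log(abs(a) + 1e-12),
      exp = exp(pmin(a, 30)),
      abs = abs(a),
      stop("unknown function '", node$sym, "'", call. = FALSE)))
  }
  b <- eval_node(node$children[[2]], data, n)
  switch(node$sym,
    add = a + b,
    sub = a - b,
    mul = a * b,
    div = { r <- a / b; r[abs(b) <= 1e-12] <- 1; r },
    eq = as.numeric(abs(a - b) <= 1e-9),
    max = pmax(a, b),
    min = pmin(a, b),
    stop("unknown function '", node$sym, "'", call. = FALSE))
}

leaf <- function(sym) list(sym = sym, arity = 0L, children = list())
branch <- function(sym, ...) {
  kids <- list(...)
  list(sym = sym, arity = as.integer(length(kids)), children = kids)
}

#' Render an expression tree as infix text
#'
#' Arithmetic is rendered infix and fully parenthesized; the other functions
#' as named calls (`Min`, `Max`, `Abs`, `Sqrt`, `Log`, `Exp`, `Eq`).
#' Constants are printed with minimal decimals. The output round-trips
#' through [parse_expression()].
#'
#' @param tree A `gep_tree`.
#' @return A single string.
#' @export
render_expression <- function(tree) {
  op <- c(add = "+", sub = "-", mul = "*", div = "/")
  fn <- c(min = "Min", max = "Max", abs = "Abs", sqrt = "Sqrt",
          log = "Log", exp = "Exp", eq = "Eq")
  rec <- function(nd) {
    if (nd$arity == 0L) {
      num <- suppressWarnings(as.numeric(nd$sym))
      if (!is.na(num) && grepl("^[-0-9.]", nd$sym))
        return(format(num, trim = TRUE, scientific = FALSE))
      return(nd$sym)
    }
    if (nd$sym %in% names(op)) {
      return(paste0("(", rec(nd$children[[1]]), op[[nd$sym]],
                    rec(nd$children[[2]]), ")"))
    }
    args <- vapply(nd$children, rec, character(1))
    paste0(fn[[nd$sym]], "(", paste(args, collapse = ","), ")")
  }
  rec(tree)
}

#' Parse an infix classifier expression into a tree
#'
#' Grammar: infix `+ - * /`, named calls `Min`, `Max`, `Abs`, `Sqrt`, `Log`,
#' `Exp`, `Eq` (case-insensitive), numeric literals, feature identifiers,
#' parentheses, and unary minus. Evaluation of the resulting tree follows
#' [evaluate_tree()] protected semantics.
#'
#' @param text Expression text.
#' @param feature_names Legal feature identifiers; any other identifier is a
#'   parse error.
#' @return A `gep_tree`.
#' @export
parse_expression <- function(text, feature_names) {
  lang <- tryCatch(str2lang(text), error = function(e) {
    stop("parse error in expression: ", conditionMessage(e), call. = FALSE)
  })
  calls <- c("min" = "min", "max" = "max", "abs" = "abs", "sqrt" = "sqrt",
             "log" = "log", "exp" = "exp", "eq" = "eq")
  ops <- c("+" = "add", "-" = "sub", "*" = "mul", "/" = "div")
  rec <- function(e) {
    if (is.numeric(e)) return(leaf(format(e, trim = TRUE, scientific = FALSE)))
    if (is.name(e)) {
      nm <- as.character(e)
      if (!nm %in% feature_names)
        stop("unknown identifier '", nm, "' in expression", call. = FALSE)
      return(leaf(nm))
    }
    if (!is.call(e)) stop("unsupported expression element", call. = FALSE)
    head <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (head == "(") return(rec(args[[1]]))
    if (head %in% names(ops)) {
      if (length(args) == 1L) { # unary +/-
        if (head == "+") return(rec(args[[1]]))
        return(branch("sub", leaf("0"), rec(args[[1]])))
      }
      return(branch(ops[[head]], rec(args[[1]]), rec(args[[2]])))
    }
    key <- tolower(head)
    if (key %in% names(calls)) {
      want <- symbol_arity(calls[[key]])
      if (length(args) != want)
        stop("'", head, "' expects ", want, " argument(s), got ",
             length(args), call. = FALSE)
      return(do.call(branch, c(list(calls[[key]]), lapply(args, rec))))
    }
    stop("unknown function '", head, "' in expression", call. = FALSE)
  }
  structure(rec(lang), class = "gep_tree")
}

#' @export
print.gep_tree <- function(x, ...) {
  cat("<gep_tree>", render_expression(x), "\n")
  invisible(x)
}

#' The published essentiality classifier (canonicalized)
#'
#' The classifier expression reported for the full-scale yeast study, in a
#' canonicalized form: the printed original contains a two-argument `Abs` and
#' unbalanced parentheses, which we resolve as an `Abs(... - 1)` term. This
#' is an interpretation, stored as a fixed scorer for reuse on any feature
#' table with the referenced columns (`lysosome`, `WDC`, `ION`,
#' `endoplasmic_reticulum`, `nucleus`, `SC`, `cytoplasm`, `vacuole`).
#'
#' @format A single string.
#' @export
published_expression_text <- paste0(
  "Min(lysosome,WDC-0.5)+(ION-0.9)",
  "+Max(0.4,Max(endoplasmic_reticulum,nucleus)-Min(0.5,SC))",
  "-Abs(Min(cytoplasm-vacuole,0.1)-1)"
)

#' Score proteins with the published classifier
#'
#' Evaluates [published_expression_text] on a feature table.
#'
#' @param features Feature tibble with a `protein` column and the feature
#'   columns the expression references.
#' @return A tibble with `protein` and `score`, in input order.
#' @export
published_score <- function(features) {
  tree <- parse_expression(published_expression_text,
                           setdiff(names(features), "protein"))
  tibble::tibble(protein = features$protein,
                 score = evaluate_tree(tree, features))
}
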
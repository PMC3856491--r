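#' Read a PPI network from a two-column edge list
#'
#' Reads a delimited edge list of protein identifiers (one interaction per
#' line, DIP-style tab export pre-cut to two columns) into an undirected
#' simple [igraph][igraph::graph] graph. Self-interactions and repeated
#' interactions (in either orientation) are dropped, and the number dropped is
#' reported via a message. Lines starting with `#` are ignored.
#'
#' @param path Path to the edge-list file.
#' @param delim Field delimiter. Default tab.
#' @param quiet Suppress the node/edge-count message.
#' @return An undirected simple `igraph` graph whose vertices are named by
#'   protein ID.
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB", "B\tA", "C\tC"), f)
#' g <- read_ppi_network(f)
#' igraph::vcount(g) # 3 (C is isolated)
#' igraph::ecount(g) # 1
#' @export
read_ppi_network <- function(path, delim = "\t", quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty edge list: returning an empty network", call. = FALSE)
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  parts <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", bad[1L], ": expected 2 columns, found ",
         length(parts[[bad[1L]]]), call. = FALSE)
  }
  from <- vapply(parts, `[[`, character(1), 1L)
  to <- vapply(parts, `[[`, character(1), 2L)
  n_raw <- length(from)
  self <- from == to
  from <- from[!self]; to <- to[!self]
  # canonical unordered orientation, then dedup
  key <- ifelse(from <= to, paste(from, to, sep = "\r"), paste(to, from, sep = "\r"))
  keep <- !duplicated(key)
  nodes <- sort(unique(c(parts |> vapply(`[[`, character(1), 1L),
                         parts |> vapply(`[[`, character(1), 2L))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  dropped <- n_raw - sum(keep)
  if (!quiet) {
    message("read_ppi_network: ", igraph::vcount(g), " proteins, ",
            igraph::ecount(g), " edges (", dropped,
            " self-loop/duplicate line(s) dropped)")
  }
  g
}

#' Write a network back to a canonical two-column edge list
#'
#' Edges are written in lexicographically canonical orientation and order, so
#' that [read_ppi_network()] on the output reproduces the same graph
#' (round-trip identity).
#'
#' @param network An igraph graph with named vertices.
#' @param path Output path.
#' @param delim Field delimiter. Default tab.
#' @return `path`, invisibly.
#' @export
write_ppi_network <- function(network, path, delim = "\t") {
  el <- igraph::as_edgelist(network)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  }
  writeLines(paste(el[, 1], el[, 2], sep = delim), path)
  invisible(path)
}

#' Read an essential-protein list and align it to a network
#'
#' Reads one protein ID per line and intersects it with the network's node
#' set: listed proteins absent from the network are counted and reported, not
#' treated as errors. Every network protein gets exactly one label.
#'
#' @param path Path to the ID list (one per line; blank lines and `#` comments
#'   ignored).
#' @param network An igraph graph with named vertices.
#' @param quiet Suppress the count message.
#' @return A tibble with columns `protein` (character) and `essential`
#'   (logical), one row per network protein.
#' @export
read_essential_proteins <- function(path, network, quiet = FALSE) {
  ids <- readLines(path, warn = FALSE)
  ids <- trimws(ids[!grepl("^\\s*#", ids)])
  ids <- unique(ids[nzchar(ids)])
  nodes <- igraph::V(network)$name
  absent <- setdiff(ids, nodes)
  if (!quiet) {
    message("read_essential_proteins: ", length(intersect(ids, nodes)),
            " of ", length(ids), " listed proteins present in network (",
            length(absent), " absent)")
  }
  tibble::tibble(protein = nodes, essential = nodes %in% ids)
}

#' Read a gene-expression matrix (protein x sample TSV)
#'
#' @param path TSV with a header row; first column protein ID, remaining
#'   columns numeric sample values.
#' @return A tibble with `protein` plus one numeric column per sample.
#'   Proteins missing from the file are simply absent (partial coverage is
#'   expected; co-expression treats uncovered proteins as correlation 0).
#' @export
read_expression_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "protein"
  tbl$protein <- as.character(tbl$protein)
  for (j in seq_along(tbl)[-1]) {
    v <- tbl[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) & !anyNA(v)) {
        i <- which(is.na(num))[1]
        stop("non-numeric expression value at row ", i, ", column '",
             names(tbl)[j], "'", call. = FALSE)
      }
      tbl[[j]] <- num
    }
  }
  if (anyNA(tbl[-1])) stop("missing expression values are not allowed", call. = FALSE)
  tbl
}

#' Read a subcellular-localization indicator table
#'
#' @param path TSV with header; first column protein ID, remaining columns
#'   0/1 compartment membership indicators.
#' @param compartments Required compartment column set; defaults to the 16
#'   yeast compartments in [yeast_compartments]. Missing columns are added as
#'   all-zero; extra columns are an error.
#' @param strict If `TRUE` (default) a value outside \{0, 1\} is an error;
#'   otherwise values are clamped into \{0, 1\} (nonzero -> 1).
#' @return A tibble with `protein` plus one 0/1 integer column per compartment
#'   (in `compartments` order).
#' @export
read_localization_matrix <- function(path, compartments = yeast_compartments,
                                     strict = TRUE) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "protein"
  tbl$protein <- as.character(tbl$protein)
  extra <- setdiff(names(tbl)[-1], compartments)
  if (length(extra) > 0)
    stop("unknown compartment column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (cmp in compartments) {
    if (!cmp %in% names(tbl)) { tbl[[cmp]] <- 0L; next }
    v <- tbl[[cmp]]
    if (strict && any(!v %in% c(0, 1))) {
      i <- which(!v %in% c(0, 1))[1]
      stop("localization value ", v[i], " at row ", i, ", column '", cmp,
           "' is not 0/1 (set strict = FALSE to clamp)", call. = FALSE)
    }
    tbl[[cmp]] <- as.integer(v != 0)
  }
  tbl[, c("protein", compartments)]
}

#' Read a per-protein orthology conservation score table
#'
#' The score is a nonnegative conservation signal (e.g. the number of
#' reference organisms in which the protein has an ortholog). Proteins absent
#' from the file receive score 0 downstream.
#'
#' @param path TSV with header; columns protein ID and numeric score.
#' @return A tibble with columns `protein` and `orthology` (numeric >= 0).
#' @export
read_orthology_scores <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1:2] <- c("protein", "orthology")
  tbl$protein <- as.character(tbl$protein)
  if (!is.numeric(tbl$orthology))
    stop("orthology score column must be numeric", call. = FALSE)
  if (any(tbl$orthology < 0))
    stop("orthology scores must be nonnegative", call. = FALSE)
  tbl[, c("protein", "orthology")]
}

#' Write / read a feature table as TSV
#'
#' The canonical on-disk form of a feature table: a `protein` ID column plus
#' one named numeric column per feature.
#'
#' @param features Feature table tibble (from [assemble_feature_table()]).
#' @param path Output path.
#' @return `path` invisibly (write); the feature tibble (read).
#' @export
write_feature_table <- function(features, path) {
  readr::write_tsv(features, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "protein"
  tbl$protein <- as.character(tbl$protein)
  tbl
}

#' Write a ranked prediction table
#'
#' @param predictions Tibble with at least `protein` and `score`; written in
#'   descending score order (ties by protein ID).
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  ord <- order(-predictions$score, predictions$protein, method = "radix")
  readr::write_tsv(predictions[ord, ], path, progress = FALSE)
  invisible(path)
}
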
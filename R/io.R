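#' Read and write graph edge lists
#'
#' Tab-separated edge lists: 3 columns (`from`, `to`, `weight`) for
#' weighted graphs, 2 columns for unweighted ones. A header line is
#' optional and auto-detected on read (a third field that does not parse
#' as a number is taken to be a header). Round-trips with the writers.
#'
#' @param path File path.
#' @return `read_weighted_edgelist()` / `read_edgelist()` return a
#'   [weighted_graph()]; the writers return `path` invisibly.
#' @name edge_list_io
NULL

#' @rdname edge_list_io
#' @export
read_weighted_edgelist <- function(path) {
  df <- read_tsv_headerless(path, 3)
  names(df) <- c("from", "to", "weight")
  df$weight <- parse_num(df$weight, path)
  weighted_graph(df)
}

#' @rdname edge_list_io
#' @export
read_edgelist <- function(path) {
  df <- read_tsv_headerless(path, 2)
  names(df) <- c("from", "to")
  weighted_graph(df)
}

#' @rdname edge_list_io
#' @param g A `weighted_graph` (or coercible).
#' @export
write_weighted_edgelist <- function(g, path) {
  g <- as_weighted_graph(g)
  readr::write_tsv(g$edges, path, col_names = FALSE)
  invisible(path)
}

#' @rdname edge_list_io
#' @export
write_edgelist <- function(g, path) {
  g <- as_weighted_graph(g)
  readr::write_tsv(g$edges[, c("from", "to")], path, col_names = FALSE)
  invisible(path)
}

read_tsv_headerless <- function(path, min_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1, warn = FALSE)) == 0) {
    stop("file ", path, " is empty", call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "", blank.lines.skip = TRUE)
  if (ncol(df) < min_cols) {
    stop("malformed edge list ", path, ": expected at least ", min_cols,
         " tab-separated columns, found ", ncol(df), call. = FALSE)
  }
  df <- df[, seq_len(min_cols), drop = FALSE]
  # header detection: numeric third column (or non-duplicated first line)
  if (nrow(df) > 0 && min_cols == 3 && is.na(suppressWarnings(as.numeric(df[1, 3])))) {
    df <- df[-1, , drop = FALSE]
  } else if (nrow(df) > 0 && min_cols == 2 &&
             tolower(df[1, 1]) %in% c("from", "source", "node_u")) {
    df <- df[-1, , drop = FALSE]
  }
  tibble::as_tibble(df)
}

parse_num <- function(x, path) {
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out)) {
    bad <- which(is.na(out))[1]
    stop("malformed edge list ", path, ": non-numeric weight at data line ",
         bad, call. = FALSE)
  }
  out
}

#' Read and write node-set files
#'
#' One subgraph per line, node identifiers separated by tabs. Used for
#' ground-truth and detected-solution files.
#'
#' @param path File path.
#' @param sets List of character vectors.
#' @return `read_node_sets()` returns a list of character vectors;
#'   `write_node_sets()` returns `path` invisibly.
#' @name node_set_io
NULL

#' @rdname node_set_io
#' @export
read_node_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  purrr::map(lines, ~ strsplit(.x, "\t", fixed = TRUE)[[1]])
}

#' @rdname node_set_io
#' @export
write_node_sets <- function(sets, path) {
  stopifnot(is.list(sets))
  writeLines(vapply(sets, function(s) paste(as.character(s), collapse = "\t"),
                    ""), path)
  invisible(path)
}

#' Read a seed-pair file
#'
#' Two tab-separated columns: conceptual id, physical id.
#'
#' @param path File path.
#' @return Tibble with columns `conceptual` and `physical`.
#' @export
read_seed_pairs <- function(path) {
  df <- read_tsv_headerless(path, 2)
  names(df) <- c("conceptual", "physical")
  if (nrow(df) == 0) stop("seed-pair file ", path, " is empty", call. = FALSE)
  df
}

#' GraphML import and export
#'
#' Thin wrappers over igraph's GraphML reader/writer preserving node names
#' and the `weight` edge attribute.
#'
#' @param g A `weighted_graph` (or coercible).
#' @param path File path.
#' @return `read_graphml()` returns a `weighted_graph`; `write_graphml()`
#'   returns `path` invisibly.
#' @name graphml_io
NULL

#' @rdname graphml_io
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as_weighted_graph(igraph::read_graph(path, format = "graphml"))
}

#' @rdname graphml_io
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' Write an alignment graph with edge provenance
#'
#' Four tab-separated columns: from, to, weight, provenance
#' (direct/path).
#'
#' @param ag An `alignment_graph` from [build_alignment_graph()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_alignment_graph <- function(ag, path) {
  stopifnot(inherits(ag, "alignment_graph"))
  readr::write_tsv(tibble::as_tibble(ag), path, col_names = FALSE)
  invisible(path)
}

#' Write a key-value summary sidecar
#'
#' One `key<TAB>value` pair per line; numeric values written at full
#' precision.
#'
#' @param x Named list or one-row data frame.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_summary_kv <- function(x, path) {
  x <- as.list(x)
  stopifnot(length(names(x)) == length(x))
  vals <- vapply(x, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, "")
  writeLines(paste(names(x), vals, sep = "\t"), path)
  invisible(path)
}
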
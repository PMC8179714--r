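#' Weighted graphs as tidy edge lists
#'
#' A `weighted_graph` is a light validated container around an undirected
#' edge-list tibble with columns `from`, `to` and `weight` (non-negative,
#' dimensionless). Node identifiers are opaque strings with a deterministic
#' total order (C-locale lexicographic), used everywhere ties must break.
#' Self-loops, duplicate edges and negative weights are rejected; isolated
#' nodes are allowed via the `nodes` argument.
#'
#' @param edges A data frame with columns `from` and `to` (coercible to
#'   character) and optionally `weight` (defaults to 1, the unweighted case).
#' @param nodes Optional character vector of node identifiers; must contain
#'   every endpoint in `edges`. Use it to carry isolated nodes.
#' @return An object of class `weighted_graph` with fields `nodes` (sorted
#'   character vector) and `edges` (tibble `from`, `to`, `weight` with
#'   `from < to` in node order).
#' @examples
#' g <- weighted_graph(tibble::tibble(
#'   from = c("a", "b"), to = c("b", "c"), weight = c(0.5, 0.7)
#' ))
#' graph_density(g)
#' @export
weighted_graph <- function(edges, nodes = NULL) {
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = double())
  }
  stopifnot(is.data.frame(edges))
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns `from` and `to`", call. = FALSE)
  }
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  weight <- if ("weight" %in% names(edges)) as.double(edges$weight) else
    rep(1, length(from))
  if (anyNA(from) || anyNA(to) || anyNA(weight)) {
    stop("edge list contains missing values", call. = FALSE)
  }
  if (any(weight < 0)) {
    stop("edge weights must be non-negative", call. = FALSE)
  }
  if (any(from == to)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  # canonical orientation: from < to under the global node order
  swap <- node_gt(from, to)
  tmp <- from[swap]; from[swap] <- to[swap]; to[swap] <- tmp
  key <- paste(from, to, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate edges: at most one edge per node pair", call. = FALSE)
  }
  all_nodes <- sort_nodes(unique(c(from, to, as.character(nodes %||% character()))))
  if (!is.null(nodes)) {
    missing <- setdiff(unique(c(from, to)), as.character(nodes))
    if (length(missing) > 0) {
      stop("`nodes` must include every edge endpoint; missing: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
  }
  ord <- order(from, to, method = "radix")
  structure(
    list(
      nodes = all_nodes,
      edges = tibble::tibble(from = from[ord], to = to[ord],
                             weight = weight[ord])
    ),
    class = "weighted_graph"
  )
}

#' Coerce to a weighted graph
#'
#' Accepts a `weighted_graph`, an edge-list data frame, or an igraph object
#' (undirected; a `weight` edge attribute is used when present).
#'
#' @param x Object to coerce.
#' @param nodes Optional node universe (see [weighted_graph()]).
#' @return A `weighted_graph`.
#' @export
as_weighted_graph <- function(x, nodes = NULL) {
  if (inherits(x, "weighted_graph")) return(x)
  if (inherits(x, "igraph")) {
    ed <- igraph::as_data_frame(x, what = "edges")
    names(ed)[1:2] <- c("from", "to")
    if (!"weight" %in% names(ed)) ed$weight <- 1
    return(weighted_graph(ed[, c("from", "to", "weight")],
                          nodes = igraph::V(x)$name %||% nodes))
  }
  if (is.data.frame(x)) return(weighted_graph(x, nodes = nodes))
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to a weighted_graph", call. = FALSE)
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat("<weighted_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges, total weight ", format(sum(x$edges$weight), digits = 6),
      "\n", sep = "")
  print(utils::head(x$edges, 5))
  invisible(x)
}

#' Convert a weighted graph to igraph
#'
#' @param g A `weighted_graph` (or coercible).
#' @return An undirected igraph object with a `weight` edge attribute.
#' @export
as_igraph <- function(g) {
  g <- as_weighted_graph(g)
  igraph::graph_from_data_frame(g$edges, directed = FALSE,
                                vertices = data.frame(name = g$nodes))
}

# C-locale lexicographic sort: the package's global node order.
sort_nodes <- function(x) sort(x, method = "radix")

node_gt <- function(a, b) {
  # TRUE where a > b in the radix (C-locale) order, vectorised
  r <- rank_nodes(c(a, b))
  n <- length(a)
  r[seq_len(n)] > r[n + seq_len(n)]
}

rank_nodes <- function(x) {
  u <- sort_nodes(unique(x))
  match(x, u)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# internal: integer-indexed adjacency structure for fast peeling
graph_index <- function(g) {
  g <- as_weighted_graph(g)
  n <- length(g$nodes)
  ei <- match(g$edges$from, g$nodes)
  ej <- match(g$edges$to, g$nodes)
  w <- g$edges$weight
  adj_n <- split(c(ej, ei), factor(c(ei, ej), levels = seq_len(n)))
  adj_w <- split(c(w, w), factor(c(ei, ej), levels = seq_len(n)))
  list(nodes = g$nodes, n = n, ei = ei, ej = ej, w = w,
       adj_n = adj_n, adj_w = adj_w,
       vol = vapply(adj_w, sum, 0))
}

check_nodes_in <- function(g, Z, what = "node set") {
  bad <- setdiff(Z, g$nodes)
  if (length(bad) > 0) {
    stop(what, " contains unknown nodes: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Node volumes (weighted degrees)
#'
#' The volume of a node is the sum of the weights of its incident edges.
#'
#' @param g A `weighted_graph` (or edge-list data frame).
#' @param nodes Nodes to report; default all nodes. Unknown nodes error.
#' @return A tibble with columns `node` and `volume`, one row per requested
#'   node, in the requested order.
#' @examples
#' g <- weighted_graph(data.frame(from = "a", to = "b", weight = 0.8))
#' node_volumes(g)
#' @export
node_volumes <- function(g, nodes = NULL) {
  g <- as_weighted_graph(g)
  nodes <- as.character(nodes %||% g$nodes)
  check_nodes_in(g, nodes)
  vol <- stats::setNames(rep(0, length(g$nodes)), g$nodes)
  add <- tapply(c(g$edges$weight, g$edges$weight),
                c(g$edges$from, g$edges$to), sum)
  vol[names(add)] <- add
  tibble::tibble(node = nodes, volume = unname(vol[nodes]))
}

#' Weighted density of a graph or induced subgraph
#'
#' Two conventions are supported. `"edge_sum"` (the default, matching the
#' benchmark tables throughout) is the total edge weight divided by the
#' number of nodes, W(Z)/|Z|. `"volume"` is the mean node volume,
#' sum(vol)/|Z| = 2W(Z)/|Z|, exactly twice the edge-sum value on any graph.
#'
#' @param g A `weighted_graph` (or coercible).
#' @param nodes Optional node subset inducing the subgraph; default the whole
#'   graph. Must be non-empty and a subset of the graph's nodes.
#' @param convention `"edge_sum"` or `"volume"`.
#' @return A single non-negative number.
#' @export
graph_density <- function(g, nodes = NULL,
                          convention = c("edge_sum", "volume")) {
  convention <- match.arg(convention)
  g <- as_weighted_graph(g)
  if (is.null(nodes)) {
    n <- length(g$nodes)
    w <- sum(g$edges$weight)
  } else {
    nodes <- unique(as.character(nodes))
    if (length(nodes) == 0) stop("`nodes` must be non-empty", call. = FALSE)
    check_nodes_in(g, nodes)
    n <- length(nodes)
    keep <- g$edges$from %in% nodes & g$edges$to %in% nodes
    w <- sum(g$edges$weight[keep])
  }
  if (n == 0) stop("density of the empty graph is undefined", call. = FALSE)
  if (convention == "edge_sum") w / n else 2 * w / n
}

#' Induced subgraph
#'
#' @param g A `weighted_graph` (or coercible).
#' @param nodes Node subset (must exist in `g`).
#' @return The `weighted_graph` induced by `nodes` (isolated nodes kept).
#' @export
induced_subgraph_w <- function(g, nodes) {
  g <- as_weighted_graph(g)
  nodes <- unique(as.character(nodes))
  check_nodes_in(g, nodes)
  keep <- g$edges$from %in% nodes & g$edges$to %in% nodes
  weighted_graph(g$edges[keep, ], nodes = nodes)
}

#' Is a node set connected in the graph?
#'
#' Connectivity of the subgraph induced by `nodes`. A single node is
#' connected; the empty set is not.
#'
#' @inheritParams induced_subgraph_w
#' @return Logical scalar.
#' @export
is_connected_set <- function(g, nodes) {
  g <- as_weighted_graph(g)
  nodes <- unique(as.character(nodes))
  if (length(nodes) == 0) return(FALSE)
  check_nodes_in(g, nodes)
  if (length(nodes) == 1) return(TRUE)
  comps <- connected_components(g, nodes)
  length(comps) == 1
}

# list of node-set components of the induced subgraph (igraph-backed)
connected_components <- function(g, nodes) {
  sub <- induced_subgraph_w(g, nodes)
  if (length(sub$nodes) == 0) return(list())
  ig <- as_igraph(sub)
  mem <- igraph::components(ig)$membership
  unname(split(names(mem), mem))
}

# densest connected component of a node set; ties by density then by the
# lexicographically smallest member node
densest_component <- function(g, nodes, convention = "edge_sum") {
  comps <- connected_components(g, nodes)
  if (length(comps) == 0) return(character())
  if (length(comps) == 1) return(sort_nodes(comps[[1]]))
  dens <- vapply(comps, function(cc) graph_density(g, cc, convention), 0)
  first <- vapply(comps, function(cc) sort_nodes(cc)[1], "")
  ord <- order(-dens, rank_nodes(first), method = "radix")
  sort_nodes(comps[[ord[1]]])
}
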
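#' Build the weighted alignment graph of a dual network
#'
#' Step 1 of the pipeline: merge a physical (unweighted) and a conceptual
#' (weighted) network into one weighted graph whose nodes are the seed
#' pairs `P`. For two alignment nodes `u`, `v` whose physical counterparts
#' are adjacent in the physical network:
#'
#' * if their conceptual counterparts are adjacent in the conceptual
#'   network, an edge is added carrying that conceptual weight
#'   (provenance `"direct"`);
#' * otherwise, if their conceptual hop distance is strictly below `delta`,
#'   an edge is added carrying the mean of the edge weights along a
#'   minimum-hop conceptual path (provenance `"path"`).
#'
#' With `delta = 1` only pairs adjacent in both networks are linked, so the
#' alignment graph is the conceptual-weighted intersection of the two edge
#' sets. Every alignment edge projects to a physical edge, hence any
#' connected alignment subgraph induces a connected physical subgraph.
#'
#' Among tied minimum-hop paths the lexicographically smallest node
#' sequence is used, making weights deterministic. `roles = "swapped"`
#' exchanges the two networks' roles (conceptual adjacency required,
#' `delta` bounds the physical hop distance) for experimentation.
#'
#' @param physical The physical network: a 2-column edge-list data frame or
#'   `weighted_graph` (weights ignored).
#' @param conceptual The conceptual network: a weighted edge list or
#'   `weighted_graph`.
#' @param pairs Seed pairs: a data frame with columns `conceptual` and
#'   `physical`, or the keyword `"identity"` to pair every node of the
#'   shared universe with itself.
#' @param delta Positive integer hop-distance threshold (strict, `< delta`).
#' @param roles `"standard"` or `"swapped"` (see above).
#' @return A tibble of class `alignment_graph` with columns `from`, `to`,
#'   `weight`, `provenance`, plus attributes `delta` and `pairs`. Alignment
#'   node identifiers are the conceptual id when the pair maps a node to
#'   itself, otherwise `"conceptual|physical"`. Feed it to
#'   [as_weighted_graph()] or directly to [iwds()].
#' @examples
#' phys <- data.frame(from = c("a", "b", "a"), to = c("b", "c", "c"))
#' conc <- data.frame(from = c("a", "b"), to = c("b", "c"),
#'                    weight = c(0.5, 0.7))
#' build_alignment_graph(phys, conc, delta = 3)
#' @export
build_alignment_graph <- function(physical, conceptual, pairs = "identity",
                                  delta = 4,
                                  roles = c("standard", "swapped")) {
  roles <- match.arg(roles)
  if (!(is.numeric(delta) && length(delta) == 1 && delta >= 1 &&
        delta == floor(delta))) {
    stop("`delta` must be a positive integer", call. = FALSE)
  }
  gp <- as_weighted_graph(physical)
  gc_ <- as_weighted_graph(conceptual)
  if (roles == "swapped") {
    tmp <- gp; gp <- gc_; gc_ <- tmp
  }
  pairs <- resolve_seed_pairs(pairs, gc_, gp, roles)
  if (nrow(pairs) == 0) stop("seed-pair list is empty", call. = FALSE)

  node_id <- ifelse(pairs$conceptual == pairs$physical, pairs$conceptual,
                    paste(pairs$conceptual, pairs$physical, sep = "|"))
  if (anyDuplicated(node_id)) {
    stop("duplicate seed pairs are not allowed", call. = FALSE)
  }

  # candidate alignment edges: pairs whose physical nodes are adjacent
  by_phys <- split(seq_len(nrow(pairs)), pairs$physical)
  cand_i <- integer(); cand_j <- integer()
  pe <- gp$edges
  for (r in seq_len(nrow(pe))) {
    ii <- by_phys[[pe$from[r]]]
    jj <- by_phys[[pe$to[r]]]
    if (is.null(ii) || is.null(jj)) next
    grid <- expand.grid(i = ii, j = jj)
    cand_i <- c(cand_i, grid$i)
    cand_j <- c(cand_j, grid$j)
  }

  out <- tibble::tibble(from = character(), to = character(),
                        weight = double(), provenance = character())
  if (length(cand_i) > 0) {
    cw <- stats::setNames(gc_$edges$weight,
                          paste(gc_$edges$from, gc_$edges$to, sep = "\r"))
    hop <- NULL # lazily computed conceptual hop-distance matrix
    rows <- purrr::map(seq_along(cand_i), function(s) {
      i <- cand_i[s]; j <- cand_j[s]
      cu <- pairs$conceptual[i]; cv <- pairs$conceptual[j]
      if (cu == cv) return(NULL)
      key <- if (node_gt(cu, cv)) paste(cv, cu, sep = "\r") else
        paste(cu, cv, sep = "\r")
      if (!is.na(cw[key])) {
        return(tibble::tibble(from = node_id[i], to = node_id[j],
                              weight = unname(cw[key]),
                              provenance = "direct"))
      }
      if (delta <= 2) return(NULL) # needs hop distance >= 2 but < delta
      sp <- conceptual_shortest_path(gc_, cu, cv, delta)
      if (is.null(sp)) return(NULL)
      tibble::tibble(from = node_id[i], to = node_id[j],
                     weight = sp$mean_weight, provenance = "path")
    })
    out <- dplyr::bind_rows(rows)
  }
  if (nrow(out) > 0) {
    swap <- node_gt(out$from, out$to)
    tmp <- out$from[swap]; out$from[swap] <- out$to[swap]; out$to[swap] <- tmp
    out <- dplyr::distinct(out, .data$from, .data$to, .keep_all = TRUE)
    out <- dplyr::arrange(out, .data$from, .data$to)
  }
  structure(out, class = c("alignment_graph", class(out)),
            delta = delta, pairs = pairs,
            align_nodes = sort_nodes(node_id))
}

resolve_seed_pairs <- function(pairs, gc_, gp, roles = "standard") {
  if (is.character(pairs) && length(pairs) == 1 && pairs == "identity") {
    shared <- intersect(gc_$nodes, gp$nodes)
    pairs <- tibble::tibble(conceptual = shared, physical = shared)
  }
  stopifnot(is.data.frame(pairs))
  if (roles == "swapped" && !all(c("conceptual", "physical") %in% names(pairs))) {
    stop("seed pairs need `conceptual` and `physical` columns", call. = FALSE)
  }
  if (roles == "swapped") {
    pairs <- tibble::tibble(conceptual = as.character(pairs$physical),
                            physical = as.character(pairs$conceptual))
  } else {
    if (!all(c("conceptual", "physical") %in% names(pairs))) {
      stop("seed pairs need `conceptual` and `physical` columns",
           call. = FALSE)
    }
    pairs <- tibble::tibble(conceptual = as.character(pairs$conceptual),
                            physical = as.character(pairs$physical))
  }
  bad_c <- setdiff(pairs$conceptual, gc_$nodes)
  bad_p <- setdiff(pairs$physical, gp$nodes)
  if (length(bad_c) + length(bad_p) > 0) {
    stop("seed pairs reference unknown nodes; conceptual: ",
         paste(utils::head(bad_c, 5), collapse = ", "), "; physical: ",
         paste(utils::head(bad_p, 5), collapse = ", "), call. = FALSE)
  }
  pairs
}

#' Minimum-hop conceptual path between two nodes
#'
#' Breadth-first hop distance in the conceptual network together with the
#' arithmetic mean of the edge weights along one minimum-hop path (the
#' lexicographically smallest node sequence among ties). Absence of a path
#' shorter than `delta` hops is a value (`NULL`), not an error.
#'
#' @param conceptual Weighted conceptual graph (or coercible).
#' @param u,v Node identifiers present in the graph.
#' @param delta Positive integer; only paths with hop count `< delta` are
#'   reported.
#' @return `NULL`, or a list with `hops` (integer) and `mean_weight`.
#' @export
conceptual_shortest_path <- function(conceptual, u, v, delta) {
  g <- as_weighted_graph(conceptual)
  u <- as.character(u); v <- as.character(v)
  check_nodes_in(g, c(u, v), "path endpoints")
  if (u == v) return(NULL)
  ig <- as_igraph(g)
  d_from_v <- igraph::distances(ig, v = v, weights = NA)[1, ]
  hops <- d_from_v[[u]]
  if (!is.finite(hops) || hops >= delta) return(NULL)
  # lexicographically smallest min-hop path: walk from u, always stepping to
  # the smallest-named neighbour one hop closer to v
  cw <- stats::setNames(g$edges$weight,
                        paste(g$edges$from, g$edges$to, sep = "\r"))
  edge_w <- function(a, b) {
    key <- if (node_gt(a, b)) paste(b, a, sep = "\r") else paste(a, b, sep = "\r")
    unname(cw[key])
  }
  cur <- u
  remaining <- hops
  wsum <- 0
  while (remaining > 0) {
    nbs <- igraph::neighbors(ig, cur)$name
    nxt <- sort_nodes(nbs[d_from_v[nbs] == remaining - 1])[1]
    wsum <- wsum + edge_w(cur, nxt)
    cur <- nxt
    remaining <- remaining - 1
  }
  list(hops = as.integer(hops), mean_weight = wsum / hops)
}
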
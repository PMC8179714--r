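#' Greedy weighted peeling
#'
#' The classic densest-subgraph peeling: starting from the full graph,
#' repeatedly delete a node of minimum volume (weighted degree), recording
#' the density of every intermediate snapshot. The snapshot of maximum
#' density is a 1/2-approximation of the weighted densest subgraph. Volume
#' ties break by the global (lexicographic) node order, so traces are fully
#' deterministic.
#'
#' @param g A non-empty `weighted_graph` (or coercible).
#' @param convention Density convention used for the recorded densities.
#' @return A `peel_trace`: list with `nodes` (graph node order), `removed`
#'   (node removed at each iteration), `n_nodes`, `density` and `score`
#'   (density plus the V-Greedy correction `2 * density / n_nodes`) for the
#'   snapshot *before* each removal, plus the `convention` used. Snapshot
#'   `i` is the set of nodes not yet removed before iteration `i`; use
#'   [peel_snapshot()] to materialise it.
#' @examples
#' tr <- greedy_peel(weighted_graph(data.frame(
#'   from = c("a", "b"), to = c("b", "c"))))
#' tidy(tr)
#' @export
greedy_peel <- function(g, convention = c("edge_sum", "volume")) {
  convention <- match.arg(convention)
  gi <- graph_index(g)
  core <- peel_core(gi)
  n <- gi$n
  dens <- core$density
  if (convention == "volume") dens <- 2 * dens
  structure(
    list(nodes = gi$nodes, removed = gi$nodes[core$order],
         n_nodes = seq(n, 1), density = dens,
         score = dens + 2 * dens / seq(n, 1),
         convention = convention),
    class = "peel_trace"
  )
}

# minimum-volume peel on an integer-indexed graph; densities in edge-sum terms
peel_core <- function(gi) {
  n <- gi$n
  if (n == 0) stop("cannot peel an empty graph", call. = FALSE)
  vol <- gi$vol
  active <- rep(TRUE, n)
  W <- sum(gi$w)
  removed <- integer(n)
  dens <- numeric(n)
  n_active <- n
  for (i in seq_len(n)) {
    dens[i] <- W / n_active
    cand <- which(active)
    v <- cand[which.min(vol[cand])] # which.min: first minimum = smallest
    removed[i] <- v                 # node index = lexicographic order
    W <- W - vol[v]
    nb <- gi$adj_n[[v]]
    if (length(nb) > 0) {
      keep <- active[nb]
      if (any(keep)) {
        vol[nb[keep]] <- vol[nb[keep]] - gi$adj_w[[v]][keep]
      }
    }
    active[v] <- FALSE
    n_active <- n_active - 1
  }
  list(order = removed, density = pmax(dens, 0))
}

# Every connected component arising in any peeling snapshot, found by
# replaying the peel backwards with a union-find: reverse step s rebuilds
# forward snapshot n - s + 1, and each node re-insertion changes exactly one
# component, so the n recorded states enumerate the whole laminar family.
# Returns parallel vectors: step, anchor node index, component weight, size,
# and the V-Greedy score (edge-sum terms).
peel_component_states <- function(gi, order) {
  n <- gi$n
  parent <- integer(n)
  compW <- numeric(n)
  compN <- integer(n)
  present <- logical(n)
  st_W <- numeric(n); st_N <- integer(n); st_v <- integer(n)
  for (s in seq_len(n)) {
    v <- order[n - s + 1]
    parent[v] <- v; compW[v] <- 0; compN[v] <- 1L; present[v] <- TRUE
    nbs <- gi$adj_n[[v]]; ws <- gi$adj_w[[v]]
    for (t in seq_along(nbs)) {
      u <- nbs[t]
      if (!present[u]) next
      while (parent[u] != u) {
        parent[u] <- parent[parent[u]]
        u <- parent[u]
      }
      rv <- v
      while (parent[rv] != rv) {
        parent[rv] <- parent[parent[rv]]
        rv <- parent[rv]
      }
      if (u == rv) {
        compW[u] <- compW[u] + ws[t]
      } else {
        if (compN[u] < compN[rv]) { tmp <- u; u <- rv; rv <- tmp }
        parent[rv] <- u
        compW[u] <- compW[u] + compW[rv] + ws[t]
        compN[u] <- compN[u] + compN[rv]
      }
    }
    r <- v
    while (parent[r] != r) {
      parent[r] <- parent[parent[r]]
      r <- parent[r]
    }
    st_W[s] <- compW[r]; st_N[s] <- compN[r]; st_v[s] <- v
  }
  dens <- st_W / st_N
  list(step = seq_len(n), anchor = st_v, weight = st_W, size = st_N,
       density = dens, score = dens + 2 * dens / st_N)
}

# node set of the component containing `anchor` after reverse step `step`
materialize_component <- function(gi, order, step, anchor) {
  n <- gi$n
  parent <- integer(n)
  present <- logical(n)
  for (s in seq_len(step)) {
    v <- order[n - s + 1]
    parent[v] <- v; present[v] <- TRUE
    nbs <- gi$adj_n[[v]]
    for (t in seq_along(nbs)) {
      u <- nbs[t]
      if (!present[u]) next
      while (parent[u] != u) {
        parent[u] <- parent[parent[u]]
        u <- parent[u]
      }
      rv <- v
      while (parent[rv] != rv) {
        parent[rv] <- parent[parent[rv]]
        rv <- parent[rv]
      }
      if (u != rv) parent[rv] <- u
    }
  }
  root_of <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  target <- root_of(anchor)
  members <- which(present)[vapply(which(present), root_of, 0L) == target]
  sort_nodes(gi$nodes[members])
}

#' @export
print.peel_trace <- function(x, ...) {
  cat("<peel_trace> ", length(x$removed), " snapshots (",
      x$convention, " density)\n", sep = "")
  print(utils::head(tidy(x), 5))
  invisible(x)
}

#' Tidy a peeling trace
#'
#' @param x A `peel_trace`.
#' @param ... Unused.
#' @return Tibble with one row per snapshot: `iteration`, `removed_node`,
#'   `n_nodes`, `density`, `score`.
#' @export
tidy.peel_trace <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$removed), removed_node = x$removed,
                 n_nodes = x$n_nodes, density = x$density, score = x$score)
}

#' Materialise a peeling snapshot
#'
#' @param trace A `peel_trace`.
#' @param i Snapshot index (1 = full graph).
#' @return Character vector of the nodes still present before iteration `i`.
#' @export
peel_snapshot <- function(trace, i) {
  stopifnot(inherits(trace, "peel_trace"),
            i >= 1, i <= length(trace$removed))
  sort_nodes(trace$removed[seq(i, length(trace$removed))])
}

#' Greedy densest subgraph (1/2-approximation)
#'
#' Returns the maximum-density peeling snapshot (earliest index on ties,
#' i.e. the largest such snapshot). Its density is guaranteed to be at
#' least half the optimum weighted densest-subgraph density.
#'
#' @inheritParams greedy_peel
#' @return Character vector of node identifiers.
#' @export
greedy_densest <- function(g, convention = c("edge_sum", "volume")) {
  convention <- match.arg(convention)
  tr <- greedy_peel(g, convention)
  peel_snapshot(tr, which.max(tr$density))
}

#' V-Greedy: peeling with a small-cut correction factor
#'
#' Like [greedy_densest()], but the selection criterion is
#' `density + 2 * density / n_nodes`. The correction term rewards smaller
#' candidates just enough that, when two dense components of nearly equal
#' density are joined by a light edge, a single component is returned
#' instead of the weakly connected union. Because the top-k problem demands
#' connected subgraphs, the criterion is evaluated on every connected
#' component arising in any peeling snapshot (an O(|V|)-sized laminar
#' family, enumerated by replaying the peel backwards with a union-find)
#' and the maximum-score component is returned; ties prefer the earliest
#' (largest) snapshot.
#'
#' @inheritParams greedy_peel
#' @return Character vector of node identifiers (a connected set).
#' @examples
#' # two unit-weight K5s joined by one light edge: returns a single K5
#' @export
v_greedy <- function(g, convention = c("edge_sum", "volume")) {
  convention <- match.arg(convention)
  gi <- graph_index(as_weighted_graph(g))
  core <- peel_core(gi)
  st <- peel_component_states(gi, core$order)
  # reverse step s maps to forward snapshot n - s + 1: scanning s upwards
  # with >= lands ties on the largest s, i.e. the earliest snapshot
  best <- 1L
  for (s in seq_along(st$score)) {
    if (st$score[s] >= st$score[best]) best <- s
  }
  materialize_component(gi, core$order, st$step[best], st$anchor[best])
}
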
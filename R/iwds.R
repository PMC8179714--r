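#' Iterative Weighted Dense Subgraphs (IWDS)
#'
#' Step 2 of the pipeline: mine k overlapping dense connected subgraphs
#' from a weighted graph (typically an alignment graph). The first
#' subgraph is `v_greedy(g)`. Each later iteration restricts the graph
#' around the already covered node set `C` (the union of the subgraphs
#' found so far) and re-runs V-Greedy:
#'
#' * if `|C| <= f * |V|` the restriction keeps the `ceiling(alpha * |C|)`
#'   covered nodes of highest weighted degree in the *full* graph and
#'   drops the remaining covered nodes;
#' * if `|C| > f * |V|` it drops the `ceiling((1 - alpha) * |C|)` covered
#'   nodes of lowest weighted degree.
#'
#' Uncovered nodes are always retained, so small `alpha` forces novel
#' regions while large `alpha` permits overlap. Candidates equal to an
#' earlier subgraph are replaced by walking the peeling trace to the next
#' best-scoring distinct connected snapshot; if no distinct subgraph can
#' be found within `max_retries` attempts the solution is truncated with a
#' warning (never silently duplicated).
#'
#' @param g A weighted graph (`weighted_graph`, edge-list data frame, or an
#'   [build_alignment_graph()] result).
#' @param k Number of subgraphs requested (positive integer).
#' @param alpha Fraction in (0, 1] of covered nodes retained (Case 1) or
#'   complement of the fraction dropped (Case 2).
#' @param f Coverage threshold in (0, 1] switching between the two cases.
#' @param lambda Positive weight of the distance term in the reported
#'   objective (does not influence the search).
#' @param convention Density convention (see [graph_density()]).
#' @param max_retries Attempts per iteration to find a distinct subgraph.
#' @return A `dcs_solution`: list with `subgraphs` (list of node-identifier
#'   vectors), per-subgraph `density`, `distance_sum`, `objective`, the
#'   configuration, and `k_requested`/`k_returned`. Has [tidy()],
#'   [glance()], `print()` and [ggplot2::autoplot()] methods.
#' @examples
#' g <- make_synthetic1("er_0.1", seed = 1)$graph
#' sol <- iwds(g, k = 5, alpha = 0.5)
#' glance(sol)
#' @export
iwds <- function(g, k, alpha = 0.5, f = 0.5, lambda = 1,
                 convention = c("edge_sum", "volume"), max_retries = 10L) {
  convention <- match.arg(convention)
  if (!(is.numeric(k) && length(k) == 1 && k >= 1 && k == floor(k))) {
    stop("`k` must be a positive integer", call. = FALSE)
  }
  stopifnot(alpha > 0, alpha <= 1, f > 0, f <= 1, lambda > 0,
            max_retries >= 1)
  g <- as_weighted_graph(g)
  if (length(g$nodes) == 0) stop("graph has no nodes", call. = FALSE)

  full_vol <- stats::setNames(node_volumes(g)$volume, g$nodes)
  subgraphs <- list()
  warnings <- character()

  for (i in seq_len(k)) {
    gi <- if (i == 1) g else {
      restrict_for_iteration(g, covered = unique(unlist(subgraphs)),
                             alpha = alpha, f = f, full_volumes = full_vol)
    }
    if (length(gi$nodes) == 0) {
      warnings <- c(warnings, sprintf(
        "iteration %d: restricted graph is empty; solution truncated", i))
      break
    }
    cand <- ensure_distinct(gi, previous = subgraphs,
                            max_retries = max_retries)
    if (is.null(cand)) {
      warnings <- c(warnings, sprintf(
        "iteration %d: no distinct connected subgraph found within %d attempts; solution truncated",
        i, max_retries))
      break
    }
    subgraphs[[i]] <- cand
  }

  if (length(subgraphs) < k) {
    warning(paste(warnings, collapse = "; "), call. = FALSE)
  }
  new_dcs_solution(subgraphs, g, k_requested = k, alpha = alpha, f = f,
                   lambda = lambda, convention = convention,
                   warnings = warnings)
}

#' Restrict a graph around the covered node set
#'
#' The per-iteration restriction used by [iwds()] (exported for inspection
#' and testing). Covered-node ranking uses the weighted degree in the full
#' graph; ties break by node order. Uncovered nodes are always retained.
#'
#' @param g Weighted graph.
#' @param covered Character vector of covered nodes (may be empty).
#' @param alpha,f As in [iwds()].
#' @param full_volumes Optional named volume vector to avoid recomputation.
#' @return The restricted `weighted_graph`.
#' @export
restrict_for_iteration <- function(g, covered, alpha, f,
                                   full_volumes = NULL) {
  g <- as_weighted_graph(g)
  covered <- sort_nodes(unique(as.character(covered)))
  if (length(covered) == 0) return(g)
  check_nodes_in(g, covered, "covered set")
  stopifnot(alpha > 0, alpha <= 1, f > 0, f <= 1)
  vol <- full_volumes %||% stats::setNames(node_volumes(g)$volume, g$nodes)
  cv <- vol[covered]
  n_cov <- length(covered)
  # covered, ranked by weighted degree descending, node-order tie-break
  ranked <- covered[order(-cv, seq_len(n_cov), method = "radix")]
  if (n_cov <= f * length(g$nodes)) {
    keep_cov <- ranked[seq_len(min(n_cov, ceiling(alpha * n_cov)))]
  } else {
    n_drop <- min(n_cov, ceiling((1 - alpha) * n_cov))
    keep_cov <- if (n_drop == n_cov) character() else
      ranked[seq_len(n_cov - n_drop)]
  }
  keep <- c(setdiff(g$nodes, covered), keep_cov)
  if (length(keep) == 0) {
    return(weighted_graph(NULL))
  }
  induced_subgraph_w(g, keep)
}

# walk the peeling component family by decreasing V-Greedy score (ties to
# the earliest snapshot, as in v_greedy); return the best candidate whose
# node set differs from every previous subgraph, or NULL on exhaustion.
# Component states are pairwise distinct sets, so at most |previous| + 1
# candidates ever need materialising.
ensure_distinct <- function(g, previous, max_retries) {
  gi <- if (is.list(g) && !is.null(g$adj_n)) g else graph_index(g)
  core <- peel_core(gi)
  st <- peel_component_states(gi, core$order)
  ord <- order(-st$score, -st$step, method = "radix")
  tries <- 0
  for (idx in ord) {
    if (tries >= max_retries) break
    tries <- tries + 1
    comp <- materialize_component(gi, core$order, st$step[idx],
                                  st$anchor[idx])
    dup <- any(vapply(previous, function(p) {
      length(p) == length(comp) && setequal(p, comp)
    }, TRUE))
    if (!dup) return(comp)
  }
  NULL
}

new_dcs_solution <- function(subgraphs, g, k_requested, alpha, f, lambda,
                             convention, warnings = character()) {
  dens <- vapply(subgraphs, function(Z) graph_density(g, Z, convention), 0)
  dsum <- distance_sum(subgraphs)
  structure(
    list(subgraphs = subgraphs,
         density = dens,
         density_sum = sum(dens),
         distance_sum = dsum,
         objective = sum(dens) + lambda * dsum,
         k_requested = k_requested,
         k_returned = length(subgraphs),
         alpha = alpha, f = f, lambda = lambda,
         convention = convention,
         warnings = warnings),
    class = "dcs_solution"
  )
}

#' @export
print.dcs_solution <- function(x, ...) {
  cat("<dcs_solution> ", x$k_returned, " of ", x$k_requested,
      " subgraphs (alpha = ", x$alpha, ", ", x$convention, " density)\n",
      "  density sum ", format(x$density_sum, digits = 6),
      ", distance sum ", format(x$distance_sum, digits = 6),
      ", objective ", format(x$objective, digits = 6), "\n", sep = "")
  if (length(x$warnings) > 0) cat("  warnings:", length(x$warnings), "\n")
  invisible(x)
}

#' Tidy a mined solution
#'
#' @param x A `dcs_solution`.
#' @param ... Unused.
#' @return Tibble with one row per subgraph: `subgraph`, `size`, `density`
#'   and a `nodes` list-column.
#' @export
tidy.dcs_solution <- function(x, ...) {
  tibble::tibble(subgraph = seq_len(x$k_returned),
                 size = lengths(x$subgraphs),
                 density = x$density,
                 nodes = x$subgraphs)
}

#' One-row summary of a mined solution
#'
#' @param x A `dcs_solution`.
#' @param ... Unused.
#' @return One-row tibble: `k_requested`, `k_returned`, `density_sum`,
#'   `distance_sum`, `objective`, `alpha`, `f`, `lambda`, `convention`.
#' @export
glance.dcs_solution <- function(x, ...) {
  tibble::tibble(k_requested = x$k_requested, k_returned = x$k_returned,
                 density_sum = x$density_sum,
                 distance_sum = x$distance_sum,
                 objective = x$objective,
                 alpha = x$alpha, f = x$f, lambda = x$lambda,
                 convention = x$convention)
}

#' Plot per-subgraph density and size of a solution
#'
#' @param object A `dcs_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dcs_solution <- function(object, ...) {
  td <- tidy(object)
  td$nodes <- NULL
  long <- tidyr::pivot_longer(td, c("size", "density"),
                              names_to = "measure", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$subgraph), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "subgraph", y = NULL,
                  title = "IWDS solution: subgraph size and weighted density")
}
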
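#' Planted-clique benchmark instances
#'
#' Seeded generators for the four synthetic benchmark families used to
#' validate the miner. Each instance plants k = 5 weighted 30-node cliques
#' (intra-clique weights ~ U\[0.8, 1\]) over a 100-node random background
#' (weights ~ U\[0, 0.5\]) and adds 50 random clique-to-background bridge
#' edges (weights ~ U\[0, 0.5\]):
#'
#' * `make_synthetic1()`: the five cliques are pairwise disjoint
#'   (250 nodes in total);
#' * `make_synthetic3()`: each clique has 20 exclusive nodes and shares a
#'   block of 5 nodes with each cyclic neighbour (125 planted nodes);
#' * `make_synthetic2()` / `make_synthetic4()`: the disjoint / overlapping
#'   instance with the noise procedure of [add_noise()] applied.
#'
#' Background kinds: Erdos-Renyi with p = 0.1 (`"er_0.1"`), Erdos-Renyi
#' with p = 0.2 (`"er_0.2"`), or Barabasi-Albert preferential attachment
#' with m = 10 edges per new node (`"ba"`). Generation is fully
#' deterministic given `seed`.
#'
#' @param background One of `"er_0.1"`, `"er_0.2"`, `"ba"`.
#' @param seed Integer RNG seed.
#' @param noise_level Perturbation level in (0, 1) for the noisy families.
#' @return A `dcs_benchmark`: list with `graph` (a [weighted_graph()]),
#'   `ground_truth` (list of 5 node sets), `background_kind`,
#'   `noise_level`, `seed` and, after noise, a `perturbed` provenance
#'   tibble.
#' @examples
#' inst <- make_synthetic1("er_0.1", seed = 42)
#' lengths(inst$ground_truth)
#' @name synthetic_benchmarks
NULL

planted_backgrounds <- c("er_0.1", "er_0.2", "ba")

#' @rdname synthetic_benchmarks
#' @export
make_synthetic1 <- function(background = planted_backgrounds, seed = 1L) {
  background <- match.arg(background)
  withr::with_seed(as.integer(seed), {
    planted <- sprintf("p%03d", 1:150)
    truth <- split(planted, rep(1:5, each = 30))
    pair_idx <- purrr::map(truth, clique_pairs)
    build_planted_instance(truth, dplyr::bind_rows(pair_idx),
                           background, seed, family = "synthetic1")
  })
}

#' @rdname synthetic_benchmarks
#' @export
make_synthetic3 <- function(background = planted_backgrounds, seed = 1L) {
  background <- match.arg(background)
  withr::with_seed(as.integer(seed), {
    exclusive <- split(sprintf("p%03d", 1:100), rep(1:5, each = 20))
    shared <- split(sprintf("s%02d", 1:25), rep(1:5, each = 5))
    # clique i = 20 exclusive + shared block i + shared block i+1 (cyclic)
    truth <- purrr::map(1:5, function(i) {
      sort_nodes(c(exclusive[[i]], shared[[i]], shared[[i %% 5 + 1]]))
    })
    pairs <- dplyr::distinct(dplyr::bind_rows(purrr::map(truth, clique_pairs)))
    build_planted_instance(truth, pairs, background, seed,
                           family = "synthetic3")
  })
}

#' @rdname synthetic_benchmarks
#' @export
make_synthetic2 <- function(background = planted_backgrounds,
                            noise_level = 0.05, seed = 1L) {
  add_noise(make_synthetic1(background, seed), level = noise_level,
            seed = as.integer(seed) + 1L)
}

#' @rdname synthetic_benchmarks
#' @export
make_synthetic4 <- function(background = planted_backgrounds,
                            noise_level = 0.05, seed = 1L) {
  add_noise(make_synthetic3(background, seed), level = noise_level,
            seed = as.integer(seed) + 1L)
}

clique_pairs <- function(nodes) {
  nodes <- sort_nodes(nodes)
  cmb <- utils::combn(nodes, 2)
  tibble::tibble(from = cmb[1, ], to = cmb[2, ])
}

# assumes the RNG state is already seeded by the caller
build_planted_instance <- function(truth, clique_edges, background, seed,
                                   family) {
  clique_edges$weight <- stats::runif(nrow(clique_edges), 0.8, 1)
  bg_nodes <- sprintf("b%03d", 1:100)
  bg <- switch(background,
    "er_0.1" = igraph::sample_gnp(100, 0.1),
    "er_0.2" = igraph::sample_gnp(100, 0.2),
    "ba" = igraph::sample_pa(100, power = 1, m = 10, directed = FALSE)
  )
  bge <- igraph::as_edgelist(bg, names = FALSE)
  bg_edges <- tibble::tibble(from = bg_nodes[bge[, 1]],
                             to = bg_nodes[bge[, 2]],
                             weight = stats::runif(nrow(bge), 0, 0.5))
  planted <- sort_nodes(unique(unlist(truth)))
  # 50 distinct planted-to-background bridges (no such edge pre-exists)
  np <- length(planted)
  bridge_idx <- sample.int(np * 100, 50)
  bridge_edges <- tibble::tibble(
    from = planted[(bridge_idx - 1) %% np + 1],
    to = bg_nodes[(bridge_idx - 1) %/% np + 1],
    weight = stats::runif(50, 0, 0.5)
  )
  graph <- weighted_graph(
    dplyr::bind_rows(clique_edges, bg_edges, bridge_edges),
    nodes = c(planted, bg_nodes)
  )
  structure(
    list(graph = graph, ground_truth = truth,
         background_kind = background, noise_level = 0,
         seed = as.integer(seed), family = family, perturbed = NULL),
    class = "dcs_benchmark"
  )
}

#' @export
print.dcs_benchmark <- function(x, ...) {
  cat("<dcs_benchmark> ", x$family, " (", x$background_kind,
      ", noise ", x$noise_level, ", seed ", x$seed, "): ",
      length(x$graph$nodes), " nodes, ", nrow(x$graph$edges), " edges, ",
      length(x$ground_truth), " planted subgraphs\n", sep = "")
  invisible(x)
}

#' Perturb a benchmark instance
#'
#' The controlled noise procedure: `ceiling(level * |E|)` node pairs are
#' sampled uniformly without replacement from all pairs of instance nodes.
#' A sampled pair that co-occurs in a planted clique and currently shares
#' an edge has that edge's weight redrawn from U\[0, 0.5\]; any other pair
#' gains an edge with weight ~ U\[0.8, 1\] if none exists (existing
#' non-clique edges are left untouched). Ground truth is unchanged; every
#' perturbed pair is recorded in the `perturbed` provenance tibble.
#'
#' @param instance A noiseless `dcs_benchmark`.
#' @param level Noise level in (0, 1).
#' @param seed Integer RNG seed.
#' @return The perturbed `dcs_benchmark`.
#' @export
add_noise <- function(instance, level, seed = 1L) {
  stopifnot(inherits(instance, "dcs_benchmark"))
  if (!(is.numeric(level) && length(level) == 1 && level > 0 && level < 1)) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (instance$noise_level != 0) {
    stop("`instance` has already been perturbed", call. = FALSE)
  }
  g <- instance$graph
  nodes <- g$nodes
  n <- length(nodes)
  m <- ceiling(level * nrow(g$edges))
  withr::with_seed(as.integer(seed), {
    pair_id <- sample(choose(n, 2), m)
    # decode linear index of unordered pair (i < j), blocks ordered by i
    cum <- cumsum(n - seq_len(n - 1))
    i <- findInterval(pair_id - 1L, c(0, cum), rightmost.closed = FALSE)
    j <- i + (pair_id - c(0, cum)[i])
    u <- nodes[i]; v <- nodes[j]

    ek <- paste(g$edges$from, g$edges$to, sep = "\r")
    wmap <- stats::setNames(g$edges$weight, ek)
    truth_member <- purrr::map(instance$ground_truth, as.character)
    same_clique <- vapply(seq_len(m), function(s) {
      any(vapply(truth_member,
                 function(tm) u[s] %in% tm && v[s] %in% tm, TRUE))
    }, TRUE)
    key <- ifelse(node_gt(u, v), paste(v, u, sep = "\r"),
                  paste(u, v, sep = "\r"))
    has_edge <- key %in% ek

    reweight <- same_clique & has_edge
    action <- rep("unchanged", m)
    if (any(reweight)) {
      wmap[key[reweight]] <- stats::runif(sum(reweight), 0, 0.5)
      action[reweight] <- "reweighted"
    }
    addit <- !same_clique & !has_edge
    new_edges <- NULL
    if (any(addit)) {
      new_edges <- tibble::tibble(
        from = u[addit], to = v[addit],
        weight = stats::runif(sum(addit), 0.8, 1))
      action[addit] <- "added"
    }
  })
  edges <- tibble::tibble(from = g$edges$from, to = g$edges$to,
                          weight = unname(wmap[ek]))
  if (!is.null(new_edges)) edges <- dplyr::bind_rows(edges, new_edges)
  out <- instance
  out$graph <- weighted_graph(edges, nodes = nodes)
  out$noise_level <- level
  out$family <- sub("synthetic1", "synthetic2",
                    sub("synthetic3", "synthetic4", instance$family))
  out$perturbed <- tibble::tibble(from = u, to = v,
                                  same_clique = same_clique,
                                  action = action)
  out
}
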
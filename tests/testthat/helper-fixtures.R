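# Shared fixtures and independent oracles, all built in code.

unit_clique <- function(nodes, weight = 1) {
  cmb <- utils::combn(as.character(nodes), 2)
  weighted_graph(tibble::tibble(from = cmb[1, ], to = cmb[2, ],
                                weight = weight))
}

# two unit-weight K5s joined by a single light edge
two_k5_graph <- function(bridge_weight = 0.1) {
  a <- paste0("a", 1:5)
  b <- paste0("b", 1:5)
  ca <- utils::combn(a, 2); cb <- utils::combn(b, 2)
  weighted_graph(tibble::tibble(
    from = c(ca[1, ], cb[1, ], "a1"),
    to = c(ca[2, ], cb[2, ], "b1"),
    weight = c(rep(1, 20), bridge_weight)
  ))
}

random_weighted_graph <- function(n, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    cmb <- utils::combn(sprintf("n%02d", seq_len(n)), 2)
    keep <- stats::runif(ncol(cmb)) < p
    if (!any(keep)) keep[1] <- TRUE
    weighted_graph(tibble::tibble(from = cmb[1, keep], to = cmb[2, keep],
                                  weight = stats::runif(sum(keep))),
                   nodes = sprintf("n%02d", seq_len(n)))
  })
}

# physical and conceptual edge lists over a shared node universe
random_dual_network <- function(n, p_phys = 0.4, p_conc = 0.4, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%02d", seq_len(n))
    cmb <- utils::combn(nodes, 2)
    kp <- stats::runif(ncol(cmb)) < p_phys
    kc <- stats::runif(ncol(cmb)) < p_conc
    if (!any(kp)) kp[1] <- TRUE
    if (!any(kc)) kc[1] <- TRUE
    list(
      physical = weighted_graph(
        tibble::tibble(from = cmb[1, kp], to = cmb[2, kp]), nodes = nodes),
      conceptual = weighted_graph(
        tibble::tibble(from = cmb[1, kc], to = cmb[2, kc],
                       weight = stats::runif(sum(kc))), nodes = nodes)
    )
  })
}

# exhaustive weighted densest-subgraph density via subset enumeration;
# independent of the peeling implementation
brute_force_densest_density <- function(g, convention = "edge_sum") {
  g <- as_weighted_graph(g)
  n <- length(g$nodes)
  stopifnot(n <= 14)
  ei <- match(g$edges$from, g$nodes)
  ej <- match(g$edges$to, g$nodes)
  S <- seq_len(2^n - 1)
  W <- numeric(length(S))
  for (r in seq_along(ei)) {
    m <- bitwOr(bitwShiftL(1L, ei[r] - 1L), bitwShiftL(1L, ej[r] - 1L))
    inside <- bitwAnd(S, m) == m
    W[inside] <- W[inside] + g$edges$weight[r]
  }
  size <- rowSums(outer(S, seq_len(n) - 1L,
                        function(s, b) bitwAnd(s, bitwShiftL(1L, b)) > 0))
  best <- max(W / size)
  if (convention == "volume") 2 * best else best
}

# the toy 3-node dual network used throughout the alignment examples
toy_dual <- function() {
  list(
    physical = data.frame(from = c("a", "b", "a"), to = c("b", "c", "c")),
    conceptual = data.frame(from = c("a", "b"), to = c("b", "c"),
                            weight = c(0.5, 0.7))
  )
}
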
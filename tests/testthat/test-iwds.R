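test_that("k = 1 reduces to V-Greedy", {
  g <- two_k5_graph(0.1)
  sol <- iwds(g, k = 1, alpha = 0.5)
  expect_equal(sol$k_returned, 1)
  expect_setequal(sol$subgraphs[[1]], v_greedy(g))
  expect_equal(sol$distance_sum, 0)
  expect_error(iwds(g, k = 0), "positive integer")
})

test_that("two bridged cliques are mined as two disjoint subgraphs", {
  g <- two_k5_graph(0.1)
  sol <- iwds(g, k = 2, alpha = 0.5)
  expect_equal(sol$k_returned, 2)
  expect_setequal(unlist(sol$subgraphs), g$nodes)
  expect_equal(sol$distance_sum, 2)
  expect_equal(sol$density, c(2, 2))
  expect_equal(sol$objective, 4 + 2)
})

test_that("coverage restriction keeps the stated covered-node counts", {
  nodes <- sprintf("n%03d", 1:100)
  # a ring so every node has equal volume; ranking falls back to node order
  g <- weighted_graph(tibble::tibble(from = nodes,
                                     to = nodes[c(2:100, 1)], weight = 1))
  expect_equal(restrict_for_iteration(g, character(), 0.5, 0.5)$nodes,
               g$nodes)

  # Case 1: |C| = 40 <= f|V| = 50; keep ceiling(0.25 * 40) = 10 covered
  r1 <- restrict_for_iteration(g, nodes[1:40], alpha = 0.25, f = 0.5)
  expect_length(r1$nodes, 70)
  expect_length(intersect(r1$nodes, nodes[1:40]), 10)
  expect_true(all(nodes[41:100] %in% r1$nodes))

  # Case 2: |C| = 80 > f|V| = 50; drop ceiling(0.25 * 80) = 20 covered
  r2 <- restrict_for_iteration(g, nodes[1:80], alpha = 0.75, f = 0.5)
  expect_length(r2$nodes, 80)
  expect_length(intersect(r2$nodes, nodes[1:80]), 60)
})

test_that("covered nodes are ranked by weighted degree in the full graph", {
  # hub has the largest volume; with alpha keeping one covered node it stays
  g <- weighted_graph(tibble::tibble(
    from = c("hub", "hub", "hub", "u1", "u2"),
    to = c("u1", "u2", "u3", "u2", "u3"),
    weight = c(1, 1, 1, 0.1, 0.1)))
  r <- restrict_for_iteration(g, c("hub", "u1", "u2"), alpha = 0.05, f = 1)
  expect_true("hub" %in% r$nodes)
  expect_false(any(c("u1", "u2") %in% r$nodes))
  expect_true("u3" %in% r$nodes)
})

test_that("duplicate candidates fall back to distinct runners-up or truncate", {
  g <- two_k5_graph(0.9)
  # k = 3 on two cliques: third subgraph must differ from both K5s
  sol <- suppressWarnings(iwds(g, k = 3, alpha = 1, f = 1))
  keys <- sapply(sol$subgraphs, function(s) paste(sort(s), collapse = ","))
  expect_equal(length(unique(keys)), sol$k_returned)

  solo <- weighted_graph(NULL, nodes = "only")
  expect_warning(res <- iwds(solo, k = 2), "truncated")
  expect_equal(res$k_returned, 1)
})

test_that("subgraphs are distinct, connected, and runs are reproducible", {
  inst <- make_synthetic1("ba", seed = 11)
  sol1 <- iwds(inst$graph, k = 5, alpha = 0.25)
  sol2 <- iwds(inst$graph, k = 5, alpha = 0.25)
  expect_identical(sol1$subgraphs, sol2$subgraphs)
  keys <- sapply(sol1$subgraphs, function(s) paste(sort(s), collapse = ","))
  expect_equal(anyDuplicated(keys), 0)
  for (s in sol1$subgraphs) {
    expect_true(is_connected_set(inst$graph, s))
  }
})

test_that("noiseless disjoint cliques are recovered exactly", {
  for (a in c(0.05, 0.9)) {
    inst <- make_synthetic1("er_0.2", seed = 21)
    sol <- iwds(inst$graph, k = 5, alpha = a)
    ev <- best_match_f1(inst$ground_truth, sol$subgraphs)
    expect_equal(ev$f1_td, 1)
    expect_equal(ev$f1_dt, 1)
  }
})

test_that("larger alpha yields denser, more overlapping solutions", {
  # statistical trend over seeded overlapping-clique instances
  alphas <- c(0.05, 0.25, 0.75)
  means <- sapply(alphas, function(a) {
    res <- sapply(1:21, function(s) {
      inst <- make_synthetic3(c("er_0.1", "er_0.2", "ba")[(s - 1) %% 3 + 1],
                              seed = 7000 + s)
      sol <- suppressWarnings(iwds(inst$graph, k = 5, alpha = a))
      c(sol$density_sum, sol$distance_sum)
    })
    rowMeans(res)
  })
  expect_true(all(diff(means[1, ]) >= 0)) # mean density non-decreasing
  expect_true(all(diff(means[2, ]) <= 0)) # mean distance non-increasing
})

test_that("solution accessors tidy and glance are consistent", {
  inst <- make_synthetic1("er_0.1", seed = 5)
  sol <- iwds(inst$graph, k = 3, alpha = 0.5)
  td <- tidy(sol)
  expect_equal(nrow(td), 3)
  expect_equal(td$size, lengths(sol$subgraphs))
  gl <- glance(sol)
  expect_equal(gl$density_sum, sum(td$density))
  expect_equal(gl$objective, gl$density_sum + gl$lambda * gl$distance_sum)
  p <- autoplot(sol)
  expect_s3_class(p, "ggplot")
})
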
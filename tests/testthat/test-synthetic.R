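test_that("disjoint planted instances have the forced structure", {
  inst <- make_synthetic1("er_0.1", seed = 9)
  expect_length(inst$graph$nodes, 250)
  expect_length(inst$ground_truth, 5)
  expect_equal(lengths(inst$ground_truth), rep(30, 5), ignore_attr = TRUE)
  expect_length(unique(unlist(inst$ground_truth)), 150)
  expect_equal(inst$noise_level, 0)

  e <- inst$graph$edges
  planted <- unlist(inst$ground_truth)
  clique_edge <- e$from %in% planted & e$to %in% planted
  expect_equal(sum(clique_edge), 5 * choose(30, 2))
  expect_true(all(e$weight[clique_edge] >= 0.8 & e$weight[clique_edge] <= 1))
  expect_true(all(e$weight[!clique_edge] >= 0 & e$weight[!clique_edge] <= 0.5))

  bg <- e[!clique_edge, ]
  bridge <- xor(bg$from %in% planted, bg$to %in% planted)
  expect_equal(sum(bridge), 50)
  # ER(p = 0.1) background edge count within 4 sigma of 495
  n_bg <- sum(!bridge)
  expect_lt(abs(n_bg - 0.1 * choose(100, 2)),
            4 * sqrt(choose(100, 2) * 0.1 * 0.9))
})

test_that("background node identifiers never overlap planted ones", {
  for (bg in c("er_0.1", "er_0.2", "ba")) {
    inst <- make_synthetic1(bg, seed = 2)
    planted <- unique(unlist(inst$ground_truth))
    expect_length(intersect(planted, setdiff(inst$graph$nodes, planted)), 0)
    expect_length(setdiff(inst$graph$nodes, planted), 100)
  }
})

test_that("overlapping instances share cyclic 5-node blocks", {
  inst <- make_synthetic3("ba", seed = 13)
  truth <- inst$ground_truth
  expect_equal(lengths(truth), rep(30, 5), ignore_attr = TRUE)
  expect_length(unique(unlist(truth)), 125)
  for (i in 1:5) {
    nxt <- i %% 5 + 1
    skip2 <- (i + 1) %% 5 + 1
    expect_length(intersect(truth[[i]], truth[[nxt]]), 5)
    expect_length(intersect(truth[[i]], truth[[skip2]]), 0)
    expect_equal(set_distance(truth[[i]], truth[[nxt]]), 2 - 25 / 900)
  }
  # shared blocks are fully wired: each planted set is a clique
  e <- inst$graph$edges
  key <- paste(e$from, e$to)
  for (i in 1:5) {
    cmb <- utils::combn(sort(truth[[i]]), 2)
    expect_true(all(paste(cmb[1, ], cmb[2, ]) %in% key))
  }
})

test_that("noiseless planted densities bracket the benchmark expectation", {
  inst <- make_synthetic1("er_0.2", seed = 17)
  dens <- sapply(inst$ground_truth,
                 function(z) graph_density(inst$graph, z))
  expect_true(all(dens >= 0.8 * 29 / 2 & dens <= 1.0 * 29 / 2))
  expect_gte(sum(dens), 58)
  expect_lte(sum(dens), 72.5)
})

test_that("generators are seed-deterministic", {
  a <- make_synthetic3("er_0.1", seed = 33)
  b <- make_synthetic3("er_0.1", seed = 33)
  expect_identical(a$graph$edges, b$graph$edges)
  expect_identical(a$ground_truth, b$ground_truth)
  c_ <- make_synthetic3("er_0.1", seed = 34)
  expect_false(identical(a$graph$edges, c_$graph$edges))

  n1 <- make_synthetic2("er_0.1", 0.1, seed = 33)
  n2 <- make_synthetic2("er_0.1", 0.1, seed = 33)
  expect_identical(n1$graph$edges, n2$graph$edges)
})

test_that("the noise procedure perturbs the stated number of pairs", {
  inst <- make_synthetic1("er_0.1", seed = 3)
  lvl <- 0.1
  noisy <- add_noise(inst, lvl, seed = 99)
  m <- ceiling(lvl * nrow(inst$graph$edges))
  expect_equal(nrow(noisy$perturbed), m)
  expect_identical(noisy$ground_truth, inst$ground_truth)
  expect_equal(noisy$noise_level, lvl)

  p <- noisy$perturbed
  expect_setequal(unique(p$action),
                  intersect(c("reweighted", "added", "unchanged"),
                            unique(p$action)))
  # intra-clique reweights leave the planted interval
  ek <- paste(noisy$graph$edges$from, noisy$graph$edges$to)
  wmap <- stats::setNames(noisy$graph$edges$weight, ek)
  rw <- p[p$action == "reweighted", ]
  if (nrow(rw) > 0) {
    keys <- ifelse(rw$from < rw$to, paste(rw$from, rw$to),
                   paste(rw$to, rw$from))
    expect_true(all(wmap[keys] <= 0.5))
  }
  ad <- p[p$action == "added", ]
  if (nrow(ad) > 0) {
    keys <- ifelse(ad$from < ad$to, paste(ad$from, ad$to),
                   paste(ad$to, ad$from))
    expect_true(all(wmap[keys] >= 0.8))
  }
  expect_error(add_noise(inst, 0), "between 0 and 1")
  expect_error(add_noise(noisy, 0.1), "already")
})

test_that("sampled noise pairs are distinct and correctly classified", {
  inst <- make_synthetic3("ba", seed = 8)
  noisy <- add_noise(inst, 0.15, seed = 77)
  p <- noisy$perturbed
  expect_equal(anyDuplicated(paste(pmin(p$from, p$to), pmax(p$from, p$to))), 0)
  in_clique <- function(u, v) {
    any(sapply(inst$ground_truth, function(tm) u %in% tm && v %in% tm))
  }
  idx <- sample(nrow(p), 25)
  expect_equal(p$same_clique[idx],
               mapply(in_clique, p$from[idx], p$to[idx]),
               ignore_attr = TRUE)
})
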
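test_that("toy dual network aligns with direct and path-derived edges", {
  td <- toy_dual()
  ag <- build_alignment_graph(td$physical, td$conceptual, delta = 3)
  expect_s3_class(ag, "alignment_graph")
  expect_equal(nrow(ag), 3)
  got <- ag[order(ag$from, ag$to), ]
  expect_equal(got$from, c("a", "a", "b"))
  expect_equal(got$to, c("b", "c", "c"))
  expect_equal(got$weight[got$from == "a" & got$to == "b"], 0.5)
  expect_equal(got$weight[got$from == "b" & got$to == "c"], 0.7)
  # a-c: physical edge, conceptual path a-b-c, mean of 0.5 and 0.7
  expect_equal(got$weight[got$from == "a" & got$to == "c"], 0.6)
  expect_equal(got$provenance[got$from == "a" & got$to == "c"], "path")
  expect_setequal(got$provenance[got$weight != 0.6], "direct")
})

test_that("delta = 1 keeps only pairs adjacent in both networks", {
  td <- toy_dual()
  ag <- build_alignment_graph(td$physical, td$conceptual, delta = 1)
  expect_equal(nrow(ag), 2)
  expect_setequal(paste(ag$from, ag$to), c("a b", "b c"))
  expect_setequal(ag$provenance, "direct")
})

test_that("degenerate and invalid seed-pair lists are handled", {
  td <- toy_dual()
  one <- data.frame(conceptual = "a", physical = "a")
  ag <- build_alignment_graph(td$physical, td$conceptual, one, delta = 3)
  expect_equal(nrow(ag), 0)
  expect_equal(attr(ag, "align_nodes"), "a")

  bad <- data.frame(conceptual = c("a", "zz"), physical = c("a", "a"))
  expect_error(
    build_alignment_graph(td$physical, td$conceptual, bad, delta = 3),
    "unknown nodes.*zz")
  expect_error(
    build_alignment_graph(td$physical, td$conceptual,
                          data.frame(conceptual = character(),
                                     physical = character()), delta = 3),
    "empty")
  expect_error(
    build_alignment_graph(td$physical, td$conceptual, delta = 0),
    "positive integer")
})

test_that("minimum-hop conceptual paths report hop count and mean weight", {
  gc_ <- weighted_graph(data.frame(from = c("u", "x"), to = c("x", "v"),
                                   weight = c(0.4, 0.8)))
  expect_equal(conceptual_shortest_path(gc_, "u", "x", 3),
               list(hops = 1L, mean_weight = 0.4))
  expect_equal(conceptual_shortest_path(gc_, "u", "v", 3),
               list(hops = 2L, mean_weight = 0.6))
  expect_null(conceptual_shortest_path(gc_, "u", "v", 2))
  disc <- weighted_graph(data.frame(from = "u", to = "x", weight = 1),
                         nodes = c("u", "x", "v"))
  expect_null(conceptual_shortest_path(disc, "u", "v", 10))
})

test_that("tied minimum-hop paths use the lexicographically smallest route", {
  # u-a-v (mean 0.9) and u-b-v (mean 0.1) tie at 2 hops; route via a wins
  gc_ <- weighted_graph(data.frame(from = c("u", "a", "u", "b"),
                                   to = c("a", "v", "b", "v"),
                                   weight = c(0.9, 0.9, 0.1, 0.1)))
  expect_equal(conceptual_shortest_path(gc_, "u", "v", 5)$mean_weight, 0.9)
})

test_that("alignment edges always project to physical edges", {
  for (s in 1:6) {
    dn <- random_dual_network(12, seed = 200 + s)
    ag <- build_alignment_graph(dn$physical, dn$conceptual, delta = 4)
    pk <- paste(dn$physical$edges$from, dn$physical$edges$to)
    if (nrow(ag) > 0) {
      expect_true(all(paste(ag$from, ag$to) %in% pk))
    }
  }
})

test_that("delta = 1 alignment equals the weighted intersection graph", {
  for (s in 1:6) {
    dn <- random_dual_network(12, seed = 300 + s)
    ag <- build_alignment_graph(dn$physical, dn$conceptual, delta = 1)
    pk <- paste(dn$physical$edges$from, dn$physical$edges$to)
    ck <- paste(dn$conceptual$edges$from, dn$conceptual$edges$to)
    both <- intersect(pk, ck)
    expect_setequal(paste(ag$from, ag$to), both)
    cw <- stats::setNames(dn$conceptual$edges$weight, ck)
    expect_equal(ag$weight, unname(cw[paste(ag$from, ag$to)]))
  }
})

test_that("the alignment edge set grows monotonically with delta", {
  for (s in 1:4) {
    dn <- random_dual_network(12, p_phys = 0.3, p_conc = 0.25,
                              seed = 400 + s)
    prev <- character()
    for (delta in 1:5) {
      ag <- build_alignment_graph(dn$physical, dn$conceptual, delta = delta)
      cur <- paste(ag$from, ag$to)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})
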
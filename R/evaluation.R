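#' F1 overlap score of two node sets
#'
#' `2 |A n B| / (|A| + |B|)`, the harmonic mean of precision and recall of
#' one set against the other; symmetric. An arithmetic-mean variant is
#' available for sensitivity checks.
#'
#' @param A,B Non-empty node-identifier vectors (duplicates ignored).
#' @param average `"harmonic"` (standard F1, default) or `"arithmetic"`.
#' @return A number in \[0, 1\]; 1 iff the sets are equal, 0 iff disjoint.
#' @export
f1_score <- function(A, B, average = c("harmonic", "arithmetic")) {
  average <- match.arg(average)
  A <- unique(as.character(A)); B <- unique(as.character(B))
  if (length(A) == 0 || length(B) == 0) {
    stop("F1 is undefined for empty sets", call. = FALSE)
  }
  i <- length(intersect(A, B))
  if (average == "harmonic") {
    2 * i / (length(A) + length(B))
  } else {
    (i / length(A) + i / length(B)) / 2
  }
}

#' Best-matching F1 between ground truth and detected subgraphs
#'
#' The two community-recovery scores used throughout the benchmarks:
#' `F1[t/d]` averages, over detected subgraphs, the F1 of the
#' best-matching ground-truth subgraph (truth to detected); `F1[d/t]`
#' averages, over ground-truth subgraphs, the F1 of the best-matching
#' detected subgraph (detected to truth). Matching is free (many-to-one
#' allowed), so both scores equal 1 exactly when the two families coincide.
#'
#' @param truth,detected Non-empty lists of non-empty node sets.
#' @param average Passed to [f1_score()].
#' @return A `dcs_eval`: list with `f1_td`, `f1_dt` and a per-set `matches`
#'   tibble (`direction`, `index`, `size`, `best_match`, `f1`).
#' @examples
#' best_match_f1(list(1:10, 11:20), list(1:10))
#' @export
best_match_f1 <- function(truth, detected, average = c("harmonic", "arithmetic")) {
  average <- match.arg(average)
  stopifnot(is.list(truth), is.list(detected))
  if (length(truth) == 0 || length(detected) == 0) {
    stop("`truth` and `detected` must be non-empty lists", call. = FALSE)
  }
  f1m <- outer(seq_along(detected), seq_along(truth),
               Vectorize(function(d, t) {
                 f1_score(detected[[d]], truth[[t]], average)
               }))
  td <- tibble::tibble(direction = "truth_to_detected",
                       index = seq_along(detected),
                       size = lengths(purrr::map(detected, unique)),
                       best_match = apply(f1m, 1, which.max),
                       f1 = apply(f1m, 1, max))
  dt <- tibble::tibble(direction = "detected_to_truth",
                       index = seq_along(truth),
                       size = lengths(purrr::map(truth, unique)),
                       best_match = apply(f1m, 2, which.max),
                       f1 = apply(f1m, 2, max))
  structure(list(f1_td = mean(td$f1), f1_dt = mean(dt$f1),
                 matches = dplyr::bind_rows(td, dt)),
            class = "dcs_eval")
}

#' @export
print.dcs_eval <- function(x, ...) {
  cat("<dcs_eval> F1[t/d] = ", format(x$f1_td, digits = 4),
      ", F1[d/t] = ", format(x$f1_dt, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.dcs_eval <- function(x, ...) {
  tibble::tibble(f1_td = x$f1_td, f1_dt = x$f1_dt)
}

#' Summarise a solution against the graph it was mined from
#'
#' Aggregates the table columns reported for every experiment: summed
#' induced density, summed pairwise distance, and the objective.
#'
#' @param solution A `dcs_solution` or a plain list of node sets.
#' @param g The weighted graph the solution lives on.
#' @param lambda Positive distance weight.
#' @param convention Density convention.
#' @return One-row tibble: `k`, `density_sum`, `distance_sum`, `objective`.
#' @export
summarize_solution <- function(solution, g, lambda = 1,
                               convention = c("edge_sum", "volume")) {
  convention <- match.arg(convention)
  subgraphs <- if (inherits(solution, "dcs_solution")) solution$subgraphs
  else solution
  stopifnot(is.list(subgraphs), length(subgraphs) >= 1)
  g <- as_weighted_graph(g)
  dens <- vapply(subgraphs, function(Z) graph_density(g, Z, convention), 0)
  dsum <- distance_sum(subgraphs)
  tibble::tibble(k = length(subgraphs), density_sum = sum(dens),
                 distance_sum = dsum,
                 objective = sum(dens) + lambda * dsum)
}
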
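#' Pairwise distance between two node sets
#'
#' The dissimilarity used to reward non-overlapping solutions:
#' `2 - |A ∩ B|^2 / (|A| |B|)` for distinct sets and 0 for identical sets.
#' It is symmetric, equals 2 exactly for disjoint sets, and always exceeds 1
#' for distinct sets (since `|A ∩ B|^2 <= |A||B|`).
#'
#' @param A,B Non-empty vectors of node identifiers (duplicates ignored).
#' @return A number in `{0} U (1, 2]`.
#' @examples
#' set_distance(1:30, c(1:5, 31:55)) # 30-sets sharing 5 nodes
#' @export
set_distance <- function(A, B) {
  A <- unique(as.character(A))
  B <- unique(as.character(B))
  if (length(A) == 0 || length(B) == 0) {
    stop("set distance is undefined for empty sets", call. = FALSE)
  }
  if (length(A) == length(B) && setequal(A, B)) return(0)
  i <- length(intersect(A, B))
  2 - i^2 / (length(A) * length(B))
}

#' Sum of pairwise distances over a family of node sets
#'
#' @param subgraphs List of non-empty node-identifier vectors.
#' @return Sum of [set_distance()] over all unordered pairs (0 when fewer
#'   than two sets).
#' @export
distance_sum <- function(subgraphs) {
  k <- length(subgraphs)
  if (k < 2) return(0)
  s <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      s <- s + set_distance(subgraphs[[i]], subgraphs[[j]])
    }
  }
  s
}

#' Top-k overlapping DCS objective
#'
#' The quantity maximised by the top-k overlapping densest-subgraph problem:
#' the sum of induced weighted densities of the k subgraphs plus `lambda`
#' times the sum of their pairwise distances.
#'
#' @param subgraphs List of non-empty node sets, each a subset of the nodes
#'   of `g`.
#' @param g The weighted (conceptual) graph.
#' @param lambda Positive trade-off weight for the distance term.
#' @param convention Density convention (see [graph_density()]).
#' @return A single number.
#' @export
solution_objective <- function(subgraphs, g, lambda = 1,
                               convention = c("edge_sum", "volume")) {
  convention <- match.arg(convention)
  stopifnot(is.list(subgraphs), length(subgraphs) >= 1, lambda > 0)
  g <- as_weighted_graph(g)
  dens <- vapply(subgraphs, function(Z) graph_density(g, Z, convention), 0)
  sum(dens) + lambda * distance_sum(subgraphs)
}
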
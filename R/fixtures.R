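#' Named example graphs
#'
#' Small canonical graphs used throughout the package and its tests:
#'
#' * `graph_two_cell()`: two vertices, single edge `1 -> 2`; the minimal
#'   system in which the saddle-node threshold of an excitable connection
#'   can be analysed.
#' * `graph_three_cycle()`: the directed 3-cycle `1 -> 2 -> 3 -> 1`; its
#'   realisation loses its equilibria in a SNIC bifurcation.
#' * `graph_kirk_silber()`: the four-vertex Kirk-Silber graph (edges
#'   `1 -> 2`, `2 -> 3`, `2 -> 4`, `3 -> 1`, `4 -> 1`); vertex 2 has two
#'   outgoing edges, which makes branching transitions and double-activation
#'   states possible.
#' * `graph_ten_node()`: a synthetic ten-vertex admissible, strongly
#'   connected random graph (fixed internal seed), standing in for the kind
#'   of larger network the construction targets.
#'
#' @return An `exna_digraph`.
#' @export
graph_two_cell <- function() {
  digraph_from_edges(rbind(c(1, 2)), n = 2)
}

#' @rdname graph_two_cell
#' @export
graph_three_cycle <- function() {
  digraph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1)))
}

#' @rdname graph_two_cell
#' @export
graph_kirk_silber <- function() {
  digraph_from_edges(rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 1), c(4, 1)))
}

#' @rdname graph_two_cell
#' @param seed Seed for the random ten-node sample (fixed default so the
#'   fixture is reproducible).
#' @param extra_prob Probability of each additional ordered pair beyond the
#'   backbone cycle.
#' @details `graph_ten_node()` is built differently from
#'   [random_admissible_graph()]: independent-pair sampling essentially
#'   never yields a ten-vertex graph that is both admissible and strongly
#'   connected, so the fixture draws a random directed Hamiltonian cycle
#'   (which guarantees strong connectivity) and adds each remaining ordered
#'   pair independently with probability `extra_prob`, rejecting draws that
#'   violate admissibility.
#' @export
graph_ten_node <- function(seed = 104L, extra_prob = 0.08) {
  n <- 10L
  withr::with_seed(as.integer(seed), {
    for (attempt in 1:10000) {
      perm <- sample(n)
      A <- matrix(rbinom(n * n, 1L, extra_prob), n, n)
      A[cbind(perm, c(perm[-1], perm[1]))] <- 1L
      diag(A) <- 0L
      if (any(A == 1L & t(A) == 1L)) next
      if (any(((A %*% A) * A) > 0)) next
      return(digraph(A))
    }
    exna_abort("ten-node fixture generation exhausted its budget", "exna_generation_failure")
  })
}

fixture_graph <- function(name) {
  switch(name,
    "two-cell" = graph_two_cell(),
    "three-cycle" = graph_three_cycle(),
    "kirk-silber" = graph_kirk_silber(),
    "ten-node" = graph_ten_node(),
    exna_abort(paste0("unknown fixture: ", name), "exna_domain")
  )
}
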
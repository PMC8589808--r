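#' Directed graphs for excitable-network construction
#'
#' A `exna_digraph` is a minimal directed-graph container: a vertex count `n`
#' and a binary `n x n` adjacency matrix with entry `(i, j) = 1` meaning a
#' directed edge from vertex `i` to vertex `j`. Vertices are labelled `1..n`
#' everywhere, including file I/O.
#'
#' @param adjacency Square numeric matrix with entries 0/1.
#' @return An object of class `exna_digraph` with fields `n` and `adjacency`.
#' @examples
#' g <- digraph(rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
#' g$n
#' @export
digraph <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency)) {
    exna_abort("adjacency must be a square matrix", "exna_malformed_input")
  }
  a <- suppressWarnings(as.numeric(adjacency))
  if (anyNA(a) || !all(a %in% c(0, 1))) {
    exna_abort("adjacency entries must be exactly 0 or 1", "exna_malformed_input")
  }
  n <- nrow(adjacency)
  if (n < 1) exna_abort("graph must have at least one vertex", "exna_malformed_input")
  A <- matrix(as.integer(a), n, n, dimnames = list(seq_len(n), seq_len(n)))
  structure(list(n = n, adjacency = A), class = "exna_digraph")
}

#' Build a digraph from an edge table
#'
#' @param edges Two-column data frame or matrix of (source, destination)
#'   vertex labels, 1-based.
#' @param n Vertex count; defaults to the largest label present.
#' @return An `exna_digraph`.
#' @export
digraph_from_edges <- function(edges, n = NULL) {
  e <- as.matrix(edges)
  if (length(e) == 0) {
    if (is.null(n)) exna_abort("empty edge set and no vertex count given", "exna_malformed_input")
    return(digraph(matrix(0, n, n)))
  }
  if (ncol(e) != 2) exna_abort("edges must have two columns", "exna_malformed_input")
  storage.mode(e) <- "integer"
  if (anyNA(e) || any(e < 1)) {
    exna_abort("vertex labels must be positive integers (1-based)", "exna_labelling")
  }
  if (is.null(n)) n <- max(e)
  if (any(e > n)) exna_abort("edge label exceeds vertex count", "exna_labelling")
  A <- matrix(0L, n, n)
  A[e] <- 1L
  digraph(A)
}

#' @export
print.exna_digraph <- function(x, ...) {
  cat("<exna_digraph> ", x$n, " vertices, ", sum(x$adjacency), " edges\n", sep = "")
  invisible(x)
}

#' Edge list of a digraph as a tibble
#'
#' @param graph An `exna_digraph`.
#' @return A tibble with integer columns `from` and `to`, one row per edge.
#' @export
graph_edges <- function(graph) {
  idx <- which(graph$adjacency == 1L, arr.ind = TRUE)
  tibble::tibble(from = as.integer(idx[, 1]), to = as.integer(idx[, 2])) |>
    dplyr::arrange(.data$from, .data$to)
}

#' Out-degrees of all vertices
#'
#' @param graph An `exna_digraph`.
#' @return Integer vector of length `n`.
#' @export
out_degree <- function(graph) {
  as.integer(rowSums(graph$adjacency))
}

#' Validate a directed graph for the excitable-network construction
#'
#' The weight-matrix construction requires the graph to contain no one-loops
#' (`a_ii = 1`), no two-loops (`a_ij a_ji = 1`) and no delta-cliques
#' (ordered triples with `a_ij a_ik a_jk = 1`, i.e. edges i->j, i->k, j->k).
#' The report lists every violating vertex, pair and triple so it can serve
#' as a direct certificate of inadmissibility.
#'
#' @param graph An `exna_digraph`.
#' @return An object of class `exna_violations`: a list with `one_loops`
#'   (integer vector), `two_loops` (tibble `i`, `j` with `i < j`),
#'   `delta_cliques` (tibble of ordered triples `i`, `j`, `k`) and the
#'   logical flag `admissible`.
#' @examples
#' validate_graph(graph_three_cycle())$admissible
#' @export
validate_graph <- function(graph) {
  if (!inherits(graph, "exna_digraph")) graph <- digraph(graph)
  A <- graph$adjacency
  n <- graph$n

  one_loops <- which(diag(A) == 1L)

  tw <- which(A == 1L & t(A) == 1L, arr.ind = TRUE)
  two_loops <- tibble::tibble(i = as.integer(tw[, 1]), j = as.integer(tw[, 2])) |>
    dplyr::filter(.data$i < .data$j) |>
    dplyr::arrange(.data$i, .data$j)

  # ordered triples (i, j, k) with i->j, i->k and j->k, enumerated directly
  # (duplicates under relabelling are not collapsed: each triple certifies)
  M <- (A %*% A) * A # M[i, k] > 0 iff some j gives i->j->k alongside i->k
  cl <- list()
  if (any(M > 0)) {
    hits <- which(M > 0, arr.ind = TRUE)
    for (r in seq_len(nrow(hits))) {
      i <- hits[r, 1]; k <- hits[r, 2]
      js <- which(A[i, ] == 1L & A[, k] == 1L)
      js <- setdiff(js, c(i, k))
      for (j in js) cl[[length(cl) + 1L]] <- c(i, j, k)
    }
  }
  delta_cliques <- if (length(cl)) {
    m <- do.call(rbind, cl)
    tibble::tibble(i = as.integer(m[, 1]), j = as.integer(m[, 2]), k = as.integer(m[, 3])) |>
      dplyr::arrange(.data$i, .data$j, .data$k)
  } else {
    tibble::tibble(i = integer(), j = integer(), k = integer())
  }

  structure(
    list(
      one_loops = as.integer(one_loops),
      two_loops = two_loops,
      delta_cliques = delta_cliques,
      admissible = length(one_loops) == 0 && nrow(two_loops) == 0 && nrow(delta_cliques) == 0
    ),
    class = "exna_violations"
  )
}

#' @export
print.exna_violations <- function(x, ...) {
  cat("<exna_violations> admissible:", x$admissible, "\n")
  if (length(x$one_loops)) cat("  one-loops at:", paste(x$one_loops, collapse = ", "), "\n")
  if (nrow(x$two_loops)) cat("  two-loops:", nrow(x$two_loops), "\n")
  if (nrow(x$delta_cliques)) cat("  delta-cliques:", nrow(x$delta_cliques), "\n")
  invisible(x)
}

#' @describeIn validate_graph long-form tibble of all violations, one row per
#'   violating vertex/pair/triple with a `type` column.
#' @param x An `exna_violations` object.
#' @param ... Unused.
#' @export
tidy.exna_violations <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(type = rep("one_loop", length(x$one_loops)),
                   i = x$one_loops, j = NA_integer_, k = NA_integer_),
    dplyr::mutate(x$two_loops, type = "two_loop", k = NA_integer_, .before = 1),
    dplyr::mutate(x$delta_cliques, type = "delta_clique", .before = 1)
  )
}

#' Is a graph admissible for the construction?
#'
#' @param graph An `exna_digraph`.
#' @return Logical scalar.
#' @export
is_admissible <- function(graph) validate_graph(graph)$admissible

#' Generate a random admissible directed graph
#'
#' Rejection sampling: each attempt draws every ordered off-diagonal pair
#' independently as an edge with probability `edge_prob`, then discards the
#' attempt if the result has any one-loop, two-loop or delta-clique (or, when
#' `require_no_sink_subgraph` is set, is not strongly connected). Strong
#' connectivity is the package's reading of "no feed-forward structure": from
#' every vertex every other vertex remains reachable, so the dynamics cannot
#' get stuck in a subgraph.
#'
#' @param n Vertex count, at least 3.
#' @param edge_prob Edge probability in (0, 1].
#' @param seed Optional integer seed; generation is deterministic given the
#'   seed and leaves the global RNG untouched.
#' @param require_no_sink_subgraph If `TRUE` (default) the sample is also
#'   required to be strongly connected.
#' @param max_attempts Rejection-sampling budget per call.
#' @return An admissible `exna_digraph`.
#' @examples
#' g <- random_admissible_graph(6, 0.2, seed = 42)
#' is_admissible(g)
#' @export
random_admissible_graph <- function(n, edge_prob, seed = NULL,
                                    require_no_sink_subgraph = TRUE,
                                    max_attempts = 10000L) {
  if (n < 3) exna_abort("n must be at least 3", "exna_domain")
  if (edge_prob <= 0 || edge_prob > 1) exna_abort("edge_prob must be in (0, 1]", "exna_domain")
  draw <- function() {
    for (attempt in seq_len(max_attempts)) {
      A <- matrix(rbinom(n * n, 1L, edge_prob), n, n)
      diag(A) <- 0L
      if (any(A == 1L & t(A) == 1L)) next
      if (any(((A %*% A) * A) > 0)) next
      if (require_no_sink_subgraph && !strongly_connected(A)) next
      return(digraph(A))
    }
    exna_abort(
      sprintf("no admissible graph found in %d attempts (n = %d, edge_prob = %g)",
              max_attempts, n, edge_prob),
      "exna_generation_failure"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# strong connectivity via igraph
strongly_connected <- function(A) {
  ig <- igraph::graph_from_adjacency_matrix(A, mode = "directed")
  igraph::components(ig, mode = "strong")$no == 1L
}

#' Read a directed graph from a file
#'
#' Three plain-text dialects are supported: `edgelist` (one
#' `src<TAB>dst` pair per line, 1-based labels), `adjacency` (CSV of 0/1
#' entries, row = source) and `dot` (a `digraph` block; edges `i -> j` and
#' bare vertex statements).
#'
#' @param path File path.
#' @param format One of `"edgelist"`, `"adjacency"`, `"dot"`.
#' @return An `exna_digraph`.
#' @seealso [write_graph()]
#' @export
load_graph <- function(path, format = c("edgelist", "adjacency", "dot")) {
  format <- match.arg(format)
  if (!file.exists(path)) exna_abort(paste0("file not found: ", path), "exna_io")
  switch(format,
    edgelist = load_graph_edgelist(path),
    adjacency = load_graph_adjacency(path),
    dot = load_graph_dot(path)
  )
}

load_graph_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("\\S", lines) & !grepl("^\\s*#", lines)
  lines <- lines[keep]
  if (length(lines) == 0) exna_abort("empty edge-list file", "exna_malformed_input")
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 2L)
  if (length(bad)) {
    exna_abort(sprintf("edge-list parse failure at line %d", which(keep)[bad[1]]), "exna_format")
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m)) exna_abort("edge-list labels must be integers", "exna_format")
  digraph_from_edges(m)
}

load_graph_adjacency <- function(path) {
  df <- tryCatch(read.csv(path, header = FALSE),
                 error = function(e) exna_abort(paste0("CSV parse failure: ", conditionMessage(e)), "exna_format"))
  if (nrow(df) == 0) exna_abort("empty adjacency file", "exna_malformed_input")
  digraph(as.matrix(df))
}

load_graph_dot <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (!grepl("digraph", txt)) exna_abort("not a DOT digraph", "exna_format")
  edge_m <- gregexpr("([0-9]+)\\s*->\\s*([0-9]+)", txt)[[1]]
  edges <- NULL
  if (edge_m[1] != -1) {
    toks <- regmatches(txt, gregexpr("([0-9]+)\\s*->\\s*([0-9]+)", txt))[[1]]
    edges <- do.call(rbind, lapply(strsplit(toks, "->"), function(p) as.integer(trimws(p))))
  }
  # bare vertex statements, e.g. "3;" keep isolated vertices in round trips
  body <- sub(".*\\{", "", sub("\\}.*", "", txt))
  iso <- regmatches(body, gregexpr("(?<![0-9>\\-])\\b([0-9]+)\\b\\s*;", body, perl = TRUE))[[1]]
  iso <- as.integer(sub(";", "", iso))
  n <- max(c(edges, iso, 0L))
  if (n == 0) exna_abort("DOT file declares no vertices", "exna_malformed_input")
  digraph_from_edges(if (is.null(edges)) matrix(integer(), 0, 2) else edges, n = n)
}

#' Write a directed graph to a file
#'
#' @param graph An `exna_digraph`.
#' @param path Output file path.
#' @param format One of `"edgelist"`, `"adjacency"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path, format = c("edgelist", "adjacency", "dot")) {
  format <- match.arg(format)
  e <- graph_edges(graph)
  switch(format,
    edgelist = writeLines(sprintf("%d\t%d", e$from, e$to), path),
    adjacency = utils::write.table(graph$adjacency, path, sep = ",",
                                   row.names = FALSE, col.names = FALSE),
    dot = {
      touched <- unique(c(e$from, e$to))
      iso <- setdiff(seq_len(graph$n), touched)
      writeLines(c(
        "digraph G {",
        sprintf("  %d;", iso),
        sprintf("  %d -> %d;", e$from, e$to),
        "}"
      ), path)
    }
  )
  invisible(path)
}
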
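# integrate from y0 and classify the omega-limit against a candidate set.
# A trajectory is declared converged to candidate m when it stays within
# max-norm radius `ball` of it continuously for `settle` time units.
# Integration proceeds in chunks so most runs stop long before `horizon`.
classify_flow <- function(weights, spec, y0, candidates, ball, horizon,
                          settle = 5, tol = 1e-9, sample_dt = 0.1,
                          chunk = 10) {
  y <- y0
  t0 <- 0
  hist_t <- 0
  hist_d <- matrix(vapply(candidates, function(cs) max(abs(y0 - cs)), 0), nrow = 1)
  first_entry <- rep(NA_real_, length(candidates))
  inb <- hist_d[1, ] < ball
  first_entry[inb] <- 0
  need <- ceiling(settle / sample_dt) + 1L

  while (t0 < horizon) {
    t1 <- min(t0 + chunk, horizon)
    times <- seq(t0, t1, by = sample_dt)
    if (times[length(times)] < t1) times <- c(times, t1)
    sol <- deSolve::lsoda(
      y = y, times = times,
      func = function(t, y, parms) list(field_y(y, weights$w, spec)),
      rtol = tol, atol = tol
    )
    states <- sol[-1, -1, drop = FALSE]
    dmat <- t(apply(states, 1, function(s) {
      vapply(candidates, function(cs) max(abs(s - cs)), 0)
    }))
    for (m in seq_along(candidates)) {
      hit <- which(dmat[, m] < ball)
      if (length(hit) && is.na(first_entry[m])) {
        first_entry[m] <- sol[-1, 1][hit[1]]
      }
    }
    hist_t <- c(hist_t, sol[-1, 1])
    hist_d <- rbind(hist_d, dmat)
    y <- as.numeric(sol[nrow(sol), -1])
    t0 <- t1

    # convergence: within the ball of one candidate for the whole of the
    # trailing `settle` window
    nr <- nrow(hist_d)
    if (nr >= need) {
      tail_rows <- hist_t >= hist_t[nr] - settle + 1e-12
      for (m in seq_along(candidates)) {
        if (all(hist_d[tail_rows, m] < ball)) {
          return(list(destination = m, transit_time = first_entry[m]))
        }
      }
    }
  }
  list(destination = NA_integer_, transit_time = NA_real_)
}

#' Test a single excitable connection
#'
#' From the equilibrium with vertex `k` active, the state of cell `l` is
#' kicked by `delta` and the input-free flow is integrated. The outcome is
#' `"connected"` if the trajectory settles at the equilibrium of vertex `l`
#' (expected exactly when `k -> l` is a graph edge), `"returned"` if it
#' falls back to vertex `k`, and `"other"` otherwise (some third
#' equilibrium, the rest state near the origin, or no settlement within the
#' horizon). Settlement means staying within max-norm `delta / 4` of a
#' candidate equilibrium continuously for 5 time units; the candidates are
#' the per-vertex equilibria plus the near-origin rest state.
#'
#' @param graph An admissible `exna_digraph`.
#' @param params An `exna_params`.
#' @param spec An `exna_activation`.
#' @param k,l Source vertex and kicked cell, `k != l`.
#' @param delta Kick amplitude.
#' @param horizon Integration horizon (default 200 time units).
#' @param wp_overrides Optional per-edge `w_p` replacements.
#' @param candidates Optional precomputed candidate list (internal reuse).
#' @return An `exna_transition`: `source`, `kicked_cell`, `destination`
#'   (vertex index or `NA`), `transit_time`, `classification`.
#' @export
test_connection <- function(graph, params, spec, k, l, delta, horizon = 200,
                            wp_overrides = NULL, candidates = NULL) {
  if (k == l) exna_abort("k and l must differ", "exna_domain")
  W <- build_weight_matrix(graph, params, wp_overrides = wp_overrides)
  if (is.null(candidates)) {
    candidates <- equilibrium_candidates(graph, params, spec, wp_overrides)
  }
  y0 <- kick(candidates[[k]], l, delta)
  # a zero kick still needs a non-degenerate acceptance ball
  ball <- max(delta / 4, 1e-8)
  res <- classify_flow(W, spec, y0, candidates, ball = ball, horizon = horizon)
  dest <- res$destination
  classification <- if (is.na(dest)) "other"
    else if (dest == l) "connected"
    else if (dest == k) "returned"
    else "other"
  structure(
    list(source = k, kicked_cell = l,
         destination = if (is.na(dest) || dest > graph$n) NA_integer_ else dest,
         transit_time = res$transit_time,
         classification = classification),
    class = "exna_transition"
  )
}

#' @export
print.exna_transition <- function(x, ...) {
  cat("<exna_transition> ", x$source, " -[kick ", x$kicked_cell, "]-> ",
      ifelse(is.na(x$destination), "none", x$destination),
      " (", x$classification, ")\n", sep = "")
  invisible(x)
}

#' Verify that a constructed network realises its graph
#'
#' Runs [test_connection()] for every ordered vertex pair: the network
#' realises the graph at amplitude `delta` when every graph edge gives a
#' `connected` outcome and every non-edge kick `returned` to its source.
#'
#' @inheritParams test_connection
#' @return An `exna_realisation`: `delta`, `outcomes` (tibble with one row
#'   per ordered pair: `from`, `to`, `is_edge`, `classification`,
#'   `destination`, `transit_time`) and the logical `realised`.
#' @examples
#' \donttest{
#' r <- verify_realisation(graph_three_cycle(), recipe_params(0.4),
#'                         params_activation(recipe_params(0.4), "piecewise"),
#'                         delta = 0.4)
#' r$realised
#' }
#' @export
verify_realisation <- function(graph, params, spec, delta, horizon = 200,
                               wp_overrides = NULL) {
  if (!is_admissible(graph)) {
    exna_abort("graph must be admissible", "exna_inadmissible")
  }
  candidates <- equilibrium_candidates(graph, params, spec, wp_overrides)
  A <- graph$adjacency
  n <- graph$n
  rows <- list()
  for (k in seq_len(n)) {
    for (l in seq_len(n)) {
      if (k == l) next
      tc <- test_connection(graph, params, spec, k, l, delta, horizon,
                            wp_overrides, candidates = candidates)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        from = k, to = l, is_edge = A[k, l] == 1L,
        classification = tc$classification,
        destination = tc$destination,
        transit_time = tc$transit_time
      )
    }
  }
  outcomes <- dplyr::bind_rows(rows)
  realised <- all(outcomes$classification[outcomes$is_edge] == "connected") &&
    all(outcomes$classification[!outcomes$is_edge] == "returned")
  structure(list(delta = delta, outcomes = outcomes, realised = realised),
            class = "exna_realisation")
}

#' @export
print.exna_realisation <- function(x, ...) {
  cat("<exna_realisation> delta =", x$delta, "- realised:", x$realised, "\n")
  print(glance(x))
  invisible(x)
}

#' @describeIn verify_realisation per-pair outcomes as a tibble.
#' @param x An `exna_realisation`.
#' @param ... Unused.
#' @export
tidy.exna_realisation <- function(x, ...) x$outcomes

#' @describeIn verify_realisation one-row summary (edge/non-edge counts and
#'   the realised flag).
#' @export
glance.exna_realisation <- function(x, ...) {
  o <- x$outcomes
  tibble::tibble(
    realised = x$realised,
    delta = x$delta,
    n_edges = sum(o$is_edge),
    n_connected = sum(o$is_edge & o$classification == "connected"),
    n_non_edges = sum(!o$is_edge),
    n_returned = sum(!o$is_edge & o$classification == "returned")
  )
}

#' Execute a finite-state walk on the network
#'
#' Starts the system at the equilibrium of the first vertex of `walk` and,
#' for each subsequent step `k -> l`, applies a rectangular input pulse to
#' cell `l` once the system has settled, then waits for settlement again.
#' The walk succeeds when the debounced single-active itinerary of the full
#' trajectory equals the walk.
#'
#' @param graph An admissible `exna_digraph`.
#' @param params An `exna_params`.
#' @param spec An `exna_activation`.
#' @param walk Integer vector of vertices; consecutive pairs must be edges.
#' @param amplitude Pulse amplitude (default: the recipe `delta`, if set).
#' @param duration Pulse duration (default 1 time unit).
#' @param settle Time allowed between pulses (default 40 time units).
#' @param wp_overrides Optional per-edge `w_p` replacements.
#' @return List with elements `itinerary` (an `exna_itinerary`), `success`
#'   (logical) and `trajectory`.
#' @export
execute_walk <- function(graph, params, spec, walk, amplitude = NULL,
                         duration = 1, settle = 40, wp_overrides = NULL) {
  walk <- as.integer(walk)
  if (length(walk) < 1) exna_abort("walk must name at least one vertex", "exna_invalid_walk")
  A <- graph$adjacency
  for (s in seq_len(length(walk) - 1)) {
    if (A[walk[s], walk[s + 1]] != 1L) {
      exna_abort(sprintf("walk step %d->%d is not a graph edge", walk[s], walk[s + 1]),
                 "exna_invalid_walk")
    }
  }
  if (is.null(amplitude)) {
    if (is.null(params$delta)) {
      exna_abort("amplitude must be given when params carry no delta", "exna_domain")
    }
    amplitude <- params$delta
  }
  W <- build_weight_matrix(graph, params, wp_overrides = wp_overrides)
  candidates <- equilibrium_candidates(graph, params, spec, wp_overrides)
  y0 <- candidates[[walk[1]]]
  n_steps <- length(walk) - 1
  protocol <- NULL
  if (n_steps > 0) {
    protocol <- dplyr::bind_rows(lapply(seq_len(n_steps), function(s) {
      pulse_spec(cell = walk[s + 1], start = s * settle,
                 duration = duration, amplitude = amplitude)
    }))
  }
  t_max <- (n_steps + 1) * settle
  traj <- simulate_ode(W, spec, y0, protocol = protocol, t_max = t_max)
  itin <- itinerary(traj, spec = spec)
  seq_labels <- debounced_singletons(itin, min_duration = 1)
  success <- identical(seq_labels, walk)
  list(itinerary = itin, success = success, trajectory = traj)
}
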
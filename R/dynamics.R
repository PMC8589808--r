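# core vector fields (internal, vectorised over cells)

field_y <- function(y, w, spec, input = NULL) {
  f <- -y + as.vector(w %*% activation(y, spec))
  if (!is.null(input)) f <- f + input
  f
}

jacobian_y <- function(y, w, spec) {
  -diag(length(y)) + w %*% diag(activation_deriv(y, spec), nrow = length(y))
}

field_J <- function(J, w, spec) {
  if (any(J <= 0 | J >= 1)) {
    exna_abort("J-coordinates must lie strictly in (0, 1)", "exna_domain")
  }
  (1 / spec$eps) * J * (1 - J) *
    (-activation_inverse(J, spec) + as.vector(w %*% J))
}

#' Instantaneous CTRNN derivative
#'
#' In `y`-coordinates the model is `dy_i/dt = -y_i + sum_j w_ij phi(y_j) +
#' I_i(t)`. For the smooth activation the change of variables `J_i =
#' phi(y_i)` gives the equivalent input-free form `dJ_i/dt = (1/eps) J_i (1
#' - J_i) (-phi^{-1}(J_i) + sum_j w_ij J_j)` on the open cube `(0, 1)^n`.
#'
#' @param state Length-`n` state vector (`y` or `J` values).
#' @param weights An `exna_weights`.
#' @param spec An `exna_activation`.
#' @param input Optional length-`n` input vector, or a function of time
#'   returning one. Only supported in `y`-coordinates.
#' @param t Evaluation time (used when `input` is a function).
#' @param coords `"y"` or `"J"`.
#' @return Length-`n` derivative vector.
#' @export
vector_field <- function(state, weights, spec, input = NULL, t = 0,
                         coords = c("y", "J")) {
  coords <- match.arg(coords)
  if (coords == "J") {
    if (!is.null(input)) {
      exna_abort("inputs are not supported in J-coordinates (the J-form is input-free)",
                 "exna_unsupported")
    }
    if (spec$kind != "smooth") {
      exna_abort("J-coordinates require the smooth activation", "exna_unsupported")
    }
    return(field_J(state, weights$w, spec))
  }
  iv <- if (is.function(input)) input(t) else input
  field_y(state, weights$w, spec, iv)
}

#' Rectangular input pulses
#'
#' A pulse protocol is a tibble of rectangular pulses: amplitude `amplitude`
#' added to the input of cell `cell` for `t` in `[start, start + duration)`.
#' Overlapping pulses on the same cell sum.
#'
#' @param cell Target cell index.
#' @param start Onset time.
#' @param duration Pulse length, positive.
#' @param amplitude Pulse height.
#' @return One-row tibble; rows from several calls can be `rbind`-ed into a
#'   protocol.
#' @export
pulse_spec <- function(cell, start, duration, amplitude) {
  if (duration <= 0) exna_abort("pulse duration must be > 0", "exna_domain")
  tibble::tibble(cell = as.integer(cell), start = start,
                 duration = duration, amplitude = amplitude)
}

# input vector at time t from a pulse protocol (right-open supports)
protocol_input <- function(protocol, n, t) {
  iv <- numeric(n)
  if (is.null(protocol) || nrow(protocol) == 0) return(iv)
  on <- protocol$start <= t & t < protocol$start + protocol$duration
  for (r in which(on)) iv[protocol$cell[r]] <- iv[protocol$cell[r]] + protocol$amplitude[r]
  iv
}

new_trajectory <- function(times, states, coords, sigma = 0, seed = NA_integer_) {
  n <- ncol(states)
  prefix <- if (coords == "J") "J" else "y"
  df <- tibble::as_tibble(as.data.frame(states, optional = TRUE),
                          .name_repair = "minimal")
  names(df) <- paste0(prefix, seq_len(n))
  out <- dplyr::bind_cols(tibble::tibble(time = times), df)
  structure(out,
            class = c("exna_trajectory", class(out)),
            coords = coords, sigma = sigma, seed = seed, n_cells = n)
}

traj_states <- function(traj) {
  as.matrix(traj[, -1, drop = FALSE])
}

#' Integrate the deterministic CTRNN
#'
#' Adaptive integration (via \pkg{deSolve}'s `lsoda`) of the CTRNN with an
#' optional rectangular pulse protocol. Integration is split at pulse
#' boundaries, where the forcing is discontinuous; within each segment the
#' input is constant, and both activation kinds give a Lipschitz vector
#' field, so no event detection is needed. Output is sampled densely enough
#' for itinerary extraction (default spacing 0.05 time units).
#'
#' @param weights An `exna_weights`.
#' @param spec An `exna_activation`.
#' @param y0 Initial state.
#' @param protocol Optional pulse protocol (see [pulse_spec()]).
#' @param t_max Horizon; `t_max = 0` returns just the initial state.
#' @param tol Absolute and relative tolerance (default `1e-9`).
#' @param sample_dt Output sample spacing, at most 0.1.
#' @return An `exna_trajectory` tibble: column `time` then `y1..yn`.
#' @examples
#' W <- build_weight_matrix(graph_three_cycle(), recipe_params(0.4))
#' sp <- params_activation(W$params, "piecewise")
#' tr <- simulate_ode(W, sp, predicted_equilibrium(W$graph, W$params, 1)$state, t_max = 5)
#' @export
simulate_ode <- function(weights, spec, y0, protocol = NULL, t_max, tol = 1e-9,
                         sample_dt = 0.05) {
  if (t_max < 0) exna_abort("t_max must be >= 0", "exna_domain")
  if (sample_dt > 0.1) exna_abort("sample_dt must be <= 0.1", "exna_domain")
  n <- weights$n
  if (length(y0) != n) exna_abort("y0 length does not match network size", "exna_domain")
  if (t_max == 0) {
    return(new_trajectory(0, matrix(y0, 1, n), coords = "y"))
  }
  bounds <- 0
  if (!is.null(protocol) && nrow(protocol) > 0) {
    bounds <- c(bounds, protocol$start, protocol$start + protocol$duration)
  }
  bounds <- sort(unique(pmin(pmax(bounds, 0), t_max)))
  if (bounds[length(bounds)] < t_max) bounds <- c(bounds, t_max)

  times_all <- numeric(0)
  states_all <- NULL
  y <- y0
  for (s in seq_len(length(bounds) - 1)) {
    t0 <- bounds[s]; t1 <- bounds[s + 1]
    iv <- protocol_input(protocol, n, (t0 + t1) / 2) # constant within segment
    times <- unique(c(seq(t0, t1, by = sample_dt), t1))
    sol <- deSolve::lsoda(
      y = y, times = times,
      func = function(t, y, parms) list(field_y(y, weights$w, spec, iv)),
      rtol = tol, atol = tol
    )
    if (attr(sol, "istate")[1] < 0) {
      exna_abort(sprintf("integration failure near t = %g", sol[nrow(sol), 1]),
                 "exna_integration_failure")
    }
    y <- as.numeric(sol[nrow(sol), -1])
    keep <- if (s == 1) seq_len(nrow(sol)) else 2:nrow(sol)
    times_all <- c(times_all, sol[keep, 1])
    states_all <- rbind(states_all, unname(sol[keep, -1, drop = FALSE]))
  }
  new_trajectory(times_all, states_all, coords = "y")
}

#' Integrate the input-free J-coordinate system
#'
#' Companion to [simulate_ode()] for the smooth activation: integrates the
#' logistic-transformed system from `J0` in the open cube. Used mainly to
#' cross-check coordinate equivalence.
#'
#' @inheritParams simulate_ode
#' @param J0 Initial state in `(0, 1)^n`.
#' @return An `exna_trajectory` with columns `J1..Jn` and `coords = "J"`.
#' @export
simulate_ode_J <- function(weights, spec, J0, t_max, tol = 1e-9, sample_dt = 0.05) {
  if (spec$kind != "smooth") {
    exna_abort("J-coordinates require the smooth activation", "exna_unsupported")
  }
  if (any(J0 <= 0 | J0 >= 1)) exna_abort("J0 must lie in (0,1)^n", "exna_domain")
  if (t_max == 0) return(new_trajectory(0, matrix(J0, 1, length(J0)), coords = "J"))
  times <- unique(c(seq(0, t_max, by = sample_dt), t_max))
  sol <- deSolve::lsoda(
    y = J0, times = times,
    func = function(t, J, parms) list(field_J(J, weights$w, spec)),
    rtol = tol, atol = tol
  )
  new_trajectory(sol[, 1], unname(sol[, -1, drop = FALSE]), coords = "J")
}

#' Simulate the CTRNN with additive noise (Euler-Maruyama)
#'
#' Fixed-step Euler-Maruyama discretisation of
#' `dy_i = (-y_i + sum_j w_ij phi(y_j)) dt + sigma dW_i`, with independent
#' Wiener processes per cell. One Gaussian increment is drawn per cell per
#' step from a seeded generator, so paths are reproducible given `seed`,
#' and `sigma = 0` reproduces the fixed-step deterministic Euler path
#' exactly.
#'
#' @param weights An `exna_weights`.
#' @param spec An `exna_activation`.
#' @param y0 Initial state.
#' @param sigma Noise amplitude, `>= 0`.
#' @param t_max Horizon, at least `dt`.
#' @param dt Step size (default 0.01).
#' @param seed Integer seed; required when `sigma > 0`.
#' @param record_every Keep every `record_every`-th step (default 1).
#' @return An `exna_trajectory`.
#' @export
simulate_sde <- function(weights, spec, y0, sigma, t_max, dt = 0.01, seed = NULL,
                         record_every = 1L) {
  if (dt <= 0) exna_abort("dt must be > 0", "exna_domain")
  if (t_max < dt) exna_abort("t_max must be at least dt", "exna_domain")
  if (sigma < 0) exna_abort("sigma must be >= 0", "exna_domain")
  if (sigma > 0 && is.null(seed)) exna_abort("a seed is required when sigma > 0", "exna_domain")
  n <- weights$n
  steps <- floor(t_max / dt + 1e-9)
  run <- function() {
    nav <- sqrt(dt) * sigma
    rec <- seq(0, steps, by = record_every)
    out <- matrix(NA_real_, length(rec), n)
    y <- y0
    out[1, ] <- y
    ri <- 2L
    w <- weights$w
    for (s in seq_len(steps)) {
      y <- y + dt * (-y + as.vector(w %*% activation(y, spec))) + nav * rnorm(n)
      if (ri <= length(rec) && s == rec[ri]) {
        out[ri, ] <- y
        ri <- ri + 1L
      }
    }
    new_trajectory(rec * dt, out, coords = "y", sigma = sigma,
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Perturb one cell of a state vector
#'
#' The excitable-connection test uses the kicked point `xi_k + delta e_l`:
#' the equilibrium with `delta` added to the component of cell `l` only.
#'
#' @param state Length-`n` state vector (or an `exna_equilibrium`).
#' @param cell Cell index to perturb.
#' @param delta Perturbation size.
#' @return The perturbed state vector.
#' @examples
#' kick(c(1, 0.3, -0.7), 2, 0.4)
#' @export
kick <- function(state, cell, delta) {
  if (inherits(state, "exna_equilibrium")) state <- state$state
  if (cell < 1 || cell > length(state)) exna_abort("cell outside 1..n", "exna_domain")
  state[cell] <- state[cell] + delta
  state
}

#' Reshape a trajectory to long (tidy) form
#'
#' @param traj An `exna_trajectory`.
#' @return Tibble with columns `time`, `cell` (integer) and `value`.
#' @export
trajectory_long <- function(traj) {
  prefix <- if (attr(traj, "coords") == "J") "J" else "y"
  tidyr::pivot_longer(tibble::as_tibble(traj), -"time",
                      names_to = "cell", values_to = "value") |>
    dplyr::mutate(cell = as.integer(sub(prefix, "", .data$cell, fixed = TRUE)))
}

#' @export
autoplot.exna_trajectory <- function(object, ...) {
  df <- trajectory_long(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = factor(.data$cell))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = if (attr(object, "coords") == "J") "J" else "y",
                  colour = "cell") +
    ggplot2::theme_minimal()
}

#' Write / read a trajectory as TSV
#'
#' Header `t, y1..yN` (or `J1..JN`), one row per sample.
#'
#' @param traj An `exna_trajectory`.
#' @param path File path.
#' @return `path` invisibly (write); an `exna_trajectory` (read).
#' @export
write_trajectory <- function(traj, path) {
  df <- tibble::as_tibble(traj)
  names(df)[1] <- "t"
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  coords <- if (any(grepl("^J", names(df)[-1]))) "J" else "y"
  new_trajectory(df[[1]], as.matrix(df[, -1, drop = FALSE]), coords = coords)
}
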
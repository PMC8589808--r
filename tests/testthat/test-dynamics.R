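test_that("the y-field matches the componentwise model equations", {
  p <- recipe_params(0.4)
  sm <- params_activation(p, "smooth")
  W <- build_weight_matrix(graph_two_cell(), p)
  phi <- function(y) 1 / (1 + exp(-(y - 0.5) / 0.05))
  ys <- withr::with_seed(2, matrix(runif(20, -1, 1.5), ncol = 2))
  for (r in seq_len(nrow(ys))) {
    y <- ys[r, ]
    expect_equal(
      vector_field(y, W, sm),
      c(-y[1] + 1 * phi(y[1]) - 0.7 * phi(y[2]),
        -y[2] + 1 * phi(y[2]) + 0.3 * phi(y[1]))
    )
  }
})

test_that("the J-field is restricted to the open cube and input-free", {
  p <- default_smooth_params()
  sm <- params_activation(p, "smooth")
  W <- build_weight_matrix(graph_three_cycle(), p)
  expect_error(vector_field(c(1, 0.5, 0.5), W, sm, coords = "J"),
               class = "exna_domain")
  expect_error(vector_field(c(0.5, 0.5, 0.5), W, sm, input = c(1, 0, 0), coords = "J"),
               class = "exna_unsupported")
  pw <- params_activation(p, "piecewise")
  expect_error(vector_field(c(0.5, 0.5, 0.5), W, pw, coords = "J"),
               class = "exna_unsupported")
  # y <-> J consistency of the field at an interior point
  J <- c(0.4, 0.2, 0.6)
  y <- activation_inverse(J, sm)
  fy <- vector_field(y, W, sm)
  fJ <- vector_field(J, W, sm, coords = "J")
  # chain rule: dJ/dt = phi'(y) dy/dt
  expect_equal(fJ, exna:::activation_deriv(y, sm) * fy, tolerance = 1e-10)
})

test_that("the excitable regime is quiescent without input", {
  p <- recipe_params(0.4)
  pw <- params_activation(p, "piecewise")
  W <- build_weight_matrix(graph_three_cycle(), p)
  xi1 <- predicted_equilibrium(graph_three_cycle(), p, 1)$state
  tr <- simulate_ode(W, pw, xi1, t_max = 100)
  final <- as.numeric(tr[nrow(tr), -1])
  expect_lt(max(abs(final - xi1)), 1e-6)
  expect_true(all(diff(tr$time) > 0))
  expect_lte(max(diff(tr$time)), 0.1)
})

test_that("above the fold the deterministic cycle oscillates through all cells", {
  p <- default_smooth_params(w_p = 0.305)
  sm <- params_activation(p, "smooth")
  W <- build_weight_matrix(graph_three_cycle(), p)
  y0 <- predicted_equilibrium(graph_three_cycle(), p, 1, kind = "smooth")$state
  tr <- simulate_ode(W, sm, y0, t_max = 300)
  it <- itinerary(tr, spec = sm)
  singles <- exna:::debounced_singletons(it, 1)
  expect_gt(length(singles), 6)
  expect_setequal(unique(singles), 1:3)
  # strict cyclic order 1 -> 2 -> 3 -> 1
  nxt <- c(2L, 3L, 1L)
  expect_true(all(singles[-1] == nxt[singles[-length(singles)]]))
})

test_that("a zero horizon returns only the initial state", {
  p <- recipe_params(0.4)
  pw <- params_activation(p, "piecewise")
  W <- build_weight_matrix(graph_three_cycle(), p)
  tr <- simulate_ode(W, pw, c(0.1, 0.2, 0.3), t_max = 0)
  expect_equal(nrow(tr), 1)
  expect_equal(as.numeric(tr[1, -1]), c(0.1, 0.2, 0.3))
})

test_that("deterministic integration is bit-stable for fixed inputs", {
  p <- default_smooth_params(w_p = 0.305)
  sm <- params_activation(p, "smooth")
  W <- build_weight_matrix(graph_three_cycle(), p)
  y0 <- c(1, 0.31, -0.69)
  t1 <- simulate_ode(W, sm, y0, t_max = 50)
  t2 <- simulate_ode(W, sm, y0, t_max = 50)
  expect_identical(as.matrix(t1), as.matrix(t2))
})

test_that("noise-free Euler-Maruyama equals a plain Euler loop bitwise", {
  p <- default_smooth_params()
  sm <- params_activation(p, "smooth")
  W <- build_weight_matrix(graph_three_cycle(), p)
  y0 <- c(0.9, 0.35, -0.6)
  tr <- simulate_sde(W, sm, y0, sigma = 0, t_max = 2, dt = 0.01)
  # independent fixed-step Euler oracle
  y <- y0
  states <- matrix(NA_real_, 201, 3)
  states[1, ] <- y
  for (s in 1:200) {
    y <- y + 0.01 * (-y + as.vector(W$w %*% activation(y, sm))) + 0 * rnorm(3)
    states[s + 1, ] <- y
  }
  expect_identical(unname(exna:::traj_states(tr)), states)
})

test_that("stochastic paths are seed-reproducible and seed-sensitive", {
  p <- default_smooth_params()
  sm <- params_activation(p, "smooth")
  W <- build_weight_matrix(graph_three_cycle(), p)
  y0 <- refine_equilibrium(W, sm, c(1, 0.3, -0.7))$state
  a <- simulate_sde(W, sm, y0, sigma = 0.05, t_max = 10, seed = 11)
  b <- simulate_sde(W, sm, y0, sigma = 0.05, t_max = 10, seed = 11)
  c_ <- simulate_sde(W, sm, y0, sigma = 0.05, t_max = 10, seed = 12)
  expect_identical(as.matrix(a), as.matrix(b))
  expect_false(identical(as.matrix(a), as.matrix(c_)))
  expect_error(simulate_sde(W, sm, y0, sigma = 0.05, t_max = 10), class = "exna_domain")
})

test_that("kicks act on a single component and commute", {
  p <- recipe_params(0.4)
  xi1 <- predicted_equilibrium(graph_three_cycle(), p, 1)$state
  expect_equal(kick(xi1, 2, 0.4), c(1, 0.7, -0.7))
  x <- c(0.3, -0.1, 0.8)
  expect_equal(kick(x, 2, 0), x)
  expect_equal(kick(kick(x, 1, 0.2), 3, -0.4), kick(kick(x, 3, -0.4), 1, 0.2))
})

test_that("rectangular pulses drive transitions and sum when overlapping", {
  p <- recipe_params(0.4)
  pw <- params_activation(p, "piecewise")
  g <- graph_three_cycle()
  W <- build_weight_matrix(g, p)
  xi1 <- predicted_equilibrium(g, p, 1)$state
  prot <- pulse_spec(cell = 2, start = 5, duration = 1, amplitude = 0.4)
  tr <- simulate_ode(W, pw, xi1, protocol = prot, t_max = 40)
  it <- itinerary(tr, spec = pw)
  expect_equal(exna:::debounced_singletons(it, 1), c(1L, 2L))
  # overlapping pulses on the same cell sum
  expect_equal(exna:::protocol_input(rbind(pulse_spec(1, 0, 2, 0.1),
                                           pulse_spec(1, 1, 2, 0.2)), 2, 1.5),
               c(0.3, 0))
})

test_that("trajectories stay inside the dissipativity bound", {
  p <- default_smooth_params()
  sm <- params_activation(p, "smooth")
  W <- build_weight_matrix(graph_kirk_silber(), p)
  y0 <- predicted_equilibrium(graph_kirk_silber(), p, 1, kind = "smooth")$state
  bound <- max(rowSums(abs(W$w))) + 0.4 + max(abs(y0))
  prot <- pulse_spec(cell = 3, start = 10, duration = 1, amplitude = 0.4)
  tr <- simulate_ode(W, sm, y0, protocol = prot, t_max = 100)
  expect_true(all(abs(exna:::traj_states(tr)) <= bound))
  trs <- simulate_sde(W, sm, y0, sigma = 0.05, t_max = 100, seed = 3)
  expect_true(all(abs(exna:::traj_states(trs)) <= bound))
})

test_that("y- and J-coordinate integrations agree through the activation map", {
  p <- default_smooth_params()
  sm <- params_activation(p, "smooth")
  W <- build_weight_matrix(graph_three_cycle(), p)
  eq <- refine_equilibrium(W, sm, c(1, 0.3, -0.7))
  y0 <- kick(eq$state, 2, 0.4) # triggers one full transition
  ty <- simulate_ode(W, sm, y0, t_max = 20, tol = 1e-10)
  tJ <- simulate_ode_J(W, sm, activation(y0, sm), t_max = 20, tol = 1e-10)
  d <- max(abs(activation(exna:::traj_states(ty), sm) - exna:::traj_states(tJ)))
  # the J-form carries a 1/eps factor that amplifies local error ~1000x
  expect_lt(d, 1e-7)
})

test_that("trajectory TSV round trip preserves samples", {
  p <- recipe_params(0.4)
  pw <- params_activation(p, "piecewise")
  W <- build_weight_matrix(graph_three_cycle(), p)
  tr <- simulate_ode(W, pw, c(1, 0.3, -0.7), t_max = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory(tr, path)
  tr2 <- read_trajectory(path)
  expect_equal(tr2$time, tr$time)
  expect_equal(unname(exna:::traj_states(tr2)), unname(exna:::traj_states(tr)),
               tolerance = 1e-12)
})
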
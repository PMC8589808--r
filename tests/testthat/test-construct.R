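test_that("the parameter recipe reproduces its defining relations exactly", {
  p <- recipe_params(0.4)
  expect_identical(p$eps, 0.05)
  expect_identical(p$theta, 0.5)
  expect_identical(p$w_s, 1)
  expect_identical(p$w_t, 0)
  expect_identical(p$w_p, 0.3)
  expect_identical(p$w_m, -0.7)

  p2 <- recipe_params(0.2)
  expect_identical(p2$eps, 0.025)
  expect_identical(p2$w_p, 0.4)
  expect_identical(p2$w_m, -0.6)

  expect_error(recipe_params(0), class = "exna_domain")
  expect_error(recipe_params(0.5), class = "exna_domain")

  # recipe consistency across the admissible range of delta
  for (d in seq(0.01, 0.49, by = 0.04)) {
    pd <- recipe_params(d)
    expect_lt(pd$w_p, pd$theta)
    expect_lt(pd$w_m, 0)
  }
})

test_that("weight synthesis matches the formula and the four-case description", {
  p <- recipe_params(0.4)
  W2 <- build_weight_matrix(graph_two_cell(), p)
  expect_equal(unname(W2$w), rbind(c(1, -0.7), c(0.3, 1)))

  empty <- digraph(matrix(0, 3, 3))
  pe <- construction_params(0.05, 0.5, 1, -0.7, 0.3, 0.1)
  We <- build_weight_matrix(empty, pe)
  expect_equal(unname(diag(We$w)), rep(1, 3))
  expect_true(all(We$w[row(We$w) != col(We$w)] == 0.1))

  # entrywise rebuild from the case description over random admissible graphs
  rebuild <- function(A, p) {
    n <- nrow(A)
    w <- matrix(NA_real_, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      w[i, j] <- if (i == j) p$w_s
        else if (A[j, i] == 1) p$w_p
        else if (A[i, j] == 1) p$w_m
        else p$w_t
    }
    w
  }
  for (s in 1:200) {
    g <- random_admissible_graph(6, 0.25, seed = 4000 + s,
                                 require_no_sink_subgraph = FALSE)
    W <- build_weight_matrix(g, pe)
    expect_equal(unname(W$w), rebuild(g$adjacency, pe))
  }
})

test_that("per-edge leading-weight overrides replace only their entry", {
  p <- default_smooth_params(w_t = -0.05)
  ov <- data.frame(from = c(2, 2), to = c(3, 4), w_p = c(0.306, 0.304))
  W <- build_weight_matrix(graph_kirk_silber(), p, wp_overrides = ov)
  expect_equal(W$w[3, 2], 0.306)
  expect_equal(W$w[4, 2], 0.304)
  expect_equal(W$w[2, 1], p$w_p) # other edges keep the shared w_p
  expect_equal(W$w[1, 3], p$w_p)
  expect_equal(W$w[1, 4], p$w_p)

  expect_error(
    build_weight_matrix(graph_kirk_silber(), p,
                        wp_overrides = data.frame(from = 1, to = 3, w_p = 0.31)),
    class = "exna_unknown_edge"
  )
})

test_that("inadmissible graphs are rejected unless explicitly allowed", {
  bad <- digraph(rbind(c(0, 1), c(1, 0)))
  p <- recipe_params(0.4)
  expect_error(build_weight_matrix(bad, p), class = "exna_inadmissible")
  expect_warning(W <- build_weight_matrix(bad, p, allow_inadmissible = TRUE))
  expect_equal(dim(W$w), c(2, 2))
})

test_that("activation functions satisfy their defining properties", {
  sm <- smooth_spec()
  pw <- activation_spec("piecewise", eps = 0.05, theta = 0.5)

  expect_equal(activation(0.5, sm), 0.5)
  expect_equal(activation(0.5, pw), 0.5)
  expect_equal(activation(0.5 + 2 * 0.05, pw), 1)
  expect_equal(activation(0.5 - 2 * 0.05, pw), 0)
  expect_equal(activation(1, sm), 1 / (1 + exp(-10)))

  # monotone and bounded (property over random pairs)
  ys <- withr::with_seed(1, sort(runif(200, -3, 3)))
  for (spec in list(sm, pw)) {
    vals <- activation(ys, spec)
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0 & vals <= 1))
  }
  # maximum slope 1/(4 eps) at threshold
  h <- 1e-6
  expect_equal((activation(0.5 + h, sm) - activation(0.5 - h, sm)) / (2 * h),
               1 / (4 * 0.05), tolerance = 1e-6)
})

test_that("the smooth activation inverse is exact on its domain", {
  sm <- smooth_spec()
  expect_equal(activation_inverse(0.5, sm), 0.5)
  xs <- seq(0.01, 0.99, by = 0.01)
  expect_equal(activation(activation_inverse(xs, sm), sm), xs, tolerance = 1e-12)
  expect_error(activation_inverse(0, sm), class = "exna_domain")
  expect_error(activation_inverse(1, sm), class = "exna_domain")
  expect_error(activation_inverse(0.5, activation_spec("piecewise", 0.05, 0.5)),
               class = "exna_unsupported")
})

test_that("predicted equilibria carry the level-role taxonomy", {
  p <- recipe_params(0.4)
  eq <- predicted_equilibrium(graph_three_cycle(), p, 1)
  expect_equal(eq$state, c(1, 0.3, -0.7))
  expect_equal(eq$roles, c("Active", "Leading", "Trailing"))
  expect_identical(eq$residual, 0)
  expect_equal(eq$eigenvalues, rep(-1 + 0i, 3))
  expect_true(eq$stable)

  eq2 <- predicted_equilibrium(graph_kirk_silber(), p, 2)
  expect_equal(eq2$roles, c("Trailing", "Active", "Leading", "Leading"))
  expect_equal(eq2$state, c(-0.7, 1, 0.3, 0.3))

  # isolated vertex: everything else is Disconnected at Y_D = w_t
  giso <- digraph_from_edges(rbind(c(1, 2), c(2, 3), c(3, 1)), n = 4)
  pw <- construction_params(0.05, 0.5, 1, -0.7, 0.3, 0.1)
  eqi <- predicted_equilibrium(giso, pw, 4, kind = "piecewise")
  expect_equal(eqi$roles, c("Disconnected", "Disconnected", "Disconnected", "Active"))
  expect_equal(eqi$state, c(0.1, 0.1, 0.1, 1))

  expect_error(predicted_equilibrium(digraph(rbind(c(0, 1), c(1, 0))), p, 1),
               class = "exna_inadmissible")
})

test_that("piecewise recipe equilibria are exact saturated fixed points", {
  p <- recipe_params(0.4)
  pw <- params_activation(p, "piecewise")
  for (s in 1:10) {
    g <- random_admissible_graph(6, 0.2, seed = 300 + s,
                                 require_no_sink_subgraph = FALSE)
    W <- build_weight_matrix(g, p)
    for (k in seq_len(g$n)) {
      eq <- predicted_equilibrium(g, p, k)
      expect_identical(eq$residual, 0)
      expect_equal(eq$eigenvalues, rep(-1 + 0i, g$n))
      # all components strictly beyond the piecewise corners
      expect_true(all(abs(eq$state - p$theta) > 2 * p$eps))
      expect_equal(vector_field(eq$state, W, pw), rep(0, g$n))
    }
  }
})

test_that("overridden leading weights move the predicted leading level", {
  p <- default_smooth_params()
  ov <- data.frame(from = 2, to = 3, w_p = 0.306)
  eq <- predicted_equilibrium(graph_kirk_silber(), p, 2, wp_overrides = ov)
  expect_equal(eq$state[3], 0.306)
  expect_equal(eq$state[4], 0.3)
})

test_that("transition cell types follow the published case table", {
  expect_equal(transition_cell_types(graph_three_cycle(), 1, 2),
               c("AT", "LA", "TL"))
  expect_equal(transition_cell_types(graph_kirk_silber(), 2, 3),
               c("TL", "AT", "LA", "LD"))
  # two disconnected bystanders
  g <- digraph_from_edges(rbind(c(1, 2)), n = 4)
  expect_equal(transition_cell_types(g, 1, 2), c("AT", "LA", "DD", "DD"))
  expect_error(transition_cell_types(graph_three_cycle(), 1, 3),
               class = "exna_not_an_edge")
})
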
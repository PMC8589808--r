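#' Activation function specification
#'
#' The CTRNN nonlinearity is a sigmoid with threshold `theta` and steepness
#' `1/(4 eps)` at threshold. Two kinds are supported: the logistic (`smooth`)
#' activation, strictly increasing with range (0, 1), and the piecewise
#' affine (`piecewise`) activation, which saturates exactly at 0 and 1
#' outside `|y - theta| <= 2 eps`. Both satisfy `phi(theta) = 1/2`.
#'
#' @param kind `"smooth"` or `"piecewise"`.
#' @param eps Steepness scale, positive.
#' @param theta Activation threshold.
#' @return An `exna_activation` object.
#' @examples
#' sp <- activation_spec("smooth", eps = 0.05, theta = 0.5)
#' activation(0.5, sp)
#' @export
activation_spec <- function(kind = c("smooth", "piecewise"), eps, theta) {
  kind <- match.arg(kind)
  if (!is.numeric(eps) || eps <= 0) exna_abort("eps must be > 0", "exna_domain")
  structure(list(kind = kind, eps = eps, theta = theta), class = "exna_activation")
}

#' Evaluate the activation function
#'
#' @param y Numeric vector of cell states.
#' @param spec An `exna_activation`.
#' @return Values in `[0, 1]`, same length as `y`.
#' @export
activation <- function(y, spec) {
  if (spec$kind == "smooth") {
    1 / (1 + exp(-(y - spec$theta) / spec$eps))
  } else {
    pmin(pmax((y - spec$theta) / (4 * spec$eps) + 0.5, 0), 1)
  }
}

# derivative of the activation, used in Jacobians; exactly zero in the
# saturated regions of the piecewise kind
activation_deriv <- function(y, spec) {
  if (spec$kind == "smooth") {
    p <- activation(y, spec)
    p * (1 - p) / spec$eps
  } else {
    ifelse(abs(y - spec$theta) <= 2 * spec$eps, 1 / (4 * spec$eps), 0)
  }
}

#' Invert the smooth activation function
#'
#' `phi^{-1}(x) = theta - eps * log((1 - x) / x)`, defined for `x` in (0, 1).
#' The piecewise activation is not invertible (it is constant on its
#' saturated branches) and requesting its inverse is an error.
#'
#' @param x Numeric vector in (0, 1).
#' @param spec An `exna_activation` with `kind = "smooth"`.
#' @return Numeric vector with `activation(activation_inverse(x)) = x`.
#' @export
activation_inverse <- function(x, spec) {
  if (spec$kind != "smooth") {
    exna_abort("activation_inverse is only defined for the smooth kind", "exna_unsupported")
  }
  if (any(x <= 0 | x >= 1)) exna_abort("x must lie strictly in (0, 1)", "exna_domain")
  spec$theta - spec$eps * log((1 - x) / x)
}

#' Construction parameters for the excitable-network weight matrix
#'
#' Bundles the six scalars of the construction: activation steepness `eps`
#' and threshold `theta`, and the four coupling weights `w_s` (self), `w_m`
#' (onto a trailing cell), `w_p` (onto a leading cell) and `w_t`
#' (transverse, between otherwise unconnected cells). `delta` records the
#' excitability threshold when the parameters came from [recipe_params()].
#'
#' @param eps,theta Activation parameters; `eps > 0`.
#' @param w_s,w_m,w_p,w_t Coupling weights.
#' @param delta Optional excitability threshold in (0, 1/2).
#' @return An `exna_params` object.
#' @export
construction_params <- function(eps, theta, w_s, w_m, w_p, w_t, delta = NULL) {
  if (eps <= 0) exna_abort("eps must be > 0", "exna_domain")
  structure(
    list(eps = eps, theta = theta, w_s = w_s, w_m = w_m, w_p = w_p, w_t = w_t,
         delta = delta),
    class = "exna_params"
  )
}

#' Parameter recipe guaranteeing an excitable realisation
#'
#' For a target excitability threshold `delta` in (0, 1/2), the recipe sets
#' `eps = delta / 8`, `theta = 1/2`, `w_s = 1`, `w_t = 0`,
#' `w_p = theta - delta / 2` and `w_m = -(w_s - theta) - delta / 2`. With the
#' piecewise activation these values make every predicted equilibrium an
#' exact fixed point with all cells saturated, and every graph edge an
#' excitable connection of amplitude `delta`.
#'
#' @param delta Excitability threshold, in (0, 1/2).
#' @return An `exna_params` object with the recipe values (exactly).
#' @examples
#' p <- recipe_params(0.4)
#' c(p$w_p, p$w_m) # 0.3, -0.7
#' @export
recipe_params <- function(delta) {
  if (!is.numeric(delta) || delta <= 0 || delta >= 0.5) {
    exna_abort("delta must lie in (0, 1/2)", "exna_domain")
  }
  theta <- 1 / 2
  w_s <- 1
  construction_params(
    eps = delta / 8, theta = theta, w_s = w_s,
    w_m = -(w_s - theta) - delta / 2,
    w_p = theta - delta / 2,
    w_t = 0,
    delta = delta
  )
}

#' @export
print.exna_params <- function(x, ...) {
  cat("<exna_params>\n")
  v <- unlist(x[c("eps", "theta", "w_s", "w_m", "w_p", "w_t")])
  cat(paste0("  ", names(v), " = ", format(v)), sep = "\n")
  if (!is.null(x$delta)) cat("  delta =", format(x$delta), "(recipe)\n")
  invisible(x)
}

#' @export
glance.exna_params <- function(x, ...) {
  tibble::tibble(eps = x$eps, theta = x$theta, w_s = x$w_s, w_m = x$w_m,
                 w_p = x$w_p, w_t = x$w_t,
                 delta = if (is.null(x$delta)) NA_real_ else x$delta)
}

#' Activation spec matching a parameter set
#'
#' @param params An `exna_params`.
#' @param kind `"smooth"` or `"piecewise"`.
#' @return An `exna_activation` with the parameter set's `eps` and `theta`.
#' @export
params_activation <- function(params, kind = c("smooth", "piecewise")) {
  activation_spec(match.arg(kind), eps = params$eps, theta = params$theta)
}

normalise_overrides <- function(wp_overrides, graph) {
  if (is.null(wp_overrides)) return(NULL)
  ov <- tibble::as_tibble(wp_overrides)
  if (!all(c("from", "to", "w_p") %in% names(ov))) {
    exna_abort("wp_overrides needs columns from, to, w_p", "exna_malformed_input")
  }
  A <- graph$adjacency
  for (r in seq_len(nrow(ov))) {
    if (ov$from[r] < 1 || ov$to[r] > graph$n || A[ov$from[r], ov$to[r]] != 1L) {
      exna_abort(sprintf("w_p override keyed on non-edge %d->%d", ov$from[r], ov$to[r]),
                 "exna_unknown_edge")
    }
  }
  ov
}

#' Synthesise the CTRNN weight matrix realising a graph
#'
#' The coupling matrix is
#' `w_ij = w_t + (w_s - w_t) [i = j] + (w_p - w_t) a_ji + (w_m - w_t) a_ij`,
#' so each entry is the self weight on the diagonal, `w_p` where cell `j`
#' feeds cell `i` along a graph edge `j -> i`, `w_m` along the reverse
#' orientation, and `w_t` otherwise. Edge-dependent leading weights are
#' supported through `wp_overrides`: an override for edge `k -> l` replaces
#' only the entry `w[l, k]`.
#'
#' @param graph An admissible `exna_digraph`.
#' @param params An `exna_params`.
#' @param wp_overrides Optional data frame with columns `from`, `to`, `w_p`
#'   giving per-edge replacements for `w_p`.
#' @param allow_inadmissible Proceed (with a warning) on an inadmissible
#'   graph; default is a hard error, since the role taxonomy behind the
#'   construction is then ill-defined.
#' @return An `exna_weights` object: fields `n`, `w` (the matrix), `params`,
#'   `graph`, `wp_overrides`.
#' @examples
#' W <- build_weight_matrix(graph_two_cell(), recipe_params(0.4))
#' W$w
#' @export
build_weight_matrix <- function(graph, params, wp_overrides = NULL,
                                allow_inadmissible = FALSE) {
  rep_ <- validate_graph(graph)
  if (!rep_$admissible) {
    if (allow_inadmissible) {
      warn("graph is not admissible; proceeding as requested")
    } else {
      exna_abort("graph is not admissible (one-loops, two-loops or delta-cliques present)",
                 "exna_inadmissible")
    }
  }
  A <- graph$adjacency
  n <- graph$n
  w <- params$w_t +
    (params$w_s - params$w_t) * diag(n) +
    (params$w_p - params$w_t) * t(A) +
    (params$w_m - params$w_t) * A
  ov <- normalise_overrides(wp_overrides, graph)
  if (!is.null(ov)) {
    for (r in seq_len(nrow(ov))) w[ov$to[r], ov$from[r]] <- ov$w_p[r]
  }
  structure(list(n = n, w = w, params = params, graph = graph, wp_overrides = ov),
            class = "exna_weights")
}

#' @export
print.exna_weights <- function(x, ...) {
  cat("<exna_weights> ", x$n, " cells\n", sep = "")
  print(round(x$w, 6))
  invisible(x)
}

# leading-weight into cell j when cell k is active, honouring overrides
wp_into <- function(weights_or_graph, params, j, k, ov = NULL) {
  if (!is.null(ov)) {
    hit <- which(ov$from == k & ov$to == j)
    if (length(hit)) return(ov$w_p[hit[1]])
  }
  params$w_p
}

#' Predicted equilibrium of the constructed network
#'
#' For active vertex `k`, the construction predicts a stable equilibrium in
#' which cell `k` sits at `Y_A = w_s`, every cell `j` with an edge `k -> j`
#' (Leading) at `Y_L = w_p`, every cell with an edge `j -> k` (Trailing) at
#' `Y_T = w_m`, and all remaining cells (Disconnected) at `Y_D = w_t`. With
#' the piecewise activation and recipe parameters every component is
#' saturated, the prediction is an exact fixed point (residual 0) and the
#' Jacobian there is `-I`.
#'
#' @param graph An admissible `exna_digraph`.
#' @param params An `exna_params`.
#' @param k Active vertex index.
#' @param kind Activation kind used for the residual/stability check.
#' @param wp_overrides Optional per-edge `w_p` replacements (see
#'   [build_weight_matrix()]); a leading cell `j` then sits at its own
#'   `w_p^{jk}` level.
#' @return An `exna_equilibrium`: fields `state`, `active_set`, `roles`,
#'   `levels`, `residual`, `eigenvalues`, `stable`.
#' @examples
#' eq <- predicted_equilibrium(graph_three_cycle(), recipe_params(0.4), k = 1)
#' eq$state # 1, 0.3, -0.7
#' @export
predicted_equilibrium <- function(graph, params, k, kind = "piecewise",
                                  wp_overrides = NULL) {
  if (!is_admissible(graph)) {
    exna_abort("cell roles are ill-defined on an inadmissible graph", "exna_inadmissible")
  }
  n <- graph$n
  if (k < 1 || k > n) exna_abort("k outside 1..n", "exna_domain")
  A <- graph$adjacency
  ov <- normalise_overrides(wp_overrides, graph)

  roles <- rep("Disconnected", n)
  roles[A[k, ] == 1L] <- "Leading"
  roles[A[, k] == 1L] <- "Trailing"
  roles[k] <- "Active"

  levels <- c(Y_A = params$w_s, Y_L = params$w_p, Y_T = params$w_m, Y_D = params$w_t)
  state <- numeric(n)
  for (j in seq_len(n)) {
    state[j] <- switch(roles[j],
      Active = params$w_s,
      Leading = wp_into(NULL, params, j, k, ov),
      Trailing = params$w_m,
      Disconnected = params$w_t
    )
  }

  W <- build_weight_matrix(graph, params, wp_overrides = ov)
  spec <- params_activation(params, kind)
  f <- field_y(state, W$w, spec)
  J <- jacobian_y(state, W$w, spec)
  ev <- as.complex(eigen(J, only.values = TRUE)$values)

  structure(
    list(state = state, active_set = k, roles = roles, levels = levels,
         residual = max(abs(f)), eigenvalues = ev, stable = all(Re(ev) < 0)),
    class = "exna_equilibrium"
  )
}

#' @export
print.exna_equilibrium <- function(x, ...) {
  cat("<exna_equilibrium> active set {", paste(x$active_set, collapse = ","),
      "}, residual ", format(x$residual), ", stable: ", x$stable, "\n", sep = "")
  invisible(x)
}

#' @describeIn predicted_equilibrium one row per cell: state component, role
#'   and predicted level.
#' @param x An `exna_equilibrium`.
#' @param ... Unused.
#' @export
tidy.exna_equilibrium <- function(x, ...) {
  tibble::tibble(
    cell = seq_along(x$state),
    state = x$state,
    role = if (is.null(x$roles)) NA_character_ else x$roles
  )
}

#' Cell types during a transition
#'
#' During the transition along edge `k -> l`, the active cell `k` is of type
#' AT (Active to Trailing) and the target `l` of type LA (Leading to
#' Active). Every other cell falls into one of six types determined by its
#' adjacency pattern `(a_jk, a_kj, a_jl, a_lj)`: DD, TD, LD, TL, DT or DL
#' (first letter: role at the source equilibrium; second: role at the
#' destination). Admissibility guarantees these eight types are exhaustive.
#'
#' @param graph An admissible `exna_digraph`.
#' @param k,l Source and target vertices of an edge `k -> l`.
#' @return Character vector of length `n` over
#'   `{AT, LA, DD, TD, LD, TL, DT, DL}`.
#' @examples
#' transition_cell_types(graph_three_cycle(), 1, 2) # "AT" "LA" "TL"
#' @export
transition_cell_types <- function(graph, k, l) {
  if (!is_admissible(graph)) {
    exna_abort("cell types are ill-defined on an inadmissible graph", "exna_inadmissible")
  }
  A <- graph$adjacency
  if (A[k, l] != 1L) exna_abort(sprintf("%d->%d is not an edge", k, l), "exna_not_an_edge")
  n <- graph$n
  types <- character(n)
  types[k] <- "AT"
  types[l] <- "LA"
  for (j in setdiff(seq_len(n), c(k, l))) {
    pat <- c(A[j, k], A[k, j], A[j, l], A[l, j])
    types[j] <- if (all(pat == c(0, 0, 0, 0))) "DD"
      else if (all(pat == c(1, 0, 0, 0))) "TD"
      else if (all(pat == c(0, 1, 0, 0))) "LD"
      else if (all(pat == c(1, 0, 0, 1))) "TL"
      else if (all(pat == c(0, 0, 1, 0))) "DT"
      else if (all(pat == c(0, 0, 0, 1))) "DL"
      else exna_abort(
        sprintf("cell %d has adjacency pattern excluded by admissibility", j),
        "exna_internal"
      )
  }
  types
}
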
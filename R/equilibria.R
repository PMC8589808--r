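#' Newton refinement of an equilibrium
#'
#' Refines `guess` to a fixed point of the input-free field by damped Newton
#' iteration on `f(y) = -y + W phi(y)` with the analytic Jacobian
#' `-I + W diag(phi'(y))`. With the piecewise activation at a fully
#' saturated prediction the residual is already zero and the guess is
#' returned unchanged with all eigenvalues exactly `-1`.
#'
#' Non-convergence is reported as an error of class
#' `exna_no_equilibrium`. This is informative rather than fatal: the
#' disappearance of a refined equilibrium as a parameter is varied is the
#' detection mechanism used by the fold and SNIC threshold searches.
#'
#' @param weights An `exna_weights`.
#' @param spec An `exna_activation`.
#' @param guess Length-`n` starting point.
#' @param tol Max-norm residual target (default `1e-10`).
#' @param max_iter Newton iteration cap (default 50).
#' @return An `exna_equilibrium` with `state`, `residual`, `eigenvalues`,
#'   `stable` (roles are not assigned by refinement).
#' @export
refine_equilibrium <- function(weights, spec, guess, tol = 1e-10, max_iter = 50L) {
  if (!all(is.finite(guess))) exna_abort("guess must be finite", "exna_domain")
  y <- as.numeric(guess)
  w <- weights$w
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- field_y(y, w, spec)
    if (max(abs(f)) <= tol) {
      converged <- TRUE
      break
    }
    J <- jacobian_y(y, w, spec)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      exna_abort("Newton step failed (singular Jacobian): no equilibrium found",
                 "exna_no_equilibrium")
    }
    # damp long steps to stay on the relaxation scale of the model
    sl <- max(abs(step))
    if (sl > 1) step <- step / sl
    y <- y - step
  }
  if (!converged) {
    f <- field_y(y, w, spec)
    if (max(abs(f)) > tol) {
      exna_abort(sprintf("Newton did not converge in %d iterations (residual %.3g)",
                         max_iter, max(abs(f))),
                 "exna_no_equilibrium")
    }
  }
  J <- jacobian_y(y, w, spec)
  ev <- as.complex(eigen(J, only.values = TRUE)$values)
  structure(
    list(state = y, active_set = NULL, roles = NULL, levels = NULL,
         residual = max(abs(field_y(y, w, spec))),
         eigenvalues = ev, stable = all(Re(ev) < 0)),
    class = "exna_equilibrium"
  )
}

# try refinement; NULL instead of error (internal)
try_refine <- function(weights, spec, guess, ...) {
  tryCatch(refine_equilibrium(weights, spec, guess, ...),
           exna_no_equilibrium = function(e) NULL)
}

# refined (smooth) or exact (piecewise) equilibria for all vertices, plus
# the near-origin rest state; used as the candidate set for classification
equilibrium_candidates <- function(graph, params, spec, wp_overrides = NULL) {
  n <- graph$n
  cands <- vector("list", n)
  for (k in seq_len(n)) {
    pred <- predicted_equilibrium(graph, params, k, kind = spec$kind,
                                  wp_overrides = wp_overrides)
    if (spec$kind == "piecewise" && pred$residual == 0) {
      cands[[k]] <- pred$state
    } else {
      W <- build_weight_matrix(graph, params, wp_overrides = wp_overrides)
      ref <- try_refine(W, spec, pred$state)
      if (is.null(ref)) {
        exna_abort(sprintf("no equilibrium near the prediction for vertex %d", k),
                   "exna_no_equilibrium")
      }
      cands[[k]] <- ref$state
    }
  }
  W <- build_weight_matrix(graph, params, wp_overrides = wp_overrides)
  origin <- try_refine(W, spec, numeric(n))
  if (!is.null(origin)) cands[["origin"]] <- origin$state
  cands
}
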
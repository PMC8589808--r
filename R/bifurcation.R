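# scalar auxiliary map g(x) = phi^{-1}(x) - w_s x and friends; the fold
# computations below all reduce to properties of this map
g_map <- function(x, eps, theta, w_s) {
  theta - eps * log((1 - x) / x) - w_s * x
}
g_prime <- function(x, eps, w_s) {
  eps / (x * (1 - x)) - w_s
}

# local extrema of g when w_s > 4 eps
g_extrema <- function(eps, w_s) {
  if (w_s <= 4 * eps) {
    exna_abort("extrema require w_s > 4 eps", "exna_domain")
  }
  r <- sqrt(1 / 4 - eps / w_s)
  c(x_minus = 1 / 2 - r, x_plus = 1 / 2 + r)
}

#' Asymptotic saddle-node threshold of the two-cell system
#'
#' Closed-form approximation (through the `eps^2` term) of the value of
#' `w_p` at which the stable one-active-cell equilibrium of the two-cell
#' network is destroyed in a saddle-node bifurcation:
#' `w_p^SN = eps log(eps) + theta - eps (1 + log(w_s)) + eps^2 / w_s`.
#' As `eps -> 0` the threshold tends to `theta`.
#'
#' @param eps,theta,w_s Smooth-activation parameters; requires
#'   `theta < w_s` (a warning is attached to the result otherwise).
#' @return The truncated threshold value. If `theta >= w_s` the result
#'   carries attribute `hypothesis_violated = TRUE`.
#' @examples
#' signif(wp_sn_closed_form(0.05, 0.5, 1), 4) # 0.3027
#' @export
wp_sn_closed_form <- function(eps, theta, w_s) {
  if (eps <= 0) exna_abort("eps must be > 0", "exna_domain")
  out <- eps * log(eps) + theta - eps * (1 + log(w_s)) + eps^2 / w_s
  if (theta >= w_s) {
    warn("closed-form threshold assumes theta < w_s")
    attr(out, "hypothesis_violated") <- TRUE
  }
  out
}

#' Numerical saddle-node threshold of the two-cell system
#'
#' Locates the fold of the two-cell smooth system exactly, by Newton
#' iteration on the extended system: the two equilibrium conditions in
#' `(J_1, J_2)` together with the vanishing of the Jacobian determinant,
#' solved for `(J_1, J_2, w_p)`. Seeded from the closed-form threshold with
#' `J_1` near 1 and `J_2` at the lower extremum `x_-` of the auxiliary map.
#' Falls back to bisection on equilibrium existence (via
#' [refine_equilibrium()]) if the extended Newton fails.
#'
#' @param params An `exna_params` (smooth activation; requires
#'   `theta < w_s` and `w_s > 4 eps`).
#' @return The critical `w_p`.
#' @export
wp_sn_numeric <- function(params) {
  eps <- params$eps; theta <- params$theta; w_s <- params$w_s; w_m <- params$w_m
  if (theta >= w_s) exna_abort("requires theta < w_s", "exna_domain")
  ex <- g_extrema(eps, w_s) # errors if w_s <= 4 eps
  phinv <- function(x) theta - eps * log((1 - x) / x)
  FF <- function(v) {
    J1 <- v[1]; J2 <- v[2]; wp <- v[3]
    c(-phinv(J1) + w_s * J1 + w_m * J2,
      -phinv(J2) + w_s * J2 + wp * J1,
      (w_s - eps / (J1 * (1 - J1))) * (w_s - eps / (J2 * (1 - J2))) - w_m * wp)
  }
  v <- c(1 - 1e-4, ex[["x_minus"]], wp_sn_closed_form(eps, theta, w_s))
  ok <- TRUE
  for (it in 1:60) {
    f0 <- FF(v)
    if (max(abs(f0)) < 1e-13) break
    h <- 1e-8
    Jn <- vapply(1:3, function(j) {
      vp <- v; vp[j] <- vp[j] + h
      (FF(vp) - f0) / h
    }, numeric(3))
    step <- tryCatch(solve(Jn, f0), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) { ok <- FALSE; break }
    v <- v - step
    if (v[1] <= 0 || v[1] >= 1 || v[2] <= 0 || v[2] >= 1) { ok <- FALSE; break }
  }
  if (ok && max(abs(FF(v))) < 1e-10) return(v[3])

  # fallback: bisection on existence of the stable two-cell equilibrium
  two_cell_exists <- function(wp) {
    p2 <- params; p2$w_p <- wp
    W <- build_weight_matrix(graph_two_cell(), p2)
    spec <- params_activation(p2, "smooth")
    guess <- c(p2$w_s, wp)
    ref <- try_refine(W, spec, guess)
    !is.null(ref) && ref$stable && max(abs(ref$state - guess)) < 0.25
  }
  bisect_existence(two_cell_exists, lo = theta - 0.25, hi = theta + 0.1, tol = 1e-9)
}

# bisection helper: f(lo) must be TRUE (exists), f(hi) FALSE
bisect_existence <- function(exists, lo, hi, tol) {
  if (!exists(lo) || exists(hi)) {
    exna_abort("bisection bracket does not straddle the threshold", "exna_detection")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (exists(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' SNIC threshold of the three-cell cycle
#'
#' The three-cell cycle loses its stable one-active-cell equilibria in three
#' simultaneous saddle-node bifurcations on an invariant circle (SNIC) as
#' `w_p` increases; the destroyed equilibria are replaced by a periodic
#' orbit whose period diverges at threshold. The threshold is located by
#' bisection in `w_p` on the existence of the stable equilibrium (Newton
#' refinement from the saturated prediction), to absolute tolerance `tol`.
#' By the cyclic symmetry all three folds coincide.
#'
#' @param params An `exna_params` (smooth activation).
#' @param tol Bisection tolerance on `w_p` (default `1e-6`).
#' @param bracket Search interval; defaults to
#'   `(theta - 0.2, theta + 0.1)`.
#' @return The critical `w_p`.
#' @export
snic_threshold_cycle <- function(params, tol = 1e-6, bracket = NULL) {
  if (is.null(bracket)) bracket <- c(params$theta - 0.2, params$theta + 0.1)
  g <- graph_three_cycle()
  exists_at <- function(wp) {
    p2 <- params; p2$w_p <- wp
    W <- build_weight_matrix(g, p2)
    spec <- params_activation(p2, "smooth")
    guess <- c(p2$w_s, wp, p2$w_m)
    ref <- try_refine(W, spec, guess)
    !is.null(ref) && ref$stable && max(abs(ref$state - guess)) < 0.25
  }
  tryCatch(
    bisect_existence(exists_at, bracket[1], bracket[2], tol),
    exna_detection = function(e) {
      exna_abort("no sign change in the SNIC bracket", "exna_detection")
    }
  )
}

#' Fold threshold at a vertex with two leading directions
#'
#' At a vertex with two outgoing edges the two leading cells interact
#' through the transverse weight `w_t`, and the pair of equilibrium
#' conditions on the active sheet is `g(J_3) = w_p3 + w_t J_4`,
#' `g(J_4) = w_p4 + w_t J_3` with `w_p3 = w_p + dw`, `w_p4 = w_p` and
#' `g(x) = phi^{-1}(x) - w_s x`. The transition between excitable and
#' spontaneous dynamics is the value of `w_p` at which the solution with
#' both leading cells at low activation disappears; it is located by
#' bisection on existence (Newton on the pair from seeds below the lower
#' extremum `x_-`). Negative `w_t` pushes the threshold up (suppression),
#' positive `w_t` pulls it down.
#'
#' @param w_t Transverse weight.
#' @param dw Leading-weight asymmetry `w_p3 - w_p4 >= 0`.
#' @param params An `exna_params` (smooth activation).
#' @param tol Bisection tolerance (default `1e-6`).
#' @return The critical `w_p` (the threshold for the weaker edge).
#' @export
wp_sn_prime <- function(w_t, dw, params, tol = 1e-6) {
  eps <- params$eps; theta <- params$theta; w_s <- params$w_s
  ex <- g_extrema(eps, w_s)
  xm <- ex[["x_minus"]]
  pair_exists <- function(wp) {
    wp3 <- wp + dw; wp4 <- wp
    FF <- function(v) {
      c(g_map(v[1], eps, theta, w_s) - wp3 - w_t * v[2],
        g_map(v[2], eps, theta, w_s) - wp4 - w_t * v[1])
    }
    for (d in c(0.02, 0.005, 0.04)) {
      v <- c(xm - d, xm - d)
      good <- TRUE
      for (it in 1:100) {
        f0 <- FF(v)
        if (max(abs(f0)) < 1e-12) break
        Jn <- rbind(c(g_prime(v[1], eps, w_s), -w_t),
                    c(-w_t, g_prime(v[2], eps, w_s)))
        step <- tryCatch(solve(Jn, f0), error = function(e) NULL)
        if (is.null(step) || !all(is.finite(step))) { good <- FALSE; break }
        # project onto the low-activation branch (0, x_-], where g' >= 0
        v <- pmin(pmax(v - step, 1e-12), xm)
      }
      if (!good || max(abs(FF(v))) > 1e-10) next
      gp <- c(g_prime(v[1], eps, w_s), g_prime(v[2], eps, w_s))
      # accept only the low-activation, dynamically stable configuration
      if (all(v > 0) && all(v < 0.4) && sum(gp) > 0 && gp[1] * gp[2] - w_t^2 > -1e-9) {
        return(TRUE)
      }
    }
    FALSE
  }
  bisect_existence(pair_exists, lo = 0.1, hi = theta + 0.05, tol = tol)
}

#' Leading-cell equilibrium positions near the fold
#'
#' Asymptotic positions of the pair of equilibria that exist just below the
#' saddle-node threshold: at `w_p = w_p^SN - eta` the leading-cell
#' coordinate sits at `J_2 = eps / w_s +- sqrt(2 eta eps) / w_s`, to
#' `O(eps^2)`, with the active cell at `J_1 = 1`. Valid for
#' `0 < eta << eps / 4` (a warning is raised outside that range).
#'
#' @param eta Distance below the fold threshold, positive.
#' @param params An `exna_params`.
#' @return Named numeric vector `c(lower, upper)` of predicted `J_2` values.
#' @export
lemma2_positions <- function(eta, params) {
  if (eta <= 0) exna_abort("eta must be > 0", "exna_domain")
  if (eta >= params$eps / 4) {
    warn("asymptotic positions assume eta << eps / 4")
  }
  centre <- params$eps / params$w_s
  dev <- sqrt(2 * eta * params$eps) / params$w_s
  c(lower = centre - dev, upper = centre + dev)
}

#' Bundle the bifurcation thresholds for a network
#'
#' Convenience wrapper computing the closed-form and numerical two-cell
#' fold, the three-cycle SNIC threshold and (optionally) the two-leading
#' fold, and returning them as one record.
#'
#' @param params An `exna_params` (smooth activation).
#' @param w_t,dw Passed to [wp_sn_prime()]; set `dw = NULL` to skip it.
#' @return A `exna_bifurcation` list; `tidy()` gives a one-row tibble.
#' @export
bifurcation_thresholds <- function(params, w_t = params$w_t, dw = 0) {
  ex <- g_extrema(params$eps, params$w_s)
  out <- list(
    wp_sn_closed = as.numeric(wp_sn_closed_form(params$eps, params$theta, params$w_s)),
    wp_sn_numeric = wp_sn_numeric(params),
    wp_snic = snic_threshold_cycle(params),
    wp_sn_prime = if (is.null(dw)) NA_real_ else wp_sn_prime(w_t, dw, params),
    x_minus = ex[["x_minus"]],
    x_plus = ex[["x_plus"]],
    dw = if (is.null(dw)) NA_real_ else dw,
    w_t = w_t
  )
  structure(out, class = "exna_bifurcation")
}

#' @export
print.exna_bifurcation <- function(x, ...) {
  cat("<exna_bifurcation>\n")
  cat("  w_p fold (closed form):", format(x$wp_sn_closed, digits = 6), "\n")
  cat("  w_p fold (numeric):    ", format(x$wp_sn_numeric, digits = 6), "\n")
  cat("  w_p SNIC (3-cycle):    ", format(x$wp_snic, digits = 6), "\n")
  if (!is.na(x$wp_sn_prime)) {
    cat("  w_p fold (two leading):", format(x$wp_sn_prime, digits = 6), "\n")
  }
  invisible(x)
}

#' @export
tidy.exna_bifurcation <- function(x, ...) {
  tibble::tibble(
    wp_sn_closed = x$wp_sn_closed, wp_sn_numeric = x$wp_sn_numeric,
    wp_snic = x$wp_snic, wp_sn_prime = x$wp_sn_prime,
    x_minus = x$x_minus, x_plus = x$x_plus, dw = x$dw, w_t = x$w_t
  )
}
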
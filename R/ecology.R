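#' Gaussian trait-matching kernel
#'
#' Strength of the mutualistic interaction between a plant and a pollinator
#' as a function of their trait mismatch:
#' `exp(-(plant_trait - pollinator_trait)^2 / (2 * sigma^2))`.
#' Equals 1 at a perfect match and decays with mismatch at a rate set by
#' the tolerance width `sigma`; symmetric in the two traits.
#'
#' @param plant_trait,pollinator_trait trait values (vectorised).
#' @param sigma positive real; width of the trait-matching tolerance.
#' @return Values in (0, 1].
#' @examples
#' trait_match(1, 3, 1)  # exp(-2)
#' @export
trait_match <- function(plant_trait, pollinator_trait, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be > 0")
  exp(-(plant_trait - pollinator_trait)^2 / (2 * sigma^2))
}

## 2x2 matrix of mutualistic coefficients theta * phi^[cross] * kernel;
## rows index plants, columns pollinators. The phi discount applies to the
## cross pair (Plant i with Pollinator j, j != i).
mutualism_matrix <- function(traits, params) {
  rho <- as.numeric(traits)
  pi_ <- c(params$pi1, params$pi2)
  m <- outer(pi_, rho, trait_match, sigma = params$sigma)
  disc <- matrix(c(1, params$phi, params$phi, 1), 2, 2)
  params$theta * disc * m
}

#' Per-capita growth rates
#'
#' The right-hand side of the model in per-capita form. For plant i:
#' logistic growth with interspecific competition `alpha` plus the
#' mutualistic benefit received from both pollinators, discounted by `phi`
#' for the cross (non-matched) pair; analogously for pollinator i, which
#' receives benefit from both plants and competes with the other pollinator
#' under the shared carrying capacity `K_R`.
#'
#' @param state a [community_state()] or numeric of length 4 (P1, P2, R1,
#'   R2).
#' @param traits a [pollinator_traits()] pair.
#' @param params a [model_parameters()] object.
#' @return Named numeric of length 4: per-capita growth of P1, P2, R1, R2.
#' @export
per_capita_growth <- function(state, traits, params) {
  x <- as.numeric(state)
  P <- x[1:2]; R <- x[3:4]
  A <- mutualism_matrix(traits, params)
  comp <- matrix(c(1, params$alpha, params$alpha, 1), 2, 2)
  gP <- params$r_m * (1 - (comp %*% P) / c(params$K1, params$K2)) + A %*% R
  gR <- params$r_m * (1 - (comp %*% R) / params$K_R) + t(A) %*% P
  c(P1 = gP[1], P2 = gP[2], R1 = gR[1], R2 = gR[2])
}

#' ODE right-hand side
#'
#' Componentwise abundance times per-capita growth; exactly zero for any
#' component whose abundance is zero (the extinction boundary is
#' absorbing).
#'
#' @inheritParams per_capita_growth
#' @return Named numeric of length 4: dP1/dt, dP2/dt, dR1/dt, dR2/dt.
#' @export
ode_rhs <- function(state, traits, params) {
  as.numeric(state) * per_capita_growth(state, traits, params)
}

## analytic Jacobian of ode_rhs at `state`; used by the Newton polish.
## d(x_i g_i)/dx_j = delta_ij g_i + x_i dg_i/dx_j, with dg/dx constant in
## the state (Lotka-Volterra structure).
ode_jacobian <- function(state, traits, params) {
  x <- as.numeric(state)
  A <- mutualism_matrix(traits, params)
  comp <- matrix(c(1, params$alpha, params$alpha, 1), 2, 2)
  dg <- matrix(0, 4, 4)
  dg[1:2, 1:2] <- -params$r_m * comp / c(params$K1, params$K2)
  dg[1:2, 3:4] <- A
  dg[3:4, 3:4] <- -params$r_m * comp / params$K_R
  dg[3:4, 1:2] <- t(A)
  diag(per_capita_growth(x, traits, params)) + x * dg
}

## damped Newton refinement of an equilibrium candidate, restricted to
## components above `active_tol` (near-extinct components are left to the
## integrator). Returns the refined state, or NULL if refinement failed to
## reduce the residual or left the admissible region.
newton_polish <- function(state, traits, params, active_tol = 1e-3,
                          max_iter = 25L) {
  x <- as.numeric(state)
  active <- which(x > active_tol)
  if (length(active) == 0L) return(NULL)
  res0 <- max(abs(ode_rhs(x, traits, params)))
  for (i in seq_len(max_iter)) {
    f <- ode_rhs(x, traits, params)[active]
    J <- ode_jacobian(x, traits, params)[active, active, drop = FALSE]
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lambda <- 1
    repeat {
      cand <- x
      cand[active] <- x[active] + lambda * step
      if (all(cand[active] > 0)) {
        fc <- ode_rhs(cand, traits, params)[active]
        if (max(abs(fc)) < max(abs(f))) break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) return(NULL)
    }
    x <- cand
    if (max(abs(ode_rhs(x, traits, params))) < 1e-13) break
  }
  if (max(abs(ode_rhs(x, traits, params))) <= res0) x else NULL
}

#' Solve for the ecological equilibrium
#'
#' Integrates the community ODEs from `initial` until the dynamics are
#' stationary (max |dX/dt| below `settings$tol_eq`, sustained over a
#' trailing window of `settings$window` model-time units), or until the
#' horizon `settings$t_max`. Abundances are kept non-negative throughout
#' (round-off negatives clipped, see [validate_state()]). After
#' integration the state is optionally refined by a damped Newton solve on
#' the right-hand side restricted to non-negligible components.
#'
#' @param traits a [pollinator_traits()] pair (held fixed).
#' @param params a [model_parameters()] object.
#' @param initial starting abundances; default is the interior point
#'   `(K1/2, K2/2, K_R/2, K_R/2)`, which avoids trivial extinction basins.
#'   During trait evolution, warm-start from the previous equilibrium.
#' @param settings a [solver_settings()] list.
#' @return An [ecological_equilibrium()]; `converged = FALSE` (with the
#'   achieved residual) if stationarity was not reached by `t_max`.
#' @examples
#' p <- model_parameters(sigma = 0.25, phi = 0.5)
#' eq <- find_equilibrium(pollinator_traits(1, 3), p)
#' eq$state
#' @export
find_equilibrium <- function(traits, params, initial = NULL,
                             settings = solver_settings()) {
  if (is.null(initial))
    initial <- c(params$K1 / 2, params$K2 / 2, params$K_R / 2,
                 params$K_R / 2)
  y <- as.numeric(validate_state(initial, settings$eps_clip))
  deriv <- function(t, y, p) list(ode_rhs(y, traits, params))

  elapsed <- 0
  chunk <- 50
  resid <- max(abs(ode_rhs(y, traits, params)))
  repeat {
    ## early exit: residual already stationary (e.g. warm start) -- still
    ## confirm over the trailing window below
    if (resid >= settings$tol_eq) {
      if (elapsed >= settings$t_max) break
      dt <- min(chunk, settings$t_max - elapsed)
      out <- deSolve::lsoda(y, c(0, dt), deriv, NULL,
                            rtol = settings$rtol, atol = settings$atol)
      y <- as.numeric(validate_state(out[nrow(out), -1], settings$eps_clip))
      elapsed <- elapsed + dt
      chunk <- min(chunk * 2, 5000)
      resid <- max(abs(ode_rhs(y, traits, params)))
    }
    if (resid < settings$tol_eq || resid < 1e-4) {
      ## candidate: polish, then require stationarity sustained over the
      ## trailing window
      if (settings$newton_polish) {
        pol <- newton_polish(y, traits, params, settings$active_tol)
        if (!is.null(pol)) y <- pol
      }
      out <- deSolve::lsoda(y, c(0, settings$window), deriv, NULL,
                            rtol = settings$rtol, atol = settings$atol)
      y2 <- as.numeric(validate_state(out[nrow(out), -1],
                                      settings$eps_clip))
      elapsed <- elapsed + settings$window
      r2 <- max(abs(ode_rhs(y2, traits, params)))
      if (r2 < settings$tol_eq) {
        return(ecological_equilibrium(y2, r2, TRUE, elapsed))
      }
      y <- y2
      resid <- r2
    }
    if (elapsed >= settings$t_max) break
  }
  ecological_equilibrium(y, resid, resid < settings$tol_eq, elapsed)
}
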
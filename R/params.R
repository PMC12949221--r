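#' Model parameters for the plant-pollinator community
#'
#' Constructs the full parameter set of the two-plant, two-pollinator
#' Lotka-Volterra mutualism model. The defaults are the canonical
#' parameterisation used throughout: `theta = 0.1`, `alpha = 0.5`,
#' `r_m = 1`, `K2 = 2`, `K_R = 1`, `pi1 = 1`, `pi2 = 3`, and `K1 = 2`
#' (equal plant abundances). Only `sigma` (width of the trait-matching
#' tolerance) and `phi` (asymmetry in mutualistic benefit) must be supplied,
#' as they define the specialisation scenario.
#'
#' `K_R` is the shared carrying capacity of both pollinator populations
#' (sometimes written KP); there is a single such quantity in the model.
#'
#' @param sigma positive real; width of the Gaussian trait-matching
#'   tolerance. Small values give specialists, large values generalists.
#' @param phi real in \[0, 1\]; asymmetry in mutualistic benefit. 0 means a
#'   pollinator benefits only from its matched plant, 1 means both
#'   plant-pollinator pairs have equal maximal benefit.
#' @param theta non-negative real; maximal intrinsic mutualistic benefit.
#' @param alpha real in \[0, 1\]; interspecific competition coefficient
#'   within a trophic level.
#' @param r_m positive real; maximal intrinsic growth rate.
#' @param K1,K2 positive reals; carrying capacities of Plant 1 and Plant 2.
#' @param K_R positive real; shared carrying capacity of the pollinators.
#' @param pi1,pi2 reals; fixed (non-evolving) trait values of the plants.
#'
#' @return An object of class `"model_parameters"`: a named list of the ten
#'   parameters.
#' @examples
#' p <- model_parameters(sigma = 1, phi = 0.5)
#' p$theta  # 0.1
#' @export
model_parameters <- function(sigma, phi, theta = 0.1, alpha = 0.5, r_m = 1,
                             K1 = 2, K2 = 2, K_R = 1, pi1 = 1, pi2 = 3) {
  stop_if_not_scalar_finite(sigma = sigma, phi = phi, theta = theta,
                            alpha = alpha, r_m = r_m, K1 = K1, K2 = K2,
                            K_R = K_R, pi1 = pi1, pi2 = pi2)
  if (sigma <= 0) stop("'sigma' must be > 0, got ", sigma)
  if (phi < 0 || phi > 1) stop("'phi' must be in [0, 1], got ", phi)
  if (theta < 0) stop("'theta' must be >= 0, got ", theta)
  if (alpha < 0 || alpha > 1) stop("'alpha' must be in [0, 1], got ", alpha)
  if (r_m <= 0) stop("'r_m' must be > 0, got ", r_m)
  if (K1 <= 0) stop("'K1' must be > 0, got ", K1)
  if (K2 <= 0) stop("'K2' must be > 0, got ", K2)
  if (K_R <= 0) stop("'K_R' must be > 0, got ", K_R)
  structure(list(sigma = sigma, phi = phi, theta = theta, alpha = alpha,
                 r_m = r_m, K1 = K1, K2 = K2, K_R = K_R,
                 pi1 = pi1, pi2 = pi2),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("Plant-pollinator model parameters\n")
  cat(sprintf("  sigma = %g, phi = %g, theta = %g, alpha = %g, r_m = %g\n",
              x$sigma, x$phi, x$theta, x$alpha, x$r_m))
  cat(sprintf("  K1 = %g, K2 = %g, K_R = %g, plant traits pi = (%g, %g)\n",
              x$K1, x$K2, x$K_R, x$pi1, x$pi2))
  invisible(x)
}

#' Pollinator trait pair
#'
#' The two evolving quantities of the model: the functional trait values of
#' Pollinator 1 and Pollinator 2. Traits are unconstrained finite reals and
#' may cross or coincide.
#'
#' @param rho1,rho2 finite reals; functional trait values.
#' @return An object of class `"pollinator_traits"` (named numeric of
#'   length 2).
#' @examples
#' pollinator_traits(1, 3)
#' @export
pollinator_traits <- function(rho1, rho2) {
  stop_if_not_scalar_finite(rho1 = rho1, rho2 = rho2)
  structure(c(rho1 = rho1, rho2 = rho2), class = "pollinator_traits")
}

#' @export
print.pollinator_traits <- function(x, ...) {
  cat(sprintf("Pollinator traits: rho1 = %g, rho2 = %g\n", x[["rho1"]],
              x[["rho2"]]))
  invisible(x)
}

#' Community abundance state
#'
#' Abundances of the four populations at one time point. All components
#' must be non-negative.
#'
#' @param P1,P2 non-negative reals; plant abundances.
#' @param R1,R2 non-negative reals; pollinator abundances.
#' @return An object of class `"community_state"` (named numeric of
#'   length 4, order P1, P2, R1, R2).
#' @examples
#' community_state(1, 2, 0.5, 0.5)
#' @export
community_state <- function(P1, P2, R1, R2) {
  stop_if_not_scalar_finite(P1 = P1, P2 = P2, R1 = R1, R2 = R2)
  x <- structure(c(P1 = P1, P2 = P2, R1 = R1, R2 = R2),
                 class = "community_state")
  validate_state(x)
}

#' @export
print.community_state <- function(x, ...) {
  cat(sprintf("Community state: P1 = %g, P2 = %g, R1 = %g, R2 = %g\n",
              x[["P1"]], x[["P2"]], x[["R1"]], x[["R2"]]))
  invisible(x)
}

#' Validate and clip a community state
#'
#' Abundances in `(-eps_clip, 0)` -- integrator round-off -- are clipped to
#' exactly 0. Components at or below `-eps_clip`, or non-finite components,
#' signal an error (integration blow-up rather than round-off).
#'
#' @param state numeric of length 4 (P1, P2, R1, R2) or a
#'   `"community_state"`.
#' @param eps_clip positive tolerance below which a negative abundance is
#'   treated as round-off. Default `1e-12`: absorbs integrator noise
#'   without masking real divergence.
#' @return The state as a `"community_state"`, with tiny negatives clipped
#'   to 0.
#' @examples
#' validate_state(c(1, -1e-15, 1, 1))  # second component clipped to 0
#' @export
validate_state <- function(state, eps_clip = 1e-12) {
  x <- as.numeric(state)
  if (length(x) != 4L)
    stop("a community state has 4 components (P1, P2, R1, R2), got ",
         length(x))
  if (any(!is.finite(x)))
    stop("non-finite abundance encountered (NaN/Inf): integration blow-up")
  if (any(x <= -eps_clip))
    stop("strongly negative abundance encountered (min = ",
         format(min(x)), "): integration blow-up")
  x[x < 0] <- 0
  structure(c(P1 = x[1], P2 = x[2], R1 = x[3], R2 = x[4]),
            class = "community_state")
}

#' Ecological equilibrium record
#'
#' Bundles an equilibrium state with its convergence diagnostics: the
#' residual (max absolute component of the ODE right-hand side at the
#' reported state), a convergence flag, and the model time spent
#' integrating.
#'
#' @param state a `"community_state"` (or coercible numeric of length 4).
#' @param residual non-negative real; max |dX/dt| at `state`.
#' @param converged logical flag.
#' @param elapsed_model_time non-negative real; integration time used.
#' @return An object of class `"ecological_equilibrium"`.
#' @seealso [find_equilibrium()]
#' @export
ecological_equilibrium <- function(state, residual, converged,
                                   elapsed_model_time = 0) {
  structure(list(state = validate_state(state),
                 residual = residual,
                 converged = isTRUE(converged),
                 elapsed_model_time = elapsed_model_time),
            class = "ecological_equilibrium")
}

#' @export
print.ecological_equilibrium <- function(x, ...) {
  s <- x$state
  cat(sprintf(
    "Ecological equilibrium (%s, residual %.3g, model time %g)\n",
    if (x$converged) "converged" else "NOT converged",
    x$residual, x$elapsed_model_time))
  cat(sprintf("  P1* = %.6g, P2* = %.6g, R1* = %.6g, R2* = %.6g\n",
              s[["P1"]], s[["P2"]], s[["R1"]], s[["R2"]]))
  invisible(x)
}

#' Equilibrium solver settings
#'
#' @param tol_eq stationarity tolerance on max |dX/dt|; the equilibrium is
#'   accepted once the residual stays below it over a trailing window.
#'   Default `1e-9`, orders of magnitude below the `1e-3` extinction and
#'   `1e-6` gradient thresholds so equilibrium error never drives
#'   termination decisions.
#' @param window model-time length over which stationarity must be
#'   sustained (default 10).
#' @param t_max integration horizon; non-convergence by `t_max` is
#'   reported via the `converged` flag, not an error.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @param eps_clip negative-abundance clipping tolerance (see
#'   [validate_state()]).
#' @param newton_polish logical; refine the integrated state with a damped
#'   Newton solve on the ODE right-hand side, restricted to components
#'   above `active_tol` (removes residual integrator drift).
#' @param active_tol abundance below which a component is excluded from
#'   Newton refinement (default `1e-3`, the extinction threshold).
#' @return A list of class `"solver_settings"`.
#' @export
solver_settings <- function(tol_eq = 1e-9, window = 10, t_max = 1e5,
                            rtol = 1e-9, atol = 1e-12, eps_clip = 1e-12,
                            newton_polish = TRUE, active_tol = 1e-3) {
  structure(list(tol_eq = tol_eq, window = window, t_max = t_max,
                 rtol = rtol, atol = atol, eps_clip = eps_clip,
                 newton_polish = newton_polish, active_tol = active_tol),
            class = "solver_settings")
}

#' Evolutionary loop settings
#'
#' @param grad_tol selection-gradient threshold below which evolution is
#'   considered to have stopped (ESS criterion `max(|s1|, |s2|) < grad_tol`).
#'   Default `1e-6`.
#' @param extinction_tol abundance below which a population is considered
#'   extinct. Default `1e-3`.
#' @param delta_max largest trait change allowed per evolutionary step, in
#'   trait units. Default 0.01 (small relative to the plant trait distance
#'   of 2, honouring the small-mutation assumption).
#' @param step_scale proportionality constant between the selection
#'   gradient and the trait step before capping at `delta_max`.
#' @param max_steps iteration cap; reaching it yields status
#'   `"max_iterations"`, not an error.
#' @param record_trajectory logical; keep the per-step trait/abundance
#'   trajectory in the result.
#' @return A list of class `"evolution_settings"`.
#' @export
evolution_settings <- function(grad_tol = 1e-6, extinction_tol = 1e-3,
                               delta_max = 0.01, step_scale = 1,
                               max_steps = 1e5, record_trajectory = TRUE) {
  structure(list(grad_tol = grad_tol, extinction_tol = extinction_tol,
                 delta_max = delta_max, step_scale = step_scale,
                 max_steps = max_steps,
                 record_trajectory = isTRUE(record_trajectory)),
            class = "evolution_settings")
}

## scalar-argument validation shared by the constructors
stop_if_not_scalar_finite <- function(...) {
  args <- list(...)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number")
  }
  invisible(NULL)
}
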
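#' Invasion fitness of a mutant pollinator
#'
#' Per-capita growth rate of a rare mutant of pollinator `pollinator_index`
#' with trait `mutant_trait`, in the environment set by the resident
#' community at ecological equilibrium:
#' \deqn{f_i(\rho') = r_m\left(1 - \frac{R_i^* + \alpha R_{-i}^*}{K_R}\right)
#'   + \theta\left[\varphi^{[i \ne 1]} e^{-(\pi_1-\rho')^2/2\sigma^2} P_1^*
#'   + \varphi^{[i \ne 2]} e^{-(\pi_2-\rho')^2/2\sigma^2} P_2^*\right]}
#' The mutant competes with the residents exactly as a resident does (its
#' own density being negligible), so fitness depends on the residents only
#' through the equilibrium abundances, not the resident trait. A persisting
#' resident therefore has fitness zero at its own trait value.
#'
#' @param mutant_trait mutant trait value(s) (vectorised).
#' @param pollinator_index 1 or 2; which pollinator the mutant belongs to.
#' @param equilibrium a converged [ecological_equilibrium()].
#' @param params a [model_parameters()] object.
#' @return Invasion fitness value(s).
#' @export
invasion_fitness <- function(mutant_trait, pollinator_index, equilibrium,
                             params) {
  check_pollinator_index(pollinator_index)
  check_converged(equilibrium)
  s <- equilibrium$state
  Rown <- s[[c("R1", "R2")[pollinator_index]]]
  Roth <- s[[c("R2", "R1")[pollinator_index]]]
  disc <- if (pollinator_index == 1L) c(1, params$phi) else c(params$phi, 1)
  params$r_m * (1 - (Rown + params$alpha * Roth) / params$K_R) +
    params$theta *
      (disc[1] * trait_match(params$pi1, mutant_trait, params$sigma) *
         s[["P1"]] +
       disc[2] * trait_match(params$pi2, mutant_trait, params$sigma) *
         s[["P2"]])
}

#' Selection gradient on a pollinator trait
#'
#' Analytic derivative of [invasion_fitness()] with respect to the mutant
#' trait, evaluated at the resident trait; its sign gives the direction of
#' evolution and its magnitude the strength of selection:
#' \deqn{s_i = \theta\varphi^{[i \ne 1]}\frac{\pi_1-\rho_i}{\sigma^2}
#'   e^{-(\pi_1-\rho_i)^2/2\sigma^2} P_1^*
#'   + \theta\varphi^{[i \ne 2]}\frac{\pi_2-\rho_i}{\sigma^2}
#'   e^{-(\pi_2-\rho_i)^2/2\sigma^2} P_2^*}
#'
#' @param pollinator_index 1 or 2.
#' @param traits resident [pollinator_traits()].
#' @param equilibrium a converged [ecological_equilibrium()].
#' @param params a [model_parameters()] object.
#' @return The selection gradient (scalar).
#' @export
selection_gradient <- function(pollinator_index, traits, equilibrium,
                               params) {
  check_pollinator_index(pollinator_index)
  check_converged(equilibrium)
  rho <- as.numeric(traits)[pollinator_index]
  s <- equilibrium$state
  disc <- if (pollinator_index == 1L) c(1, params$phi) else c(params$phi, 1)
  params$theta * disc[1] * (params$pi1 - rho) / params$sigma^2 *
    trait_match(params$pi1, rho, params$sigma) * s[["P1"]] +
  params$theta * disc[2] * (params$pi2 - rho) / params$sigma^2 *
    trait_match(params$pi2, rho, params$sigma) * s[["P2"]]
}

#' Fitness landscape over a trait grid
#'
#' Pointwise invasion fitness of mutants across `trait_grid`, for plotting
#' or inspection. When the resident persists, the landscape crosses zero
#' at the resident trait.
#'
#' @param pollinator_index 1 or 2.
#' @param trait_grid strictly increasing numeric vector of mutant traits.
#' @inheritParams invasion_fitness
#' @return A `data.frame` with columns `trait` and `fitness`.
#' @export
fitness_landscape <- function(pollinator_index, trait_grid, equilibrium,
                              params) {
  if (length(trait_grid) == 0L || is.unsorted(trait_grid, strictly = TRUE))
    stop("'trait_grid' must be non-empty and strictly increasing")
  data.frame(trait = trait_grid,
             fitness = invasion_fitness(trait_grid, pollinator_index,
                                        equilibrium, params))
}

#' Classify an evolutionary singularity
#'
#' At a trait value where the selection gradient (directional selection)
#' has vanished, the curvature of the fitness landscape decides the
#' character of the singular point: negative curvature means no nearby
#' mutant can invade (`"locally_uninvadable"`, a true ESS), positive
#' curvature means nearby mutants invade (`"invadable"`, an evolutionary
#' branching point). Curvature is measured by a central second difference
#' of [invasion_fitness()].
#'
#' @inheritParams selection_gradient
#' @param step finite-difference step for the second derivative (default
#'   `1e-4`).
#' @param grad_tol gradient threshold below which classification is
#'   meaningful (default `1e-6`).
#' @return `"locally_uninvadable"`, `"invadable"`, or `"degenerate"`
#'   (|curvature| < 1e-8), with the curvature estimate attached as
#'   attribute `"curvature"`.
#' @export
classify_singularity <- function(pollinator_index, traits, equilibrium,
                                 params, step = 1e-4, grad_tol = 1e-6) {
  g <- selection_gradient(pollinator_index, traits, equilibrium, params)
  if (abs(g) >= grad_tol)
    stop("selection gradient (", format(g), ") is not below ", grad_tol,
         ": not at a singular point")
  rho <- as.numeric(traits)[pollinator_index]
  f <- invasion_fitness(c(rho - step, rho, rho + step), pollinator_index,
                        equilibrium, params)
  curv <- (f[1] - 2 * f[2] + f[3]) / step^2
  cls <- if (abs(curv) < 1e-8) "degenerate"
         else if (curv < 0) "locally_uninvadable" else "invadable"
  structure(cls, curvature = curv)
}

#' Evolve pollinator traits to an evolutionarily stable state
#'
#' Iterates the adaptive-dynamics loop: (a) solve the ecological
#' equilibrium for the current resident traits (warm-started from the
#' previous step), (b) compute both analytic selection gradients, (c) move
#' both traits simultaneously up their gradients, (d) repeat. The step is
#' scaled so the larger trait change equals
#' `min(delta_max, step_scale * max(|s1|, |s2|))` -- deterministic
#' gradient ascent that reproduces canonical-equation dynamics up to a
#' time rescaling, leaving ESS locations and termination outcomes
#' unchanged, while simultaneous updates preserve the model's symmetries.
#' If a step increases `max(|s1|, |s2|)` more than tenfold (overshoot near
#' a sharp landscape) it is halved and retried.
#'
#' Termination: `"ess_reached"` when `max(|s1|, |s2|) < grad_tol`;
#' `"pollinator1_extinct"` / `"pollinator2_extinct"` when that
#' pollinator's equilibrium abundance falls below `extinction_tol` while
#' the survivor's gradient is below `grad_tol` (the extinct pollinator is
#' frozen -- trait no longer updated -- while the survivor converges);
#' `"plant_extinct"` when a plant falls below `extinction_tol` while a
#' pollinator is at an ESS adapted to the other plant; otherwise
#' `"max_iterations"`.
#'
#' @param initial_traits starting [pollinator_traits()].
#' @param params a [model_parameters()] object.
#' @param settings an [evolution_settings()] list.
#' @param solver a [solver_settings()] list for the inner equilibrium
#'   solves.
#' @param initial abundances for the first equilibrium solve (default:
#'   interior cold start). When evolution follows a carrying-capacity
#'   perturbation, pass the pre-perturbation equilibrium state so the
#'   ecological trajectory starts where the community actually was.
#' @return An object of class `"ess_result"`: list with elements `traits`,
#'   `equilibrium`, `status`, `gradients` (s1, s2 at termination), `steps`,
#'   and `trajectory` (data.frame of step, rho1, rho2, s1, s2, P1, P2, R1,
#'   R2, one row per evolutionary step, if recorded).
#' @examples
#' \donttest{
#' p <- model_parameters(sigma = 1.5, phi = 0.5, K1 = 3)
#' res <- evolve_to_ess(pollinator_traits(1, 3), p)
#' res$status
#' }
#' @export
evolve_to_ess <- function(initial_traits, params,
                          settings = evolution_settings(),
                          solver = solver_settings(), initial = NULL) {
  rho <- as.numeric(initial_traits)
  if (any(!is.finite(rho))) stop("initial traits must be finite")
  eq <- find_equilibrium(pollinator_traits(rho[1], rho[2]), params,
                         initial = initial, settings = solver)
  if (!eq$converged)
    stop("ecological equilibrium did not converge for the initial traits ",
         "(residual ", format(eq$residual), ")")
  traj <- if (settings$record_trajectory) vector("list", 256L) else NULL
  frozen <- c(FALSE, FALSE)

  grad_pair <- function(rho, eq) {
    tr <- pollinator_traits(rho[1], rho[2])
    c(selection_gradient(1L, tr, eq, params),
      selection_gradient(2L, tr, eq, params))
  }

  s <- grad_pair(rho, eq)
  status <- "max_iterations"
  step <- 0L
  while (step < settings$max_steps) {
    step <- step + 1L
    Rst <- c(eq$state[["R1"]], eq$state[["R2"]])
    frozen <- frozen | (Rst < settings$extinction_tol)
    s_eff <- ifelse(frozen, 0, s)
    smax <- max(abs(s_eff))

    if (settings$record_trajectory) {
      if (step > length(traj)) traj <- c(traj, vector("list", length(traj)))
      traj[[step]] <- c(step = step, rho1 = rho[1], rho2 = rho[2],
                        s1 = s[1], s2 = s[2], unclass(eq$state))
    }

    ## termination checks (extinctions take precedence over a plain ESS)
    if (any(frozen) && smax < settings$grad_tol) {
      status <- if (frozen[1]) "pollinator1_extinct" else
        "pollinator2_extinct"
      break
    }
    if (any(c(eq$state[["P1"]], eq$state[["P2"]]) <
              settings$extinction_tol) &&
        min(abs(s)) < settings$grad_tol) {
      status <- "plant_extinct"
      break
    }
    if (smax < settings$grad_tol) {
      status <- "ess_reached"
      break
    }

    ## gradient-ascent step with overshoot safeguard
    h <- min(settings$delta_max, settings$step_scale * smax) / smax
    repeat {
      rho_new <- rho + h * s_eff
      eq_new <- find_equilibrium(pollinator_traits(rho_new[1], rho_new[2]),
                                 params, initial = eq$state,
                                 settings = solver)
      if (!eq_new$converged)
        stop("equilibrium failed to converge at evolutionary step ", step,
             " (traits ", format(rho_new[1]), ", ", format(rho_new[2]),
             "; residual ", format(eq_new$residual), ")")
      s_new <- grad_pair(rho_new, eq_new)
      if (max(abs(ifelse(frozen, 0, s_new))) <= 10 * smax || h < 1e-12)
        break
      h <- h / 2
    }
    rho <- rho_new
    eq <- eq_new
    s <- s_new
  }

  trajectory <- NULL
  if (settings$record_trajectory) {
    traj <- traj[!vapply(traj, is.null, logical(1))]
    trajectory <- as.data.frame(do.call(rbind, traj))
  }
  structure(list(traits = pollinator_traits(rho[1], rho[2]),
                 equilibrium = eq,
                 status = status,
                 gradients = c(s1 = s[1], s2 = s[2]),
                 steps = step,
                 trajectory = trajectory),
            class = "ess_result")
}

#' @export
print.ess_result <- function(x, ...) {
  cat(sprintf("Adaptive-dynamics result: %s after %d steps\n", x$status,
              x$steps))
  cat(sprintf("  traits: rho1 = %.6g, rho2 = %.6g\n",
              x$traits[["rho1"]], x$traits[["rho2"]]))
  cat(sprintf("  gradients: s1 = %.3g, s2 = %.3g\n",
              x$gradients[["s1"]], x$gradients[["s2"]]))
  print(x$equilibrium)
  invisible(x)
}

check_pollinator_index <- function(i) {
  if (!(length(i) == 1L && i %in% c(1, 2)))
    stop("'pollinator_index' must be 1 or 2")
}

check_converged <- function(eq) {
  if (!inherits(eq, "ecological_equilibrium"))
    stop("'equilibrium' must be an ecological_equilibrium object")
  if (!eq$converged)
    stop("equilibrium is not converged (residual ", format(eq$residual),
         ")")
}
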
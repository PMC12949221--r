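## Orchestration of the computational experiments: baseline ESS at equal
## plant abundances, carrying-capacity sweeps with traits frozen
## (ecological response) or re-evolved (eco-evolutionary response),
## sensitivity slopes, diversity before/after evolution, and pollination
## benefit curves.

## per-session cache of baseline ESS results keyed by (sigma, phi)
.ess_cache <- new.env(parent = emptyenv())

#' Baseline evolutionarily stable state at equal plant abundances
#'
#' Evolves the pollinator traits from `(pi1, pi2)` -- each pollinator
#' initially matched to "its" plant -- at `K1 = K2 = 2` until the system
#' reaches its initial ESS. This defines the baseline traits and
#' abundances from which all carrying-capacity perturbations start.
#' Results are cached per `(sigma, phi)` within the session.
#'
#' @param sigma,phi specialisation scenario (see [model_parameters()]).
#' @param ... further parameter overrides passed to [model_parameters()]
#'   (e.g. `theta = 0` for the pure Lotka-Volterra limit).
#' @param settings,solver evolution and solver settings.
#' @param cache logical; reuse a previously computed baseline.
#' @return An `"ess_result"` (see [evolve_to_ess()]).
#' @export
baseline_ess <- function(sigma, phi, ..., settings = evolution_settings(),
                         solver = solver_settings(), cache = TRUE) {
  params <- model_parameters(sigma = sigma, phi = phi, ...)
  key <- paste(c(unlist(params), settings$delta_max, settings$grad_tol),
               collapse = "|")
  if (cache && !is.null(.ess_cache[[key]])) return(.ess_cache[[key]])
  res <- evolve_to_ess(pollinator_traits(params$pi1, params$pi2), params,
                       settings = settings, solver = solver)
  if (cache) .ess_cache[[key]] <- res
  res
}

#' Ecological response to a carrying-capacity sweep
#'
#' Equilibrium abundances across a grid of Plant 1 carrying capacities
#' with pollinator traits held fixed (by default frozen at the baseline
#' ESS): the short-timescale, pre-evolution response to plant-abundance
#' change. Each row carries the equilibrium, its diagnostics and the two
#' diversity metrics.
#'
#' Every `K1` row is integrated from the baseline equilibrium abundances:
#' the perturbation scenario is a community sitting at its baseline state
#' when the carrying capacity changes. (A cold interior start can fall
#' into a competitive-exclusion basin that the perturbed community never
#' visits, because zero abundance is absorbing.)
#'
#' @param sigma,phi specialisation scenario.
#' @param K1_values numeric vector of Plant 1 carrying capacities.
#' @param traits optional [pollinator_traits()]; default is the baseline
#'   ESS traits from [baseline_ess()].
#' @param initial abundances each row is integrated from; default is the
#'   baseline-ESS equilibrium state when `traits` is defaulted, otherwise
#'   the interior cold start.
#' @param ... parameter overrides forwarded to [model_parameters()].
#' @param solver a [solver_settings()] list.
#' @return A `data.frame` with one row per `K1`: `sigma, phi, K1, rho1,
#'   rho2, P1, P2, R1, R2, residual, converged, gini_simpson, rao_q`.
#' @export
ecological_response <- function(sigma, phi, K1_values, traits = NULL,
                                initial = NULL, ...,
                                solver = solver_settings()) {
  if (is.null(traits)) {
    base <- baseline_ess(sigma, phi, ..., solver = solver)
    traits <- base$traits
    if (is.null(initial)) initial <- base$equilibrium$state
  }
  rho <- as.numeric(traits)
  rows <- lapply(K1_values, function(k1) {
    params <- model_parameters(sigma = sigma, phi = phi, K1 = k1, ...)
    eq <- find_equilibrium(pollinator_traits(rho[1], rho[2]), params,
                           initial = initial, settings = solver)
    s <- eq$state
    data.frame(sigma = sigma, phi = phi, K1 = k1,
               rho1 = rho[1], rho2 = rho[2],
               P1 = s[["P1"]], P2 = s[["P2"]],
               R1 = s[["R1"]], R2 = s[["R2"]],
               residual = eq$residual, converged = eq$converged,
               gini_simpson = gini_simpson(s[["R1"]], s[["R2"]]),
               rao_q = rao_q(s[["R1"]], s[["R2"]], rho[1], rho[2]))
  })
  do.call(rbind, rows)
}

#' Sensitivity of pollinator equilibrium abundances to plant abundance
#'
#' Ordinary-least-squares slopes of the pollinator equilibrium abundances
#' `R1*` and `R2*` against the Plant 1 carrying capacity `K1`, with traits
#' frozen at the baseline ESS. The relationship is linear to high
#' precision, so the slopes summarise how strongly each pollinator is
#' affected by plant-abundance change on ecological timescales (positive
#' for the pollinator matched to Plant 1, negative for the other).
#'
#' @param sigma,phi specialisation scenario.
#' @param K1_values at least 3 carrying capacities spanning the sweep
#'   range; default `seq(1, 4, by = 0.25)`.
#' @param traits,initial,...,solver passed to [ecological_response()].
#' @return Named numeric: `slope_R1`, `slope_R2` (abundance per unit K1).
#' @examples
#' \donttest{
#' sensitivity_slopes(0.25, 0.25)  # approx c(0.256, -0.205)
#' }
#' @export
sensitivity_slopes <- function(sigma, phi, K1_values = seq(1, 4, by = 0.25),
                               traits = NULL, initial = NULL, ...,
                               solver = solver_settings()) {
  if (length(K1_values) < 3L)
    stop("need at least 3 K1 values for a slope estimate")
  resp <- ecological_response(sigma, phi, K1_values, traits = traits,
                              initial = initial, ..., solver = solver)
  if (!all(resp$converged))
    stop("equilibrium did not converge for K1 = ",
         paste(resp$K1[!resp$converged], collapse = ", "))
  c(slope_R1 = unname(stats::coef(stats::lm(R1 ~ K1, data = resp))["K1"]),
    slope_R2 = unname(stats::coef(stats::lm(R2 ~ K1, data = resp))["K1"]))
}

#' Full sensitivity table over the specialisation grid
#'
#' [sensitivity_slopes()] for every combination of `sigma_values` and
#' `phi_values`.
#'
#' @param sigma_values,phi_values grids of the two specialisation
#'   parameters; defaults are the canonical 8 x 3 grid.
#' @param K1_values carrying-capacity grid for the slope regression.
#' @return A `data.frame` with columns `sigma, phi, slope_R1, slope_R2`.
#' @export
sensitivity_table <- function(sigma_values = c(0.25, 0.5, 0.75, 1, 1.25,
                                               1.5, 1.75, 2),
                              phi_values = c(0.25, 0.5, 0.75),
                              K1_values = seq(1, 4, by = 0.25)) {
  grid <- expand.grid(sigma = sigma_values, phi = phi_values,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sl <- sensitivity_slopes(grid$sigma[i], grid$phi[i], K1_values)
    data.frame(sigma = grid$sigma[i], phi = grid$phi[i],
               slope_R1 = sl[["slope_R1"]], slope_R2 = sl[["slope_R2"]])
  })
  do.call(rbind, rows)
}

#' Pollinator diversity before and after evolution
#'
#' For a perturbed Plant 1 carrying capacity, computes the scaled
#' Gini-Simpson index and Rao's quadratic entropy (i) at the ecological
#' equilibrium reached with traits frozen at the baseline ESS ("before
#' evolution") and (ii) at the new ESS reached by re-evolving the traits
#' under the perturbed conditions ("after evolution"). Abundances below
#' the extinction threshold are treated as exact zeros in the terminal
#' metrics, matching the evolution loop's extinction semantics.
#'
#' @param sigma,phi specialisation scenario.
#' @param K1 perturbed Plant 1 carrying capacity.
#' @param settings,solver evolution and solver settings.
#' @return A one-row `data.frame`: `sigma, phi, K1, gs_before, gs_after,
#'   q_before, q_after, rho1_after, rho2_after, status`.
#' @export
diversity_before_after <- function(sigma, phi, K1,
                                   settings = evolution_settings(),
                                   solver = solver_settings()) {
  base <- baseline_ess(sigma, phi, settings = settings, solver = solver)
  rho0 <- as.numeric(base$traits)
  params <- model_parameters(sigma = sigma, phi = phi, K1 = K1)

  before <- find_equilibrium(base$traits, params,
                             initial = base$equilibrium$state,
                             settings = solver)
  Rb <- threshold_extinct(c(before$state[["R1"]], before$state[["R2"]]),
                          settings$extinction_tol)

  after <- evolve_to_ess(base$traits, params, settings = settings,
                         solver = solver,
                         initial = base$equilibrium$state)
  rho1 <- as.numeric(after$traits)
  Ra <- threshold_extinct(c(after$equilibrium$state[["R1"]],
                            after$equilibrium$state[["R2"]]),
                          settings$extinction_tol)

  data.frame(sigma = sigma, phi = phi, K1 = K1,
             gs_before = gini_simpson(Rb[1], Rb[2]),
             gs_after = gini_simpson(Ra[1], Ra[2]),
             q_before = rao_q(Rb[1], Rb[2], rho0[1], rho0[2]),
             q_after = rao_q(Ra[1], Ra[2], rho1[1], rho1[2]),
             rho1_after = rho1[1], rho2_after = rho1[2],
             status = after$status)
}

#' Pollination benefit received by a plant
#'
#' The mutualism term of the plant's per-capita growth at equilibrium:
#' the increase in population growth plant `plant_index` receives from
#' pollination, `sum_j theta * phi^[cross] * K(pi_i, rho_j) * Rj*`.
#'
#' @param plant_index 1 or 2.
#' @param traits [pollinator_traits()] of the resident pollinators.
#' @param equilibrium a converged [ecological_equilibrium()].
#' @param params a [model_parameters()] object.
#' @return Non-negative scalar (per-capita growth increment).
#' @export
mutualistic_benefit <- function(plant_index, traits, equilibrium, params) {
  if (!(length(plant_index) == 1L && plant_index %in% c(1, 2)))
    stop("'plant_index' must be 1 or 2")
  check_converged(equilibrium)
  A <- mutualism_matrix(traits, params)
  R <- c(equilibrium$state[["R1"]], equilibrium$state[["R2"]])
  sum(A[plant_index, ] * R)
}

#' Pollination benefit across a carrying-capacity sweep
#'
#' For each `K1`, the per-capita pollination benefit of both plants at the
#' pre-evolution equilibrium (baseline traits) and at the re-evolved ESS.
#'
#' @inheritParams diversity_before_after
#' @param K1_values carrying-capacity grid.
#' @return A `data.frame` with one row per `K1`: `sigma, phi, K1,
#'   benefit_P1_before, benefit_P2_before, benefit_P1_after,
#'   benefit_P2_after, status`.
#' @export
benefit_curve <- function(sigma, phi, K1_values,
                          settings = evolution_settings(),
                          solver = solver_settings()) {
  base <- baseline_ess(sigma, phi, settings = settings, solver = solver)
  rows <- lapply(K1_values, function(k1) {
    params <- model_parameters(sigma = sigma, phi = phi, K1 = k1)
    before <- find_equilibrium(base$traits, params,
                               initial = base$equilibrium$state,
                               settings = solver)
    after <- evolve_to_ess(base$traits, params, settings = settings,
                           solver = solver,
                           initial = base$equilibrium$state)
    data.frame(sigma = sigma, phi = phi, K1 = k1,
               benefit_P1_before = mutualistic_benefit(1L, base$traits,
                                                       before, params),
               benefit_P2_before = mutualistic_benefit(2L, base$traits,
                                                       before, params),
               benefit_P1_after = mutualistic_benefit(1L, after$traits,
                                                      after$equilibrium,
                                                      params),
               benefit_P2_after = mutualistic_benefit(2L, after$traits,
                                                      after$equilibrium,
                                                      params),
               status = after$status)
  })
  do.call(rbind, rows)
}

#' Run the full experimental sweep
#'
#' For every `(sigma, phi)` combination in the configuration: sensitivity
#' slopes (traits frozen at the baseline ESS), diversity before/after
#' evolution across the `K1` grid (keyed also by the relative plant
#' abundance `K1 / (K1 + K2)`), and pollination-benefit curves. Results
#' are written as CSV files plus a JSON manifest recording the full
#' configuration and all threshold constants; the pipeline is fully
#' deterministic, so re-running a configuration reproduces the outputs
#' bit for bit.
#'
#' @param config list with elements `sigma_values`, `phi_values`,
#'   `K1_values` (slope grid), and `K1_diversity` (grid for the
#'   diversity/benefit experiments); missing elements take the canonical
#'   defaults (8 sigma values, 3 phi values, K1 from 1 to 4).
#' @param output_dir directory for `slopes.csv`, `diversity.csv`,
#'   `benefit.csv` and `manifest.json`; created if needed. `NULL` skips
#'   writing.
#' @param settings,solver evolution and solver settings.
#' @return Invisibly, a list of the three data frames (`slopes`,
#'   `diversity`, `benefit`) and the manifest list. Rows whose evolution
#'   failed carry `NA` results and the error message in `status`; the
#'   sweep continues past them.
#' @export
run_sweep <- function(config = list(), output_dir = NULL,
                      settings = evolution_settings(),
                      solver = solver_settings()) {
  cfg <- list(sigma_values = c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2),
              phi_values = c(0.25, 0.5, 0.75),
              K1_values = seq(1, 4, by = 0.25),
              K1_diversity = seq(1, 4, by = 0.5))
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0)
    stop("unknown sweep configuration keys: ",
         paste(unknown, collapse = ", "))
  cfg[names(config)] <- config

  grid <- expand.grid(sigma = cfg$sigma_values, phi = cfg$phi_values,
                      KEEP.OUT.ATTRS = FALSE)
  slopes <- list(); divers <- list(); benef <- list()
  for (i in seq_len(nrow(grid))) {
    sg <- grid$sigma[i]; ph <- grid$phi[i]
    res <- tryCatch({
      sl <- sensitivity_slopes(sg, ph, cfg$K1_values, solver = solver)
      dv <- do.call(rbind, lapply(cfg$K1_diversity, function(k1)
        diversity_before_after(sg, ph, k1, settings = settings,
                               solver = solver)))
      bf <- benefit_curve(sg, ph, cfg$K1_diversity, settings = settings,
                          solver = solver)
      list(slopes = data.frame(sigma = sg, phi = ph,
                               slope_R1 = sl[["slope_R1"]],
                               slope_R2 = sl[["slope_R2"]]),
           diversity = dv, benefit = bf)
    }, error = function(e) {
      list(slopes = data.frame(sigma = sg, phi = ph, slope_R1 = NA_real_,
                               slope_R2 = NA_real_),
           diversity = data.frame(sigma = sg, phi = ph, K1 = NA_real_,
                                  gs_before = NA_real_, gs_after = NA_real_,
                                  q_before = NA_real_, q_after = NA_real_,
                                  rho1_after = NA_real_,
                                  rho2_after = NA_real_,
                                  status = paste("error:",
                                                 conditionMessage(e))),
           benefit = NULL)
    })
    slopes[[i]] <- res$slopes
    divers[[i]] <- res$diversity
    benef[[i]] <- res$benefit
  }
  slopes <- do.call(rbind, slopes)
  divers <- do.call(rbind, divers)
  benef <- do.call(rbind, benef)
  divers$relative_plant_abundance <- divers$K1 / (divers$K1 + 2)

  manifest <- list(
    configuration = cfg,
    thresholds = list(grad_tol = settings$grad_tol,
                      extinction_tol = settings$extinction_tol,
                      delta_max = settings$delta_max,
                      tol_eq = solver$tol_eq,
                      eps_clip = solver$eps_clip,
                      rtol = solver$rtol, atol = solver$atol,
                      t_max = solver$t_max),
    deterministic = TRUE,
    random_seeds = "none: the pipeline has no stochastic component",
    package_version = as.character(utils::packageVersion("pollevol")))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_result_csv(slopes, file.path(output_dir, "slopes.csv"))
    write_result_csv(divers, file.path(output_dir, "diversity.csv"))
    write_result_csv(benef, file.path(output_dir, "benefit.csv"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(slopes = slopes, diversity = divers, benefit = benef,
                 manifest = manifest))
}

## CSV dialect: comma-separated, '.' decimal, scientific notation for
## |x| < 1e-4, mandatory header.
write_result_csv <- function(df, path) {
  if (is.null(df)) return(invisible(NULL))
  fmt <- function(col) {
    if (!is.numeric(col)) return(as.character(col))
    vapply(col, function(x) {
      if (is.na(x)) "NA"
      else if (x != 0 && abs(x) < 1e-4) sprintf("%.10e", x)
      else sprintf("%.10g", x)
    }, character(1))
  }
  out <- as.data.frame(lapply(df, fmt), stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
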
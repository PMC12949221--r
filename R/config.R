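## Scenario configuration files: a flat, human-readable `key: value` text
## format (a YAML subset). Recognised keys, all optional except sigma and
## phi, with defaults applied for the rest:
##   model:      sigma, phi, theta, alpha, r_m, K1, K2, K_R, pi1, pi2
##   traits:     rho1_init, rho2_init        (default: pi1, pi2)
##   abundances: P1_init, P2_init, R1_init, R2_init  (default: K/2 start)
##   solver:     tol_eq, window, t_max, rtol, atol, eps_clip
##   evolution:  grad_tol, extinction_tol, delta_max, max_steps
##   sweep:      k1_min, k1_max, k1_step

.config_keys <- list(
  model = c("sigma", "phi", "theta", "alpha", "r_m", "K1", "K2", "K_R",
            "pi1", "pi2"),
  traits = c("rho1_init", "rho2_init"),
  abundances = c("P1_init", "P2_init", "R1_init", "R2_init"),
  solver = c("tol_eq", "window", "t_max", "rtol", "atol", "eps_clip"),
  evolution = c("grad_tol", "extinction_tol", "delta_max", "max_steps"),
  sweep = c("k1_min", "k1_max", "k1_step"))

#' Load and validate a scenario configuration file
#'
#' Reads a flat `key: value` scenario file, applies the canonical defaults
#' for omitted keys, and validates every value. `sigma` and `phi` have no
#' default and must be present. Unknown keys are an error (typo
#' protection).
#'
#' @param path path to a configuration file.
#' @return A list of class `"scenario_config"` with elements `params` (a
#'   [model_parameters()]), `traits_init` (a [pollinator_traits()]),
#'   `initial_state` (a [community_state()] or `NULL` for the default
#'   interior start), `solver` ([solver_settings()]), `evolution`
#'   ([evolution_settings()]), `k1_grid` (numeric or `NULL`), and `raw`
#'   (the key-value pairs as read).
#' @seealso [write_config()], [generate_fixtures()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- unlist(.config_keys, use.names = FALSE)
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys in ", path, ": ",
         paste(unknown, collapse = ", "))
  missing_req <- setdiff(c("sigma", "phi"), names(raw))
  if (length(missing_req) > 0)
    stop("required configuration keys missing in ", path, ": ",
         paste(missing_req, collapse = ", "))
  ## YAML 1.1 reads exponent forms without a decimal point (1e-8) as
  ## strings; coerce any numeric-looking string back to a double
  raw <- lapply(raw, function(v) {
    if (is.character(v) && length(v) == 1L &&
        !is.na(suppressWarnings(as.numeric(v)))) as.numeric(v) else v
  })
  bad <- names(raw)[!vapply(raw, function(v)
    is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))]
  if (length(bad) > 0)
    stop("configuration values must be single finite numbers; offending ",
         "keys in ", path, ": ", paste(bad, collapse = ", "))

  pget <- function(keys) raw[intersect(names(raw), keys)]
  params <- do.call(model_parameters, pget(.config_keys$model))
  traits <- pollinator_traits(
    if ("rho1_init" %in% names(raw)) raw$rho1_init else params$pi1,
    if ("rho2_init" %in% names(raw)) raw$rho2_init else params$pi2)
  initial <- NULL
  if (any(.config_keys$abundances %in% names(raw))) {
    g <- function(k, d) if (k %in% names(raw)) raw[[k]] else d
    initial <- community_state(g("P1_init", params$K1 / 2),
                               g("P2_init", params$K2 / 2),
                               g("R1_init", params$K_R / 2),
                               g("R2_init", params$K_R / 2))
  }
  solver <- do.call(solver_settings, pget(.config_keys$solver))
  evolution <- do.call(evolution_settings, pget(.config_keys$evolution))
  k1_grid <- NULL
  if (any(.config_keys$sweep %in% names(raw))) {
    need <- setdiff(.config_keys$sweep, names(raw))
    if (length(need) > 0)
      stop("incomplete sweep specification in ", path, "; missing: ",
           paste(need, collapse = ", "))
    if (raw$k1_step <= 0 || raw$k1_max < raw$k1_min)
      stop("invalid sweep specification in ", path,
           ": require k1_step > 0 and k1_max >= k1_min")
    k1_grid <- seq(raw$k1_min, raw$k1_max, by = raw$k1_step)
  }
  structure(list(params = params, traits_init = traits,
                 initial_state = initial, solver = solver,
                 evolution = evolution, k1_grid = k1_grid, raw = raw),
            class = "scenario_config")
}

#' Write a scenario configuration file
#'
#' Serialises a flat named list of numeric values in the `key: value`
#' format read by [load_config()]. Values are written with 17 significant
#' digits so that a write/read round trip reproduces every double bit for
#' bit.
#'
#' @param values named list or vector of single numeric values.
#' @param path output file path.
#' @param comment optional comment line placed at the top of the file.
#' @return `path`, invisibly.
#' @export
write_config <- function(values, path, comment = NULL) {
  values <- as.list(values)
  if (is.null(names(values)) || any(names(values) == ""))
    stop("all configuration values must be named")
  lines <- character(0)
  if (!is.null(comment)) lines <- paste0("# ", comment)
  lines <- c(lines, vapply(names(values), function(k) {
    v <- values[[k]]
    sprintf("%s: %s", k,
            formatC(v, digits = 17, format = "g", drop0trailing = TRUE))
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Generate the canonical scenario fixtures
#'
#' Writes the 24 specialisation scenarios (8 values of `sigma` crossed
#' with 3 values of `phi`, at equal plant abundances `K1 = K2 = 2`), the
#' carrying-capacity sweep specification (`K1` from 1 to 4 in steps of
#' 0.25), and three reduced test scenarios: the pure Lotka-Volterra limit
#' (`theta = 0`), a single-pollinator community (`R2_init = 0`), and the
#' symmetric baseline. 28 files in total.
#'
#' @param output_dir writable directory; created if needed.
#' @return Character vector of the 28 file paths, invisibly.
#' @export
generate_fixtures <- function(output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (phi in c(0.25, 0.5, 0.75)) {
    for (sigma in c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)) {
      p <- file.path(output_dir,
                     sprintf("scenario_sigma%s_phi%s.yml", sigma, phi))
      write_config(list(sigma = sigma, phi = phi), p,
                   comment = sprintf(
                     "specialisation scenario sigma=%g phi=%g", sigma, phi))
      paths <- c(paths, p)
    }
  }
  p <- file.path(output_dir, "k1_sweep.yml")
  write_config(list(sigma = 1, phi = 0.5, k1_min = 1, k1_max = 4,
                    k1_step = 0.25), p,
               comment = "carrying-capacity sweep specification")
  paths <- c(paths, p)
  p <- file.path(output_dir, "toy_lv_limit.yml")
  write_config(list(sigma = 1, phi = 0.5, theta = 0), p,
               comment = paste("pure Lotka-Volterra limit: no mutualism,",
                               "equilibria K/(1+alpha) in closed form"))
  paths <- c(paths, p)
  p <- file.path(output_dir, "toy_single_pollinator.yml")
  write_config(list(sigma = 1, phi = 0.5, theta = 0, R2_init = 0), p,
               comment = "single-pollinator community (R2 absent)")
  paths <- c(paths, p)
  p <- file.path(output_dir, "toy_symmetric_baseline.yml")
  write_config(list(sigma = 1, phi = 0.5), p,
               comment = "symmetric baseline: equal plant abundances")
  paths <- c(paths, p)
  invisible(paths)
}
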
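## Independent oracles and fixture builders shared across the test files.
## Everything here is deliberately written as plain scalar arithmetic,
## independent of the package's vectorised internals.

## straight scalar transliteration of the growth equations
hand_per_capita <- function(state, rho, p) {
  P1 <- state[1]; P2 <- state[2]; R1 <- state[3]; R2 <- state[4]
  k <- function(a, b) exp(-0.5 * ((a - b) / p$sigma)^2)
  c(p$r_m * (1 - (P1 + p$alpha * P2) / p$K1) +
      p$theta * (k(p$pi1, rho[1]) * R1 + p$phi * k(p$pi1, rho[2]) * R2),
    p$r_m * (1 - (P2 + p$alpha * P1) / p$K2) +
      p$theta * (p$phi * k(p$pi2, rho[1]) * R1 + k(p$pi2, rho[2]) * R2),
    p$r_m * (1 - (R1 + p$alpha * R2) / p$K_R) +
      p$theta * (k(p$pi1, rho[1]) * P1 + p$phi * k(p$pi2, rho[1]) * P2),
    p$r_m * (1 - (R2 + p$alpha * R1) / p$K_R) +
      p$theta * (p$phi * k(p$pi1, rho[2]) * P1 + k(p$pi2, rho[2]) * P2))
}

## scalar transliteration of the mutant per-capita growth rate
hand_invasion_fitness <- function(rho_prime, i, eqstate, p) {
  P1 <- eqstate[1]; P2 <- eqstate[2]; R1 <- eqstate[3]; R2 <- eqstate[4]
  k <- function(a, b) exp(-0.5 * ((a - b) / p$sigma)^2)
  comp <- if (i == 1) R1 + p$alpha * R2 else R2 + p$alpha * R1
  w1 <- if (i == 1) 1 else p$phi
  w2 <- if (i == 2) 1 else p$phi
  p$r_m * (1 - comp / p$K_R) +
    p$theta * (w1 * k(p$pi1, rho_prime) * P1 +
               w2 * k(p$pi2, rho_prime) * P2)
}

## central finite difference of the package's invasion fitness
fd_gradient <- function(i, traits, eq, params, h = 1e-6) {
  rho <- as.numeric(traits)[i]
  (invasion_fitness(rho + h, i, eq, params) -
     invasion_fitness(rho - h, i, eq, params)) / (2 * h)
}

## a synthetic converged-equilibrium record with prescribed abundances,
## for derivative-identity checks that do not depend on solving the ODEs
synthetic_equilibrium <- function(P1, P2, R1, R2) {
  ecological_equilibrium(c(P1, P2, R1, R2), residual = 0,
                         converged = TRUE)
}

## random scenario draw used by the property-style sweeps
random_scenario <- function() {
  list(params = model_parameters(sigma = runif(1, 0.25, 2),
                                 phi = runif(1, 0, 1),
                                 theta = runif(1, 0, 0.2),
                                 alpha = runif(1, 0, 1),
                                 K1 = runif(1, 0.5, 4)),
       traits = pollinator_traits(runif(1, 0, 4), runif(1, 0, 4)),
       eq = synthetic_equilibrium(runif(1, 0, 5), runif(1, 0, 5),
                                  runif(1, 0, 2), runif(1, 0, 2)))
}

## closed-form two-species Lotka-Volterra equilibrium in the theta = 0
## limit with K1 = K2 = K: both species settle at K / (1 + alpha)
lv_equilibrium <- function(K, K_R, alpha) {
  c(K / (1 + alpha), K / (1 + alpha), K_R / (1 + alpha), K_R / (1 + alpha))
}
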
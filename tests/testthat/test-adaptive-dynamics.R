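test_that("invasion fitness matches the hand-coded mutant growth rate", {
  p <- model_parameters(sigma = 1, phi = 0.75)
  eq <- find_equilibrium(pollinator_traits(1, 3), p)
  grid <- seq(-1, 5, by = 0.25)
  for (i in 1:2) {
    expect_equal(invasion_fitness(grid, i, eq, p),
                 vapply(grid, hand_invasion_fitness, numeric(1), i = i,
                        eqstate = as.numeric(eq$state), p = p),
                 tolerance = 1e-12)
  }
})

test_that("a persisting resident has zero invasion fitness at equilibrium", {
  set.seed(3)
  for (i in 1:6) {
    p <- model_parameters(sigma = runif(1, 0.3, 2), phi = runif(1),
                          K1 = runif(1, 1.5, 3))
    tr <- pollinator_traits(runif(1, 0.5, 3.5), runif(1, 0.5, 3.5))
    eq <- find_equilibrium(tr, p)
    expect_true(eq$converged)
    for (j in 1:2)
      expect_lt(abs(invasion_fitness(as.numeric(tr)[j], j, eq, p)), 1e-8)
  }
})

test_that("without plants the fitness reduces to the competition term", {
  p <- model_parameters(sigma = 1, phi = 0.5)
  eq <- synthetic_equilibrium(0, 0, 0.4, 0.3)
  expect_equal(invasion_fitness(2.2, 1, eq, p),
               p$r_m * (1 - (0.4 + 0.5 * 0.3) / p$K_R))
  expect_equal(invasion_fitness(2.2, 2, eq, p),
               p$r_m * (1 - (0.3 + 0.5 * 0.4) / p$K_R))
})

test_that("invasion fitness refuses an unconverged equilibrium", {
  p <- model_parameters(sigma = 1, phi = 0.5)
  bad <- ecological_equilibrium(c(1, 1, 1, 1), residual = 0.1,
                                converged = FALSE)
  expect_error(invasion_fitness(2, 1, bad, p), "not converged")
  expect_error(selection_gradient(1, pollinator_traits(1, 3), bad, p),
               "not converged")
})

test_that("analytic selection gradients equal finite differences of fitness", {
  set.seed(101)
  for (i in 1:200) {
    sc <- random_scenario()
    for (j in 1:2) {
      s <- selection_gradient(j, sc$traits, sc$eq, sc$params)
      expect_equal(s, fd_gradient(j, sc$traits, sc$eq, sc$params),
                   tolerance = 1e-6)
    }
  }
})

test_that("selection gradient vanishes where selection must cancel", {
  p <- model_parameters(sigma = 1, phi = 0.5)
  # matched to its own plant with the other plant absent
  eq <- synthetic_equilibrium(2, 0, 0.7, 0.7)
  expect_identical(selection_gradient(1, pollinator_traits(1, 2), eq, p), 0)
  # symmetric benefit, equal plant abundances, trait at the midpoint
  p1 <- model_parameters(sigma = 1.5, phi = 1)
  eqs <- synthetic_equilibrium(1.8, 1.8, 0.7, 0.7)
  mid <- (p1$pi1 + p1$pi2) / 2
  for (j in 1:2)
    expect_equal(selection_gradient(j, pollinator_traits(mid, mid), eqs,
                                    p1), 0, tolerance = 1e-15)
})

test_that("fitness landscape is consistent with the gradient at the resident", {
  p <- model_parameters(sigma = 1.25, phi = 0.5, K1 = 1)
  tr <- pollinator_traits(1.1, 2.9)
  eq <- find_equilibrium(tr, p)
  land <- fitness_landscape(1, seq(0.6, 3.4, by = 0.1), eq, p)
  expect_named(land, c("trait", "fitness"))
  # resident neutrality on the grid point at the resident trait
  i <- which.min(abs(land$trait - 1.1))
  expect_lt(abs(land$fitness[i]), 1e-8)
  # numerical slope at the resident has the sign of the analytic gradient
  slope <- (land$fitness[i + 1] - land$fitness[i - 1]) / 0.2
  expect_identical(sign(slope), sign(selection_gradient(1, tr, eq, p)))
  expect_error(fitness_landscape(1, numeric(0), eq, p), "strictly")
  expect_error(fitness_landscape(1, c(2, 1), eq, p), "strictly")
})

test_that("singularity classification separates ESS from branching points", {
  # specialist matched to its own plant: kernel peak, negative curvature
  p <- model_parameters(sigma = 0.25, phi = 0.5)
  tr <- pollinator_traits(1, 3)
  eq <- find_equilibrium(tr, p)
  expect_equal(as.character(classify_singularity(1, tr, eq, p)),
               "locally_uninvadable")
  # narrow tolerance at the symmetric midpoint: fitness minimum between
  # the two plant optima, positive curvature (branching point)
  p2 <- model_parameters(sigma = 0.5, phi = 1)
  eq2 <- synthetic_equilibrium(2, 2, 0.7, 0.7)
  tr2 <- pollinator_traits(2, 2)
  expect_equal(as.character(classify_singularity(1, tr2, eq2, p2)),
               "invadable")
  # wide tolerance at the midpoint: single fitness hump, uninvadable
  p3 <- model_parameters(sigma = 2, phi = 1)
  expect_equal(as.character(classify_singularity(1, tr2, eq2, p3)),
               "locally_uninvadable")
  # refuse classification away from a singular point
  eq4 <- find_equilibrium(tr, model_parameters(sigma = 1.5, phi = 0.75,
                                               K1 = 1))
  expect_error(classify_singularity(1, tr, eq4,
                                    model_parameters(sigma = 1.5,
                                                     phi = 0.75, K1 = 1)),
               "not below")
})

test_that("specialists do not evolve away from their matched plants", {
  res <- evolve_to_ess(pollinator_traits(1, 3),
                       model_parameters(sigma = 0.25, phi = 0.5))
  expect_identical(res$status, "ess_reached")
  expect_lt(abs(res$traits[["rho1"]] - 1), 1e-3)
  expect_lt(abs(res$traits[["rho2"]] - 3), 1e-3)
  expect_lt(max(abs(res$gradients)), 1e-6)
})

test_that("symmetric communities evolve to mirror-symmetric states", {
  res <- evolve_to_ess(pollinator_traits(1, 3),
                       model_parameters(sigma = 1.5, phi = 0.5))
  expect_identical(res$status, "ess_reached")
  mid <- 2  # (pi1 + pi2) / 2
  expect_equal(res$traits[["rho1"]] - mid, mid - res$traits[["rho2"]],
               tolerance = 1e-6)
  s <- res$equilibrium$state
  expect_equal(s[["R1"]], s[["R2"]], tolerance = 1e-6)
  expect_equal(gini_simpson(s[["R1"]], s[["R2"]]), 1, tolerance = 1e-6)
  # resident neutrality at termination
  for (j in 1:2)
    expect_lt(abs(invasion_fitness(as.numeric(res$traits)[j], j,
                                   res$equilibrium,
                                   model_parameters(sigma = 1.5,
                                                    phi = 0.5))), 1e-8)
  # trajectory bookkeeping
  expect_equal(nrow(res$trajectory), res$steps)
  expect_equal(res$trajectory$rho1[1], 1)
})

test_that("the ESS location is insensitive to the mutation step size", {
  p <- model_parameters(sigma = 1.5, phi = 0.75, K1 = 3)
  base <- baseline_ess(1.5, 0.75)
  coarse <- evolve_to_ess(base$traits, p, initial = base$equilibrium$state)
  fine <- evolve_to_ess(base$traits, p,
                        settings = evolution_settings(delta_max = 0.005),
                        initial = base$equilibrium$state)
  expect_identical(coarse$status, fine$status)
  expect_equal(as.numeric(coarse$traits), as.numeric(fine$traits),
               tolerance = 1e-4)
})

test_that("selection points toward the more abundant plant after a K1 drop", {
  for (sg in c(0.75, 1, 1.25, 1.5, 1.75, 2)) {
    base <- baseline_ess(sg, 0.5)
    p <- model_parameters(sigma = sg, phi = 0.5, K1 = 1)
    eq <- find_equilibrium(base$traits, p,
                           initial = base$equilibrium$state)
    for (j in 1:2) {
      s <- selection_gradient(j, base$traits, eq, p)
      expect_identical(sign(s), sign(3 - as.numeric(base$traits)[j]))
    }
  }
})

test_that("selection strength is unimodal in the tolerance width", {
  # |s| at the perturbed baseline rises then falls across sigma, with an
  # interior maximum
  sigmas <- c(0.25, 0.5, 0.75, 1, 1.25, 1.5, 1.75, 2)
  mag <- vapply(sigmas, function(sg) {
    base <- baseline_ess(sg, 0.5)
    p <- model_parameters(sigma = sg, phi = 0.5, K1 = 1)
    eq <- find_equilibrium(base$traits, p,
                           initial = base$equilibrium$state)
    max(abs(c(selection_gradient(1, base$traits, eq, p),
              selection_gradient(2, base$traits, eq, p))))
  }, numeric(1))
  peak <- which.max(mag)
  expect_gt(peak, 1)
  expect_lt(peak, length(sigmas))
  expect_true(all(diff(mag[1:peak]) > 0))
  expect_true(all(diff(mag[peak:length(mag)]) < 0))
})

test_that("a pollinator excluded by competition yields an extinction status", {
  # full competitive overlap (alpha = 1) and a pollinator mismatched with
  # both plants: it is excluded while the other sits at its optimum
  p <- model_parameters(sigma = 0.25, phi = 0, alpha = 1, K1 = 4)
  res <- evolve_to_ess(pollinator_traits(1, 10), p)
  expect_identical(res$status, "pollinator2_extinct")
  expect_lt(res$equilibrium$state[["R2"]], 1e-3)
  expect_lt(abs(res$gradients[["s1"]]), 1e-6)
})

test_that("plant collapse under convergent evolution is reported as such", {
  base <- baseline_ess(1, 0.75)
  p <- model_parameters(sigma = 1, phi = 0.75, K1 = 4)
  res <- evolve_to_ess(base$traits, p, initial = base$equilibrium$state)
  expect_identical(res$status, "plant_extinct")
  expect_lt(res$equilibrium$state[["P2"]], 1e-3)
  expect_lt(min(abs(res$gradients)), 1e-6)
})
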
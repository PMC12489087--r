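test_that("trajectory bounds are sup-norms over the requested interval", {
  frozen <- simulate_enzyme(kinetic_parameters(0, 0, 0), T = 10, h = 0.1)
  b <- trajectory_bounds(frozen)
  expect_equal(c(b), c(S = 10, E = 5, H = 4, P = 0.1))

  # zero dynamics from the zero state: all bounds 0
  sys0 <- delayed_system(3, function(t, y, ylag) rep(0, 3))
  tr0 <- solve_vofdde(sys0, rep(0, 3), order_function("constant", 0.9),
                      solver_config(h = 0.1, T = 1))
  expect_true(all(trajectory_bounds(tr0) == 0))

  # conservation + positivity give b2 <= E0 + H0 on zero-delay runs
  sim <- simulate_enzyme(default_params(), T = 200, h = 0.01)
  b <- trajectory_bounds(sim, c(0, 200))
  expect_lte(b[["E"]], 9 + 1e-6)

  expect_error(trajectory_bounds(sim, c(300, 400)))
})

test_that("Lipschitz constants follow their defining arithmetic", {
  params <- default_params()
  lc <- lipschitz_constants(params, c(10, 9, 7, 1))
  expect_equal(unname(lc$Phi), c(0.477, 0.530, 0.052, 0.040), tolerance = 1e-12)
  expect_equal(lc$zeta, 0.530)

  expect_equal(lipschitz_constants(kinetic_parameters(0, 0, 0), c(1, 1))$zeta, 0)
  lc0 <- lipschitz_constants(params, c(0, 0))
  expect_equal(unname(lc0$Phi), c(0, 0, 0.052, 0.040))
})

test_that("Lipschitz constants agree with brute-force estimates over the box", {
  params <- default_params()
  b <- c(10, 9, 7, 1)
  lc <- lipschitz_constants(params, b)
  b1 <- params$beta1; b2 <- params$beta2; b3 <- params$beta3

  # kernel 1 in S, with E ranging over [0, b2-bound]; sup over E
  est1 <- max(vapply(seq(0, b[2], length.out = 11), function(E)
    lipschitz_bruteforce(function(S) b2 * 3 - b1 * E * S, b[1]), numeric(1)))
  expect_equal(est1, lc$Phi[["Phi1"]], tolerance = 0.05)

  est2 <- max(vapply(seq(0, b[1], length.out = 11), function(S)
    lipschitz_bruteforce(function(E) b3 * 3 + b2 * 3 - b1 * E * S, b[2]),
    numeric(1)))
  expect_equal(est2, lc$Phi[["Phi2"]], tolerance = 0.05)

  est3 <- lipschitz_bruteforce(function(H) -b3 * H - b2 * H + b1 * 2, b[3])
  expect_equal(est3, lc$Phi[["Phi3"]], tolerance = 0.05)

  est4 <- lipschitz_bruteforce(function(P) b3 * P, b[4])
  expect_equal(est4, lc$Phi[["Phi4"]], tolerance = 0.05)
})

test_that("uniqueness condition factor behaves as t^delta/Gamma(delta+1) * Phi", {
  one <- order_function("constant", 1)
  uc <- uniqueness_condition(1, one, 0.53)
  expect_equal(uc$kappa, 0.53)
  expect_true(uc$satisfied)

  uc0 <- uniqueness_condition(0, order_function("cosine", 0.98, 0.008, 10), 5)
  expect_equal(uc0$kappa, 0)
  expect_true(uc0$satisfied)

  ucT <- uniqueness_condition(200, one, 0.53)
  expect_equal(ucT$kappa, 106)
  expect_false(ucT$satisfied)
})

test_that("Ulam-Hyers constants match direct arithmetic and reject kappa >= 1", {
  one <- order_function("constant", 1)
  expect_equal(ulam_hyers_constants(1, one, 0.5), 2)
  expect_equal(ulam_hyers_constants(1, one, 0.477), 1 / 0.523, tolerance = 1e-6)
  expect_equal(ulam_hyers_constants(1, one, 0.477), 1.91205, tolerance = 1e-5)
  # Phi = 0: psi reduces to kappa_tilde itself
  half <- order_function("constant", 0.5)
  expect_equal(ulam_hyers_constants(2, half, 0),
               2^0.5 / gamma(1.5), tolerance = 1e-12)
  expect_error(ulam_hyers_constants(200, one, c(Phi1 = 0.53)), "Phi1")
})

test_that("psi is monotone in Phi and t, and vanishes as t -> 0", {
  set.seed(7)
  ord <- order_function("constant", 0.9)
  for (i in 1:20) {
    t1 <- stats::runif(1, 0.1, 1); t2 <- t1 + stats::runif(1, 0.01, 0.3)
    Phi1 <- stats::runif(1, 0, 0.5); Phi2 <- Phi1 + stats::runif(1, 0, 0.2)
    k2 <- uniqueness_condition(t2, ord, Phi2)$kappa
    if (k2 >= 1) next
    expect_gt(ulam_hyers_constants(t1, ord, Phi2),
              ulam_hyers_constants(t1, ord, Phi1) - 1e-14)
    expect_gt(ulam_hyers_constants(t2, ord, Phi1),
              ulam_hyers_constants(t1, ord, Phi1))
  }
  expect_lt(ulam_hyers_constants(1e-10, ord, 0.5), 1e-8)
})

test_that("the perturbation experiment verifies the Ulam-Hyers bound", {
  # no perturbation: identical runs, zero deviation
  zero <- uh_experiment(perturbation = list(NULL, NULL, NULL, NULL),
                        h = 0.01)
  expect_true(all(zero$deviation == 0))
  expect_true(all(zero$holds))

  # bounded sine forcing on the substrate equation only
  ue <- uh_experiment(epsilon = 0.01,
                      perturbation = list(function(t) 0.01 * sin(t),
                                          NULL, NULL, NULL),
                      h = 0.005)
  expect_true(all(ue$holds))
  expect_lte(ue$deviation[["S"]], ue$bound[["S"]])
  expect_gt(ue$deviation[["S"]], 0)

  # deviations scale linearly as epsilon -> 0, with slope below psi
  ue2 <- uh_experiment(epsilon = 0.005,
                       perturbation = list(function(t) 0.005 * sin(t),
                                           NULL, NULL, NULL),
                       h = 0.005)
  ratio <- ue$deviation[["S"]] / ue2$deviation[["S"]]
  expect_equal(ratio, 2, tolerance = 0.05)
  expect_lt(ue$deviation[["S"]] / 0.01, ue$psi[["Phi1"]])
})

test_that("the experiment refuses intervals where the condition is vacuous", {
  expect_error(uh_experiment(interval = c(0, 40), h = 0.05),
               "condition fails")
  expect_warning(
    uh_experiment(interval = c(0, 40), h = 0.05, override = TRUE,
                  perturbation = list(NULL, NULL, NULL, NULL)),
    "condition fails")
  expect_error(uh_experiment(epsilon = 0.01,
                             perturbation = list(function(t) 0.02 * sin(t),
                                                 NULL, NULL, NULL)),
               "exceeds its bound")
})

test_that("the stability report wires bounds, constants and conditions together", {
  sr <- stability_report(interval = c(0, 1), h = 0.01)
  expect_equal(sr$zeta, max(sr$Phi))
  expect_true(all(sr$satisfied))
  expect_true(all(is.finite(sr$psi)))

  srT <- stability_report(interval = c(0, 200), h = 0.05)
  expect_false(all(srT$satisfied))
  expect_true(all(is.na(srT$psi)))

  sr0 <- stability_report(kinetic_parameters(0, 0, 0), interval = c(0, 1),
                          h = 0.01)
  expect_true(all(sr0$Phi == 0))
  expect_true(all(sr0$satisfied))
})
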
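test_that("kernel rates match direct arithmetic", {
  params <- default_params()
  sys <- make_enzyme_rhs(params, delays = c(0.5, 2))
  lag <- list(c(0, 5, 0, 0), c(10, 0, 0, 0))   # E(t-tau1) = 5, S(t-tau2) = 10
  r <- sys$rhs(0, c(10, 5, 4, 0.1), lag)
  expect_equal(r, c(-2.602, -2.442, 2.442, 0.004), tolerance = 1e-12)

  # all-zero state: kernels are homogeneous
  zero <- list(rep(0, 4), rep(0, 4))
  expect_identical(sys$rhs(0, rep(0, 4), zero), rep(0, 4))

  # complex only: H = 1, everything else 0
  r2 <- sys$rhs(0, c(0, 0, 1, 0), zero)
  expect_equal(r2, c(0.012, 0.052, -0.052, 0), tolerance = 1e-12)

  # classical product variant changes only the P equation
  sysc <- make_enzyme_rhs(default_params("classical_product"), c(0.5, 2))
  rc <- sysc$rhs(0, c(10, 5, 4, 0.1), lag)
  expect_equal(rc[1:3], r[1:3])
  expect_equal(rc[4], params$beta3 * 4)
})

test_that("zero rates freeze the trajectory", {
  sim <- simulate_enzyme(kinetic_parameters(0, 0, 0), T = 10, h = 0.1)
  expect_true(all(sim$state[, "S"] == 10 & sim$state[, "E"] == 5 &
                  sim$state[, "H"] == 4 & sim$state[, "P"] == 0.1))
})

test_that("integer-order trajectories match an independently computed solution", {
  # frozen reference values from an independent DDE integration
  # (deSolve::dede, h = 0.01) of the same kernels
  params <- default_params()
  s0 <- simulate_enzyme(params, T = 40, h = 0.01)
  expect_equal(drop(interpolate_state(s0, 20))[["H"]], 6.5765, tolerance = 5e-4)

  s2 <- simulate_enzyme(params, delays = c(0.5, 2), T = 40, h = 0.01)
  expect_equal(drop(interpolate_state(s2, 20))[["H"]], 8.4411, tolerance = 5e-4)

  s3 <- simulate_enzyme(params, delays = c(0.5, 0.5), T = 40, h = 0.01)
  expect_equal(drop(interpolate_state(s3, 20))[["H"]], 7.3306, tolerance = 5e-4)
})

test_that("E + H is conserved on zero-delay runs for every shipped order", {
  params <- default_params()
  orders <- list(order_function("constant", 1),
                 order_function("constant", 0.97),
                 order_function("cosine", 0.98, 0.008, 10),
                 order_function("sine", 0.95, 0.001, 10),
                 order_function("sine", 0.99, -0.001, 100),
                 order_function("linear", 0.99, slope = -1e-4))
  for (ord in orders) {
    sim <- simulate_enzyme(params, order = ord, T = 200)
    expect_lt(conservation_check(sim), 1e-3)
  }
  # variant choice does not affect the conservation law
  simc <- simulate_enzyme(default_params("classical_product"), T = 200)
  expect_lt(conservation_check(simc), 1e-3)
})

test_that("positivity holds for constant and monotone orders", {
  params <- default_params()
  orders <- list(order_function("constant", 1),
                 order_function("constant", 0.97),
                 order_function("sine", 0.95, 0.001, 10),
                 order_function("sine", 0.99, -0.001, 100),
                 order_function("linear", 0.99, slope = -1e-4))
  for (ord in orders) {
    sim <- simulate_enzyme(params, order = ord, T = 200)
    expect_true(all(positivity_check(sim)$minima >= -1e-8))
  }
})

test_that("a strongly oscillating order drives late-time compartments negative", {
  # Under the frozen-order convention the whole memory integral is
  # re-weighted whenever delta(t) moves, so an oscillating order makes the
  # solution oscillate; near-zero compartments then swing below zero.
  # This is a property of the model convention, not discretization error:
  # the excursion converges under step halving while E + H stays at 9.
  params <- default_params()
  ordc <- order_function("cosine", 0.98, 0.008, 10)
  a <- simulate_enzyme(params, order = ordc, T = 200, h = 0.05)
  b <- simulate_enzyme(params, order = ordc, T = 200, h = 0.025)
  pa <- positivity_check(a)
  expect_false(all(pa$pass))
  expect_lt(pa$minima[["H"]], -0.4)
  expect_equal(min(b$state[, "H"]), pa$minima[["H"]], tolerance = 1e-3)
  expect_lt(conservation_check(a), 1e-6)
})

test_that("delayed runs break conservation by exactly the delayed-binding imbalance", {
  params <- default_params()
  sim <- simulate_enzyme(params, delays = c(0.5, 2), T = 50, h = 0.01)
  drift <- conservation_check(sim)
  expect_gt(drift, 1e-3)   # the cancellation genuinely breaks
  # d(E+H)/dt = beta1 * (E(t-tau1) S(t-tau2) - E S); integrate it directly
  tt <- sim$time
  Elag <- ifelse(tt - 0.5 <= 0, 5, drop(interpolate_state(sim, pmax(tt - 0.5, 0))[, "E"]))
  Slag <- ifelse(tt - 2 <= 0, 10, drop(interpolate_state(sim, pmax(tt - 2, 0))[, "S"]))
  integrand <- params$beta1 * (Elag * Slag - sim$state[, "E"] * sim$state[, "S"])
  h <- sim$config$h
  quad <- cumsum(c(0, (integrand[-1] + integrand[-length(integrand)]) / 2 * h))
  eh_drift <- sim$state[, "E"] + sim$state[, "H"] - 9
  expect_lt(max(abs(eh_drift - quad)), 1e-3)
})

test_that("positivity monitor reports minima and failures faithfully", {
  sim <- simulate_enzyme(default_params(), T = 50, h = 0.01)
  pc <- positivity_check(sim)
  expect_named(pc$minima, c("S", "E", "H", "P"))
  expect_true(all(pc$pass))

  # a synthetic trajectory containing -1 must fail
  bad <- sim
  bad$state[5, "H"] <- -1
  pcb <- positivity_check(bad)
  expect_equal(pcb$minima[["H"]], -1)
  expect_false(pcb$pass[["H"]])
})

test_that("total mass starts at the configured sum and obeys its balance law", {
  sim <- simulate_enzyme(default_params(), T = 10, h = 0.01)
  tm <- total_mass(sim)
  expect_equal(tm$N[1], 19.1)

  frozen <- simulate_enzyme(kinetic_parameters(0, 0, 0), T = 10, h = 0.1)
  expect_true(all(total_mass(frozen)$N == 19.1))

  # classical variant: dN = beta2 H + beta3 H - beta1 E S; check by quadrature
  params <- default_params("classical_product")
  simc <- simulate_enzyme(params, T = 50, h = 0.01)
  Nc <- total_mass(simc)$N
  dN <- (params$beta2 + params$beta3) * simc$state[, "H"] -
    params$beta1 * simc$state[, "E"] * simc$state[, "S"]
  h <- simc$config$h
  quad <- cumsum(c(0, (dN[-1] + dN[-length(dN)]) / 2 * h))
  expect_lt(max(abs(Nc - Nc[1] - quad)), 1e-3)
  # binding dominates early, so N decreases on an initial interval
  expect_true(all(diff(Nc[1:500]) < 0))
})

test_that("substrate decays from the start under the reference parameters", {
  sim <- simulate_enzyme(default_params(), T = 20, h = 0.01)
  # dS(0) = beta2*4 - beta1*50 < 0 by arithmetic
  expect_lt(0.012 * 4 - 0.053 * 50, 0)
  expect_true(all(diff(sim$state[1:1000, "S"]) < 0))
})

test_that("the two product variants agree on S, E, H and differ only in P", {
  a <- simulate_enzyme(default_params(), delays = c(0.5, 2), T = 30, h = 0.05,
                       order = order_function("constant", 0.97))
  b <- simulate_enzyme(default_params("classical_product"), delays = c(0.5, 2),
                       T = 30, h = 0.05,
                       order = order_function("constant", 0.97))
  expect_equal(a$state[, c("S", "E", "H")], b$state[, c("S", "E", "H")],
               tolerance = 1e-12)
  expect_gt(max(abs(a$state[, "P"] - b$state[, "P"])), 0.1)
})

test_that("state validation enforces the admissible initial region", {
  expect_error(enzyme_state(S = 0))
  expect_error(enzyme_state(E = -1))
  expect_silent(enzyme_state(H = 0, P = 0))
  expect_equal(coef(simulate_enzyme(T = 1, h = 0.01)),
               c(beta1 = 0.0530, beta2 = 0.012, beta3 = 0.040))
})
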
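# Lipschitz / uniqueness / Ulam-Hyers machinery.
#
# On a bounded trajectory box (sup-norms b1..b4 of S, E, H, P) the four
# kernels are Lipschitz in their own compartment with constants
#   Phi1 = beta1*b2,  Phi2 = beta1*b1,  Phi3 = beta3 + beta2,  Phi4 = beta3,
# zeta = max_j Phi_j.  The uniqueness condition at horizon t is
# kappa_j = t^{delta(t)} / Gamma(delta(t)+1) * Phi_j <= 1, and whenever
# kappa_j < 1 the Ulam-Hyers constant psi_j = ktilde / (1 - ktilde*Phi_j)
# (ktilde = t^{delta(t)}/Gamma(delta(t)+1)) bounds the response to an
# epsilon-perturbation of equation j: sup|y_j - yhat_j| <= psi_j * eps_j.

#' Sup-norm trajectory bounds
#'
#' Per-compartment maximum absolute value over a stated interval; these are
#' the b-constants entering the Lipschitz constants.
#'
#' @param traj A `vofde_trajectory` with named state columns.
#' @param interval `c(a, b)` inside the trajectory horizon.
#' @return Named numeric vector of class `trajectory_bounds`
#'   (b1..b4 for an enzyme run: S, E, H, P).
#' @export
trajectory_bounds <- function(traj, interval = range(traj$time)) {
  stopifnot(inherits(traj, "vofde_trajectory"),
            length(interval) == 2L, interval[1L] < interval[2L])
  sel <- traj$time >= interval[1L] - 1e-12 & traj$time <= interval[2L] + 1e-12
  if (!any(sel)) stop("trajectory_bounds(): empty interval")
  b <- apply(abs(traj$state[sel, , drop = FALSE]), 2L, max)
  structure(b, class = "trajectory_bounds", interval = interval)
}

#' Kernel Lipschitz constants
#'
#' @param params A [kinetic_parameters()].
#' @param bounds Sup-norm bounds: a [trajectory_bounds()] or a numeric
#'   vector `c(b1, b2, b3, b4)` (only `b1`, `b2` enter the constants).
#' @return List with `Phi` (named Phi1..Phi4) and `zeta = max(Phi)`.
#' @export
lipschitz_constants <- function(params, bounds) {
  stopifnot(inherits(params, "kinetic_parameters"),
            is.numeric(bounds), length(bounds) >= 2L, all(bounds >= 0))
  Phi <- c(Phi1 = params$beta1 * bounds[[2L]],
           Phi2 = params$beta1 * bounds[[1L]],
           Phi3 = params$beta3 + params$beta2,
           Phi4 = params$beta3)
  list(Phi = Phi, zeta = max(Phi))
}

# ktilde = t^{delta(t)} / Gamma(delta(t) + 1), order frozen at t
kappa_tilde <- function(t, order) {
  stopifnot(length(t) == 1L, t >= 0)
  if (t == 0) return(0)
  d <- eval_order(order, t)
  exp(d * log(t) - lgamma(d + 1))
}

#' Uniqueness condition factor
#'
#' Evaluates \eqn{\kappa = t^{\delta(t)} / \Gamma(\delta(t)+1)\, \Phi} and
#' whether the uniqueness condition \eqn{\kappa \le 1} holds at horizon
#' `t`.  Vectorised over `Phi`.
#'
#' @param t Horizon time (scalar, `>= 0`).
#' @param order An [order_function()].
#' @param Phi Lipschitz constant(s).
#' @return List with `kappa` and logical `satisfied` (same shape as `Phi`).
#' @export
uniqueness_condition <- function(t, order, Phi) {
  kt <- kappa_tilde(t, order)
  kappa <- kt * Phi
  list(kappa = kappa, satisfied = kappa <= 1, kappa_tilde = kt)
}

#' Ulam-Hyers stability constants
#'
#' \eqn{\psi_j = \tilde\kappa / (1 - \tilde\kappa\,\Phi_j)} with
#' \eqn{\tilde\kappa = t^{\delta(t)}/\Gamma(\delta(t)+1)}, defined only
#' while \eqn{\kappa_j = \tilde\kappa\,\Phi_j < 1}; violation is an error
#' naming the offending constant.
#'
#' @inheritParams uniqueness_condition
#' @return Numeric vector of psi constants, named after `Phi` when named.
#' @export
ulam_hyers_constants <- function(t, order, Phi) {
  kt <- kappa_tilde(t, order)
  kappa <- kt * Phi
  bad <- which(kappa >= 1)
  if (length(bad))
    stop(sprintf(
      "Ulam-Hyers condition violated for constant %s: kappa = %g >= 1 at t = %g",
      if (!is.null(names(Phi))) names(Phi)[bad[1L]] else paste0("#", bad[1L]),
      kappa[bad[1L]], t))
  psi <- kt / (1 - kt * Phi)
  names(psi) <- names(Phi)
  psi
}

#' Empirical Ulam-Hyers perturbation experiment
#'
#' Integrates the enzyme model twice with identical solver settings - once
#' unperturbed and once with bounded forcings \eqn{\vartheta_j(t)},
#' \eqn{|\vartheta_j| \le \epsilon_j}, added to the right-hand sides - and
#' compares the observed sup deviations per compartment against the
#' theoretical bounds \eqn{\psi_j\,\epsilon_j}.  The experiment refuses
#' intervals on which any \eqn{\kappa_j \ge 1} (where the bound is
#' vacuous) unless `override = TRUE`, which downgrades the refusal to a
#' warning.
#'
#' @param params,y0,order,delays Model configuration as in
#'   [simulate_enzyme()].
#' @param epsilon Perturbation size(s); recycled to length 4.
#' @param perturbation List of 4 functions of `t` (or `NULL` entries for
#'   no forcing on that equation).  The default applies
#'   \eqn{\epsilon_j \sin t} to every equation.  Each function is validated
#'   against its bound by dense sampling (1000 points).
#' @param interval `c(0, b)` experiment interval (default `[0, 1]`).
#' @param h Step size (default 0.001).
#' @param override Logical; proceed with a warning where the condition
#'   fails.
#' @param ... Further [solver_config()] arguments.
#' @return An object of class `uh_experiment`: observed per-compartment sup
#'   deviations, the `psi` constants, the bounds `psi * epsilon`, and
#'   logical `holds` flags.
#' @export
uh_experiment <- function(params = kinetic_parameters(),
                          y0 = enzyme_state(),
                          order = order_function("constant", 1),
                          delays = c(0, 0), epsilon = 0.01,
                          perturbation = NULL, interval = c(0, 1),
                          h = 0.001, override = FALSE, ...) {
  stopifnot(length(interval) == 2L, interval[1L] == 0, interval[2L] > 0)
  eps <- rep_len(epsilon, 4L)
  if (is.null(perturbation))
    perturbation <- lapply(eps, function(e) local({
      e0 <- e
      function(t) e0 * sin(t)
    }))
  stopifnot(is.list(perturbation), length(perturbation) == 4L)
  # validate |theta_j| <= eps_j by dense sampling
  ts <- seq(interval[1L], interval[2L], length.out = 1000L)
  for (j in 1:4) {
    pj <- perturbation[[j]]
    if (is.null(pj)) next
    v <- vapply(ts, pj, numeric(1))
    if (max(abs(v)) > eps[j] * (1 + 1e-8))
      stop(sprintf("perturbation %d exceeds its bound: max |theta| = %g > %g",
                   j, max(abs(v)), eps[j]))
  }
  Tend <- interval[2L]
  base <- simulate_enzyme(params, y0, order, delays, h = h, T = Tend,
                          scheme = "pece", ...)
  bounds <- trajectory_bounds(base)
  lc <- lipschitz_constants(params, bounds)
  uc <- uniqueness_condition(Tend, order, lc$Phi)
  if (any(!uc$satisfied | uc$kappa >= 1)) {
    msg <- paste0("Ulam-Hyers condition fails on [0, ", Tend, "]: kappa = ",
                  paste(format(uc$kappa, digits = 4), collapse = ", "))
    if (override) warning(msg) else stop(msg)
  }
  psi <- if (all(uc$kappa < 1)) {
    ulam_hyers_constants(Tend, order, lc$Phi)
  } else rep(NA_real_, 4L)

  sys <- make_enzyme_rhs(params, delays)
  base_rhs <- sys$rhs
  pert_rhs <- function(t, y, ylag) {
    r <- base_rhs(t, y, ylag)
    for (j in 1:4)
      if (!is.null(perturbation[[j]])) r[j] <- r[j] + perturbation[[j]](t)
    r
  }
  psys <- delayed_system(4L, pert_rhs, sys$delays)
  cfg <- solver_config(h = h, T = Tend, scheme = "pece", ...)
  pert <- solve_vofdde(psys, as.numeric(y0), order, cfg)

  dev <- apply(abs(pert$state - base$state), 2L, max)
  names(dev) <- c("S", "E", "H", "P")
  bound <- unname(psi) * eps
  names(bound) <- names(dev)
  structure(list(deviation = dev, psi = psi, epsilon = eps, bound = bound,
                 holds = dev <= bound, kappa = uc$kappa,
                 interval = interval, h = h),
            class = "uh_experiment")
}

#' @export
print.uh_experiment <- function(x, ...) {
  cat(sprintf("Ulam-Hyers perturbation experiment on [%g, %g] (h = %g)\n",
              x$interval[1L], x$interval[2L], x$h))
  df <- data.frame(kappa = x$kappa, psi = x$psi, epsilon = x$epsilon,
                   bound = x$bound, observed = x$deviation,
                   holds = x$holds)
  rownames(df) <- c("S", "E", "H", "P")
  print(df, digits = 4)
  invisible(x)
}

#' Full stability report
#'
#' Simulates the model on an interval, derives trajectory bounds, Lipschitz
#' constants, the uniqueness condition at the interval end and (where
#' defined) the Ulam-Hyers constants, and packages everything for
#' inspection.
#'
#' @inheritParams uh_experiment
#' @param interval `c(0, b)` report interval.
#' @param h Step size (default 0.001 for unit-scale intervals, 0.05
#'   otherwise).
#' @return An object of class `stability_report`.
#' @export
stability_report <- function(params = kinetic_parameters(),
                             y0 = enzyme_state(),
                             order = order_function("constant", 1),
                             delays = c(0, 0), interval = c(0, 1),
                             h = NULL, ...) {
  stopifnot(length(interval) == 2L, interval[1L] == 0, interval[2L] > 0)
  Tend <- interval[2L]
  if (is.null(h)) h <- if (Tend <= 2) 0.001 else 0.05
  traj <- simulate_enzyme(params, y0, order, delays, h = h, T = Tend,
                          scheme = if (is_constant_one(order))
                            "classical_rk4_order1" else "pece", ...)
  b <- trajectory_bounds(traj)
  lc <- lipschitz_constants(params, b)
  uc <- uniqueness_condition(Tend, order, lc$Phi)
  psi <- if (all(uc$kappa < 1)) {
    kappa_tilde(Tend, order) / (1 - uc$kappa)
  } else rep(NA_real_, 4L)
  names(psi) <- names(lc$Phi)
  structure(list(bounds = b, Phi = lc$Phi, zeta = lc$zeta,
                 kappa = uc$kappa, satisfied = uc$satisfied, psi = psi,
                 interval = interval, order = order, params = params,
                 trajectory = traj),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability report on [%g, %g], %s\n",
              x$interval[1L], x$interval[2L], x$order$label))
  cat("  trajectory bounds b1..b4:", format(unclass(x$bounds), digits = 5), "\n")
  cat("  Lipschitz constants:", paste(names(x$Phi), "=",
      format(x$Phi, digits = 4), collapse = ", "), "\n")
  cat("  zeta = max Phi =", format(x$zeta, digits = 4), "\n")
  cat("  uniqueness factors kappa:", format(x$kappa, digits = 4), "\n")
  cat("  condition satisfied:",
      if (all(x$satisfied)) "yes (all kappa <= 1)" else "NOT satisfied", "\n")
  if (all(is.finite(x$psi)))
    cat("  Ulam-Hyers constants psi:", format(x$psi, digits = 4), "\n")
  else
    cat("  Ulam-Hyers constants undefined (some kappa >= 1)\n")
  invisible(x)
}
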
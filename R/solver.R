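#' Specify a delayed vector system
#'
#' Describes a right-hand side \eqn{f(t, y(t), y(t-\tau_1), y(t-\tau_2),
#' \dots)} with constant, per-term delays.  The RHS must be total (defined
#' for every finite state).  The pre-history rule is constant: for any
#' lagged time \eqn{t - \tau \le 0} the solvers substitute the initial
#' state vector.
#'
#' @param dimension Number of state components.
#' @param rhs Function `f(t, y, ylag)` returning the rate vector, where
#'   `ylag` is a list with one lagged state vector per delay (in the order
#'   of `delays`); it is empty when there are no delays.
#' @param delays Numeric vector of constant delays (time units, `>= 0`).
#'   May be empty.
#' @return An object of class `delayed_system`.
#' @export
delayed_system <- function(dimension, rhs, delays = numeric(0)) {
  stopifnot(length(dimension) == 1L, dimension >= 1,
            dimension == as.integer(dimension), is.function(rhs),
            is.numeric(delays), all(is.finite(delays)), all(delays >= 0))
  structure(list(dimension = as.integer(dimension), rhs = rhs,
                 delays = as.numeric(delays)),
            class = "delayed_system")
}

#' @export
print.delayed_system <- function(x, ...) {
  cat(sprintf("<delayed_system> dimension %d, delays: %s\n", x$dimension,
              if (length(x$delays)) paste(x$delays, collapse = ", ") else "none"))
  invisible(x)
}

#' Solver settings
#'
#' @param h Step size (time units).
#' @param T Horizon; `T/h` must be an integer.
#' @param scheme `"pece"` (product-integration predictor-corrector, any
#'   order function) or `"classical_rk4_order1"` (classical 4th-order
#'   Runge-Kutta; only valid when the order is identically 1).
#' @param corrector_iterations Number of corrector sweeps per step (>= 1).
#' @param startup_substeps The first grid interval is integrated with this
#'   many substeps of the same scheme before continuing on the coarse grid.
#'   This resolves the \eqn{t^\alpha} start singularity that otherwise
#'   concentrates the scheme error at the first node; set to 1 to disable.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(h, T, scheme = c("pece", "classical_rk4_order1"),
                          corrector_iterations = 1L, startup_substeps = 16L) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(h), length(h) == 1L, h > 0,
            is.numeric(T), length(T) == 1L, T > 0,
            corrector_iterations >= 1, startup_substeps >= 1)
  steps <- T / h
  if (abs(steps - round(steps)) > 1e-8)
    stop("solver_config(): T/h must be an integer (T = ", T, ", h = ", h, ")")
  structure(list(h = h, T = T, scheme = scheme,
                 corrector_iterations = as.integer(corrector_iterations),
                 startup_substeps = as.integer(startup_substeps),
                 n_steps = as.integer(round(steps))),
            class = "solver_config")
}

# delays as integer multiples of h; error on misalignment
delay_steps <- function(delays, h) {
  if (!length(delays)) return(integer(0))
  m <- delays / h
  if (any(abs(m - round(m)) > 1e-8))
    stop("delay/step misalignment: every tau/h must be an integer ",
         "(tau = ", paste(delays, collapse = ", "), ", h = ", h, ")")
  as.integer(round(m))
}

new_trajectory <- function(time, state, order, config, system,
                           metadata = list(), class = character(0)) {
  structure(list(time = time, state = state, order = order,
                 config = config, system = system, metadata = metadata),
            class = c(class, "vofde_trajectory"))
}

#' Solve a variable-order fractional delay system
#'
#' Time-steps \eqn{D^{\delta(t)} y(t) = f(t, y(t), y(t-\tau_1), \dots)}
#' with the Adams-Bashforth-Moulton product-integration predictor-corrector
#' applied to the equivalent Volterra integral form.  At each step the
#' order is frozen at the new node, \eqn{\alpha = \delta(t_{n+1})}, and the
#' full-memory convolution over all previous nodes is recomputed with
#' rectangle (predictor) and trapezoid (corrector) weights.  Delayed states
#' are read from already-computed grid rows, or from the constant
#' pre-history (the initial state) for \eqn{t - \tau \le 0}.
#'
#' @param system A [delayed_system()].
#' @param y0 Initial state vector.
#' @param order An [order_function()], valid on `[0, T]`.
#' @param config A [solver_config()].
#' @return An object of class `vofde_trajectory` with components `time`
#'   (uniform grid), `state` (matrix, one row per node), and the inputs.
#' @examples
#' sys <- delayed_system(1, function(t, y, ylag) -y)
#' cfg <- solver_config(h = 0.01, T = 1)
#' tr <- solve_vofdde(sys, 1, order_function("constant", 0.5), cfg)
#' tail(tr$state, 1)   # ~ exp(1) * erfc(1)
#' @export
solve_vofdde <- function(system, y0, order, config) {
  stopifnot(inherits(system, "delayed_system"),
            inherits(order, "order_function"),
            inherits(config, "solver_config"),
            is.numeric(y0), length(y0) == system$dimension, all(is.finite(y0)))
  if (config$scheme == "classical_rk4_order1") {
    if (!is_constant_one(order))
      stop("scheme 'classical_rk4_order1' requires the constant order 1, got: ",
           order$label)
    return(solve_reference_order1(system, y0, config, order = order))
  }
  h <- config$h; N <- config$n_steps
  m <- delay_steps(system$delays, h)
  tgrid <- seq(0, by = h, length.out = N + 1L)
  alpha_grid <- eval_order(order, tgrid)  # validates (0,1] on the grid

  res <- pece_march(system$rhs, y0, alpha_grid, h, N, m,
                    config$corrector_iterations, config$startup_substeps,
                    order)
  new_trajectory(tgrid, res, order, config, system,
                 metadata = list(scheme = "pece",
                                 history = "constant = y0 for t <= 0"))
}

# Core PECE march on the coarse grid.  alpha_grid[k] = delta(t_{k-1}).
pece_march <- function(f, y0, alpha_grid, h, N, m, ncorr, startup, order) {
  d <- length(y0)
  Y <- matrix(NA_real_, N + 1L, d)
  Fm <- matrix(NA_real_, N + 1L, d)
  Y[1L, ] <- y0

  lag_at <- function(k) {            # lagged states for node index k (t = k h)
    lapply(m, function(mm) if (k - mm <= 0L) y0 else Y[k - mm + 1L, ])
  }
  Fm[1L, ] <- f(0, y0, lag_at(0L))
  if (any(!is.finite(Fm[1L, ])))
    stop("divergence: non-finite rate at t = 0")

  # cache k^alpha tables; rebuilt only when alpha changes between steps
  alpha_cached <- NA_real_; pk <- NULL; pk1 <- NULL
  kk <- 0:(N + 1L)

  first_step <- 1L
  if (startup > 1L && N >= 1L) {
    # refined start: integrate [0, h] with `startup` substeps of the same
    # scheme (delays, if any, are aligned to h so lagged times fall in the
    # constant pre-history there)
    hs <- h / startup
    sub_alpha <- eval_order(order, seq(0, by = hs, length.out = startup + 1L))
    msub <- if (length(m)) ifelse(m == 0L, 0L, .Machine$integer.max) else integer(0)
    sub <- pece_march(f, y0, sub_alpha, hs, startup, msub,
                      ncorr, 1L, order)
    Y[2L, ] <- sub[startup + 1L, ]
    Fm[2L, ] <- f(h, Y[2L, ], lag_at(1L))
    first_step <- 2L
  }

  for (n in seq.int(first_step - 1L, length.out = N - first_step + 1L)) {
    a <- alpha_grid[n + 2L]
    if (is.na(alpha_cached) || a != alpha_cached) {
      pk <- kk^a; pk1 <- kk^(a + 1); alpha_cached <- a
    }
    b  <- pred_weights_raw(n, h, a, pk)
    ac <- corr_weights_raw(n, h, a, pk, pk1)
    Fh <- Fm[1:(n + 1L), , drop = FALSE]
    ypred <- y0 + drop(crossprod(Fh, b))
    base  <- y0 + drop(crossprod(Fh, ac[1:(n + 1L)]))
    wnew  <- ac[n + 2L]
    lag_new <- lag_at(n + 1L)
    yc <- ypred
    for (it in seq_len(ncorr)) {
      lg <- if (length(m)) {
        lapply(seq_along(m), function(i) if (m[i] == 0L) yc else lag_new[[i]])
      } else list()
      yc <- base + wnew * f((n + 1L) * h, yc, lg)
    }
    if (any(!is.finite(yc)))
      stop(sprintf("divergence: non-finite state at step %d (t = %g)",
                   n + 1L, (n + 1L) * h))
    Y[n + 2L, ] <- yc
    lg <- if (length(m)) {
      lapply(seq_along(m), function(i) if (m[i] == 0L) yc else lag_new[[i]])
    } else list()
    Fm[n + 2L, ] <- f((n + 1L) * h, yc, lg)
  }
  Y
}

#' Classical order-1 reference solver (RK4 with delay interpolation)
#'
#' Integrates the system as a classical delay ODE (\eqn{\delta \equiv 1})
#' with fourth-order Runge-Kutta.  Lagged stage values are obtained by
#' cubic Hermite interpolation of the already-computed history (node values
#' and node derivatives); lagged times at or before 0 use the constant
#' pre-history.  Serves as the scheme-independent cross-validation path for
#' integer-order runs.
#'
#' @inheritParams solve_vofdde
#' @param order Optional `order_function`; must be the constant order 1
#'   when supplied.
#' @return A `vofde_trajectory`.
#' @export
solve_reference_order1 <- function(system, y0, config, order = NULL) {
  stopifnot(inherits(system, "delayed_system"),
            inherits(config, "solver_config"),
            is.numeric(y0), length(y0) == system$dimension, all(is.finite(y0)))
  if (is.null(order)) order <- order_function("constant", 1)
  if (!is_constant_one(order))
    stop("solve_reference_order1(): order must be identically 1")
  h <- config$h; N <- config$n_steps
  m <- delay_steps(system$delays, h)
  d <- length(y0)
  f <- system$rhs
  Y <- matrix(NA_real_, N + 1L, d)
  Fm <- matrix(NA_real_, N + 1L, d)   # node derivatives, for Hermite interpolation

  node_lag <- function(k) {
    lapply(m, function(mm) if (k - mm <= 0L) y0 else Y[k - mm + 1L, ])
  }
  Y[1L, ] <- y0
  Fm[1L, ] <- f(0, y0, node_lag(0L))

  # lagged state at stage time t_k + c*h for delay index i (m[i] >= 1)
  stage_lag <- function(k, cfrac, ycur) {
    lapply(seq_along(m), function(i) {
      mm <- m[i]
      if (mm == 0L) return(ycur)
      ts <- (k + cfrac - mm) * h
      if (ts <= 0) return(y0)
      j <- k - mm            # lagged time lies in [t_j, t_{j+1}]
      if (cfrac == 0) return(Y[j + 1L, ])
      if (cfrac == 1) return(Y[j + 2L, ])
      hermite_mid(Y[j + 1L, ], Fm[j + 1L, ], Y[j + 2L, ], Fm[j + 2L, ], h)
    })
  }

  for (k in 0:(N - 1L)) {
    t <- k * h
    y <- Y[k + 1L, ]
    k1 <- Fm[k + 1L, ]
    y2 <- y + h / 2 * k1
    k2 <- f(t + h / 2, y2, stage_lag(k, 0.5, y2))
    y3 <- y + h / 2 * k2
    k3 <- f(t + h / 2, y3, stage_lag(k, 0.5, y3))
    y4 <- y + h * k3
    k4 <- f(t + h, y4, stage_lag(k, 1, y4))
    ynew <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(ynew)))
      stop(sprintf("divergence: non-finite state at step %d (t = %g)",
                   k + 1L, (k + 1L) * h))
    Y[k + 2L, ] <- ynew
    Fm[k + 2L, ] <- f((k + 1L) * h, ynew, node_lag(k + 1L))
  }
  new_trajectory(seq(0, by = h, length.out = N + 1L), Y,
                 order, config, system,
                 metadata = list(scheme = "classical_rk4_order1",
                                 history = "constant = y0 for t <= 0"))
}

# cubic Hermite value at the midpoint of [0, h] given endpoint values and
# derivatives (vectorised over components)
hermite_mid <- function(y0, d0, y1, d1, h) {
  0.5 * (y0 + y1) + h / 8 * (d0 - d1)
}

#' Interpolate a trajectory at arbitrary times
#'
#' Linear interpolation between bracketing grid rows; exact at grid nodes.
#' Times outside `[0, T]` are a range error.
#'
#' @param traj A `vofde_trajectory`.
#' @param t Numeric vector of query times.
#' @return A matrix with one row per query time (a named vector when a
#'   single time is queried and the state has one column stays a matrix).
#' @export
interpolate_state <- function(traj, t) {
  stopifnot(inherits(traj, "vofde_trajectory"), is.numeric(t), all(is.finite(t)))
  tmax <- traj$time[length(traj$time)]
  if (any(t < 0 | t > tmax))
    stop("interpolate_state(): t outside [0, ", tmax, "]")
  out <- apply(traj$state, 2L, function(col)
    stats::approx(traj$time, col, xout = t)$y)
  out <- matrix(out, nrow = length(t),
                dimnames = list(NULL, colnames(traj$state)))
  out
}

#' @export
predict.vofde_trajectory <- function(object, t, ...) interpolate_state(object, t)

#' @export
print.vofde_trajectory <- function(x, ...) {
  cat(sprintf("<vofde_trajectory> %d nodes on [0, %g], h = %g, scheme = %s\n",
              length(x$time), x$time[length(x$time)], x$config$h,
              x$metadata$scheme))
  cat("  order: ", x$order$label, "\n", sep = "")
  if (length(x$system$delays))
    cat("  delays:", paste(x$system$delays, collapse = ", "), "\n")
  cat("  terminal state:", format(x$state[nrow(x$state), ], digits = 6), "\n")
  invisible(x)
}

#' @export
as.data.frame.vofde_trajectory <- function(x, ...) {
  df <- as.data.frame(x$state)
  if (is.null(colnames(x$state)))
    names(df) <- paste0("y", seq_len(ncol(x$state)))
  cbind(t = x$time, df)
}

#' @export
plot.vofde_trajectory <- function(x, components = NULL, ...) {
  st <- x$state
  if (!is.null(components)) st <- st[, components, drop = FALSE]
  graphics::matplot(x$time, st, type = "l", lty = 1,
                    xlab = "t", ylab = "state", ...)
  nm <- colnames(st)
  if (!is.null(nm))
    graphics::legend("topright", legend = nm, col = seq_len(ncol(st)),
                     lty = 1, bty = "n")
  invisible(x)
}

#' Empirical convergence order of the solver
#'
#' Runs the solver on a ladder of step sizes (each level halving the
#' previous) and estimates the observed order from Richardson-style
#' terminal-state differences: \eqn{p_i = \log_2(e_i / e_{i+1})} with
#' \eqn{e_i = \lVert y_{h_i}(T) - y_{h_{i+1}}(T) \rVert_\infty}.
#'
#' @param system A [delayed_system()].
#' @param y0 Initial state.
#' @param order An [order_function()].
#' @param h_levels Decreasing step sizes, at least 3, each half the previous.
#' @param T Horizon (integer multiple of every level).
#' @param scheme Passed to [solver_config()].
#' @param ... Further [solver_config()] arguments.
#' @return A list with `errors`, `orders`, and a `status` of `"ok"`,
#'   `"exact"` (all differences at rounding level) or `"nonmonotone"`
#'   (reported via a warning, not an error).
#' @export
convergence_probe <- function(system, y0, order, h_levels, T,
                              scheme = "pece", ...) {
  stopifnot(length(h_levels) >= 3)
  r <- h_levels[-length(h_levels)] / h_levels[-1L]
  if (any(abs(r - 2) > 1e-8))
    stop("convergence_probe(): each h level must halve the previous")
  terminal <- lapply(h_levels, function(h) {
    cfg <- solver_config(h = h, T = T, scheme = scheme, ...)
    tr <- solve_vofdde(system, y0, order, cfg)
    tr$state[nrow(tr$state), ]
  })
  errors <- vapply(seq_len(length(terminal) - 1L), function(i)
    max(abs(terminal[[i]] - terminal[[i + 1L]])), numeric(1))
  if (all(errors < 1e-14))
    return(list(errors = errors, orders = NA_real_, status = "exact"))
  orders <- log2(errors[-length(errors)] / errors[-1L])
  status <- "ok"
  if (any(diff(errors) > 0)) {
    status <- "nonmonotone"
    warning("convergence_probe(): error sequence is not monotone")
  }
  list(errors = errors, orders = orders, status = status)
}
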
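# Product-integration quadrature for the weakly singular Volterra kernel
# (t - v)^(alpha - 1) / Gamma(alpha).
#
# The predictor uses the product-rectangle rule (integrand piecewise
# constant on each subinterval), the corrector the product-trapezoid rule
# (piecewise linear).  Both integrate their interpolant against the kernel
# exactly, so the weights carry the full singular mass: the corrector
# weights sum to t_{n+1}^alpha / Gamma(alpha + 1) exactly.

# Internal kernels.  pk = k^alpha and pk1 = k^(alpha+1) for k = 0..(n+1)
# are passed in so the solver can cache them across steps when the order is
# constant.  Gamma factors go through lgamma for stability.

pred_weights_raw <- function(n, h, alpha, pk) {
  j <- 0:n
  exp(alpha * log(h) - log(alpha) - lgamma(alpha)) * (pk[n + 2L - j] - pk[n + 1L - j])
}

corr_weights_raw <- function(n, h, alpha, pk, pk1) {
  ha <- exp(alpha * log(h) - lgamma(alpha + 2))
  w <- numeric(n + 2L)
  # weight of the oldest node f_0
  w[1L] <- ha * (pk1[n + 1L] - (n - alpha) * pk[n + 2L])
  if (n >= 1L) {
    j <- 1:n
    w[j + 1L] <- ha * (pk1[n - j + 3L] + pk1[n - j + 1L] - 2 * pk1[n - j + 2L])
  }
  w[n + 2L] <- ha
  w
}

pow_tables <- function(n, alpha) {
  k <- 0:(n + 1L)
  list(pk = k^alpha, pk1 = k^(alpha + 1))
}

#' Predictor and corrector weights for one fractional step
#'
#' Returns the Adams-Bashforth-Moulton product-integration weights used to
#' advance a solution of \eqn{D^\alpha y = f} from step index `n` to
#' `n + 1` on a uniform grid of spacing `h`: rectangle-rule predictor
#' weights for the history nodes \eqn{t_0, \dots, t_n} and trapezoid-rule
#' corrector weights for \eqn{t_0, \dots, t_{n+1}}.  At \eqn{\alpha = 1}
#' these reduce to the classical rectangle and composite-trapezoid rules.
#'
#' @param n Step index (current number of completed steps), `n >= 0`.
#' @param h Step size, `h > 0`.
#' @param alpha Fractional order in \eqn{(0, 1]}.
#' @return An object of class `pece_weights` with components `predictor`
#'   (length `n + 1`) and `corrector` (length `n + 2`), plus `n`, `h`,
#'   `alpha`.
#' @examples
#' w <- pece_weights(3, 0.1, 1)
#' w$corrector   # composite trapezoid: 0.05 0.10 0.10 0.10 0.05
#' @export
pece_weights <- function(n, h, alpha) {
  stopifnot(length(n) == 1L, n >= 0, n == as.integer(n),
            length(h) == 1L, is.finite(h), h > 0,
            length(alpha) == 1L, is.finite(alpha))
  if (alpha <= 0 || alpha > 1)
    stop("pece_weights(): alpha must lie in (0, 1], got ", alpha)
  n <- as.integer(n)
  pw <- pow_tables(n, alpha)
  structure(list(predictor = pred_weights_raw(n, h, alpha, pw$pk),
                 corrector = corr_weights_raw(n, h, alpha, pw$pk, pw$pk1),
                 n = n, h = h, alpha = alpha),
            class = "pece_weights")
}

#' @export
print.pece_weights <- function(x, ...) {
  cat(sprintf("<pece_weights> n = %d, h = %g, alpha = %g\n", x$n, x$h, x$alpha))
  cat("  predictor:", format(x$predictor, digits = 6), "\n")
  cat("  corrector:", format(x$corrector, digits = 6), "\n")
  invisible(x)
}

#' Variable-order Riemann-Liouville integral on a uniform grid
#'
#' Computes the fractional integral
#' \deqn{(I^{\delta} G)(t_n) = \frac{1}{\Gamma(\delta(t_n))}
#'       \int_0^{t_n} (t_n - v)^{\delta(t_n) - 1} G(v)\, dv}
#' at every node of a uniform grid, using product-trapezoid weights.  The
#' order is frozen at the outer evaluation time \eqn{t_n}: both the kernel
#' exponent and the Gamma factor use \eqn{\delta(t_n)}.  The value at
#' \eqn{t_0 = 0} is 0.
#'
#' @param samples Numeric vector of integrand values \eqn{G(t_0), \dots,
#'   G(t_n)} on the grid (at least 2 points).
#' @param h Uniform grid spacing.  May be omitted when `t` is given.
#' @param order An [order_function()], or a single numeric constant order.
#' @param t Optional vector of grid times; must be uniform starting at 0.
#'   Supplying a non-uniform grid is an error (never approximated).
#' @return Numeric vector of integral values, same length as `samples`.
#' @examples
#' h <- 0.01; tt <- seq(0, 1, by = h)
#' # I^0.5 of 1 is t^0.5 / Gamma(1.5)
#' rl_integral(rep(1, length(tt)), h, 0.5)[length(tt)]
#' @export
rl_integral <- function(samples, h = NULL, order, t = NULL) {
  if (length(samples) == 0L) stop("rl_integral(): empty grid")
  if (length(samples) < 2L) stop("rl_integral(): need at least 2 grid points")
  stopifnot(is.numeric(samples), all(is.finite(samples)))
  if (!is.null(t)) {
    stopifnot(length(t) == length(samples))
    if (abs(t[1L]) > 1e-12) stop("rl_integral(): grid must start at t = 0")
    dt <- diff(t)
    if (any(abs(dt - dt[1L]) > 1e-8 * max(abs(dt))))
      stop("rl_integral(): non-uniform grid")
    if (is.null(h)) h <- dt[1L]
    else if (abs(h - dt[1L]) > 1e-8 * h)
      stop("rl_integral(): h does not match the spacing of t")
  }
  stopifnot(is.numeric(h), length(h) == 1L, h > 0)
  if (is.numeric(order) && length(order) == 1L)
    order <- order_function("constant", base = order)
  stopifnot(inherits(order, "order_function"))
  nmax <- length(samples) - 1L
  tn <- (0:nmax) * h
  alpha <- eval_order(order, tn)   # validates range over the grid
  out <- numeric(nmax + 1L)
  for (n in seq_len(nmax)) {
    pw <- pow_tables(n - 1L, alpha[n + 1L])
    w <- corr_weights_raw(n - 1L, h, alpha[n + 1L], pw$pk, pw$pk1)
    out[n + 1L] <- sum(w * samples[1:(n + 1L)])
  }
  out
}

#' Mittag-Leffler function (one parameter, truncated series)
#'
#' Evaluates \eqn{E_\alpha(z) = \sum_{k \ge 0} z^k / \Gamma(\alpha k + 1)}
#' by direct series summation with a relative stopping criterion.  Intended
#' for moderate arguments (the closed-form solutions of constant-order
#' linear fractional problems, e.g. \eqn{E_{1/2}(-\sqrt{t}) =
#' e^t\,\mathrm{erfc}(\sqrt{t})}); the series route is independent of the
#' time-stepping solver and therefore usable as a cross-check oracle.
#'
#' @param z Numeric vector of arguments.
#' @param alpha Positive order parameter.
#' @param tol Relative truncation tolerance.
#' @param max_terms Series length cap; exceeding it is an error.
#' @return Numeric vector `E_alpha(z)`.
#' @export
mittag_leffler <- function(z, alpha, tol = 1e-14, max_terms = 1000L) {
  stopifnot(is.numeric(z), all(is.finite(z)), alpha > 0)
  vapply(z, function(zi) {
    acc <- 0
    for (k in 0:max_terms) {
      term <- if (zi == 0 && k == 0) 1 else
        sign(zi)^k * exp(k * log(abs(zi)) - lgamma(alpha * k + 1))
      acc <- acc + term
      if (k > 2 && abs(term) < tol * max(1, abs(acc))) return(acc)
    }
    stop("mittag_leffler(): series did not converge within ", max_terms,
         " terms at z = ", zi)
  }, numeric(1))
}
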
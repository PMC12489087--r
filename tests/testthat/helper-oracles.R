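# Independent oracles used across the suite.

# Closed-form solution of D^{1/2} y = -y, y(0) = 1:
# y(t) = E_{1/2}(-sqrt(t)) = exp(t) * erfc(sqrt(t))
ml_half_decay <- function(t) exp(t) * 2 * stats::pnorm(sqrt(2 * t), lower.tail = FALSE)

# Brute-force fractional integral of a smooth integrand by adaptive
# quadrature (independent of the product-integration weights).
rl_quadrature <- function(g, tn, alpha) {
  if (tn == 0) return(0)
  stats::integrate(function(v) g(v) * (tn - v)^(alpha - 1), 0, tn,
                   rel.tol = 1e-10)$value / gamma(alpha)
}

# Dense-sampling Lipschitz estimate of a scalar function f over [0, bmax]
# in its own argument, with a fixed partner value.
lipschitz_bruteforce <- function(f, bmax, n = 41L) {
  xs <- seq(0, bmax, length.out = n)
  best <- 0
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    r <- abs(f(xs[k]) - f(xs[i])) / (xs[k] - xs[i])
    if (r > best) best <- r
  }
  best
}

# Default model configuration used throughout the reference runs.
default_params <- function(variant = "as_printed")
  kinetic_parameters(0.0530, 0.012, 0.040, variant = variant)
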
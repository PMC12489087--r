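#' Time-dependent fractional order specification
#'
#' Constructs an evaluable order function \eqn{\delta(t)} for the
#' variable-order Caputo operator.  Four families are supported:
#' \describe{
#'   \item{constant}{\eqn{\delta(t) = b}}
#'   \item{cosine}{\eqn{\delta(t) = b + a\,\cos(t/s)}}
#'   \item{sine}{\eqn{\delta(t) = b + a\,\sin(t/s)}}
#'   \item{linear}{\eqn{\delta(t) = b + m\,t}}
#' }
#' where \eqn{b} is `base`, \eqn{a} is `amplitude`, \eqn{s} is `timescale`
#' (time units) and \eqn{m} is `slope` (per time unit).  Every evaluation
#' must land in \eqn{(0, 1]}; values outside that range raise an error and
#' are never clamped, since the memory kernel \eqn{(t-v)^{\delta(t)-1}} is
#' only meaningful for orders in that interval.
#'
#' @param family One of `"constant"`, `"cosine"`, `"sine"`, `"linear"`.
#' @param base Base level of the order (dimensionless, in (0, 1]).
#' @param amplitude Oscillation amplitude for the `cosine`/`sine` families.
#' @param timescale Time scale \eqn{s} of the oscillation argument `t/s`.
#' @param slope Slope of the `linear` family (per time unit).
#' @param label Optional display label; a formula-like label is generated
#'   when omitted.
#' @return An object of class `order_function`.
#' @examples
#' d <- order_function("cosine", base = 0.98, amplitude = 0.008, timescale = 10)
#' eval_order(d, 0)    # 0.988
#' @seealso [eval_order()]
#' @export
order_function <- function(family = c("constant", "cosine", "sine", "linear"),
                           base, amplitude = 0, timescale = 1, slope = 0,
                           label = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(base), length(base) == 1L, is.finite(base))
  if (family %in% c("cosine", "sine")) {
    stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
              is.numeric(timescale), length(timescale) == 1L, timescale > 0)
  }
  if (family == "linear")
    stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  if (is.null(label)) {
    label <- switch(family,
      constant = sprintf("delta(t) = %g", base),
      cosine   = sprintf("delta(t) = %g + %g*cos(t/%g)", base, amplitude, timescale),
      sine     = sprintf("delta(t) = %g + %g*sin(t/%g)", base, amplitude, timescale),
      linear   = sprintf("delta(t) = %g + %g*t", base, slope))
  }
  structure(list(family = family, base = base, amplitude = amplitude,
                 timescale = timescale, slope = slope, label = label),
            class = "order_function")
}

#' Evaluate an order function
#'
#' Evaluates \eqn{\delta(t)} for one or more times.  Results outside
#' \eqn{(0, 1]} are a domain error (reported with the offending `t` and the
#' computed value), never silently clamped.
#'
#' @param spec An [order_function()].
#' @param t Numeric vector of non-negative times.
#' @return Numeric vector of order values in \eqn{(0, 1]}.
#' @export
eval_order <- function(spec, t) {
  stopifnot(inherits(spec, "order_function"), is.numeric(t), all(is.finite(t)))
  if (any(t < 0)) stop("eval_order(): t must be >= 0, got ", min(t))
  val <- switch(spec$family,
    constant = rep_len(spec$base, length(t)),
    cosine   = spec$base + spec$amplitude * cos(t / spec$timescale),
    sine     = spec$base + spec$amplitude * sin(t / spec$timescale),
    linear   = spec$base + spec$slope * t)
  bad <- which(val <= 0 | val > 1)
  if (length(bad)) {
    stop(sprintf(
      "order function '%s' leaves (0, 1]: delta(%g) = %g",
      spec$label, t[bad[1L]], val[bad[1L]]))
  }
  val
}

# TRUE when the order is identically 1 (the classical integer-order case).
is_constant_one <- function(spec) {
  inherits(spec, "order_function") &&
    spec$family == "constant" && spec$base == 1
}

#' @export
print.order_function <- function(x, ...) {
  cat("<order_function> ", x$label, "  [family: ", x$family, "]\n", sep = "")
  invisible(x)
}
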
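#' Whole attachment-time distribution and its prevalent-cohort transforms
#'
#' A tick attached to a captured host is observed mid-feed: its whole
#' attachment time `T` (landing to drop-off) is modelled as Weibull with
#' shape `k` and scale `lambda` (days), but sampling at capture is
#' length-biased (inclusion probability proportional to `T`) and only the
#' forward recurrence time `V` (capture to drop-off) is seen. Under a
#' capture instant uniform over the attachment spell, `V` follows the
#' equilibrium (renewal) distribution with density `S_T(v) / E[T]`, a
#' generalised gamma law whose density is monotone non-increasing.
#'
#' These functions give the closed forms for the whole-time law
#' ([dwhole()]), its length-biased version ([dbiased()], [rbiased()]), the
#' forward-recurrence law ([dforward()], [pforward()], [rforward()]), the
#' two means, and the whole/observed mean ratio which depends on the shape
#' only ([mean_ratio()]). Log-gamma arithmetic is used throughout so large
#' shapes do not overflow.
#'
#' @param t,v Non-negative times in days. Values below zero get density 0.
#' @param n Number of draws.
#' @param shape,scale Weibull shape `k > 0` (dimensionless) and scale
#'   `lambda > 0` (days) of the whole attachment time.
#' @param log Return the log density?
#' @return Densities per day, probabilities, means in days, or draws in
#'   days, vectorised over the inputs.
#' @examples
#' whole_mean(shape = 1, scale = 7)         # exponential mean: 7
#' mean_ratio(1)                            # memoryless: whole == observed
#' v <- rforward(5, shape = 4.5, scale = 6)
#' dforward(v, shape = 4.5, scale = 6)
#' @name attachment_model
NULL

check_weibull_pars <- function(shape, scale) {
  if (!is.numeric(shape) || any(!is.finite(shape)) || any(shape <= 0))
    stop("'shape' must be a positive finite number", call. = FALSE)
  if (!is.numeric(scale) || any(!is.finite(scale)) || any(scale <= 0))
    stop("'scale' must be a positive finite number (days)", call. = FALSE)
  invisible(TRUE)
}

#' @rdname attachment_model
#' @export
dwhole <- function(t, shape, scale, log = FALSE) {
  check_weibull_pars(shape, scale)
  dweibull(t, shape = shape, scale = scale, log = log)
}

#' @rdname attachment_model
#' @export
whole_mean <- function(shape, scale) {
  check_weibull_pars(shape, scale)
  scale * exp(lgamma(1 + 1 / shape))
}

#' @rdname attachment_model
#' @export
dbiased <- function(t, shape, scale, log = FALSE) {
  check_weibull_pars(shape, scale)
  ld <- ifelse(t > 0,
    log(pmax(t, .Machine$double.xmin)) +
      dweibull(pmax(t, 0), shape, scale, log = TRUE) -
      log(whole_mean(shape, scale)),
    -Inf)
  if (log) ld else exp(ld)
}

# exact draw: if U = (T*/scale)^shape then U ~ Gamma(1 + 1/shape) under the
# length-biased law, so no rejection step is needed
#' @rdname attachment_model
#' @export
rbiased <- function(n, shape, scale) {
  check_weibull_pars(shape, scale)
  scale * rgamma(n, shape = 1 + 1 / shape)^(1 / shape)
}

#' @rdname attachment_model
#' @export
dforward <- function(v, shape, scale, log = FALSE) {
  check_weibull_pars(shape, scale)
  ld <- ifelse(v >= 0,
    -(pmax(v, 0) / scale)^shape - log(scale) - lgamma(1 + 1 / shape),
    -Inf)
  if (log) ld else exp(ld)
}

# F_V(v) = P(V <= v) reduces to a regularised incomplete gamma:
# substituting u = (x/scale)^shape in the integral of S_T gives
# F_V(v) = pgamma((v/scale)^shape, shape = 1/shape)
#' @rdname attachment_model
#' @export
pforward <- function(v, shape, scale) {
  check_weibull_pars(shape, scale)
  pgamma((pmax(v, 0) / scale)^shape, shape = 1 / shape)
}

#' @rdname attachment_model
#' @export
rforward <- function(n, shape, scale) {
  runif(n) * rbiased(n, shape, scale)
}

#' @rdname attachment_model
#' @export
forward_mean <- function(shape, scale) {
  check_weibull_pars(shape, scale)
  scale * exp(lgamma(1 + 2 / shape) - lgamma(1 + 1 / shape)) / 2
}

#' Ratio of mean whole to mean observed attachment time
#'
#' Under the length-biased Weibull model the ratio
#' `E[T] / E[V] = 2 * Gamma(1 + 1/k)^2 / Gamma(1 + 2/k)` depends only on
#' the shape `k`: it is 1 in the memoryless case `k = 1`, increases
#' strictly with `k`, and approaches 2 as the whole-time law degenerates
#' to a point mass. [mean_ratio_ci()] propagates the uncertainty of an
#' estimated shape to the ratio by the delta method, truncating to the
#' attainable interval (0, 2).
#'
#' @param shape Weibull shape parameter(s), positive.
#' @param shape_se Standard error of the estimated shape (non-negative).
#' @param level Confidence level in (0, 1).
#' @return `mean_ratio()`: the dimensionless ratio. `mean_ratio_deriv()`:
#'   its derivative in the shape. `mean_ratio_ci()`: a list with
#'   `estimate`, `lower`, `upper`, `level`.
#' @examples
#' mean_ratio(4.5)
#' mean_ratio_ci(4.15, shape_se = 0.3)
#' @export
mean_ratio <- function(shape) {
  if (any(!is.finite(shape)) || any(shape <= 0))
    stop("'shape' must be positive and finite", call. = FALSE)
  2 * exp(2 * lgamma(1 + 1 / shape) - lgamma(1 + 2 / shape))
}

#' @rdname mean_ratio
#' @export
mean_ratio_deriv <- function(shape) {
  mean_ratio(shape) * (2 / shape^2) *
    (digamma(1 + 2 / shape) - digamma(1 + 1 / shape))
}

#' @rdname mean_ratio
#' @export
mean_ratio_ci <- function(shape, shape_se, level = 0.95) {
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("'level' must lie strictly between 0 and 1", call. = FALSE)
  if (shape_se < 0) stop("'shape_se' must be non-negative", call. = FALSE)
  est <- mean_ratio(shape)
  z <- qnorm(1 - (1 - level) / 2)
  half <- z * abs(mean_ratio_deriv(shape)) * shape_se
  list(estimate = est,
       lower = max(0, est - half),
       upper = min(2, est + half),
       level = level)
}
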
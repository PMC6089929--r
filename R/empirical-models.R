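# Empirical sub-models: proportional SI approximation, dose-dependent
# logistic slope family, dose-dependent quadratic rate map, and the
# closed-form integrals of the logistic and squared logistic.

#' Approximate the sensitivity index of INR to factor VII
#'
#' The sensitivity index `SI_VII` (the magnitude of the partial derivative
#' of INR with respect to factor VII) is approximated by the proportional
#' model `SI = q * INR / VII`, valid once factor VII has reached its own
#' steady state (about two days after a dose change, given its ~6 h
#' half-life).
#'
#' @param inr INR value(s), dimensionless, > 0.
#' @param vii Factor VII activity, percent of the pre-treatment baseline
#'   (100 at baseline), > 0.
#' @param params An [published_parameters()] object (defaults to the
#'   published set).
#' @return Sensitivity index (per \%), vectorised over `inr` and `vii`.
#'   Strictly increasing in `inr` and strictly decreasing in `vii`.
#' @examples
#' approx_si(inr = 2.0, vii = 20)
#' @export
approx_si <- function(inr, vii, params = published_parameters()) {
  params <- as_inr_params(params)
  if (any(!is.finite(inr)) || any(inr <= 0)) {
    stop("`inr` must be positive and finite (invalid measurement)",
         call. = FALSE)
  }
  if (any(!is.finite(vii)) || any(vii <= 0)) {
    stop("`vii` must be positive and finite (invalid measurement)",
         call. = FALSE)
  }
  params$q * inr / vii
}

#' Dose-dependent logistic model for the sensitivity-index slope
#'
#' The rate of change of the sensitivity index after a dose change follows
#' a 3-parameter logistic decline
#' `dSI/dt = h / (1 + exp(p * (t - g)))`, where both the upper asymptote
#' `h` and the horizontal shift `g` depend on the reference dose:
#' `h = a0 + a1 * dref` and `g = b0 + b1 * log(dref)`.
#'
#' @param dref Reference dose (mg/day), > 0 (the log-dose shift is
#'   undefined otherwise).
#' @inheritParams approx_si
#' @return An object of class `logistic_slope` with fields `h`, `g`, `p`
#'   and `dref`.
#' @examples
#' mod <- logistic_slope(4)
#' logistic_slope_at(c(0, 3, 4, 15), mod)
#' @export
logistic_slope <- function(dref, params = published_parameters()) {
  params <- as_inr_params(params)
  if (!is.numeric(dref) || length(dref) != 1L || !is.finite(dref) ||
      dref <= 0) {
    stop("`dref` must be a single positive dose (g(D_ref) is undefined ",
         "for D_ref <= 0)", call. = FALSE)
  }
  structure(
    list(
      h = params$a0 + params$a1 * dref,
      g = params$b0 + params$b1 * log(dref),
      p = params$p,
      dref = dref
    ),
    class = "logistic_slope"
  )
}

#' @export
print.logistic_slope <- function(x, ...) {
  cat(sprintf("<logistic_slope> dref = %g mg/day: h = %.4g /day, g = %.4g days, p = %.3g /day\n",
              x$dref, x$h, x$g, x$p))
  invisible(x)
}

#' Evaluate the sensitivity-index slope at given times
#'
#' @param t Time(s) since the dose change, days, >= 0.
#' @param model A [logistic_slope()] object.
#' @return `dSI/dt` (per day), non-increasing in `t`; exactly `h/2` at
#'   `t = g`. Overflow-safe for `p * (t - g)` up to several hundred.
#' @export
logistic_slope_at <- function(t, model) {
  stopifnot(inherits(model, "logistic_slope"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and non-negative", call. = FALSE)
  }
  # h * sigmoid(-p (t - g)); plogis is the stable logistic CDF
  model$h * stats::plogis(model$p * (model$g - t))
}

# log(1 + exp(x)) without overflow for large |x|
log1pexp <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

#' Closed-form integrals of the logistic slope and its square
#'
#' `integral_slope()` gives the cumulative change of the sensitivity index
#' over `[t_lo, t_hi]`,
#' \deqn{\int h/(1+e^{p(t-g)}) dt =
#'   h\,[(t_{hi}-t_{lo}) - (1/p)\,(\ln(1+e^{u_{hi}}) - \ln(1+e^{u_{lo}}))]}
#' with `u = p (t - g)`. `integral_slope_squared()` integrates the squared
#' slope using the antiderivative
#' `F(u) = u - ln(1 + e^u) + 1/(1 + e^u)`, so the integral equals
#' `(h^2 / p) * (F(u_hi) - F(u_lo))`. Both are evaluated in overflow-safe
#' form and agree with adaptive quadrature of the corresponding integrand
#' to better than 1e-8 relative error.
#'
#' @param t_lo,t_hi Integration limits, days, `0 <= t_lo <= t_hi`.
#' @param model A [logistic_slope()] object.
#' @return The definite integral: cumulative sensitivity-index change
#'   (per \%) for `integral_slope()`, and the integral of the squared
#'   slope (per \%^2 / day) for `integral_slope_squared()`.
#' @export
integral_slope <- function(t_lo, t_hi, model) {
  stopifnot(inherits(model, "logistic_slope"))
  check_interval(t_lo, t_hi)
  u_lo <- model$p * (t_lo - model$g)
  u_hi <- model$p * (t_hi - model$g)
  model$h * ((t_hi - t_lo) - (log1pexp(u_hi) - log1pexp(u_lo)) / model$p)
}

#' @rdname integral_slope
#' @export
integral_slope_squared <- function(t_lo, t_hi, model) {
  stopifnot(inherits(model, "logistic_slope"))
  check_interval(t_lo, t_hi)
  u_lo <- model$p * (t_lo - model$g)
  u_hi <- model$p * (t_hi - model$g)
  # F(u) = u - ln(1+e^u) + 1/(1+e^u). For u >= 0 rewrite via x = e^(-u):
  # F(u) = x/(1+x) - log1p(x), avoiding the u - (u + log1p(x)) cancellation
  # that loses the tiny tail values.
  F_ad <- function(u) {
    ifelse(u >= 0,
           { x <- exp(-pmax(u, 0)); x / (1 + x) - log1p(x) },
           u - log1p(exp(pmin(u, 0))) + 1 / (1 + exp(pmin(u, 0))))
  }
  val <- (model$h^2 / model$p) * (F_ad(u_hi) - F_ad(u_lo))
  pmax(val, 0) # guard tiny negative round-off at t_lo == t_hi
}

check_interval <- function(t_lo, t_hi) {
  if (any(!is.finite(t_lo)) || any(!is.finite(t_hi)) || any(t_lo < 0)) {
    stop("integration limits must be finite and non-negative", call. = FALSE)
  }
  if (any(t_hi < t_lo)) {
    stop("`t_hi` must not be smaller than `t_lo`", call. = FALSE)
  }
  invisible(TRUE)
}

#' Dose-dependent quadratic map from sensitivity-index slope to INR slope
#'
#' The rate of INR change is a no-intercept quadratic in the
#' sensitivity-index slope, `dINR/dt = k * slope^2 + m * slope`, with
#' dose-dependent coefficients `k = -exp(c0 + c1 * log(dref))` (negative)
#' and `m = exp(s0 + s1 * log(dref))` (positive).
#'
#' @inheritParams logistic_slope
#' @return An object of class `quadratic_map` with fields `k`, `m`, `dref`.
#' @examples
#' qm <- quadratic_map(4)
#' quadratic_map_apply(c(0, 0.002, 0.004), qm)
#' @export
quadratic_map <- function(dref, params = published_parameters()) {
  params <- as_inr_params(params)
  if (!is.numeric(dref) || length(dref) != 1L || !is.finite(dref) ||
      dref <= 0) {
    stop("`dref` must be a single positive dose", call. = FALSE)
  }
  structure(
    list(
      k = -exp(params$c0 + params$c1 * log(dref)),
      m = exp(params$s0 + params$s1 * log(dref)),
      dref = dref
    ),
    class = "quadratic_map"
  )
}

#' @export
print.quadratic_map <- function(x, ...) {
  cat(sprintf("<quadratic_map> dref = %g mg/day: k = %.4g, m = %.4g\n",
              x$dref, x$k, x$m))
  invisible(x)
}

#' Apply the quadratic rate map
#'
#' @param slope Sensitivity-index slope(s), per day, >= 0.
#' @param map A [quadratic_map()] object.
#' @return `dINR/dt` (per day); zero at `slope = 0` (no intercept).
#' @export
quadratic_map_apply <- function(slope, map) {
  stopifnot(inherits(map, "quadratic_map"))
  if (any(!is.finite(slope)) || any(slope < 0)) {
    stop("`slope` must be finite and non-negative", call. = FALSE)
  }
  map$k * slope^2 + map$m * slope
}
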
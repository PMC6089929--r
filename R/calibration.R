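# Calibration machinery that produced the empirical sub-models: the
# proportional SI approximation (one-parameter regression through the
# origin), the dose-dependent logistic slope family, and the
# dose-dependent quadratic rate map, fitted by nonlinear least squares
# to factor/INR time-course data.

#' Sensitivity-index slope series from a time course
#'
#' Computes the sensitivity index pointwise via [approx_si()], then
#' differentiates on the time grid with central finite differences
#' (one-sided at the ends).
#'
#' @param tc A data frame with columns `time_days` (strictly increasing),
#'   `inr` and `factor_vii_pct`, and optionally `dose_mg_day`.
#' @inheritParams approx_si
#' @return A tibble with `time_days`, `si` and `dsi_dt` (per day), plus
#'   `dose_mg_day` when present in the input.
#' @examples
#' tc <- simulate_time_course(synthetic_patient(4), seq(0.5, 20, 0.1))
#' derive_slope_series(tc)
#' @export
derive_slope_series <- function(tc, params = published_parameters()) {
  params <- as_inr_params(params)
  frame <- check_sample_frame(tc)
  if (nrow(frame) < 3L) {
    stop("need at least 3 time points to differentiate", call. = FALSE)
  }
  if (is.unsorted(frame$time_days, strictly = TRUE)) {
    stop("`time_days` must be strictly increasing", call. = FALSE)
  }
  si <- approx_si(frame$inr, frame$vii_pct, params)
  out <- tibble::tibble(
    time_days = frame$time_days,
    si = si,
    dsi_dt = finite_diff(frame$time_days, si)
  )
  if ("dose_mg_day" %in% names(tc)) {
    out <- dplyr::bind_cols(tibble::tibble(dose_mg_day = tc$dose_mg_day), out)
  }
  out
}

# central differences on a (possibly non-uniform) grid; second-order
# three-point one-sided stencils at the ends so the boundary error is
# O(h^2) like the interior
finite_diff <- function(t, y) {
  n <- length(t)
  d <- numeric(n)
  if (n == 2L) {
    d[] <- (y[2] - y[1]) / (t[2] - t[1])
    return(d)
  }
  one_sided <- function(i1, i2, i3) {
    x1 <- t[i1]; x2 <- t[i2]; x3 <- t[i3]
    y[i1] * (2 * x1 - x2 - x3) / ((x1 - x2) * (x1 - x3)) +
      y[i2] * (x1 - x3) / ((x2 - x1) * (x2 - x3)) +
      y[i3] * (x1 - x2) / ((x3 - x1) * (x3 - x2))
  }
  d[1] <- one_sided(1L, 2L, 3L)
  d[n] <- one_sided(n, n - 1L, n - 2L)
  i <- 2:(n - 1)
  d[i] <- (y[i + 1] - y[i - 1]) / (t[i + 1] - t[i - 1])
  d
}

new_si_fit <- function(estimates, se, r_squared, residuals, fitted,
                       method, n, n_par) {
  rse_pct <- 100 * se / abs(estimates)
  structure(
    list(
      estimates = estimates,
      se = se,
      rse_pct = rse_pct,
      r_squared = r_squared,
      residuals = residuals,
      fitted = fitted,
      method = method,
      n = n,
      n_par = n_par
    ),
    class = "si_fit"
  )
}

#' @export
print.si_fit <- function(x, ...) {
  cat(sprintf("<si_fit> %s (n = %d, adj. r^2 = %.4f)\n",
              x$method, x$n, x$r_squared))
  est <- tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    rse_pct = unname(x$rse_pct)
  )
  print(est)
  invisible(x)
}

#' @export
tidy.si_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    std.error = unname(x$se),
    rse_pct = unname(x$rse_pct)
  )
}

#' @export
glance.si_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n = x$n,
    n_par = x$n_par,
    adj.r.squared = x$r_squared,
    sigma = sqrt(sum(x$residuals^2) / max(x$n - x$n_par, 1))
  )
}

adj_r_squared <- function(y, residuals, n_par) {
  n <- length(y)
  ss_res <- sum(residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - (ss_res / (n - n_par)) / (ss_tot / (n - 1))
}

#' Fit the proportionality constant of the SI approximation
#'
#' One-parameter least squares through the origin for
#' `si = q * (INR / VII)`: regressing reference sensitivity-index values
#' on the INR-to-factor-VII ratio.
#'
#' @param data A data frame with columns `si` (reference sensitivity
#'   index) and `ratio` (INR / factor VII), at least two rows.
#' @param weighting `"none"` (ordinary least squares, the default) or
#'   `"proportional"` (weights `1/si^2`, the correct objective when the
#'   residual error is proportional to the signal, as in a constant-CV
#'   error model).
#' @return An `si_fit` with the estimate `q`, its \%RSE and adjusted r^2.
#' @examples
#' d <- tibble::tibble(ratio = seq(0.01, 0.1, length.out = 50))
#' d$si <- 0.233 * d$ratio
#' fit_q(d)
#' @export
fit_q <- function(data, weighting = c("none", "proportional")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(data))
  if (!all(c("si", "ratio") %in% names(data))) {
    stop("`data` needs columns `si` and `ratio`", call. = FALSE)
  }
  si <- as.numeric(data$si)
  ratio <- as.numeric(data$ratio)
  if (length(si) != length(ratio) || length(si) < 2L) {
    stop("need at least 2 matched (si, ratio) observations", call. = FALSE)
  }
  if (any(ratio <= 0)) stop("ratios must be positive", call. = FALSE)
  w <- if (weighting == "proportional") {
    if (any(si <= 0)) {
      stop("proportional weighting requires positive `si`", call. = FALSE)
    }
    1 / si^2
  } else {
    rep(1, length(si))
  }
  fit <- stats::lm(si ~ 0 + ratio, weights = w)
  est <- stats::coef(fit)
  # noiseless calibration data legitimately yields a perfect fit; the
  # "summary may be unreliable" warning is expected there
  se <- suppressWarnings(summary(fit))$coefficients[, "Std. Error"]
  new_si_fit(
    estimates = c(q = unname(est)),
    se = c(q = unname(se)),
    r_squared = adj_r_squared(si, stats::residuals(fit), 1L),
    residuals = stats::residuals(fit),
    fitted = stats::fitted(fit),
    method = "origin regression si ~ q * ratio",
    n = length(si), n_par = 1L
  )
}

# Levenberg-Marquardt with deterministic multi-start perturbations.
# start_list: list of named start vectors tried in order; best SSR wins.
nls_multistart <- function(formula, data, start, lower, upper,
                           n_restarts = 5L, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(data))
  data$.w <- weights
  starts <- c(
    list(start),
    lapply(seq_len(n_restarts), function(i) {
      # deterministic geometric perturbations, alternating direction
      fac <- 1 + 0.25 * i * (-1)^i
      out <- start * fac
      pmin(pmax(out, lower + 1e-12), upper - 1e-12)
    })
  )
  best <- NULL
  errors <- character()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        formula, data = data, start = as.list(s),
        lower = lower, upper = upper, weights = .w,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      next
    }
    ssr <- sum(stats::residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best)) {
    stop("nonlinear least squares failed to converge from any start: ",
         paste(unique(errors), collapse = " | "), call. = FALSE)
  }
  best$fit
}

#' Fit the dose-dependent logistic family for the sensitivity-index slope
#'
#' Joint nonlinear least squares across dose levels for the model
#' `dsi_dt = (a0 + a1 * dose) / (1 + exp(p * (t - (b0 + b1 * log(dose)))))`,
#' with the shape `p` fixed (default 0.300) or estimated.
#'
#' @param data A data frame with columns `dose_mg_day`, `time_days` and
#'   `dsi_dt`; at least 2 dose levels with at least 4 time points each.
#' @param fix_p Fixed shape value (per day), or `NULL` to estimate `p`.
#' @param start Optional named start vector overriding the defaults.
#' @inheritParams fit_q
#' @return An `si_fit` with estimates `a0`, `a1`, `b0`, `b1` (and `p` when
#'   free), Jacobian-based \%RSE, and adjusted r^2.
#' @export
fit_logistic_family <- function(data, fix_p = 0.300, start = NULL,
                                weighting = c("none", "proportional")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(data))
  need <- c("dose_mg_day", "time_days", "dsi_dt")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  doses <- unique(data$dose_mg_day)
  if (length(doses) < 2L) {
    stop("need at least 2 dose levels: the dose-dependency of h and g is ",
         "unidentifiable from a single dose", call. = FALSE)
  }
  counts <- table(data$dose_mg_day)
  if (any(counts < 4L)) {
    stop("each dose level needs at least 4 time points", call. = FALSE)
  }
  if (any(data$dose_mg_day <= 0)) {
    stop("doses must be positive", call. = FALSE)
  }
  d <- data.frame(dose = data$dose_mg_day, t = data$time_days,
                  y = data$dsi_dt)
  # crude moment-based starts: asymptote from early slope values,
  # shift from where the slope halves
  y_early <- stats::aggregate(y ~ dose, data = d[d$t <= stats::quantile(d$t, 0.25), ],
                              FUN = max)
  h_start <- stats::coef(stats::lm(y ~ dose, data = y_early))
  if (!is.finite(h_start[1])) h_start[1] <- 1e-4
  default_start <- c(a0 = max(unname(h_start[1]), 1e-6),
                     a1 = max(unname(h_start[2]), 1e-6),
                     b0 = -1, b1 = 3)
  lower <- c(a0 = 1e-8, a1 = 1e-8, b0 = -50, b1 = 1e-6)
  upper <- c(a0 = 1, a1 = 1, b0 = 50, b1 = 50)
  if (is.null(fix_p)) {
    default_start <- c(default_start, p = 0.3)
    lower <- c(lower, p = 1e-3)
    upper <- c(upper, p = 10)
    formula <- y ~ (a0 + a1 * dose) /
      (1 + exp(p * (t - (b0 + b1 * log(dose)))))
    method <- "joint logistic family (p free)"
  } else {
    d$p_fix <- fix_p
    formula <- y ~ (a0 + a1 * dose) /
      (1 + exp(p_fix * (t - (b0 + b1 * log(dose)))))
    method <- sprintf("joint logistic family (p fixed at %g)", fix_p)
  }
  if (!is.null(start)) default_start[names(start)] <- start
  w <- make_weights(d$y, weighting)
  fit <- nls_multistart(formula, d, default_start, lower, upper,
                        weights = w)
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  new_si_fit(
    estimates = est, se = se,
    r_squared = adj_r_squared(d$y, raw_residuals(fit, d$y), length(est)),
    residuals = raw_residuals(fit, d$y),
    fitted = stats::fitted(fit),
    method = method, n = nrow(d), n_par = length(est)
  )
}

make_weights <- function(y, weighting) {
  if (weighting == "none") return(NULL)
  if (any(y <= 0)) {
    stop("proportional weighting requires strictly positive responses",
         call. = FALSE)
  }
  1 / y^2
}

# nls residuals are weighted when weights were supplied; recover raw
raw_residuals <- function(fit, y) {
  y - stats::fitted(fit)
}

#' Fit the dose-dependent quadratic rate map
#'
#' Joint nonlinear least squares across dose levels for the no-intercept
#' quadratic `dinr_dt = -exp(c0 + c1 * log(dose)) * dsi_dt^2 +
#' exp(s0 + s1 * log(dose)) * dsi_dt`.
#'
#' @param data A data frame with columns `dose_mg_day`, `dsi_dt` and
#'   `dinr_dt`; at least 2 dose levels.
#' @param start Optional named start vector (`c0`, `c1`, `s0`, `s1`).
#' @inheritParams fit_q
#' @return An `si_fit` with estimates `c0`, `c1`, `s0`, `s1`,
#'   Jacobian-based \%RSE, and adjusted r^2.
#' @export
fit_quadratic_family <- function(data, start = NULL,
                                 weighting = c("none", "proportional")) {
  weighting <- match.arg(weighting)
  stopifnot(is.data.frame(data))
  need <- c("dose_mg_day", "dsi_dt", "dinr_dt")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(data$dose_mg_day)) < 2L) {
    stop("need at least 2 dose levels: the dose-dependency of k and m is ",
         "unidentifiable from a single dose", call. = FALSE)
  }
  if (any(data$dose_mg_day <= 0)) {
    stop("doses must be positive", call. = FALSE)
  }
  if (all(data$dsi_dt == 0)) {
    stop("all sensitivity-index slopes are zero: the quadratic is ",
         "unidentifiable", call. = FALSE)
  }
  d <- data.frame(dose = data$dose_mg_day, x = data$dsi_dt,
                  y = data$dinr_dt)
  default_start <- c(c0 = 10, c1 = -2, s0 = 5, s1 = -0.5)
  if (!is.null(start)) default_start[names(start)] <- start
  lower <- c(c0 = -50, c1 = -20, s0 = -50, s1 = -20)
  upper <- c(c0 = 50, c1 = 20, s0 = 50, s1 = 20)
  formula <- y ~ -exp(c0 + c1 * log(dose)) * x^2 +
    exp(s0 + s1 * log(dose)) * x
  w <- make_weights(d$y, weighting)
  fit <- nls_multistart(formula, d, default_start, lower, upper,
                        weights = w)
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  new_si_fit(
    estimates = est, se = se,
    r_squared = adj_r_squared(d$y, raw_residuals(fit, d$y), length(est)),
    residuals = raw_residuals(fit, d$y),
    fitted = stats::fitted(fit),
    method = "joint no-intercept quadratic family",
    n = nrow(d), n_par = length(est)
  )
}

#' Two-stage per-dose logistic fits (diagnostic)
#'
#' Fits a separate 2-parameter logistic (`h`, `g`; shared fixed `p`) to
#' each dose level. Useful to inspect how the per-dose `h` and `g`
#' estimates vary with dose before the joint fit; the joint
#' [fit_logistic_family()] is the production fit.
#'
#' @inheritParams fit_logistic_family
#' @return A tibble with one row per dose: `dose_mg_day`, `h`, `g`, and
#'   the per-dose residual sum of squares.
#' @export
fit_logistic_per_dose <- function(data, fix_p = 0.300) {
  stopifnot(is.data.frame(data))
  need <- c("dose_mg_day", "time_days", "dsi_dt")
  if (!all(need %in% names(data))) {
    stop("`data` needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  data |>
    dplyr::group_by(.data$dose_mg_day) |>
    dplyr::group_modify(function(df, key) {
      d <- data.frame(t = df$time_days, y = df$dsi_dt, p_fix = fix_p)
      fit <- nls_multistart(
        y ~ h / (1 + exp(p_fix * (t - g))), d,
        start = c(h = max(d$y), g = stats::median(d$t)),
        lower = c(h = 1e-10, g = -50), upper = c(h = 1, g = 100)
      )
      est <- stats::coef(fit)
      tibble::tibble(h = est[["h"]], g = est[["g"]],
                     ssr = sum(stats::residuals(fit)^2))
    }) |>
    dplyr::ungroup()
}
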
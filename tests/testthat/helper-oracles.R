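# Independent oracles and shared data generators for the test suite.

`%||%` <- function(x, y) if (is.null(x)) y else x

# adaptive quadrature of the logistic slope (independent of the
# closed-form path under test)
quad_integral_slope <- function(t_lo, t_hi, model, rel.tol = 1e-10) {
  if (t_hi == t_lo) return(0)
  f <- function(t) model$h / (1 + exp(model$p * (t - model$g)))
  stats::integrate(f, t_lo, t_hi, rel.tol = rel.tol,
                   subdivisions = 2000L)$value
}

quad_integral_slope_squared <- function(t_lo, t_hi, model,
                                        rel.tol = 1e-10) {
  if (t_hi == t_lo) return(0)
  f <- function(t) (model$h / (1 + exp(model$p * (t - model$g))))^2
  stats::integrate(f, t_lo, t_hi, rel.tol = rel.tol,
                   subdivisions = 2000L)$value
}

# brute-force scan for the first time the slope drops to the tolerance
scan_time_to_ss <- function(dref, params = published_parameters(),
                            dt = 0.001, t_max = 60) {
  model <- logistic_slope(dref, params)
  t <- seq(0, t_max, by = dt)
  idx <- which(logistic_slope_at(t, model) <= params$eps_si)[1]
  t[idx]
}

# plain bisection, independent of uniroot
bisect <- function(f, lo, hi, tol = 1e-9, max_iter = 200L) {
  f_lo <- f(lo)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- f(mid)
    if (abs(hi - lo) < tol) return(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid
      f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

# noiseless slope time series from the published logistic family
make_slope_family_data <- function(doses = c(1, 4, 7, 10, 13),
                                   times = seq(0.5, 30, by = 0.5),
                                   params = published_parameters()) {
  purrr::map_dfr(doses, function(d) {
    tibble::tibble(
      dose_mg_day = d,
      time_days = times,
      dsi_dt = logistic_slope_at(times, logistic_slope(d, params))
    )
  })
}

# noiseless (dsi_dt, dinr_dt) pairs in each dose's positive-response
# region (up to the quadratic vertex)
make_quadratic_family_data <- function(doses = c(1, 4, 7, 10, 13),
                                       n = 40,
                                       params = published_parameters()) {
  purrr::map_dfr(doses, function(d) {
    qm <- quadratic_map(d, params)
    x_max <- min(logistic_slope(d, params)$h, qm$m / (2 * abs(qm$k)))
    x <- seq(0.05, 1, length.out = n) * x_max
    tibble::tibble(dose_mg_day = d, dsi_dt = x,
                   dinr_dt = quadratic_map_apply(x, qm))
  })
}

# multiplicative log-normal noise with unit mean and the given CV
lnorm_noise <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

published_truth <- c(
  q = 0.233, a0 = 0.000392, a1 = 0.00108, b0 = -1.48, b1 = 4.13,
  c0 = 11.9, c1 = -2.05, s0 = 5.26, s1 = -0.672
)
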
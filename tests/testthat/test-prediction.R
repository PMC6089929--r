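pair_frame <- function(t, inr, vii, id = NULL) {
  out <- tibble::tibble(time_days = t, inr = inr, factor_vii_pct = vii)
  if (!is.null(id)) out <- dplyr::mutate(out, patient_id = id)
  out
}

test_that("slope_from_pair is the finite difference of the sensitivity indices", {
  params <- published_parameters()
  # construct samples whose SI values are exactly 0.010 and 0.015
  s <- pair_frame(c(3, 4), inr = c(0.010 * 50 / params$q,
                                   0.015 * 40 / params$q),
                  vii = c(50, 40))
  res <- slope_from_pair(s, params)
  expect_equal(res$si_t1, 0.010)
  expect_equal(res$si_t2, 0.015)
  expect_equal(res$slope, 0.005)
  # identical samples give slope zero, rejected downstream
  s0 <- pair_frame(c(3, 4), c(2, 2), c(40, 40))
  expect_equal(slope_from_pair(s0)$slope, 0)
  expect_error(invert_dref(0, 3, 4), "non-increasing")
})

test_that("slope_from_pair enforces ordering and factor VII equilibration", {
  expect_error(slope_from_pair(pair_frame(c(3, 3), c(2, 2.1), c(40, 38))),
               "distinct times")
  expect_error(slope_from_pair(pair_frame(c(1, 2), c(1.5, 1.8), c(60, 50))),
               "equilibration|>=")
  # negative-path override used by the synthetic generator
  expect_silent(slope_from_pair(pair_frame(c(1, 2), c(1.5, 1.8), c(60, 50)),
                                enforce_equilibration = FALSE))
  expect_error(slope_from_pair(pair_frame(3, 2, 40)), "exactly 2")
})

test_that("slope from noiseless synthetic pairs equals the interval-mean of the logistic", {
  pt <- synthetic_patient(dref_true = 6)
  samples <- make_paired_samples(pt)$samples
  slope <- slope_from_pair(samples)$slope
  expect_equal(slope, integral_slope(3, 4, logistic_slope(6)),
               tolerance = 1e-12)
})

test_that("reference-dose inversion round-trips the forward model", {
  for (d in c(1, 6, 13)) {
    slope <- integral_slope(3, 4, logistic_slope(d)) / 1
    # at d = 1 the root lands epsilon below the support boundary, which may
    # trigger the extrapolation warning; the value itself must still round-trip
    expect_equal(suppressWarnings(invert_dref(slope, 3, 4)), d,
                 tolerance = 1e-6)
  }
  # midpoint variant round-trips its own forward model
  slope_mid <- logistic_slope_at(3.5, logistic_slope(6))
  expect_equal(invert_dref(slope_mid, 3, 4, mode = "midpoint"), 6,
               tolerance = 1e-6)
  # out-of-support solutions warn but are returned
  slope_lo <- integral_slope(3, 4, logistic_slope(0.5)) / 1
  expect_warning(d_lo <- invert_dref(slope_lo, 3, 4), "extrapolation")
  expect_equal(d_lo, 0.5, tolerance = 1e-6)
  # no solution within the bracket
  expect_error(invert_dref(1, 3, 4), "no reference dose")
})

test_that("time to steady state matches the printed typical-patient values", {
  expect_equal(time_to_steady_state(3.97), 15.6, tolerance = 0.1 / 15.6)
  expect_equal(time_to_steady_state(9.90), 22.3, tolerance = 0.1 / 22.3)
})

test_that("time to steady state agrees with a brute-force grid scan", {
  for (d in c(1, 2.5, 4.5, 8, 13)) {
    expect_equal(time_to_steady_state(d), scan_time_to_ss(d),
                 tolerance = 2e-3)
  }
})

test_that("time to steady state clamps to zero when the tolerance is already met", {
  # raise the tolerance above the whole slope curve
  params <- published_parameters(eps_si = 1)
  expect_equal(time_to_steady_state(4, params), 0)
  expect_error(time_to_steady_state(-1), "positive")
})

test_that("steady-state INR matches the printed values and quadrature", {
  expect_equal(steady_state_inr(3.97), 2.28, tolerance = 0.03 / 2.28)
  expect_equal(steady_state_inr(13.3), 4.66, tolerance = 0.03 / 4.66)
  # additivity in the baseline INR
  expect_equal(steady_state_inr(6, inr0 = 1.5) - steady_state_inr(6, 1.0),
               0.5, tolerance = 1e-12)
  # quadrature-based evaluation of the closed form
  for (d in c(1.2, 4, 9, 13)) {
    model <- logistic_slope(d)
    qm <- quadratic_map(d)
    t_ss <- time_to_steady_state(d)
    oracle <- 1 + qm$k * quad_integral_slope_squared(0, t_ss, model) +
      qm$m * quad_integral_slope(0, t_ss, model)
    expect_equal(suppressWarnings(steady_state_inr(d)), oracle,
                 tolerance = 1e-8)
  }
})

test_that("predicted INR rise is non-negative and predictions are monotone in dose", {
  d_grid <- seq(1, 13, by = 0.25)
  t_ss <- time_to_steady_state(d_grid)
  inr_ss <- suppressWarnings(steady_state_inr(d_grid))
  expect_true(all(inr_ss >= 1))
  expect_true(all(diff(t_ss) > 0))
  expect_true(all(diff(inr_ss) > 0))
})

test_that("full predictor recovers the generating dose on a noiseless grid", {
  for (d in seq(1, 13, by = 0.5)) {
    samples <- make_paired_samples(synthetic_patient(d))$samples
    res <- predict_steady_state(samples, dose = d)
    expect_equal(res$dref, d, tolerance = 1e-6)
    expect_equal(res$sensitivity_ratio, 1, tolerance = 1e-6)
  }
})

test_that("predictor reproduces the two retrospective patient summaries", {
  # construct exact day-3/day-4 samples whose inversion yields the
  # reported individualised reference doses
  for (case in list(list(dref = 6.10, t_ss = 18.7, inr_ss = 2.9,
                         tol_inr = 0.06),
                    list(dref = 7.32, t_ss = 20.0, inr_ss = 3.2,
                         tol_inr = 0.06))) {
    samples <- make_paired_samples(synthetic_patient(case$dref))$samples
    res <- predict_steady_state(samples, dose = 5)
    expect_equal(res$t_ss_inr, case$t_ss, tolerance = 0.1 / case$t_ss)
    expect_equal(res$inr_ss, case$inr_ss,
                 tolerance = case$tol_inr / case$inr_ss)
    expect_equal(res$sensitivity_ratio, case$dref / 5, tolerance = 1e-6)
  }
})

test_that("predictor propagates guards with stage labels and collects warnings", {
  early <- pair_frame(c(1, 1.5), c(1.4, 1.6), c(70, 60), id = "p1")
  expect_error(predict_steady_state(early, dose = 5), "equilibration|>=")
  expect_error(predict_steady_state(pair_frame(c(3, 4), c(2, 2), c(40, 40),
                                               id = "p1"), dose = 5),
               "reference-dose inversion")
  expect_error(predict_steady_state(pair_frame(c(3, 4), c(2, 2.4),
                                               c(40, 34)), dose = -5),
               "dose")
  # an extrapolated reference dose lands in the warnings column
  lo <- make_paired_samples(synthetic_patient(0.5))$samples
  res <- predict_steady_state(lo, dose = 1)
  expect_true(any(grepl("extrapolation", res$warnings[[1]])))
})

test_that("predictor handles several patients with per-patient doses", {
  s <- dplyr::bind_rows(
    make_paired_samples(synthetic_patient(4))$samples,
    make_paired_samples(synthetic_patient(9))$samples
  )
  res <- predict_steady_state(s, dose = c(5, 5))
  expect_equal(nrow(res), 2L)
  expect_equal(res$dref, c(4, 9), tolerance = 1e-6)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("dref", "t_ss_inr", "inr_ss", "n_warnings") %in%
                    names(td)))
  gl <- glance(res)
  expect_equal(gl$n_patients, 2L)
})

test_that("dose_for_target_inr inverts the steady-state prediction", {
  target <- suppressWarnings(steady_state_inr(4.0, 1.0))
  expect_equal(dose_for_target_inr(target, sensitivity_ratio = 1), 4.0,
               tolerance = 1e-6)
  target8 <- suppressWarnings(steady_state_inr(8.0, 1.0))
  expect_equal(dose_for_target_inr(target8, sensitivity_ratio = 2), 4.0,
               tolerance = 1e-6)
  # monotone in the target
  targets <- seq(1.6, 4.5, length.out = 8)
  doses <- vapply(targets, dose_for_target_inr, numeric(1))
  expect_true(all(diff(doses) > 0))
  expect_error(dose_for_target_inr(10), "unreachable")
  expect_error(dose_for_target_inr(0.9), "exceed the baseline")
})

test_that("dose_for_target_inr agrees with an independent bisection oracle", {
  set.seed(7)
  for (i in 1:20) {
    dref <- runif(1, 1.2, 12.8)
    ratio <- runif(1, 0.5, 2)
    target <- suppressWarnings(steady_state_inr(dref, 1.0))
    oracle <- bisect(
      function(d) suppressWarnings(steady_state_inr(d, 1.0)) - target,
      1, 13, tol = 1e-9
    ) / ratio
    expect_equal(dose_for_target_inr(target, ratio), oracle,
                 tolerance = 1e-6)
  }
})
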
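test_that("derive_slope_series differentiates the sensitivity index on the grid", {
  params <- published_parameters()
  t <- seq(1, 10, by = 0.5)
  # constant SI -> zero slope: INR proportional to VII
  vii <- 100 * exp(-0.1 * t)
  tc_const <- tibble::tibble(time_days = t, inr = 0.01 * vii / params$q,
                             factor_vii_pct = vii)
  expect_equal(derive_slope_series(tc_const)$dsi_dt, rep(0, length(t)),
               tolerance = 1e-12)
  # SI linear in t with slope 0.002/day -> constant derivative
  si <- 0.005 + 0.002 * t
  tc_lin <- tibble::tibble(time_days = t, inr = si * vii / params$q,
                           factor_vii_pct = vii)
  expect_equal(derive_slope_series(tc_lin)$dsi_dt, rep(0.002, length(t)),
               tolerance = 1e-10)
  expect_error(derive_slope_series(tc_lin[1:2, ]), "at least 3")
})

test_that("finite differences recover the logistic slope within truncation error", {
  pt <- synthetic_patient(dref_true = 4)
  t <- seq(0.5, 25, by = 0.1)
  tc <- simulate_time_course(pt, t)
  out <- derive_slope_series(tc)
  truth <- logistic_slope_at(t, logistic_slope(4))
  interior <- 2:(length(t) - 1)
  expect_lt(max(abs(out$dsi_dt[interior] - truth[interior])), 1e-4)
})

test_that("fit_q recovers the proportionality constant", {
  ratio <- seq(0.005, 0.1, length.out = 50)
  noiseless <- tibble::tibble(ratio = ratio, si = 0.233 * ratio)
  fit <- fit_q(noiseless)
  expect_equal(unname(fit$estimates["q"]), 0.233, tolerance = 1e-12)
  expect_gte(fit$r_squared, 0.999)

  set.seed(11)
  noisy <- tibble::tibble(
    ratio = seq(0.005, 0.1, length.out = 200),
    si = 0.233 * seq(0.005, 0.1, length.out = 200) * lnorm_noise(200, 0.05)
  )
  fit_noisy <- fit_q(noisy)
  expect_equal(unname(fit_noisy$estimates["q"]), 0.233, tolerance = 0.02)

  expect_error(fit_q(tibble::tibble(ratio = 0.01, si = 0.002)),
               "at least 2")
  expect_error(fit_q(tibble::tibble(ratio = c(0, 0), si = c(0, 0))),
               "positive")
})

test_that("logistic family fit recovers the published set from noiseless data", {
  data <- make_slope_family_data()
  fit <- fit_logistic_family(data)
  truth <- published_truth[c("a0", "a1", "b0", "b1")]
  expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-3)
  rel_err <- abs(fit$estimates[names(truth)] - truth) / abs(truth)
  expect_true(all(rel_err < 1e-3))
  expect_gte(fit$r_squared, 0.999)
  # with p free the same optimum is found
  fit_free <- fit_logistic_family(data, fix_p = NULL)
  expect_equal(unname(fit_free$estimates["p"]), 0.300, tolerance = 1e-3)
  expect_error(
    fit_logistic_family(dplyr::filter(data, dose_mg_day == 4)),
    "2 dose levels"
  )
  expect_error(
    fit_logistic_family(dplyr::slice_head(data, n = 2, by = dose_mg_day)),
    "4 time points"
  )
})

test_that("quadratic family fit recovers the published set from noiseless data", {
  data <- make_quadratic_family_data()
  fit <- fit_quadratic_family(data)
  truth <- published_truth[c("c0", "c1", "s0", "s1")]
  rel_err <- abs(fit$estimates[names(truth)] - truth) / abs(truth)
  expect_true(all(rel_err < 1e-3))
  expect_gte(fit$r_squared, 0.999)
  expect_error(
    fit_quadratic_family(dplyr::filter(data, dose_mg_day == 4)),
    "2 dose levels"
  )
  degenerate <- dplyr::mutate(data, dsi_dt = 0, dinr_dt = 0)
  expect_error(fit_quadratic_family(degenerate), "unidentifiable")
})

test_that("noisy fits stay within 3 reported standard errors of truth", {
  slope_data <- make_slope_family_data()
  quad_data <- make_quadratic_family_data()
  set.seed(101)
  ok_logistic <- ok_quadratic <- matrix(NA, nrow = 25, ncol = 4)
  for (r in 1:25) {
    noisy_s <- dplyr::mutate(
      slope_data, dsi_dt = dsi_dt * lnorm_noise(dplyr::n(), 0.05)
    )
    f1 <- fit_logistic_family(noisy_s, weighting = "proportional")
    truth1 <- published_truth[c("a0", "a1", "b0", "b1")]
    ok_logistic[r, ] <- abs(f1$estimates[names(truth1)] - truth1) <=
      3 * f1$se[names(truth1)]
    noisy_q <- dplyr::mutate(
      quad_data, dinr_dt = dinr_dt * lnorm_noise(dplyr::n(), 0.05)
    )
    f2 <- fit_quadratic_family(noisy_q, weighting = "proportional")
    truth2 <- published_truth[c("c0", "c1", "s0", "s1")]
    ok_quadratic[r, ] <- abs(f2$estimates[names(truth2)] - truth2) <=
      3 * f2$se[names(truth2)]
  }
  expect_gte(min(colMeans(ok_logistic)), 0.9)
  expect_gte(min(colMeans(ok_quadratic)), 0.9)
})

test_that("fits are invariant to row order", {
  data <- make_slope_family_data()
  set.seed(3)
  shuffled <- data[sample(nrow(data)), ]
  f1 <- fit_logistic_family(data)
  f2 <- fit_logistic_family(shuffled)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-10)
  qd <- make_quadratic_family_data()
  q1 <- fit_quadratic_family(qd)
  q2 <- fit_quadratic_family(qd[sample(nrow(qd)), ])
  expect_equal(q1$estimates, q2$estimates, tolerance = 1e-10)
})

test_that("per-dose diagnostic fits track the dose-dependency of h and g", {
  data <- make_slope_family_data()
  per_dose <- fit_logistic_per_dose(data)
  expect_equal(nrow(per_dose), 5L)
  expect_equal(per_dose$h, 0.000392 + 0.00108 * per_dose$dose_mg_day,
               tolerance = 1e-4)
  expect_equal(per_dose$g, -1.48 + 4.13 * log(per_dose$dose_mg_day),
               tolerance = 1e-3)
})

test_that("tidy and glance summarise fit objects", {
  fit <- fit_logistic_family(make_slope_family_data())
  td <- tidy(fit)
  expect_identical(td$term, c("a0", "a1", "b0", "b1"))
  expect_true(all(td$rse_pct >= 0))
  gl <- glance(fit)
  expect_lte(gl$adj.r.squared, 1)
  expect_identical(gl$n_par, 4L)
})
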
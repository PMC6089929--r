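# Synthetic-patient generator. Factor VII and INR trajectories are
# constructed to be exactly consistent with the empirical system: the
# sensitivity index evolves by the dose-dependent logistic slope, factor
# VII declines mono-exponentially (6 h half-life) to a dose-dependent
# plateau, and INR is back-solved from the proportional SI approximation,
# so that noiseless output satisfies INR * q / VII = SI identically.

#' Define a synthetic warfarin patient
#'
#' @param dref_true True reference dose driving the sensitivity-index
#'   dynamics, mg/day.
#' @param dose_given Daily dose the patient actually takes, mg/day
#'   (defaults to `dref_true`, i.e. a typical patient).
#' @param inr0 Baseline INR.
#' @param vii_half_life Factor VII degradation half-life, days (default
#'   0.25 d = 6 h, the fastest of the vitamin K-dependent factors).
#' @param vii_ss_frac Steady-state factor VII as a fraction of baseline.
#'   Default is a saturating dose-response
#'   `1 - emax * d / (d + d50)` evaluated at `dose_given`.
#' @param vii_emax,vii_d50 Maximum fractional suppression and half-maximal
#'   dose (mg/day) of the default dose-response.
#' @param noise_cv_inr,noise_cv_vii Proportional (log-normal) noise
#'   coefficients of variation; 0 disables noise.
#' @param seed Random seed used whenever noise is applied.
#' @return An object of class `synthetic_patient`.
#' @examples
#' synthetic_patient(dref_true = 4)
#' @export
synthetic_patient <- function(dref_true,
                              dose_given = dref_true,
                              inr0 = 1.0,
                              vii_half_life = 0.25,
                              vii_ss_frac = NULL,
                              vii_emax = 0.5,
                              vii_d50 = 6,
                              noise_cv_inr = 0,
                              noise_cv_vii = 0,
                              seed = 1L) {
  if (!is.numeric(dref_true) || dref_true <= 0) {
    stop("`dref_true` must be positive", call. = FALSE)
  }
  if (dose_given <= 0 || inr0 <= 0 || vii_half_life <= 0) {
    stop("`dose_given`, `inr0` and `vii_half_life` must be positive",
         call. = FALSE)
  }
  if (is.null(vii_ss_frac)) {
    vii_ss_frac <- 1 - vii_emax * dose_given / (dose_given + vii_d50)
  }
  if (vii_ss_frac <= 0 || vii_ss_frac > 1) {
    stop("`vii_ss_frac` must be in (0, 1]", call. = FALSE)
  }
  if (noise_cv_inr < 0 || noise_cv_vii < 0) {
    stop("noise CVs must be non-negative", call. = FALSE)
  }
  structure(
    list(
      dref_true = dref_true, dose_given = dose_given, inr0 = inr0,
      vii_half_life = vii_half_life, vii_ss_frac = vii_ss_frac,
      noise_cv_inr = noise_cv_inr, noise_cv_vii = noise_cv_vii,
      seed = as.integer(seed)
    ),
    class = "synthetic_patient"
  )
}

#' @export
print.synthetic_patient <- function(x, ...) {
  cat(sprintf(
    "<synthetic_patient> dref_true = %g, dose = %g mg/day, inr0 = %g,\n  VII: t1/2 = %g d, plateau = %.3g of baseline; noise CV (INR, VII) = (%g, %g); seed %d\n",
    x$dref_true, x$dose_given, x$inr0, x$vii_half_life, x$vii_ss_frac,
    x$noise_cv_inr, x$noise_cv_vii, x$seed
  ))
  invisible(x)
}

#' Simulate a factor VII / INR time course
#'
#' The deterministic construction is:
#' `VII(t) = 100 * (f_ss + (1 - f_ss) * 2^(-t / half_life))`,
#' `SI(t) = q * inr0 / 100 + integral_slope(0, t)` at the true reference
#' dose, and `INR(t) = SI(t) * VII(t) / q`. Optional proportional
#' log-normal noise is applied last, under the patient's seed, so the same
#' seed always yields identical output.
#'
#' @param patient A [synthetic_patient()].
#' @param times Strictly increasing sampling grid, days, all > 0.
#' @inheritParams approx_si
#' @return A tibble with columns `dose_mg_day`, `time_days`, `inr`,
#'   `factor_vii_pct` (and attribute `"truth"` holding the patient).
#' @examples
#' pt <- synthetic_patient(dref_true = 4)
#' simulate_time_course(pt, times = seq(0.5, 20, by = 0.5))
#' @export
simulate_time_course <- function(patient, times,
                                 params = published_parameters()) {
  stopifnot(inherits(patient, "synthetic_patient"))
  params <- as_inr_params(params)
  if (any(!is.finite(times)) || any(times <= 0)) {
    stop("`times` must be positive and finite", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  model <- logistic_slope(patient$dref_true, params)
  vii <- 100 * (patient$vii_ss_frac +
                  (1 - patient$vii_ss_frac) *
                  exp(-log(2) * times / patient$vii_half_life))
  si <- params$q * patient$inr0 / 100 +
    vapply(times, function(t) integral_slope(0, t, model), numeric(1))
  inr <- si * vii / params$q

  if (patient$noise_cv_inr > 0 || patient$noise_cv_vii > 0) {
    noisy <- withr::with_seed(patient$seed, {
      list(
        inr = inr * rlnorm_cv(length(inr), patient$noise_cv_inr),
        vii = vii * rlnorm_cv(length(vii), patient$noise_cv_vii)
      )
    })
    inr <- noisy$inr
    vii <- noisy$vii
  }

  out <- tibble::tibble(
    dose_mg_day = patient$dose_given,
    time_days = times,
    inr = inr,
    factor_vii_pct = vii
  )
  attr(out, "truth") <- patient
  out
}

# log-normal multiplicative noise with the given CV and unit mean
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a pair of timed samples for the prediction workflow
#'
#' @param patient A [synthetic_patient()].
#' @param t1,t2 Sample times, days (defaults: day 3 and day 4, after
#'   factor VII has equilibrated).
#' @inheritParams approx_si
#' @return A list of class `sample_set` with `samples` (a two-row tibble
#'   with `patient_id`, `time_days`, `inr`, `factor_vii_pct`) and `truth`
#'   (the patient, with an `early_sampling` flag when `t1` is below the
#'   equilibration threshold).
#' @examples
#' make_paired_samples(synthetic_patient(5))
#' @export
make_paired_samples <- function(patient, t1 = 3, t2 = 4,
                                params = published_parameters()) {
  stopifnot(inherits(patient, "synthetic_patient"))
  params <- as_inr_params(params)
  if (t2 <= t1 || t1 <= 0) {
    stop("require 0 < t1 < t2", call. = FALSE)
  }
  truth <- patient
  truth$early_sampling <- t1 < params$vii_equilibration_days
  if (truth$early_sampling) {
    warning(sprintf(
      "t1 = %.3g days is before factor VII equilibration (%g days); samples flagged",
      t1, params$vii_equilibration_days
    ), call. = FALSE)
  }
  tc <- simulate_time_course(patient, times = c(t1, t2), params = params)
  samples <- tibble::tibble(
    patient_id = sprintf("synthetic-dref-%g", patient$dref_true),
    time_days = tc$time_days,
    inr = tc$inr,
    factor_vii_pct = tc$factor_vii_pct
  )
  structure(list(samples = samples, truth = truth), class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set>\n")
  print(x$samples)
  invisible(x)
}

#' Write a deterministic suite of CSV fixtures
#'
#' Writes per-dose time courses (for calibration round trips) and paired
#' day-3/day-4 sample files (for prediction round trips) at reference
#' doses 1, 4, 7, 10 and 13 mg/day, plus a JSON manifest recording the
#' generating truths. Output is byte-identical across runs for a fixed
#' seed.
#'
#' @param out_dir Writable output directory (created if absent).
#' @inheritParams approx_si
#' @param doses Reference doses, mg/day.
#' @param times Time grid for the time-course files, days.
#' @param seed Seed recorded in the truths (files are noiseless).
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_fixture_suite <- function(out_dir, params = published_parameters(),
                               doses = c(1, 4, 7, 10, 13),
                               times = seq(0.5, 30, by = 0.1),
                               seed = 1L) {
  params <- as_inr_params(params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  entries <- lapply(doses, function(d) {
    pt <- synthetic_patient(dref_true = d, seed = seed)
    tc <- simulate_time_course(pt, times, params)
    tc_file <- sprintf("time_course_dose_%g.csv", d)
    readr::write_csv(tc, file.path(out_dir, tc_file))
    ss <- suppressWarnings(make_paired_samples(pt, params = params))
    pair_file <- sprintf("paired_samples_dose_%g.csv", d)
    readr::write_csv(ss$samples, file.path(out_dir, pair_file))
    list(
      dref_true = d,
      time_course = tc_file,
      paired_samples = pair_file,
      truth = unclass(ss$truth)
    )
  })
  manifest <- list(seed = as.integer(seed), doses = doses, files = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
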
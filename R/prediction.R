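# The 4-step predictor: paired samples -> SI slope -> reference dose ->
# time to steady-state INR -> steady-state INR.

#' Sensitivity-index slope from two timed, paired samples
#'
#' Converts each (INR, factor VII) pair to a sensitivity index via
#' [approx_si()] and returns the finite-difference slope
#' `(SI(t2) - SI(t1)) / (t2 - t1)`. The proportional approximation does not
#' hold during the first days of therapy, while factor VII is still
#' equilibrating; samples earlier than
#' `params$vii_equilibration_days` are rejected.
#'
#' @param samples A data frame with exactly two rows and columns
#'   `time_days`, `inr`, `factor_vii_pct` (extra columns are ignored).
#'   Rows need not be ordered.
#' @inheritParams approx_si
#' @param enforce_equilibration Reject samples taken before factor VII has
#'   equilibrated (default `TRUE`; disable only for negative-path testing).
#' @return A one-row tibble with `t1`, `t2`, `si_t1`, `si_t2` and `slope`
#'   (per day).
#' @examples
#' samples <- tibble::tibble(
#'   time_days = c(3, 4), inr = c(1.8, 2.2), factor_vii_pct = c(40, 32)
#' )
#' slope_from_pair(samples)
#' @export
slope_from_pair <- function(samples, params = published_parameters(),
                            enforce_equilibration = TRUE) {
  params <- as_inr_params(params)
  samples <- check_sample_frame(samples, n_required = 2L)
  samples <- samples[order(samples$time_days), , drop = FALSE]
  t1 <- samples$time_days[1]
  t2 <- samples$time_days[2]
  if (t2 <= t1) {
    stop("the two samples must have distinct times (t2 > t1)", call. = FALSE)
  }
  if (enforce_equilibration && t1 < params$vii_equilibration_days) {
    stop(sprintf(
      paste0("samples at %.3g and %.3g days: the factor VII steady-state ",
             "approximation requires both samples at >= %.3g days after ",
             "the dose change"),
      t1, t2, params$vii_equilibration_days
    ), call. = FALSE)
  }
  si <- approx_si(samples$inr, samples$vii_pct, params)
  tibble::tibble(
    t1 = t1, t2 = t2,
    si_t1 = si[1], si_t2 = si[2],
    slope = (si[2] - si[1]) / (t2 - t1)
  )
}

# Accepts `factor_vii_pct` (canonical) or `vii` column; returns a frame with
# time_days, inr, vii_pct.
check_sample_frame <- function(samples, n_required = NULL) {
  if (!is.data.frame(samples)) {
    stop("`samples` must be a data frame", call. = FALSE)
  }
  nm <- names(samples)
  vii_col <- if ("factor_vii_pct" %in% nm) "factor_vii_pct"
             else if ("vii" %in% nm) "vii"
             else NA_character_
  missing_cols <- setdiff(c("time_days", "inr"), nm)
  if (length(missing_cols) || is.na(vii_col)) {
    stop("`samples` needs columns time_days, inr, factor_vii_pct",
         call. = FALSE)
  }
  if (!is.null(n_required) && nrow(samples) != n_required) {
    stop("`samples` must contain exactly ", n_required,
         " rows (one pair of timed measurements)", call. = FALSE)
  }
  out <- data.frame(
    time_days = as.numeric(samples$time_days),
    inr = as.numeric(samples$inr),
    vii_pct = as.numeric(samples[[vii_col]])
  )
  if (any(!is.finite(out$time_days)) || any(out$time_days <= 0)) {
    stop("sample times must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(out$inr)) || any(out$inr <= 0) ||
      any(!is.finite(out$vii_pct)) || any(out$vii_pct <= 0)) {
    stop("INR and factor VII must be positive and finite", call. = FALSE)
  }
  out
}

#' Invert the logistic family for the individualised reference dose
#'
#' Finds the reference dose whose logistic slope model reproduces the
#' observed sensitivity-index slope over the sampling window. By default
#' the observed finite-difference slope is equated to the *interval mean*
#' of the logistic over `[t1, t2]`
#' (`integral_slope(t1, t2) / (t2 - t1)`), which makes the noiseless
#' forward-then-invert round trip exact; the midpoint variant (logistic
#' evaluated at `(t1 + t2) / 2`) is available via `mode`.
#'
#' The root is isolated by bisection-style bracketing ([stats::uniroot()])
#' on a fixed dose bracket; the interval-mean slope is strictly increasing
#' in the reference dose over the bracket for sampling windows within the
#' model's validity region, so the root is unique.
#'
#' @param slope Observed sensitivity-index slope, per day, > 0.
#' @param t1,t2 Sample times, days, `t2 > t1 >=` the equilibration
#'   threshold.
#' @inheritParams approx_si
#' @param mode `"interval-mean"` (default) or `"midpoint"`.
#' @param bracket Dose bracket (mg/day) searched for the root.
#' @return The reference dose (mg/day). A warning is signalled when the
#'   result lies outside `params$dref_support`.
#' @export
invert_dref <- function(slope, t1, t2, params = published_parameters(),
                        mode = c("interval-mean", "midpoint"),
                        bracket = c(0.01, 50)) {
  params <- as_inr_params(params)
  mode <- match.arg(mode)
  if (!is.numeric(slope) || length(slope) != 1L || !is.finite(slope)) {
    stop("`slope` must be a single finite number", call. = FALSE)
  }
  if (slope <= 0) {
    stop("non-increasing sensitivity index (slope <= 0): the patient is ",
         "already at or beyond steady state, or the measurements are ",
         "invalid; no reference dose exists", call. = FALSE)
  }
  if (t2 <= t1 || t1 < params$vii_equilibration_days) {
    stop("require t2 > t1 >= ", params$vii_equilibration_days,
         " days", call. = FALSE)
  }
  predicted <- function(dref) {
    model <- logistic_slope(dref, params)
    if (mode == "interval-mean") {
      integral_slope(t1, t2, model) / (t2 - t1)
    } else {
      logistic_slope_at((t1 + t2) / 2, model)
    }
  }
  f <- function(dref) predicted(dref) - slope
  f_lo <- f(bracket[1])
  f_hi <- f(bracket[2])
  if (sign(f_lo) == sign(f_hi)) {
    stop(sprintf(
      paste0("no reference dose in [%g, %g] mg/day reproduces the observed ",
             "slope %.4g /day (window %.3g-%.3g days)"),
      bracket[1], bracket[2], slope, t1, t2
    ), call. = FALSE)
  }
  dref <- stats::uniroot(f, interval = bracket, tol = 1e-10,
                         f.lower = f_lo, f.upper = f_hi)$root
  if (dref < params$dref_support[1] || dref > params$dref_support[2]) {
    warning(sprintf(
      "reference dose %.3g mg/day is outside the supported range [%g, %g]: extrapolation",
      dref, params$dref_support[1], params$dref_support[2]
    ), call. = FALSE)
  }
  dref
}

#' Time to steady-state INR
#'
#' The steady-state INR is declared once the sensitivity-index slope falls
#' to the tolerance `eps_si`; with the logistic slope model this has the
#' closed form `t = g(dref) + (1/p) * log(h(dref)/eps_si - 1)`, clamped at
#' zero when the tolerance is already met at the start.
#'
#' @param dref Reference dose(s), mg/day, > 0 (vectorised).
#' @inheritParams approx_si
#' @return Time(s) to steady-state INR, days, >= 0.
#' @examples
#' time_to_steady_state(c(3.97, 9.90))
#' @export
time_to_steady_state <- function(dref, params = published_parameters()) {
  params <- as_inr_params(params)
  if (any(!is.finite(dref)) || any(dref <= 0)) {
    stop("`dref` must be positive and finite", call. = FALSE)
  }
  h <- params$a0 + params$a1 * dref
  g <- params$b0 + params$b1 * log(dref)
  ratio <- h / params$eps_si - 1
  t_ss <- ifelse(ratio <= 0, 0, g + log(pmax(ratio, .Machine$double.xmin)) / params$p)
  pmax(t_ss, 0)
}

#' Steady-state INR
#'
#' Baseline INR plus the integrated quadratic rate map of the logistic
#' sensitivity-index slope up to the time of steady state:
#' `INR_ss = INR_0 + k(dref) * \int slope^2 dt + m(dref) * \int slope dt`,
#' with both integrals in closed form over `[0, t_ss]`.
#'
#' @param dref Reference dose(s), mg/day, > 0 (vectorised).
#' @param inr0 Baseline INR (defaults to `params$inr0_default`). The
#'   predicted rise `INR_ss - inr0` does not depend on `inr0`.
#' @inheritParams approx_si
#' @return Predicted steady-state INR(s). A warning is signalled when a
#'   prediction falls outside `params$inr_support`.
#' @examples
#' steady_state_inr(c(3.97, 13.3))
#' @export
steady_state_inr <- function(dref, inr0 = NULL,
                             params = published_parameters()) {
  params <- as_inr_params(params)
  if (is.null(inr0)) inr0 <- params$inr0_default
  if (any(!is.finite(dref)) || any(dref <= 0)) {
    stop("`dref` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(inr0)) || any(inr0 <= 0)) {
    stop("`inr0` must be positive and finite", call. = FALSE)
  }
  out <- vapply(seq_along(dref), function(i) {
    d <- dref[i]
    model <- logistic_slope(d, params)
    map <- quadratic_map(d, params)
    t_ss <- time_to_steady_state(d, params)
    map$k * integral_slope_squared(0, t_ss, model) +
      map$m * integral_slope(0, t_ss, model)
  }, numeric(1))
  inr_ss <- inr0 + out
  outside <- inr_ss < params$inr_support[1] | inr_ss > params$inr_support[2]
  if (any(outside)) {
    warning(sprintf(
      "%d prediction(s) outside the supported INR range [%g, %g]: extrapolation",
      sum(outside), params$inr_support[1], params$inr_support[2]
    ), call. = FALSE)
  }
  inr_ss
}

#' Predict time to steady-state INR and steady-state INR from paired samples
#'
#' Runs the full 4-step workflow per patient: (1) sensitivity indices from
#' the two paired (INR, factor VII) measurements, (2) finite-difference
#' slope, (3) inversion of the dose-dependent logistic family for the
#' individualised reference dose, (4) closed-form time to steady-state INR
#' and steady-state INR.
#'
#' @param samples A data frame with columns `time_days`, `inr`,
#'   `factor_vii_pct` and optionally `patient_id`; exactly two rows per
#'   patient. Multiple dose rates per patient are not supported: all rows
#'   for a patient must refer to the same (most recent) dose change.
#' @param dose The given daily dose, mg/day; either a single value or one
#'   per patient (named by `patient_id` or in patient order).
#' @param inr0 Baseline INR (default `params$inr0_default`); single value
#'   or one per patient.
#' @inheritParams approx_si
#' @inheritParams invert_dref
#' @return A tibble of class `inr_prediction`, one row per patient, with
#'   columns `patient_id`, `si_t1`, `si_t2`, `slope` (per day), `dref`
#'   (mg/day), `sensitivity_ratio` (`dref/dose`), `t_ss_inr` (days),
#'   `inr_ss`, and `warnings` (list column of guard-rail flags; empty when
#'   the prediction is inside the model's validity region).
#' @examples
#' pt <- synthetic_patient(dref_true = 5, dose_given = 5)
#' samples <- make_paired_samples(pt)$samples
#' predict_steady_state(samples, dose = 5)
#' @export
predict_steady_state <- function(samples, dose, inr0 = NULL,
                                 params = published_parameters(),
                                 mode = c("interval-mean", "midpoint")) {
  params <- as_inr_params(params)
  mode <- match.arg(mode)
  if (is.null(inr0)) inr0 <- params$inr0_default
  if (!is.data.frame(samples)) {
    stop("`samples` must be a data frame", call. = FALSE)
  }
  if (!"patient_id" %in% names(samples)) samples$patient_id <- "patient"
  ids <- unique(samples$patient_id)
  dose <- recycle_per_patient(dose, ids, "dose")
  inr0 <- recycle_per_patient(inr0, ids, "inr0")
  if (any(!is.finite(dose)) || any(dose <= 0)) {
    stop("`dose` must be positive and finite", call. = FALSE)
  }

  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    one <- samples[samples$patient_id == id, , drop = FALSE]
    warns <- character()
    pair <- withCallingHandlers(
      slope_from_pair(one, params),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    dref <- withCallingHandlers(
      tryCatch(
        invert_dref(pair$slope, pair$t1, pair$t2, params, mode = mode),
        error = function(e) {
          stop("patient ", id, " [reference-dose inversion]: ",
               conditionMessage(e), call. = FALSE)
        }
      ),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    t_ss <- time_to_steady_state(dref, params)
    inr_ss <- withCallingHandlers(
      steady_state_inr(dref, inr0[i], params),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
    tibble::tibble(
      patient_id = id,
      si_t1 = pair$si_t1, si_t2 = pair$si_t2, slope = pair$slope,
      dref = dref,
      sensitivity_ratio = dref / dose[i],
      t_ss_inr = t_ss, inr_ss = inr_ss,
      warnings = list(warns)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("inr_prediction", class(out))
  attr(out, "params") <- params
  attr(out, "mode") <- mode
  out
}

recycle_per_patient <- function(x, ids, what) {
  n <- length(ids)
  if (!is.null(names(x))) {
    missing_ids <- setdiff(ids, names(x))
    if (length(missing_ids)) {
      stop("`", what, "` is named but misses patient(s): ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    }
    return(as.numeric(x[ids]))
  }
  if (length(x) == 1L) return(rep(as.numeric(x), n))
  if (length(x) == n) return(as.numeric(x))
  stop("`", what, "` must have length 1 or one value per patient",
       call. = FALSE)
}

#' Daily dose required for a target steady-state INR
#'
#' Inverts the steady-state INR prediction for dose: finds the daily dose
#' `D` such that `steady_state_inr(sensitivity_ratio * D, inr0)` equals the
#' target, where `sensitivity_ratio = dref / dose` is the patient's
#' individual sensitivity from a previous [predict_steady_state()] run
#' (1 for a typical patient). The search is restricted to reference doses
#' within the supported range.
#'
#' @param target_inr Desired steady-state INR, must exceed `inr0`.
#' @param sensitivity_ratio Individual sensitivity `dref / dose`, > 0.
#' @inheritParams steady_state_inr
#' @return Daily dose, mg/day; monotone increasing in `target_inr`.
#' @examples
#' dose_for_target_inr(2.5)
#' @export
dose_for_target_inr <- function(target_inr, sensitivity_ratio = 1,
                                inr0 = NULL,
                                params = published_parameters()) {
  params <- as_inr_params(params)
  if (is.null(inr0)) inr0 <- params$inr0_default
  stopifnot(length(target_inr) == 1L, length(sensitivity_ratio) == 1L)
  if (!is.finite(sensitivity_ratio) || sensitivity_ratio <= 0) {
    stop("`sensitivity_ratio` must be positive", call. = FALSE)
  }
  if (!is.finite(target_inr) || target_inr <= inr0) {
    stop("`target_inr` must exceed the baseline INR", call. = FALSE)
  }
  lo <- params$dref_support[1]
  hi <- params$dref_support[2]
  f <- function(dref) {
    suppressWarnings(steady_state_inr(dref, inr0, params)) - target_inr
  }
  f_lo <- f(lo)
  f_hi <- f(hi)
  if (f_lo > 0 || f_hi < 0) {
    stop(sprintf(
      paste0("target INR %.3g is unreachable within the supported ",
             "reference-dose range [%g, %g] mg/day (achievable INR ",
             "%.3g-%.3g at baseline %.3g)"),
      target_inr, lo, hi, f_lo + target_inr, f_hi + target_inr, inr0
    ), call. = FALSE)
  }
  dref <- stats::uniroot(f, interval = c(lo, hi), tol = 1e-10,
                         f.lower = f_lo, f.upper = f_hi)$root
  dref / sensitivity_ratio
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.inr_prediction <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$n_warnings <- vapply(out$warnings, length, integer(1))
  out$warnings <- vapply(out$warnings, paste, character(1), collapse = "; ")
  out
}

#' @export
glance.inr_prediction <- function(x, ...) {
  tibble::tibble(
    n_patients = nrow(x),
    mode = attr(x, "mode"),
    median_dref = stats::median(x$dref),
    median_t_ss_inr = stats::median(x$t_ss_inr),
    median_inr_ss = stats::median(x$inr_ss),
    n_with_warnings = sum(vapply(x$warnings, length, integer(1)) > 0)
  )
}
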
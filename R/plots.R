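# ggplot2 visualisations of the empirical system and prediction results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the dose-dependent logistic slope family
#'
#' Sensitivity-index slope trajectories for a set of reference doses, with
#' the steady-state tolerance and the per-dose time to steady-state INR
#' marked.
#'
#' @param dref Reference doses, mg/day.
#' @param t_max Right edge of the time axis, days.
#' @inheritParams approx_si
#' @return A ggplot object.
#' @export
plot_slope_family <- function(dref = c(1, 4, 7, 10, 13), t_max = 30,
                              params = published_parameters()) {
  params <- as_inr_params(params)
  grid <- tidyr::expand_grid(
    dref = dref,
    time_days = seq(0, t_max, length.out = 300)
  ) |>
    dplyr::mutate(
      dsi_dt = purrr::map2_dbl(
        .data$time_days, .data$dref,
        ~ logistic_slope_at(.x, logistic_slope(.y, params))
      ),
      dose = factor(.data$dref)
    )
  marks <- tibble::tibble(
    dref = dref,
    t_ss = time_to_steady_state(dref, params),
    dose = factor(dref)
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$time_days, y = .data$dsi_dt,
                                     colour = .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = params$eps_si, linetype = "dashed") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$t_ss, colour = .data$dose),
      linetype = "dotted", show.legend = FALSE
    ) +
    ggplot2::labs(
      x = "time since dose change (days)",
      y = "sensitivity-index slope (/day)",
      colour = "reference dose\n(mg/day)",
      title = "Logistic decline of the sensitivity-index slope",
      subtitle = "dashed: steady-state tolerance; dotted: time to steady-state INR"
    ) +
    ggplot2::theme_minimal()
}

#' Plot predicted steady-state INR and time to steady state versus dose
#'
#' @param dref_range Reference-dose interval to sweep, mg/day.
#' @param inr0 Baseline INR.
#' @inheritParams approx_si
#' @return A ggplot object (two facets: days to steady state, INR).
#' @export
plot_dose_response <- function(dref_range = c(1, 13), inr0 = 1,
                               params = published_parameters()) {
  params <- as_inr_params(params)
  dref <- seq(dref_range[1], dref_range[2], length.out = 120)
  curve <- tibble::tibble(
    dref = dref,
    `time to steady-state INR (days)` = time_to_steady_state(dref, params),
    `steady-state INR` = suppressWarnings(
      steady_state_inr(dref, inr0, params)
    )
  ) |>
    tidyr::pivot_longer(-"dref", names_to = "quantity")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$dref, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "reference dose (mg/day)", y = NULL,
                  title = "Dose dependence of the steady-state predictions") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.inr_prediction <- function(object, ...) {
  params <- attr(object, "params")
  if (is.null(params)) params <- published_parameters()
  t_max <- max(object$t_ss_inr) * 1.15
  grid <- tidyr::expand_grid(
    patient_id = object$patient_id,
    time_days = seq(0, t_max, length.out = 300)
  ) |>
    dplyr::left_join(
      tibble::tibble(patient_id = object$patient_id, dref = object$dref),
      by = "patient_id"
    ) |>
    dplyr::mutate(
      dsi_dt = purrr::map2_dbl(
        .data$time_days, .data$dref,
        ~ logistic_slope_at(.x, logistic_slope(.y, params))
      )
    )
  marks <- tibble::tibble(
    patient_id = object$patient_id,
    t_ss = object$t_ss_inr
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$time_days, y = .data$dsi_dt,
                                     colour = .data$patient_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = params$eps_si, linetype = "dashed") +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$t_ss, colour = .data$patient_id),
      linetype = "dotted", show.legend = FALSE
    ) +
    ggplot2::labs(
      x = "time since dose change (days)",
      y = "sensitivity-index slope (/day)",
      colour = "patient",
      title = "Fitted sensitivity-index decline per patient",
      subtitle = "dotted lines: predicted time to steady-state INR"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.si_fit <- function(object, ...) {
  d <- tibble::tibble(fitted = object$fitted,
                      observed = object$fitted + object$residuals)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "fitted", y = "observed",
      title = object$method,
      subtitle = sprintf("n = %d, adj. r² = %.4f", object$n,
                         object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
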
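# CSV input/output for paired samples and calibration time courses.

SAMPLE_HEADER <- c("patient_id", "time_days", "inr", "factor_vii_pct")

#' Read timed, paired samples from CSV
#'
#' The file must have the exact header
#' `patient_id,time_days,inr,factor_vii_pct`, one row per measurement.
#' Rows are grouped by patient and sorted by time; units are validated
#' (factor VII in (0, 200] \% of baseline, INR in (0.5, 20], time >= 0).
#'
#' @param path Path to a CSV file.
#' @return A tibble with the four columns above, sorted by
#'   `(patient_id, time_days)`.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  header <- trimws(header)
  if (!identical(header, SAMPLE_HEADER)) {
    stop("line 1: header must be exactly `",
         paste(SAMPLE_HEADER, collapse = ","), "`, got `",
         paste(header, collapse = ","), "`", call. = FALSE)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      patient_id = readr::col_character(),
      time_days = readr::col_character(),
      inr = readr::col_character(),
      factor_vii_pct = readr::col_character()
    ),
    progress = FALSE
  )
  out <- raw
  for (col in c("time_days", "inr", "factor_vii_pct")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad)) {
      stop("line ", bad[1] + 1L, ": non-numeric value in column `", col,
           "`", call. = FALSE)
    }
    out[[col]] <- vals
  }
  dup <- duplicated(out[, c("patient_id", "time_days")])
  if (any(dup)) {
    stop("line ", which(dup)[1] + 1L,
         ": duplicate (patient_id, time_days) row", call. = FALSE)
  }
  check_units <- function(col, lo, hi, lo_open = TRUE) {
    v <- out[[col]]
    bad <- if (lo_open) which(v <= lo | v > hi) else which(v < lo | v > hi)
    if (length(bad)) {
      stop("line ", bad[1] + 1L, ": `", col, "` = ", v[bad[1]],
           " outside the plausible range (", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  check_units("factor_vii_pct", 0, 200)
  check_units("inr", 0.5, 20)
  if (any(out$time_days < 0)) {
    bad <- which(out$time_days < 0)[1]
    stop("line ", bad + 1L, ": negative `time_days`", call. = FALSE)
  }
  out |>
    dplyr::arrange(.data$patient_id, .data$time_days)
}

#' @rdname read_samples
#' @param samples A data frame with columns
#'   `patient_id,time_days,inr,factor_vii_pct`.
#' @export
write_samples <- function(samples, path) {
  stopifnot(is.data.frame(samples))
  if (!all(SAMPLE_HEADER %in% names(samples))) {
    stop("`samples` needs columns ", paste(SAMPLE_HEADER, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(samples[, SAMPLE_HEADER], path)
  invisible(path)
}

#' Read calibration time courses from CSV
#'
#' Expects the header `dose_mg_day,time_days,inr,factor_vii_pct`; one
#' dose level per `dose_mg_day` value, times strictly increasing within a
#' dose.
#'
#' @param path Path to a CSV file.
#' @return A tibble sorted by `(dose_mg_day, time_days)`.
#' @export
read_time_courses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  need <- c("dose_mg_day", "time_days", "inr", "factor_vii_pct")
  tc <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                        progress = FALSE)
  if (!all(need %in% names(tc))) {
    stop("header must contain `", paste(need, collapse = ","), "`",
         call. = FALSE)
  }
  if (any(!is.finite(as.matrix(tc[need])))) {
    stop("non-numeric or missing values in time-course file", call. = FALSE)
  }
  tc |>
    dplyr::arrange(.data$dose_mg_day, .data$time_days)
}

#' Serialise a prediction report to JSON
#'
#' Writes one record per patient mirroring the columns of
#' [predict_steady_state()] output (full precision), plus display-rounded
#' copies (`t_ss_inr_display` to 0.1 day, `inr_ss_display` to 0.01) and a
#' `schema_version` field.
#'
#' @param prediction An `inr_prediction` tibble.
#' @param path Output path, or `NULL` to return the JSON string.
#' @export
write_prediction_report <- function(prediction, path = NULL) {
  stopifnot(inherits(prediction, "inr_prediction"))
  records <- lapply(seq_len(nrow(prediction)), function(i) {
    row <- prediction[i, ]
    list(
      patient_id = row$patient_id,
      si_t1 = row$si_t1,
      si_t2 = row$si_t2,
      slope_per_day = row$slope,
      dref_mg_day = row$dref,
      sensitivity_ratio = row$sensitivity_ratio,
      t_ss_inr_days = row$t_ss_inr,
      inr_ss = row$inr_ss,
      t_ss_inr_display = round(row$t_ss_inr, 1),
      inr_ss_display = round(row$inr_ss, 2),
      warnings = I(row$warnings[[1]])
    )
  })
  report <- list(schema_version = "1.0", patients = records)
  if (is.null(path)) {
    return(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE))
  }
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
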
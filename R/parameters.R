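#' Published parameters of the empirical INR steady-state system
#'
#' Constructs the immutable set of constants behind the prediction
#' algorithm: the proportionality constant of the sensitivity-index
#' approximation, the dose-dependent logistic model for the rate of change
#' of the sensitivity index, the dose-dependent quadratic map from that
#' rate to the rate of INR change, the steady-state tolerance, and the
#' validity bounds within which the system was developed.
#'
#' The defaults are the published estimates; any field can be overridden,
#' and overrides are validated against the model's invariants before use.
#'
#' @param q Proportionality constant of the sensitivity-index
#'   approximation `SI = q * INR / VII` (dimensionless).
#' @param p Shape parameter of the logistic slope model (per day).
#' @param a0,a1 Intercept (per \%/day) and dose slope (per \%/mg) of the
#'   logistic upper asymptote `h(D_ref) = a0 + a1 * D_ref`.
#' @param b0,b1 Intercept and log-dose slope (days) of the horizontal
#'   shift `g(D_ref) = b0 + b1 * log(D_ref)`.
#' @param c0,c1 Log-scale coefficients of the (negative) second-order
#'   quadratic coefficient `k(D_ref) = -exp(c0 + c1 * log(D_ref))`.
#' @param s0,s1 Log-scale coefficients of the first-order quadratic
#'   coefficient `m(D_ref) = exp(s0 + s1 * log(D_ref))`.
#' @param eps_si Steady-state tolerance on the sensitivity-index slope
#'   (per day); steady-state INR is declared once the slope falls to or
#'   below this value.
#' @param inr0_default Baseline INR assumed when none is measured.
#' @param vii_equilibration_days Minimum sample time (days after a dose
#'   change) for the factor VII steady-state approximation to hold.
#' @param dref_support Reference-dose interval (mg/day) over which the
#'   empirical system was developed; predictions outside it carry an
#'   extrapolation warning.
#' @param inr_support INR interval over which the system was developed.
#'
#' @return An object of class `inr_params`: a named list of validated,
#'   read-only constants.
#' @examples
#' params <- published_parameters()
#' params$q
#' published_parameters(eps_si = 2e-4)
#' @export
published_parameters <- function(q = 0.233,
                                 p = 0.300,
                                 a0 = 0.000392,
                                 a1 = 0.00108,
                                 b0 = -1.48,
                                 b1 = 4.13,
                                 c0 = 11.9,
                                 c1 = -2.05,
                                 s0 = 5.26,
                                 s1 = -0.672,
                                 eps_si = 0.000150,
                                 inr0_default = 1.0,
                                 vii_equilibration_days = 2.0,
                                 dref_support = c(1, 13),
                                 inr_support = c(1.4, 4.7)) {
  params <- list(
    q = q, p = p, a0 = a0, a1 = a1, b0 = b0, b1 = b1,
    c0 = c0, c1 = c1, s0 = s0, s1 = s1,
    eps_si = eps_si, inr0_default = inr0_default,
    vii_equilibration_days = vii_equilibration_days,
    dref_support = as.numeric(dref_support),
    inr_support = as.numeric(inr_support)
  )
  validate_params(params)
  structure(params, class = "inr_params")
}

validate_params <- function(params) {
  scalars <- setdiff(names(params), c("dref_support", "inr_support"))
  for (nm in scalars) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter `", nm, "` must be a single finite number",
           call. = FALSE)
    }
  }
  for (nm in c("dref_support", "inr_support")) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) ||
        v[1] >= v[2]) {
      stop("parameter `", nm, "` must be an increasing interval c(lo, hi)",
           call. = FALSE)
    }
  }
  stopifnot_param(params$q > 0, "q must be positive")
  stopifnot_param(params$p > 0, "p must be positive")
  stopifnot_param(params$a1 > 0, "a1 must be positive")
  stopifnot_param(params$b1 > 0, "b1 must be positive")
  stopifnot_param(params$eps_si > 0, "eps_si must be positive")
  stopifnot_param(params$inr0_default > 0, "inr0_default must be positive")
  stopifnot_param(params$vii_equilibration_days >= 0,
                  "vii_equilibration_days must be non-negative")
  stopifnot_param(params$dref_support[1] > 0,
                  "dref_support lower bound must be positive")
  invisible(params)
}

stopifnot_param <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}

#' @export
print.inr_params <- function(x, ...) {
  cat("<inr_params>\n")
  cat(sprintf("  SI approximation      q = %.4g\n", x$q))
  cat(sprintf("  logistic slope        p = %.4g /day, h = %.4g + %.4g*D_ref,\n",
              x$p, x$a0, x$a1))
  cat(sprintf("                        g = %.4g + %.4g*ln(D_ref) days\n",
              x$b0, x$b1))
  cat(sprintf("  quadratic map         k = -exp(%.4g %+.4g*ln(D_ref)), m = exp(%.4g %+.4g*ln(D_ref))\n",
              x$c0, x$c1, x$s0, x$s1))
  cat(sprintf("  steady-state tol      eps_si = %.4g /day\n", x$eps_si))
  cat(sprintf("  supported D_ref       [%g, %g] mg/day; INR [%g, %g]\n",
              x$dref_support[1], x$dref_support[2],
              x$inr_support[1], x$inr_support[2]))
  invisible(x)
}

#' Read or write a parameter set as a flat YAML or JSON mapping
#'
#' Parameter files are flat mappings with the exact field names of
#' [published_parameters()]; fields not present keep their published
#' defaults. Values read from file are validated before use.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param params An `inr_params` object (for writing).
#' @return `read_parameters()` returns an `inr_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(published_parameters))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(published_parameters, raw)
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path) {
  params <- as_inr_params(params)
  flat <- unclass(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(flat, path)
  }
  invisible(path)
}

as_inr_params <- function(params) {
  if (is.null(params)) return(published_parameters())
  if (inherits(params, "inr_params")) return(params)
  if (is.list(params)) return(do.call(published_parameters, params))
  stop("`params` must be an inr_params object or a named list", call. = FALSE)
}
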
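#' Hyaluronidase activity in turbidity reduction units
#'
#' One TRU is the amount of enzyme that reduces the turbidity of the
#' hyaluronic-acid reaction by 50\%; partial reductions are prorated
#' linearly (reduction\% / 50). Specific activity is TRU per mg of venom per
#' minute of incubation, so it scales exactly inversely with both mass and
#' time.
#'
#' @param a_control control (no-venom) absorbance, > 0.
#' @param a_sample sample absorbance after incubation.
#' @param venom_mass_mg venom amount in mg, > 0.
#' @param time_min incubation time in minutes, > 0.
#' @return list with \code{activity} (TRU mg^-1 min^-1),
#'   \code{reduction_percent}, \code{tru} and \code{negative_reduction}. A
#'   sample more turbid than the control yields a warning and activity 0.
#' @export
turbidity_reduction_units <- function(a_control, a_sample, venom_mass_mg,
                                      time_min) {
  if (a_control <= 0) {
    stop_venomcomp("control absorbance must be > 0",
                   "venomcomp_validation_error")
  }
  if (venom_mass_mg <= 0 || time_min <= 0) {
    stop_venomcomp("venom mass and incubation time must be > 0",
                   "venomcomp_validation_error")
  }
  reduction <- 100 * (a_control - a_sample) / a_control
  negative <- reduction < 0
  if (negative) {
    warning("sample absorbance exceeds control: negative turbidity reduction, activity reported as 0")
    reduction <- 0
  }
  tru <- reduction / 50
  list(activity = tru / (venom_mass_mg * time_min),
       reduction_percent = reduction, tru = tru,
       negative_reduction = negative)
}

#' Fit a standard curve by ordinary least squares
#'
#' @param amount_nmol analyte amounts (nmol), at least 2 distinct values.
#' @param absorbance matching absorbance readings.
#' @return A \code{standard_curve} object with \code{slope},
#'   \code{intercept}, \code{residuals}, the amount \code{range}, and the
#'   underlying \code{lm} fit.
#' @export
fit_standard_curve <- function(amount_nmol, absorbance) {
  if (length(unique(amount_nmol)) < 2) {
    stop_venomcomp("standard curve needs >= 2 distinct amounts",
                   "venomcomp_validation_error")
  }
  fit <- stats::lm(absorbance ~ amount_nmol)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-12) {
    stop_venomcomp("unusable standard curve: zero slope",
                   "venomcomp_curve_error")
  }
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(stats::residuals(fit)),
                 range = range(amount_nmol), fit = fit),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: absorbance = %.6g + %.6g * nmol (range %g-%g nmol)\n",
              x$intercept, x$slope, x$range[1], x$range[2]))
  cat(sprintf("  residual SD: %.3g\n", stats::sd(x$residuals)))
  invisible(x)
}

#' Specific activity from a standard curve
#'
#' Inverts the fitted line to convert the sample absorbance into the amount
#' of substrate cleaved (nmol), then normalises by venom mass and
#' incubation time. Readings outside the calibrated amount range are
#' permitted (extrapolation) but flagged, as are negative inferred amounts.
#'
#' @param curve a [fit_standard_curve()] object.
#' @param a_sample sample absorbance.
#' @param venom_mass_mg venom amount in mg, > 0.
#' @param time_min incubation time in minutes, > 0.
#' @return list with \code{activity} (nmol mg^-1 min^-1), \code{nmol},
#'   \code{extrapolated} and \code{negative}.
#' @export
specific_activity_from_curve <- function(curve, a_sample, venom_mass_mg,
                                         time_min) {
  if (venom_mass_mg <= 0 || time_min <= 0) {
    stop_venomcomp("venom mass and incubation time must be > 0",
                   "venomcomp_validation_error")
  }
  nmol <- (a_sample - curve$intercept) / curve$slope
  list(activity = nmol / (venom_mass_mg * time_min),
       nmol = nmol,
       extrapolated = nmol < curve$range[1] || nmol > curve$range[2],
       negative = nmol < 0)
}

#' Relative haemolysis against a positive control
#'
#' The lysis positive control (e.g. 0.5\% Triton X) is treated as 100\%
#' activity; the blank as 0\%. The result is blank-corrected and not
#' clipped, so readings above the positive control exceed 100\%. Adding a
#' constant to all three absorbances leaves the percentage unchanged.
#'
#' @param a_sample sample absorbance.
#' @param a_blank blank (no-venom) absorbance; set \code{blank_correct =
#'   FALSE} to treat zero absorbance as 0\% instead.
#' @param a_positive positive-control absorbance, strictly above the blank.
#' @param blank_correct subtract the blank (default TRUE).
#' @return haemolysis percentage.
#' @export
relative_haemolysis <- function(a_sample, a_blank, a_positive,
                                blank_correct = TRUE) {
  if (!blank_correct) a_blank <- 0
  if (a_positive <= a_blank) {
    stop_venomcomp("invalid positive control: absorbance not above blank",
                   "venomcomp_validation_error")
  }
  100 * (a_sample - a_blank) / (a_positive - a_blank)
}

#' Clotting-time delay and fold change
#'
#' Compares a venom-treated plasma clotting time against the control plasma.
#' A censored result (no clot within the instrument's observation window)
#' reports the fold change as a lower bound at
#' \code{censoring_limit / control_time}.
#'
#' @param control_time control plasma clotting time in seconds, > 0.
#' @param venom_time venom-treated clotting time in seconds (for censored
#'   runs, the censoring limit).
#' @param censored whether no clot formed within the observation window.
#' @param censoring_limit the window length in seconds (defaults to
#'   \code{venom_time} when censored).
#' @return list with \code{delay_s}, \code{fold}, \code{censored} and
#'   \code{fold_is_lower_bound}.
#' @export
clotting_delay <- function(control_time, venom_time, censored = FALSE,
                           censoring_limit = if (censored) venom_time else Inf) {
  if (control_time <= 0) {
    stop_venomcomp("control clotting time must be > 0",
                   "venomcomp_validation_error")
  }
  if (censored) {
    if (venom_time < censoring_limit) {
      stop_venomcomp("censored result requires venom_time >= censoring_limit",
                     "venomcomp_validation_error")
    }
    return(list(delay_s = censoring_limit - control_time,
                fold = censoring_limit / control_time,
                censored = TRUE, fold_is_lower_bound = TRUE))
  }
  list(delay_s = venom_time - control_time,
       fold = venom_time / control_time,
       censored = FALSE, fold_is_lower_bound = FALSE)
}
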
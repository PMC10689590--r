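#' Simplified single-time-point estimators of the FDG net influx constant
#'
#' All four methods share one core: a two-point Patlak line through the
#' population intercept `(0, v_d)` and the single late point
#' `(theta_est, v_t_late)`, where the late apparent distribution volume
#' `v_t_late` comes from one averaged frame (52-67 min) and the methods
#' differ only in how they estimate the normalized arterial integral
#' `theta` without the full dynamic blood curve:
#'
#' * **Method 1** fits the terminal clearance \eqn{C e^{-\lambda_3 t}} to the
#'   late blood frames, integrates it analytically, and scales up by the
#'   population mean fraction of the total AUC carried by that term.
#' * **Method 2** predicts AUC(0-67) from the terminal arterial
#'   concentration via the site regression.
#' * **Method 3** predicts theta directly from the individual terminal
#'   clearance rate \eqn{\lambda_3} via the site regression.
#' * **Method 4** predicts theta from the subject's age via the site
#'   regression.
#'
#' @name simplified_methods
#' @return Each method returns a `method_result`: list with `method`,
#'   `region`, `ki` (mL/g/min), `theta_used` (min) and `inputs_used`
#'   (provenance list).
NULL

method_result <- function(method, ki, theta_used, region = "GM",
                          inputs_used = list()) {
  if (!is.finite(ki)) stop("ki must be finite", call. = FALSE)
  if (!is.finite(theta_used) || theta_used <= 0) {
    stop("theta_used must be positive", call. = FALSE)
  }
  structure(list(method = method, region = region, ki = ki,
                 theta_used = theta_used, inputs_used = inputs_used),
            class = "method_result")
}

#' @export
print.method_result <- function(x, ...) {
  cat(sprintf("method_result [%s, %s]: Ki=%.4g mL/g/min (theta=%.4g min)\n",
              x$method, x$region, x$ki, x$theta_used))
  invisible(x)
}

#' @describeIn simplified_methods Ki from the late blood curve via the
#'   terminal-clearance AUC and the population recovery fraction.
#' @param idif_late blood [tac()] covering at least the tail window (frames
#'   before the window are ignored).
#' @param ca_late terminal arterial concentration (mean over 52-67 min); if
#'   `NULL`, computed from `idif_late`.
#' @param v_t_late late apparent tissue distribution volume, mL/g (see
#'   [distribution_volume_late()]).
#' @param cal a [site_calibration()].
#' @param tail_window semi-log fitting window in minutes, default `c(35, 67)`.
#' @param t_appear_default start of the analytic tail integration, minutes
#'   (default 0.5, a typical appearance time when none is measured).
#' @param region tissue region label carried into the result.
#' @export
method1 <- function(idif_late, ca_late = NULL, v_t_late, cal,
                    tail_window = c(35, 67), t_appear_default = 0.5,
                    region = "GM") {
  stopifnot(inherits(cal, "site_calibration"))
  tail_fit <- fit_loglinear_tail(idif_late, tail_window)
  if (is.null(ca_late)) {
    idx <- frames_in_window(idif_late, 52, 67)
    if (length(idx) < 1L) stop("no frames in [52, 67] min", call. = FALSE)
    ca_late <- mean(idif_late$value[idx])
  }
  if (ca_late <= 0) stop("ca_late must be positive", call. = FALSE)
  auc_tail <- tail_fit$c_tail / tail_fit$lambda *
    (exp(-tail_fit$lambda * t_appear_default) - exp(-tail_fit$lambda * 67))
  auc_full_est <- auc_tail / cal$recovery_late
  theta_est <- auc_full_est / ca_late
  ki <- patlak_two_point(v_t_late, theta_est, cal$v_d)
  method_result("M1", ki, theta_est, region,
                inputs_used = list(c_tail = tail_fit$c_tail,
                                   lambda3 = tail_fit$lambda,
                                   ca_late = ca_late, v_t_late = v_t_late,
                                   recovery_late = cal$recovery_late,
                                   v_d = cal$v_d))
}

#' @describeIn simplified_methods Ki from the terminal arterial concentration
#'   alone, via the site AUC-vs-Ca regression.
#' @param units units string of `ca_late`'s concentration scale; when given,
#'   it must match the calibration's `units_note` (the regression intercept
#'   is bound to its source scale).
#' @export
method2 <- function(ca_late, v_t_late, cal, units = NULL, region = "GM") {
  stopifnot(inherits(cal, "site_calibration"))
  if (!is.finite(ca_late) || ca_late <= 0) stop("ca_late must be positive", call. = FALSE)
  if (!is.null(units) && !identical(units, cal$units_note)) {
    stop(sprintf(paste0("calibration units mismatch: auc_vs_ca is bound to '%s' ",
                        "but the data are in '%s'"),
                 cal$units_note, units), call. = FALSE)
  }
  auc_est <- cal$auc_vs_ca$slope * ca_late + cal$auc_vs_ca$intercept
  if (auc_est <= 0) {
    stop("calibration-domain error: predicted AUC is non-positive", call. = FALSE)
  }
  theta_est <- auc_est / ca_late
  ki <- patlak_two_point(v_t_late, theta_est, cal$v_d)
  method_result("M2", ki, theta_est, region,
                inputs_used = list(ca_late = ca_late, v_t_late = v_t_late,
                                   auc_est = auc_est, v_d = cal$v_d))
}

#' @describeIn simplified_methods Ki from the individual terminal clearance
#'   rate, via the site theta-vs-lambda3 regression.
#' @param lambda3 terminal clearance rate constant, 1/min.
#' @export
method3 <- function(lambda3, v_t_late, cal, region = "GM") {
  stopifnot(inherits(cal, "site_calibration"))
  if (!is.finite(lambda3) || lambda3 <= 0) stop("lambda3 must be positive", call. = FALSE)
  theta_est <- cal$theta_vs_lambda3$slope * lambda3 + cal$theta_vs_lambda3$intercept
  if (theta_est <= 0) {
    stop("calibration-domain error: predicted theta is non-positive", call. = FALSE)
  }
  ki <- patlak_two_point(v_t_late, theta_est, cal$v_d)
  method_result("M3", ki, theta_est, region,
                inputs_used = list(lambda3 = lambda3, v_t_late = v_t_late,
                                   v_d = cal$v_d))
}

#' @describeIn simplified_methods Ki from the subject's age, via the site
#'   theta-vs-age regression.
#' @param age subject age, years.
#' @export
method4 <- function(age, v_t_late, cal, region = "GM") {
  stopifnot(inherits(cal, "site_calibration"))
  if (!is.finite(age) || age <= 0) stop("age must be positive", call. = FALSE)
  theta_est <- cal$theta_vs_age$slope * age + cal$theta_vs_age$intercept
  if (theta_est <= 0) {
    stop("calibration-domain error: predicted theta is non-positive", call. = FALSE)
  }
  ki <- patlak_two_point(v_t_late, theta_est, cal$v_d)
  method_result("M4", ki, theta_est, region,
                inputs_used = list(age = age, v_t_late = v_t_late, v_d = cal$v_d))
}

#' Percentage error of a simplified Ki estimate
#'
#' `100 * (method - reference) / reference`, the signed error of a
#' simplified estimate relative to the full-input reference value.
#'
#' @param method_ki simplified estimate, mL/g/min.
#' @param reference_ki full-input reference, mL/g/min (non-zero).
#' @return Signed percent error.
#' @export
percent_error <- function(method_ki, reference_ki) {
  if (any(reference_ki == 0)) stop("reference_ki must be non-zero", call. = FALSE)
  100 * (method_ki - reference_ki) / reference_ki
}
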
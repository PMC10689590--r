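#' Site calibration for the simplified Ki estimators
#'
#' Bundles the population quantities that the four single-time-point methods
#' need: the population gray-matter Patlak intercept `v_d`, the fraction of
#' the total measured plasma integral carried by the terminal clearance term
#' (`recovery_late`, used by Method 1), and the four simple linear
#' population regressions (used by Methods 2-4 and by the simulator's
#' age model).
#'
#' @param site site name (free text; `"aarhus"` and `"bern"` ship as
#'   defaults, see [default_calibration()]).
#' @param v_d population ordinate intercept, mL/g.
#' @param recovery_late fraction in (0, 1) of the measured AUC(0-67)
#'   recovered by the terminal exponential term alone.
#' @param auc_vs_ca list `(slope, intercept)`: AUC(0-67) as a linear function
#'   of the terminal arterial concentration (slope in minutes, intercept in
#'   concentration-minutes on the scale named by `units_note`).
#' @param theta_vs_lambda3 list `(slope, intercept)`: normalized arterial
#'   integral (min) vs terminal clearance rate (1/min); slope in min^2.
#' @param theta_vs_age list `(slope, intercept)`: theta (min) vs age (years).
#' @param lambda3_vs_age list `(slope, intercept)`: terminal clearance rate
#'   (1/min) vs age (years).
#' @param units_note free text naming the concentration scale the
#'   `auc_vs_ca` coefficients are bound to; Method 2 refuses to run when this
#'   mismatches the units of the data it is given.
#' @param diagnostics optional list of per-regression fit diagnostics
#'   (`r`, `p`, `n`), as attached by [fit_site_calibration()].
#' @return An object of class `site_calibration`.
#' @export
site_calibration <- function(site, v_d, recovery_late, auc_vs_ca,
                             theta_vs_lambda3, theta_vs_age, lambda3_vs_age,
                             units_note = "arbitrary", diagnostics = NULL) {
  if (!is.finite(v_d) || v_d <= 0) stop("v_d must be positive", call. = FALSE)
  if (!is.finite(recovery_late) || recovery_late <= 0 || recovery_late >= 1) {
    stop("recovery_late must lie in (0, 1)", call. = FALSE)
  }
  as_line <- function(x, name) {
    if (is.null(x$slope) || is.null(x$intercept)) {
      stop(sprintf("%s must provide slope and intercept", name), call. = FALSE)
    }
    list(slope = as.numeric(x$slope), intercept = as.numeric(x$intercept))
  }
  cal <- structure(list(site = as.character(site), v_d = v_d,
                        recovery_late = recovery_late,
                        auc_vs_ca = as_line(auc_vs_ca, "auc_vs_ca"),
                        theta_vs_lambda3 = as_line(theta_vs_lambda3, "theta_vs_lambda3"),
                        theta_vs_age = as_line(theta_vs_age, "theta_vs_age"),
                        lambda3_vs_age = as_line(lambda3_vs_age, "lambda3_vs_age"),
                        units_note = as.character(units_note),
                        diagnostics = diagnostics),
                   class = "site_calibration")
  # theta predictions must stay positive over the plausible adult domain
  ages <- c(18, 95)
  l3s <- c(0.004, 0.02)
  th_age <- cal$theta_vs_age$slope * ages + cal$theta_vs_age$intercept
  th_l3 <- cal$theta_vs_lambda3$slope * l3s + cal$theta_vs_lambda3$intercept
  if (any(th_age <= 0) || any(th_l3 <= 0)) {
    stop("calibration predicts non-positive theta over the adult domain",
         call. = FALSE)
  }
  cal
}

#' @export
print.site_calibration <- function(x, ...) {
  cat(sprintf("site_calibration [%s]: v_d=%.3g mL/g, recovery_late=%.3f\n",
              x$site, x$v_d, x$recovery_late))
  line <- function(nm) sprintf("  %s: slope=%.6g, intercept=%.6g\n", nm,
                               x[[nm]]$slope, x[[nm]]$intercept)
  cat(line("auc_vs_ca"), line("theta_vs_lambda3"), line("theta_vs_age"),
      line("lambda3_vs_age"), sep = "")
  invisible(x)
}

#' Read / write a site calibration as JSON
#'
#' The JSON schema mirrors the [site_calibration()] fields:
#' `{site, v_d, recovery_late, auc_vs_ca:{slope,intercept}, ...,
#' units_note}`.
#'
#' @param path JSON file path.
#' @return `read_calibration()` returns a [site_calibration()];
#'   `write_calibration()` invisibly returns `path`.
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  site_calibration(site = j$site, v_d = j$v_d,
                   recovery_late = j$recovery_late,
                   auc_vs_ca = j$auc_vs_ca,
                   theta_vs_lambda3 = j$theta_vs_lambda3,
                   theta_vs_age = j$theta_vs_age,
                   lambda3_vs_age = j$lambda3_vs_age,
                   units_note = j$units_note %||% "arbitrary",
                   diagnostics = j$diagnostics)
}

#' @rdname read_calibration
#' @param cal a [site_calibration()].
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "site_calibration"))
  out <- unclass(cal)
  out$diagnostics <- cal$diagnostics
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Shipped default site calibrations
#'
#' Population calibrations for the two supported acquisition sites, loaded
#' from the versioned JSON files under `inst/extdata/`. The Aarhus
#' `auc_vs_ca` regression is bound to the raw (unnormalized) concentration
#' scale of its source data, as recorded in `units_note`.
#'
#' @param site `"aarhus"` or `"bern"` (case-insensitive).
#' @return A [site_calibration()].
#' @export
default_calibration <- function(site = c("aarhus", "bern")) {
  site <- match.arg(tolower(site), c("aarhus", "bern"))
  path <- system.file("extdata", sprintf("calibration_%s.json", site),
                      package = "fdgki", mustWork = TRUE)
  read_calibration(path)
}
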
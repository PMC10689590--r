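#' Per-subject pharmacokinetic parameter table for a cohort
#'
#' Runs the tri-exponential decomposition and the late-phase input metrics on
#' every subject's blood curve and collects the results into one data.frame,
#' the input to [fit_site_calibration()] and [correlation_matrix()].
#'
#' @param subjects list of `subject_record`s (see [subject_record()],
#'   [generate_cohort()]).
#' @param ... passed to [decompose_triexp()].
#' @return data.frame with one row per subject: `subject_id`, `age`, `A`,
#'   `lambda1`, `B`, `lambda2`, `C`, `lambda3`, `t_appear`, `auc_0_67`,
#'   `ca_52_67`, `theta_52_67`, `recovery_mono`, `recovery_bi`,
#'   `recovery_tri`.
#' @export
cohort_parameter_table <- function(subjects, ...) {
  rows <- lapply(subjects, function(s) {
    p <- decompose_triexp(s$idif, ...)
    m <- compute_input_metrics(s$idif, p)
    data.frame(subject_id = s$subject_id, age = s$age,
               A = p$A, lambda1 = p$lambda1, B = p$B, lambda2 = p$lambda2,
               C = p$C, lambda3 = p$lambda3, t_appear = p$t_appear,
               auc_0_67 = m$auc_0_67, ca_52_67 = m$ca_52_67,
               theta_52_67 = m$theta_52_67,
               recovery_mono = m$recovery_mono, recovery_bi = m$recovery_bi,
               recovery_tri = m$recovery_tri)
  })
  do.call(rbind, rows)
}

# simple one-predictor OLS with Pearson r and two-sided p (t-dist, n-2 df)
ols_line <- function(x, y, name) {
  n <- length(x)
  if (n < 3L) stop(sprintf("regression '%s' needs n >= 3", name), call. = FALSE)
  if (stats::sd(x) == 0) {
    stop(sprintf("degenerate predictor variance in regression '%s'", name),
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(slope = fit$coefficients[[2L]], intercept = fit$coefficients[[1L]],
       r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

#' Fit a site calibration from a cohort parameter table
#'
#' Refits the four population regressions (AUC vs terminal concentration,
#' theta vs terminal clearance rate, theta vs age, terminal clearance rate
#' vs age) by simple ordinary least squares, and sets the Method-1 recovery
#' fraction to the cohort mean mono-exponential AUC recovery. Fit
#' diagnostics (Pearson r, two-sided p, n) are stored in the calibration's
#' `diagnostics` field.
#'
#' @param table data.frame from [cohort_parameter_table()].
#' @param v_d population ordinate intercept to embed in the calibration,
#'   mL/g (typically the cohort mean full-Patlak gray-matter intercept).
#' @param site site name recorded in the calibration (default `"custom"`).
#' @param units_note concentration-scale note bound to the `auc_vs_ca`
#'   coefficients.
#' @return A [site_calibration()].
#' @export
fit_site_calibration <- function(table, v_d = 0.55, site = "custom",
                                 units_note = "arbitrary") {
  needed <- c("age", "lambda3", "auc_0_67", "ca_52_67", "theta_52_67",
              "recovery_mono")
  if (!all(needed %in% names(table))) {
    stop("parameter table is missing required columns", call. = FALSE)
  }
  if (anyNA(table[needed])) stop("parameter table contains missing values", call. = FALSE)
  auc_ca <- ols_line(table$ca_52_67, table$auc_0_67, "auc_vs_ca")
  th_l3 <- ols_line(table$lambda3, table$theta_52_67, "theta_vs_lambda3")
  th_age <- ols_line(table$age, table$theta_52_67, "theta_vs_age")
  l3_age <- ols_line(table$age, table$lambda3, "lambda3_vs_age")
  strip <- function(f) f[c("slope", "intercept")]
  diag <- function(f) f[c("r", "p", "n")]
  site_calibration(site = site, v_d = v_d,
                   recovery_late = mean(table$recovery_mono) / 100,
                   auc_vs_ca = strip(auc_ca),
                   theta_vs_lambda3 = strip(th_l3),
                   theta_vs_age = strip(th_age),
                   lambda3_vs_age = strip(l3_age),
                   units_note = units_note,
                   diagnostics = list(auc_vs_ca = diag(auc_ca),
                                      theta_vs_lambda3 = diag(th_l3),
                                      theta_vs_age = diag(th_age),
                                      lambda3_vs_age = diag(l3_age)))
}

#' Correlation matrix of cohort pharmacokinetic parameters
#'
#' Pearson correlations over all pairs of the tri-exponential coefficients,
#' the input metrics and age, with uncorrected two-sided p values from the
#' t distribution (n - 2 df) and significance tiers flagged at 0.05, 0.002,
#' 0.0002 and 1e-5 (`*`, `**`, `***`, `#`). A constant column yields `NA`
#' correlations for its pairs.
#'
#' @param table data.frame from [cohort_parameter_table()].
#' @param vars columns to correlate; defaults to the standard parameter set.
#' @return List of class `pk_correlation` with matrices `r`, `p` and
#'   character matrix `stars`, plus `n`.
#' @export
correlation_matrix <- function(table,
                               vars = c("A", "lambda1", "B", "lambda2", "C",
                                        "lambda3", "auc_0_67", "ca_52_67",
                                        "theta_52_67", "age")) {
  vars <- intersect(vars, names(table))
  n <- nrow(table)
  if (n < 4L) stop("correlation matrix needs n >= 4", call. = FALSE)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  stars <- matrix("", k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      xi <- table[[vars[i]]]
      xj <- table[[vars[j]]]
      if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      rij <- stats::cor(xi, xj)
      tt <- rij * sqrt((n - 2) / max(1 - rij^2, .Machine$double.eps))
      r[i, j] <- rij
      p[i, j] <- 2 * stats::pt(-abs(tt), df = n - 2)
      stars[i, j] <- if (p[i, j] < 1e-5) "#" else if (p[i, j] < 2e-4) "***"
        else if (p[i, j] < 2e-3) "**" else if (p[i, j] < 0.05) "*" else ""
    }
  }
  structure(list(r = r, p = p, stars = stars, n = n), class = "pk_correlation")
}

#' @export
print.pk_correlation <- function(x, digits = 3, ...) {
  cat(sprintf("pk_correlation (n = %d): Pearson r with significance tiers\n", x$n))
  shown <- matrix(paste0(format(round(x$r, digits)), x$stars),
                  nrow = nrow(x$r), dimnames = dimnames(x$r))
  shown[is.na(x$r)] <- "."
  print(shown, quote = FALSE)
  invisible(x)
}
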
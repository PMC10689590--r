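#' Patlak-Gjedde linear graphic analysis
#'
#' For an irreversibly trapped tracer, plotting the apparent tissue
#' distribution volume \eqn{y_j = C_T(t_j)/C_a(t_j)} against the normalized
#' time \eqn{x_j = \int_0^{t_j} C_a \, d\tau / C_a(t_j)} (minutes) yields a
#' straight line once the reversible compartments have equilibrated; the
#' slope is the net influx constant Ki (mL/g/min) and the ordinate intercept
#' the distribution volume V_D (mL/g).
#'
#' @param idif blood [tac()].
#' @param tissue tissue [tac()] on the same frame schedule.
#' @param t_lo first frame mid-time included in the regression, minutes
#'   (default 12).
#' @param t_appear appearance time for the running integral's zero anchor;
#'   detected from the blood curve when `NULL`.
#' @return A `patlak_result`: list with `ki`, `vd`, `r` (Pearson correlation
#'   of the fit), `n_frames`, `window`, `mode = "full"`.
#' @export
patlak_full <- function(idif, tissue, t_lo = 12, t_appear = NULL) {
  stopifnot(inherits(idif, "tac"), inherits(tissue, "tac"))
  if (length(idif$value) != length(tissue$value) ||
      max(abs(idif$schedule$mid - tissue$schedule$mid)) > 1e-9) {
    stop("blood and tissue curves must share one frame schedule", call. = FALSE)
  }
  if (is.null(t_appear)) t_appear <- detect_first_appearance(idif)$t_appear
  mids <- idif$schedule$mid
  use <- which(mids >= t_lo)
  if (length(use) < 3L) stop("need >= 3 frames at or beyond t_lo", call. = FALSE)
  if (any(idif$value[use] <= 0)) {
    stop("non-positive blood value in the Patlak window", call. = FALSE)
  }
  x <- vapply(mids[use],
              function(tm) auc_trapezoid(idif, t_appear, tm, t_appear = t_appear),
              numeric(1)) / idif$value[use]
  y <- tissue$value[use] / idif$value[use]
  fit <- stats::lm.fit(cbind(1, x), y)
  r <- if (stats::sd(y) > 0) stats::cor(x, y) else NA_real_
  structure(list(ki = fit$coefficients[[2L]], vd = fit$coefficients[[1L]],
                 r = r, n_frames = length(use),
                 window = c(t_lo, mids[length(mids)]), mode = "full"),
            class = "patlak_result")
}

#' @export
print.patlak_result <- function(x, ...) {
  cat(sprintf("patlak_result [%s]: Ki=%.4g mL/g/min, V_D=%.3g mL/g (n=%d, r=%.3f)\n",
              x$mode, x$ki, x$vd, x$n_frames, x$r))
  invisible(x)
}

#' Late-window apparent tissue distribution volume
#'
#' Ratio of the mean tissue to mean blood concentration over the terminal
#' window: the single "point" of the two-point Patlak analysis.
#'
#' @param tissue,idif [tac()]s with frames in the window.
#' @param window terminal window in minutes, default `c(52, 67)`.
#' @return V_T (mL/g).
#' @export
distribution_volume_late <- function(tissue, idif, window = c(52, 67)) {
  it <- frames_in_window(tissue, window[1L], window[2L])
  ib <- frames_in_window(idif, window[1L], window[2L])
  if (length(it) < 1L || length(ib) < 1L) {
    stop(sprintf("no frames in the late window [%g, %g] min",
                 window[1L], window[2L]), call. = FALSE)
  }
  blood <- mean(idif$value[ib])
  if (blood <= 0) stop("non-positive late blood mean", call. = FALSE)
  mean(tissue$value[it]) / blood
}

#' Two-point Patlak estimate of Ki
#'
#' Slope of the line through the fixed population intercept `(0, v_d)` and a
#' single late-time point `(theta_late, v_t_late)`:
#' \deqn{K_i = (V_T - V_D) / \theta.}
#'
#' @param v_t_late late apparent tissue distribution volume, mL/g.
#' @param theta_late normalized arterial integral at the late point, minutes.
#' @param v_d population ordinate intercept, mL/g (default 0.55, the gray
#'   matter population value).
#' @return Ki, mL/g/min.
#' @export
patlak_two_point <- function(v_t_late, theta_late, v_d = 0.55) {
  if (!is.finite(theta_late) || theta_late <= 0) {
    stop("theta_late must be positive", call. = FALSE)
  }
  (v_t_late - v_d) / theta_late
}
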
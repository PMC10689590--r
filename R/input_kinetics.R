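#' Tri-exponential input-function parameters
#'
#' The arterial FDG concentration after a bolus is modelled as
#' \deqn{C_a(t) = A e^{-\lambda_1 t} + B e^{-\lambda_2 t} + C e^{-\lambda_3 t}}
#' for `t >= t_appear` (zero before), with time measured from injection.
#' The three phases reflect mixing of the bolus in the blood pool
#' (\eqn{\lambda_1}), partitioning of plasma FDG into body tissues
#' (\eqn{\lambda_2}), and renal elimination (\eqn{\lambda_3}). Amplitudes of
#' dropped phases may be zero (bi- or mono-exponential degenerate forms), but
#' the rate constants of phases with positive amplitude must be strictly
#' ordered `lambda1 > lambda2 > lambda3 > 0` and `C > 0`.
#'
#' @param A,B,C amplitudes (concentration units, intercepts extrapolated to
#'   injection time); `A`, `B` >= 0, `C` > 0.
#' @param lambda1,lambda2,lambda3 fractional rate constants, 1/min.
#' @param t_appear time of first appearance of radioactivity, minutes (>= 0).
#' @param flags character vector of decomposition warnings (e.g. a phase
#'   degraded to zero amplitude).
#' @return An object of class `triexp_params`.
#' @export
triexp_params <- function(A, B, C, lambda1, lambda2, lambda3, t_appear = 0,
                          flags = character()) {
  if (!is.finite(C) || C <= 0) stop("C must be positive", call. = FALSE)
  if (A < 0 || B < 0) stop("A and B must be non-negative", call. = FALSE)
  if (!is.finite(lambda3) || lambda3 <= 0) stop("lambda3 must be positive", call. = FALSE)
  if (t_appear < 0) stop("t_appear must be non-negative", call. = FALSE)
  # ordering is only enforced across phases that are actually present
  rates <- c(if (A > 0) lambda1, if (B > 0) lambda2, lambda3)
  if (any(diff(rates) >= 0)) {
    stop("rate constants must satisfy lambda1 > lambda2 > lambda3 > 0",
         call. = FALSE)
  }
  structure(list(A = A, B = B, C = C,
                 lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 t_appear = t_appear, flags = flags),
            class = "triexp_params")
}

#' @export
print.triexp_params <- function(x, ...) {
  cat(sprintf(paste0("triexp_params: A=%.4g (l1=%.4g), B=%.4g (l2=%.4g), ",
                     "C=%.4g (l3=%.5g), t_appear=%.3g min\n"),
              x$A, x$lambda1, x$B, x$lambda2, x$C, x$lambda3, x$t_appear))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Evaluate the tri-exponential input model
#'
#' @param p a [triexp_params()].
#' @param t time(s) post-injection, minutes (vectorized).
#' @return Concentration at `t`; zero for `t < t_appear`.
#' @export
eval_triexp <- function(p, t) {
  out <- p$A * exp(-p$lambda1 * t) + p$B * exp(-p$lambda2 * t) +
    p$C * exp(-p$lambda3 * t)
  out[t < p$t_appear] <- 0
  out
}

#' Detect first appearance of radioactivity in a blood curve
#'
#' First appearance is the mid-time of the first frame whose value exceeds
#' 5\% of the curve maximum; time-to-peak is the mid-time of the maximum
#' frame.
#'
#' @param idif blood [tac()].
#' @param threshold fraction of the curve maximum defining appearance
#'   (default 0.05).
#' @return List with `t_appear` and `t_peak` (minutes).
#' @export
detect_first_appearance <- function(idif, threshold = 0.05) {
  stopifnot(inherits(idif, "tac"))
  peak <- max(idif$value)
  if (peak <= 0) stop("degenerate input: all-zero blood curve", call. = FALSE)
  i <- which(idif$value > threshold * peak)[1L]
  list(t_appear = idif$schedule$mid[i],
       t_peak = idif$schedule$mid[which.max(idif$value)])
}

#' Log-linear fit of the late blood clearance phase
#'
#' Ordinary least squares of `ln(value)` on frame mid-time over a late
#' window gives the terminal plasma clearance \eqn{C e^{-\lambda_3 t}}: the
#' intercept is back-transformed to a concentration extrapolated to injection
#' time and the negated slope is the fractional elimination rate constant.
#'
#' @param idif blood [tac()].
#' @param window numeric length-2, window in minutes (closed, on mid-times);
#'   default `c(35, 67)`.
#' @return List with `c_tail` (concentration at t = 0) and `lambda` (1/min).
#' @export
fit_loglinear_tail <- function(idif, window = c(35, 67)) {
  stopifnot(inherits(idif, "tac"), length(window) == 2L)
  idx <- frames_in_window(idif, window[1L], window[2L])
  if (length(idx) < 3L) {
    stop(sprintf("need >= 3 frames in [%g, %g] min, found %d",
                 window[1L], window[2L], length(idx)), call. = FALSE)
  }
  y <- idif$value[idx]
  if (any(y <= 0)) {
    stop("non-positive blood value in the tail window", call. = FALSE)
  }
  t <- idif$schedule$mid[idx]
  fit <- stats::lm.fit(cbind(1, t), log(y))
  list(c_tail = exp(fit$coefficients[[1L]]), lambda = -fit$coefficients[[2L]])
}

# log-linear fit on prepared (t, r) samples; returns NULL if fewer than 3
# residuals exceed the floor (residuals at numerical-noise level carry no
# phase information and would fit garbage rates)
peel_phase <- function(t, r, floor = 0) {
  keep <- r > floor
  if (sum(keep) < 3L) return(NULL)
  fit <- stats::lm.fit(cbind(1, t[keep]), log(r[keep]))
  list(amp = exp(fit$coefficients[[1L]]), lambda = -fit$coefficients[[2L]])
}

#' Decompose a blood curve into the tri-exponential model by the method of
#' residuals
#'
#' Sequential exponential peeling: (i) the slowest phase is fitted on a
#' semi-log plot of the late window, (ii) its extrapolated magnitude is
#' subtracted from the measured series and the intermediate phase fitted to
#' the positive residuals in the intermediate window, (iii) a second round of
#' residuals between the time-to-peak and the intermediate window yields the
#' fast phase. If fewer than 3 positive residuals remain at a stage, the
#' corresponding amplitude is set to zero and the result flagged (bi- or
#' mono-exponential degenerate fit).
#'
#' A single stripping pass leaves a small bias in the slow phase wherever the
#' intermediate phase has not fully decayed by the start of the tail window.
#' The decomposition therefore re-strips iteratively (`refine` passes): each
#' phase is refitted on the data minus the current estimates of the other
#' two phases, which drives the cross-phase contamination to zero on
#' noiseless model data while leaving degenerate fits untouched.
#'
#' @param idif blood [tac()].
#' @param tail_window late window for the slow phase, minutes; default
#'   `c(35, 67)`.
#' @param mid_window window for the intermediate phase, minutes; default
#'   `c(2, 20)`.
#' @param fast_upper upper bound of the fast-phase window (its lower bound is
#'   the time-to-peak, exclusive); default 2 min.
#' @param refine number of iterative re-stripping passes after the initial
#'   peel (default 5; 0 reproduces plain one-pass stripping).
#' @return A [triexp_params()] with `t_appear` set from
#'   [detect_first_appearance()].
#' @export
decompose_triexp <- function(idif, tail_window = c(35, 67),
                             mid_window = c(2, 20), fast_upper = 2,
                             refine = 5) {
  stopifnot(inherits(idif, "tac"))
  app <- detect_first_appearance(idif)
  tail_fit <- fit_loglinear_tail(idif, tail_window)
  C <- tail_fit$c_tail
  l3 <- tail_fit$lambda
  if (l3 <= 0) stop("tail fit gave a non-decaying slow phase", call. = FALSE)
  flags <- character()

  t <- idif$schedule$mid
  res_floor <- 1e-6 * max(idif$value)
  r1 <- idif$value - C * exp(-l3 * t)
  in_mid <- t >= mid_window[1L] & t <= mid_window[2L]
  ph2 <- peel_phase(t[in_mid], r1[in_mid], res_floor)
  if (is.null(ph2) || ph2$lambda <= 0) {
    B <- 0; l2 <- l3 * 10
    flags <- c(flags, "intermediate phase degraded to zero amplitude")
  } else {
    B <- ph2$amp; l2 <- ph2$lambda
  }

  r2 <- r1 - B * exp(-l2 * t)
  in_fast <- t > app$t_peak & t <= fast_upper
  ph3 <- peel_phase(t[in_fast], r2[in_fast], res_floor)
  if (is.null(ph3) || ph3$lambda <= 0) {
    A <- 0; l1 <- l2 * 10
    flags <- c(flags, "fast phase degraded to zero amplitude")
  } else {
    A <- ph3$amp; l1 <- ph3$lambda
  }

  # iterative re-stripping: refit each phase against the residual of the
  # other two; a no-op for phases degraded to zero amplitude
  in_tail <- t >= tail_window[1L] & t <= tail_window[2L]
  for (k in seq_len(refine)) {
    ph1 <- peel_phase(t[in_tail],
                      (idif$value - B * exp(-l2 * t) - A * exp(-l1 * t))[in_tail],
                      res_floor)
    if (!is.null(ph1) && ph1$lambda > 0) { C <- ph1$amp; l3 <- ph1$lambda }
    if (B > 0) {
      ph2 <- peel_phase(t[in_mid],
                        (idif$value - C * exp(-l3 * t) - A * exp(-l1 * t))[in_mid],
                        res_floor)
      if (!is.null(ph2) && ph2$lambda > 0) { B <- ph2$amp; l2 <- ph2$lambda }
    }
    if (A > 0) {
      ph3 <- peel_phase(t[in_fast],
                        (idif$value - C * exp(-l3 * t) - B * exp(-l2 * t))[in_fast],
                        res_floor)
      if (!is.null(ph3) && ph3$lambda > 0) { A <- ph3$amp; l1 <- ph3$lambda }
    }
  }

  rates <- c(if (A > 0) l1, if (B > 0) l2, l3)
  if (any(diff(rates) >= 0)) {
    stop("decomposition failure: fitted rate constants are not ordered",
         call. = FALSE)
  }
  triexp_params(A, B, C, l1, l2, l3, t_appear = app$t_appear, flags = flags)
}

#' Trapezoidal area under a time-activity curve
#'
#' Integrates the piecewise-linear interpolant of the (mid-time, value)
#' samples over `[t_start, t_end]`, with linear interpolation at the window
#' edges. When `t_start` precedes the first mid-time, an anchor point
#' `(t_appear, 0)` is prepended so the integral starts from the appearance of
#' radioactivity.
#'
#' @param x a [tac()].
#' @param t_start,t_end integration limits, minutes; `t_end` must not exceed
#'   the last frame end.
#' @param t_appear appearance time used for the zero anchor; if `NULL`,
#'   detected with [detect_first_appearance()].
#' @return Area, concentration-minutes.
#' @export
auc_trapezoid <- function(x, t_start, t_end, t_appear = NULL) {
  stopifnot(inherits(x, "tac"))
  if (t_start > t_end) stop("t_start must not exceed t_end", call. = FALSE)
  if (t_start == t_end) return(0)
  n <- length(x$value)
  if (t_end > x$schedule$end[n] + 1e-9) {
    stop("t_end exceeds the end of the recording", call. = FALSE)
  }
  tt <- x$schedule$mid
  vv <- x$value
  if (t_start < tt[1L]) {
    if (is.null(t_appear)) t_appear <- detect_first_appearance(x)$t_appear
    if (t_appear < tt[1L]) {
      tt <- c(t_appear, tt)
      vv <- c(0, vv)
    }
    t_start <- max(t_start, tt[1L])
  }
  if (t_start >= t_end) return(0)
  # beyond the last mid-time the last frame's average is carried to the frame
  # end (constant extrapolation), matching how frame averages tile the window
  keep <- tt > t_start & tt < t_end
  xs <- c(t_start, tt[keep], t_end)
  ys <- c(stats::approx(tt, vv, xout = t_start, rule = 2)$y,
          vv[keep],
          stats::approx(tt, vv, xout = t_end, rule = 2)$y)
  sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2)
}

#' Closed-form area under the exponential input model
#'
#' \deqn{\int_{t_0}^{t_1} \sum_i c_i e^{-\lambda_i t} dt =
#'   \sum_i \frac{c_i}{\lambda_i}(e^{-\lambda_i t_0} - e^{-\lambda_i t_1})}
#' over the phases selected by `terms`.
#'
#' @param p a [triexp_params()].
#' @param t_start,t_end integration limits, minutes (`t_start >= t_appear`).
#' @param terms `"mono"` (slow phase only), `"bi"` (intermediate + slow) or
#'   `"tri"` (all phases); default `"tri"`.
#' @return Area, concentration-minutes.
#' @export
auc_analytic <- function(p, t_start, t_end, terms = c("tri", "bi", "mono")) {
  terms <- match.arg(terms)
  if (t_start > t_end) stop("t_start must not exceed t_end", call. = FALSE)
  coefs <- switch(terms,
                  mono = list(c(p$C, p$lambda3)),
                  bi = list(c(p$B, p$lambda2), c(p$C, p$lambda3)),
                  tri = list(c(p$A, p$lambda1), c(p$B, p$lambda2),
                             c(p$C, p$lambda3)))
  total <- 0
  for (cf in coefs) {
    if (cf[1L] > 0) {
      total <- total + cf[1L] / cf[2L] *
        (exp(-cf[2L] * t_start) - exp(-cf[2L] * t_end))
    }
  }
  total
}

#' Late-phase input metrics of a decomposed blood curve
#'
#' Computes the measured plasma integral to the end of the recording
#' (trapezoidal, from the appearance time), the terminal arterial
#' concentration (unweighted mean of frames with mid-time in the terminal
#' window), the normalized arterial integral
#' \eqn{\theta = \mathrm{AUC}(0\mbox{-}67)/C_a(52\mbox{-}67)} (minutes), the
#' terminal clearance parameters, and the percentage of the measured AUC
#' recovered by the mono-, bi- and tri-exponential models evaluated from the
#' appearance time.
#'
#' @param idif blood [tac()].
#' @param p its [triexp_params()] decomposition.
#' @param ca_window terminal averaging window, minutes; default `c(52, 67)`.
#' @param t_end end of the recording, minutes; default 67.
#' @return List of class `input_metrics` with fields `auc_0_67`, `ca_52_67`,
#'   `theta_52_67`, `lambda3_tail`, `c_tail`, `recovery_mono`, `recovery_bi`,
#'   `recovery_tri`.
#' @export
compute_input_metrics <- function(idif, p, ca_window = c(52, 67), t_end = 67) {
  stopifnot(inherits(idif, "tac"), inherits(p, "triexp_params"))
  idx <- frames_in_window(idif, ca_window[1L], ca_window[2L])
  if (length(idx) < 1L) {
    stop(sprintf("no frames in the terminal window [%g, %g] min",
                 ca_window[1L], ca_window[2L]), call. = FALSE)
  }
  ca <- mean(idif$value[idx])
  if (ca <= 0) stop("terminal arterial concentration must be positive", call. = FALSE)
  auc <- auc_trapezoid(idif, p$t_appear, t_end, t_appear = p$t_appear)
  if (auc <= 0) stop("measured AUC must be positive", call. = FALSE)
  rec <- function(terms) 100 * auc_analytic(p, p$t_appear, t_end, terms) / auc
  structure(list(auc_0_67 = auc, ca_52_67 = ca, theta_52_67 = auc / ca,
                 lambda3_tail = p$lambda3, c_tail = p$C,
                 recovery_mono = rec("mono"), recovery_bi = rec("bi"),
                 recovery_tri = rec("tri")),
            class = "input_metrics")
}

#' @export
print.input_metrics <- function(x, ...) {
  cat(sprintf("input_metrics: AUC(0-67)=%.4g, Ca(52-67)=%.4g, theta=%.4g min\n",
              x$auc_0_67, x$ca_52_67, x$theta_52_67))
  cat(sprintf("  lambda3=%.5g /min, recovery mono/bi/tri = %.1f/%.1f/%.1f %%\n",
              x$lambda3_tail, x$recovery_mono, x$recovery_bi, x$recovery_tri))
  invisible(x)
}
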
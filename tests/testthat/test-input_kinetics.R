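test_that("first appearance is the first supra-threshold frame mid-time", {
  sch <- frame_schedule(seq(0, 0.9, 0.1), seq(0.1, 1, 0.1))
  x <- tac(sch, c(0, 0, 10, 20, 15, 12, 10, 9, 8, 7), label = "blood")
  app <- detect_first_appearance(x)
  expect_equal(app$t_appear, 0.25)
  expect_equal(app$t_peak, 0.35)

  # bolus with true onset 0.24 min: detected within one early-frame width
  idif <- simulate_idif(default_triexp(), site_schedule("aarhus"), 0)
  expect_lt(abs(detect_first_appearance(idif)$t_appear - 0.24), 0.1)

  expect_error(detect_first_appearance(tac(sch, rep(0, 10), label = "blood")),
               "all-zero")
})

test_that("log-linear tail fit recovers exact exponentials under contamination", {
  sch <- site_schedule("aarhus")
  x <- sampled_tac(sch, function(t) 5 * exp(-0.012 * t))
  fit <- fit_loglinear_tail(x, c(35, 67))
  expect_equal(fit$c_tail, 5, tolerance = 1e-10)
  expect_equal(fit$lambda, 0.012, tolerance = 1e-10)

  # fast contaminant decayed by the window: lambda within 1% of the value a
  # nonlinear least-squares fit of the full model finds on the same samples
  y <- sampled_tac(sch, function(t) 5 * exp(-0.012 * t) + 0.05 * exp(-0.15 * t))
  fit2 <- fit_loglinear_tail(y, c(35, 67))
  idx <- which(y$schedule$mid >= 35 & y$schedule$mid <= 67)
  df <- data.frame(t = y$schedule$mid[idx], v = y$value[idx])
  oracle <- stats::nls(v ~ C * exp(-l3 * t) + b * exp(-0.15 * t), data = df,
                       start = list(C = 4, l3 = 0.02, b = 0.1),
                       algorithm = "port", lower = c(0, 1e-4, 0))
  l3_oracle <- coef(oracle)[["l3"]]
  expect_equal(l3_oracle, 0.012, tolerance = 1e-6)
  expect_lt(abs(fit2$lambda - l3_oracle) / l3_oracle, 0.01)

  expect_error(fit_loglinear_tail(x, c(60, 61)), ">= 3 frames")
  z <- tac(frame_schedule(c(40, 50, 60), c(45, 55, 65)), c(1, 0, 1),
           label = "blood")
  expect_error(fit_loglinear_tail(z, c(35, 67)), "non-positive")
})

test_that("eval_triexp matches the term-by-term sum and decay identities", {
  p0 <- triexp_params(0, 0, 1, 3, 0.15, 0.01, t_appear = 0)
  expect_equal(eval_triexp(p0, 0), 1)
  expect_equal(eval_triexp(p0, 100 * log(2)), 0.5)
  expect_equal(eval_triexp(p0, -0.1), 0)  # before appearance

  set.seed(21)
  for (i in 1:20) {
    l3 <- runif(1, 0.005, 0.02)
    l2 <- l3 * runif(1, 6, 20)
    l1 <- l2 * runif(1, 6, 20)
    p <- triexp_params(runif(1, 1, 60), runif(1, 1, 10), runif(1, 1, 10),
                       l1, l2, l3, t_appear = runif(1, 0, 0.5))
    t <- seq(p$t_appear, 67, length.out = 11)
    brute <- p$A * exp(-p$lambda1 * t) + p$B * exp(-p$lambda2 * t) +
      p$C * exp(-p$lambda3 * t)
    expect_equal(eval_triexp(p, t), brute, tolerance = 1e-14)
  }
})

test_that("trapezoidal AUC matches rectangles, closed forms and edge cases", {
  # constant value 2 sampled at mid-times 1..10, window [1, 10]
  x <- make_tac(seq(0.5, 9.5, 1), seq(1.5, 10.5, 1), rep(2, 10))
  expect_equal(auc_trapezoid(x, 1, 10, t_appear = 0), 18)
  expect_equal(auc_trapezoid(x, 5, 5, t_appear = 0), 0)

  y <- sampled_tac(dense_schedule(0.05), function(t) exp(-0.01 * t))
  closed <- (exp(-0.01 * 0.5) - exp(-0.01 * 67)) / 0.01
  expect_equal(auc_trapezoid(y, 0.5, 67, t_appear = 0), closed,
               tolerance = 1e-3)

  expect_error(auc_trapezoid(x, 1, 80, t_appear = 0), "exceeds")
})

test_that("analytic exponential AUC matches quadrature on random draws", {
  p0 <- triexp_params(0, 0, 1, 3, 0.15, 0.01, t_appear = 0)
  expect_equal(auc_analytic(p0, 0, 67), 100 * (1 - exp(-0.67)))
  expect_equal(auc_analytic(p0, 30, 30), 0)

  set.seed(33)
  for (i in 1:20) {
    l3 <- runif(1, 0.005, 0.02)
    p <- triexp_params(runif(1, 5, 60), runif(1, 1, 10), runif(1, 1, 10),
                       l3 * runif(1, 30, 80), l3 * runif(1, 6, 15), l3,
                       t_appear = runif(1, 0, 0.5))
    lim <- sort(runif(2, p$t_appear, 67))
    quad <- stats::integrate(function(t) eval_triexp(p, t), lim[1], lim[2],
                             rel.tol = 1e-12, abs.tol = 0)$value
    expect_equal(auc_analytic(p, lim[1], lim[2]), quad, tolerance = 1e-8)
  }
})

test_that("method of residuals recovers mono- and tri-exponential inputs", {
  sch <- site_schedule("aarhus")

  # pure mono-exponential: fast phases degrade to zero amplitude, flagged
  pm <- triexp_params(0, 0, 10, 3, 0.15, 0.01, t_appear = 0.05)
  mono <- decompose_triexp(simulate_idif(pm, sch, 0))
  expect_equal(mono$A, 0)
  expect_equal(mono$B, 0)
  expect_length(mono$flags, 2L)
  expect_equal(mono$C, 10, tolerance = 2e-3)
  expect_equal(mono$lambda3, 0.01, tolerance = 2e-3)

  # full tri-exponential vs a nonlinear least-squares oracle on the same
  # frame-averaged samples: slow phase within 2%, intermediate within 10%
  p <- triexp_params(40, 8, 5, 3.0, 0.15, 0.012, t_appear = 0.3)
  idif <- simulate_idif(p, sch, 0)
  dec <- decompose_triexp(idif)
  use <- idif$schedule$mid > 0.4
  df <- data.frame(t = idif$schedule$mid[use], v = idif$value[use])
  oracle <- stats::nls(
    v ~ A * exp(-l1 * t) + B * exp(-l2 * t) + C * exp(-l3 * t), data = df,
    start = list(A = 30, l1 = 2, B = 10, l2 = 0.2, C = 4, l3 = 0.02),
    algorithm = "port",
    lower = c(0, 0.5, 0, 0.02, 0.5, 1e-3), control = list(maxiter = 200))
  co <- coef(oracle)
  expect_lt(abs(dec$C - co[["C"]]) / co[["C"]], 0.02)
  expect_lt(abs(dec$lambda3 - co[["l3"]]) / co[["l3"]], 0.02)
  expect_lt(abs(dec$B - co[["B"]]) / co[["B"]], 0.10)
  expect_lt(abs(dec$lambda2 - co[["l2"]]) / co[["l2"]], 0.10)

  # negative concentrations are rejected at construction
  expect_error(tac(frame_schedule(0:2, 1:3), c(1, -0.5, 1), label = "blood"),
               "negative")
})

test_that("input metrics satisfy their defining identities", {
  sch <- site_schedule("aarhus")
  p <- default_triexp()
  idif <- simulate_idif(p, sch, 0)
  dec <- decompose_triexp(idif)
  m <- compute_input_metrics(idif, dec)

  # theta is the ratio of the plasma integral to the terminal concentration
  expect_equal(m$theta_52_67 * m$ca_52_67, m$auc_0_67, tolerance = 1e-12)

  # data generated by the model itself: tri-exponential recovery near 100%
  expect_lt(abs(m$recovery_tri - 100), 2)
  expect_true(m$recovery_mono <= m$recovery_bi)
  expect_true(m$recovery_bi <= m$recovery_tri)

  # pure mono-exponential: all recoveries coincide near 100%
  pm <- triexp_params(0, 0, 10, 3, 0.15, 0.01, t_appear = 0.05)
  im <- simulate_idif(pm, dense_schedule(0.05), 0)
  dm <- decompose_triexp(im)
  mm <- compute_input_metrics(im, dm)
  expect_equal(mm$recovery_mono, mm$recovery_tri, tolerance = 1e-6)
  expect_lt(abs(mm$recovery_mono - 100), 0.5)

  # constant blood value k: ca = k, auc ~ 66.5 k from t_appear = 0.5
  k <- 3.2
  const <- sampled_tac(dense_schedule(0.05), function(t) rep(k, length(t)))
  pc <- triexp_params(0, 0, k, 3, 0.15, 1e-6, t_appear = 0.5)
  mc <- compute_input_metrics(const, pc)
  expect_equal(mc$ca_52_67, k)
  expect_equal(mc$auc_0_67, 66.5 * k, tolerance = 1e-2)
  expect_equal(mc$theta_52_67, 66.5, tolerance = 1e-2)

  expect_error(compute_input_metrics(idif, dec, ca_window = c(68, 69)),
               "no frames")
})

test_that("recovery fractions are ordered on every generated curve", {
  coh <- generate_cohort("aarhus", seed = 5, n_subjects = 8)
  tab <- cohort_parameter_table(coh$subjects)
  expect_true(all(tab$recovery_mono > 0))
  expect_true(all(tab$recovery_mono <= tab$recovery_bi))
  expect_true(all(tab$recovery_bi <= tab$recovery_tri))
})
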
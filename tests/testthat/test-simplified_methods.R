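test_that("site regressions at population mean predictors give mean responses", {
  aarhus <- default_calibration("aarhus")
  bern <- default_calibration("bern")

  m3a <- method3(0.0121, v_t_late = 4.4455, cal = aarhus)
  expect_equal(m3a$theta_used, 111.3, tolerance = 5e-3)
  m3b <- method3(0.0094, v_t_late = 4.4455, cal = bern)
  expect_equal(m3b$theta_used, 100.8, tolerance = 5e-3)

  m4a <- method4(56.5, v_t_late = 4.4455, cal = aarhus)
  expect_equal(m4a$theta_used, 111.3, tolerance = 5e-3)
  m4b <- method4(59.7, v_t_late = 4.4455, cal = bern)
  expect_equal(m4b$theta_used, 100.8, tolerance = 5e-3)

  m2b <- method2(1.0, v_t_late = 4.4455, cal = bern)
  expect_equal(m2b$theta_used, 106.9, tolerance = 5e-3)
})

test_that("method 2 respects its unit binding and calibration domain", {
  bern <- default_calibration("bern")
  # zero intercept: theta equals the slope for every concentration
  cal0 <- site_calibration("test", v_d = 0.55, recovery_late = 0.85,
                           auc_vs_ca = list(slope = 104, intercept = 0),
                           theta_vs_lambda3 = bern$theta_vs_lambda3,
                           theta_vs_age = bern$theta_vs_age,
                           lambda3_vs_age = bern$lambda3_vs_age,
                           units_note = "kBq/mL")
  for (ca in c(0.2, 1, 9)) {
    expect_equal(method2(ca, 4.4, cal0)$theta_used, 104)
  }
  expect_error(method2(1.0, 4.4, cal0, units = "SUV"), "units mismatch")
  expect_silent(method2(1.0, 4.4, cal0, units = "kBq/mL"))

  calneg <- site_calibration("test", v_d = 0.55, recovery_late = 0.85,
                             auc_vs_ca = list(slope = 10, intercept = -500),
                             theta_vs_lambda3 = bern$theta_vs_lambda3,
                             theta_vs_age = bern$theta_vs_age,
                             lambda3_vs_age = bern$lambda3_vs_age)
  expect_error(method2(1.0, 4.4, calneg), "calibration-domain")
})

test_that("method 1 recovers theta when the calibration matches the data", {
  sch <- site_schedule("aarhus")
  # near-mono-exponential blood curve with recovery fraction ~1: the
  # tail-based AUC estimate reproduces the measured theta up to quadrature
  pm <- triexp_params(0, 0, 6, 3, 0.15, 0.0121, t_appear = 0.5)
  idif <- simulate_idif(pm, dense_schedule(0.05), 0)
  dec <- decompose_triexp(idif)
  met <- compute_input_metrics(idif, dec)
  cal1 <- site_calibration("test", v_d = 0.55,
                           recovery_late = 1 - 1e-9,
                           auc_vs_ca = list(slope = 100, intercept = 0),
                           theta_vs_lambda3 = list(slope = 2953, intercept = 75.57),
                           theta_vs_age = list(slope = -0.313, intercept = 129),
                           lambda3_vs_age = list(slope = -0.0000936, intercept = 0.0174))
  m1 <- method1(idif, v_t_late = 4.4, cal = cal1)
  expect_lt(abs(m1$theta_used - met$theta_52_67) / met$theta_52_67, 0.01)

  # tri-exponential subject scored against its own true late-AUC fraction
  p <- default_triexp()
  idif3 <- simulate_idif(p, sch, 0)
  met3 <- compute_input_metrics(idif3, decompose_triexp(idif3))
  frac <- auc_analytic(p, 0.5, 67, terms = "mono") / met3$auc_0_67
  cal3 <- site_calibration("test", v_d = 0.55, recovery_late = frac,
                           auc_vs_ca = list(slope = 100, intercept = 0),
                           theta_vs_lambda3 = list(slope = 2953, intercept = 75.57),
                           theta_vs_age = list(slope = -0.313, intercept = 129),
                           lambda3_vs_age = list(slope = -0.0000936, intercept = 0.0174))
  m13 <- method1(idif3, v_t_late = 4.4, cal = cal3)
  expect_lt(abs(m13$theta_used - met3$theta_52_67) / met3$theta_52_67, 0.015)
})

test_that("all methods share the two-point core: equal theta gives equal ki", {
  base <- default_calibration("aarhus")
  theta <- 107.5
  cal <- site_calibration("test", v_d = 0.55, recovery_late = 0.85,
                          auc_vs_ca = list(slope = theta, intercept = 0),
                          theta_vs_lambda3 = list(slope = 0, intercept = theta),
                          theta_vs_age = list(slope = 0, intercept = theta),
                          lambda3_vs_age = base$lambda3_vs_age)
  v_t <- 4.1
  k2 <- method2(2.4, v_t, cal)$ki
  k3 <- method3(0.0121, v_t, cal)$ki
  k4 <- method4(63, v_t, cal)$ki
  expect_equal(k2, k3)
  expect_equal(k3, k4)
  expect_equal(k2, patlak_two_point(v_t, theta, 0.55))
})

test_that("methods are scale-free under unit-consistent recalibration", {
  # rescaling all concentrations by k, with the auc_vs_ca intercept rescaled
  # accordingly, leaves every Ki unchanged (v_t and theta are ratios)
  set.seed(9)
  for (i in 1:10) {
    k <- runif(1, 0.1, 10)
    ca <- runif(1, 1, 5)
    v_t <- runif(1, 1, 5)
    slope <- runif(1, 60, 110)
    icpt <- runif(1, 0, 400)
    cal_a <- site_calibration("a", 0.55, 0.85,
                              auc_vs_ca = list(slope = slope, intercept = icpt),
                              theta_vs_lambda3 = list(slope = 2953, intercept = 75.57),
                              theta_vs_age = list(slope = -0.313, intercept = 129),
                              lambda3_vs_age = list(slope = 0, intercept = 0.0121))
    cal_b <- site_calibration("b", 0.55, 0.85,
                              auc_vs_ca = list(slope = slope, intercept = k * icpt),
                              theta_vs_lambda3 = list(slope = 2953, intercept = 75.57),
                              theta_vs_age = list(slope = -0.313, intercept = 129),
                              lambda3_vs_age = list(slope = 0, intercept = 0.0121))
    expect_equal(method2(k * ca, v_t, cal_b)$ki, method2(ca, v_t, cal_a)$ki,
                 tolerance = 1e-12)
    expect_equal(method3(0.011, v_t, cal_b)$ki, method3(0.011, v_t, cal_a)$ki)
    expect_equal(method4(50, v_t, cal_b)$ki, method4(50, v_t, cal_a)$ki)
  }
})

test_that("percent error follows the (method - reference)/reference convention", {
  expect_equal(percent_error(0.0350, 0.0350), 0)
  expect_equal(percent_error(0.0336, 0.0350), -4.0)
  expect_equal(percent_error(0.07, 0.035), 100)
  expect_error(percent_error(0.03, 0), "non-zero")
})

test_that("calibration JSON round-trips and rejects invalid values", {
  cal <- default_calibration("aarhus")
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration(cal, f)
  cal2 <- read_calibration(f)
  expect_equal(cal2$recovery_late, cal$recovery_late)
  expect_equal(cal2$theta_vs_lambda3, cal$theta_vs_lambda3)
  expect_identical(cal2$units_note, cal$units_note)

  expect_error(site_calibration("x", 0.55, 1.2,
                                auc_vs_ca = list(slope = 1, intercept = 0),
                                theta_vs_lambda3 = list(slope = 0, intercept = 100),
                                theta_vs_age = list(slope = 0, intercept = 100),
                                lambda3_vs_age = list(slope = 0, intercept = 0.01)),
               "recovery_late")
  expect_error(site_calibration("x", 0.55, 0.85,
                                auc_vs_ca = list(slope = 1, intercept = 0),
                                theta_vs_lambda3 = list(slope = 0, intercept = -5),
                                theta_vs_age = list(slope = 0, intercept = 100),
                                lambda3_vs_age = list(slope = 0, intercept = 0.01)),
               "non-positive theta")
})
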
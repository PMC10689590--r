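#' Irreversible two-tissue-compartment parameters
#'
#' Standard irreversible FDG kinetics: unidirectional blood-brain clearance
#' `K1` (mL/g/min), efflux `k2` (1/min) and trapping (phosphorylation) rate
#' `k3` (1/min). The implied macro-parameters are the net influx constant
#' \eqn{K_i = K_1 k_3/(k_2+k_3)} and the free-tracer distribution volume
#' \eqn{V_D = K_1/k_2}; the constructor enforces physiological ranges
#' `Ki in [0.005, 0.06]` and `V_D in [0.3, 0.8]`.
#'
#' @param K1,k2,k3 rate constants, all positive.
#' @param region `"GM"` or `"WM"`.
#' @return Object of class `two_tc_params` with derived `ki_true`, `vd_true`.
#' @export
two_tc_params <- function(K1, k2, k3, region = c("GM", "WM")) {
  region <- match.arg(region)
  if (any(!is.finite(c(K1, k2, k3))) || any(c(K1, k2, k3) <= 0)) {
    stop("K1, k2, k3 must all be positive", call. = FALSE)
  }
  ki <- K1 * k3 / (k2 + k3)
  vd <- K1 / k2
  if (ki < 0.005 || ki > 0.06) {
    stop(sprintf("implied Ki %.4g outside [0.005, 0.06]", ki), call. = FALSE)
  }
  if (vd < 0.3 || vd > 0.8) {
    stop(sprintf("implied V_D %.3g outside [0.3, 0.8]", vd), call. = FALSE)
  }
  structure(list(K1 = K1, k2 = k2, k3 = k3, region = region,
                 ki_true = ki, vd_true = vd),
            class = "two_tc_params")
}

#' Age model for the terminal clearance rate
#'
#' Evaluates the site calibration's lambda3-vs-age line, floored at a
#' physiological minimum.
#'
#' @param age age in years (> 0).
#' @param cal a [site_calibration()].
#' @param floor lower bound, 1/min (default 0.002).
#' @return Terminal clearance rate constant, 1/min.
#' @export
lambda3_of_age <- function(age, cal, floor = 0.002) {
  stopifnot(inherits(cal, "site_calibration"))
  if (any(age <= 0)) stop("age must be positive", call. = FALSE)
  pmax(cal$lambda3_vs_age$slope * age + cal$lambda3_vs_age$intercept, floor)
}

# exact integral of a * t^pow * exp(-mu t) over [lo, hi], pow in {0, 1}
exp_term_integral <- function(a, mu, pow, lo, hi) {
  if (hi <= lo) return(0)
  if (mu == 0) {
    return(if (pow == 0L) a * (hi - lo) else a * (hi^2 - lo^2) / 2)
  }
  if (pow == 0L) {
    a / mu * (exp(-mu * lo) - exp(-mu * hi))
  } else {
    anti <- function(t) -(t / mu + 1 / mu^2) * exp(-mu * t)
    a * (anti(hi) - anti(lo))
  }
}

# frame averages of a sum of terms list(a=, mu=, pow=) that is zero before
# t_appear; averaging divides by the full frame duration
frame_average_terms <- function(terms, schedule, t_appear) {
  vapply(seq_along(schedule$start), function(i) {
    lo <- max(schedule$start[i], t_appear)
    hi <- schedule$end[i]
    if (hi <= t_appear) return(0)
    tot <- 0
    for (tm in terms) tot <- tot + exp_term_integral(tm$a, tm$mu, tm$pow, lo, hi)
    tot / (schedule$end[i] - schedule$start[i])
  }, numeric(1))
}

triexp_terms <- function(p) {
  Filter(function(tm) tm$a != 0,
         list(list(a = p$A, mu = p$lambda1, pow = 0L),
              list(a = p$B, mu = p$lambda2, pow = 0L),
              list(a = p$C, mu = p$lambda3, pow = 0L)))
}

# closed-form irreversible 2TC tissue response to a (shifted) exponential-sum
# input: C_T(t) = int_{ta}^{t} Ca(u) h(t-u) du with
# h(t) = K1 k3/(k2+k3) + K1 k2/(k2+k3) exp(-(k2+k3) t).
# Each input term c e^{-lambda u} convolved with a response term d e^{-beta t}
# contributes c d (e^{-beta t} e^{-(lambda-beta) ta} - e^{-lambda t})/(lambda-beta),
# degenerating to c d (t - ta) e^{-beta t} when lambda = beta.
tissue_response_terms <- function(p, q) {
  beta <- q$k2 + q$k3
  d1 <- q$K1 * q$k3 / beta  # trapping branch, beta0 = 0
  d2 <- q$K1 * q$k2 / beta  # reversible branch
  ta <- p$t_appear
  terms <- list()
  add <- function(a, mu, pow = 0L) {
    terms[[length(terms) + 1L]] <<- list(a = a, mu = mu, pow = pow)
  }
  for (tm in triexp_terms(p)) {
    cf <- tm$a; lam <- tm$mu
    # trapping branch (beta = 0): c d1 (e^{-lam ta} - e^{-lam t}) / lam
    add(cf * d1 * exp(-lam * ta) / lam, 0)
    add(-cf * d1 / lam, lam)
    # reversible branch
    if (abs(lam - beta) > 1e-10) {
      add(cf * d2 * exp(-(lam - beta) * ta) / (lam - beta), beta)
      add(-cf * d2 / (lam - beta), lam)
    } else {
      add(cf * d2, beta, pow = 1L)       # c d2 t e^{-beta t}
      add(-cf * d2 * ta, beta)           # - c d2 ta e^{-beta t}
    }
  }
  terms
}

#' Evaluate the noiseless two-tissue-compartment tissue curve
#'
#' Closed-form tissue concentration at arbitrary times for a tri-exponential
#' input convolved with the irreversible two-tissue-compartment impulse
#' response. Mainly useful for oracles and plotting.
#'
#' @param p input [triexp_params()].
#' @param q tissue [two_tc_params()].
#' @param t times post-injection, minutes (vectorized).
#' @return Tissue concentration at `t` (zero before `p$t_appear`).
#' @export
eval_tissue_2tc <- function(p, q, t) {
  terms <- tissue_response_terms(p, q)
  out <- numeric(length(t))
  for (tm in terms) out <- out + tm$a * t^tm$pow * exp(-tm$mu * t)
  out[t < p$t_appear] <- 0
  out
}

# multiplicative lognormal noise with unit mean and the given CV
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a framed blood curve from the tri-exponential model
#'
#' Frame values are analytic frame averages of the input model over each
#' frame (zero before the appearance time; partial frames average the model
#' over the post-appearance part against the full frame duration), then
#' multiplied by lognormal noise with unit mean and the given coefficient of
#' variation.
#'
#' @param p [triexp_params()].
#' @param schedule [frame_schedule()].
#' @param noise_cv per-frame multiplicative noise CV (0 = noiseless).
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   first for reproducibility.
#' @param subject_id,units passed to [tac()].
#' @return A blood [tac()].
#' @export
simulate_idif <- function(p, schedule, noise_cv = 0, seed = NULL,
                          subject_id = "", units = "arbitrary") {
  stopifnot(inherits(p, "triexp_params"), inherits(schedule, "frame_schedule"))
  if (!is.null(seed)) set.seed(seed)
  v <- frame_average_terms(triexp_terms(p), schedule, p$t_appear)
  v <- v * lognormal_noise(length(v), noise_cv)
  tac(schedule, v, label = "blood", subject_id = subject_id, units = units)
}

#' Simulate a framed tissue curve from irreversible two-tissue-compartment
#' kinetics
#'
#' The tissue response to the tri-exponential input is evaluated in closed
#' form term by term (sum of exponential-convolution primitives), frame
#' averaged, and degraded with the same multiplicative noise model as
#' [simulate_idif()]. The blood volume fraction is fixed at zero.
#'
#' @inheritParams simulate_idif
#' @param q [two_tc_params()].
#' @return A tissue [tac()] labelled with `q$region`.
#' @export
simulate_tissue <- function(p, q, schedule, noise_cv = 0, seed = NULL,
                            subject_id = "", units = "arbitrary") {
  stopifnot(inherits(p, "triexp_params"), inherits(q, "two_tc_params"),
            inherits(schedule, "frame_schedule"))
  if (!is.null(seed)) set.seed(seed)
  v <- frame_average_terms(tissue_response_terms(p, q), schedule, p$t_appear)
  v <- v * lognormal_noise(length(v), noise_cv)
  tac(schedule, v, label = q$region, subject_id = subject_id, units = units)
}

# lognormal draw with given mean and CV
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Default cohort-generation parameters for a site
#'
#' Population statistics for the virtual cohorts. Ages and the
#' lambda3-vs-age line come from the shipped site calibrations; the
#' amplitude and fast/intermediate rate distributions are simulator
#' assumptions (no published population values exist for them), chosen so
#' that the simulated cohort-mean mono/bi/tri AUC recovery fractions and the
#' normalized arterial integral land near the published population values.
#'
#' @param site `"aarhus"` or `"bern"`.
#' @return List of generation parameters, editable before passing to
#'   [generate_cohort()].
#' @export
cohort_defaults <- function(site = c("aarhus", "bern")) {
  site <- match.arg(tolower(site), c("aarhus", "bern"))
  common <- list(
    site = site,
    n_subjects = if (site == "aarhus") 52L else 24L,
    noise_cv = 0.03,
    c_mean = 5, c_cv = 0.10,
    lambda1_mean = 3.0, lambda1_cv = 0.20,
    lambda2_mean = 0.15, lambda2_cv = 0.15,
    t_appear_mean = 0.24, t_appear_sd = 0.05,
    gm = list(K1 = 0.102, K1_cv = 0.15, k2 = 0.185, k2_cv = 0.10,
              k3 = 0.095, k3_cv = 0.20),
    wm = list(K1 = 0.054, K1_cv = 0.15, k2 = 0.106, k2_cv = 0.10,
              k3 = 0.0382, k3_cv = 0.20),
    max_tries = 1000L)
  site_specific <- if (site == "aarhus") {
    list(age_mean = 56.5, age_sd = 14.1,
         lambda3_scatter_sd = 0.0022,
         b_over_c = 0.9, b_cv = 0.20,
         a_over_c = 11, a_cv = 0.30)
  } else {
    list(age_mean = 59.7, age_sd = 15.2,
         lambda3_scatter_sd = 0.0019,
         b_over_c = 1.0, b_cv = 0.20,
         a_over_c = 12.4, a_cv = 0.30)
  }
  c(common, site_specific)
}

draw_until <- function(draw, ok, max_tries, what) {
  for (i in seq_len(max_tries)) {
    x <- draw()
    if (ok(x)) return(x)
  }
  stop(sprintf("parameterization error: no valid %s after %d tries",
               what, max_tries), call. = FALSE)
}

#' Generate a virtual cohort with known ground truth
#'
#' Draws per-subject ages, tri-exponential input parameters (terminal
#' clearance rate from the site's age model plus Gaussian scatter) and
#' regional two-tissue-compartment parameters, simulates framed blood, gray
#' matter and white matter curves on the site's frame schedule, and returns
#' the subjects together with a ground-truth table (true Ki and V_D per
#' region, true AUC, terminal concentration and normalized arterial integral
#' per subject, computed from the closed-form model).
#'
#' @param site `"aarhus"` or `"bern"`.
#' @param seed integer seed (mandatory: the generator is stochastic).
#' @param n_subjects cohort size; defaults to the site's published size.
#' @param noise_cv per-frame multiplicative noise CV (default 0.03).
#' @param params full generation-parameter list; defaults to
#'   [cohort_defaults()] for the site with the above overrides applied.
#' @return List of class `synthetic_cohort`: `subjects` (list of
#'   `subject_record`s), `truth` (data.frame), `params`.
#' @export
generate_cohort <- function(site = c("aarhus", "bern"), seed,
                            n_subjects = NULL, noise_cv = NULL,
                            params = NULL) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(params)) params <- cohort_defaults(site)
  if (!is.null(n_subjects)) params$n_subjects <- as.integer(n_subjects)
  if (!is.null(noise_cv)) params$noise_cv <- noise_cv
  g <- params
  set.seed(seed)
  cal <- default_calibration(g$site)
  schedule <- site_schedule(g$site)

  subjects <- vector("list", g$n_subjects)
  truth <- vector("list", g$n_subjects)
  for (i in seq_len(g$n_subjects)) {
    sid <- sprintf("%s-%03d", toupper(substr(g$site, 1, 2)), i)
    age <- draw_until(function() stats::rnorm(1, g$age_mean, g$age_sd),
                      function(a) a >= 20 && a <= 90, g$max_tries, "age")
    p <- draw_until(function() {
      l3 <- lambda3_of_age(age, cal) + stats::rnorm(1, 0, g$lambda3_scatter_sd)
      C <- rlnorm_cv(1, g$c_mean, g$c_cv)
      B <- C * rlnorm_cv(1, g$b_over_c, g$b_cv)
      A <- C * rlnorm_cv(1, g$a_over_c, g$a_cv)
      l1 <- rlnorm_cv(1, g$lambda1_mean, g$lambda1_cv)
      l2 <- rlnorm_cv(1, g$lambda2_mean, g$lambda2_cv)
      ta <- stats::rnorm(1, g$t_appear_mean, g$t_appear_sd)
      list(A = A, B = B, C = C, l1 = l1, l2 = l2, l3 = l3, ta = ta)
    }, function(x) {
      x$l3 > 0.003 && x$l2 > 5 * x$l3 && x$l1 > 5 * x$l2 &&
        x$ta >= 0.05 && x$ta <= 0.6
    }, g$max_tries, "input parameters")
    p <- triexp_params(p$A, p$B, p$C, p$l1, p$l2, p$l3, t_appear = p$ta)

    draw_2tc <- function(d, region) {
      draw_until(function() {
        K1 <- rlnorm_cv(1, d$K1, d$K1_cv)
        k2 <- rlnorm_cv(1, d$k2, d$k2_cv)
        k3 <- rlnorm_cv(1, d$k3, d$k3_cv)
        list(K1 = K1, k2 = k2, k3 = k3)
      }, function(x) {
        ki <- x$K1 * x$k3 / (x$k2 + x$k3); vd <- x$K1 / x$k2
        ki >= 0.005 && ki <= 0.06 && vd >= 0.3 && vd <= 0.8
      }, g$max_tries, paste(region, "kinetics"))
    }
    qg <- draw_2tc(g$gm, "GM")
    qg <- two_tc_params(qg$K1, qg$k2, qg$k3, "GM")
    qw <- draw_2tc(g$wm, "WM")
    qw <- two_tc_params(qw$K1, qw$k2, qw$k3, "WM")

    idif <- simulate_idif(p, schedule, g$noise_cv, subject_id = sid)
    gm <- simulate_tissue(p, qg, schedule, g$noise_cv, subject_id = sid)
    wm <- simulate_tissue(p, qw, schedule, g$noise_cv, subject_id = sid)
    subjects[[i]] <- subject_record(sid, age, g$site, idif, gm, wm)

    auc_true <- auc_analytic(p, p$t_appear, 67)
    ca_true <- auc_analytic(p, 52, 67) / 15
    truth[[i]] <- data.frame(
      subject_id = sid, age = age, t_appear = p$t_appear,
      A = p$A, lambda1 = p$lambda1, B = p$B, lambda2 = p$lambda2,
      C = p$C, lambda3 = p$lambda3,
      auc_true = auc_true, ca_true = ca_true,
      theta_true = auc_true / ca_true,
      ki_true_gm = qg$ki_true, vd_true_gm = qg$vd_true,
      ki_true_wm = qw$ki_true, vd_true_wm = qw$vd_true)
  }
  structure(list(subjects = subjects, truth = do.call(rbind, truth),
                 params = g, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort [%s]: %d subjects, noise CV %.3g, seed %s\n",
              x$params$site, length(x$subjects), x$params$noise_cv,
              format(x$seed)))
  invisible(x)
}
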
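test_that("reference subjects recover the typical structural values", {
  p <- individual_params(dtg_model(), ref_dtg_cov)
  expect_equal(p$cl, 0.858)
  expect_equal(p$v2, 16.7)
  expect_equal(p$ka, 2.15)
  expect_equal(p$f, 1)

  l <- individual_params(lam_model(), ref_lam_cov)
  expect_equal(l$cl, 19.6)
  expect_equal(l$v2, 105)
  expect_equal(l$v3, 105)
  expect_equal(l$q, 2.97)
  expect_equal(l$ka, 2.30)
})

test_that("covariate multipliers compose multiplicatively", {
  p <- individual_params(dtg_model(),
                         data.frame(weight = 79, bilirubin = 8,
                                    ethnicity_hispanic = 1))
  expect_equal(p$cl, 0.858 * 0.844)

  l <- individual_params(lam_model(),
                         data.frame(weight = 153, egfr = 99, race_black = 0))
  expect_equal(l$v2, 105 * 153 / 70)  # linear allometry on volume
  expect_equal(l$cl, 19.6 * (153 / 70)^0.75)
})

test_that("random effects enter as exp(eta) on their targets", {
  eta <- matrix(c(log(2), log(3)), 1,
                dimnames = list(NULL, c("eta_cl", "eta_ruv")))
  p <- individual_params(dtg_model(), ref_dtg_cov, eta)
  expect_equal(p$cl, 0.858 * 2)
  expect_equal(p$ruv_scale, 3)
  # lamivudine: eta_v2 propagates to the constrained peripheral volume
  eta3 <- matrix(c(0, log(1.5), 0), 1,
                 dimnames = list(NULL, c("eta_cl", "eta_v2", "eta_ruv")))
  l <- individual_params(lam_model(), ref_lam_cov, eta3)
  expect_equal(l$v2, 105 * 1.5)
  expect_equal(l$v3, l$v2)
})

test_that("invalid covariates are rejected", {
  expect_error(individual_params(dtg_model(), data.frame(weight = 79)),
               "not found")
  expect_error(
    individual_params(dtg_model(),
                      data.frame(weight = -1, bilirubin = 8,
                                 ethnicity_hispanic = 0)),
    "positive")
  expect_error(
    individual_params(dtg_model(),
                      data.frame(weight = 79, bilirubin = 8,
                                 ethnicity_hispanic = 2)),
    "indicator")
})

test_that("steady-state AUC over one interval equals dose/CL", {
  p <- individual_params(dtg_model(), ref_dtg_cov)
  a <- integrate(function(t) css_one_compartment(p, 50, 24, t), 0, 24,
                 rel.tol = 1e-10)$value
  expect_equal(a, 50 / p$cl, tolerance = 1e-6)

  l <- individual_params(lam_model(), ref_lam_cov)
  a2 <- integrate(function(t) css_two_compartment(l, 300, 24, t), 0, 24,
                  rel.tol = 1e-10)$value
  expect_equal(a2, 300 / l$cl, tolerance = 1e-6)

  # degenerate ka == k keeps the identity
  pd <- p; pd$ka <- p$cl / p$v2
  a3 <- integrate(function(t) css_one_compartment(pd, 50, 24, t), 0, 24,
                  rel.tol = 1e-10)$value
  expect_equal(a3, 50 / pd$cl, tolerance = 1e-6)
})

test_that("profiles are periodic: C(0) == C(tau)", {
  p <- individual_params(dtg_model(), ref_dtg_cov)
  expect_equal(css_one_compartment(p, 50, 24, 0),
               css_one_compartment(p, 50, 24, 24), tolerance = 1e-9)
  l <- individual_params(lam_model(), ref_lam_cov)
  expect_equal(css_two_compartment(l, 300, 24, 0),
               css_two_compartment(l, 300, 24, 24), tolerance = 1e-9)
})

test_that("closed forms match a multi-dose ODE integration to 1e-6", {
  skip_if_not_installed("deSolve")
  grid <- c(0.5, 1, 2, 3, 4, 6, 8, 12, 23.5)
  # one-compartment
  p <- individual_params(dtg_model(), ref_dtg_cov)
  rhs1 <- function(t, y, pr)
    list(c(-pr$ka * y[1], pr$ka * y[1] / pr$v - pr$k * y[2]))
  nd <- 40
  ev <- data.frame(var = "gut", time = (0:(nd - 1)) * 24, value = 50,
                   method = "add")
  tt <- sort(unique(c(ev$time, (nd - 1) * 24 + grid)))
  o <- deSolve::ode(c(gut = 0, conc = 0), tt, rhs1,
                    list(ka = p$ka, v = p$v2, k = p$cl / p$v2),
                    events = list(data = ev), rtol = 1e-11, atol = 1e-11)
  ode1 <- o[match((nd - 1) * 24 + grid, o[, 1]), 3]
  cf1 <- css_one_compartment(p, 50, 24, grid)
  expect_lt(max(abs(cf1 / ode1 - 1)), 1e-6)
  # two-compartment
  l <- individual_params(lam_model(), ref_lam_cov)
  rhs2 <- function(t, y, pr) {
    list(c(-pr$ka * y[1],
           pr$ka * y[1] - (pr$k10 + pr$k12) * y[2] + pr$k21 * y[3],
           pr$k12 * y[2] - pr$k21 * y[3]))
  }
  ev2 <- data.frame(var = "gut", time = (0:(nd - 1)) * 24, value = 300,
                    method = "add")
  tt2 <- sort(unique(c(ev2$time, (nd - 1) * 24 + grid)))
  o2 <- deSolve::ode(c(gut = 0, ctr = 0, per = 0), tt2, rhs2,
                     list(ka = l$ka, k10 = l$cl / l$v2, k12 = l$q / l$v2,
                          k21 = l$q / l$v3),
                     events = list(data = ev2), rtol = 1e-11, atol = 1e-11)
  ode2 <- o2[match((nd - 1) * 24 + grid, o2[, 1]), 3] / l$v2
  cf2 <- css_two_compartment(l, 300, 24, grid)
  expect_lt(max(abs(cf2 / ode2 - 1)), 1e-6)
})

test_that("large ka converges to the accumulating bolus profile", {
  p <- individual_params(dtg_model(), ref_dtg_cov)
  p$ka <- 1e6
  k <- p$cl / p$v2
  t <- c(0.5, 2, 10, 24)
  bolus <- 50 / p$v2 * exp(-k * t) / (1 - exp(-k * 24))
  expect_equal(css_one_compartment(p, 50, 24, t), bolus, tolerance = 1e-4)
})

test_that("two-compartment profile collapses to one-compartment as q -> 0", {
  l <- individual_params(lam_model(), ref_lam_cov)
  t <- c(0, 0.5, 1, 2, 6, 12, 24)
  one <- css_one_compartment(l, 300, 24, t)
  for (q0 in c(0, 1e-12, 1e-7)) {
    l2 <- l; l2$q <- q0
    expect_equal(css_two_compartment(l2, 300, 24, t), one, tolerance = 1e-5)
  }
})

test_that("confluent limits are continuous in the rate constants", {
  p <- individual_params(dtg_model(), ref_dtg_cov)
  k <- p$cl / p$v2
  t <- c(0.5, 2, 10, 24)
  pd <- p; pd$ka <- k
  pn <- p; pn$ka <- k * (1 + 1e-4)
  expect_equal(css_one_compartment(pd, 50, 24, t),
               css_one_compartment(pn, 50, 24, t), tolerance = 1e-3)
  # two-compartment: force ka onto the fast hybrid root
  l <- individual_params(lam_model(), ref_lam_cov)
  k10 <- l$cl / l$v2; k12 <- l$q / l$v2; k21 <- l$q / l$v3
  s <- k10 + k12 + k21
  alpha <- (s + sqrt(s^2 - 4 * k10 * k21)) / 2
  ld <- l; ld$ka <- alpha
  ln <- l; ln$ka <- alpha * (1 + 1e-4)
  expect_equal(css_two_compartment(ld, 300, 24, t),
               css_two_compartment(ln, 300, 24, t), tolerance = 1e-3)
})

test_that("times outside the dosing interval are rejected", {
  p <- individual_params(dtg_model(), ref_dtg_cov)
  expect_error(css_one_compartment(p, 50, 24, 25), "within")
  expect_error(css_one_compartment(p, 50, 24, -1), "within")
  expect_error(css_two_compartment(p, 50, 24, 2), "v3")
})

test_that("residual error model is Y = IPRED(1 + sd * scale * eps)", {
  expect_equal(apply_residual_error(2.5, 0.341, 1, 0), 2.5)
  expect_equal(apply_residual_error(1, 0.341, 1, 1), 1.341)
  expect_equal(apply_residual_error(1, 0.341, 2, -1), 1 - 0.682)
  expect_error(apply_residual_error(-1, 0.3, 1, 0), "non-negative")
  set.seed(42)
  y <- apply_residual_error(rep(1, 1e5), 0.341, 1.3, rnorm(1e5))
  expect_equal(sd(y), 0.341 * 1.3, tolerance = 0.02)
})

test_that("log-normal variance to percent CV transform and inverse", {
  expect_equal(round(iiv_percent_cv(0.0682), 1), 26.6)
  expect_equal(round(iiv_percent_cv(0.247), 1), 52.9)
  expect_equal(iiv_percent_cv(0), 0)
  expect_error(iiv_percent_cv(-0.1), "non-negative")
  for (w in c(0.01, 0.0682, 0.247, 1.5))
    expect_equal(percent_cv_to_omega2(iiv_percent_cv(w)), w,
                 tolerance = 1e-12)
})

test_that("covariate effect percentages match the closed forms", {
  expect_equal(covariate_effect_percent("power", 2, 8, -0.153),
               100 * ((2 / 8)^-0.153 - 1))
  expect_equal(round(covariate_effect_percent("power", 2, 8, -0.153)), 24)
  expect_equal(covariate_effect_percent("categorical", estimate = 0.844),
               -15.6, tolerance = 1e-10)
  expect_equal(covariate_effect_percent("power", 8, 8, -0.153), 0)
  expect_error(covariate_effect_percent("power", -2, 8, 1), "positive")
})

test_that("clearance is monotone in its continuous covariates", {
  bili <- c(2, 5, 8, 15, 34)
  cl_b <- sapply(bili, function(b)
    individual_params(dtg_model(),
                      data.frame(weight = 79, bilirubin = b,
                                 ethnicity_hispanic = 0))$cl)
  expect_true(all(diff(cl_b) < 0))
  wt <- c(50, 70, 79, 100, 153)
  cl_w <- sapply(wt, function(w)
    individual_params(dtg_model(),
                      data.frame(weight = w, bilirubin = 8,
                                 ethnicity_hispanic = 0))$cl)
  expect_true(all(diff(cl_w) > 0))
  eg <- c(44, 70, 99, 147)
  cl_e <- sapply(eg, function(e)
    individual_params(lam_model(),
                      data.frame(weight = 70, egfr = e, race_black = 0))$cl)
  expect_true(all(diff(cl_e) > 0))
})

test_that("model definition files round-trip through YAML", {
  path <- file.path(tempdir(), "m.yaml")
  write_model_yaml(lam_model(), path)
  m <- read_model_yaml(path)
  expect_equal(m$theta, lam_model()$theta)
  expect_equal(m$omega, lam_model()$omega)
  expect_equal(length(m$covariates), length(lam_model()$covariates))
  expect_equal(m$prop_sd, lam_model()$prop_sd)
  shipped <- system.file("extdata", "dolutegravir_final_model.yaml",
                         package = "dlpoppk")
  expect_equal(read_model_yaml(shipped)$theta$cl, 0.858)
})

test_that("model validation enforces positivity and omega shape", {
  om <- matrix(0.05, 1, 1, dimnames = list("eta_cl", "eta_cl"))
  expect_error(pk_model("x", 1, list(cl = -1, v2 = 10, ka = 1), "none",
                        list(), om, 0.3, dose = 50),
               "positive")
  bad_om <- matrix(c(0.1, 0.5, 0.5, 0.1), 2, 2,
                   dimnames = list(c("eta_cl", "eta_v2"),
                                   c("eta_cl", "eta_v2")))
  expect_error(pk_model("x", 1, list(cl = 1, v2 = 10, ka = 1), "none",
                        list(), bad_om, 0.3, dose = 50),
               "semi-definite")
})
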
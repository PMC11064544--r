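test_that("objective collapses to the fixed-effects deviance when omega = 0", {
  m <- dtg_model()
  m$omega[] <- 0
  st <- make_study(m, 12, 4, seed = 201)
  obs <- st$data[st$data$evid == 0 & st$data$mdv == 0, ]
  p <- individual_params(m, st$covs)
  ipred <- css_one_compartment(p[match(obs$id, st$covs$id), ], 50, 24,
                               obs$tad)
  direct <- -2 * sum(dnorm(obs$dv, ipred, m$prop_sd * ipred, log = TRUE))
  expect_equal(ofv(st$data, m), direct, tolerance = 1e-10)
})

test_that("the generating parameters beat a perturbed clearance", {
  st <- make_study(dtg_model(), 100, 30, seed = 211)
  bad <- dtg_model()
  bad$theta$cl <- bad$theta$cl * 1.5
  expect_lt(ofv(st$data, dtg_model()), ofv(st$data, bad))
})

test_that("a neutral covariate term leaves the objective unchanged", {
  st <- make_study(dtg_model(), 15, 5, seed = 221)
  m2 <- dtg_model()
  m2$covariates <- c(m2$covariates,
                     list(covariate_term("cl", "age", "power",
                                         reference = 40, value = 0)))
  st$data$age <- 40 + (st$data$id %% 30)
  expect_equal(ofv(st$data, m2), ofv(st$data, dtg_model()), tolerance = 1e-8)
})

test_that("subjects without quantifiable observations are rejected", {
  st <- make_study(dtg_model(), 6, 2, seed = 231)
  d <- st$data
  d$mdv[d$id == 3 & d$evid == 0] <- 1
  expect_error(ofv(d, dtg_model()), "without quantifiable")
})

test_that("noise-free data recover the structural parameters exactly", {
  m <- dtg_model()
  m$omega[] <- 0
  m$prop_sd <- 1e-6
  st <- make_study(m, 12, 12, seed = 241)
  start <- m
  start$theta <- list(cl = 1.3, v2 = 25, ka = 1.2)
  f <- fit_pk_model(st$data, start,
                    fix = c("cl~weight", "cl~bilirubin",
                            "cl~ethnicity_hispanic", "v2~weight", "prop_sd"))
  est <- setNames(f$estimates$estimate, f$estimates$parameter)
  expect_equal(est[["cl"]], 0.858, tolerance = 1e-3)
  expect_equal(est[["v2"]], 16.7, tolerance = 1e-3)
  expect_equal(est[["ka"]], 2.15, tolerance = 1e-3)
})

test_that("freeing a parameter never worsens the minimised objective", {
  st <- make_study(toy_model(), 25, 0, seed = 251)
  st$data <- simulate_pk_dataset(toy_model(),
                                 draw_covariates(toy_popspec(25), seed = 251),
                                 toy_schedule(25), seed = 252)
  f_restricted <- fit_pk_model(st$data, toy_model(),
                               fix = c("v2", "ka", "prop_sd", "omega_cl"))
  f_free <- fit_pk_model(st$data, toy_model(),
                         fix = c("ka", "prop_sd", "omega_cl"))
  expect_lte(f_free$ofv, f_restricted$ofv + 0.1)
})

test_that("clearance bias shrinks with the sample size", {
  errs <- sapply(c(40, 160), function(n) {
    covs <- draw_covariates(toy_popspec(n), seed = 300 + n)
    dat <- simulate_pk_dataset(toy_model(), covs, toy_schedule(n),
                               seed = 301 + n)
    f <- fit_pk_model(dat, toy_model(), fix = c("v2", "ka", "prop_sd"))
    est <- setNames(f$estimates$estimate, f$estimates$parameter)
    abs(est[["cl"]] - 1)
  })
  expect_lt(errs[1], 0.2)
  expect_lt(errs[2], 0.1)
})

test_that("null covariate likelihood-ratio statistics are chi-square(1)", {
  # information-rich design; the approximation is known to inflate the
  # statistic on very sparse designs
  n <- 40
  base <- toy_model()
  cand <- covariate_term("cl", "weight", "power", reference = 78.8,
                         value = 0)
  ext <- base
  ext$covariates <- list(cand)
  fixall <- setdiff(c("cl", "v2", "ka", "cl~weight", "prop_sd", "omega_cl"),
                    "cl~weight")
  sch <- toy_schedule(n)
  spec <- toy_popspec(n)
  set.seed(99)
  dofv <- replicate(200, {
    covs <- draw_covariates(spec)
    dat <- simulate_pk_dataset(base, covs, sch)
    ofv(dat, base) - fit_pk_model(dat, ext, fix = fixall)$ofv
  })
  expect_true(all(dofv > -0.1))
  s <- sort(pmax(dofv, 0))
  theo <- qchisq(ppoints(200), df = 1)
  slope <- unname(coef(lm(s ~ 0 + theo))[1])
  expect_gt(slope, 0.85)
  expect_lt(slope, 1.15)
  # forward-selection false retention near the nominal 1% level
  expect_lte(mean(dofv >= 6.63), 0.04)
})

test_that("covariate search with no candidates returns the base model", {
  st <- make_study(dtg_model(), 10, 3, seed = 261)
  cs <- covariate_search(st$data, dtg_model(), list(), refit = "coef")
  expect_equal(length(cs$retained), 0)
  expect_equal(cs$ofv, ofv(st$data, dtg_model()), tolerance = 1e-6)
})

test_that("bootstrap resampling is deterministic and ordered", {
  n <- 20
  covs <- draw_covariates(toy_popspec(n), seed = 401)
  dat <- simulate_pk_dataset(toy_model(), covs, toy_schedule(n), seed = 402)
  b1 <- bootstrap_pk(dat, toy_model(), n_replicates = 8, seed = 5,
                     fix = c("v2", "ka", "prop_sd"))
  b2 <- bootstrap_pk(dat, toy_model(), n_replicates = 8, seed = 5,
                     fix = c("v2", "ka", "prop_sd"))
  expect_identical(b1$summary, b2$summary)
  expect_true(all(b1$summary$lo <= b1$summary$median))
  expect_true(all(b1$summary$median <= b1$summary$hi))
  expect_gt(b1$converged_fraction, 0.5)
  # median near the full-data point estimate
  f <- fit_pk_model(dat, toy_model(), fix = c("v2", "ka", "prop_sd"))
  est <- setNames(f$estimates$estimate, f$estimates$parameter)
  expect_equal(b1$summary$median[b1$summary$parameter == "cl"],
               est[["cl"]], tolerance = 0.1)
  expect_error(bootstrap_pk(dat, toy_model(), n_replicates = 1), "at least")
  one <- dat[dat$id == 1, ]
  expect_error(bootstrap_pk(one, toy_model(), n_replicates = 5),
               "two subjects")
})

test_that("standard errors are reported as percent RSE", {
  n <- 40
  covs <- draw_covariates(toy_popspec(n), seed = 421)
  dat <- simulate_pk_dataset(toy_model(), covs, toy_schedule(n), seed = 422)
  f <- fit_pk_model(dat, toy_model(), fix = c("v2", "ka", "prop_sd"),
                    se = TRUE)
  expect_true(all(c("se", "rse_pct") %in% names(f$estimates)))
  rse <- f$estimates$rse_pct[f$estimates$parameter == "cl"]
  expect_gt(rse, 0.5)
  expect_lt(rse, 25)
})
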
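test_that("continuous covariates hit the study medians and ranges", {
  spec <- population_spec()
  covs <- draw_covariates(spec, seed = 101)
  expect_equal(nrow(covs), 361)
  expect_gt(median(covs$weight), 78.8 * 0.95)
  expect_lt(median(covs$weight), 78.8 * 1.05)
  for (nm in names(spec$continuous)) {
    rng <- spec$continuous[[nm]]$range
    expect_true(all(covs[[nm]] >= rng[1] & covs[[nm]] <= rng[2]),
                label = paste(nm, "within range"))
    # sampling error of a log-normal median at n = 361: allow 5% or
    # 3.5 standard errors, whichever is larger (bilirubin's log-scale
    # spread makes a flat 5% a ~1.4-sigma band)
    sdlog <- (log(rng[2]) - log(rng[1])) / (2 * spec$z_range)
    tol <- max(0.05, 3.5 * 1.2533 * sdlog / sqrt(361))
    med <- spec$continuous[[nm]]$median
    expect_gt(median(covs[[nm]]), med * (1 - tol))
    expect_lt(median(covs[[nm]]), med * (1 + tol))
  }
  expect_true(all(covs$ethnicity_hispanic %in% 0:1))
  # BSA is computed from weight and height, not drawn
  expect_equal(covs$bsa, 0.007184 * covs$height^0.725 * covs$weight^0.425)
})

test_that("categorical proportions match at large n", {
  spec <- population_spec(n_subjects = 1e4)
  covs <- draw_covariates(spec, seed = 7)
  expect_equal(mean(covs$ethnicity_hispanic), 0.193, tolerance = 0.05)
  expect_lt(abs(mean(covs$ethnicity_hispanic) - 0.193), 0.01)
  expect_lt(abs(mean(covs$race_black) - 0.135), 0.015)
  expect_lt(abs(mean(covs$sex_male) - 0.931), 0.015)
  # mutually exclusive smoking categories
  expect_true(all(covs$smoker_current + covs$smoker_former <= 1))
})

test_that("degenerate range collapses to a point mass", {
  spec <- population_spec(
    n_subjects = 20, n_intensive = 0,
    continuous = list(weight = list(median = 70, range = c(70, 70))),
    proportions = list())
  covs <- draw_covariates(spec, seed = 1)
  expect_true(all(covs$weight == 70))
})

test_that("infeasible specifications are rejected", {
  expect_error(population_spec(
    continuous = list(weight = list(median = 40, range = c(50, 150)))),
    "outside")
  expect_error(population_spec(n_subjects = 10, n_intensive = 20), "exceed")
  expect_error(population_spec(proportions = list(race_black = 1.4)), "0, 1")
})

test_that("two independent large draws agree in distribution", {
  spec <- population_spec(n_subjects = 1e4)
  a <- draw_covariates(spec, seed = 21)
  b <- draw_covariates(spec, seed = 22)
  for (nm in c("weight", "bilirubin", "egfr")) {
    d <- suppressWarnings(ks.test(a[[nm]], b[[nm]])$statistic)
    expect_lt(d, 0.03)
  }
})

test_that("schedules implement the intensive/sparse visit structure", {
  sch <- assign_schedules(361, 30, seed = 3)
  n_int <- length(unique(sch$id[sch$design == "intensive"]))
  expect_equal(n_int, 30)
  expect_equal(sort(unique(sch$week)), c(4, 8, 12, 24, 36, 48))
  # intensive week-4 grid
  iid <- unique(sch$id[sch$design == "intensive"])[1]
  expect_equal(sort(sch$time[sch$id == iid & sch$week == 4]),
               c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 10, 24))
  # sparse week 4 is pre-dose and 1 h; late visits are pre-dose
  sid <- setdiff(unique(sch$id), iid)[1]
  expect_equal(sort(sch$time[sch$id == sid & sch$week == 4]), c(0, 1))
  expect_true(all(sch$time[sch$week %in% c(24, 36, 48)] == 0))
  # week 8/12 windows: one early (1-4 h), one mid (4-12 h) per subject
  for (s in unique(sch$id)[1:5]) {
    t8 <- sch$time[sch$id == s & sch$week == 8]
    t12 <- sch$time[sch$id == s & sch$week == 12]
    expect_true((t8 >= 1 & t8 <= 4 & t12 >= 4 & t12 <= 12) ||
                  (t8 >= 4 & t8 <= 12 & t12 >= 1 & t12 <= 4))
  }
  expect_true(all(sch$time >= 0 & sch$time <= 24))
  # all-sparse design
  sch0 <- assign_schedules(10, 0, seed = 4)
  expect_equal(sum(sch0$design == "intensive"), 0)
})

test_that("noise-free simulation returns the typical predictions", {
  m <- dtg_model()
  m$omega[] <- 0
  m$prop_sd <- 0
  covs <- draw_covariates(population_spec(5, 2), seed = 9)
  sch <- assign_schedules(5, 2, seed = 10)
  dat <- simulate_pk_dataset(m, covs, sch, seed = 11)
  obs <- dat[dat$evid == 0, ]
  p <- individual_params(m, covs)
  expected <- css_one_compartment(p[match(obs$id, covs$id), ], 50, 24,
                                  obs$tad)
  expect_equal(obs$dv, expected)
})

test_that("simulation is reproducible under a fixed seed", {
  st <- make_study(dtg_model(), 20, 5, seed = 77)
  st2 <- make_study(dtg_model(), 20, 5, seed = 77)
  expect_identical(st$data, st2$data)
  st3 <- make_study(dtg_model(), 20, 5, seed = 78)
  expect_false(identical(st3$data$dv, st$data$dv))
})

test_that("quantification flagging is rare for dolutegravir troughs", {
  m <- dtg_model()
  covs <- draw_covariates(population_spec(500, 0), seed = 31)
  sch <- data.frame(id = rep(1:500, each = 3), week = rep(c(24, 36, 48), 500),
                    design = "sparse", time = 0)
  dat <- simulate_pk_dataset(m, covs, sch, seed = 32)
  obs <- dat[dat$evid == 0, ]
  expect_lt(mean(obs$blq), 0.01)
  expect_true(all(obs$blq == as.integer(obs$dv < 0.020)))
  expect_true(all(obs$mdv[obs$blq == 1] == 1))
})

test_that("dosing rows precede observations with steady-state flags", {
  st <- make_study(lam_model(), 8, 2, seed = 55)
  d <- st$data
  expect_true(all(d$ss[d$evid == 1] == 1))
  expect_true(all(d$ii[d$evid == 1] == 24))
  for (s in unique(d$id)) {
    b <- d[d$id == s, ]
    expect_true(all(diff(b$time) >= 0))
    expect_lte(min(b$time[b$evid == 1]), min(b$time[b$evid == 0]))
  }
})
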
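# Virtual-population generator emulating the steady-state PK substudy
# design: 361 virologically suppressed adults on once-daily dolutegravir
# 50 mg / lamivudine 300 mg, with a 30-subject intensive-sampling subset
# and sparse sampling windows for everyone else.

#' Specification of a virtual study population
#'
#' Defaults encode the analysis population demographics: continuous
#' covariates are summarised by their median and observed range, categorical
#' covariates by their observed proportions. Continuous covariates are drawn
#' from truncated log-normal distributions whose median equals the study
#' median and whose range endpoints sit roughly 2.7 SD from the median on
#' the log scale (the expected extremes of a sample of a few hundred).
#'
#' Renal function is drawn jointly with race: the study computed eGFR with
#' the 2009 CKD-EPI equation, whose Black-race coefficient (1.159) makes
#' eGFR systematically higher for Black/African American subjects. The
#' generator reproduces this by scaling a common base draw by 1.159 for
#' Black subjects (capped at the observed maximum), with the base median
#' chosen so the overall median still matches the study value.
#'
#' @param n_subjects number of subjects (default 361).
#' @param n_intensive size of the intensive-sampling subset (default 30).
#' @param continuous named list; each element `list(median=, range=c(lo,hi))`.
#' @param proportions named list of Bernoulli/categorical probabilities.
#' @param z_range how many log-scale SDs the range endpoints represent.
#' @param egfr_race_factor CKD-EPI race coefficient applied to the eGFR of
#'   Black/African American subjects (set to 1 to draw eGFR independently).
#' @return list of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 361, n_intensive = 30,
                            continuous = list(
                              weight = list(median = 78.8, range = c(50.2, 153.0)),
                              height = list(median = 176.5, range = c(150.0, 195.6)),
                              bilirubin = list(median = 8.0, range = c(2.0, 34.0)),
                              egfr = list(median = 99.0, range = c(44.0, 147.0)),
                              age = list(median = 40, range = c(20, 74)),
                              crcl = list(median = 113.9, range = c(56.3, 355.9)),
                              albumin = list(median = 45.0, range = c(37.0, 53.0))
                            ),
                            proportions = list(
                              ethnicity_hispanic = 0.193,
                              race_black = 0.135,
                              sex_male = 0.931,
                              smoker_current = 0.315,
                              smoker_former = 0.188,
                              cdc_class1 = 0.688
                            ),
                            z_range = 2.7, egfr_race_factor = 1.159) {
  for (nm in names(continuous)) {
    cc <- continuous[[nm]]
    if (cc$median < cc$range[1] || cc$median > cc$range[2])
      stop("median of '", nm, "' lies outside its range")
  }
  if (any(unlist(proportions) < 0 | unlist(proportions) > 1))
    stop("proportions must lie in [0, 1]")
  if (n_intensive > n_subjects) stop("n_intensive cannot exceed n_subjects")
  structure(list(n_subjects = n_subjects, n_intensive = n_intensive,
                 continuous = continuous, proportions = proportions,
                 z_range = z_range, egfr_race_factor = egfr_race_factor),
            class = "population_spec")
}

# Truncated log-normal draw: median-anchored, truncated to the stated range.
rtrunc_lnorm <- function(n, median, range, z_range) {
  if (range[1] == range[2]) return(rep(range[1], n))
  meanlog <- log(median)
  sdlog <- (log(range[2]) - log(range[1])) / (2 * z_range)
  plo <- stats::pnorm((log(range[1]) - meanlog) / sdlog)
  phi <- stats::pnorm((log(range[2]) - meanlog) / sdlog)
  u <- stats::runif(n, plo, phi)
  exp(meanlog + sdlog * stats::qnorm(u))
}

#' Draw baseline covariates for a virtual population
#'
#' Continuous covariates are truncated log-normal calibrated to the study
#' median and range; indicators are Bernoulli at the study proportions.
#' Body surface area is computed from weight and height (DuBois), not drawn,
#' so weight/height/BSA stay mutually consistent; other correlations are not
#' imposed.
#'
#' @param spec a [population_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return data.frame with one row per subject: `id`, the continuous
#'   covariates, `bsa`, `bmi`, and indicator columns.
#' @export
draw_covariates <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  out <- data.frame(id = seq_len(n))
  pr <- spec$proportions
  simple <- setdiff(names(pr), c("smoker_current", "smoker_former"))
  for (nm in simple) out[[nm]] <- stats::rbinom(n, 1, pr[[nm]])
  if (all(c("smoker_current", "smoker_former") %in% names(pr))) {
    u <- stats::runif(n)
    out$smoker_current <- as.integer(u < pr$smoker_current)
    out$smoker_former <- as.integer(u >= pr$smoker_current &
                                      u < pr$smoker_current + pr$smoker_former)
  }
  fac <- spec$egfr_race_factor
  couple_egfr <- "egfr" %in% names(spec$continuous) &&
    "race_black" %in% names(out) && !is.null(fac) && fac != 1
  for (nm in names(spec$continuous)) {
    cc <- spec$continuous[[nm]]
    if (nm == "egfr" && couple_egfr) {
      # CKD-EPI race coefficient: common base draw, scaled for Black
      # subjects; base median set so the overall median stays on target
      p_black <- mean(out$race_black)
      base_med <- cc$median / fac^p_black
      base <- rtrunc_lnorm(n, base_med, cc$range, spec$z_range)
      out[[nm]] <- pmin(base * fac^out$race_black, cc$range[2])
    } else {
      out[[nm]] <- rtrunc_lnorm(n, cc$median, cc$range, spec$z_range)
    }
  }
  if (all(c("weight", "height") %in% names(out))) {
    out$bsa <- 0.007184 * out$height^0.725 * out$weight^0.425
    out$bmi <- out$weight / (out$height / 100)^2
  }
  out
}

#' Assign intensive/sparse sampling schedules
#'
#' A random subset of `n_intensive` subjects receives the intensive week-4
#' profile (pre-dose, 0.5, 1, 1.5, 2, 3, 4, 6, 10 and 24 h post-dose); all
#' subjects contribute sparse samples: week 4 pre-dose and 1 h, weeks 8 and
#' 12 one sample each in the 1-4 h and 4-12 h windows (window order
#' alternating between subjects), and weeks 24, 36 and 48 pre-dose. Sparse
#' times are drawn uniformly within their window; point times are exact.
#'
#' @param n_subjects,n_intensive counts.
#' @param seed optional integer seed.
#' @return data.frame with columns `id`, `week`, `design`
#'   (`"intensive"`/`"sparse"`), `time` (h post-dose within the interval).
#' @export
assign_schedules <- function(n_subjects, n_intensive, seed = NULL) {
  if (n_intensive > n_subjects) stop("n_intensive cannot exceed n_subjects")
  if (!is.null(seed)) set.seed(seed)
  intensive_ids <- if (n_intensive > 0)
    sort(sample.int(n_subjects, n_intensive)) else integer(0)
  intensive_times <- c(0, 0.5, 1, 1.5, 2, 3, 4, 6, 10, 24)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    early_first <- i %% 2L == 1L  # alternate the week-8/12 window pairing
    w8 <- if (early_first) c(1, 4) else c(4, 12)
    w12 <- if (early_first) c(4, 12) else c(1, 4)
    if (i %in% intensive_ids) {
      wk4 <- data.frame(week = 4, design = "intensive", time = intensive_times)
    } else {
      wk4 <- data.frame(week = 4, design = "sparse", time = c(0, 1))
    }
    sp <- data.frame(
      week = c(8, 12, 24, 36, 48), design = "sparse",
      time = c(stats::runif(1, w8[1], w8[2]), stats::runif(1, w12[1], w12[2]),
               0, 0, 0))
    r <- rbind(wk4, sp)
    r$id <- i
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("id", "week", "design", "time")]
}

#' Simulate an estimation-ready steady-state PK dataset
#'
#' For each subject, random effects are drawn jointly normal from the model
#' omega block, individual parameters built from the covariates, the
#' steady-state profile evaluated at the scheduled times, and proportional
#' residual error applied. Observations below the assay LLOQ are flagged
#' (`blq = 1`, `mdv = 1`) and left in the table; estimation excludes them.
#'
#' @param model a [pk_model()].
#' @param covariates covariate table from [draw_covariates()] (column `id`).
#' @param schedules schedule table from [assign_schedules()].
#' @param dose,tau dosing regimen; default from the model.
#' @param lloq quantification limit (ug/mL); default from the model.
#' @param seed optional integer seed.
#' @return event-record data.frame with columns `id`, `week`, `design`,
#'   `time` (h since first dose), `tad` (h after dose), `amt`, `evid`,
#'   `mdv`, `dv`, `blq`, plus the subject covariate columns. Each visit has
#'   a steady-state dosing row (`evid = 1`, `ss = 1`, `ii = tau`) preceding
#'   its observations.
#' @export
simulate_pk_dataset <- function(model, covariates, schedules,
                                dose = model$dose, tau = model$tau,
                                lloq = model$lloq, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(schedules$id %in% covariates$id))
    stop("schedules reference subjects missing from the covariate table")
  n <- nrow(covariates)
  eta <- draw_eta(model, n)
  params <- individual_params(model, covariates, eta)
  sidx <- match(schedules$id, covariates$id)
  ipred <- conc_at(model, params[sidx, , drop = FALSE], schedules$time,
                   dose = dose, tau = tau)
  eps <- stats::rnorm(nrow(schedules))
  dv <- apply_residual_error(ipred, model$prop_sd,
                             params$ruv_scale[sidx], eps)
  blq <- as.integer(!is.na(lloq) & dv < lloq)
  obs <- data.frame(id = schedules$id, week = schedules$week,
                    design = schedules$design,
                    time = schedules$week * 168 + schedules$time,
                    tad = schedules$time, amt = 0, evid = 0L, ss = 0L,
                    ii = 0, mdv = blq, dv = dv, blq = blq)
  dose_rows <- unique(obs[, c("id", "week", "design")])
  dose_rows <- data.frame(id = dose_rows$id, week = dose_rows$week,
                          design = dose_rows$design,
                          time = dose_rows$week * 168, tad = 0, amt = dose,
                          evid = 1L, ss = 1L, ii = tau, mdv = 1L,
                          dv = NA_real_, blq = 0L)
  dat <- rbind(dose_rows, obs)
  dat <- dat[order(dat$id, dat$time, -dat$evid), ]
  rownames(dat) <- NULL
  dat <- merge(dat, covariates, by = "id", sort = FALSE)
  attr(dat, "drug") <- model$drug
  attr(dat, "eta") <- eta
  dat
}

# Joint normal draw of the model's random effects (rows = subjects).
draw_eta <- function(model, n) {
  om <- model$omega
  en <- rownames(om)
  eta <- matrix(0, n, length(en), dimnames = list(NULL, en))
  act <- diag(om) > 0
  if (any(act)) {
    blk <- om[act, act, drop = FALSE]
    eta[, act] <- MASS::mvrnorm(n, mu = rep(0, sum(act)), Sigma = blk)
  }
  eta
}
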
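# Shared fixtures: small simulated studies built in code.

ref_dtg_cov <- data.frame(id = 1, weight = 79, bilirubin = 8,
                          ethnicity_hispanic = 0)
ref_lam_cov <- data.frame(id = 1, weight = 70, egfr = 99, race_black = 0)

# Simulated study of the given size under the final model truths.
make_study <- function(model, n, n_intensive, seed) {
  spec <- population_spec(n_subjects = n, n_intensive = n_intensive)
  covs <- draw_covariates(spec, seed = seed)
  sched <- assign_schedules(n, n_intensive, seed = seed + 1L)
  dat <- simulate_pk_dataset(model, covs, sched, seed = seed + 2L)
  list(model = model, covs = covs, sched = sched, data = dat)
}

# Minimal one-eta model on a rich fixed grid, for estimation properties.
toy_model <- function(omega_cl = 0.09, prop_sd = 0.15) {
  om <- matrix(omega_cl, 1, 1, dimnames = list("eta_cl", "eta_cl"))
  pk_model("toy", 1, list(cl = 1, v2 = 20, ka = 1.5), "none",
           list(), om, prop_sd = prop_sd, dose = 100, tau = 24)
}

toy_schedule <- function(n, times = c(0.5, 1, 2, 4, 6, 10, 16, 24)) {
  do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(id = i, week = 4, design = "sparse", time = times)))
}

toy_popspec <- function(n) {
  population_spec(n, 0,
                  continuous = list(weight = list(median = 78.8,
                                                  range = c(50, 153))),
                  proportions = list())
}
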
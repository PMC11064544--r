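# End-to-end pipeline driver: simulate -> fit -> covsearch -> bootstrap ->
# nca -> forest -> vpc -> npde, configured by a list or YAML file, with
# deterministic stage seeds derived from one base seed and a config hash
# stamped into every run.

#' Run the analysis pipeline
#'
#' Executes the configured stages in order, writing each stage's artifacts
#' (CSV/YAML) and a run log into `out_dir`. Stage seeds are derived
#' deterministically from the base seed so a rerun with the same
#' configuration reproduces every artifact bit for bit.
#'
#' @param config list or path to a YAML file with fields:
#'   `drug` (`"dtg"` or `"3tc"`), `out_dir`, `seed`, `stages` (subset of
#'   simulate, fit, covsearch, bootstrap, nca, forest, vpc, npde; default
#'   all), `n_subjects`, `n_intensive`, and optional `n_trials`,
#'   `n_sim`, `n_replicates`, `fix`, `control`, `candidates`.
#' @return named list of stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(stages = c("simulate", "nca"), n_subjects = 361,
                   n_intensive = 30, seed = 1L, n_trials = 200,
                   n_sim = 200, n_replicates = 50, fix = character(),
                   control = list())
  config <- utils::modifyList(defaults, config)
  if (is.null(config$drug) || !config$drug %in% c("dtg", "3tc"))
    stop("config$drug must be 'dtg' or '3tc'")
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  model <- if (config$drug == "dtg") dtg_model() else lam_model()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(config[order(names(config))], cfg_path)
  # hash the scientific configuration only, not where it is written
  hcfg <- config[setdiff(sort(names(config)), "out_dir")]
  htmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(hcfg, htmp)
  cfg_hash <- unname(tools::md5sum(htmp))
  unlink(htmp)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("pipeline run | drug %s | seed %d | config %s\n",
              config$drug, config$seed, cfg_hash),
      file = log_path)
  seed_for <- function(stage)
    (config$seed * 97L + match(stage, c("simulate", "fit", "covsearch",
                                        "bootstrap", "nca", "forest",
                                        "vpc", "npde")) * 1009L) %% 2147483647L
  out <- list(config_hash = cfg_hash)
  t0 <- proc.time()[["elapsed"]]
  stage_done <- function(stage) {
    logf("stage %s done at %.1f s", stage, proc.time()[["elapsed"]] - t0)
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  spec <- population_spec(n_subjects = config$n_subjects,
                          n_intensive = config$n_intensive)
  covs <- wrap("simulate", draw_covariates(spec, seed = seed_for("simulate")))
  sched <- assign_schedules(config$n_subjects, config$n_intensive,
                            seed = seed_for("simulate") + 1L)
  if ("simulate" %in% config$stages) {
    dat <- wrap("simulate",
                simulate_pk_dataset(model, covs, sched,
                                    seed = seed_for("simulate") + 2L))
    write_pk_dataset(dat, file.path(config$out_dir, "dataset.csv"))
    utils::write.csv(covs, file.path(config$out_dir, "covariates.csv"),
                     row.names = FALSE)
    out$dataset <- dat
    stage_done("simulate")
  } else dat <- NULL
  fit <- NULL
  if ("fit" %in% config$stages) {
    if (is.null(dat)) stop("pipeline stage 'fit' requires stage 'simulate'")
    fit <- wrap("fit", fit_pk_model(dat, model, fix = config$fix,
                                    control = config$control))
    logf("fit OFV %.3f converged %s", fit$ofv, fit$converged)
    utils::write.csv(fit$estimates,
                     file.path(config$out_dir, "fit_estimates.csv"),
                     row.names = FALSE)
    out$fit <- fit
    stage_done("fit")
  }
  if ("covsearch" %in% config$stages) {
    if (is.null(dat)) stop("pipeline stage 'covsearch' requires stage 'simulate'")
    cand <- config$candidates
    if (is.null(cand)) stop("covsearch stage needs config$candidates")
    cand <- lapply(cand, function(x)
      covariate_term(x$target, x$covariate, x$form,
                     reference = if (is.null(x$reference)) NA_real_ else x$reference,
                     value = if (is.null(x$value)) 0 else x$value))
    cs <- wrap("covsearch",
               covariate_search(dat, model, cand, fix = config$fix,
                                control = config$control))
    utils::write.csv(cs$steps, file.path(config$out_dir, "covsearch_steps.csv"),
                     row.names = FALSE)
    for (s in seq_len(nrow(cs$steps)))
      logf("covsearch %s %s dOFV %.3f accepted %s", cs$steps$phase[s],
           cs$steps$term[s], cs$steps$dofv[s], cs$steps$accepted[s])
    out$covsearch <- cs
    stage_done("covsearch")
  }
  if ("bootstrap" %in% config$stages) {
    if (is.null(dat)) stop("pipeline stage 'bootstrap' requires stage 'simulate'")
    bs <- wrap("bootstrap",
               bootstrap_pk(dat, model, config$n_replicates,
                            seed = seed_for("bootstrap"), fix = config$fix,
                            control = config$control))
    utils::write.csv(bs$summary, file.path(config$out_dir, "bootstrap.csv"),
                     row.names = FALSE)
    out$bootstrap <- bs
    stage_done("bootstrap")
  }
  if ("nca" %in% config$stages) {
    exp_tab <- wrap("nca", simulate_exposure(model, covs,
                                             seed = seed_for("nca")))
    utils::write.csv(exp_tab, file.path(config$out_dir, "exposure.csv"),
                     row.names = FALSE)
    summ <- summarize_exposure(exp_tab)
    utils::write.csv(summ, file.path(config$out_dir, "exposure_summary.csv"),
                     row.names = FALSE)
    logf("nca geomean AUC %.3f Cmax %.3f Ctau %.4f",
         summ$geomean[summ$metric == "auc"],
         summ$geomean[summ$metric == "cmax"],
         summ$geomean[summ$metric == "ctau"])
    out$nca <- exp_tab
    stage_done("nca")
  }
  if ("forest" %in% config$stages) {
    fs <- wrap("forest", forest_simulation(model, covs,
                                           n_trials = config$n_trials,
                                           seed = seed_for("forest")))
    utils::write.csv(fs$summary, file.path(config$out_dir, "forest.csv"),
                     row.names = FALSE)
    out$forest <- fs
    stage_done("forest")
  }
  if ("vpc" %in% config$stages) {
    if (is.null(dat)) stop("pipeline stage 'vpc' requires stage 'simulate'")
    v <- wrap("vpc", pcvpc(dat, if (!is.null(fit)) fit$model else model,
                           n_sim = config$n_sim, seed = seed_for("vpc")))
    utils::write.csv(v$bins, file.path(config$out_dir, "pcvpc.csv"),
                     row.names = FALSE)
    out$vpc <- v
    stage_done("vpc")
  }
  if ("npde" %in% config$stages) {
    if (is.null(dat)) stop("pipeline stage 'npde' requires stage 'simulate'")
    nd <- wrap("npde", npde(dat, if (!is.null(fit)) fit$model else model,
                            n_sim = max(config$n_sim, 500),
                            seed = seed_for("npde")))
    utils::write.csv(nd$npde, file.path(config$out_dir, "npde.csv"),
                     row.names = FALSE)
    logf("npde mean %.3f var %.3f ks_p %.3g", nd$mean, nd$var, nd$ks_p)
    out$npde <- nd
    stage_done("npde")
  }
  invisible(out)
}
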
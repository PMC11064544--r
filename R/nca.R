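# Steady-state exposure metrics (AUC0-tau, Cmax, Ctau) from model-predicted
# profiles on the standard 9-point grid, grouped summaries, and the
# covariate forest-plot trial simulation.

NCA_GRID <- c(0, 1, 2, 3, 4, 6, 8, 12, 24)

#' Predict a steady-state profile on the standard grid
#'
#' @param model a [pk_model()].
#' @param params individual parameter table ([individual_params()]).
#' @param times prediction grid (h), default 0, 1, 2, 3, 4, 6, 8, 12, 24.
#' @param dose,tau regimen; default from the model.
#' @return matrix of concentrations, one row per subject, columns named by
#'   time.
#' @export
predict_profile <- function(model, params, times = NCA_GRID,
                            dose = model$dose, tau = model$tau) {
  out <- conc_matrix(model, params, times, dose, tau)
  colnames(out) <- as.character(times)
  out
}

#' Linear-up/log-down trapezoidal AUC
#'
#' Each segment uses the linear trapezoid when the concentration is rising
#' (or either endpoint is non-positive) and the logarithmic trapezoid
#' `(C1 - C2) * dt / log(C1 / C2)` when it is falling with both endpoints
#' positive.
#'
#' @param times strictly increasing sampling times (h).
#' @param conc concentrations at `times`.
#' @return area under the curve (concentration x h).
#' @examples
#' auc_linear_up_log_down(c(0, 1), c(2, 1))  # (2-1)/log(2)
#' @export
auc_linear_up_log_down <- function(times, conc) {
  if (length(times) < 2) stop("need at least two points")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  c1 <- conc[-length(conc)]; c2 <- conc[-1]
  dt <- diff(times)
  lin <- (c1 + c2) / 2 * dt
  logseg <- c2 < c1 & c1 > 0 & c2 > 0
  out <- lin
  out[logseg] <- (c1[logseg] - c2[logseg]) * dt[logseg] /
    log(c1[logseg] / c2[logseg])
  sum(out)
}

#' Noncompartmental exposure metrics from a gridded profile
#'
#' `auc` by [auc_linear_up_log_down()], `cmax` as the grid maximum, `ctau`
#' as the concentration at the end of the interval (last grid time).
#'
#' @param times sampling grid (h).
#' @param conc concentration vector, or a matrix with one row per subject.
#' @return data.frame with columns `auc`, `cmax`, `ctau`.
#' @export
exposure_metrics <- function(times, conc) {
  if (is.matrix(conc)) {
    data.frame(auc = apply(conc, 1, function(x) auc_linear_up_log_down(times, x)),
               cmax = apply(conc, 1, max),
               ctau = conc[, length(times)])
  } else {
    data.frame(auc = auc_linear_up_log_down(times, conc),
               cmax = max(conc), ctau = conc[length(times)])
  }
}

#' Per-subject steady-state exposure from a model
#'
#' Builds individual parameters from covariates and random effects, predicts
#' the 9-point steady-state profile and derives the exposure metrics. With
#' `eta = "draw"` random effects are redrawn (pure simulation); a matrix of
#' empirical Bayes estimates gives the post hoc path; `NULL` gives typical
#' values.
#'
#' @param model a [pk_model()].
#' @param covariates covariate table with column `id`.
#' @param eta `"draw"`, `NULL`, or an n-by-q matrix of random effects.
#' @param seed optional seed used when `eta = "draw"`.
#' @return data.frame: `id`, `auc` (ug*h/mL), `cmax`, `ctau` (ug/mL) and the
#'   covariate columns.
#' @export
simulate_exposure <- function(model, covariates, eta = "draw", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (identical(eta, "draw")) eta <- draw_eta(model, nrow(covariates))
  params <- individual_params(model, covariates, eta)
  prof <- predict_profile(model, params)
  met <- exposure_metrics(NCA_GRID, prof)
  cbind(data.frame(id = covariates$id), met,
        covariates[, setdiff(names(covariates), "id"), drop = FALSE])
}

#' Geometric mean
#' @param x positive values.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) exp(mean(log(x)))

#' Summarise exposure metrics by covariate group
#'
#' Geometric mean and 95% CI (t-interval on the log scale) of each metric
#' per group. Continuous grouping covariates are split at sample quartiles
#' (boundary values fall in the lower bin).
#'
#' @param records exposure table ([simulate_exposure()]).
#' @param by name of the grouping column in `records`; `NULL` summarises
#'   the whole table as one group.
#' @param metrics metric columns to summarise.
#' @return data.frame: `group`, `metric`, `n`, `geomean`, `lo`, `hi`.
#' @export
summarize_exposure <- function(records, by = NULL,
                               metrics = c("auc", "cmax", "ctau")) {
  grp <- if (is.null(by)) factor(rep("all", nrow(records)))
         else group_labels(records[[by]])
  out <- list()
  for (g in levels(grp)) {
    sel <- grp == g
    if (!any(sel)) next
    for (mname in metrics) {
      x <- records[[mname]][sel]
      if (any(x <= 0)) stop("non-positive ", mname, " in group ", g)
      lx <- log(x)
      se <- if (length(lx) > 1) stats::sd(lx) / sqrt(length(lx)) else 0
      hw <- if (length(lx) > 1) stats::qt(0.975, length(lx) - 1) * se else 0
      out[[length(out) + 1]] <- data.frame(
        group = g, metric = mname, n = sum(sel),
        geomean = exp(mean(lx)), lo = exp(mean(lx) - hw),
        hi = exp(mean(lx) + hw))
    }
  }
  do.call(rbind, out)
}

# Factor labels for a grouping covariate: indicators keep 0/1, continuous
# covariates are cut at sample quartiles with ties to the lower bin.
group_labels <- function(x) {
  if (all(x %in% c(0, 1))) return(factor(x, levels = c(0, 1)))
  br <- unique(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1)))
  cut(x, breaks = br, include.lowest = TRUE, right = TRUE,
      labels = paste0("Q", seq_len(length(br) - 1)))
}

#' Covariate-effect trial simulation for forest plots
#'
#' Repeats the study `n_trials` times: each trial redraws every subject's
#' random effects, computes steady-state exposure metrics, and takes the
#' geometric mean per covariate category (indicators) or quartile
#' (continuous covariates), plus the overall population. Each trial's
#' category geometric means are normalised by the median across trials of
#' the overall-population geometric mean; the summary reports the median
#' and 2.5th/97.5th percentiles of the normalised values, to be judged
#' against the 0.8-1.25 bioequivalence band.
#'
#' @param model a [pk_model()].
#' @param covariates covariate table (the fixed virtual population).
#' @param group_vars covariate columns defining the categories; defaults to
#'   the covariates in the model's terms.
#' @param n_trials number of simulated trials (>= 2).
#' @param seed optional integer seed.
#' @return list of class `forest_summary`: `summary` data.frame
#'   (`metric`, `covariate`, `category`, `n_subjects`, `median`, `lo`,
#'   `hi`), `reference` (per-metric normalising constants), `n_trials`.
#' @export
forest_simulation <- function(model, covariates, group_vars = NULL,
                              n_trials = 1000, seed = NULL) {
  if (n_trials < 2) stop("n_trials must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(group_vars))
    group_vars <- unique(vapply(model$covariates, `[[`, "", "covariate"))
  n <- nrow(covariates)
  groups <- lapply(group_vars, function(v) group_labels(covariates[[v]]))
  names(groups) <- group_vars
  metrics <- c("auc", "cmax", "ctau")
  cells <- c("overall", unlist(lapply(group_vars, function(v)
    paste0(v, ":", levels(groups[[v]])))))
  res <- array(NA_real_, dim = c(n_trials, length(cells), 3),
               dimnames = list(NULL, cells, metrics))
  for (tr in seq_len(n_trials)) {
    eta <- draw_eta(model, n)
    params <- individual_params(model, covariates, eta)
    prof <- predict_profile(model, params)
    met <- exposure_metrics(NCA_GRID, prof)
    for (mname in metrics) {
      x <- log(met[[mname]])
      res[tr, "overall", mname] <- exp(mean(x))
      for (v in group_vars) for (g in levels(groups[[v]]))
        res[tr, paste0(v, ":", g), mname] <- exp(mean(x[groups[[v]] == g]))
    }
  }
  ref <- apply(res[, "overall", , drop = FALSE], 3, stats::median)
  rows <- list()
  for (mname in metrics) for (cell in cells) {
    norm <- res[, cell, mname] / ref[[mname]]
    cv <- strsplit(cell, ":", fixed = TRUE)[[1]]
    nsub <- if (cell == "overall") n else {
      v <- cv[1]; sum(groups[[v]] == cv[2])
    }
    rows[[length(rows) + 1]] <- data.frame(
      metric = mname, covariate = cv[1],
      category = if (length(cv) > 1) cv[2] else "overall",
      n_subjects = nsub,
      median = stats::median(norm),
      lo = stats::quantile(norm, 0.025, names = FALSE),
      hi = stats::quantile(norm, 0.975, names = FALSE))
  }
  structure(list(summary = do.call(rbind, rows), reference = ref,
                 n_trials = n_trials), class = "forest_summary")
}

#' @export
print.forest_summary <- function(x, ...) {
  cat(sprintf("Covariate forest simulation: %d trials\n", x$n_trials))
  cat(sprintf("Reference (median of overall geometric means): AUC %.3g, Cmax %.3g, Ctau %.3g\n",
              x$reference[["auc"]], x$reference[["cmax"]], x$reference[["ctau"]]))
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
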
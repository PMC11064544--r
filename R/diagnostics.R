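# Model-evaluation operators: prediction-corrected visual predictive check,
# normalised prediction distribution errors, and goodness-of-fit summaries.

# Simulate replicate observation vectors under `model` for the design
# (subjects, times, covariates) of `data`. Returns n_obs x n_sim matrix
# aligned with the observation rows of `data` (evid == 0, mdv == 0).
simulate_replicates <- function(data, model, n_sim, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- data[data$evid == 0 & data$mdv == 0, , drop = FALSE]
  covnames <- unique(vapply(model$covariates, `[[`, "", "covariate"))
  ids <- unique(obs$id)
  n <- length(ids)
  sidx <- match(obs$id, ids)
  cov1 <- obs[match(ids, obs$id), covnames, drop = FALSE]
  out <- matrix(NA_real_, nrow(obs), n_sim)
  for (s in seq_len(n_sim)) {
    eta <- draw_eta(model, n)
    params <- individual_params(model, cov1, eta)
    ipred <- conc_at(model, params[sidx, , drop = FALSE], obs$tad)
    eps <- stats::rnorm(nrow(obs))
    out[, s] <- apply_residual_error(ipred, model$prop_sd,
                                     params$ruv_scale[sidx], eps)
  }
  list(obs = obs, sims = out, ids = ids, subject_index = sidx)
}

# Typical-value (eta = 0) predictions for the observation rows.
typical_pred <- function(obs, model) {
  covnames <- unique(vapply(model$covariates, `[[`, "", "covariate"))
  ids <- unique(obs$id)
  cov1 <- obs[match(ids, obs$id), covnames, drop = FALSE]
  params <- individual_params(model, cov1)
  conc_at(model, params[match(obs$id, ids), , drop = FALSE], obs$tad)
}

#' Prediction-corrected visual predictive check
#'
#' Observations (and every simulated replicate) are prediction-corrected by
#' scaling each value with the ratio of its time-bin's median typical-value
#' prediction to the record's own typical-value prediction. Time bins are
#' quantile-based on time after dose, merging bins below a minimum count.
#' The result holds the observed 5th/50th/95th percentiles per bin and a
#' simulation-based confidence interval for each percentile.
#'
#' @param data event-record dataset.
#' @param model evaluated [pk_model()].
#' @param n_sim number of replicate studies (>= 100).
#' @param bins target number of quantile time bins.
#' @param min_bin minimum observations per bin before merging.
#' @param ci confidence level for the simulation bands.
#' @param seed optional integer seed.
#' @return list of class `pcvpc_result` with `bins` (data.frame: bin edges,
#'   n, observed p5/p50/p95, and lo/hi of each percentile's simulation CI)
#'   and `corrected` (per-observation corrected values).
#' @export
pcvpc <- function(data, model, n_sim = 200, bins = 8, min_bin = 10,
                  ci = 0.95, seed = NULL) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  rep <- simulate_replicates(data, model, n_sim, seed)
  obs <- rep$obs
  pred <- typical_pred(obs, model)
  edges <- unique(stats::quantile(obs$tad, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(obs$tad, breaks = edges, include.lowest = TRUE)
  # merge sparse bins into their left neighbour
  repeat {
    cnt <- table(bin)
    small <- which(cnt < min_bin)
    if (!length(small) || length(levels(bin)) == 1) break
    i <- small[1]
    j <- if (i == 1) 2 else i - 1
    lev <- levels(bin)
    lev[lev == lev[i]] <- lev[j]
    levels(bin) <- lev
  }
  binmed <- tapply(pred, bin, stats::median)
  corr <- as.numeric(binmed[bin]) / pred
  pc_obs <- obs$dv * corr
  pc_sim <- rep$sims * corr
  qs <- c(0.05, 0.5, 0.95)
  lvl <- levels(droplevels(bin))
  a <- (1 - ci) / 2
  rows <- lapply(lvl, function(g) {
    sel <- bin == g
    if (!any(sel)) stop("empty time bin: ", g)
    op <- stats::quantile(pc_obs[sel], qs, names = FALSE)
    sim_q <- apply(pc_sim[sel, , drop = FALSE], 2, stats::quantile, qs)
    cis <- apply(sim_q, 1, stats::quantile, c(a, 1 - a))
    data.frame(bin = g, t_mid = stats::median(obs$tad[sel]), n = sum(sel),
               obs_p5 = op[1], obs_p50 = op[2], obs_p95 = op[3],
               p5_lo = cis[1, 1], p5_hi = cis[2, 1],
               p50_lo = cis[1, 2], p50_hi = cis[2, 2],
               p95_lo = cis[1, 3], p95_hi = cis[2, 3])
  })
  structure(list(bins = do.call(rbind, rows),
                 corrected = data.frame(id = obs$id, tad = obs$tad,
                                        pc_dv = pc_obs),
                 n_sim = n_sim),
            class = "pcvpc_result")
}

#' @export
print.pcvpc_result <- function(x, ...) {
  cat(sprintf("Prediction-corrected VPC (%d simulated studies)\n", x$n_sim))
  print(x$bins, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Normalised prediction distribution errors
#'
#' Standard simulation-based construction: for each subject the observed
#' vector and `n_sim` simulated vectors are decorrelated with the Cholesky
#' factor of the simulation covariance (after centring on the simulation
#' mean); each decorrelated observation is then ranked among its
#' decorrelated simulations and the rank mapped to a standard-normal
#' quantile. Under the true model the result is approximately N(0, 1).
#' A singular simulation covariance triggers a flagged ridge fallback.
#'
#' @param data event-record dataset.
#' @param model evaluated [pk_model()].
#' @param n_sim number of simulated replicates (>= 500 recommended).
#' @param seed optional integer seed.
#' @return list of class `npde_result`: `npde` (per-observation values with
#'   id/time), `mean`, `var`, `ks_p` (Kolmogorov-Smirnov test vs N(0,1)),
#'   `ridged` (ids needing the ridge fallback).
#' @export
npde <- function(data, model, n_sim = 500, seed = NULL) {
  rep <- simulate_replicates(data, model, n_sim, seed)
  obs <- rep$obs
  vals <- numeric(nrow(obs))
  ridged <- character(0)
  for (id in rep$ids) {
    sel <- which(obs$id == id)
    Y <- rep$sims[sel, , drop = FALSE]            # m x n_sim
    mu <- rowMeans(Y)
    Vc <- Y - mu
    V <- tcrossprod(Vc) / (ncol(Y) - 1)
    L <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(L)) {
      ridged <- c(ridged, as.character(id))
      V <- V + diag(1e-6 * mean(diag(V)) + 1e-12, nrow(V))
      L <- chol(V)
    }
    ystar <- backsolve(L, obs$dv[sel] - mu, transpose = TRUE)
    sstar <- backsolve(L, Vc, transpose = TRUE)
    cnt <- rowSums(sstar < ystar)
    pde <- (cnt + 0.5) / (ncol(Y) + 1)
    vals[sel] <- stats::qnorm(pde)
  }
  ks <- suppressWarnings(stats::ks.test(vals, "pnorm"))
  structure(list(npde = data.frame(id = obs$id, tad = obs$tad, npde = vals),
                 mean = mean(vals), var = stats::var(vals),
                 ks_p = ks$p.value, ridged = ridged, n_sim = n_sim),
            class = "npde_result")
}

#' @export
print.npde_result <- function(x, ...) {
  cat(sprintf("NPDE (%d simulations): mean %.3f, variance %.3f, KS p = %.3g\n",
              x$n_sim, x$mean, x$var, x$ks_p))
  if (length(x$ridged))
    cat("  ridge fallback used for subject(s):",
        paste(x$ridged, collapse = ", "), "\n")
  invisible(x)
}

#' Goodness-of-fit summary for a fitted model
#'
#' Per-observation population predictions (typical values), individual
#' predictions at the posterior-mode random effects, individual weighted
#' residuals, and conditional weighted residuals from the first-order
#' expansion around the posterior modes. Also reports the slope of the
#' observed-vs-individual-predicted regression.
#'
#' @param data event-record dataset.
#' @param fit a `pk_fit` from [fit_pk_model()] (or a list with elements
#'   `model` and `eta`).
#' @return list of class `gof_table`: `table` (id, tad, dv, pred, ipred,
#'   iwres, cwres) and `dv_ipred_slope`.
#' @export
gof_table <- function(data, fit) {
  model <- fit$model
  obs <- data[data$evid == 0 & data$mdv == 0, , drop = FALSE]
  covnames <- unique(vapply(model$covariates, `[[`, "", "covariate"))
  ids <- unique(obs$id)
  cov1 <- obs[match(ids, obs$id), covnames, drop = FALSE]
  en <- eta_names(model)
  eta <- matrix(0, length(ids), length(en), dimnames = list(ids, en))
  if (!is.null(fit$eta) && length(fit$eta)) {
    common <- intersect(rownames(fit$eta), as.character(ids))
    eta[common, colnames(fit$eta)] <- fit$eta[common, , drop = FALSE]
  }
  p_typ <- individual_params(model, cov1)
  p_ind <- individual_params(model, cov1, eta)
  sidx <- match(obs$id, ids)
  pred <- conc_at(model, p_typ[sidx, , drop = FALSE], obs$tad)
  ipred <- conc_at(model, p_ind[sidx, , drop = FALSE], obs$tad)
  sdi <- model$prop_sd * p_ind$ruv_scale[sidx] * ipred
  iwres <- ifelse(sdi > 0, (obs$dv - ipred) / sdi, 0)
  # conditional weighted residuals by linearisation around the modes
  cwres <- numeric(nrow(obs))
  oi <- omega_info(model)
  act <- oi$active
  d <- 1e-5
  for (i in seq_along(ids)) {
    sel <- which(obs$id == ids[i])
    sub <- list(t = obs$tad[sel], y = obs$dv[sel],
                cov = cov1[i, , drop = FALSE])
    base <- individual_params(model, sub$cov)
    predf <- function(ev) {
      p <- base
      if ("eta_cl" %in% names(ev)) p$cl <- base$cl * exp(ev[["eta_cl"]])
      if ("eta_v2" %in% names(ev)) {
        p$v2 <- base$v2 * exp(ev[["eta_v2"]])
        if (model$v3_rule == "equal_v2") p$v3 <- p$v2
      }
      conc_at(model, p, sub$t)
    }
    ev <- stats::setNames(eta[i, act], act)
    f0 <- predf(ev)
    if (length(act)) {
      J <- vapply(act, function(k) {
        e2 <- ev; e2[[k]] <- e2[[k]] + d
        (predf(e2) - f0) / d
      }, numeric(length(sel)))
      J <- matrix(J, nrow = length(sel))
      Om <- model$omega[act, act, drop = FALSE]
      res <- sub$y - f0 + drop(J %*% ev)
      v <- (model$prop_sd * exp(if ("eta_ruv" %in% act) ev[["eta_ruv"]] else 0) * f0)^2
      Cov <- J %*% Om %*% t(J) + diag(v, length(sel))
      L <- chol(Cov)
      cwres[sel] <- backsolve(L, res, transpose = TRUE)
    } else {
      v <- model$prop_sd * f0
      cwres[sel] <- ifelse(v > 0, (sub$y - f0) / v, 0)
    }
  }
  slope <- if (stats::var(ipred) > 0)
    unname(stats::coef(stats::lm(obs$dv ~ ipred))[2]) else NA_real_
  structure(list(table = data.frame(id = obs$id, tad = obs$tad, dv = obs$dv,
                                    pred = pred, ipred = ipred,
                                    iwres = iwres, cwres = cwres),
                 dv_ipred_slope = slope),
            class = "gof_table")
}

#' @export
print.gof_table <- function(x, ...) {
  cat(sprintf("Goodness of fit: %d observations, DV~IPRED slope %.3f\n",
              nrow(x$table), x$dv_ipred_slope))
  cat(sprintf("  IWRES mean %.3f sd %.3f | CWRES mean %.3f sd %.3f\n",
              mean(x$table$iwres), stats::sd(x$table$iwres),
              mean(x$table$cwres), stats::sd(x$table$cwres)))
  invisible(x)
}
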
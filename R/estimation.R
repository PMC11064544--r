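# Nonlinear mixed-effects estimation for the steady-state PK models.
#
# The marginal likelihood is approximated per subject by a Laplace-type
# expansion around the empirical Bayes (posterior-mode) random effects,
# with the curvature taken from the Fisher/Gauss-Newton information of the
# heteroscedastic Gaussian observation model -- the classic conditional
# linearisation with interaction (the residual variance depends on the
# random effects both through the prediction and through the magnitude
# effect eta_ruv). The objective is -2 x approximate marginal
# log-likelihood; differences between nested models are the selection
# statistic.

OFV_BIG <- 1e10

# ---- parameter packing -----------------------------------------------------

term_name <- function(term) paste0(term$target, "~", term$covariate)

# Names, transforms and current values of the estimable parameters.
est_structure <- function(model, fix = character()) {
  nm <- c("cl", "v2", if (model$n_cmt == 2L) "q", "ka")
  tr <- rep("log", length(nm))
  val <- unlist(model$theta[nm], use.names = FALSE)
  for (term in model$covariates) {
    if (term$form == "allometric") next  # fixed by design, never estimated
    nm <- c(nm, term_name(term))
    tr <- c(tr, if (term$form == "categorical") "log" else "identity")
    val <- c(val, term$value)
  }
  nm <- c(nm, "prop_sd"); tr <- c(tr, "log"); val <- c(val, model$prop_sd)
  en <- eta_names(model)
  act <- en[diag(model$omega)[en] > 0]
  for (e in act) {
    nm <- c(nm, sub("^eta_", "omega_", e)); tr <- c(tr, "log")
    val <- c(val, model$omega[e, e])
  }
  if (all(c("eta_cl", "eta_v2") %in% act)) {
    nm <- c(nm, "corr_cl_v2"); tr <- c(tr, "atanh")
    val <- c(val, model$omega["eta_cl", "eta_v2"] /
               sqrt(model$omega["eta_cl", "eta_cl"] * model$omega["eta_v2", "eta_v2"]))
  }
  keep <- !(nm %in% fix)
  bad <- setdiff(fix, nm)
  if (length(bad)) stop("unknown parameter(s) in fix: ", paste(bad, collapse = ", "))
  list(names = nm[keep], transform = tr[keep], values = val[keep])
}

to_packed <- function(values, transform) {
  out <- values
  out[transform == "log"] <- log(values[transform == "log"])
  out[transform == "atanh"] <- atanh(values[transform == "atanh"])
  out
}

from_packed <- function(packed, transform) {
  out <- packed
  out[transform == "log"] <- exp(packed[transform == "log"])
  out[transform == "atanh"] <- tanh(packed[transform == "atanh"])
  out
}

# Rebuild a pk_model with the named natural-scale values applied.
apply_estimates <- function(model, values) {
  m <- model
  for (nm in names(values)) {
    v <- values[[nm]]
    if (nm %in% c("cl", "v2", "q", "ka")) {
      m$theta[[nm]] <- v
    } else if (nm == "prop_sd") {
      m$prop_sd <- v
    } else if (grepl("^omega_", nm)) {
      e <- sub("^omega_", "eta_", nm)
      m$omega[e, e] <- v
    } else if (nm == "corr_cl_v2") {
      # applied after the variances below
    } else {
      hit <- FALSE
      for (i in seq_along(m$covariates)) {
        if (term_name(m$covariates[[i]]) == nm) {
          m$covariates[[i]]$value <- v; hit <- TRUE; break
        }
      }
      if (!hit) stop("cannot apply estimate for unknown parameter: ", nm)
    }
  }
  if ("corr_cl_v2" %in% names(values)) {
    rho <- values[["corr_cl_v2"]]
    cv <- rho * sqrt(m$omega["eta_cl", "eta_cl"] * m$omega["eta_v2", "eta_v2"])
    m$omega["eta_cl", "eta_v2"] <- cv
    m$omega["eta_v2", "eta_cl"] <- cv
  }
  m
}

# ---- data preparation ------------------------------------------------------

# Split observation records into per-subject blocks (BLQ/dose rows dropped).
prepare_subjects <- function(data, model) {
  need <- c("id", "tad", "dv", "evid", "mdv")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("dataset is missing column(s): ", paste(miss, collapse = ", "))
  obs <- data[data$evid == 0 & data$mdv == 0, , drop = FALSE]
  covnames <- unique(vapply(model$covariates, `[[`, "", "covariate"))
  miss <- setdiff(covnames, names(data))
  if (length(miss)) stop("dataset is missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  ids <- unique(data$id)
  no_obs <- setdiff(ids, unique(obs$id))
  if (length(no_obs))
    stop("subject(s) without quantifiable observations: ",
         paste(utils::head(no_obs, 5), collapse = ", "))
  split_idx <- split(seq_len(nrow(obs)), obs$id)
  lapply(split_idx, function(ix) {
    cov_row <- obs[ix[1], covnames, drop = FALSE]
    list(id = obs$id[ix[1]], t = obs$tad[ix], y = obs$dv[ix],
         cov = cov_row,
         covl = stats::setNames(as.list(as.numeric(cov_row)), covnames))
  })
}

# Typical-value parameters for one subject as a plain list: the inner loop
# calls this once per objective evaluation per subject, so no data.frame
# machinery here.
typical_scalar_params <- function(model, covl) {
  p <- list(cl = model$theta$cl, v2 = model$theta$v2,
            q = if (is.null(model$theta$q)) NA_real_ else model$theta$q,
            ka = model$theta$ka, v3 = NA_real_)
  for (term in model$covariates) {
    x <- covl[[term$covariate]]
    mult <- if (term$form == "categorical") term$value^x
            else (x / term$reference)^term$value
    p[[term$target]] <- p[[term$target]] * mult
  }
  if (model$v3_rule == "equal_v2") p$v3 <- p$v2
  p
}

# ---- per-subject Laplace contribution --------------------------------------

# One subject's -2 log marginal likelihood contribution and posterior-mode
# random effects. `eta0` is the warm start.
subject_ofv <- function(sub, model, omega_info, eta0 = NULL) {
  act <- omega_info$active
  base <- typical_scalar_params(model, sub$covl)
  equal_v3 <- model$v3_rule == "equal_v2"
  cmt1 <- model$n_cmt == 1L
  dose <- model$dose; tau <- model$tau; tt <- sub$t
  cl_free <- "eta_cl" %in% act
  v2_free <- "eta_v2" %in% act
  pred <- function(eta) {
    cl <- if (cl_free) base$cl * exp(eta[["eta_cl"]]) else base$cl
    v2 <- if (v2_free) base$v2 * exp(eta[["eta_v2"]]) else base$v2
    if (cmt1) return(conc1_fast(cl, v2, base$ka, dose, tau, tt))
    v3 <- if (equal_v3) v2 else base$v3
    conc2_fast(cl, v2, v3, base$q, base$ka, dose, tau, tt)
  }
  if (!length(act)) {
    f <- pred(numeric(0))
    s2 <- (model$prop_sd * f)^2
    r <- sub$y - f
    return(list(ofv = sum(log(2 * pi * s2) + r^2 / s2), eta = numeric(0)))
  }
  Oinv <- omega_info$inv
  ldO <- omega_info$logdet
  struct <- intersect(act, c("eta_cl", "eta_v2"))
  has_ruv <- "eta_ruv" %in% act
  m <- length(sub$y)
  hfun <- function(eta) {
    f <- pred(eta)
    a <- model$prop_sd * if (has_ruv) exp(eta[["eta_ruv"]]) else 1
    s2 <- (a * f)^2
    if (any(!is.finite(s2)) || any(s2 <= 0)) return(Inf)
    r <- sub$y - f
    sum(log(2 * pi * s2) + r^2 / s2) + ldO +
      drop(eta %*% Oinv %*% eta)
  }
  eta <- if (is.null(eta0)) stats::setNames(rep(0, length(act)), act) else eta0
  h <- hfun(eta)
  if (!is.finite(h)) { eta[] <- 0; h <- hfun(eta) }
  d <- 1e-5
  stalls <- 0L
  for (iter in 1:100) {
    f <- pred(eta)
    a <- model$prop_sd * if (has_ruv) exp(eta[["eta_ruv"]]) else 1
    s <- a * f; s2 <- s^2
    r <- sub$y - f
    J <- vapply(struct, function(k) {
      e2 <- eta; e2[[k]] <- e2[[k]] + d
      (pred(e2) - f) / d
    }, numeric(m))
    if (length(struct)) J <- matrix(J, nrow = m)
    gpri <- 2 * drop(Oinv %*% eta)
    grad <- stats::setNames(numeric(length(act)), act)
    dh_df <- 2 / f - 2 * r / s2 - 2 * r^2 / (s2 * f)
    for (j in seq_along(struct))
      grad[[struct[j]]] <- sum(J[, j] * dh_df)
    if (has_ruv) grad[["eta_ruv"]] <- sum(2 - 2 * r^2 / s2)
    grad <- grad + gpri[match(act, act)]
    info <- matrix(0, length(act), length(act), dimnames = list(act, act))
    if (length(struct)) {
      w <- (1 + 2 * a^2) / s2
      Ist <- crossprod(J * sqrt(w))
      info[struct, struct] <- Ist
      if (has_ruv)
        for (j in seq_along(struct))
          info[struct[j], "eta_ruv"] <- info["eta_ruv", struct[j]] <-
            sum(2 * J[, j] / f)
    }
    if (has_ruv) info["eta_ruv", "eta_ruv"] <- 2 * m
    A <- info + Oinv
    step <- tryCatch(-solve(A + diag(1e-10, nrow(A)), grad) / 2,
                     error = function(e) -grad / (2 * max(diag(A))))
    gd <- sum(grad * step)
    if (gd > 0) step <- -grad / (2 * max(diag(A)))
    if (max(abs(grad)) < 1e-6) break
    tstep <- 1
    repeat {
      hn <- hfun(eta + tstep * step)
      if (is.finite(hn) && hn <= h + 1e-4 * tstep * min(gd, 0)) break
      tstep <- tstep / 2
      if (tstep < 1e-10) break
    }
    if (tstep < 1e-10 || !is.finite(hn) || hn >= h) break  # no usable step
    eta <- eta + tstep * step
    gain <- h - hn
    h <- hn
    # mode accuracy drives the Laplace term; only give up on the gradient
    # criterion after repeated negligible gains (curvature mismatch stall)
    stalls <- if (gain < 1e-12 * (1 + abs(h))) stalls + 1L else 0L
    if (stalls >= 2L) break
  }
  # Curvature at the mode for the Laplace normalising term: exact central
  # finite-difference Hessian of the penalised deviance (the Gauss-Newton
  # information used for the Newton steps drops residual-times-curvature
  # terms, which noticeably inflates null likelihood-ratio statistics).
  q <- length(act)
  dh <- 1e-3
  H2 <- matrix(0, q, q)
  h0 <- hfun(eta)
  hp <- numeric(q); hm <- numeric(q)
  for (j in seq_len(q)) {
    ej <- eta; ej[j] <- ej[j] + dh; hp[j] <- hfun(ej)
    ej <- eta; ej[j] <- ej[j] - dh; hm[j] <- hfun(ej)
    H2[j, j] <- (hp[j] + hm[j] - 2 * h0) / dh^2
  }
  if (q > 1) for (j in seq_len(q - 1)) for (k in (j + 1):q) {
    epp <- eta; epp[j] <- epp[j] + dh; epp[k] <- epp[k] + dh
    emm <- eta; emm[j] <- emm[j] - dh; emm[k] <- emm[k] - dh
    H2[j, k] <- H2[k, j] <-
      (hfun(epp) + hfun(emm) + 2 * h0 -
         hp[j] - hm[j] - hp[k] - hm[k]) / (2 * dh^2)
  }
  A_exact <- H2 / 2
  # eigenvalue-based positive-definiteness check: no condition signalling
  # in this hot path (exceptions here are costly under deep handler stacks)
  ev <- eigen(A_exact, symmetric = TRUE, only.values = TRUE)$values
  ld <- if (all(ev > 1e-12)) sum(log(ev)) else NULL
  if (is.null(ld)) {
    # fall back to the always-PD Gauss-Newton curvature
    f <- pred(eta)
    a <- model$prop_sd * if (has_ruv) exp(eta[["eta_ruv"]]) else 1
    s2 <- (a * f)^2
    J <- vapply(struct, function(k) {
      e2 <- eta; e2[[k]] <- e2[[k]] + d
      (pred(e2) - f) / d
    }, numeric(m))
    if (length(struct)) J <- matrix(J, nrow = m)
    info <- matrix(0, q, q, dimnames = list(act, act))
    if (length(struct)) {
      w <- (1 + 2 * a^2) / s2
      info[struct, struct] <- crossprod(J * sqrt(w))
      if (has_ruv)
        for (j in seq_along(struct))
          info[struct[j], "eta_ruv"] <- info["eta_ruv", struct[j]] <-
            sum(2 * J[, j] / f)
    }
    if (has_ruv) info["eta_ruv", "eta_ruv"] <- 2 * m
    A <- info + Oinv
    ld <- tryCatch(2 * sum(log(diag(chol(A)))),
                   error = function(e) as.numeric(
                     determinant(A, logarithm = TRUE)$modulus))
  }
  list(ofv = h + as.numeric(ld), eta = eta)
}

omega_info <- function(model) {
  om <- model$omega
  act <- rownames(om)[diag(om) > 0]
  if (!length(act)) return(list(active = character(0)))
  blk <- om[act, act, drop = FALSE]
  ch <- tryCatch(chol(blk), error = function(e) NULL)
  if (is.null(ch)) stop("omega block is not positive definite")
  list(active = act, inv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
}

#' Objective function value of a model on a dataset
#'
#' Minus twice the approximate marginal log-likelihood (Laplace expansion
#' around the per-subject posterior-mode random effects, Gauss-Newton
#' curvature with interaction). Quantification-flagged (`mdv = 1`) rows are
#' excluded. With all random-effect variances zero this collapses exactly to
#' the fixed-effects Gaussian deviance.
#'
#' @param data event-record dataset ([simulate_pk_dataset()] or
#'   [read_pk_dataset()]).
#' @param model a [pk_model()].
#' @param return_eta if `TRUE`, attach the per-subject posterior-mode random
#'   effects as attribute `"eta"`.
#' @return the objective value (numeric scalar).
#' @export
ofv <- function(data, model, return_eta = FALSE) {
  subs <- prepare_subjects(data, model)
  oi <- omega_info(model)
  res <- lapply(subs, subject_ofv, model = model, omega_info = oi)
  total <- sum(vapply(res, `[[`, 0, "ofv"))
  if (return_eta) {
    eta <- do.call(rbind, lapply(res, `[[`, "eta"))
    if (!is.null(eta)) rownames(eta) <- names(subs)
    attr(total, "eta") <- eta
  }
  total
}

# Shared objective over the packed parameter vector. Inner mode searches
# start from the per-subject anchors in `cache`, which are NOT updated
# inside an optimiser run -- the objective stays a pure function of the
# parameters (a history-dependent warm start would inject noise into the
# optimiser's finite-difference gradients). Anchors are refreshed between
# runs with `update_anchors`.
make_objective <- function(subs, model, struct, cache) {
  function(packed) {
    vals <- stats::setNames(from_packed(packed, struct$transform), struct$names)
    m <- tryCatch(apply_estimates(model, vals), error = function(e) NULL)
    if (is.null(m)) return(OFV_BIG)
    oi <- tryCatch(omega_info(m), error = function(e) NULL)
    if (is.null(oi)) return(OFV_BIG)
    tot <- 0
    for (i in seq_along(subs)) {
      r <- subject_ofv(subs[[i]], m, oi, eta0 = cache$anchor[[i]])
      tot <- tot + r$ofv
    }
    if (!is.finite(tot)) OFV_BIG else tot
  }
}

update_anchors <- function(subs, model, struct, cache, packed) {
  vals <- stats::setNames(from_packed(packed, struct$transform), struct$names)
  m <- apply_estimates(model, vals)
  oi <- omega_info(m)
  for (i in seq_along(subs))
    cache$anchor[[i]] <- subject_ofv(subs[[i]], m, oi,
                                     eta0 = cache$anchor[[i]])$eta
  invisible(cache)
}

#' Fit a population PK model by approximate marginal likelihood
#'
#' Minimises [ofv()] over the structural parameters, estimated covariate
#' coefficients, residual-error magnitude and random-effect (co)variances.
#' Positivity is enforced by log parameterisation (correlations by atanh);
#' optimisation uses a quasi-Newton method with optional jittered
#' multi-start. Non-convergence is flagged on the result, not thrown.
#'
#' @param data event-record dataset.
#' @param model starting [pk_model()]; its current values are the initial
#'   estimates.
#' @param fix character vector of parameter names to hold fixed, e.g.
#'   `c("ka", "omega_ruv")`; covariate coefficients are named
#'   `"<target>~<covariate>"`. Allometric (fixed-exponent) terms are never
#'   estimated.
#' @param se compute standard errors from a finite-difference Hessian of
#'   the objective (adds many objective evaluations).
#' @param control list: `n_starts` (default 1), `jitter_sd` (log-scale SD of
#'   start jitter, 0.2), `iter_max` (150), `rel_tol` (1e-8).
#' @return object of class `pk_fit`: fitted `model`, `ofv`, `converged`,
#'   `message`, `estimates` (data.frame with `parameter`, `estimate`, and
#'   when requested `se`, `rse_pct`), `eta` (per-subject posterior modes),
#'   counts, and the optimiser details.
#' @export
fit_pk_model <- function(data, model, fix = character(), se = FALSE,
                         control = list()) {
  ctl <- utils::modifyList(list(n_starts = 1, jitter_sd = 0.2,
                                iter_max = 150, rel_tol = 1e-8), control)
  subs <- prepare_subjects(data, model)
  struct <- est_structure(model, fix)
  if (!length(struct$names)) stop("no free parameters to estimate")
  cache <- new.env(parent = emptyenv())
  obj <- make_objective(subs, model, struct, cache)
  start0 <- to_packed(struct$values, struct$transform)
  run_one <- function(st) {
    # rounds of quasi-Newton minimisation, refreshing the per-subject mode
    # anchors at each round's solution, until the objective stabilises
    cache$anchor <- vector("list", length(subs))
    update_anchors(subs, model, struct, cache, st)
    prev <- Inf
    res <- NULL
    stable <- FALSE
    for (round in 1:6) {
      res <- tryCatch(
        stats::nlminb(st, obj, control = list(iter.max = ctl$iter_max,
                                              eval.max = 8 * ctl$iter_max,
                                              rel.tol = ctl$rel_tol)),
        error = function(e) list(objective = Inf, convergence = 1L,
                                 message = conditionMessage(e), par = st))
      if (!is.finite(res$objective)) break
      update_anchors(subs, model, struct, cache, res$par)
      stable <- prev - res$objective < 1e-3
      prev <- res$objective
      st <- res$par
      if (identical(res$convergence, 0L) || stable) break
    }
    if (!is.null(res) && is.finite(res$objective))
      res$converged <- identical(res$convergence, 0L) || stable
    else res$converged <- FALSE
    res
  }
  best <- NULL
  for (s in seq_len(ctl$n_starts)) {
    st <- if (s == 1) start0 else start0 + stats::rnorm(length(start0), 0, ctl$jitter_sd)
    res <- run_one(st)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  converged <- isTRUE(best$converged)
  vals <- stats::setNames(from_packed(best$par, struct$transform), struct$names)
  fitted <- apply_estimates(model, vals)
  final_ofv <- best$objective
  oi_fin <- omega_info(fitted)
  eta <- do.call(rbind, lapply(seq_along(subs), function(i)
    subject_ofv(subs[[i]], fitted, oi_fin, eta0 = cache$anchor[[i]])$eta))
  if (!is.null(eta)) rownames(eta) <- names(subs)
  est <- data.frame(parameter = struct$names, estimate = unname(vals))
  if (se) {
    H <- tryCatch(pracma::hessian(obj, best$par), error = function(e) NULL)
    covp <- if (!is.null(H))
      tryCatch(2 * solve(H), error = function(e) NULL) else NULL
    if (!is.null(covp)) {
      se_packed <- sqrt(pmax(diag(covp), 0))
      dnat <- ifelse(struct$transform == "log", abs(unname(vals)),
                     ifelse(struct$transform == "atanh",
                            1 - unname(vals)^2, 1))
      est$se <- se_packed * dnat
      est$rse_pct <- 100 * est$se / abs(est$estimate)
    }
  }
  structure(list(model = fitted, ofv = final_ofv,
                 converged = converged,
                 message = best$message, estimates = est, eta = eta,
                 n_subjects = length(subs),
                 n_obs = sum(vapply(subs, function(s) length(s$y), 0L)),
                 optimizer = best[c("convergence", "iterations", "evaluations")]),
            class = "pk_fit")
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("PK model fit: %s | OFV %.3f | %s\n", x$model$drug, x$ofv,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  %d subjects, %d observations\n", x$n_subjects, x$n_obs))
  print(x$estimates, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Forward/backward covariate selection on the objective function
#'
#' Greedy forward addition: at each round every remaining candidate term is
#' fitted on top of the current model and the best drop in objective is
#' accepted if it meets `forward_dofv` (default 6.63, the 1-d.f. chi-square
#' point at alpha 0.01). Backward elimination then removes any searched term
#' whose deletion worsens the objective by less than `backward_dofv`
#' (default 10.83, alpha 0.001). Candidate coefficients start neutral
#' (exponent 0 / ratio 1).
#'
#' @param data event-record dataset.
#' @param model base [pk_model()].
#' @param candidates list of [covariate_term()] candidates.
#' @param forward_dofv,backward_dofv selection thresholds (objective points).
#' @param refit `"full"` refits all free parameters for every candidate;
#'   `"coef"` freezes the current estimates and profiles only the candidate
#'   coefficient (a fast screen; backward deltas are then plain objective
#'   re-evaluations).
#' @param fix parameters to hold fixed throughout (see [fit_pk_model()]).
#' @param control passed to [fit_pk_model()].
#' @return list of class `covariate_search`: `model` (final), `steps`
#'   (data.frame log with phase, term, dOFV, accepted), `retained`
#'   (term names), `ofv`.
#' @export
covariate_search <- function(data, model, candidates,
                             forward_dofv = 6.63, backward_dofv = 10.83,
                             refit = c("full", "coef"), fix = character(),
                             control = list()) {
  refit <- match.arg(refit)
  steps <- list()
  neutral <- function(term) {
    term$value <- if (term$form == "categorical") 1 else 0
    term
  }
  current <- model
  cur_ofv <- if (refit == "full" && length(candidates)) {
    f <- fit_pk_model(data, current, fix = fix, control = control)
    current <- f$model
    f$ofv
  } else ofv(data, current)
  base_names <- vapply(model$covariates, term_name, "")
  remaining <- lapply(candidates, neutral)
  added <- character(0)
  repeat {
    if (!length(remaining)) break
    trial <- lapply(remaining, function(term) {
      ext <- current
      ext$covariates <- c(ext$covariates, list(term))
      fx <- if (refit == "coef")
        c(setdiff(est_structure(ext)$names, term_name(term)), fix)
      else fix
      fit_pk_model(data, ext, fix = unique(fx), control = control)
    })
    dofv <- cur_ofv - vapply(trial, `[[`, 0, "ofv")
    best <- which.max(dofv)
    for (j in seq_along(remaining))
      steps[[length(steps) + 1]] <- data.frame(
        phase = "forward", term = term_name(remaining[[j]]),
        dofv = dofv[j], accepted = j == best && dofv[j] >= forward_dofv)
    if (dofv[best] < forward_dofv) break
    current <- trial[[best]]$model
    cur_ofv <- trial[[best]]$ofv
    added <- c(added, term_name(remaining[[best]]))
    remaining <- remaining[-best]
  }
  # backward elimination over the terms added by the search
  repeat {
    searched <- setdiff(vapply(current$covariates, term_name, ""), base_names)
    if (!length(searched)) break
    dofv_rm <- vapply(searched, function(nm) {
      red <- current
      red$covariates <- red$covariates[
        vapply(red$covariates, term_name, "") != nm]
      o <- if (refit == "coef") ofv(data, red)
      else fit_pk_model(data, red, fix = fix, control = control)$ofv
      o - cur_ofv
    }, 0)
    worst <- which.min(dofv_rm)
    for (j in seq_along(searched))
      steps[[length(steps) + 1]] <- data.frame(
        phase = "backward", term = searched[j], dofv = dofv_rm[j],
        accepted = !(j == worst && dofv_rm[j] < backward_dofv))
    if (dofv_rm[worst] >= backward_dofv) break
    nm <- searched[worst]
    current$covariates <- current$covariates[
      vapply(current$covariates, term_name, "") != nm]
    cur_ofv <- if (refit == "coef") ofv(data, current)
    else {
      f <- fit_pk_model(data, current, fix = fix, control = control)
      current <- f$model
      f$ofv
    }
  }
  structure(list(model = current, steps = do.call(rbind, steps),
                 retained = setdiff(vapply(current$covariates, term_name, ""),
                                    base_names),
                 ofv = cur_ofv),
            class = "covariate_search")
}

#' @export
print.covariate_search <- function(x, ...) {
  cat("Covariate search: retained",
      if (length(x$retained)) paste(x$retained, collapse = ", ") else "none",
      sprintf("| final OFV %.3f\n", x$ofv))
  print(x$steps, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Nonparametric bootstrap of a model fit
#'
#' Resamples subjects with replacement (preserving n), refits each
#' replicate, and reports the median and 2.5/97.5 percentiles of every
#' estimated parameter over the converged replicates.
#'
#' @param data event-record dataset.
#' @param model [pk_model()] whose current values start every replicate fit.
#' @param n_replicates number of bootstrap replicates (>= 2).
#' @param seed optional integer seed for the resampling.
#' @param fix,control passed to [fit_pk_model()].
#' @return list of class `pk_bootstrap`: `estimates` (replicate x parameter
#'   matrix, non-converged rows `NA`), `summary` (median, lo, hi),
#'   `converged_fraction`, `n_replicates`.
#' @export
bootstrap_pk <- function(data, model, n_replicates, seed = NULL,
                         fix = character(), control = list()) {
  if (n_replicates < 2) stop("n_replicates must be at least 2")
  ids <- unique(data$id)
  if (length(ids) < 2) stop("bootstrap needs at least two subjects")
  if (!is.null(seed)) set.seed(seed)
  blocks <- split(seq_len(nrow(data)), data$id)
  pnames <- est_structure(model, fix)$names
  est <- matrix(NA_real_, n_replicates, length(pnames),
                dimnames = list(NULL, pnames))
  conv <- logical(n_replicates)
  for (r in seq_len(n_replicates)) {
    take <- sample(ids, length(ids), replace = TRUE)
    rep_data <- do.call(rbind, lapply(seq_along(take), function(j) {
      b <- data[blocks[[as.character(take[j])]], , drop = FALSE]
      b$id <- j
      b
    }))
    f <- tryCatch(fit_pk_model(rep_data, model, fix = fix, control = control),
                  error = function(e) NULL)
    if (!is.null(f)) {
      conv[r] <- f$converged
      if (f$converged) est[r, f$estimates$parameter] <- f$estimates$estimate
    }
  }
  ok <- conv & stats::complete.cases(est)
  summ <- data.frame(
    parameter = pnames,
    median = apply(est[ok, , drop = FALSE], 2, stats::median),
    lo = apply(est[ok, , drop = FALSE], 2, stats::quantile, 0.025),
    hi = apply(est[ok, , drop = FALSE], 2, stats::quantile, 0.975))
  structure(list(estimates = est, summary = summ,
                 converged_fraction = mean(conv),
                 n_replicates = n_replicates),
            class = "pk_bootstrap")
}

#' @export
print.pk_bootstrap <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates, %.0f%% converged\n",
              x$n_replicates, 100 * x$converged_fraction))
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}
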
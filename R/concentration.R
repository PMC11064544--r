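# Closed-form steady-state concentrations for repeated oral dosing.
#
# Every exponential exp(-lam*t) of the single-dose solution carries its own
# steady-state accumulation factor 1/(1 - exp(-lam*tau)); concentrations are
# amount/volume, i.e. mg/L == ug/mL. Near-coincident rate constants are
# evaluated with the analytic confluent limit (the t*exp(-kt) form) instead
# of perturbing parameters, which would lose precision to cancellation.

RATE_TOL <- 1e-8

ss_exp <- function(lam, t, tau) exp(-lam * t) / (1 - exp(-lam * tau))

# d/dlam of ss_exp, used by the confluent limits
ss_exp_d <- function(lam, t, tau) {
  E <- exp(-lam * tau)
  -t * exp(-lam * t) / (1 - E) - exp(-lam * t) * tau * E / (1 - E)^2
}

conc1_core <- function(cl, v, ka, dose, tau, t) {
  n <- max(length(cl), length(v), length(ka), length(dose), length(t))
  cl <- rep_len(cl, n); v <- rep_len(v, n); ka <- rep_len(ka, n)
  dose <- rep_len(dose, n); t <- rep_len(t, n)
  k <- cl / v
  out <- numeric(n)
  deg <- abs(ka - k) < RATE_TOL * pmax(k, ka)
  if (any(!deg)) {
    i <- !deg
    out[i] <- dose[i] * ka[i] / (v[i] * (ka[i] - k[i])) *
      (ss_exp(k[i], t[i], tau) - ss_exp(ka[i], t[i], tau))
  }
  if (any(deg)) {
    i <- deg
    out[i] <- -dose[i] * ka[i] / v[i] * ss_exp_d(k[i], t[i], tau)
  }
  out
}

conc2_core <- function(cl, v2, v3, q, ka, dose, tau, t) {
  n <- max(length(cl), length(v2), length(v3), length(q), length(ka),
           length(dose), length(t))
  cl <- rep_len(cl, n); v2 <- rep_len(v2, n); v3 <- rep_len(v3, n)
  q <- rep_len(q, n); ka <- rep_len(ka, n)
  dose <- rep_len(dose, n); t <- rep_len(t, n)
  tiny_q <- q < 1e-10 * cl
  out <- numeric(n)
  if (any(tiny_q))
    out[tiny_q] <- conc1_core(cl[tiny_q], v2[tiny_q], ka[tiny_q],
                              dose[tiny_q], tau, t[tiny_q])
  if (!any(!tiny_q)) return(out)
  i <- which(!tiny_q)
  k10 <- cl[i] / v2[i]; k12 <- q[i] / v2[i]; k21 <- q[i] / v3[i]
  s <- k10 + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  kai <- ka[i]; ti <- t[i]
  scale <- dose[i] * kai / v2[i]
  val <- numeric(length(i))
  ab_deg <- (alpha - beta) < RATE_TOL * alpha
  ka_a_deg <- !ab_deg & abs(kai - alpha) < RATE_TOL * pmax(kai, alpha)
  ka_b_deg <- !ab_deg & !ka_a_deg & abs(kai - beta) < RATE_TOL * pmax(kai, beta)
  reg <- !(ab_deg | ka_a_deg | ka_b_deg)
  if (any(reg)) {
    j <- reg
    A <- (k21[j] - alpha[j]) / ((kai[j] - alpha[j]) * (beta[j] - alpha[j]))
    B <- (k21[j] - beta[j]) / ((kai[j] - beta[j]) * (alpha[j] - beta[j]))
    C <- (k21[j] - kai[j]) / ((alpha[j] - kai[j]) * (beta[j] - kai[j]))
    val[j] <- A * ss_exp(alpha[j], ti[j], tau) +
      B * ss_exp(beta[j], ti[j], tau) + C * ss_exp(kai[j], ti[j], tau)
  }
  if (any(ka_a_deg)) {
    # ka -> alpha: merged limit of the alpha and ka terms
    j <- ka_a_deg
    a <- alpha[j]; b <- beta[j]; K21 <- k21[j]
    val[j] <- ss_exp(a, ti[j], tau) / (b - a) -
      (K21 - a) * ss_exp_d(a, ti[j], tau) / (b - a) -
      (K21 - a) * ss_exp(a, ti[j], tau) / (b - a)^2 +
      (K21 - b) / ((kai[j] - b) * (a - b)) * ss_exp(b, ti[j], tau)
  }
  if (any(ka_b_deg)) {
    # ka -> beta: symmetric merged limit of the beta and ka terms
    j <- ka_b_deg
    a <- alpha[j]; b <- beta[j]; K21 <- k21[j]
    val[j] <- ss_exp(b, ti[j], tau) / (a - b) -
      (K21 - b) * ss_exp_d(b, ti[j], tau) / (a - b) -
      (K21 - b) * ss_exp(b, ti[j], tau) / (a - b)^2 +
      (K21 - a) / ((kai[j] - a) * (b - a)) * ss_exp(a, ti[j], tau)
  }
  if (any(ab_deg)) {
    # alpha -> beta: merged limit of the two hybrid-root terms
    j <- ab_deg
    b <- beta[j]; K21 <- k21[j]
    val[j] <- ss_exp(b, ti[j], tau) / (kai[j] - b) -
      (K21 - b) * ss_exp_d(b, ti[j], tau) / (kai[j] - b) -
      (K21 - b) * ss_exp(b, ti[j], tau) / (kai[j] - b)^2 +
      (K21 - kai[j]) / (b - kai[j])^2 * ss_exp(kai[j], ti[j], tau)
  }
  out[i] <- scale * val
  out
}

check_time <- function(t, tau) {
  if (any(t < 0 | t > tau)) stop("times must lie within [0, tau]")
}

#' Steady-state concentration, one-compartment first-order absorption
#'
#' Standard superposition closed form for repeated dosing every `tau` hours
#' at steady state; satisfies `C(0) == C(tau)` and integrates to `dose/cl`
#' over one interval.
#'
#' @param params list or one-row data.frame with `cl` (L/h), `v2` (L) and
#'   `ka` (1/h), e.g. a row of [individual_params()].
#' @param dose dose (mg).
#' @param tau dosing interval (h).
#' @param t times after dose (h), within `[0, tau]`.
#' @return concentrations (ug/mL) at `t`.
#' @export
css_one_compartment <- function(params, dose, tau, t) {
  check_time(t, tau)
  conc1_core(params$cl, params$v2, params$ka, dose, tau, t)
}

#' Steady-state concentration, two-compartment first-order absorption
#'
#' Central-compartment closed form via the micro-constants `k10 = CL/V2`,
#' `k12 = Q/V2`, `k21 = Q/V3` and hybrid roots alpha/beta
#' (`alpha + beta = k10 + k12 + k21`, `alpha * beta = k10 * k21`), each
#' exponential carrying its own steady-state accumulation factor. With
#' `q -> 0` the profile collapses to the one-compartment form.
#'
#' @inheritParams css_one_compartment
#' @param params must additionally hold `v3` (L) and `q` (L/h).
#' @return concentrations (ug/mL) at `t`.
#' @export
css_two_compartment <- function(params, dose, tau, t) {
  check_time(t, tau)
  if (is.null(params$v3) || is.null(params$q) ||
      any(is.na(params$v3)) || any(is.na(params$q)))
    stop("two-compartment prediction requires v3 and q")
  conc2_core(params$cl, params$v2, params$v3, params$q, params$ka,
             dose, tau, t)
}

# Scalar-parameter fast paths used by the estimation inner loop: plain
# arithmetic on a time vector, delegating to the masked vector code only
# for degenerate rate constants.
conc1_fast <- function(cl, v, ka, dose, tau, t) {
  k <- cl / v
  if (abs(ka - k) < RATE_TOL * max(k, ka))
    return(conc1_core(cl, v, ka, dose, tau, t))
  dose * ka / (v * (ka - k)) *
    (exp(-k * t) / (1 - exp(-k * tau)) -
       exp(-ka * t) / (1 - exp(-ka * tau)))
}

conc2_fast <- function(cl, v2, v3, q, ka, dose, tau, t) {
  if (q < 1e-10 * cl) return(conc1_fast(cl, v2, ka, dose, tau, t))
  k10 <- cl / v2; k12 <- q / v2; k21 <- q / v3
  s <- k10 + k12 + k21
  disc <- sqrt(max(s^2 - 4 * k10 * k21, 0))
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  if ((alpha - beta) < RATE_TOL * alpha ||
      abs(ka - alpha) < RATE_TOL * max(ka, alpha) ||
      abs(ka - beta) < RATE_TOL * max(ka, beta))
    return(conc2_core(cl, v2, v3, q, ka, dose, tau, t))
  A <- (k21 - alpha) / ((ka - alpha) * (beta - alpha))
  B <- (k21 - beta) / ((ka - beta) * (alpha - beta))
  C <- (k21 - ka) / ((alpha - ka) * (beta - ka))
  dose * ka / v2 *
    (A * exp(-alpha * t) / (1 - exp(-alpha * tau)) +
       B * exp(-beta * t) / (1 - exp(-beta * tau)) +
       C * exp(-ka * t) / (1 - exp(-ka * tau)))
}

# Elementwise dispatcher used internally: params columns recycled against t.
conc_at <- function(model, params, t, dose = model$dose, tau = model$tau) {
  if (model$n_cmt == 1L)
    conc1_core(params$cl, params$v2, params$ka, dose, tau, t)
  else
    conc2_core(params$cl, params$v2, params$v3, params$q, params$ka,
               dose, tau, t)
}

# params: data.frame n rows; times: vector m. Returns n x m matrix.
conc_matrix <- function(model, params, times, dose = model$dose,
                        tau = model$tau) {
  n <- nrow(params); m <- length(times)
  idx <- rep(seq_len(n), times = m)
  tt <- rep(times, each = n)
  matrix(conc_at(model, params[idx, , drop = FALSE], tt, dose, tau), n, m)
}

#' Proportional residual-error model with subject-level magnitude
#'
#' Observed concentration `Y = ipred * (1 + prop_sd * ruv_scale * epsilon)`
#' where `epsilon` is standard normal with variance fixed at 1 and
#' `ruv_scale = exp(eta_ruv)` is the subject-specific multiplier on the
#' error magnitude. Negative simulated values are retained (quantification
#' flagging happens downstream), preserving the error distribution.
#'
#' @param ipred individual predicted concentration(s), non-negative.
#' @param prop_sd proportional-error magnitude.
#' @param ruv_scale subject-level multiplier `exp(eta_ruv)`.
#' @param epsilon standard-normal draw(s).
#' @return simulated observation(s).
#' @export
apply_residual_error <- function(ipred, prop_sd, ruv_scale = 1, epsilon) {
  if (any(ipred < 0)) stop("ipred must be non-negative")
  ipred * (1 + prop_sd * ruv_scale * epsilon)
}
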
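#' Define a population pharmacokinetic model
#'
#' Builds the model object used throughout the package: structural fixed
#' effects for a one- or two-compartment model with first-order absorption,
#' multiplicative covariate terms, a log-normal random-effects block, and a
#' proportional residual-error model whose magnitude itself carries
#' inter-individual variability.
#'
#' @param drug character label, e.g. `"dolutegravir"`.
#' @param n_cmt number of disposition compartments (1 or 2).
#' @param theta named list of structural typical values: `cl` (apparent
#'   clearance, L/h), `v2` (apparent central volume, L), `q` (apparent
#'   inter-compartmental clearance, L/h; two-compartment only), `ka`
#'   (first-order absorption rate constant, 1/h). Bioavailability is fixed
#'   at 1; all parameters are apparent (dose-normalised by F).
#' @param v3_rule peripheral-volume rule: `"none"` (one-compartment) or
#'   `"equal_v2"` (peripheral volume constrained equal to the central volume).
#' @param covariates list of covariate terms created by [covariate_term()].
#' @param omega named positive semi-definite variance-covariance matrix of
#'   the log-normal random effects. Row/column names identify the effects:
#'   `eta_cl` (on clearance), `eta_v2` (on central/peripheral volume),
#'   `eta_ruv` (on the proportional-error magnitude). A zero diagonal entry
#'   switches that effect off.
#' @param prop_sd proportional residual-error magnitude (dimensionless).
#' @param dose default dose per administration (mg).
#' @param tau dosing interval (h).
#' @param lloq assay lower limit of quantification (ug/mL).
#' @return an object of class `pk_model`.
#' @seealso [dtg_model()], [lam_model()], [read_model_yaml()]
#' @export
pk_model <- function(drug, n_cmt, theta, v3_rule = c("none", "equal_v2"),
                     covariates = list(), omega, prop_sd,
                     dose, tau = 24, lloq = NA_real_) {
  v3_rule <- match.arg(v3_rule)
  m <- structure(list(
    drug = drug, n_cmt = as.integer(n_cmt), theta = theta,
    v3_rule = v3_rule, covariates = covariates, omega = omega,
    prop_sd = prop_sd, dose = dose, tau = tau, lloq = lloq
  ), class = "pk_model")
  validate_pk_model(m)
  m
}

#' Covariate term on a structural parameter
#'
#' @param target structural parameter the term multiplies (`"cl"`, `"v2"`,
#'   `"q"`, `"ka"`). With the `equal_v2` peripheral rule, terms on `v2`
#'   propagate to `v3`.
#' @param covariate name of the covariate column it reads.
#' @param form `"power"` (estimated exponent on the ratio to a reference
#'   value), `"categorical"` (estimated multiplier applied when a 0/1
#'   indicator is 1), or `"allometric"` (power with an exponent fixed from
#'   size theory, not estimated).
#' @param reference reference covariate value (continuous forms only).
#' @param value exponent (power/allometric) or multiplicative ratio
#'   (categorical).
#' @return a list of class `covariate_term`.
#' @export
covariate_term <- function(target, covariate,
                           form = c("power", "categorical", "allometric"),
                           reference = NA_real_, value) {
  form <- match.arg(form)
  if (form != "categorical" && !is.finite(reference))
    stop("power/allometric covariate terms need a finite reference value")
  if (form == "categorical" && value <= 0)
    stop("categorical multiplier must be positive")
  structure(list(target = target, covariate = covariate, form = form,
                 reference = reference, value = value),
            class = "covariate_term")
}

validate_pk_model <- function(m) {
  stopifnot(m$n_cmt %in% c(1L, 2L))
  need <- c("cl", "v2", "ka")
  if (m$n_cmt == 2L) need <- c(need, "q")
  miss <- setdiff(need, names(m$theta))
  if (length(miss)) stop("theta is missing: ", paste(miss, collapse = ", "))
  th <- unlist(m$theta[need])
  if (any(!is.finite(th) | th <= 0))
    stop("all structural parameters must be finite and strictly positive")
  if (m$n_cmt == 2L && m$v3_rule == "none")
    stop("two-compartment model requires a peripheral-volume rule")
  for (term in m$covariates) {
    if (!inherits(term, "covariate_term")) stop("covariates must be covariate_term objects")
    if (!term$target %in% c("cl", "v2", "q", "ka"))
      stop("unknown covariate target: ", term$target)
  }
  om <- m$omega
  if (!is.matrix(om) || nrow(om) != ncol(om) ||
      is.null(rownames(om)) || !identical(rownames(om), colnames(om)))
    stop("omega must be a square matrix with matching row/column names")
  if (!all(rownames(om) %in% c("eta_cl", "eta_v2", "eta_ruv")))
    stop("omega names must be among eta_cl, eta_v2, eta_ruv")
  if (any(diag(om) < 0)) stop("omega variances must be non-negative")
  ev <- eigen(om, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(1, max(abs(ev)))))
    stop("omega must be positive semi-definite")
  if (!is.finite(m$prop_sd) || m$prop_sd < 0)
    stop("prop_sd must be non-negative")
  invisible(m)
}

#' @export
print.pk_model <- function(x, ...) {
  cat(sprintf("Population PK model: %s (%d-compartment, first-order absorption)\n",
              x$drug, x$n_cmt))
  th <- x$theta
  cat(sprintf("  CL/F %.4g L/h, V2/F %.4g L%s, Ka %.4g 1/h\n",
              th$cl, th$v2,
              if (x$n_cmt == 2L) sprintf(", V3/F = V2/F, Q/F %.4g L/h", th$q) else "",
              th$ka))
  for (tm in x$covariates)
    cat(sprintf("  %s ~ %s [%s%s] value %.4g\n", tm$target, tm$covariate, tm$form,
                if (is.finite(tm$reference)) sprintf(", ref %.4g", tm$reference) else "",
                tm$value))
  cat("  omega diag:", paste(sprintf("%s=%.4g", rownames(x$omega), diag(x$omega)),
                             collapse = ", "), "\n")
  cat(sprintf("  proportional error sd %.4g; dose %g mg q%gh; LLOQ %g ug/mL\n",
              x$prop_sd, x$dose, x$tau, x$lloq))
  invisible(x)
}

#' Final once-daily dolutegravir model
#'
#' One-compartment model with first-order absorption. Reference subject for
#' CL/F: 79 kg, non-Hispanic/Latino, total bilirubin 8 umol/L; for V/F:
#' 79 kg. Inter-individual variability on CL/F and on the proportional
#' residual-error magnitude.
#'
#' @return a `pk_model`.
#' @export
dtg_model <- function() {
  om <- diag(c(0.0682, 0.0567))
  dimnames(om) <- list(c("eta_cl", "eta_ruv"), c("eta_cl", "eta_ruv"))
  pk_model(
    drug = "dolutegravir", n_cmt = 1L,
    theta = list(cl = 0.858, v2 = 16.7, ka = 2.15),
    v3_rule = "none",
    covariates = list(
      covariate_term("cl", "weight", "power", reference = 79, value = 0.427),
      covariate_term("cl", "bilirubin", "power", reference = 8, value = -0.153),
      covariate_term("cl", "ethnicity_hispanic", "categorical", value = 0.844),
      covariate_term("v2", "weight", "power", reference = 79, value = 0.917)
    ),
    omega = om, prop_sd = 0.341, dose = 50, tau = 24, lloq = 0.020
  )
}

#' Final once-daily lamivudine model
#'
#' Two-compartment model with first-order absorption, peripheral volume
#' constrained equal to the central volume. Weight enters allometrically
#' (fixed exponents 0.75 on clearances, 1.0 on volume, reference 70 kg);
#' eGFR (reference 99 mL/min/1.73 m2) and Black/African American race are
#' estimated covariates on CL/F. Correlated inter-individual variability on
#' CL/F and V2/F, plus variability on the proportional-error magnitude.
#'
#' @return a `pk_model`.
#' @export
lam_model <- function() {
  om <- matrix(c(0.0883, -0.0531, 0,
                 -0.0531, 0.158, 0,
                 0, 0, 0.247), 3, 3,
               dimnames = list(c("eta_cl", "eta_v2", "eta_ruv"),
                               c("eta_cl", "eta_v2", "eta_ruv")))
  pk_model(
    drug = "lamivudine", n_cmt = 2L,
    theta = list(cl = 19.6, v2 = 105, q = 2.97, ka = 2.30),
    v3_rule = "equal_v2",
    covariates = list(
      covariate_term("cl", "weight", "allometric", reference = 70, value = 0.75),
      covariate_term("cl", "egfr", "power", reference = 99, value = 0.533),
      covariate_term("cl", "race_black", "categorical", value = 0.789),
      covariate_term("v2", "weight", "allometric", reference = 70, value = 1.0),
      covariate_term("q", "weight", "allometric", reference = 70, value = 0.75)
    ),
    omega = om, prop_sd = 0.359, dose = 300, tau = 24, lloq = 0.0025
  )
}

eta_names <- function(model) rownames(model$omega)

#' Realise individual PK parameters from covariates and random effects
#'
#' Each structural parameter equals its typical value times the product of
#' its covariate multipliers, times `exp(eta)` where a random effect applies
#' (`eta_cl` on clearance, `eta_v2` on the central volume and, through the
#' equality rule, the peripheral volume). `eta_ruv` scales the proportional
#' residual-error magnitude as `exp(eta_ruv)` and is returned as
#' `ruv_scale`. Bioavailability is fixed at 1.
#'
#' @param model a [pk_model()].
#' @param covariates data.frame (or coercible list) with one row per subject
#'   holding the covariate columns referenced by the model terms.
#' @param eta numeric matrix of random effects, one row per subject and
#'   columns named as in `rownames(model$omega)`; defaults to all zero.
#' @return data.frame with columns `cl`, `v2`, `v3`, `q`, `ka`, `f`,
#'   `ruv_scale`, one row per subject (`v3`/`q` are `NA` for the
#'   one-compartment model).
#' @examples
#' individual_params(dtg_model(), data.frame(weight = 79, bilirubin = 8,
#'                                           ethnicity_hispanic = 0))
#' @export
individual_params <- function(model, covariates, eta = NULL) {
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  en <- eta_names(model)
  if (is.null(eta)) {
    eta <- matrix(0, n, length(en), dimnames = list(NULL, en))
  } else {
    eta <- as.matrix(eta)
    if (is.null(colnames(eta))) colnames(eta) <- en
    if (nrow(eta) != n || !all(en %in% colnames(eta)))
      stop("eta must have one row per subject and columns ", paste(en, collapse = ", "))
  }
  p <- list(cl = rep(model$theta$cl, n), v2 = rep(model$theta$v2, n),
            q = rep(if (is.null(model$theta$q)) NA_real_ else model$theta$q, n),
            ka = rep(model$theta$ka, n))
  for (term in model$covariates) {
    if (!term$covariate %in% names(covariates))
      stop("covariate '", term$covariate, "' not found in covariate table")
    x <- covariates[[term$covariate]]
    mult <- covariate_multiplier(term, x)
    p[[term$target]] <- p[[term$target]] * mult
  }
  if ("eta_cl" %in% en) p$cl <- p$cl * exp(eta[, "eta_cl"])
  if ("eta_v2" %in% en) p$v2 <- p$v2 * exp(eta[, "eta_v2"])
  v3 <- if (model$v3_rule == "equal_v2") p$v2 else rep(NA_real_, n)
  ruv <- if ("eta_ruv" %in% en) exp(eta[, "eta_ruv"]) else rep(1, n)
  data.frame(cl = p$cl, v2 = p$v2, v3 = v3, q = p$q, ka = p$ka,
             f = rep(1, n), ruv_scale = ruv)
}

covariate_multiplier <- function(term, x) {
  if (term$form %in% c("power", "allometric")) {
    if (any(!is.finite(x) | x <= 0))
      stop("covariate '", term$covariate, "' must be positive for a power term")
    (x / term$reference)^term$value
  } else {
    if (any(!x %in% c(0, 1)))
      stop("covariate '", term$covariate, "' must be a 0/1 indicator")
    term$value^x
  }
}

#' Percent change in a parameter relative to its reference subject
#'
#' For a power term the effect of covariate value `x` against reference
#' `ref` with exponent `e` is `100 * ((x/ref)^e - 1)`; for a categorical
#' term with multiplier `r` it is `100 * (r - 1)`.
#'
#' @param form `"power"` (or `"allometric"`) or `"categorical"`.
#' @param value covariate value (ignored for categorical).
#' @param reference reference covariate value (ignored for categorical).
#' @param estimate exponent or categorical multiplier.
#' @return percent change versus the reference subject.
#' @examples
#' covariate_effect_percent("power", 2, 8, -0.153)    # low bilirubin
#' covariate_effect_percent("categorical", estimate = 0.844)
#' @export
covariate_effect_percent <- function(form, value = NA_real_,
                                     reference = NA_real_, estimate) {
  if (form %in% c("power", "allometric")) {
    if (!is.finite(value) || value <= 0) stop("power form needs a positive covariate value")
    100 * ((value / reference)^estimate - 1)
  } else if (form == "categorical") {
    100 * (estimate - 1)
  } else stop("unknown form: ", form)
}

#' Variance of a log-normal random effect expressed as percent CV
#'
#' Uses the exact log-normal relation `%CV = 100 * sqrt(exp(omega2) - 1)`.
#'
#' @param omega2 variance of the random effect on the log scale.
#' @return percent coefficient of variation.
#' @export
iiv_percent_cv <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be non-negative")
  100 * sqrt(exp(omega2) - 1)
}

#' Inverse of [iiv_percent_cv()]
#' @param cv percent coefficient of variation.
#' @return log-scale variance.
#' @export
percent_cv_to_omega2 <- function(cv) log(1 + (cv / 100)^2)

#' Read / write a model definition file
#'
#' Model definition files are YAML with fields `drug`, `n_cmt`, `theta`,
#' `v3_rule`, `covariates` (list of target/covariate/form/reference/value),
#' `omega` (names + matrix rows), `prop_sd`, `dose`, `tau`, `lloq`. The
#' package ships definitions of both final models under
#' `system.file("extdata", package = "dlpoppk")`.
#'
#' @param path file path.
#' @return [read_model_yaml()] returns a `pk_model`;
#'   [write_model_yaml()] returns `path` invisibly.
#' @export
read_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  om <- do.call(rbind, y$omega$matrix)
  dimnames(om) <- list(y$omega$names, y$omega$names)
  terms <- lapply(y$covariates, function(tm)
    covariate_term(tm$target, tm$covariate, tm$form,
                   reference = if (is.null(tm$reference)) NA_real_ else tm$reference,
                   value = tm$value))
  pk_model(drug = y$drug, n_cmt = y$n_cmt, theta = y$theta,
           v3_rule = y$v3_rule, covariates = terms, omega = om,
           prop_sd = y$prop_sd, dose = y$dose, tau = y$tau,
           lloq = if (is.null(y$lloq)) NA_real_ else y$lloq)
}

#' @rdname read_model_yaml
#' @param model a `pk_model` to serialise.
#' @export
write_model_yaml <- function(model, path) {
  y <- list(
    drug = model$drug, n_cmt = model$n_cmt,
    theta = model$theta, v3_rule = model$v3_rule,
    covariates = lapply(model$covariates, function(tm)
      list(target = tm$target, covariate = tm$covariate, form = tm$form,
           reference = if (is.finite(tm$reference)) tm$reference else NULL,
           value = tm$value)),
    omega = list(names = rownames(model$omega),
                 matrix = lapply(seq_len(nrow(model$omega)),
                                 function(i) unname(model$omega[i, ]))),
    prop_sd = model$prop_sd, dose = model$dose, tau = model$tau,
    lloq = model$lloq)
  yaml::write_yaml(y, path)
  invisible(path)
}
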
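#' Prepare the swipe-level covariate frame for modelling
#'
#' Joins participant metadata onto the retained swipes and applies the
#' centring conventions used throughout the models: target-distance category
#' is mapped to an integer index centred at the median category (30-40 mm,
#' so `dist_c` runs over -2..3), and age is scaled to years and centred at
#' 4.7 years. Positively skewed outcomes (MT, PV, TTPV) get log-transformed
#' companions.
#'
#' @param kin Retained swipe-level kinematics (must carry `dist_cat`).
#' @param participants Tibble with `participant_id`, `group` (`"ASD"` /
#'   `"TD"`), `age_months`, and optionally `sex`.
#' @param age_center Centring age in years (default 4.7, the cohort mean).
#' @return A covariate frame: one row per swipe with `subject`, `asd`,
#'   `age_c`, `dist_c`, raw and log outcomes.
#' @export
prepare_covariates <- function(kin, participants, age_center = 4.7) {
  need <- c("participant_id", "group", "age_months")
  if (!all(need %in% names(participants))) {
    stopf("`participants` must carry columns: %s", paste(need, collapse = ", "))
  }
  missing <- setdiff(unique(kin$participant_id), participants$participant_id)
  if (length(missing)) {
    stopf("participants missing age/group metadata: %s", paste(missing, collapse = ", "))
  }
  if (any(is.na(kin$dist_cat))) {
    stopf("all retained swipes must have a distance category (run the cohort filter first)")
  }
  p <- participants[c("participant_id", "group", "age_months",
                      intersect("sex", names(participants)))]
  out <- dplyr::left_join(kin, p, by = "participant_id")
  tibble(
    subject = factor(out$participant_id),
    group = out$group,
    asd = as.integer(out$group == "ASD"),
    age_years = out$age_months / 12,
    age_c = out$age_months / 12 - age_center,
    dist_cat = out$dist_cat,
    dist_c = as.integer(out$dist_cat) - 3L,
    mt = out$mt, pv = out$pv, ttpv = out$ttpv,
    log_mt = log(out$mt), log_pv = log(out$pv), log_ttpv = log(out$ttpv),
    pv1 = out$pv1, pct_dec = out$pct_dec,
    mu = out$mu, mu_apv = out$mu_apv,
    pv1_b = as.integer(out$pv1_b)
  )
}

#' Declarative mixed-model specification
#'
#' @param outcome Outcome label (e.g. `"MT"`).
#' @param family `"gaussian"`, `"binomial"`, `"poisson"` or `"ztpoisson"`
#'   (zero-truncated Poisson, for the movement-unit count which is at least
#'   1 by construction).
#' @param transform `"log"` or `"identity"` (gaussian outcomes only).
#' @param fixed Character vector of fixed-effect terms among `"Dist"`,
#'   `"age"`, `"ASD"`, `"ASD:age"`, `"ASD:Dist"`, `"Dist:age"`.
#' @return A `model_spec`. Gaussian models are fitted by REML, all others
#'   by ML (Laplace approximation).
#' @export
model_spec <- function(outcome, family = "gaussian", transform = "identity",
                       fixed = c("Dist", "age", "ASD")) {
  family <- match.arg(family, c("gaussian", "binomial", "poisson", "ztpoisson"))
  transform <- match.arg(transform, c("identity", "log"))
  allowed <- c("Dist", "age", "ASD", "ASD:age", "ASD:Dist", "Dist:age")
  bad <- setdiff(fixed, allowed)
  if (length(bad)) stopf("unknown fixed terms: %s", paste(bad, collapse = ", "))
  structure(list(outcome = outcome, family = family, transform = transform,
                 fixed = fixed,
                 estimator = if (family == "gaussian") "REML" else "ML"),
            class = "model_spec")
}

#' Final model specifications for all swipe outcomes
#'
#' The per-outcome fixed-effect sets retained by the model-building
#' procedure (hypothesised main effects of Dist, age and ASD, plus only the
#' interactions that improved the model), each with a by-subject random
#' intercept and Dist slope:
#' \itemize{
#'   \item log MT, log PV, log TTPV: `Dist + age + ASD + ASD:age`
#'   \item PV1-b (logistic): `Dist + age + ASD`, no interactions
#'   \item MU-APV (Poisson): `Dist + age + ASD + ASD:age + ASD:Dist`
#'   \item MU (zero-truncated Poisson), %Dec: `Dist + age + ASD`
#'   \item PV1 (linear): `Dist + age + ASD + Dist:age`
#' }
#'
#' @return Named list of [model_spec()] objects.
#' @export
final_model_specs <- function() {
  list(
    MT = model_spec("MT", "gaussian", "log", c("Dist", "age", "ASD", "ASD:age")),
    PV = model_spec("PV", "gaussian", "log", c("Dist", "age", "ASD", "ASD:age")),
    TTPV = model_spec("TTPV", "gaussian", "log", c("Dist", "age", "ASD", "ASD:age")),
    PV1_b = model_spec("PV1_b", "binomial", "identity", c("Dist", "age", "ASD")),
    MU_APV = model_spec("MU_APV", "poisson", "identity",
                        c("Dist", "age", "ASD", "ASD:age", "ASD:Dist")),
    MU = model_spec("MU", "ztpoisson", "identity", c("Dist", "age", "ASD")),
    PV1 = model_spec("PV1", "gaussian", "identity", c("Dist", "age", "ASD", "Dist:age")),
    pct_dec = model_spec("pct_dec", "gaussian", "identity", c("Dist", "age", "ASD"))
  )
}

# term translation: model-speak -> covariate-frame columns
term_to_var <- function(terms) {
  map <- c("Dist" = "dist_c", "age" = "age_c", "ASD" = "asd",
           "ASD:age" = "asd:age_c", "ASD:Dist" = "asd:dist_c",
           "Dist:age" = "dist_c:age_c")
  unname(map[terms])
}

response_var <- function(spec) {
  base <- tolower(spec$outcome)
  if (spec$transform == "log") paste0("log_", base) else base
}

#' Fit a mixed model from a specification
#'
#' Gaussian outcomes are fitted with `lmerTest::lmer` (REML, Satterthwaite
#' degrees of freedom for p-values and confidence intervals); binomial,
#' Poisson and zero-truncated Poisson outcomes with `glmmTMB` (ML, Laplace
#' approximation, Wald z inference). Coefficients are reported on the
#' link/log scale and exponentiated (multiplicative effect / odds ratio /
#' incidence-rate ratio) where the scale is log or logit.
#'
#' A singular random-effects fit (a variance component collapsing to zero)
#' is returned with `singular = TRUE` rather than raising an error. A
#' generalised fit whose Hessian is not positive definite under the full
#' random structure is refitted with a by-group random intercept only
#' (recorded in `re_structure`); if that also fails to converge, an error
#' is raised.
#'
#' @param frame Covariate frame from [prepare_covariates()] (or the
#'   synthetic equivalent).
#' @param spec A [model_spec()].
#' @param random Random-effects formula chunk (default
#'   `"(1 + dist_c | subject)"`).
#' @return A `kin_fit`: list with the fitted `model`, tidy `coefficients`
#'   tibble, `varcomp` (variance components with ICC and marginal /
#'   conditional R-squared), `aic`, `deviance`, `singular`, the
#'   `re_structure` actually fitted, and sizes.
#' @export
fit_mixed <- function(frame, spec, random = "(1 + dist_c | subject)") {
  stopifnot(inherits(spec, "model_spec"))
  if (length(unique(frame$subject)) < 2 || length(unique(frame$dist_c)) < 2) {
    stopf("frame is degenerate: need >= 2 subjects and >= 2 distance values")
  }
  resp <- response_var(spec)
  if (!resp %in% names(frame)) stopf("outcome column `%s` not found in frame", resp)
  rhs <- paste(c(term_to_var(spec$fixed), random), collapse = " + ")
  form <- as.formula(paste(resp, "~", rhs))

  if (spec$family == "gaussian") {
    re_structure <- random
    model <- lmerTest::lmer(form, data = frame, REML = TRUE)
    cf <- summary(model)$coefficients
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]; df <- cf[, "df"]
    crit <- qt(0.975, df)
    coefs <- tibble(term = rownames(cf), estimate = est, se = se, df = df,
                    statistic = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                    ci_lo = est - crit * se, ci_hi = est + crit * se)
    vc <- lme4::VarCorr(model)
    subj <- vc[["subject"]]
    tau00 <- subj[1, 1]
    tau11 <- if (nrow(subj) > 1) subj[2, 2] else 0
    rho01 <- if (nrow(subj) > 1) attr(subj, "correlation")[1, 2] else NA_real_
    sigma2 <- stats::sigma(model)^2
    singular <- lme4::isSingular(model)
    dev <- -2 * as.numeric(logLik(model))
  } else {
    fam <- switch(spec$family,
                  binomial = stats::binomial(),
                  poisson = stats::poisson(),
                  ztpoisson = glmmTMB::truncated_poisson())
    # near-boundary variance components (a tiny slope variance or a
    # correlation close to +/-1) can leave the Laplace fit with a
    # non-positive-definite Hessian; fall back to an intercept-only random
    # structure rather than failing the whole analysis
    grouping <- sub(".*\\|\\s*([^)]+)\\)$", "\\1", random)
    candidates <- unique(c(random, sprintf("(1 | %s)", grouping)))
    model <- NULL
    re_structure <- NA_character_
    for (cand in candidates) {
      form_c <- as.formula(paste(resp, "~",
                                 paste(c(term_to_var(spec$fixed), cand), collapse = " + ")))
      m <- suppressWarnings(glmmTMB::glmmTMB(form_c, data = frame, family = fam))
      if (isTRUE(m$sdr$pdHess)) {
        model <- m
        re_structure <- cand
        break
      }
    }
    if (is.null(model)) {
      stopf("mixed-model optimiser did not converge (non-positive-definite Hessian) for %s",
            spec$outcome)
    }
    cf <- summary(model)$coefficients$cond
    est <- cf[, "Estimate"]; se <- cf[, "Std. Error"]
    crit <- qnorm(0.975)
    coefs <- tibble(term = rownames(cf), estimate = est, se = se, df = NA_real_,
                    statistic = cf[, "z value"], p = cf[, "Pr(>|z|)"],
                    ci_lo = est - crit * se, ci_hi = est + crit * se)
    subj <- glmmTMB::VarCorr(model)$cond[["subject"]]
    tau00 <- subj[1, 1]
    tau11 <- if (nrow(subj) > 1) subj[2, 2] else 0
    rho01 <- if (nrow(subj) > 1) attr(subj, "correlation")[1, 2] else NA_real_
    sigma2 <- NA_real_
    sds <- attr(subj, "stddev")
    singular <- any(sds < 1e-4) || (!is.na(rho01) && abs(rho01) > 0.9999)
    dev <- -2 * as.numeric(logLik(model))
  }

  exponentiate <- spec$transform == "log" || spec$family != "gaussian"
  if (exponentiate) {
    coefs$exp_estimate <- exp(coefs$estimate)
    coefs$exp_ci_lo <- exp(coefs$ci_lo)
    coefs$exp_ci_hi <- exp(coefs$ci_hi)
  }

  fit <- structure(
    list(model = model, spec = spec, coefficients = coefs,
         tau00 = tau00, tau11 = tau11, rho01 = rho01, sigma2 = sigma2,
         singular = singular, re_structure = re_structure,
         aic = AIC(model), deviance = dev,
         n_obs = nrow(frame), n_subjects = length(unique(frame$subject)),
         fixed_formula = as.formula(paste("~", paste(term_to_var(spec$fixed), collapse = " + "))),
         frame = frame),
    class = "kin_fit")
  fit$varcomp <- variance_components(fit)
  fit
}

#' Variance components, ICC and marginal / conditional R-squared
#'
#' Variance partitioning follows the Nakagawa-Schielzeth framework: the
#' fixed-effect variance is the variance of the linear predictor built from
#' the estimated fixed effects; the random-effect variance averages the
#' subject-level variance `tau00 + 2 rho sqrt(tau00 tau11) d + tau11 d^2`
#' over the observed distance indices; the residual variance is the model
#' sigma-squared for gaussian outcomes, `pi^2 / 3` on the latent scale for
#' logistic models, and the log-normal approximation `ln(1 + 1/lambda)`
#' for (truncated) Poisson models with `lambda = exp(b0 + var_re / 2)`.
#' ICC is the random-effect share of the non-fixed variance; marginal R2
#' the fixed-effect share of the total, conditional R2 adds the random
#' effects.
#'
#' @param fit A `kin_fit` from [fit_mixed()].
#' @return A tibble with `sigma2`, `tau00`, `tau11`, `rho01`, `icc`,
#'   `r2_marginal`, `r2_conditional`.
#' @export
variance_components <- function(fit) {
  stopifnot(inherits(fit, "kin_fit"))
  X <- model.matrix(fit$fixed_formula, data = fit$frame)
  beta <- fit$coefficients$estimate[match(colnames(X), fit$coefficients$term)]
  var_f <- var(as.vector(X %*% beta))
  d <- fit$frame$dist_c
  covar <- if (is.na(fit$rho01)) 0 else fit$rho01 * sqrt(fit$tau00 * fit$tau11)
  var_re <- mean(fit$tau00 + 2 * covar * d + fit$tau11 * d^2)
  var_resid <- switch(fit$spec$family,
    gaussian = fit$sigma2,
    binomial = pi^2 / 3,
    poisson = ,
    ztpoisson = {
      b0 <- fit$coefficients$estimate[fit$coefficients$term == "(Intercept)"]
      log(1 + 1 / exp(b0 + var_re / 2))
    })
  tibble(
    sigma2 = var_resid, tau00 = fit$tau00, tau11 = fit$tau11, rho01 = fit$rho01,
    icc = var_re / (var_re + var_resid),
    r2_marginal = var_f / (var_f + var_re + var_resid),
    r2_conditional = (var_f + var_re) / (var_f + var_re + var_resid)
  )
}

#' Dispersion ratio of a count-family fit
#'
#' Sum of squared Pearson residuals divided by the residual degrees of
#' freedom (observations minus fixed-effect parameters). Values near 1
#' indicate the Poisson variance assumption holds; values above 1 indicate
#' overdispersion.
#'
#' @param fit A `kin_fit` with a Poisson or zero-truncated Poisson family.
#' @return Scalar dispersion ratio.
#' @export
dispersion_ratio <- function(fit) {
  stopifnot(inherits(fit, "kin_fit"))
  if (!fit$spec$family %in% c("poisson", "ztpoisson")) {
    stopf("dispersion ratio is defined for count families, not %s", fit$spec$family)
  }
  pr <- residuals(fit$model, type = "pearson")
  df_resid <- fit$n_obs - nrow(fit$coefficients)
  sum(pr^2) / df_resid
}

#' Zero-truncated Poisson log-likelihood
#'
#' `sum(y log(mu) - mu - log(1 - exp(-mu)) - log(y!))` for counts `y >= 1`
#' with untruncated rate `mu`. Exposed for verification of truncated-count
#' fits.
#'
#' @param y Integer counts (all >= 1).
#' @param mu Untruncated Poisson rate(s).
#' @return Scalar log-likelihood.
#' @export
ztp_loglik <- function(y, mu) {
  if (any(y < 1)) stopf("zero-truncated counts must be >= 1")
  sum(y * log(mu) - mu - log(1 - exp(-mu)) - lgamma(y + 1))
}

#' Pairwise correlations between kinematic outcomes
#'
#' Pearson correlations over the eight swipe-level outcomes (the binary
#' PV1-b enters as 0/1, i.e. a point-biserial correlation). Constant
#' columns yield `NA` entries with a warning instead of propagating NaN.
#'
#' @param kin Swipe-level table with columns `ttpv`, `mt`, `mu`, `pct_dec`,
#'   `mu_apv`, `pv1_b`, `pv1`, `pv`.
#' @return Symmetric correlation matrix.
#' @export
pairwise_correlations <- function(kin) {
  vars <- c("ttpv", "mt", "mu", "pct_dec", "mu_apv", "pv1_b", "pv1", "pv")
  if (nrow(kin) < 3) stopf("need at least 3 swipes for correlations")
  m <- sapply(vars, function(v) as.numeric(kin[[v]]))
  const <- apply(m, 2, function(col) sd(col, na.rm = TRUE) == 0 || all(is.na(col)))
  if (any(const)) {
    warnf("constant columns excluded from correlations: %s",
          paste(vars[const], collapse = ", "))
  }
  out <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  out[const, ] <- NA_real_
  out[, const] <- NA_real_
  diag(out) <- ifelse(const, NA_real_, 1)
  out
}

#' @export
print.kin_fit <- function(x, ...) {
  cat(sprintf("<kin_fit> %s: %s (%s)%s\n", x$spec$outcome, x$spec$family,
              x$spec$estimator, if (x$singular) " [singular]" else ""))
  cat(sprintf("  %d swipes, %d subjects; AIC %.1f\n", x$n_obs, x$n_subjects, x$aic))
  print(as.data.frame(x$coefficients), row.names = FALSE, digits = 3)
  print(as.data.frame(x$varcomp), row.names = FALSE, digits = 3)
  invisible(x)
}
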
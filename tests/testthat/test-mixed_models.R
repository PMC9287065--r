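make_participants <- function(ids, group, age_months, sex = NULL) {
  out <- tibble::tibble(participant_id = ids, group = group, age_months = age_months)
  if (!is.null(sex)) out$sex <- sex
  out
}

test_that("prepare_covariates applies the centring conventions", {
  kin <- tibble::tibble(
    participant_id = c("a", "a", "b"),
    dist_cat = dist_category(c(35, 15, 70)),
    mt = c(0.5, 0.7, 1.0), pv = c(100, 80, 150), ttpv = c(0.2, 0.3, 0.4),
    pv1 = c(100, 80, 150), pct_dec = c(55, 50, 60),
    mu = c(1L, 2L, 1L), mu_apv = c(0L, 1L, 0L), pv1_b = c(TRUE, FALSE, TRUE)
  )
  parts <- make_participants(c("a", "b"), c("TD", "ASD"), c(4.7 * 12, 3.7 * 12))
  cv <- prepare_covariates(kin, parts)
  # the median category 30-40 maps to 0; categories run -2..3
  expect_equal(cv$dist_c, c(0L, -2L, 3L))
  expect_equal(cv$age_c, c(0, 0, -1))
  expect_equal(cv$asd, c(0L, 0L, 1L))
  expect_equal(cv$log_mt, log(kin$mt))
  expect_equal(cv$pv1_b, c(1L, 0L, 1L))
  expect_s3_class(cv$subject, "factor")

  # missing metadata and missing distance categories are hard errors
  expect_error(prepare_covariates(kin, parts[1, ]), "missing")
  kin2 <- kin; kin2$dist_cat[2] <- NA
  expect_error(prepare_covariates(kin2, parts), "distance category")
})

test_that("final model specifications encode the retained fixed effects", {
  specs <- final_model_specs()
  expect_setequal(names(specs),
                  c("MT", "PV", "TTPV", "PV1_b", "MU_APV", "MU", "PV1", "pct_dec"))
  expect_equal(specs$MT$fixed, c("Dist", "age", "ASD", "ASD:age"))
  expect_equal(specs$MT$transform, "log")
  expect_equal(specs$PV1_b$family, "binomial")
  expect_equal(specs$PV1_b$fixed, c("Dist", "age", "ASD"))
  expect_equal(specs$MU_APV$fixed, c("Dist", "age", "ASD", "ASD:age", "ASD:Dist"))
  expect_equal(specs$MU$family, "ztpoisson")
  expect_equal(specs$MT$estimator, "REML")
  expect_equal(specs$MU$estimator, "ML")
  expect_error(model_spec("X", fixed = "banana"), "unknown fixed terms")
})

test_that("a gaussian fit recovers generating coefficients on one cohort", {
  frame <- simulate_cohort_outcomes(cohort_sim_config(seed = 7))
  truth <- attr(frame, "generative_params")$MT
  fit <- fit_mixed(frame, final_model_specs()$MT)
  expect_s3_class(fit, "kin_fit")
  cf <- fit$coefficients
  est <- setNames(cf$estimate, cf$term)
  # single-cohort sampling noise: compare within ~3 SEs of each term
  for (term in c("(Intercept)", "dist_c", "age_c", "asd")) {
    tr <- switch(term, "(Intercept)" = truth$beta[["intercept"]],
                 dist_c = truth$beta[["dist"]], age_c = truth$beta[["age"]],
                 asd = truth$beta[["asd"]])
    expect_lt(abs(est[[term]] - tr), 3.5 * cf$se[cf$term == term])
  }
  expect_true(all(c("exp_estimate", "exp_ci_lo", "exp_ci_hi") %in% names(cf)))
  expect_equal(cf$exp_estimate, exp(cf$estimate))
  expect_equal(fit$n_subjects, 70)
  expect_false(fit$singular)
  expect_gt(fit$tau00, 0.05)
})

test_that("zero random-effect data is flagged singular and matches OLS", {
  params <- default_generative_params()
  params$pct_dec$tau00 <- 0
  params$pct_dec$tau11 <- 0
  params$pct_dec$rho01 <- 0
  frame <- simulate_cohort_outcomes(
    cohort_sim_config(n_td = 15, n_asd = 15, swipes_per_subject = 30,
                      params = params, seed = 3))
  fit <- fit_mixed(frame, final_model_specs()$pct_dec)
  expect_true(fit$singular)
  # with no subject variance the fixed effects collapse to the OLS solution
  ols <- lm(pct_dec ~ dist_c + age_c + asd, data = frame)
  expect_equal(setNames(fit$coefficients$estimate, NULL),
               unname(coef(ols)), tolerance = 0.02)
})

test_that("the ICC reflects a known variance split", {
  params <- default_generative_params()
  params$pct_dec$tau00 <- 350   # equal to sigma2 => ICC 0.5
  params$pct_dec$tau11 <- 0
  params$pct_dec$rho01 <- 0
  params$pct_dec$sigma2 <- 350
  frame <- simulate_cohort_outcomes(cohort_sim_config(params = params, seed = 11))
  fit <- fit_mixed(frame, final_model_specs()$pct_dec)
  expect_equal(fit$varcomp$icc, 0.5, tolerance = 0.08)
  expect_gte(fit$varcomp$r2_conditional, fit$varcomp$r2_marginal)
  expect_lte(fit$varcomp$r2_conditional, 1)
})

test_that("the zero-truncated Poisson likelihood matches first principles", {
  y <- c(1L, 1L, 2L, 3L, 1L, 5L, 2L)
  mu <- 1.7
  manual <- sum(dpois(y, mu, log = TRUE) - log(1 - dpois(0, mu)))
  expect_equal(ztp_loglik(y, mu), manual, tolerance = 1e-12)
  expect_error(ztp_loglik(c(0L, 1L), 1), ">= 1")

  # the MLE satisfies mean(y) = mu / (1 - exp(-mu))
  set.seed(5)
  y2 <- rztpois(4000, 1.4)
  mu_hat <- optimize(function(m) -ztp_loglik(y2, m), c(0.01, 10))$minimum
  expect_equal(mu_hat / (1 - exp(-mu_hat)), mean(y2), tolerance = 1e-4)
})

test_that("fitting a truncated-count model agrees with the exposed likelihood", {
  params <- default_generative_params()
  set.seed(13)
  y <- rztpois(500, 1.6)
  # intercept-only fixed-effect fit: its log-likelihood must equal the
  # exposed truncated likelihood at the fitted rate, and the fitted rate
  # must match the direct MLE of ztp_loglik
  d <- data.frame(y = y)
  m <- glmmTMB::glmmTMB(y ~ 1, data = d, family = glmmTMB::truncated_poisson())
  lambda_hat <- exp(unname(glmmTMB::fixef(m)$cond))
  expect_equal(ztp_loglik(y, lambda_hat), as.numeric(logLik(m)),
               tolerance = 1e-8)
  mle <- optimize(function(l) -ztp_loglik(y, l), c(0.01, 10))$minimum
  expect_equal(lambda_hat, mle, tolerance = 1e-4)
})

test_that("dispersion ratio is near 1 for Poisson data and above 1 when overdispersed", {
  params <- default_generative_params()
  frame <- simulate_cohort_outcomes(
    cohort_sim_config(n_td = 20, n_asd = 20, swipes_per_subject = 40,
                      params = params[c("MU_APV", "pct_dec")], seed = 17))
  fit <- fit_mixed(frame, final_model_specs()$MU_APV)
  expect_equal(dispersion_ratio(fit), 1, tolerance = 0.12)

  over <- frame
  set.seed(23)
  over$mu_apv <- rnbinom(nrow(over), mu = pmax(exp(-1), over$mu_apv), size = 0.8)
  # gross overdispersion can leave the RE fit singular; only the ratio matters
  fit2 <- suppressWarnings(fit_mixed(over, final_model_specs()$MU_APV))
  expect_gt(dispersion_ratio(fit2), 1.3)

  fitg <- fit_mixed(frame, final_model_specs()$pct_dec)
  expect_error(dispersion_ratio(fitg), "count families")
})

test_that("pairwise correlations are symmetric with sane trivial cases", {
  set.seed(31)
  n <- 50
  kin <- tibble::tibble(
    ttpv = runif(n, 0.1, 0.5), mt = NA, mu = sample(1:4, n, TRUE),
    pct_dec = runif(n, 30, 80), mu_apv = rpois(n, 0.4),
    pv1_b = rbinom(n, 1, 0.8) == 1, pv1 = runif(n, 50, 200), pv = NA
  )
  kin$mt <- 2 * kin$ttpv            # perfectly correlated pair
  kin$pv <- -kin$pv1                # perfectly anti-correlated pair
  m <- pairwise_correlations(kin)
  expect_equal(dim(m), c(8, 8))
  expect_equal(m, t(m))
  expect_equal(m["ttpv", "mt"], 1)
  expect_equal(m["pv1", "pv"], -1)
  expect_true(all(abs(m[!is.na(m)]) <= 1 + 1e-12))

  kin$mu <- 2L                       # constant column
  expect_warning(m2 <- pairwise_correlations(kin), "constant")
  expect_true(all(is.na(m2["mu", ])))
  expect_error(pairwise_correlations(kin[1:2, ]), "at least 3")
})

test_that("cohort descriptive tests reproduce hand-checked chi-squared values", {
  # exclusion-by-group 2x2 with 640 excluded / 2593 analysed vs
  # 351 excluded / 1333 analysed: Yates-corrected X2 = 0.6911, p = 0.4058
  # (hand-computed from the continuity-corrected formula, frozen here)
  tab <- tibble::tibble(
    reason = c(rep("mt_outlier", 640), rep(NA, 2593),
               rep("mt_outlier", 351), rep(NA, 1333)),
    group = c(rep("TD", 640 + 2593), rep("ASD", 351 + 1333))
  )
  report <- structure(list(table = tab), class = "exclusion_report")

  set.seed(41)
  n_per <- sample(20:40, 20, replace = TRUE)
  parts <- make_participants(sprintf("p%02d", 1:20),
                             rep(c("TD", "ASD"), each = 10),
                             round(runif(20, 36, 78)),
                             sex = sample(c("M", "F"), 20, TRUE))
  kin <- tibble::tibble(
    participant_id = rep(parts$participant_id, n_per),
    group = rep(parts$group, n_per),
    dist_cat = dist_category(runif(sum(n_per), 12, 68))
  )
  res <- cohort_tests(kin, parts, report)
  excl <- res[res$test == "exclusion_by_group", ]
  expect_equal(excl$statistic, 0.691, tolerance = 0.001)
  expect_equal(excl$p, 0.406, tolerance = 0.001)
  expect_equal(excl$df, 1)

  expect_setequal(res$test,
                  c("exclusion_by_group", "sex_by_group", "dist_by_group",
                    "age_t", "age_var_F", "swipes_per_participant_t",
                    "dist_median_mw"))
  expect_true(all(res$p >= 0 & res$p <= 1))

  # degenerate data (identical swipe counts everywhere) degrades softly
  kin2 <- tibble::tibble(
    participant_id = rep(parts$participant_id, each = 10),
    group = rep(parts$group, each = 10),
    dist_cat = dist_category(runif(200, 12, 68))
  )
  res2 <- cohort_tests(kin2, parts)
  spp <- res2[res2$test == "swipes_per_participant_t", ]
  expect_true(is.na(spp$statistic))
  expect_match(spp$note, "constant")
})

test_that("an empty contingency cell falls back to Fisher's exact test", {
  parts <- make_participants(sprintf("p%02d", 1:10),
                             rep(c("TD", "ASD"), each = 5),
                             round(runif(10, 36, 78)),
                             sex = c(rep("M", 5), rep(c("M", "F"), c(2, 3))))
  kin <- tibble::tibble(
    participant_id = rep(parts$participant_id, each = 10),
    group = rep(parts$group, each = 10),
    dist_cat = dist_category(runif(100, 12, 68))
  )
  res <- cohort_tests(kin, parts)
  expect_match(res$note[res$test == "sex_by_group"], "Fisher")
})
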
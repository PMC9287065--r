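test_that("minimum-jerk primitives match their closed forms", {
  tau <- seq(0, 1, by = 0.01)
  # displacement: 10 tau^3 - 15 tau^4 + 6 tau^5; speed: 30 tau^2 - 60 tau^3 + 30 tau^4
  expect_equal(min_jerk_displacement(tau), 10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  expect_equal(min_jerk_speed(tau), 30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  # clamped outside [0, 1]
  expect_equal(min_jerk_displacement(c(-0.5, 1.5)), c(0, 1))
  expect_equal(min_jerk_speed(c(-0.5, 1.5)), c(0, 0))
  # peak speed 1.875 at the midpoint
  expect_equal(max(min_jerk_speed(tau)), 1.875)
  expect_equal(tau[which.max(min_jerk_speed(tau))], 0.5)
})

test_that("trajectory simulation is a pure function of config and seed", {
  cfg <- trajectory_sim_config(submovement(30, 0, 0.5), noise_sd = 0.4, seed = 9)
  a <- simulate_trajectory(cfg)
  b <- simulate_trajectory(cfg)
  expect_identical(a$events, b$events)
  cfg2 <- cfg; cfg2$seed <- 10
  expect_false(identical(simulate_trajectory(cfg2)$events$x, a$events$x))
  # the global RNG stream is left untouched
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(simulate_trajectory(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("noiseless multi-submovement trajectories recover their unit count", {
  for (k in 1:5) {
    sm <- do.call(rbind, lapply(seq_len(k), function(j) {
      submovement(amplitude = 12, onset = (j - 1) * 0.5, duration = 0.35,
                  angle = (j %% 2) * pi / 6)
    }))
    sim <- simulate_trajectory(trajectory_sim_config(sm, noise_sd = 0, seed = k))
    traj <- regularise_sampling(parse_touch_log(sim$events)$swipes[[1]])
    vel <- velocity_profile(traj)
    expect_equal(nrow(segment_units(vel$speed)), k, info = paste("k =", k))
  }
})

test_that("trajectories that exit the screen are rejected", {
  expect_error(
    simulate_trajectory(trajectory_sim_config(submovement(200, 0, 0.5),
                                              noise_sd = 0, seed = 1)),
    "screen bounds")
})

test_that("cohort simulation is deterministic with the documented structure", {
  cfg <- cohort_sim_config(n_td = 8, n_asd = 8, swipes_per_subject = 12, seed = 5)
  a <- simulate_cohort_outcomes(cfg)
  b <- simulate_cohort_outcomes(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a), 16 * 12)
  expect_equal(length(unique(a$subject)), 16)
  expect_setequal(unique(a$asd), c(0L, 1L))
  expect_true(all(a$dist_c %in% -2:3))
  expect_true(all(a$mu >= 1))
  expect_true(all(a$mu_apv >= 0))
  expect_true(all(a$pv1_b %in% 0:1))
  expect_true(all(a$age_years >= 2.8 & a$age_years <= 6.6))
  expect_equal(a$log_mt, log(a$mt))
  # ground truth rides along
  expect_named(attr(a, "generative_params"), names(default_generative_params()))
})

test_that("distance categories follow the configured proportions", {
  probs <- c(0.059, 0.307, 0.189, 0.217, 0.164, 0.064)
  frame <- simulate_cohort_outcomes(
    cohort_sim_config(n_td = 50, n_asd = 50, swipes_per_subject = 60, seed = 21))
  obs <- as.numeric(table(frame$dist_c)) / nrow(frame)
  expect_lt(max(abs(obs - probs)), 0.025)
})

test_that("zeroing group effects removes the ASD association", {
  params <- zero_group_effects(default_generative_params())
  for (nm in names(params)) {
    expect_true(all(params[[nm]]$beta[c("asd", "asd_age", "asd_dist")] %in% c(0, NA) |
                      is.na(params[[nm]]$beta[c("asd", "asd_age", "asd_dist")])))
  }
  frame <- simulate_cohort_outcomes(
    cohort_sim_config(params = params, seed = 33))
  fit <- fit_mixed(frame, final_model_specs()$MT)
  asd <- fit$coefficients[fit$coefficients$term == "asd", ]
  # under the null the ASD estimate sits within ~3 SEs of zero
  expect_lt(abs(asd$estimate), 3.5 * asd$se)
})

test_that("zero-truncated Poisson draws have the right support and moments", {
  set.seed(77)
  lam <- 1.3
  y <- rztpois(20000, lam)
  expect_true(all(y >= 1))
  # E[Y] = lambda / (1 - exp(-lambda))
  expect_equal(mean(y), lam / (1 - exp(-lam)), tolerance = 0.01)
  # P(Y = 1) = lambda exp(-lambda) / (1 - exp(-lambda))
  expect_equal(mean(y == 1), lam * exp(-lam) / (1 - exp(-lam)), tolerance = 0.01)
  # vectorised rates
  y2 <- rztpois(3, c(0.1, 1, 10))
  expect_length(y2, 3)
})

test_that("negative-binomial swipe counts respect the floor of 5", {
  cfg <- cohort_sim_config(n_td = 20, n_asd = 20,
                           swipes_per_subject = c(10, 1), seed = 13)
  frame <- simulate_cohort_outcomes(cfg)
  counts <- table(frame$subject)
  expect_true(all(counts >= 5))
  expect_gt(length(unique(as.integer(counts))), 3)  # actually dispersed
})

test_that("generative defaults validate their variance parameters", {
  params <- default_generative_params()
  expect_error(cohort_sim_config(params = modifyList(params, list(
    MT = modifyList(params$MT, list(tau00 = -1))))), "variance")
  expect_error(cohort_sim_config(params = modifyList(params, list(
    MT = modifyList(params$MT, list(rho01 = 1.5))))), "rho01")
  expect_error(cohort_sim_config(dist_probs = c(0.5, 0.5)), "six")
})

test_that("movement-unit recovery calibration reports rates per cell", {
  cal <- mu_recovery_calibration(k_values = c(1, 3), noise_sds = c(0, 0.3),
                                 n_reps = 5, seed = 2)
  expect_equal(nrow(cal), 4)
  expect_true(all(cal$recovery_rate >= 0 & cal$recovery_rate <= 1))
  # noiseless, well-separated submovements recover perfectly
  expect_equal(cal$recovery_rate[cal$noise_sd == 0], c(1, 1))
})

test_that("a small parameter-recovery study has the documented shape", {
  study <- parameter_recovery_study(
    n_replicates = 3,
    config = cohort_sim_config(n_td = 10, n_asd = 10, swipes_per_subject = 25,
                               seed = 8),
    outcomes = "MT")
  expect_s3_class(study, "recovery_study")
  s <- study$summary
  expect_setequal(s$term, c("(Intercept)", "dist_c", "age_c", "asd", "age_c:asd"))
  expect_true(all(s$n_ok + s$n_fail == 3))
  expect_true(all(is.finite(s$bias)))
  # truths are wired to the right terms
  gp <- default_generative_params()$MT
  expect_equal(unname(s$truth[s$term == "dist_c"]), gp$beta[["dist"]])
  expect_equal(unname(s$truth[s$term == "age_c:asd"]), gp$beta[["asd_age"]])
})
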
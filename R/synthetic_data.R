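#' Minimum-jerk profile primitives
#'
#' The smoothest point-to-point movement (minimising integrated squared
#' jerk) follows `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5` for normalised
#' time `tau` in `[0, 1]`, with bell-shaped speed
#' `v(tau) = 30 tau^2 - 60 tau^3 + 30 tau^4` peaking at `1.875` (per unit
#' amplitude and duration) at `tau = 0.5`. A submovement of amplitude `A`
#' mm and duration `T` s therefore has peak speed `1.875 * A / T` mm/s.
#'
#' @param tau Normalised time; values outside `[0, 1]` are clamped.
#' @return Normalised displacement or speed.
#' @export
min_jerk_displacement <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' @rdname min_jerk_displacement
#' @export
min_jerk_speed <- function(tau) {
  ifelse(tau < 0 | tau > 1, 0, 30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}

#' Build a submovement row
#'
#' @param amplitude Amplitude in mm (> 0).
#' @param onset Onset time in s.
#' @param duration Duration in s (> 0).
#' @param angle Direction in radians (0 = +x, pi/2 = +y).
#' @return One-row tibble with columns `amplitude`, `onset`, `duration`,
#'   `ux`, `uy`.
#' @export
submovement <- function(amplitude, onset, duration, angle = 0) {
  tibble(amplitude = amplitude, onset = onset, duration = duration,
         ux = cos(angle), uy = sin(angle))
}

#' Configuration for simulating a single touch trajectory
#'
#' Describes a 60-Hz sampled 2-D finger trajectory composed of overlapping
#' minimum-jerk submovements with additive positional noise, emitted as a
#' touch-event log in device pixels. The default positional noise SD of
#' 0.3 mm is a calibration choice for touchscreen sensor noise, exposed
#' here rather than fixed.
#'
#' @param submovements Tibble of submovements (see [submovement()]);
#'   onsets must be non-decreasing, durations positive.
#' @param noise_sd Positional noise SD in mm (>= 0).
#' @param fs Sampling rate, Hz.
#' @param ppi Device pixel density.
#' @param layout A `game_layout` (screen bounds and default start point).
#' @param start_px Start position `c(x, y)` in pixels; defaults to the food
#'   area centre.
#' @param participant_id,gesture_id Identifiers for the emitted events.
#' @param t0 Absolute time of the first event, s.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A `trajectory_sim_config`.
#' @export
trajectory_sim_config <- function(submovements, noise_sd = 0.3, fs = 60, ppi = 326,
                                  layout = default_layout(), start_px = NULL,
                                  participant_id = "sim", gesture_id = "g001",
                                  t0 = 0, seed = 1) {
  sm <- as_tibble(submovements)
  need <- c("amplitude", "onset", "duration", "ux", "uy")
  if (!all(need %in% names(sm)) || nrow(sm) == 0) {
    stopf("`submovements` needs >= 1 row with columns %s", paste(need, collapse = ", "))
  }
  if (any(sm$duration <= 0) || any(sm$amplitude <= 0)) {
    stopf("submovement amplitudes and durations must be positive")
  }
  if (is.unsorted(sm$onset)) stopf("submovement onsets must be non-decreasing")
  if (noise_sd < 0) stopf("`noise_sd` must be >= 0")
  nrm <- sqrt(sm$ux^2 + sm$uy^2)
  sm$ux <- sm$ux / nrm
  sm$uy <- sm$uy / nrm
  if (is.null(start_px)) {
    start_px <- c(mean(layout$food_area[c(1, 3)]), mean(layout$food_area[c(2, 4)]))
  }
  structure(list(submovements = sm, noise_sd = noise_sd, fs = fs, ppi = ppi,
                 layout = layout, start_px = start_px,
                 participant_id = participant_id, gesture_id = gesture_id,
                 t0 = t0, seed = seed),
            class = "trajectory_sim_config")
}

#' Simulate a touch-event log from overlapping minimum-jerk submovements
#'
#' Submovement velocities sum in velocity space; positions are the summed
#' displacement profiles plus Gaussian positional noise, sampled at `fs`
#' and emitted as device-pixel events with began/moved/ended phase codes.
#' Ground truth (movement time, submovement count, noiseless peak speed on
#' a 10x oversampled grid, and whether the noiseless peak lies in the first
#' submovement's span) is attached for end-to-end validation. The recovered
#' movement-unit count can legitimately differ from the submovement count
#' when submovements overlap enough to merge speed peaks; both are
#' recorded.
#'
#' @param config A [trajectory_sim_config()].
#' @return List with `events` (tibble: participant_id, gesture_id, t, x, y,
#'   phase) and `truth` (list).
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "trajectory_sim_config"))
  sm <- config$submovements
  fs <- config$fs
  t_end <- max(sm$onset + sm$duration)
  n <- round(t_end * fs) + 1
  tg <- seq(0, t_end, length.out = n)

  pos <- function(tt) {
    x <- numeric(length(tt)); y <- numeric(length(tt))
    for (k in seq_len(nrow(sm))) {
      s <- sm$amplitude[k] * min_jerk_displacement((tt - sm$onset[k]) / sm$duration[k])
      x <- x + s * sm$ux[k]
      y <- y + s * sm$uy[k]
    }
    list(x = x, y = y)
  }
  spd <- function(tt) {
    vx <- numeric(length(tt)); vy <- numeric(length(tt))
    for (k in seq_len(nrow(sm))) {
      v <- (sm$amplitude[k] / sm$duration[k]) *
        min_jerk_speed((tt - sm$onset[k]) / sm$duration[k])
      vx <- vx + v * sm$ux[k]
      vy <- vy + v * sm$uy[k]
    }
    sqrt(vx^2 + vy^2)
  }

  start_mm <- px_to_mm(config$start_px, config$ppi)
  p <- pos(tg)
  x_mm <- start_mm[1] + p$x
  y_mm <- start_mm[2] + p$y
  if (config$noise_sd > 0) {
    noise <- with_seed(config$seed,
                       list(x = rnorm(n, 0, config$noise_sd),
                            y = rnorm(n, 0, config$noise_sd)))
    x_mm <- x_mm + noise$x
    y_mm <- y_mm + noise$y
  }
  x_px <- mm_to_px(x_mm, config$ppi)
  y_px <- mm_to_px(y_mm, config$ppi)
  scr <- config$layout$screen
  if (any(x_px < 0 | x_px > scr[1] | y_px < 0 | y_px > scr[2])) {
    stopf("simulated trajectory exits the screen bounds")
  }

  fine <- seq(0, t_end, length.out = 10 * n)
  speed_fine <- spd(fine)
  pv_idx <- which.max(speed_fine)[1]
  first_span <- c(sm$onset[1], sm$onset[1] + sm$duration[1])

  events <- tibble(
    participant_id = config$participant_id, gesture_id = config$gesture_id,
    t = config$t0 + tg, x = x_px, y = y_px,
    phase = c(0L, rep(1L, n - 2), 3L)
  )
  truth <- list(
    mt = t_end,
    n_submovements = nrow(sm),
    pv = speed_fine[pv_idx],
    ttpv = fine[pv_idx],
    pv_in_first_span = fine[pv_idx] >= first_span[1] && fine[pv_idx] <= first_span[2],
    end_mm = c(x_mm[n], y_mm[n])
  )
  list(events = events, truth = truth)
}

#' Configuration for simulating cohort-level swipe outcomes
#'
#' Generates swipe outcome tables with the hierarchical structure of the
#' study cohort: subjects carry correlated random intercepts and distance
#' slopes drawn from a bivariate normal, swipe-level distance categories
#' follow the pooled observed proportions, and each outcome is drawn from
#' its model family (log-normal MT/PV/TTPV, Bernoulli PV1-b, Poisson
#' MU-APV, zero-truncated Poisson MU, gaussian PV1 and %Dec). Generative
#' defaults are the estimated fixed effects and variance components of the
#' final models (see [default_generative_params()]).
#'
#' @param n_td,n_asd Subjects per group (defaults 35 + 35).
#' @param swipes_per_subject Swipes per subject. A single number gives a
#'   fixed count; `c(mean, size)` draws negative-binomial counts (min 5).
#' @param age_range Age range in years (default 2.8 to 6.6, sampled
#'   uniformly).
#' @param age_center Centring constant in years (default 4.7).
#' @param dist_probs Probabilities of the six distance categories.
#' @param params Named list of per-outcome generative parameters.
#' @param seed Integer seed.
#' @return A `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_td = 35, n_asd = 35, swipes_per_subject = 55,
                              age_range = c(2.8, 6.6), age_center = 4.7,
                              dist_probs = c(0.059, 0.307, 0.189, 0.217, 0.164, 0.064),
                              params = default_generative_params(), seed = 1) {
  if (length(dist_probs) != 6 || any(dist_probs < 0)) {
    stopf("`dist_probs` must be six non-negative probabilities")
  }
  for (nm in names(params)) {
    p <- params[[nm]]
    if (p$tau00 < 0 || p$tau11 < 0) stopf("variance parameters must be >= 0 (%s)", nm)
    if (!is.na(p$rho01) && abs(p$rho01) > 1) stopf("|rho01| must be <= 1 (%s)", nm)
  }
  structure(list(n_td = n_td, n_asd = n_asd,
                 swipes_per_subject = swipes_per_subject,
                 age_range = age_range, age_center = age_center,
                 dist_probs = dist_probs / sum(dist_probs),
                 params = params, seed = seed),
            class = "cohort_sim_config")
}

#' Generative parameter defaults for the cohort simulator
#'
#' Fixed effects are stored on the link/log scale; the values are the final
#' models' estimates (exponentiated coefficients for MT/PV/TTPV/PV1-b/
#' MU-APV as published for this cohort). The printed slope variances for
#' the gaussian outcomes round to 0.00 while their intercept-slope
#' correlations are nonzero, so a small positive `tau11` (0.003) is used.
#' MU, PV1 and %Dec defaults are this package's own plausible choices (the
#' corresponding fits were not tabulated) and are marked `synthetic`.
#'
#' @return Named list; each element has `family`, `transform`, `beta`
#'   (named: `intercept`, `dist`, `age`, `asd`, `asd_age`, `asd_dist`),
#'   `tau00`, `tau11`, `rho01`, `sigma2`, and a `synthetic` flag.
#' @export
default_generative_params <- function() {
  gp <- function(family, transform, beta, tau00, tau11, rho01, sigma2 = NA_real_,
                 synthetic = FALSE) {
    list(family = family, transform = transform, beta = beta,
         tau00 = tau00, tau11 = tau11, rho01 = rho01, sigma2 = sigma2,
         synthetic = synthetic)
  }
  list(
    MT = gp("gaussian", "log",
            c(intercept = log(0.70), dist = log(1.10), age = log(0.71),
              asd = log(1.13), asd_age = log(1.33)),
            tau00 = 0.13, tau11 = 0.003, rho01 = -0.48, sigma2 = 0.08),
    PV = gp("gaussian", "log",
            c(intercept = log(114.11), dist = log(1.17), age = log(1.25),
              asd = log(0.92), asd_age = log(0.88)),
            tau00 = 0.06, tau11 = 0.003, rho01 = -0.32, sigma2 = 0.09),
    TTPV = gp("gaussian", "log",
              c(intercept = log(0.28), dist = log(1.13), age = log(0.74),
                asd = log(1.20), asd_age = log(1.21)),
              tau00 = 0.14, tau11 = 0.003, rho01 = -0.11, sigma2 = 0.21),
    PV1_b = gp("binomial", "identity",
               c(intercept = log(4.45), dist = log(0.75), age = log(1.89),
                 asd = log(0.56)),
               tau00 = 0.62, tau11 = 0.03, rho01 = -0.52),
    MU_APV = gp("poisson", "identity",
                c(intercept = log(0.29), dist = log(1.33), age = log(0.61),
                  asd = log(1.36), asd_age = log(1.35), asd_dist = log(0.91)),
                tau00 = 0.30, tau11 = 0.01, rho01 = -0.86),
    MU = gp("ztpoisson", "identity",
            c(intercept = log(1.8), dist = log(1.15), age = log(0.85),
              asd = log(1.10)),
            tau00 = 0.04, tau11 = 0.002, rho01 = -0.30, synthetic = TRUE),
    PV1 = gp("gaussian", "identity",
             c(intercept = 100, dist = 10, age = 12, asd = -5),
             tau00 = 300, tau11 = 5, rho01 = -0.30, sigma2 = 1600, synthetic = TRUE),
    pct_dec = gp("gaussian", "identity",
                 c(intercept = 50, dist = 1, age = -1.5, asd = 1),
                 tau00 = 20, tau11 = 0.5, rho01 = -0.20, sigma2 = 350, synthetic = TRUE)
  )
}

#' Set all group effects to zero in a generative parameter list
#'
#' For null-calibration studies (type-I error of the ASD term).
#'
#' @param params A generative parameter list (see
#'   [default_generative_params()]).
#' @return The list with `asd`, `asd_age`, `asd_dist` components zeroed.
#' @export
zero_group_effects <- function(params) {
  for (nm in names(params)) {
    b <- params[[nm]]$beta
    b[intersect(names(b), c("asd", "asd_age", "asd_dist"))] <- 0
    params[[nm]]$beta <- b
  }
  params
}

#' Draw zero-truncated Poisson counts
#'
#' Inverse-CDF sampling conditioned on `y >= 1`.
#'
#' @param n Number of draws.
#' @param lambda Untruncated rate(s).
#' @return Integer counts >= 1.
#' @export
rztpois <- function(n, lambda) {
  u <- runif(n, dpois(0, lambda), 1)
  qpois(u, lambda)
}

#' Simulate a cohort-level covariate frame with known ground truth
#'
#' @param config A [cohort_sim_config()].
#' @return A covariate frame shaped like [prepare_covariates()] output, with
#'   attributes `generative_params` (the truth) and `subjects` (the subject
#'   table).
#' @export
simulate_cohort_outcomes <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  with_seed(config$seed, {
    n_sub <- config$n_td + config$n_asd
    subjects <- tibble(
      subject = factor(sprintf("S%03d", seq_len(n_sub))),
      asd = rep(c(0L, 1L), c(config$n_td, config$n_asd)),
      age_years = runif(n_sub, config$age_range[1], config$age_range[2])
    )
    subjects$group <- ifelse(subjects$asd == 1, "ASD", "TD")
    subjects$age_c <- subjects$age_years - config$age_center

    spp <- config$swipes_per_subject
    n_swipes <- if (length(spp) == 2) {
      pmax(5L, stats::rnbinom(n_sub, mu = spp[1], size = spp[2]))
    } else rep(as.integer(spp), n_sub)
    idx <- rep(seq_len(n_sub), n_swipes)
    n <- length(idx)
    dist_c <- sample(-2:3, n, replace = TRUE, prob = config$dist_probs)

    frame <- tibble(
      subject = subjects$subject[idx],
      group = subjects$group[idx],
      asd = subjects$asd[idx],
      age_years = subjects$age_years[idx],
      age_c = subjects$age_c[idx],
      dist_c = dist_c,
      dist_cat = factor(dist_category_levels()[dist_c + 3L],
                        levels = dist_category_levels(), ordered = TRUE)
    )

    for (nm in names(config$params)) {
      p <- config$params[[nm]]
      b <- function(key) if (key %in% names(p$beta)) p$beta[[key]] else 0
      re_cov <- p$rho01 * sqrt(p$tau00 * p$tau11)
      Sigma <- matrix(c(p$tau00, re_cov, re_cov, p$tau11), 2)
      u <- if (p$tau00 + p$tau11 > 0) MASS::mvrnorm(n_sub, c(0, 0), Sigma)
           else matrix(0, n_sub, 2)
      eta <- b("intercept") + b("dist") * frame$dist_c + b("age") * frame$age_c +
        b("asd") * frame$asd + b("asd_age") * frame$asd * frame$age_c +
        b("asd_dist") * frame$asd * frame$dist_c +
        u[idx, 1] + u[idx, 2] * frame$dist_c
      col <- tolower(nm)
      if (p$family == "gaussian" && p$transform == "log") {
        y <- eta + rnorm(n, 0, sqrt(p$sigma2))
        frame[[paste0("log_", col)]] <- y
        frame[[col]] <- exp(y)
      } else if (p$family == "gaussian") {
        frame[[col]] <- eta + rnorm(n, 0, sqrt(p$sigma2))
      } else if (p$family == "binomial") {
        frame[[col]] <- rbinom(n, 1, plogis(eta))
      } else if (p$family == "poisson") {
        frame[[col]] <- rpois(n, exp(eta))
      } else if (p$family == "ztpoisson") {
        frame[[col]] <- rztpois(n, exp(eta))
      }
    }
    attr(frame, "generative_params") <- config$params
    attr(frame, "subjects") <- subjects
    frame
  })
}

# canonical interaction-free key for matching fitted terms to truth names
canon_term <- function(x) {
  vapply(strsplit(x, ":", fixed = TRUE),
         function(p) paste(sort(p), collapse = ":"), character(1))
}

truth_for_spec <- function(spec, params) {
  p <- params[[spec$outcome]]
  key <- c("(Intercept)" = "intercept",
           "dist_c" = "dist", "age_c" = "age", "asd" = "asd",
           "age_c:asd" = "asd_age", "asd:dist_c" = "asd_dist",
           "age_c:dist_c" = "dist_age")
  function(term) {
    k <- key[[canon_term(term)]]
    if (is.null(k) || !k %in% names(p$beta)) 0 else p$beta[[k]]
  }
}

#' Parameter-recovery study for the final mixed models
#'
#' Repeatedly simulates cohorts from the generative defaults, refits each
#' requested final model, and summarises per-coefficient bias (with its
#' Monte-Carlo standard error), RMSE and 95% confidence-interval coverage.
#' Replicate-level fit failures are recorded as a failure rate, not raised.
#'
#' @param n_replicates Number of simulation replicates (>= 50 recommended).
#' @param config A [cohort_sim_config()]; each replicate uses a seed derived
#'   from `config$seed` and the replicate number.
#' @param outcomes Which final models to refit (default: the five
#'   headline outcomes).
#' @return A `recovery_study`: list with `summary` (per outcome x term:
#'   truth, mean estimate, bias, mc_se, rmse, coverage, n_ok, n_fail) and
#'   `replicates` (long per-replicate estimates).
#' @export
parameter_recovery_study <- function(n_replicates = 200,
                                     config = cohort_sim_config(),
                                     outcomes = c("MT", "PV", "TTPV", "PV1_b", "MU_APV")) {
  specs <- final_model_specs()[outcomes]
  rows <- vector("list", n_replicates * length(specs))
  k <- 0
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer((as.numeric(config$seed) * 1009 + r) %% 2147483647)
    frame <- simulate_cohort_outcomes(cfg)
    for (nm in names(specs)) {
      k <- k + 1
      truth_fn <- truth_for_spec(specs[[nm]], config$params)
      rows[[k]] <- tryCatch({
        fit <- fit_mixed(frame, specs[[nm]])
        cf <- fit$coefficients
        tibble(replicate = r, outcome = nm, term = cf$term,
               truth = vapply(cf$term, truth_fn, numeric(1)),
               estimate = cf$estimate, se = cf$se,
               ci_lo = cf$ci_lo, ci_hi = cf$ci_hi,
               covered = cf$ci_lo <= vapply(cf$term, truth_fn, numeric(1)) &
                         vapply(cf$term, truth_fn, numeric(1)) <= cf$ci_hi,
               singular = fit$singular, failed = FALSE)
      }, error = function(e) {
        tibble(replicate = r, outcome = nm, term = NA_character_,
               truth = NA_real_, estimate = NA_real_, se = NA_real_,
               ci_lo = NA_real_, ci_hi = NA_real_, covered = NA,
               singular = NA, failed = TRUE)
      })
    }
  }
  reps <- dplyr::bind_rows(rows)
  summary <- reps |>
    dplyr::filter(!.data$failed) |>
    dplyr::group_by(.data$outcome, .data$term) |>
    dplyr::summarise(
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate) - .data$truth[1],
      mc_se = sd(.data$estimate) / sqrt(dplyr::n()),
      rmse = sqrt(mean((.data$estimate - .data$truth[1])^2)),
      coverage = mean(.data$covered),
      n_ok = dplyr::n(),
      .groups = "drop")
  fails <- reps |>
    dplyr::filter(.data$failed) |>
    dplyr::count(.data$outcome, name = "n_fail")
  summary <- dplyr::left_join(summary, fails, by = "outcome")
  summary$n_fail[is.na(summary$n_fail)] <- 0L
  structure(list(summary = summary, replicates = reps), class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("<recovery_study> %d replicates, %d model(s)\n",
              max(x$replicates$replicate), length(unique(x$replicates$outcome))))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Movement-unit recovery vs positional noise
#'
#' Simulates trajectories with `k` well-separated minimum-jerk submovements
#' at each noise level, runs the full preprocessing and segmentation chain,
#' and reports the fraction of trajectories whose recovered movement-unit
#' count equals `k`. This quantifies, rather than assumes, the noise
#' robustness of the segmentation.
#'
#' @param k_values Submovement counts to test.
#' @param noise_sds Positional noise SDs in mm.
#' @param n_reps Trajectories per (k, noise) cell.
#' @param gap Temporal gap between submovements, s (default 0.15, enough to
#'   separate speed bells).
#' @param seed Integer seed.
#' @return Tibble with `k`, `noise_sd`, `recovery_rate`.
#' @export
mu_recovery_calibration <- function(k_values = 1:5, noise_sds = c(0, 0.15, 0.3, 0.6),
                                    n_reps = 20, gap = 0.15, seed = 1) {
  grid <- expand.grid(k = k_values, noise_sd = noise_sds)
  rates <- mapply(function(k, nsd) {
    hit <- 0
    for (r in seq_len(n_reps)) {
      sm <- do.call(rbind, lapply(seq_len(k), function(j) {
        submovement(amplitude = 12, onset = (j - 1) * (0.35 + gap),
                    duration = 0.35, angle = (j %% 2) * pi / 6)
      }))
      cfg <- trajectory_sim_config(
        sm, noise_sd = nsd,
        seed = as.integer((as.numeric(seed) * 131 + r * 7 + k) %% 2147483647))
      sim <- simulate_trajectory(cfg)
      mu <- tryCatch({
        ss <- parse_touch_log(sim$events)
        traj <- regularise_sampling(ss$swipes[[1]])
        vel <- velocity_profile(traj)
        nrow(segment_units(vel$speed))
      }, error = function(e) NA_integer_)
      if (!is.na(mu) && mu == k) hit <- hit + 1
    }
    hit / n_reps
  }, grid$k, grid$noise_sd)
  tibble(k = grid$k, noise_sd = grid$noise_sd, recovery_rate = rates)
}
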
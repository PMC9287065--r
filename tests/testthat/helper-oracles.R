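# Independent oracles and fixture builders, kept deliberately naive.

# Plateau-aware extrema scan: walks the series run by run and classifies each
# plateau against its differing neighbours. Boundary samples enter as minima
# when the series rises from / falls to them.
oracle_extrema <- function(s) {
  n <- length(s)
  out <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1] == s[i]) j <- j + 1
    left <- if (i == 1) NA else s[i - 1]
    right <- if (j == n) NA else s[j + 1]
    mid <- floor((i + j) / 2)
    if (!is.na(left) && !is.na(right)) {
      if (s[i] > left && s[i] > right) out <- rbind(out, c(mid, 1))
      if (s[i] < left && s[i] < right) out <- rbind(out, c(mid, -1))
    } else if (is.na(left) && !is.na(right)) {
      if (s[i] < right) out <- rbind(out, c(1, -1))
    } else if (!is.na(left) && is.na(right)) {
      if (s[i] < left) out <- rbind(out, c(n, -1))
    }
    i <- j + 1
  }
  out
}

# Exhaustive reference segmentation: enumerate candidate peaks, then
# repeatedly drop the weakest candidate failing either retention criterion,
# merging it into a neighbour by removing the higher shared minimum.
oracle_segment <- function(s, mcc = 8, mpf = 0.05, criterion = "summed") {
  n <- length(s)
  fallback <- function() {
    p <- which(s == max(s))[1]
    data.frame(start_idx = 1L, peak_idx = as.integer(p), end_idx = as.integer(n),
               peak_speed = s[p], rise = s[p] - s[1], fall = s[p] - s[n])
  }
  if (n < 3) return(fallback())
  ext <- oracle_extrema(s)
  if (is.null(ext) || !any(ext[, 2] == 1)) return(fallback())
  mins <- ext[ext[, 2] == -1, 1]
  peaks <- ext[ext[, 2] == 1, 1]
  if (length(mins) == 0 || mins[1] > peaks[1]) mins <- c(peaks[1], mins)
  if (mins[length(mins)] < peaks[length(peaks)]) mins <- c(mins, peaks[length(peaks)])
  pv_floor <- mpf * max(s)
  repeat {
    m <- length(peaks)
    status <- rep(TRUE, m)
    strength <- rep(NA_real_, m)
    for (j in 1:m) {
      rise <- s[peaks[j]] - s[mins[j]]
      fall <- s[peaks[j]] - s[mins[j + 1]]
      ok_cum <- if (criterion == "summed") (rise + fall) >= mcc else (rise >= mcc && fall >= mcc)
      status[j] <- ok_cum && s[peaks[j]] > pv_floor
      strength[j] <- rise + fall
    }
    if (all(status) || m == 1) break
    bad <- which(!status)
    bad <- bad[order(strength[bad], s[peaks[bad]], peaks[bad])]
    w <- bad[1]
    if (w == 1) {
      drop_min <- 2
    } else if (w == m) {
      drop_min <- m
    } else {
      drop_min <- if (s[mins[w]] >= s[mins[w + 1]]) w else w + 1
    }
    left_peak <- peaks[drop_min - 1]
    right_peak <- peaks[drop_min]
    winner <- if (s[left_peak] >= s[right_peak]) left_peak else right_peak
    peaks <- peaks[-c(drop_min - 1, drop_min)]
    peaks <- sort(c(peaks, winner))
    mins <- mins[-drop_min]
  }
  m <- length(peaks)
  data.frame(
    start_idx = as.integer(mins[1:m]), peak_idx = as.integer(peaks),
    end_idx = as.integer(mins[2:(m + 1)]), peak_speed = s[peaks],
    rise = s[peaks] - s[mins[1:m]], fall = s[peaks] - s[mins[2:(m + 1)]]
  )
}

# Random multi-bell speed profile: sum of 1-5 Gaussian bumps with varied
# widths and heights, so sub-threshold ripples and sub-5% peaks arise
# naturally.
random_profile <- function(seed) {
  set.seed(seed)
  k <- sample(1:5, 1)
  n <- sample(60:300, 1)
  tt <- seq(0, 1, length.out = n)
  s <- rep(0, n)
  for (b in seq_len(k)) {
    centre <- runif(1, 0.05, 0.95)
    width <- runif(1, 0.02, 0.25)
    height <- runif(1, 2, 250)
    s <- s + height * exp(-((tt - centre) / width)^2)
  }
  s
}

# Event log for a single well-formed gesture moving in a straight line.
make_gesture_log <- function(pid = "p1", gid = "g1", t0 = 0, n = 12,
                             x0 = 100, x1 = 650, y0 = 300, y1 = 300, fs = 60) {
  data.frame(
    participant_id = pid, gesture_id = gid,
    t = t0 + (seq_len(n) - 1) / fs,
    x = seq(x0, x1, length.out = n), y = seq(y0, y1, length.out = n),
    phase = c(0L, rep(1L, n - 2), 3L)
  )
}

# One raw_swipe built directly from coordinate vectors (mm converted to px).
make_swipe_from_mm <- function(x_mm, y_mm, fs = 60, ppi = 326,
                               pid = "p1", gid = "g1") {
  n <- length(x_mm)
  log <- data.frame(
    participant_id = pid, gesture_id = gid,
    t = (seq_len(n) - 1) / fs,
    x = mm_to_px(x_mm, ppi), y = mm_to_px(y_mm, ppi),
    phase = c(0L, rep(1L, n - 2), 3L)
  )
  parse_touch_log(log)$swipes[[1]]
}

# A 500-swipe kinematics table with exclusion-rule hits known by construction.
# Each violating row triggers exactly one cascade rule; clean rows satisfy all.
make_filter_fixture <- function() {
  n <- 500
  base <- tibble::tibble(
    participant_id = rep(sprintf("p%02d", 1:10), each = 50),
    gesture_id = sprintf("g%03d", 1:n),
    n_samples = 30L,
    validity = "valid",
    goal_directed = TRUE,
    mt = 0.5, pv = 120, ttpv = 0.25, pct_dec = 50, pv1 = 120,
    pv1_b = TRUE, mu = 1L, mu_apv = 0L,
    target_distance = 40, dist_cat = dist_category(40),
    path_length = 44, straightness = 1.1,
    pre_first_min_dist = 0, post_last_min_dist = 0, flagged = FALSE,
    group = rep(c("TD", "ASD"), c(300, 200))
  )
  hits <- list(multiple_touch = 1:30, too_few_samples = 31:40,
               short_distance = 41:60, mt_outlier = 61:100,
               dist_outlier = 101:125, straightness = 126:160)
  base$validity[hits$multiple_touch] <- "multiple_touch"
  base$validity[hits$too_few_samples] <- "too_few_samples"
  base$n_samples[hits$too_few_samples] <- 4L
  base$target_distance[hits$short_distance] <- 8
  base$dist_cat[hits$short_distance] <- NA
  base$mt[hits$mt_outlier] <- 2.5
  base$target_distance[hits$dist_outlier] <- 75
  base$dist_cat[hits$dist_outlier] <- NA
  base$straightness[hits$straightness] <- 1.8
  list(kin = base, hits = vapply(hits, length, integer(1)), n_retained = n - 160L)
}
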
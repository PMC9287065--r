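#' Path length of a sampled 2-D curve
#'
#' @param x,y Coordinate vectors (mm), equal length.
#' @return Sum of inter-sample Euclidean steps, mm.
#' @export
path_length <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Straightness index of a trajectory
#'
#' Ratio of the distance moved (path length) to the straight-line
#' displacement between the first and last samples. Equal to 1 for a
#' perfectly straight swipe and invariant under rotation, translation and
#' uniform scaling.
#'
#' @param x,y Coordinate vectors (mm), or a `trajectory` as `x` with `y`
#'   missing.
#' @return Straightness ratio (>= 1 up to numerical error).
#' @export
straightness <- function(x, y = NULL) {
  if (inherits(x, "trajectory")) { y <- x$y; x <- x$x }
  chord <- sqrt((x[length(x)] - x[1])^2 + (y[length(y)] - y[1])^2)
  if (chord <= 0) stopf("zero displacement: straightness undefined for a non-goal-directed swipe")
  path_length(x, y) / chord
}

#' Bin a target distance into its 10-mm ordinal category
#'
#' Target distance (the straight-line displacement from swipe start to end)
#' enters the models as an ordered categorical variable in 10-mm intervals,
#' six categories from 10 to 70 mm. Membership is half-open
#' `[lower, upper)` except the top bin, which is closed at 70 mm (the
#' maximum displacement a retained swipe can have).
#'
#' @param target_distance Distance(s) in mm, in `(10, 70]`.
#' @return Ordered factor with levels `"10-20"` ... `"60-70"`.
#' @examples
#' dist_category(c(13.5, 35, 40, 70))
#' @export
dist_category <- function(target_distance) {
  labs <- dist_category_levels()
  if (any(target_distance > 70, na.rm = TRUE)) {
    stopf("target distance above 70 mm should have been excluded upstream")
  }
  if (any(target_distance < 10, na.rm = TRUE)) {
    stopf("target distance below the lowest bin (10 mm) should have been excluded upstream")
  }
  i <- ifelse(target_distance == 70, 6L, as.integer(floor(target_distance / 10)))
  factor(labs[i], levels = labs, ordered = TRUE)
}

dist_category_levels <- function() {
  sprintf("%d-%d", seq(10, 60, 10), seq(20, 70, 10))
}

# tolerant version used inside the pipeline before exclusions run:
# out-of-range distances map to NA and are handled by the cohort filter
dist_category_or_na <- function(target_distance) {
  labs <- dist_category_levels()
  i <- ifelse(is.na(target_distance) | target_distance < 10 | target_distance > 70,
              NA_integer_,
              ifelse(target_distance == 70, 6L, as.integer(floor(target_distance / 10))))
  factor(labs[i], levels = labs, ordered = TRUE)
}

#' Swipe-level kinematic outcomes
#'
#' Derives the outcome variables of one swipe from its trajectory, velocity
#' profile and movement units:
#' \describe{
#'   \item{mt}{movement time: touch begun to touch end, s}
#'   \item{pv, ttpv}{peak speed (mm/s) and time from touch onset to it (s)}
#'   \item{pct_dec}{deceleration phase: percentage of movement time after
#'     peak velocity, `100 * (mt - ttpv) / mt`}
#'   \item{pv1, pv1_b}{peak speed of the first movement unit, and whether
#'     the global peak lies in the first unit}
#'   \item{mu, mu_apv}{movement-unit count and units after peak velocity}
#'   \item{target_distance}{straight-line displacement between the raw
#'     recorded start and end positions, mm}
#'   \item{path_length, straightness}{filtered path length (mm) and its
#'     ratio to target distance}
#'   \item{pre_first_min_dist, post_last_min_dist}{distance covered before
#'     the first velocity minimum / after the last one, mm (sensitivity
#'     margins)}
#' }
#'
#' @param traj A `trajectory` (used for the raw endpoints).
#' @param vel A `velocity_profile` for the same swipe.
#' @param units Movement units from [segment_units()].
#' @return A one-row tibble; `flagged` is `TRUE` for degenerate (all-zero
#'   speed) swipes, which downstream filtering excludes.
#' @export
compute_features <- function(traj, vel, units) {
  stopifnot(inherits(vel, "velocity_profile"), nrow(units) >= 1)
  n <- length(vel$t)
  mt <- vel$t[n] - vel$t[1]
  if (mt <= 0) stopf("movement time must be positive")
  speed <- vel$speed
  flagged <- all(speed == 0)
  pv_idx <- which.max(speed)[1]
  pv <- speed[pv_idx]
  ttpv <- vel$t[pv_idx] - vel$t[1]
  td <- sqrt(sum((traj$raw_end - traj$raw_start)^2))
  pl <- path_length(vel$x, vel$y)
  s1 <- units$start_idx[1]
  sN <- units$end_idx[nrow(units)]
  tibble(
    participant_id = traj$participant_id %||% NA_character_,
    gesture_id = traj$gesture_id %||% NA_character_,
    mt = mt,
    pv = pv,
    ttpv = ttpv,
    pct_dec = 100 * (mt - ttpv) / mt,
    pv1 = units$peak_speed[1],
    pv1_b = if (flagged) NA else pv_in_first_unit(units, pv_idx),
    mu = nrow(units),
    mu_apv = if (flagged) NA_integer_ else as.integer(units_after_pv(units, pv_idx)),
    target_distance = td,
    dist_cat = dist_category_or_na(td),
    path_length = pl,
    straightness = if (td > 0) pl / td else NA_real_,
    pre_first_min_dist = if (s1 > 1) path_length(vel$x[1:s1], vel$y[1:s1]) else 0,
    post_last_min_dist = if (sN < n) path_length(vel$x[sN:n], vel$y[sN:n]) else 0,
    flagged = flagged
  )
}

#' Full kinematic feature extraction for a set of swipes
#'
#' Runs the per-swipe pipeline (resample to a uniform grid in mm, zero-phase
#' filter, five-point-stencil velocity, movement-unit segmentation, feature
#' derivation) over every swipe and returns a swipe-level table carrying the
#' structural validity flags and goal-directed classification needed by the
#' cohort filter. Swipes that are structurally invalid, or whose kinematics
#' cannot be computed (too short, zero displacement), get `NA` features and
#' a `compute_error` note.
#'
#' @param x A `swipe_set` (from [parse_touch_log()]) or list of `raw_swipe`.
#' @param layout A `game_layout` for goal-directed classification.
#' @param fs,ppi,fc,order Sampling / conversion / filter settings; see
#'   [regularise_sampling()] and [lowpass_zero_phase()].
#' @param seg_params Segmentation thresholds; see [segmentation_params()].
#' @return A tibble with one row per swipe: identifiers, `validity`,
#'   `goal_directed`, `n_samples`, and the [compute_features()] columns.
#' @export
swipe_kinematics <- function(x, layout = default_layout(), fs = 60, ppi = 326,
                             fc = 8, order = 4, seg_params = segmentation_params()) {
  swipes <- if (inherits(x, "swipe_set")) x$swipes else x
  rows <- lapply(swipes, function(s) {
    gd <- if (s$validity == "missing_structure") NA else classify_goal_directed(s, layout)
    base <- tibble(participant_id = s$participant_id, gesture_id = s$gesture_id,
                   n_samples = s$n_samples, validity = s$validity, goal_directed = gd)
    if (s$validity %in% c("missing_structure", "too_few_samples")) {
      return(dplyr::bind_cols(base, empty_features(), tibble(compute_error = NA_character_)))
    }
    feat <- tryCatch({
      traj <- regularise_sampling(s, fs = fs, ppi = ppi)
      vel <- velocity_profile(traj, fc = fc, order = order)
      units <- segment_units(vel$speed, seg_params)
      f <- compute_features(traj, vel, units)
      f$participant_id <- NULL; f$gesture_id <- NULL
      dplyr::bind_cols(f, tibble(compute_error = NA_character_))
    }, error = function(e) {
      dplyr::bind_cols(empty_features(), tibble(compute_error = conditionMessage(e)))
    })
    dplyr::bind_cols(base, feat)
  })
  dplyr::bind_rows(rows)
}

empty_features <- function() {
  tibble(
    mt = NA_real_, pv = NA_real_, ttpv = NA_real_, pct_dec = NA_real_,
    pv1 = NA_real_, pv1_b = NA, mu = NA_integer_, mu_apv = NA_integer_,
    target_distance = NA_real_, dist_cat = dist_category_or_na(NA_real_),
    path_length = NA_real_, straightness = NA_real_,
    pre_first_min_dist = NA_real_, post_last_min_dist = NA_real_, flagged = NA
  )
}
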
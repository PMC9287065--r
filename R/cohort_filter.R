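#' Inclusion/exclusion parameters for the analysis cohort
#'
#' Thresholds for the swipe-level exclusion cascade and the participant-level
#' inclusion rule:
#' \itemize{
#'   \item swipes flagged `multiple_touch` or with fewer than `min_samples`
#'     samples are structurally unusable;
#'   \item swipes shorter than `dist_min` (the shortest food-to-plate
#'     distance; defaults to 13.5 mm, see [min_food_plate_distance()]) cannot
#'     be genuine food-to-plate movements;
#'   \item outliers on movement time (`mt_max` = 2.0 s), target distance
#'     (`dist_max` = 70 mm) and straightness (`straightness_max` = 1.5) are
#'     unlikely to be efficient single-goal movements;
#'   \item participants are retained only when their goal-directed
#'     (food-to-plate) swipes make up at least `participant_goal_ratio`
#'     (10%) of all swipes they made -- evidence of engaged, task-directed
#'     play. Set `literal_participant_rule = TRUE` to invert the rule
#'     (exclude participants at or above 10%), for auditing the alternative
#'     literal reading of the criterion.
#'   \item the sensitivity subset keeps swipes whose distance covered before
#'     the first velocity minimum and after the last one are both below
#'     `sensitivity_margin` (5 mm).
#' }
#'
#' @param mt_max,dist_max,straightness_max,min_samples,dist_min,participant_goal_ratio,sensitivity_margin
#'   Thresholds as described above.
#' @param literal_participant_rule Logical; see above.
#' @return A `filter_params` object.
#' @export
filter_params <- function(mt_max = 2.0, dist_max = 70, straightness_max = 1.5,
                          min_samples = 5, dist_min = 13.5,
                          participant_goal_ratio = 0.10, sensitivity_margin = 5,
                          literal_participant_rule = FALSE) {
  vals <- c(mt_max, dist_max, straightness_max, min_samples, dist_min,
            participant_goal_ratio, sensitivity_margin)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stopf("all filter thresholds must be positive", class = "swipekin_config_error")
  }
  structure(list(mt_max = mt_max, dist_max = dist_max,
                 straightness_max = straightness_max, min_samples = min_samples,
                 dist_min = dist_min, participant_goal_ratio = participant_goal_ratio,
                 sensitivity_margin = sensitivity_margin,
                 literal_participant_rule = literal_participant_rule),
            class = "filter_params")
}

exclusion_reasons <- function() {
  c("multiple_touch", "too_few_samples", "short_distance",
    "mt_outlier", "dist_outlier", "straightness")
}

#' Apply the swipe-level exclusion cascade
#'
#' Rules fire in a fixed order -- multiple touch, too few samples, distance
#' below the shortest food-to-plate gap, movement time above 2.0 s, target
#' distance above 70 mm, straightness above 1.5 -- and each swipe carries
#' the first reason that fires as its primary exclusion reason, so
#' alternative orderings can be audited from the per-swipe trail. Swipes
#' with missing began/ended structure must be screened out before this
#' cascade (they have no kinematics).
#'
#' @param kin Swipe-level kinematics table from [swipe_kinematics()]
#'   (must carry `validity`; typically the goal-directed subset). An
#'   optional `group` column enables by-group counts.
#' @param params A [filter_params()] object.
#' @return An `exclusion_report`: list with `table` (input plus `reason`,
#'   `NA` when retained), `retained` (surviving rows), `counts` (per-reason
#'   counts, by group when available), and `params`.
#' @export
apply_swipe_exclusions <- function(kin, params = filter_params()) {
  if (!all(c("validity", "mt", "target_distance", "straightness") %in% names(kin))) {
    stopf("`kin` must carry validity flags and kinematic features")
  }
  reason <- rep(NA_character_, nrow(kin))
  fire <- function(cond, label) {
    hit <- is.na(reason) & !is.na(cond) & cond
    reason[hit] <<- label
  }
  fire(kin$validity == "multiple_touch", "multiple_touch")
  fire(kin$validity == "too_few_samples" | kin$n_samples < params$min_samples,
       "too_few_samples")
  fire(kin$target_distance < params$dist_min, "short_distance")
  fire(kin$mt > params$mt_max, "mt_outlier")
  fire(kin$target_distance > params$dist_max, "dist_outlier")
  fire(kin$straightness > params$straightness_max, "straightness")
  # degenerate swipes (flat speed, failed computation) cannot be analysed
  fire(is.na(kin$mt) | (!is.na(kin$flagged) & kin$flagged), "not_computable")

  tab <- kin
  tab$reason <- reason
  retained <- tab[is.na(reason), , drop = FALSE]
  counts <- count_by_reason(tab)
  structure(list(table = tab, retained = retained, counts = counts, params = params),
            class = "exclusion_report")
}

count_by_reason <- function(tab) {
  lev <- c(exclusion_reasons(), "not_computable", "retained")
  r <- factor(ifelse(is.na(tab$reason), "retained", tab$reason), levels = lev)
  out <- tibble(reason = lev, n = as.integer(table(r)))
  if ("group" %in% names(tab)) {
    for (g in unique(tab$group)) {
      out[[paste0("n_", g)]] <- as.integer(table(r[tab$group == g]))
    }
  }
  out
}

#' Apply the participant-level inclusion rule
#'
#' A participant is retained when their food-to-plate swipes make up at
#' least the configured share (default 10%) of all swipes they made during
#' gameplay; a ratio of exactly 10% is retained. Participants with zero
#' recorded swipes are excluded with a distinct reason.
#'
#' @param swipe_counts A tibble with columns `participant_id`,
#'   `n_total` (all swipes) and `n_goal` (food-to-plate swipes); built with
#'   [participant_swipe_counts()].
#' @param params A [filter_params()] object.
#' @return `swipe_counts` with `ratio`, `retained` and `reason` columns.
#' @export
apply_participant_inclusion <- function(swipe_counts, params = filter_params()) {
  sc <- swipe_counts
  sc$ratio <- ifelse(sc$n_total > 0, sc$n_goal / sc$n_total, NA_real_)
  meets <- !is.na(sc$ratio) & sc$ratio >= params$participant_goal_ratio
  keep <- if (params$literal_participant_rule) !meets & sc$n_total > 0 else meets
  sc$retained <- keep
  sc$reason <- ifelse(sc$n_total == 0, "no_swipes",
                      ifelse(keep, NA_character_, "low_goal_directed_ratio"))
  sc
}

#' Per-participant swipe counts
#'
#' @param kin Full swipe-level table (all swipes, any validity) with a
#'   `goal_directed` column.
#' @param participants Optional participant table; participants absent from
#'   `kin` get zero counts.
#' @return Tibble with `participant_id`, `n_total`, `n_goal`.
#' @export
participant_swipe_counts <- function(kin, participants = NULL) {
  out <- kin |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_total = dplyr::n(),
                     n_goal = sum(.data$goal_directed %in% TRUE),
                     .groups = "drop")
  if (!is.null(participants)) {
    missing <- setdiff(participants$participant_id, out$participant_id)
    if (length(missing)) {
      out <- dplyr::bind_rows(out, tibble(participant_id = missing, n_total = 0L, n_goal = 0L))
    }
  }
  out
}

#' Sensitivity-analysis subset
#'
#' Retains swipes whose distance covered before the first velocity minimum
#' and after the last velocity minimum are both below the margin (default
#' 5 mm). This drops movements that decelerate over a sizeable share of the
#' target distance before the swipe proper, or that creep towards the goal
#' and only accelerate while lifting off -- both of which distort the
#' distance covariate or the kinematic form. Margins that are undefined
#' (the first unit starts at touch onset / ends at lift-off) pass the
#' corresponding check.
#'
#' @param kin Swipe-level kinematics table with `pre_first_min_dist` and
#'   `post_last_min_dist` columns.
#' @param params A [filter_params()] object.
#' @return The retained subset of `kin`.
#' @export
sensitivity_subset <- function(kin, params = filter_params()) {
  pre_ok <- is.na(kin$pre_first_min_dist) | kin$pre_first_min_dist < params$sensitivity_margin
  post_ok <- is.na(kin$post_last_min_dist) | kin$post_last_min_dist < params$sensitivity_margin
  kin[pre_ok & post_ok, , drop = FALSE]
}

#' Run the full cohort filter
#'
#' Convenience wrapper: classifies the goal-directed subset, applies the
#' swipe exclusion cascade, then the participant inclusion rule, and
#' returns a combined report.
#'
#' @param kin Full swipe-level table from [swipe_kinematics()] (all swipes,
#'   with `goal_directed` and `validity` columns; optionally `group`).
#' @param params A [filter_params()] object.
#' @return A list with `swipe_report` (an `exclusion_report` over the
#'   goal-directed swipes), `participants` (inclusion table), and
#'   `retained` (analysis-sample rows from retained participants).
#' @export
apply_cohort_filter <- function(kin, params = filter_params()) {
  goal <- kin[kin$goal_directed %in% TRUE, , drop = FALSE]
  rep_s <- apply_swipe_exclusions(goal, params)
  counts <- participant_swipe_counts(kin)
  rep_p <- apply_participant_inclusion(counts, params)
  keep_ids <- rep_p$participant_id[rep_p$retained]
  retained <- rep_s$retained[rep_s$retained$participant_id %in% keep_ids, , drop = FALSE]
  list(swipe_report = rep_s, participants = rep_p, retained = retained)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d swipes: %d retained, %d excluded\n",
              nrow(x$table), nrow(x$retained), nrow(x$table) - nrow(x$retained)))
  print(as.data.frame(x$counts), row.names = FALSE)
  invisible(x)
}

#' Serialise an exclusion report to JSON
#'
#' @param report An `exclusion_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  jsonlite::write_json(
    list(counts = report$counts,
         retained_swipes = report$retained[c("participant_id", "gesture_id")],
         params = unclass(report$params)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
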
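#' Extract swipe-level kinematics from a raw event log
#'
#' One-call wrapper over [parse_touch_log()] and [swipe_kinematics()]:
#' parses the event stream, classifies goal-directed swipes against the
#' layout, and derives the kinematic outcome table.
#'
#' @param events Touch-event data frame or CSV path.
#' @param layout A `game_layout` or path to a layout JSON.
#' @param cols Column mapping, see [touch_columns()].
#' @param ... Passed to [swipe_kinematics()].
#' @return List with `kin` (swipe-level table), `swipe_set`, and `rejects`.
#' @export
extract_kinematics <- function(events, layout = default_layout(),
                               cols = touch_columns(), ...) {
  if (is.character(layout)) layout <- read_layout(layout)
  ss <- parse_touch_log(events, cols = cols)
  kin <- swipe_kinematics(ss, layout = layout, ...)
  list(kin = kin, swipe_set = ss, rejects = ss$rejects)
}

#' Attach participant group labels to a kinematics table
#'
#' @param kin Swipe-level table.
#' @param participants Tibble with `participant_id` and `group`.
#' @return `kin` with a `group` column.
#' @export
attach_groups <- function(kin, participants) {
  dplyr::left_join(kin, participants[c("participant_id", "group")],
                   by = "participant_id")
}
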
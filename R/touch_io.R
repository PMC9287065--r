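#' Column mapping for touch-event logs
#'
#' Touch logs are delimited text with one row per touch event. The defaults
#' match the column names this package writes; remap them for logs exported
#' with different headers.
#'
#' @param participant,gesture,t,x,y,phase Column names in the input table.
#' @return A named character vector used by [parse_touch_log()].
#' @export
touch_columns <- function(participant = "participant_id", gesture = "gesture_id",
                          t = "t", x = "x", y = "y", phase = "phase") {
  c(participant = participant, gesture = gesture, t = t, x = x, y = y, phase = phase)
}

#' Parse a raw touch-event log into candidate swipes
#'
#' Events carry a touch phase code following the UITouch convention:
#' 0 = touch began, 1 = touch moved, 3 = touch ended. A structurally valid
#' swipe starts with a `began` event, ends with an `ended` event, and has at
#' least `min_samples` samples (five are needed for the five-point velocity
#' stencil). Swipes registered at the same time as another swipe by the same
#' participant are flagged `multiple_touch`, since a unique swipe path cannot
#' be distinguished.
#'
#' Every input row is accounted for: it ends up in a returned swipe or in the
#' rejects table (malformed rows, orphan events when gesture ids are
#' reconstructed). Duplicate `(gesture, t, phase)` rows keep the first
#' occurrence with a warning.
#'
#' @param records A data frame of touch events (or a path to a CSV file).
#' @param cols Column mapping from [touch_columns()]. If the gesture column is
#'   absent, gestures are reconstructed per participant from the phase
#'   sequence: `began` opens a gesture, `ended` closes it.
#' @param min_samples Minimum samples for a valid swipe (default 5).
#' @return A `swipe_set`: list with `swipes` (list of `raw_swipe`) and
#'   `rejects` (tibble of dropped rows with diagnostics).
#' @examples
#' log <- data.frame(
#'   participant_id = "p1", gesture_id = "g1",
#'   t = (0:11) / 60, x = seq(100, 650, 50), y = 300,
#'   phase = c(0, rep(1, 10), 3)
#' )
#' ss <- parse_touch_log(log)
#' swipe_index(ss)
#' @export
parse_touch_log <- function(records, cols = touch_columns(), min_samples = 5) {
  if (is.character(records) && length(records) == 1) {
    records <- read.csv(records, stringsAsFactors = FALSE)
  }
  records <- as.data.frame(records)
  needed <- cols[c("participant", "t", "x", "y", "phase")]
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stopf("event log is missing columns: %s", paste(missing_cols, collapse = ", "))
  }
  has_gesture <- cols[["gesture"]] %in% names(records)

  n <- nrow(records)
  ev <- tibble(
    row = seq_len(n),
    participant_id = as.character(records[[cols[["participant"]]]]),
    gesture_id = if (has_gesture) as.character(records[[cols[["gesture"]]]]) else NA_character_,
    t = suppressWarnings(as.numeric(records[[cols[["t"]]]])),
    x = suppressWarnings(as.numeric(records[[cols[["x"]]]])),
    y = suppressWarnings(as.numeric(records[[cols[["y"]]]])),
    phase = suppressWarnings(as.integer(records[[cols[["phase"]]]]))
  )

  # row-level screening
  bad_num <- is.na(ev$t) | is.na(ev$x) | is.na(ev$y)
  bad_phase <- is.na(ev$phase) | !(ev$phase %in% c(0L, 1L, 3L))
  bad_t <- !bad_num & ev$t < 0
  reject_reason <- rep(NA_character_, n)
  reject_reason[bad_phase] <- "invalid_phase_code"
  reject_reason[bad_num] <- "non_numeric_field"
  reject_reason[bad_t] <- "negative_timestamp"
  rejects <- ev[!is.na(reject_reason), , drop = FALSE]
  rejects$reason <- reject_reason[!is.na(reject_reason)]
  ev <- ev[is.na(reject_reason), , drop = FALSE]

  if (!has_gesture && nrow(ev) > 0) {
    res <- reconstruct_gestures(ev)
    ev <- res$events
    if (nrow(res$rejects)) rejects <- dplyr::bind_rows(rejects, res$rejects)
  }

  ev <- ev[order(ev$participant_id, ev$gesture_id, ev$t, ev$phase), , drop = FALSE]
  dup <- duplicated(ev[c("participant_id", "gesture_id", "t", "phase")])
  if (any(dup)) {
    warnf("%d duplicate (gesture, t, phase) events dropped (first kept)", sum(dup))
    rejects <- dplyr::bind_rows(rejects, cbind(ev[dup, , drop = FALSE], reason = "duplicate_event"))
    ev <- ev[!dup, , drop = FALSE]
  }

  swipes <- lapply(split(ev, paste(ev$participant_id, ev$gesture_id, sep = "\r")), function(g) {
    g <- g[order(g$t), , drop = FALSE]
    validity <- "valid"
    if (g$phase[1] != 0L || g$phase[nrow(g)] != 3L || !any(g$phase == 0L) || !any(g$phase == 3L)) {
      validity <- "missing_structure"
    } else if (nrow(g) < min_samples) {
      validity <- "too_few_samples"
    }
    new_raw_swipe(
      participant_id = g$participant_id[1], gesture_id = g$gesture_id[1],
      events = g[c("t", "x", "y", "phase")], validity = validity
    )
  })
  names(swipes) <- NULL
  # stable ordering: by participant then first timestamp
  ord <- order(vapply(swipes, function(s) s$participant_id, character(1)),
               vapply(swipes, function(s) s$t_begin, numeric(1)))
  swipes <- swipes[ord]
  swipes <- flag_multiple_touch(swipes)

  structure(
    list(swipes = swipes,
         rejects = as_tibble(rejects[c("row", "participant_id", "gesture_id",
                                       "t", "x", "y", "phase", "reason")])),
    class = "swipe_set"
  )
}

new_raw_swipe <- function(participant_id, gesture_id, events, validity) {
  structure(
    list(participant_id = participant_id, gesture_id = gesture_id,
         events = as_tibble(events), n_samples = nrow(events),
         t_begin = events$t[1], t_end = events$t[nrow(events)],
         validity = validity),
    class = "raw_swipe"
  )
}

# Assign gesture ids from the phase stream when the log lacks them.
# `began` opens a gesture; `ended` closes the open gesture; interleaved
# `began` events open concurrent gestures (later flagged multiple_touch via
# interval overlap). moved/ended events with no open gesture are rejected.
reconstruct_gestures <- function(ev) {
  out <- vector("list", length(unique(ev$participant_id)))
  rej <- list()
  k <- 0
  for (pid in unique(ev$participant_id)) {
    k <- k + 1
    g <- ev[ev$participant_id == pid, , drop = FALSE]
    g <- g[order(g$t, -g$phase), , drop = FALSE]  # ended before began on ties
    open <- character(0)
    counter <- 0
    ids <- rep(NA_character_, nrow(g))
    for (i in seq_len(nrow(g))) {
      ph <- g$phase[i]
      if (ph == 0L) {
        counter <- counter + 1
        gid <- sprintf("%s-r%03d", pid, counter)
        open <- c(open, gid)
        ids[i] <- gid
      } else {
        if (length(open) == 0) next  # orphan, rejected below
        ids[i] <- open[length(open)]  # attach to most recent open gesture
        if (ph == 3L) open <- open[-length(open)]
      }
    }
    g$gesture_id <- ids
    rej[[k]] <- g[is.na(ids), , drop = FALSE]
    out[[k]] <- g[!is.na(ids), , drop = FALSE]
  }
  rejects <- dplyr::bind_rows(rej)
  if (nrow(rejects)) rejects$reason <- "orphan_event_no_open_gesture"
  list(events = dplyr::bind_rows(out), rejects = rejects)
}

#' Flag temporally overlapping swipes as multiple-touch
#'
#' Two swipes by the same participant whose `[t_begin, t_end]` intervals
#' strictly overlap are both flagged `multiple_touch`. Intervals that share
#' exactly one endpoint do not count as simultaneous: legitimate rapid
#' sequential taps can abut in time.
#'
#' @param swipes A list of `raw_swipe` objects (or a `swipe_set`).
#' @return The input with `validity` updated (symmetric annotation).
#' @export
flag_multiple_touch <- function(swipes) {
  if (inherits(swipes, "swipe_set")) {
    swipes$swipes <- flag_multiple_touch(swipes$swipes)
    return(swipes)
  }
  pid <- vapply(swipes, function(s) s$participant_id, character(1))
  b <- vapply(swipes, function(s) s$t_begin, numeric(1))
  e <- vapply(swipes, function(s) s$t_end, numeric(1))
  for (p in unique(pid)) {
    idx <- which(pid == p)
    if (length(idx) < 2) next
    for (i in idx) {
      # strict overlap: open-interval intersection is non-empty
      ov <- any(b[idx] < e[i] & e[idx] > b[i] & idx != i)
      if (ov) swipes[[i]]$validity <- "multiple_touch"
    }
  }
  swipes
}

#' Classify a swipe as goal-directed (food-to-plate)
#'
#' A swipe is goal-directed when its first event lies inside the food area
#' and its last event lies inside the end area (any plate rectangle). Only
#' the endpoints matter; the path between them is free.
#'
#' @param swipe A `raw_swipe`.
#' @param layout A `game_layout`.
#' @return `TRUE` or `FALSE`.
#' @export
classify_goal_directed <- function(swipe, layout) {
  stopifnot(inherits(swipe, "raw_swipe"))
  if (!inherits(layout, "game_layout")) {
    stopf("`layout` must be a game_layout", class = "swipekin_config_error")
  }
  if (swipe$validity == "missing_structure") {
    stopf("cannot classify a swipe with missing began/ended structure")
  }
  ev <- swipe$events
  n <- nrow(ev)
  point_in_rect(ev$x[1], ev$y[1], layout$food_area) &&
    point_in_end_area(ev$x[n], ev$y[n], layout)
}

#' Tabulate a swipe set
#'
#' @param x A `swipe_set` or list of `raw_swipe` objects.
#' @param layout Optional `game_layout`; adds a `goal_directed` column
#'   (NA for swipes with missing structure).
#' @return A tibble with one row per swipe.
#' @export
swipe_index <- function(x, layout = NULL) {
  swipes <- if (inherits(x, "swipe_set")) x$swipes else x
  out <- tibble(
    participant_id = vapply(swipes, function(s) s$participant_id, character(1)),
    gesture_id = vapply(swipes, function(s) s$gesture_id, character(1)),
    n_samples = vapply(swipes, function(s) s$n_samples, integer(1)),
    t_begin = vapply(swipes, function(s) s$t_begin, numeric(1)),
    t_end = vapply(swipes, function(s) s$t_end, numeric(1)),
    validity = vapply(swipes, function(s) s$validity, character(1))
  )
  if (!is.null(layout)) {
    out$goal_directed <- vapply(swipes, function(s) {
      if (s$validity == "missing_structure") return(NA)
      classify_goal_directed(s, layout)
    }, logical(1))
  }
  out
}

#' @export
print.swipe_set <- function(x, ...) {
  tab <- table(vapply(x$swipes, function(s) s$validity, character(1)))
  cat(sprintf("<swipe_set> %d swipes, %d rejected rows\n", length(x$swipes), nrow(x$rejects)))
  for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' @export
print.raw_swipe <- function(x, ...) {
  cat(sprintf("<raw_swipe> %s / %s: %d samples over %.3f s [%s]\n",
              x$participant_id, x$gesture_id, x$n_samples,
              x$t_end - x$t_begin, x$validity))
  invisible(x)
}
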
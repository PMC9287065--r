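#' Movement-unit segmentation parameters
#'
#' A movement unit (MU) is one acceleration-deceleration phase of the speed
#' profile: a velocity maximum with its flanking minima. A candidate maximum
#' is retained only if (a) its acceleration and deceleration phases
#' cumulatively amount to a velocity change of at least
#' `min_cumulative_change` (8 mm/s), and (b) its peak speed exceeds
#' `min_peak_fraction` (5%) of the swipe's overall peak velocity. The
#' cumulative-change criterion is applied to the sum of rise and fall by
#' default, matching the movement-unit conventions of the infant-reaching
#' literature; set `criterion = "separate"` to require both phases to exceed
#' the threshold individually (for sensitivity analyses).
#'
#' @param min_cumulative_change Minimum summed rise + fall, mm/s (default 8).
#' @param min_peak_fraction Minimum peak speed as a fraction of the swipe's
#'   peak velocity (default 0.05).
#' @param criterion `"summed"` (default) or `"separate"`.
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(min_cumulative_change = 8, min_peak_fraction = 0.05,
                                criterion = c("summed", "separate")) {
  criterion <- match.arg(criterion)
  if (min_cumulative_change <= 0 || min_peak_fraction <= 0 || min_peak_fraction >= 1) {
    stopf("segmentation thresholds must be positive (and peak fraction < 1)",
          class = "swipekin_config_error")
  }
  structure(list(min_cumulative_change = min_cumulative_change,
                 min_peak_fraction = min_peak_fraction,
                 criterion = criterion),
            class = "segmentation_params")
}

#' Locate alternating local extrema of a speed profile
#'
#' Returns a strictly alternating minimum/maximum sequence. Plateaus (runs of
#' equal values) collapse to their midpoint sample. The first (last) sample
#' is included as a boundary minimum when speed rises from (falls to) it, so
#' a profile that starts accelerating has its first minimum at sample 1.
#'
#' @param speed Numeric speed vector, length >= 3.
#' @return A tibble with columns `idx` and `kind` (`"min"`/`"max"`).
#' @export
find_local_extrema <- function(speed) {
  assert_numeric(speed, "speed")
  n <- length(speed)
  if (n < 3) stopf("need at least 3 samples to locate extrema")
  r <- rle(speed)
  K <- length(r$values)
  if (K == 1) return(tibble(idx = integer(0), kind = character(0)))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- as.integer(floor((starts + ends) / 2))
  idx <- integer(0); kind <- character(0)
  v <- r$values
  if (K >= 2 && v[1] < v[2]) { idx <- c(idx, 1L); kind <- c(kind, "min") }
  if (K >= 3) {
    for (k in 2:(K - 1)) {
      if (v[k] > v[k - 1] && v[k] > v[k + 1]) { idx <- c(idx, mids[k]); kind <- c(kind, "max") }
      else if (v[k] < v[k - 1] && v[k] < v[k + 1]) { idx <- c(idx, mids[k]); kind <- c(kind, "min") }
    }
  }
  if (v[K] < v[K - 1]) { idx <- c(idx, n); kind <- c(kind, "min") }
  tibble(idx = idx, kind = kind)
}

#' Segment a speed profile into movement units
#'
#' Candidate units are the local velocity maxima with their flanking minima.
#' Each candidate peak must satisfy both retention criteria (see
#' [segmentation_params()]); the 5%-of-peak rule is evaluated against the
#' swipe's global peak velocity computed before any rejection. A rejected
#' peak is merged into its larger neighbouring unit by deleting the higher
#' of its two shared boundary minima; criteria are re-evaluated iteratively
#' (weakest candidate first) until all remaining peaks pass. At least one
#' unit is always returned: the first unit starts at the first velocity
#' minimum or at sample 1 when speed rises from touch onset, and the last
#' unit ends at the last velocity minimum or the final sample.
#'
#' @param speed Numeric speed vector (mm/s) from a valid trajectory.
#' @param params A [segmentation_params()] object.
#' @return A tibble of movement units with columns `start_idx`, `peak_idx`,
#'   `end_idx`, `peak_speed`, `rise`, `fall`, ordered in time. Attribute
#'   `degenerate` is `TRUE` for flat/monotone profiles where a single
#'   spanning unit is returned.
#' @export
segment_units <- function(speed, params = segmentation_params()) {
  assert_numeric(speed, "speed")
  n <- length(speed)
  degenerate_unit <- function() {
    p <- which.max(speed)[1]
    u <- tibble(start_idx = 1L, peak_idx = as.integer(p), end_idx = as.integer(n),
                peak_speed = speed[p], rise = speed[p] - speed[1], fall = speed[p] - speed[n])
    attr(u, "degenerate") <- TRUE
    u
  }
  if (n < 3) return(degenerate_unit())
  ext <- find_local_extrema(speed)
  if (!any(ext$kind == "max")) return(degenerate_unit())

  # alternating representation: minima m[1..m+1] flanking peaks p[1..m]
  pk <- ext$idx[ext$kind == "max"]
  mn <- ext$idx[ext$kind == "min"]
  # guarantee boundary minima so units tile the profile
  if (length(mn) == 0 || mn[1] > pk[1]) mn <- c(pk[1], mn)        # degenerate guard (rare)
  if (mn[length(mn)] < pk[length(pk)]) mn <- c(mn, pk[length(pk)]) # degenerate guard (rare)
  # boundary minima per spec: first unit starts at first min (or sample 1 when
  # rising from onset -- find_local_extrema already returns sample 1 then)
  pv <- max(speed)
  pv_floor <- params$min_peak_fraction * pv

  passes <- function(rise, fall, ps) {
    cum_ok <- if (params$criterion == "summed") (rise + fall) >= params$min_cumulative_change
              else rise >= params$min_cumulative_change && fall >= params$min_cumulative_change
    cum_ok && ps > pv_floor
  }

  repeat {
    m <- length(pk)
    rise <- speed[pk] - speed[mn[seq_len(m)]]
    fall <- speed[pk] - speed[mn[seq_len(m) + 1L]]
    ok <- vapply(seq_len(m), function(j) passes(rise[j], fall[j], speed[pk[j]]), logical(1))
    if (all(ok) || m == 1L) break
    fail <- which(!ok)
    # weakest failing candidate: smallest rise + fall, then lowest peak, then first
    w <- fail[order(rise[fail] + fall[fail], speed[pk[fail]], pk[fail])][1]
    # choose which shared boundary minimum to delete so the bump joins a neighbour
    if (w == 1L) del <- 2L                # only a right neighbour
    else if (w == m) del <- m             # only a left neighbour
    else del <- if (speed[mn[w]] >= speed[mn[w + 1L]]) w else w + 1L
    mn <- mn[-del]
    # the two peaks around the deleted minimum merge: keep the higher (first on tie)
    j <- del - 1L
    keep <- if (speed[pk[j]] >= speed[pk[j + 1L]]) j else j + 1L
    pk <- pk[-(if (keep == j) j + 1L else j)]
  }

  m <- length(pk)
  tibble(
    start_idx = as.integer(mn[seq_len(m)]),
    peak_idx = as.integer(pk),
    end_idx = as.integer(mn[seq_len(m) + 1L]),
    peak_speed = speed[pk],
    rise = speed[pk] - speed[mn[seq_len(m)]],
    fall = speed[pk] - speed[mn[seq_len(m) + 1L]]
  )
}

# index of the unit containing a sample index (first match at shared boundaries)
unit_containing <- function(units, idx) {
  hit <- which(units$start_idx <= idx & idx <= units$end_idx)
  if (length(hit) == 0) {
    stopf("sample %d lies outside all movement units (segmentation inconsistency)", idx)
  }
  hit[1]
}

#' Count movement units occurring after peak velocity
#'
#' Counts units whose peak falls strictly after the sample where the swipe's
#' peak velocity occurs; the unit containing the peak itself is not counted.
#' This indexes corrective submovements appended after the main transport.
#'
#' @param units Movement-unit tibble from [segment_units()].
#' @param pv_idx Sample index of the global peak velocity (first occurrence).
#' @return Integer count in `[0, nrow(units) - 1]`.
#' @export
units_after_pv <- function(units, pv_idx) {
  j <- unit_containing(units, pv_idx)  # errors if pv_idx is outside all units
  sum(units$peak_idx > pv_idx & seq_len(nrow(units)) != j)
}

#' Is peak velocity in the first movement unit?
#'
#' The binary marker of fluent action chaining: a mature goal-directed swipe
#' reaches its peak velocity during the first movement unit. Ties in peak
#' speed resolve to the first sample attaining the global maximum.
#'
#' @inheritParams units_after_pv
#' @return `TRUE` iff the unit containing `pv_idx` is the first unit.
#' @export
pv_in_first_unit <- function(units, pv_idx) {
  unit_containing(units, pv_idx) == 1L
}
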
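#' Game layout geometry
#'
#' A layout describes the rectangular screen regions of the sharing game in
#' device-pixel coordinates: the central `food_area` where food items appear,
#' and the `end_area`, a set of plate rectangles where goal-directed swipes
#' terminate. Region membership uses half-open rectangles
#' `[x0, x1) x [y0, y1)` so that points on a shared edge belong to exactly
#' one region.
#'
#' @param food_area Numeric vector `c(x0, y0, x1, y1)` in device pixels.
#' @param end_area Named list of plate rectangles, each `c(x0, y0, x1, y1)`.
#' @param screen Screen size `c(width, height)` in pixels.
#' @param ppi Pixel density of the device (pixels per inch).
#' @return An object of class `game_layout`.
#' @examples
#' layout <- default_layout()
#' min_food_plate_distance(layout)
#' @export
game_layout <- function(food_area, end_area, screen = c(2048, 1536), ppi = 326) {
  food_area <- as.numeric(food_area)
  if (length(food_area) != 4 || food_area[3] <= food_area[1] || food_area[4] <= food_area[2]) {
    stopf("`food_area` must be c(x0, y0, x1, y1) with positive extent", class = "swipekin_config_error")
  }
  if (!is.list(end_area) || length(end_area) == 0) {
    stopf("`end_area` must be a non-empty list of plate rectangles", class = "swipekin_config_error")
  }
  end_area <- lapply(end_area, as.numeric)
  for (nm in seq_along(end_area)) {
    r <- end_area[[nm]]
    if (length(r) != 4 || r[3] <= r[1] || r[4] <= r[2]) {
      stopf("end_area rectangle %s must be c(x0, y0, x1, y1) with positive extent", nm,
            class = "swipekin_config_error")
    }
    if (rects_intersect(food_area, r)) {
      stopf("food_area and end_area rectangles must be disjoint", class = "swipekin_config_error")
    }
  }
  structure(
    list(food_area = food_area, end_area = end_area,
         screen = as.numeric(screen), ppi = as.numeric(ppi)),
    class = "game_layout"
  )
}

#' Default game layout
#'
#' A layout mimicking the sharing game's proportions on a 2048 x 1536 canvas:
#' a central square food area and four plates (left, right, top, bottom)
#' placed so the shortest food-to-plate gap is 173 px, i.e. about 13.5 mm at
#' 326 ppi -- the shortest goal-directed displacement observed in this kind
#' of gameplay.
#'
#' @return A `game_layout` object.
#' @export
default_layout <- function() {
  game_layout(
    food_area = c(760, 504, 1288, 1032),
    end_area = list(
      left   = c(227, 568, 587, 968),
      right  = c(1461, 568, 1821, 968),
      top    = c(824, 151, 1224, 331),
      bottom = c(824, 1205, 1224, 1385)
    )
  )
}

#' Read a layout from a JSON config file
#'
#' Expects keys `food_area` (length-4 array), `end_area` (object of length-4
#' arrays), and optionally `screen` and `ppi`.
#'
#' @param path Path to a JSON file.
#' @return A `game_layout` object.
#' @export
read_layout <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$food_area) || is.null(cfg$end_area)) {
    stopf("layout config must define `food_area` and `end_area`", class = "swipekin_config_error")
  }
  end_area <- cfg$end_area
  if (is.matrix(end_area)) end_area <- split(end_area, seq_len(nrow(end_area)))
  if (is.data.frame(end_area)) end_area <- as.list(as.data.frame(t(end_area)))
  game_layout(cfg$food_area, as.list(end_area),
              screen = cfg$screen %||% c(2048, 1536),
              ppi = cfg$ppi %||% 326)
}

#' Write a layout to a JSON config file
#'
#' @param layout A `game_layout` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "game_layout"))
  jsonlite::write_json(unclass(layout), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Shortest distance between the food area and any plate
#'
#' Used by the cohort filter as the smallest displacement a genuine
#' food-to-plate swipe can have.
#'
#' @param layout A `game_layout` object.
#' @param units `"mm"` (default) or `"px"`.
#' @return Scalar distance.
#' @export
min_food_plate_distance <- function(layout, units = c("mm", "px")) {
  units <- match.arg(units)
  d_px <- min(vapply(layout$end_area, rect_distance, numeric(1), b = layout$food_area))
  if (units == "px") d_px else px_to_mm(d_px, ppi = layout$ppi)
}

#' @export
print.game_layout <- function(x, ...) {
  cat("<game_layout>\n")
  cat(sprintf("  screen: %g x %g px @ %g ppi\n", x$screen[1], x$screen[2], x$ppi))
  cat(sprintf("  food_area: [%g, %g] x [%g, %g]\n",
              x$food_area[1], x$food_area[3], x$food_area[2], x$food_area[4]))
  cat(sprintf("  end_area: %d plates (%s)\n", length(x$end_area),
              paste(names(x$end_area), collapse = ", ")))
  invisible(x)
}

# half-open rectangle membership: [x0, x1) x [y0, y1)
point_in_rect <- function(x, y, rect) {
  x >= rect[1] & x < rect[3] & y >= rect[2] & y < rect[4]
}

point_in_end_area <- function(x, y, layout) {
  any(vapply(layout$end_area, function(r) point_in_rect(x, y, r), logical(1)))
}

rects_intersect <- function(a, b) {
  a[1] < b[3] && b[1] < a[3] && a[2] < b[4] && b[2] < a[4]
}

# minimum Euclidean distance between two axis-aligned rectangles (0 if they touch)
rect_distance <- function(a, b) {
  dx <- max(0, a[1] - b[3], b[1] - a[3])
  dy <- max(0, a[2] - b[4], b[2] - a[4])
  sqrt(dx^2 + dy^2)
}
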
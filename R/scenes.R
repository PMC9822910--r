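#' Annotated waiting-room scene
#'
#' An image together with its per-head point annotations. Coordinates are
#' 0-based pixels, `x` = column, `y` = row, origin top-left; the count is
#' always the number of annotation points and every point lies inside the
#' image.
#'
#' @param image numeric matrix (grayscale intensities in `[0, 1]`).
#' @param heads data frame with columns `x` and `y` (may have zero rows).
#' @return An object of class `annotated_scene`: `image`, `heads`,
#'   `count`.
#' @export
annotated_scene <- function(image, heads = data.frame(x = numeric(0),
                                                      y = numeric(0))) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_invalid("`image` must be a numeric matrix")
  }
  if (!is.data.frame(heads) || !all(c("x", "y") %in% names(heads))) {
    stop_invalid("`heads` must be a data frame with columns x and y")
  }
  heads <- heads[, c("x", "y"), drop = FALSE]
  check_heads(heads, nrow(image), ncol(image))
  structure(list(image = image, heads = heads, count = nrow(heads)),
            class = "annotated_scene")
}

#' @export
print.annotated_scene <- function(x, ...) {
  cat(sprintf("Annotated scene %dx%d px, %d head(s)\n",
              nrow(x$image), ncol(x$image), x$count))
  invisible(x)
}

default_scene_style <- function() {
  list(radius_range = c(4, 12),    # px, blob semi-axes
       intensity_range = c(0.55, 0.95),
       background_level = 0.18,
       background_noise = 0.05)
}

# Renders using the current RNG state (callers control seeding).
render_scene <- function(n_heads, height, width, style) {
  bg <- style$background_level +
    0.04 * outer(sin(seq_len(height) / 7), cos(seq_len(width) / 9)) +
    matrix(runif(height * width, 0, style$background_noise), height, width)
  img <- pmin(pmax(bg, 0), 1)
  if (n_heads == 0L) {
    return(annotated_scene(img))
  }
  cx <- floor(runif(n_heads, 0, width))    # 0-based column
  cy <- floor(runif(n_heads, 0, height))   # 0-based row
  rx <- runif(n_heads, style$radius_range[1], style$radius_range[2])
  ry <- runif(n_heads, style$radius_range[1], style$radius_range[2])
  val <- runif(n_heads, style$intensity_range[1], style$intensity_range[2])
  for (i in seq_len(n_heads)) {
    rows <- max(1, ceiling(cy[i] + 1 - ry[i])):min(height, floor(cy[i] + 1 + ry[i]))
    cols <- max(1, ceiling(cx[i] + 1 - rx[i])):min(width, floor(cx[i] + 1 + rx[i]))
    d2 <- outer(((rows - 1 - cy[i]) / ry[i])^2, ((cols - 1 - cx[i]) / rx[i])^2, `+`)
    blob <- val[i] * (1 - 0.35 * d2)
    sub <- img[rows, cols]
    inside <- d2 <= 1
    sub[inside] <- pmax(sub[inside], blob[inside])
    img[rows, cols] <- sub
  }
  annotated_scene(pmin(pmax(img, 0), 1), data.frame(x = cx, y = cy))
}

#' Generate a synthetic waiting-room scene
#'
#' Renders `n_heads` head-like blobs (filled ellipses with randomised
#' 4--12 px radii, intensity and mild overlap) on a textured background
#' and returns the image together with the exact blob-centre annotations.
#' Identical seeds give bit-identical scenes. These scenes stand in for
#' surveillance frames: they exercise the counting task, not photographic
#' realism.
#'
#' @param n_heads number of heads to render (>= 0).
#' @param height,width image size in pixels (>= 64).
#' @param seed RNG seed; all randomness flows from it.
#' @param style appearance parameters, see `default_scene_style()`.
#' @return An [annotated_scene].
#' @examples
#' sc <- generate_scene(25, 96, 128, seed = 1)
#' sc$count  # 25
#' @export
generate_scene <- function(n_heads, height = 64L, width = 64L, seed = 1L,
                           style = default_scene_style()) {
  n_heads <- check_count(n_heads, "n_heads", 0L)
  height <- check_count(height, "height", 1L)
  width <- check_count(width, "width", 1L)
  if (height < 64L || width < 64L) {
    stop_invalid("scene dimensions must be at least 64x64 pixels")
  }
  with_seed(seed, render_scene(n_heads, height, width, style))
}

slot_grid_minutes <- function(hours, interval_min = 30L) {
  if (is_24h(hours)) {
    seq(hours$open_min, hours$close_min - interval_min, by = interval_min)
  } else {
    seq(hours$open_min, hours$close_min, by = interval_min)
  }
}

minutes_to_label <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

#' Generate a daily crowd profile for one area
#'
#' Expected people counts on the half-hourly sampling grid: a base level
#' plus Gaussian bumps at the given peak times (e.g. the morning surge in
#' a paediatric waiting area), clipped at zero. A 24-hour area yields 48
#' slots per day; an 08:00--18:00 area yields 21 (both endpoints
#' inclusive).
#'
#' @param area_name area label.
#' @param hours an [operating_hours()] spec.
#' @param peaks list of peaks, each `list(time = "HH:MM", amplitude =,
#'   width_min =)`; peak times must fall within the operating hours.
#' @param base baseline expected count.
#' @param noise_sd optional seeded slot-level jitter (expected counts are
#'   re-clipped at 0).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return A `crowd_profile`: data frame with `slot_min`, `slot`,
#'   `expected`, plus the area name as an attribute.
#' @examples
#' p <- generate_daily_profile("Pediatrics", operating_hours("00:00", "24:00"),
#'   peaks = list(list(time = "09:30", amplitude = 35, width_min = 90)),
#'   base = 5)
#' nrow(p)  # 48
#' @export
generate_daily_profile <- function(area_name, hours, peaks = list(),
                                   base = 0, noise_sd = 0, seed = 1L) {
  if (!inherits(hours, "operating_hours")) {
    stop_invalid("`hours` must be an operating_hours object")
  }
  check_number(base, "base", 0)
  grid <- slot_grid_minutes(hours)
  if (length(grid) == 0L) stop_invalid("empty operating-hours spec")
  expected <- rep(base, length(grid))
  for (p in peaks) {
    pm <- operating_hours(p$time, p$time)$open_min
    if (pm < hours$open_min || pm > hours$close_min) {
      stop_invalid("peak at ", p$time, " lies outside the operating hours")
    }
    expected <- expected + p$amplitude * exp(-0.5 * ((grid - pm) / p$width_min)^2)
  }
  if (noise_sd > 0) {
    expected <- with_seed(seed, expected + rnorm(length(grid), 0, noise_sd))
  }
  out <- data.frame(slot_min = grid, slot = minutes_to_label(grid),
                    expected = pmax(expected, 0))
  structure(out, area_name = area_name,
            class = c("crowd_profile", "data.frame"))
}

#' Generate the ten frames of one sampling slot
#'
#' Draws the slot's crowd size from a Poisson distribution with the
#' profile's expected count, then renders the video's frames with that
#' many heads give or take at most one person (waiting crowds are nearly
#' stationary, so frames within one minute barely differ).
#'
#' @param expected expected people count for the slot (>= 0).
#' @param seed RNG seed.
#' @param n_frames frames per video (default 10).
#' @inheritParams generate_scene
#' @return List of `n_frames` [annotated_scene] objects.
#' @export
generate_frame_bundle <- function(expected, seed = 1L, n_frames = 10L,
                                  height = 64L, width = 64L,
                                  style = default_scene_style()) {
  check_number(expected, "expected", 0)
  n_frames <- check_count(n_frames, "n_frames", 1L)
  with_seed(seed, {
    n <- rpois(1L, expected)
    jitter <- sample(c(-1L, 0L, 1L), n_frames, replace = TRUE,
                     prob = c(0.1, 0.8, 0.1))
    if (n == 0L) jitter <- rep(0L, n_frames)  # an empty room stays empty
    lapply(pmax(0L, n + jitter), render_scene, height = height,
           width = width, style = style)
  })
}

#' Write / read a scene as PNG plus a sidecar annotation file
#'
#' The image is written as grayscale PNG; annotations go to a sidecar
#' file, either CSV (`x,y` per row) or JSON (which also records the image
#' dimensions).
#'
#' @param scene an [annotated_scene].
#' @param png_path PNG output path.
#' @param ann_path sidecar path; `.csv` or `.json` decides the format
#'   (default: `png_path` with extension replaced by `.csv`).
#' @return `write_scene` returns `png_path` invisibly; `read_scene`
#'   returns an [annotated_scene].
#' @export
write_scene <- function(scene, png_path,
                        ann_path = sub("\\.png$", ".csv", png_path)) {
  stopifnot(inherits(scene, "annotated_scene"))
  png::writePNG(scene$image, png_path)
  if (grepl("\\.json$", ann_path, ignore.case = TRUE)) {
    jsonlite::write_json(list(height = nrow(scene$image),
                              width = ncol(scene$image),
                              heads = scene$heads),
                         ann_path, auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(scene$heads, ann_path, row.names = FALSE)
  }
  invisible(png_path)
}

#' @rdname write_scene
#' @export
read_scene <- function(png_path,
                       ann_path = sub("\\.png$", ".csv", png_path)) {
  img <- png::readPNG(png_path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  heads <- if (grepl("\\.json$", ann_path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(ann_path, simplifyVector = TRUE)
    as.data.frame(j$heads)
  } else {
    read.csv(ann_path)
  }
  if (nrow(heads) == 0L) heads <- data.frame(x = numeric(0), y = numeric(0))
  annotated_scene(img, heads)
}
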
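#' Operating hours of a surveillance area
#'
#' @param open,close opening and closing clock times, `"HH:MM"` strings.
#'   A 24-hour area is written `operating_hours("00:00", "24:00")`.
#' @return An object of class `operating_hours` with `open_min` and
#'   `close_min` (minutes after midnight).
#' @export
operating_hours <- function(open = "08:00", close = "18:00") {
  parse_clock <- function(s, name) {
    if (inherits(s, "operating_hours")) stop_invalid("nested hours spec")
    if (!is.character(s) || length(s) != 1L ||
        !grepl("^([01]?[0-9]|2[0-4]):[0-5][0-9]$", s)) {
      stop_invalid("`", name, "` must be an \"HH:MM\" clock time, got ",
                   deparse(s))
    }
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1L]])
    m <- p[1L] * 60L + p[2L]
    if (m > 1440L) stop_invalid("`", name, "` is past 24:00")
    m
  }
  o <- parse_clock(open, "open")
  c_ <- parse_clock(close, "close")
  if (c_ < o) stop_invalid("closing time precedes opening time")
  structure(list(open_min = o, close_min = c_), class = "operating_hours")
}

is_24h <- function(hours) (hours$close_min - hours$open_min) == 1440L

#' Surveillance sampling plan
#'
#' The frame-sampling design: every `interval_min` minutes a
#' `video_length_s`-second video is captured, from which frames are
#' extracted at `fps` frames per second, capped at `frames_per_video`
#' frames.
#'
#' @param interval_min minutes between consecutive videos (default 30).
#' @param video_length_s length of each video in seconds (default 60).
#' @param fps frame-extraction rate in frames per second (default 0.2,
#'   i.e. one frame every five seconds).
#' @param frames_per_video number of frames kept per video (default 10).
#' @return An object of class `sampling_plan`.
#' @export
sampling_plan <- function(interval_min = 30, video_length_s = 60,
                          fps = 0.2, frames_per_video = 10L) {
  check_number(interval_min, "interval_min", 0, strict = TRUE)
  check_number(video_length_s, "video_length_s", 0, strict = TRUE)
  check_number(fps, "fps", 0, strict = TRUE)
  frames_per_video <- check_count(frames_per_video, "frames_per_video", 1L)
  if (interval_min * 60 <= video_length_s) {
    stop_invalid("sampling interval must exceed the video length")
  }
  if ((frames_per_video - 1L) / fps > video_length_s) {
    stop_invalid("infeasible plan: ", frames_per_video, " frames at ",
                 fps, " fps do not fit in a ", video_length_s, "-s video")
  }
  structure(list(interval_min = interval_min,
                 video_length_s = video_length_s,
                 fps = fps, frames_per_video = frames_per_video),
            class = "sampling_plan")
}

#' Number of videos captured per day in one area
#'
#' Videos are taken on the half-hour grid over the operating hours,
#' inclusive of both endpoints for bounded hours (so a 08:00--18:00 area
#' yields 21 videos/day); a 24-hour area yields one video per grid point of
#' the clock (48/day), since 24:00 coincides with the next day's 00:00.
#'
#' @param hours an [operating_hours()] spec.
#' @param plan a [sampling_plan()].
#' @return Integer number of videos.
#' @export
videos_per_day <- function(hours, plan = sampling_plan()) {
  if (!inherits(hours, "operating_hours")) {
    stop_invalid("`hours` must be an operating_hours object")
  }
  span <- hours$close_min - hours$open_min
  if (is_24h(hours)) {
    as.integer(1440 %/% plan$interval_min)
  } else {
    as.integer(span %/% plan$interval_min + 1L)
  }
}

#' Total videos over a multi-day, multi-area collection
#'
#' @param areas list of [operating_hours()] specs, one per area.
#' @param days number of collection days.
#' @inheritParams videos_per_day
#' @return Integer total.
#' @examples
#' h24 <- operating_hours("00:00", "24:00")
#' h10 <- operating_hours("08:00", "18:00")
#' weekly_video_count(list(h24, h24, h10, h10, h10), days = 7) # 1113
#' @export
weekly_video_count <- function(areas, days = 7L, plan = sampling_plan()) {
  days <- check_count(days, "days", 1L)
  if (length(areas) == 0L) return(0L)
  sum(vapply(areas, videos_per_day, integer(1), plan = plan)) * days
}

#' Frame-extraction time offsets within one video
#'
#' @inheritParams videos_per_day
#' @return Numeric vector of offsets in seconds from the start of the
#'   video: `0, 1/fps, ...` up to `frames_per_video` frames.
#' @export
frame_times <- function(plan = sampling_plan()) {
  seq(0, by = 1 / plan$fps, length.out = plan$frames_per_video)
}

#' Mean people count over the frames of one sampling slot
#'
#' @param counts per-frame people counts for one video.
#' @return The arithmetic mean.
#' @export
aggregate_slot <- function(counts) {
  if (length(counts) == 0L) stop_invalid("no frame counts to aggregate")
  if (!is.numeric(counts) || any(!is.finite(counts))) {
    stop_invalid("frame counts must be finite numbers")
  }
  mean(counts)
}

#' Chronological count table with recomputed margins
#'
#' Assembles per-slot mean counts into an areas-by-time table with daily
#' and weekly margins. Margins are always recomputed from the cells, never
#' trusted from the input.
#'
#' @param cells data frame with columns `area`, `day`, `count` and
#'   optionally `slot` (a slot label or time; omitted when the input is
#'   already a daily aggregate, one row per area-day).
#' @return A `count_table` object: the cell data plus a `daily` area x day
#'   matrix of per-day sums, `area_totals`, `day_totals` and `grand_total`.
#' @examples
#' cells <- data.frame(area = "Pharmacy", day = "Monday",
#'                     slot = c("08:00", "08:30"), count = c(4, 6))
#' build_count_table(cells)$daily
#' @export
build_count_table <- function(cells) {
  need <- c("area", "day", "count")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    stop_invalid("`cells` must have columns area, day, count")
  }
  if (!"slot" %in% names(cells)) cells$slot <- NA_character_
  if (any(cells$count < 0)) stop_invalid("counts must be non-negative")
  key <- paste(cells$area, cells$day, cells$slot, sep = "\r")
  if (anyDuplicated(key)) {
    stop_invalid("duplicate (area, day, slot) cells: ",
                 paste(unique(gsub("\r", "/", key[duplicated(key)])),
                       collapse = ", "))
  }
  areas <- unique(cells$area)
  days <- unique(cells$day)
  daily <- matrix(0, length(areas), length(days),
                  dimnames = list(areas, days))
  agg <- tapply(cells$count, list(cells$area, cells$day), sum)
  daily[rownames(agg), colnames(agg)] <- ifelse(is.na(agg), 0, agg)
  structure(list(cells = cells,
                 daily = daily,
                 area_totals = rowSums(daily),
                 day_totals = colSums(daily),
                 grand_total = sum(daily)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, digits = 2, ...) {
  cat("Count table:", nrow(x$daily), "area(s) x", ncol(x$daily), "day(s)\n")
  m <- cbind(x$daily, Sum = x$area_totals)
  m <- rbind(m, Sum = c(x$day_totals, x$grand_total))
  print(round_half_up(m, digits))
  invisible(x)
}

#' Write / read a count table as CSV
#'
#' The CSV mirrors the weekly report layout: one row per area, one column
#' per day, plus recomputed `Sum` row and column.
#'
#' @param x a `count_table`.
#' @param path file path.
#' @param digits decimals for report-time rounding (half-up); `NA` keeps
#'   exact means.
#' @return `write_count_table` returns `path` invisibly;
#'   `read_count_table` returns a `count_table` rebuilt from the daily
#'   cells (margins recomputed).
#' @export
write_count_table <- function(x, path, digits = NA) {
  stopifnot(inherits(x, "count_table"))
  m <- x$daily
  if (!is.na(digits)) m <- round_half_up(m, digits)
  out <- data.frame(area = rownames(m), m, Sum = rowSums(m),
                    check.names = FALSE)
  out <- rbind(out, c(area = "Sum", as.list(colSums(m)),
                      Sum = sum(m)))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  df <- df[df$area != "Sum", , drop = FALSE]
  days <- setdiff(names(df), c("area", "Sum"))
  long <- data.frame(
    area = rep(df$area, times = length(days)),
    day = rep(days, each = nrow(df)),
    count = unlist(df[days], use.names = FALSE)
  )
  build_count_table(long)
}
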
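#' Theoretical capacity of a waiting area from personal space
#'
#' The number of people an area can hold before the waiting crowd feels
#' psychologically uncomfortable, derived from proxemics: each person
#' claims a disc of radius `d_personal` (Hall's personal distance, 4 ft =
#' 1.2 m by default), so capacity is `area / (pi * d_personal^2)`.
#'
#' @param area floor area of the waiting zone (square metres when
#'   `d_personal` is in metres; any consistent unit pair works).
#' @param d_personal personal distance radius (default 1.2 m).
#' @return An object of class `capacity`: `N_theoretical`, `d_personal`,
#'   `area`.
#' @examples
#' theoretical_capacity(67.14)   # paediatric waiting area: 14.84 people
#' @export
theoretical_capacity <- function(area, d_personal = 1.2) {
  check_number(area, "area", 0, strict = TRUE)
  check_number(d_personal, "d_personal", 0, strict = TRUE)
  structure(list(N_theoretical = area / (pi * d_personal^2),
                 d_personal = d_personal, area = area),
            class = "capacity")
}

#' @export
print.capacity <- function(x, ...) {
  cat(sprintf("Theoretical capacity: %.2f people (area %.2f, d = %.2f)\n",
              x$N_theoretical, x$area, x$d_personal))
  invisible(x)
}

#' Unit congestion rate
#'
#' The ratio of the actual number of people present to the theoretical
#' capacity of the area. Values above 1 mean the waiting crowd is packed
#' tighter than the personal-space comfort limit.
#'
#' @param N_actual observed number of people (per slot, or a mean).
#' @param capacity a [theoretical_capacity()] result.
#' @return Dimensionless rate(s), same length as `N_actual`.
#' @examples
#' congestion_rate(40.75, theoretical_capacity(67.14))  # 2.75
#' @export
congestion_rate <- function(N_actual, capacity) {
  if (!inherits(capacity, "capacity")) {
    stop_invalid("`capacity` must come from theoretical_capacity()")
  }
  if (any(N_actual < 0)) stop_invalid("`N_actual` must be non-negative")
  N_actual / capacity$N_theoretical
}

area_hours <- function(spec_row) operating_hours(spec_row$open, spec_row$close)

match_specs <- function(table, specs) {
  areas <- rownames(table$daily)
  missing <- setdiff(areas, specs$name)
  if (length(missing)) {
    stop_invalid("no area spec for: ", paste(missing, collapse = ", "))
  }
  specs[match(areas, specs$name), , drop = FALSE]
}

#' Time-resolved congestion profile per area
#'
#' Converts a per-slot [build_count_table()] into per-slot congestion
#' rates, optionally smoothed by a centred moving average (the default
#' window of 3 slots traces the within-day trend without flattening the
#' morning/evening peaks). The returned cells support the three standard
#' views: rate over time within an area-day, rate along the care process
#' (across areas) at a fixed time, and day-over-day rate at a fixed time
#' (see [rate_across_areas()] / [rate_across_days()]).
#'
#' @param table a `count_table` with slot-level cells.
#' @param specs data frame of area specs (`name`, `area_m2`, `seats`,
#'   `open`, `close`), e.g. [ed_area_specs()].
#' @param d_personal personal distance in metres.
#' @param smooth_window odd moving-average window in slots; 1 disables
#'   smoothing.
#' @return Data frame: `area`, `day`, `slot`, `N_actual`, `rate`,
#'   `rate_smooth`.
#' @export
congestion_profile <- function(table, specs, d_personal = 1.2,
                               smooth_window = 3L) {
  stopifnot(inherits(table, "count_table"))
  smooth_window <- check_count(smooth_window, "smooth_window", 1L)
  if (smooth_window %% 2L == 0L) {
    stop_invalid("`smooth_window` must be odd (centred window)")
  }
  specs <- match_specs(table, specs)
  cap <- vapply(specs$area_m2,
                function(a) theoretical_capacity(a, d_personal)$N_theoretical,
                numeric(1))
  names(cap) <- specs$name
  cells <- table$cells
  out <- data.frame(area = cells$area, day = cells$day, slot = cells$slot,
                    N_actual = cells$count,
                    rate = cells$count / cap[cells$area])
  sm <- function(v) {
    if (smooth_window == 1L || length(v) == 1L) return(v)
    h <- (smooth_window - 1L) %/% 2L
    vapply(seq_along(v), function(i) {
      mean(v[max(1L, i - h):min(length(v), i + h)])
    }, numeric(1))
  }
  out$rate_smooth <- out$rate
  for (g in split(seq_len(nrow(out)), list(out$area, out$day), drop = TRUE)) {
    out$rate_smooth[g] <- sm(out$rate[g])
  }
  out
}

#' @rdname congestion_profile
#' @param profile result of `congestion_profile()`.
#' @param day,slot,area fixed coordinates for the cross-sections.
#' @export
rate_across_areas <- function(profile, day, slot) {
  p <- profile[profile$day == day & profile$slot == slot, ]
  p[order(match(p$area, unique(profile$area))), ]
}

#' @rdname congestion_profile
#' @export
rate_across_days <- function(profile, area, slot) {
  p <- profile[profile$area == area & profile$slot == slot, ]
  p[order(match(p$day, unique(profile$day))), ]
}

#' Per-area congestion report
#'
#' One row per area: floor area, seats, theoretical capacity, mean number
#' of people actually waiting, and the mean unit congestion rate. The mean
#' is taken over operating-hour slots only: for slot-level tables it is the
#' mean of the slot means; for daily-aggregate tables it divides the weekly
#' person-time total by (slots per day x days), with slots per day derived
#' from the area's operating hours and the sampling plan.
#'
#' @inheritParams congestion_profile
#' @param plan the [sampling_plan()] defining the slot grid.
#' @return Data frame with columns `area`, `area_m2`, `seats`,
#'   `N_theoretical`, `mean_N_actual`, `mean_rate`.
#' @examples
#' ct <- build_count_table(
#'   data.frame(area = "Pharmacy", day = "Monday",
#'              slot = c("08:00", "08:30"), count = c(2, 4)))
#' congestion_report(ct, ed_area_specs())
#' @export
congestion_report <- function(table, specs, d_personal = 1.2,
                              plan = sampling_plan()) {
  stopifnot(inherits(table, "count_table"))
  specs <- match_specs(table, specs)
  ndays <- ncol(table$daily)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    nm <- specs$name[i]
    cells <- table$cells[table$cells$area == nm, ]
    if (all(is.na(cells$slot))) {
      slots <- videos_per_day(area_hours(specs[i, ]), plan) * ndays
      mean_actual <- table$area_totals[[nm]] / slots
    } else {
      mean_actual <- mean(cells$count)
    }
    cap <- theoretical_capacity(specs$area_m2[i], d_personal)
    data.frame(area = nm, area_m2 = specs$area_m2[i],
               seats = specs$seats[i],
               N_theoretical = cap$N_theoretical,
               mean_N_actual = mean_actual,
               mean_rate = congestion_rate(mean_actual, cap))
  })
  do.call(rbind, rows)
}
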
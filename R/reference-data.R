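#' Reference data: one-week emergency-department surveillance survey
#'
#' Summary data from a one-week (Monday--Sunday) surveillance survey of five
#' areas of a tertiary-hospital emergency department: the registration hall,
#' the paediatric waiting area, the internal-medicine-and-surgery waiting
#' area, the inspection (laboratory) waiting area and an independent
#' pharmacy. Paediatrics and internal medicine/surgery operate around the
#' clock; the other three areas operate 08:00--18:00.
#'
#' `ed_weekly_counts()` returns the daily person-time totals per area (the
#' sum over a day's half-hourly slot means). `ed_area_specs()` returns the
#' architectural planning data (floor area in square metres, seats, operating
#' hours) together with the surveyed mean number of people waiting.
#' `ed_visit_groups()` returns the demographic grouping of the usable visit
#' records (counts and percentages per factor level).
#'
#' @return A data frame (see Details).
#' @examples
#' ed_weekly_counts()
#' ed_area_specs()
#' @name ed_reference_data
NULL

ed_area_names <- function() {
  c("Registered", "Pediatrics", "Internal medicine and Surgery",
    "Inspection", "Pharmacy")
}

#' @rdname ed_reference_data
#' @export
ed_weekly_counts <- function() {
  days <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
            "Saturday", "Sunday")
  m <- matrix(
    c(693, 1485,  963, 183, 75,
      599, 1584,  850, 136, 91,
      637, 1387,  902, 169, 89,
      582, 1639,  869, 103, 78,
      650, 1541,  944, 114, 68,
      682, 1335,  947, 225, 87,
      647, 1465, 1037, 229, 78),
    nrow = 7, byrow = TRUE, dimnames = list(days, ed_area_names())
  )
  as.data.frame(m)
}

#' @rdname ed_reference_data
#' @export
ed_area_specs <- function() {
  data.frame(
    name = ed_area_names(),
    area_m2 = c(115.02, 67.14, 66.78, 44.73, 110.24),
    seats = c(12L, 30L, 16L, 1L, 10L),
    open  = c("08:00", "00:00", "00:00", "08:00", "08:00"),
    close = c("18:00", "24:00", "24:00", "18:00", "18:00"),
    # surveyed mean number of people waiting (per occupied slot)
    mean_waiting = c(30.54, 40.75, 23.19, 7.84, 3.82),
    stringsAsFactors = FALSE
  )
}

#' Disease-category vocabulary of the visit records
#'
#' The fourteen diagnosis categories used to classify emergency visits, in
#' reporting order.
#'
#' @return Character vector of length 14.
#' @export
disease_categories <- function() {
  c("Various infectious diseases", "Oncology cancer", "Endocrine system",
    "Nervous system", "Circulatory system", "Respiratory system",
    "Digestive system", "Immune system", "Motor system",
    "Genitourinary system", "Obstetrics and congenital disorders",
    "Trauma", "Accident", "Psychological problems and examination")
}

#' @rdname ed_reference_data
#' @export
ed_visit_groups <- function() {
  rbind(
    data.frame(factor = "sex", level = c("Male", "Female"),
               n = c(1889L, 1741L)),
    data.frame(factor = "age_band",
               level = c("[0,1)", "[1,3)", "[3,6)", "[6,12)", "[12,20)",
                         "[20,30)", "[30,40)", "[40,50)", "[50,60)",
                         "[60,Inf)"),
               n = c(288L, 721L, 1007L, 457L, 178L, 195L, 221L, 158L,
                     190L, 260L)),
    data.frame(factor = "n_diagnoses", level = c("1", "2", "3", "4"),
               n = c(2853L, 727L, 37L, 3L)),
    data.frame(factor = "disease_type", level = disease_categories(),
               n = c(151L, 2L, 7L, 29L, 32L, 2036L, 396L, 525L, 21L, 64L,
                     10L, 200L, 78L, 197L))
  )
}
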
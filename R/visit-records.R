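#' Configuration for the synthetic visit-record generator
#'
#' Controls the emergency-visit record simulator. Defaults reproduce the
#' surveyed cohort structure: 4717 records of which ~22.1% lack a
#' milestone needed to compute durations, sex close to balanced, two
#' thirds of patients children, mostly single diagnoses, and respiratory
#' problems dominating the disease mix (54.3% of diagnoses).
#'
#' Effect sizes are expressed in units of the residual SD (`noise_sd`):
#' `age_t2` is the diagnosis-time trend per age SD (positive: older
#' patients need longer consultations), `age_t1` the post-diagnosis trend
#' per age SD (negative: younger patients linger longer after diagnosis),
#' `ndiag_t1` the post-diagnosis shift per additional diagnosis.
#'
#' @param n_records number of records to simulate.
#' @param effects named list: `age_t2`, `age_t1`, `ndiag_t1` (SD units;
#'   all 0 gives null data).
#' @param category_probs probabilities over the 14 [disease_categories()];
#'   must sum to 1.
#' @param ndiag_probs probabilities of 1, 2 or 3 diagnoses; must sum to 1.
#' @param p_male probability of a male record.
#' @param missing_fraction fraction of records with a missing milestone
#'   that makes the durations uncomputable (missing completely at random).
#' @param base_t2,base_post baseline diagnosis time and post-diagnosis
#'   time, minutes.
#' @param noise_sd residual SD of the duration model, minutes.
#' @param start_date first day of the simulated week (`Date` or string).
#' @param seed RNG seed.
#' @return A `synthetic_visit_config` object.
#' @export
synthetic_visit_config <- function(n_records = 4717L,
                                   effects = list(age_t2 = 0.5,
                                                  age_t1 = -0.3,
                                                  ndiag_t1 = 0.5),
                                   category_probs = NULL,
                                   ndiag_probs = NULL,
                                   p_male = 0.5203,
                                   missing_fraction = 0.221,
                                   base_t2 = 25, base_post = 60,
                                   noise_sd = 15,
                                   start_date = "2020-10-26",
                                   seed = 1L) {
  n_records <- check_count(n_records, "n_records", 1L)
  groups <- ed_visit_groups()
  if (is.null(category_probs)) {
    cnt <- groups$n[groups$factor == "disease_type"]
    category_probs <- cnt / sum(cnt)
  }
  if (length(category_probs) != 14L || abs(sum(category_probs) - 1) > 1e-8 ||
      any(category_probs < 0)) {
    stop_invalid("`category_probs` must be 14 probabilities summing to 1")
  }
  if (is.null(ndiag_probs)) {
    cnt <- groups$n[groups$factor == "n_diagnoses"][1:3]
    ndiag_probs <- cnt / sum(cnt)
  }
  if (length(ndiag_probs) != 3L || abs(sum(ndiag_probs) - 1) > 1e-8 ||
      any(ndiag_probs < 0)) {
    stop_invalid("`ndiag_probs` must be 3 probabilities summing to 1")
  }
  check_number(missing_fraction, "missing_fraction", 0)
  if (missing_fraction >= 1) stop_invalid("`missing_fraction` must be < 1")
  eff <- list(age_t2 = 0, age_t1 = 0, ndiag_t1 = 0)
  eff[names(effects)] <- effects
  structure(list(n_records = n_records, effects = eff,
                 category_probs = category_probs,
                 ndiag_probs = ndiag_probs, p_male = p_male,
                 missing_fraction = missing_fraction,
                 base_t2 = base_t2, base_post = base_post,
                 noise_sd = noise_sd,
                 start_date = as.Date(start_date), seed = as.integer(seed)),
            class = "synthetic_visit_config")
}

sample_ages <- function(n) {
  groups <- ed_visit_groups()
  bands <- groups[groups$factor == "age_band", ]
  lower <- c(0, 1, 3, 6, 12, 20, 30, 40, 50, 60)
  upper <- c(1, 3, 6, 12, 20, 30, 40, 50, 60, 90)
  band <- sample.int(length(lower), n, replace = TRUE,
                     prob = bands$n / sum(bands$n))
  runif(n, lower[band], upper[band])
}

#' Generate synthetic emergency-visit records
#'
#' Simulates one week of visit records with receipt, diagnosis, payment
#' and dispensing timestamps. Diagnosis time (T2) and post-diagnosis time
#' carry the configured planted effects of age and number of diagnoses; a
#' configurable fraction of records has a milestone deleted completely at
#' random, making their durations uncomputable. Fully seeded.
#'
#' @param config a [synthetic_visit_config()].
#' @return A data frame of class `visit_records`: `id`, `sex`, `age`,
#'   `diagnoses` (semicolon-separated categories), `n_diagnoses`,
#'   `t_receipt`, `t_diagnosis`, `t_payment`, `t_dispense` (POSIXct, NA
#'   when missing).
#' @examples
#' rec <- generate_visit_records(synthetic_visit_config(n_records = 100))
#' usable_fraction(compute_durations(rec))
#' @export
generate_visit_records <- function(config = synthetic_visit_config()) {
  if (!inherits(config, "synthetic_visit_config")) {
    stop_invalid("`config` must come from synthetic_visit_config()")
  }
  n <- config$n_records
  with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$p_male, "Male", "Female")
    age <- sample_ages(n)
    ndiag <- sample.int(3L, n, replace = TRUE, prob = config$ndiag_probs)
    cats <- disease_categories()
    diagnoses <- vapply(ndiag, function(k) {
      paste(sample(cats, k, replace = FALSE, prob = config$category_probs),
            collapse = ";")
    }, character(1))
    # arrival: uniform day of week, time of day peaked mid-morning
    day <- sample.int(7L, n, replace = TRUE) - 1L
    tod <- pmin(pmax(rnorm(n, mean = 10.5 * 60, sd = 180), 0), 1439)
    t_receipt <- as.POSIXct(config$start_date, tz = "UTC") +
      day * 86400 + round(tod) * 60
    z_age <- (age - 30) / 25
    e <- config$effects
    t2 <- pmax(1, config$base_t2 + e$age_t2 * config$noise_sd * z_age +
                 rnorm(n, 0, config$noise_sd))
    post <- pmax(5, config$base_post + e$age_t1 * config$noise_sd * z_age +
                   e$ndiag_t1 * config$noise_sd * (ndiag - 1) +
                   rnorm(n, 0, config$noise_sd))
    t_diagnosis <- t_receipt + round(t2 * 60)
    t_payment <- t_diagnosis + round(0.6 * post * 60)
    t_dispense <- t_diagnosis + round(post * 60)
    # MCAR milestone deletion: remove the diagnosis time, or both
    # post-diagnosis milestones, so the record's durations cannot be formed
    drop <- runif(n) < config$missing_fraction
    drop_diag <- drop & runif(n) < 0.5
    drop_post <- drop & !drop_diag
    t_diagnosis[drop_diag] <- NA
    t_payment[drop_post] <- NA
    t_dispense[drop_post] <- NA
    out <- data.frame(id = sprintf("V%05d", seq_len(n)),
                      sex = sex, age = age, diagnoses = diagnoses,
                      n_diagnoses = ndiag,
                      t_receipt = t_receipt, t_diagnosis = t_diagnosis,
                      t_payment = t_payment, t_dispense = t_dispense,
                      stringsAsFactors = FALSE)
    class(out) <- c("visit_records", "data.frame")
    out
  })
}

#' Write / read visit records as CSV
#'
#' Timestamps are ISO-8601 (`YYYY-MM-DDTHH:MM:SSZ`); an empty cell is a
#' missing milestone.
#'
#' @param records a `visit_records` data frame.
#' @param path CSV path.
#' @return `write_visit_records` returns `path` invisibly;
#'   `read_visit_records` returns a `visit_records` data frame.
#' @export
write_visit_records <- function(records, path) {
  out <- as.data.frame(records)
  for (col in c("t_receipt", "t_diagnosis", "t_payment", "t_dispense")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         format(out[[col]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_visit_records
#' @export
read_visit_records <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("t_receipt", "t_diagnosis", "t_payment", "t_dispense")) {
    v <- df[[col]]
    v[v == ""] <- NA
    df[[col]] <- as.POSIXct(v, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  class(df) <- c("visit_records", "data.frame")
  df
}
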
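stamp <- function(s) as.POSIXct(s, tz = "UTC")

one_record <- function(receipt, diagnosis = NA, payment = NA, dispense = NA) {
  data.frame(id = "r1", sex = "Male", age = 30,
             diagnoses = "Respiratory system", n_diagnoses = 1L,
             t_receipt = stamp(receipt),
             t_diagnosis = if (is.na(diagnosis)) stamp(NA) else stamp(diagnosis),
             t_payment = if (is.na(payment)) stamp(NA) else stamp(payment),
             t_dispense = if (is.na(dispense)) stamp(NA) else stamp(dispense))
}

test_that("durations anchor at receipt with the documented milestone preference", {
  r <- one_record("2020-10-26 09:00:00", diagnosis = "2020-10-26 09:37:00",
                  payment = "2020-10-26 10:15:00",
                  dispense = "2020-10-26 10:40:00")
  d <- compute_durations(r)
  expect_equal(d$T2, 37)
  expect_equal(d$T1, 100)          # dispensing preferred over payment
  expect_equal(d$t1_post, 63)
  expect_true(d$usable)

  pay_first <- compute_durations(r, group_scheme(t1_milestone = "payment"))
  expect_equal(pay_first$T1, 75)

  no_disp <- compute_durations(one_record("2020-10-26 09:00:00",
    diagnosis = "2020-10-26 09:30:00", payment = "2020-10-26 10:15:00"))
  expect_equal(no_disp$T1, 75)     # payment fallback

  no_diag <- compute_durations(one_record("2020-10-26 09:00:00",
    payment = "2020-10-26 10:15:00"))
  expect_false(no_diag$usable)

  negative <- compute_durations(one_record("2020-10-26 09:00:00",
    diagnosis = "2020-10-26 08:30:00", dispense = "2020-10-26 10:00:00"))
  expect_false(negative$usable)
})

test_that("usable fractions count computable records, order-invariantly", {
  rec <- generate_visit_records(synthetic_visit_config(n_records = 400,
                                                       seed = 8))
  uf <- usable_fraction(rec)
  shuffled <- rec[sample(nrow(rec)), ]
  expect_equal(usable_fraction(shuffled)$fraction, uf$fraction)
  expect_equal(uf$fraction, uf$n_usable / uf$n_total)
  expect_error(usable_fraction(rec[0, ]), class = "edcrowd_invalid_argument")
})

test_that("every age maps to exactly one band", {
  scheme <- group_scheme()
  ages <- c(0, 0.5, 1, 2.9, 3, 5, 6, 11.9, 12, 19, 20, 59.9, 60, 97)
  bands <- assign_age_band(ages, scheme)
  expect_false(anyNA(bands))
  expect_equal(as.character(bands[ages == 12]), "[12,20)")
  expect_equal(as.character(bands[ages == 0]), "[0,1)")
  expect_equal(as.character(bands[ages == 60]), "[60,Inf)")
  # property: random ages always land in one band
  set.seed(1)
  expect_false(anyNA(assign_age_band(runif(500, 0, 110), scheme)))
  expect_error(assign_age_band(-1), class = "edcrowd_invalid_argument")
})

test_that("group summaries conserve counts within each factor", {
  rec <- generate_visit_records(synthetic_visit_config(n_records = 800,
                                                       seed = 4))
  rec <- compute_durations(rec)
  gs <- group_summary(rec)
  n_usable <- usable_fraction(rec)$n_usable
  for (f in unique(gs$factor)) {
    expect_equal(sum(gs$n[gs$factor == f]), n_usable)
    expect_equal(sum(gs$percent[gs$factor == f]), 100, tolerance = 1e-9)
  }
  one <- compute_durations(one_record("2020-10-26 09:00:00",
    diagnosis = "2020-10-26 09:30:00", dispense = "2020-10-26 11:00:00"))
  gs1 <- group_summary(one)
  expect_equal(gs1$percent[gs1$factor == "sex" & gs1$n > 0], 100)
})

test_that("unknown disease categories are rejected", {
  bad <- one_record("2020-10-26 09:00:00", diagnosis = "2020-10-26 09:30:00",
                    dispense = "2020-10-26 11:00:00")
  bad$diagnoses <- "Dermatology"
  expect_error(group_summary(compute_durations(bad)),
               "unknown disease category")
})

test_that("two identical groups are never declared different", {
  x <- rep(c(10, 12, 14, 16, 18), 8)
  g <- rep(c("a", "b"), each = 20)
  res <- compare_groups(c(x[1:20], x[1:20]), g)
  expect_false(res$significant)
  expect_gt(res$p.value, 0.9)
})

test_that("a one-SD mean shift is detected almost always", {
  hits <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    v <- c(rnorm(200, 0, 1), rnorm(200, 1, 1))
    compare_groups(v, rep(c("a", "b"), each = 200))$significant
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("test selection follows the normality and homogeneity gates", {
  set.seed(77)
  skewed <- exp(rnorm(300, sd = 1.2))
  labels3 <- rep(c("a", "b", "c"), each = 100)
  sel <- compare_groups(skewed * c(1, 1.2, 1.5)[as.integer(factor(labels3))],
                        labels3)
  expect_equal(sel$test, "kruskal-wallis")

  set.seed(78)
  normal <- rnorm(300, mean = c(0, 0.2, 0.4)[as.integer(factor(labels3))])
  sel2 <- compare_groups(normal, labels3)
  expect_equal(sel2$test, "anova")

  two <- compare_groups(rnorm(40), rep(c("a", "b"), 20))
  expect_equal(two$test, "t-test")

  expect_error(compare_groups(rnorm(3), c("a", "a", "b")),
               class = "edcrowd_invalid_argument")
  expect_error(compare_groups(rnorm(10), rep("a", 10)),
               class = "edcrowd_invalid_argument")
})

test_that("influence reports recover planted effects and keep the summary structure", {
  rec <- generate_visit_records(synthetic_visit_config(
    n_records = 1500, effects = list(age_t2 = 0.8, age_t1 = -0.5,
                                     ndiag_t1 = 0.8), seed = 21))
  rep <- influence_report(rec)
  expect_equal(rep[, c("factor", "level", "n", "percent")],
               group_summary(compute_durations(rec)))
  expect_lt(rep$p_T2[rep$factor == "age_band"][1], 0.05)
  expect_lt(rep$p_T1[rep$factor == "n_diagnoses"][1], 0.05)
  # Bonferroni correction never lowers a p-value
  rep_adj <- influence_report(rec, adjust = "bonferroni")
  expect_true(all(rep_adj$p_T1 >= rep$p_T1 - 1e-12, na.rm = TRUE))
})
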
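test_that("theoretical capacity follows the personal-space formula", {
  expect_equal(theoretical_capacity(pi * 1.2^2)$N_theoretical, 1)
  expect_equal(theoretical_capacity(115.02)$N_theoretical, 25.42,
               tolerance = 0.01 / 25.42)
  expect_equal(theoretical_capacity(67.14)$N_theoretical, 14.84,
               tolerance = 0.01 / 14.84)
  expect_error(theoretical_capacity(0), class = "edcrowd_invalid_argument")
  expect_error(theoretical_capacity(10, 0), class = "edcrowd_invalid_argument")
})

test_that("congestion rates match the surveyed areas at 2 decimals", {
  r_ped <- congestion_rate(40.75, theoretical_capacity(67.14))
  expect_equal(round_any(r_ped), 2.75)
  r_pha <- congestion_rate(3.82, theoretical_capacity(110.24))
  expect_equal(round_any(r_pha), 0.16)
  r_ins <- congestion_rate(7.84, theoretical_capacity(44.73))
  expect_equal(round_any(r_ins), 0.79)
  r_reg <- congestion_rate(30.54, theoretical_capacity(115.02))
  expect_equal(round(r_reg, 1), 1.2)
  expect_equal(congestion_rate(0, theoretical_capacity(50)), 0)
})

test_that("congestion rate is linear in occupancy and scale-consistent", {
  cap <- theoretical_capacity(80)
  expect_equal(congestion_rate(30, cap), 3 * congestion_rate(10, cap))
  # quadrupling personal distance area per person quarters the rate
  expect_equal(congestion_rate(10, theoretical_capacity(80, 2.4)),
               4 * congestion_rate(10, theoretical_capacity(80, 1.2)) / 1,
               tolerance = 1e-12)
  # consistent unit change (m^2 -> cm^2, m -> cm) leaves the rate unchanged
  expect_equal(congestion_rate(10, theoretical_capacity(80e4, 120)),
               congestion_rate(10, theoretical_capacity(80, 1.2)))
})

test_that("congestion profiles track counts per slot", {
  cap <- theoretical_capacity(60)$N_theoretical
  cells <- data.frame(area = "A", day = "d1",
                      slot = sprintf("%02d:00", 8:12),
                      count = rep(cap, 5))
  specs <- data.frame(name = "A", area_m2 = 60, seats = 0,
                      open = "08:00", close = "18:00")
  prof <- congestion_profile(build_count_table(cells), specs)
  expect_equal(prof$rate, rep(1, 5))
  expect_equal(prof$rate_smooth, rep(1, 5))

  varied <- cells; varied$count <- c(0, 10, 20, 10, 0)
  p1 <- congestion_profile(build_count_table(varied), specs,
                           smooth_window = 1L)
  expect_equal(p1$rate_smooth, p1$rate)  # window 1 is the identity
  p3 <- congestion_profile(build_count_table(varied), specs,
                           smooth_window = 3L)
  expect_equal(p3$rate_smooth[3], mean(p3$rate[2:4]))

  expect_error(congestion_profile(build_count_table(cells),
                                  specs[0, , drop = FALSE]),
               "no area spec for: A")
})

test_that("profile cross-sections order by process and by day", {
  cells <- expand.grid(area = c("Registered", "Pharmacy"),
                       day = c("d1", "d2"), slot = c("09:00", "10:00"),
                       stringsAsFactors = FALSE)
  cells$count <- seq_len(nrow(cells))
  prof <- congestion_profile(build_count_table(cells), ed_area_specs())
  across <- rate_across_areas(prof, "d1", "09:00")
  expect_equal(across$area, c("Registered", "Pharmacy"))
  by_day <- rate_across_days(prof, "Pharmacy", "09:00")
  expect_equal(by_day$day, c("d1", "d2"))
})

test_that("the weekly congestion report reproduces the consistent planning rows", {
  ct <- build_count_table(weekly_cells_long())
  rep <- congestion_report(ct, ed_area_specs())
  reg <- rep[rep$area == "Registered", ]
  # weekly person-time 4490 over 21 slots x 7 days
  expect_equal(reg$mean_N_actual, 4490 / 147, tolerance = 1e-12)
  expect_equal(round_any(reg$mean_N_actual), 30.54)
  expect_equal(round(reg$mean_rate, 1), 1.2)
  ins <- rep[rep$area == "Inspection", ]
  expect_equal(round_any(congestion_rate(7.84,
    theoretical_capacity(44.73))), 0.79)
  expect_equal(ins$mean_N_actual, 1159 / 147, tolerance = 1e-12)

  # single-area sanity: counts equal to capacity give rate 1
  one <- build_count_table(data.frame(area = "A", day = "d1",
                                      slot = c("08:00", "08:30"),
                                      count = rep(10, 2)))
  spec1 <- data.frame(name = "A", area_m2 = pi * 1.44 * 10, seats = 0,
                      open = "08:00", close = "18:00")
  r1 <- congestion_report(one, spec1)
  expect_equal(r1$mean_rate, 1, tolerance = 1e-12)
})
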
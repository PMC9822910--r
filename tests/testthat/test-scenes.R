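test_that("generated scenes honour count, bounds and determinism", {
  empty <- generate_scene(0, 64, 64, seed = 2)
  expect_equal(empty$count, 0)
  expect_equal(nrow(empty$heads), 0)
  expect_true(all(empty$image >= 0 & empty$image <= 1))

  sc <- generate_scene(25, 96, 128, seed = 1)
  expect_equal(sc$count, 25)
  expect_equal(nrow(sc$heads), sc$count)
  expect_true(all(sc$heads$x >= 0 & sc$heads$x <= 127))
  expect_true(all(sc$heads$y >= 0 & sc$heads$y <= 95))

  a <- generate_scene(40, 64, 64, seed = 7)
  b <- generate_scene(40, 64, 64, seed = 7)
  expect_identical(a, b)
  c <- generate_scene(40, 64, 64, seed = 8)
  expect_false(identical(a$image, c$image))

  expect_error(generate_scene(5, 32, 64), class = "edcrowd_invalid_argument")
  expect_error(generate_scene(-1, 64, 64), class = "edcrowd_invalid_argument")
})

test_that("scene generation does not disturb the caller's RNG", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_scene(10, 64, 64, seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("daily profiles follow the sampling-grid arithmetic", {
  h <- survey_hours()
  p24 <- generate_daily_profile("Pediatrics", h$h24, base = 5)
  expect_equal(nrow(p24), 48)
  p10 <- generate_daily_profile("Registered", h$h10, base = 5)
  expect_equal(nrow(p10), 21)
  expect_equal(p10$expected, rep(5, 21))

  peaked <- generate_daily_profile("Pediatrics", h$h24, base = 2,
    peaks = list(list(time = "09:30", amplitude = 35, width_min = 60)))
  expect_equal(peaked$slot[which.max(peaked$expected)], "09:30")
  expect_true(all(peaked$expected >= 0))

  expect_error(
    generate_daily_profile("X", h$h10, base = 1,
      peaks = list(list(time = "19:00", amplitude = 5, width_min = 30))),
    class = "edcrowd_invalid_argument")
})

test_that("frame bundles are stationary crowds with at most one person of jitter", {
  frames <- generate_frame_bundle(0, seed = 1)
  expect_length(frames, 10)
  expect_true(all(vapply(frames, function(f) f$count, numeric(1)) == 0))

  b1 <- generate_frame_bundle(20, seed = 5)
  b2 <- generate_frame_bundle(20, seed = 5)
  expect_identical(b1, b2)
  counts <- vapply(b1, function(f) f$count, numeric(1))
  expect_lte(diff(range(counts)), 2)  # draw +/- 1 person
})

test_that("slot counts are Poisson around the profile expectation", {
  lambda <- 6
  draws <- vapply(1:1000, function(i) {
    generate_frame_bundle(lambda, seed = i, n_frames = 1)[[1]]$count
  }, numeric(1))
  se <- sqrt(lambda / length(draws))
  expect_lt(abs(mean(draws) - lambda), 3 * se)
})

test_that("scenes round-trip through PNG + sidecar annotations", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(12, 64, 64, seed = 4)
  write_scene(sc, file.path(dir, "s.png"))
  back <- read_scene(file.path(dir, "s.png"))
  expect_equal(back$count, 12)
  expect_equal(back$heads, sc$heads)
  expect_equal(back$image, sc$image, tolerance = 1 / 255)

  write_scene(sc, file.path(dir, "s2.png"), file.path(dir, "s2.json"))
  back2 <- read_scene(file.path(dir, "s2.png"), file.path(dir, "s2.json"))
  expect_equal(back2$heads$x, sc$heads$x)
})
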
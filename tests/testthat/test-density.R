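test_that("annotation maps place unit mass at annotated pixels", {
  expect_equal(annotation_map(blank_scene(10, 12)), matrix(0L, 10, 12))

  one <- blank_scene(10, 12, data.frame(x = 3, y = 4))
  m <- annotation_map(one)
  expect_equal(m[5, 4], 1)   # row y+1, col x+1
  expect_equal(sum(m), 1)

  twice <- blank_scene(10, 12, data.frame(x = c(3, 3), y = c(4, 4)))
  m2 <- annotation_map(twice)
  expect_equal(m2[5, 4], 2)  # coincident heads accumulate
  expect_equal(sum(m2), 2)

  expect_error(annotated_scene(matrix(0, 10, 12), data.frame(x = 12, y = 0)),
               "out of bounds")
})

test_that("density maps conserve mass exactly, including at borders", {
  expect_equal(sum(density_from_annotations(blank_scene(32, 32))), 0)

  centre <- blank_scene(33, 33, data.frame(x = 16, y = 16))
  expect_equal(sum(density_from_annotations(centre)), 1, tolerance = 1e-9)

  corner <- blank_scene(33, 33, data.frame(x = 0, y = 0))
  dm <- density_from_annotations(corner)
  expect_equal(sum(dm), 1, tolerance = 1e-9)
  expect_true(all(unclass(dm) >= 0))

  # corner kernel equals brute-force clip-and-renormalise
  k <- edcrowd:::gaussian_kernel(15, 4)
  clipped <- k[8:15, 8:15]
  expect_equal(unclass(dm)[1:8, 1:8], clipped / sum(clipped),
               tolerance = 1e-12)

  # random annotation sets, corners and edges included
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    heads <- data.frame(x = c(0, 39, 0, sample(0:39, n - 3, TRUE)),
                        y = c(0, 0, 27, sample(0:27, n - 3, TRUE)))
    dm <- density_from_annotations(blank_scene(28, 40, heads))
    expect_lt(abs(sum(dm) - n), 1e-6 * n)
  }
})

test_that("interior heads reproduce plain Gaussian filtering of the annotation map", {
  set.seed(42)
  heads <- data.frame(x = sample(7:42, 20, TRUE), y = sample(7:32, 20, TRUE))
  sc <- blank_scene(40, 50, heads)
  expect_equal(unclass(density_from_annotations(sc)), brute_force_density(sc),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("density maps are translation-equivariant away from borders", {
  base <- data.frame(x = c(10, 14, 20), y = c(12, 18, 11))
  d1 <- unclass(density_from_annotations(blank_scene(40, 40, base)))
  d2 <- unclass(density_from_annotations(
    blank_scene(40, 40, transform(base, x = x + 5, y = y + 3))))
  expect_equal(d2[(1 + 3):40, (1 + 5):40], d1[1:37, 1:35], tolerance = 1e-12)
})

test_that("counts are the total mass and are linear in the map", {
  expect_equal(count_from_density(matrix(0, 8, 8)), 0)
  sc <- generate_scene(37, 64, 64, seed = 11)
  dm <- density_from_annotations(sc)
  expect_equal(count_from_density(dm), 37, tolerance = 1e-6)
  expect_equal(count_from_density(unclass(dm) + unclass(dm)), 74,
               tolerance = 1e-6)
})

test_that("density maps round-trip through CSV and TIFF", {
  dir <- withr::local_tempdir()
  dm <- density_from_annotations(generate_scene(9, 64, 64, seed = 2))
  write_density_map(dm, file.path(dir, "d.csv"))
  expect_equal(unclass(read_density_map(file.path(dir, "d.csv"))),
               unclass(dm), tolerance = 1e-12, ignore_attr = TRUE)
  write_density_map(dm, file.path(dir, "d.tiff"))
  expect_equal(unclass(read_density_map(file.path(dir, "d.tiff"))),
               unclass(dm), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("density configuration is validated", {
  expect_error(density_config(kernel_size = 14),
               class = "edcrowd_invalid_argument")
  expect_error(density_config(sigma = 0), class = "edcrowd_invalid_argument")
})
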
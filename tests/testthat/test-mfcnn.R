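small_net <- function(seed = 1) network_config(base_width = 8L, seed = seed)

test_that("network configuration invariants are enforced", {
  expect_error(network_config(blocks_per_stage = c(2, 1, 3, 4)),
               class = "edcrowd_invalid_argument")
  expect_error(network_config(blocks_per_stage = c(1, 2, 3)),
               class = "edcrowd_invalid_argument")
  expect_error(network_config(strip_count = 0),
               class = "edcrowd_invalid_argument")
  expect_error(network_config(base_width = 4),
               class = "edcrowd_invalid_argument")
})

test_that("weight initialisation is a pure function of the seed", {
  a <- build_model(network_config(seed = 42))
  b <- build_model(network_config(seed = 42))
  expect_identical(a$params, b$params)
  c <- build_model(network_config(seed = 43))
  expect_false(identical(a$params, c$params))
})

test_that("the network is fully convolutional: output size equals input size", {
  m <- build_model(small_net())
  for (sz in list(c(64, 64), c(65, 67), c(96, 160), c(128, 128),
                  c(100, 172))) {
    img <- matrix(0.5, sz[1], sz[2])
    p <- forward(m, img)
    expect_equal(dim(p$map), sz)
    expect_true(all(p$map >= 0))          # rectified output
    expect_equal(p$count, sum(p$map), tolerance = 1e-5 * max(1, p$count))
  }
  expect_error(forward(m, matrix(0, 32, 64)),
               class = "edcrowd_invalid_argument")
})

test_that("strip split and splice round-trip any feature map", {
  set.seed(3)
  for (k in c(1, 2, 3, 4, 5)) {
    x <- array(rnorm(13 * 17 * 2), dim = c(13, 17, 2))
    for (margin in 1:2) {
      spliced <- strip_splice(strip_split(x, k, margin), margin)
      expect_equal(spliced[1:13, 1:17, , drop = FALSE], x)
    }
  }
})

test_that("fine-grained regression preserves shape and degenerates cleanly", {
  set.seed(4)
  x <- array(rnorm(12 * 15 * 3), dim = c(12, 15, 3))
  out <- fine_grained_regress(x, 4)
  expect_equal(dim(out), dim(x))
  # identity blocks: each dimension reconstructs x, fusion adds them
  expect_equal(fine_grained_regress(x, 3), 2 * x)
  # strip_count = 1 is one block pass per dimension, then fusion
  dbl <- function(s) 2 * s
  expect_equal(fine_grained_regress(x, 1, block = dbl), 4 * x)
  expect_error(fine_grained_regress(x, 20),
               class = "edcrowd_invalid_argument")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- small_net(seed = 5)
  m <- build_model(cfg)
  set.seed(1)
  img <- matrix(runif(64 * 64), 64, 64)
  gt <- array(runif(64 * 64, 0, 0.01), dim = c(64, 64, 1))
  fg <- edcrowd:::forward_graph(m$params, cfg, img)
  diffmap <- fg$out$value - gt
  loss0 <- 0.5 * sum(diffmap^2)
  edcrowd:::nn_backward(fg$tape, fg$out, diffmap)
  grads <- fg$tape$pgrad
  eps <- 1e-5
  for (id in c("stem.c1.w", "s3b1.c2.w", "fgr.col.c1.w", "head.dil.w")) {
    k <- which.max(abs(grads[[id]]))
    p <- m$params
    p[[id]][k] <- p[[id]][k] + eps
    f1 <- edcrowd:::forward_graph(p, cfg, img)
    l1 <- 0.5 * sum((f1$out$value - gt)^2)
    expect_equal((l1 - loss0) / eps, grads[[id]][k],
                 tolerance = 1e-3)
  }
})

test_that("training records history, selects the best epoch and is reproducible", {
  scenes <- lapply(1:8, function(i) generate_scene(i %% 3, seed = 50 + i))
  cases <- lapply(scenes, function(s)
    list(image = s$image, density = unclass(density_from_annotations(s))))
  m <- build_model(small_net(seed = 2))
  tc <- training_config(epochs = 1, learning_rate = 1e-4, val_fraction = 0,
                        seed = 3)
  tr <- train_model(m, cases, tc)
  expect_equal(nrow(tr$history), 1)
  expect_equal(tr$best_epoch, 1)

  tc2 <- training_config(epochs = 3, learning_rate = 1e-4, val_fraction = 0,
                         seed = 3)
  a <- train_model(m, cases, tc2)
  b <- train_model(m, cases, tc2)
  expect_identical(a$history, b$history)
  expect_identical(a$model$params, b$model$params)
  expect_equal(a$best_epoch, which.min(a$history$mce))

  bad <- cases
  bad[[1]]$density <- matrix(0, 32, 32)
  expect_error(train_model(m, bad, tc), class = "edcrowd_invalid_argument")
  expect_error(train_model(m, list(), tc), class = "edcrowd_invalid_argument")
})

test_that("the fit interface exposes the standard model methods", {
  scenes <- lapply(1:8, function(i) generate_scene(i %% 4, seed = 70 + i))
  fit <- mfcnn(scenes, network = small_net(seed = 9),
               training = training_config(epochs = 2, learning_rate = 1e-4,
                                          val_fraction = 0.25, seed = 1))
  expect_s3_class(fit, "mfcnn")
  expect_equal(nrow(fit$history), 2)
  p <- predict(fit, scenes[[1]])
  expect_s3_class(p, "density_prediction")
  expect_equal(dim(p$map), dim(scenes[[1]]$image))
  expect_length(residuals(fit), 8)
  expect_equal(residuals(fit), fit$gt - fitted(fit))
  expect_output(print(fit), "Multi-fusion")
  expect_output(summary(fit), "parameters")

  dir <- withr::local_tempdir()
  save_checkpoint(fit, file.path(dir, "ck.rds"))
  expect_true(file.exists(file.path(dir, "ck.json")))
  back <- load_checkpoint(file.path(dir, "ck.rds"))
  expect_equal(predict(back, scenes[[1]])$count, p$count)
  write_training_log(fit, file.path(dir, "log.csv"))
  expect_equal(nrow(read.csv(file.path(dir, "log.csv"))), 2)
})
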
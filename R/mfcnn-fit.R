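#' Fit the multi-fusion counting network to annotated scenes
#'
#' The one-stop model interface: converts the scenes' head annotations
#' into Gaussian density-map ground truth, builds the encoder--decoder
#' network and trains it, returning a fitted model with the usual methods
#' ([predict()], [print()], [summary()], [plot()], [residuals()],
#' [fitted()]).
#'
#' @param scenes list of [annotated_scene] objects.
#' @param network a [network_config()].
#' @param training a [training_config()].
#' @param density a [density_config()].
#' @return An object of class `mfcnn`: the trained `model`, the training
#'   `history` (epoch, loss, MCE, RMSE), `best_epoch`, per-scene training
#'   `gt`/`pred` counts, and the call.
#' @examples
#' \donttest{
#' scenes <- lapply(1:10, function(i) generate_scene(i %% 4, seed = i))
#' fit <- mfcnn(scenes, training = training_config(epochs = 2,
#'                                                 val_fraction = 0))
#' predict(fit, scenes[[1]])
#' }
#' @export
mfcnn <- function(scenes, network = network_config(),
                  training = training_config(),
                  density = density_config()) {
  if (!length(scenes) || !all(vapply(scenes, inherits, TRUE, "annotated_scene"))) {
    stop_invalid("`scenes` must be a non-empty list of annotated scenes")
  }
  cases <- lapply(scenes, function(s) {
    list(image = s$image,
         density = unclass(density_from_annotations(s, density)))
  })
  model <- build_model(network)
  tr <- train_model(model, cases, training)
  ev <- evaluate_model(tr$model, scenes)
  structure(list(model = tr$model, history = tr$history,
                 best_epoch = tr$best_epoch,
                 gt = ev$gt, pred = ev$pred,
                 network = network, training = training, density = density,
                 call = match.call()),
            class = "mfcnn")
}

#' @export
predict.mfcnn <- function(object, newdata, ...) {
  forward(object$model, newdata)
}

#' @export
print.mfcnn <- function(x, ...) {
  cat("Multi-fusion counting network\n")
  cat(sprintf("  base width %d, blocks %s, strip count %d\n",
              x$network$base_width,
              paste(x$network$blocks_per_stage, collapse = "-"),
              x$network$strip_count))
  cat(sprintf("  trained %d epoch(s), best epoch %d (MCE %.4f)\n",
              nrow(x$history), x$best_epoch,
              x$history$mce[x$best_epoch]))
  invisible(x)
}

#' @export
summary.mfcnn <- function(object, ...) {
  n_par <- sum(vapply(object$model$params, length, numeric(1)))
  cat("Multi-fusion counting network\n")
  cat(sprintf("  parameters: %s\n", format(n_par, big.mark = ",")))
  cat(sprintf("  training scenes: %d; epochs: %d; best epoch: %d\n",
              length(object$gt), nrow(object$history), object$best_epoch))
  cat(sprintf("  training-set MCE %.4f, RMSE %.4f\n",
              mce(object$gt, object$pred), rmse(object$gt, object$pred)))
  invisible(object)
}

#' @export
plot.mfcnn <- function(x, ...) {
  h <- x$history
  graphics::par(mfrow = c(1, 2))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "Loss", ...)
  graphics::plot(h$epoch, h$mce, type = "l", xlab = "epoch",
                 ylab = "count error", main = "MCE / RMSE", ...)
  graphics::lines(h$epoch, h$rmse, lty = 2)
  graphics::abline(v = x$best_epoch, col = "grey")
  invisible(x)
}

#' @export
residuals.mfcnn <- function(object, ...) object$gt - object$pred

#' @export
fitted.mfcnn <- function(object, ...) object$pred

#' Save / load a model checkpoint
#'
#' The weights are stored in R's native serialisation; a JSON sidecar
#' records the network and training configurations so a checkpoint is
#' self-describing.
#'
#' @param object an `mfcnn` fit or `mfcnn_model`.
#' @param path checkpoint path (`.rds`).
#' @param sidecar JSON sidecar path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the saved object.
#' @export
save_checkpoint <- function(object, path,
                            sidecar = sub("\\.rds$", ".json", path)) {
  saveRDS(object, path)
  cfg <- if (inherits(object, "mfcnn")) {
    list(network = unclass(object$network), training = unclass(object$training),
         density = unclass(object$density), best_epoch = object$best_epoch)
  } else {
    list(network = unclass(object$config))
  }
  jsonlite::write_json(cfg, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write a training log as CSV
#'
#' One row per epoch: epoch, training loss, validation MCE and RMSE.
#'
#' @param fit an `mfcnn` fit (or the result of [train_model()]).
#' @param path CSV path.
#' @export
write_training_log <- function(fit, path) {
  write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
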
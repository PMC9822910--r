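check_batch <- function(gt, pred) {
  if (length(gt) == 0L) stop_invalid("empty evaluation batch")
  if (length(gt) != length(pred)) {
    stop_invalid("ground-truth and predicted counts differ in length")
  }
  if (any(gt < 0)) stop_invalid("ground-truth counts must be non-negative")
  invisible(NULL)
}

#' Counting-accuracy metrics
#'
#' `mce()` is the mean counting error, the mean absolute difference between
#' ground-truth and predicted counts over a batch of images: the average
#' number of mis-identifications per image. `rmse()` is the root mean
#' squared count error, which weights large per-image deviations more
#' heavily; `rmse >= mce` always, with equality when every absolute error
#' is the same. Predicted counts are used un-rounded.
#'
#' @param gt numeric vector of ground-truth counts (one per image).
#' @param pred numeric vector of predicted counts, same length.
#' @return A single non-negative number.
#' @examples
#' mce(c(10, 20), c(12, 19))   # 1.5
#' rmse(c(10, 20), c(12, 19))  # sqrt(2.5)
#' @export
mce <- function(gt, pred) {
  check_batch(gt, pred)
  mean(abs(gt - pred))
}

#' @rdname mce
#' @export
rmse <- function(gt, pred) {
  check_batch(gt, pred)
  sqrt(mean((gt - pred)^2))
}

#' Evaluate a counting model on annotated scenes
#'
#' Runs the model forward on every scene, pairs each predicted count with
#' the scene's annotated head count, and returns both accuracy metrics.
#'
#' @param model a fitted counting model (see [mfcnn()]); any object with a
#'   [predict()] method returning a `$count`, or a function
#'   `scene -> count`, is accepted.
#' @param scenes list of [annotated_scene] objects.
#' @return Named list: `mce`, `rmse`, and the per-scene `gt`/`pred`
#'   vectors.
#' @export
evaluate_model <- function(model, scenes) {
  if (length(scenes) == 0L) stop_invalid("no scenes to evaluate")
  predict_count <- function(scene) {
    if (is.function(model)) return(model(scene))
    if (inherits(model, c("mfcnn", "mfcnn_model"))) {
      return(forward(model, scene)$count)
    }
    predict(model, scene$image)$count
  }
  gt <- vapply(scenes, function(s) s$count, numeric(1))
  pred <- vapply(scenes, predict_count, numeric(1))
  list(mce = mce(gt, pred), rmse = rmse(gt, pred), gt = gt, pred = pred)
}
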
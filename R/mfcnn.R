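#' Network configuration for the multi-fusion counting network
#'
#' The network is a fully-convolutional encoder--decoder. The encoder's
#' input block condenses each spatial dimension of the image to a quarter
#' (two stride-2 convolutions; set `input_reduction = 2` for the
#' quarter-area reading), then four downsampling stages of residual
#' bottleneck blocks each halve the spatial size, with more blocks in the
#' deeper stages. The decoder upsamples deep feature maps and fuses them
#' with the same-size shallower encoder maps; a fine-grained regressor then
#' enhances the fused map with width-wise and height-wise strip processing,
#' and a head of global-average-pool channel gating plus 1x1 convolution
#' (no fully connected layer, so any input size is accepted) emits a
#' density map that is enlarged back to the input size and refined by a
#' dilated convolution.
#'
#' @param base_width channels of the shallowest stage (stage widths double
#'   per stage, capped at `8 * base_width`).
#' @param blocks_per_stage integer vector of length 4, non-decreasing:
#'   bottleneck blocks per encoder stage, shallow to deep.
#' @param strip_count strips per spatial dimension in the fine-grained
#'   regressor.
#' @param upsample_mode interpolation used by the decoder (`"nearest"`).
#' @param input_reduction 4 (quarter per dimension, default) or 2
#'   (quarter area).
#' @param output_scale ground-truth magnification: the network regresses
#'   `output_scale` times the density map and predictions are divided back
#'   down, a standard device in density regression that keeps the target
#'   dynamic range well above the rectifier's dead zone. Counts are
#'   unaffected.
#' @param seed seed for weight initialisation.
#' @return A `network_config` object.
#' @export
network_config <- function(base_width = 32L, blocks_per_stage = c(1L, 2L, 3L, 4L),
                           strip_count = 4L, upsample_mode = "nearest",
                           input_reduction = 4L, output_scale = 100,
                           seed = 1L) {
  base_width <- check_count(base_width, "base_width", 8L)
  if (length(blocks_per_stage) != 4L || any(blocks_per_stage < 1L)) {
    stop_invalid("`blocks_per_stage` must be four positive integers")
  }
  if (is.unsorted(blocks_per_stage)) {
    stop_invalid("`blocks_per_stage` must be non-decreasing (deeper stages ",
                 "include more base blocks)")
  }
  strip_count <- check_count(strip_count, "strip_count", 1L)
  upsample_mode <- match.arg(upsample_mode, "nearest")
  if (!input_reduction %in% c(2L, 4L)) {
    stop_invalid("`input_reduction` must be 2 or 4")
  }
  check_number(output_scale, "output_scale", 0, strict = TRUE)
  structure(list(base_width = base_width,
                 blocks_per_stage = as.integer(blocks_per_stage),
                 strip_count = strip_count,
                 upsample_mode = upsample_mode,
                 input_reduction = as.integer(input_reduction),
                 output_scale = output_scale,
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Training configuration
#'
#' Defaults follow the study protocol: batch size 8, Adam at a fixed
#' learning rate of 1e-5, 50 epochs, pixel-wise squared-error loss on
#' density maps, best epoch selected by validation mean counting error.
#'
#' @param batch_size images per optimisation step.
#' @param learning_rate fixed Adam step size (never decayed).
#' @param epochs training epochs.
#' @param val_fraction fraction of scenes held out for per-epoch
#'   validation MCE/RMSE; 0 selects the best epoch on training MCE.
#' @param seed seed for the split and batch shuffling.
#' @return A `training_config` object.
#' @export
training_config <- function(batch_size = 8L, learning_rate = 1e-5,
                            epochs = 50L, val_fraction = 0.2, seed = 1L) {
  structure(list(batch_size = check_count(batch_size, "batch_size", 1L),
                 learning_rate = check_number(learning_rate, "learning_rate",
                                              0, strict = TRUE),
                 epochs = check_count(epochs, "epochs", 1L),
                 val_fraction = check_number(val_fraction, "val_fraction", 0),
                 seed = as.integer(seed)),
            class = "training_config")
}

stage_widths <- function(cfg) {
  pmin(cfg$base_width * 2L^(0:3), cfg$base_width * 8L)
}

he_init <- function(kh, kw, cin, cout) {
  array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        dim = c(kh, kw, cin, cout))
}

bottleneck_param_init <- function(prefix, w_in, w_out, project) {
  mid <- max(4L, w_out %/% 4L)
  p <- list()
  p[[paste0(prefix, ".c1.w")]] <- he_init(1L, 1L, w_in, mid)
  p[[paste0(prefix, ".c1.b")]] <- numeric(mid)
  p[[paste0(prefix, ".c2.w")]] <- he_init(3L, 3L, mid, mid)
  p[[paste0(prefix, ".c2.b")]] <- numeric(mid)
  p[[paste0(prefix, ".c3.w")]] <- he_init(1L, 1L, mid, w_out)
  p[[paste0(prefix, ".c3.b")]] <- numeric(w_out)
  if (project) {
    p[[paste0(prefix, ".sc.w")]] <- he_init(1L, 1L, w_in, w_out)
    p[[paste0(prefix, ".sc.b")]] <- numeric(w_out)
  }
  p
}

init_params <- function(cfg) {
  bw <- cfg$base_width
  ws <- stage_widths(cfg)
  with_seed(cfg$seed, {
    p <- list()
    p[["stem.c1.w"]] <- he_init(3L, 3L, 1L, bw)
    p[["stem.c1.b"]] <- numeric(bw)
    if (cfg$input_reduction == 4L) {
      p[["stem.c2.w"]] <- he_init(3L, 3L, bw, bw)
      p[["stem.c2.b"]] <- numeric(bw)
    }
    w_in <- bw
    for (s in 1:4) {
      for (b in seq_len(cfg$blocks_per_stage[s])) {
        prefix <- sprintf("s%db%d", s, b)
        p <- c(p, bottleneck_param_init(prefix, w_in, ws[s],
                                        project = (b == 1L)))
        w_in <- ws[s]
      }
    }
    p[["dec.top.w"]] <- he_init(1L, 1L, ws[4], bw)
    p[["dec.top.b"]] <- numeric(bw)
    for (s in c(3, 2, 1, 0)) {
      wl <- if (s == 0) bw else ws[s]
      p[[sprintf("dec.lat%d.w", s)]] <- he_init(1L, 1L, wl, bw)
      p[[sprintf("dec.lat%d.b", s)]] <- numeric(bw)
      p[[sprintf("dec.ref%d.w", s)]] <- he_init(3L, 3L, bw, bw)
      p[[sprintf("dec.ref%d.b", s)]] <- numeric(bw)
    }
    p <- c(p, bottleneck_param_init("fgr.row", bw, bw, project = FALSE))
    p <- c(p, bottleneck_param_init("fgr.col", bw, bw, project = FALSE))
    p[["head.gate.w"]] <- he_init(1L, 1L, bw, bw)
    p[["head.gate.b"]] <- numeric(bw)
    p[["head.out.w"]] <- he_init(1L, 1L, bw, 1L)
    p[["head.out.b"]] <- 0
    p[["head.dil.w"]] <- he_init(3L, 3L, 1L, 1L)
    p[["head.dil.b"]] <- 0.01
    p
  })
}

#' Build an untrained counting model
#'
#' Initialises all weights from `config$seed` (two builds with the same
#' seed are identical) and returns an `mfcnn_model` ready for
#' [train_model()] or [forward()].
#'
#' @param config a [network_config()].
#' @return An `mfcnn_model`: the parameter list plus the configuration.
#' @export
build_model <- function(config = network_config()) {
  if (!inherits(config, "network_config")) {
    stop_invalid("`config` must come from network_config()")
  }
  structure(list(params = init_params(config), config = config),
            class = "mfcnn_model")
}

param_cache <- function(tape, params) {
  cache <- new.env(parent = emptyenv())
  get <- function(id) {
    if (is.null(cache[[id]])) {
      if (is.null(params[[id]])) stop("internal: unknown parameter ", id)
      cache[[id]] <- nn_param(tape, params, id)
    }
    cache[[id]]
  }
  attr(get, "has") <- function(id) !is.null(params[[id]])
  get
}

bottleneck_fwd <- function(tape, P, x, prefix, stride = 1L) {
  project <- attr(P, "has")(paste0(prefix, ".sc.w"))
  h <- nn_conv(tape, x, P(paste0(prefix, ".c1.w")), P(paste0(prefix, ".c1.b")),
               stride = stride)
  h <- nn_relu(tape, h)
  h <- nn_conv(tape, h, P(paste0(prefix, ".c2.w")), P(paste0(prefix, ".c2.b")),
               pad = 1L)
  h <- nn_relu(tape, h)
  h <- nn_conv(tape, h, P(paste0(prefix, ".c3.w")), P(paste0(prefix, ".c3.b")))
  sc <- if (project) {
    nn_conv(tape, x, P(paste0(prefix, ".sc.w")), P(paste0(prefix, ".sc.b")),
            stride = stride)
  } else x
  nn_relu(tape, nn_add(tape, h, sc))
}

strip_bounds <- function(n, k) {
  size <- ceiling(n / k)
  starts <- seq(1L, by = size, length.out = k)
  lapply(starts, function(s) s:(s + size - 1L))
}

# Width/height strip enhancement on the tape; shares one bottleneck block
# per dimension across all strips.
fgr_fwd <- function(tape, P, x, strip_count) {
  d <- dim(x$value)
  if (min(d[1], d[2]) < strip_count) {
    stop_invalid("strip_count (", strip_count, ") exceeds the feature map ",
                 "spatial extent (", d[1], "x", d[2], ")")
  }
  enhance <- function(margin, prefix) {
    n <- d[margin]
    size <- ceiling(n / strip_count)
    padded <- size * strip_count
    xp <- if (margin == 1L) nn_pad_hw(tape, x, padded - n, 0L)
          else nn_pad_hw(tape, x, 0L, padded - n)
    idxs <- strip_bounds(padded, strip_count)
    pieces <- lapply(idxs, function(idx) {
      bottleneck_fwd(tape, P, nn_slice(tape, xp, idx, margin), prefix)
    })
    spliced <- nn_concat(tape, pieces, margin)
    nn_crop(tape, spliced, d[1], d[2])
  }
  nn_add(tape, enhance(1L, "fgr.row"), enhance(2L, "fgr.col"))
}

forward_graph <- function(params, config, image) {
  tape <- new_tape()
  P <- param_cache(tape, params)
  x <- nn_input(tape, image)
  d <- dim(x$value)
  if (d[1] < 64L || d[2] < 64L) {
    stop_invalid("input images must be at least 64x64 pixels, got ",
                 d[1], "x", d[2])
  }
  # input block: condense to 1/input_reduction per spatial dimension
  h <- nn_relu(tape, nn_conv(tape, x, P("stem.c1.w"), P("stem.c1.b"),
                             stride = 2L, pad = 1L))
  if (config$input_reduction == 4L) {
    h <- nn_relu(tape, nn_conv(tape, h, P("stem.c2.w"), P("stem.c2.b"),
                               stride = 2L, pad = 1L))
  }
  feats <- list(`0` = h)
  for (s in 1:4) {
    for (b in seq_len(config$blocks_per_stage[s])) {
      h <- bottleneck_fwd(tape, P, h, sprintf("s%db%d", s, b),
                          stride = if (b == 1L) 2L else 1L)
    }
    feats[[as.character(s)]] <- h
  }
  # decoder: upsample deep maps, fuse with the same-size shallower maps
  dtop <- nn_conv(tape, feats[["4"]], P("dec.top.w"), P("dec.top.b"))
  dec <- dtop
  for (s in c(3, 2, 1, 0)) {
    fs <- feats[[as.character(s)]]
    ds <- dim(fs$value)
    up <- nn_resample(tape, dec, ds[1], ds[2])
    lat <- nn_conv(tape, fs, P(sprintf("dec.lat%d.w", s)),
                   P(sprintf("dec.lat%d.b", s)))
    dec <- nn_add(tape, up, lat)
    dec <- nn_relu(tape, nn_conv(tape, dec, P(sprintf("dec.ref%d.w", s)),
                                 P(sprintf("dec.ref%d.b", s)), pad = 1L))
  }
  # fine-grained regressor on the fused quarter-resolution map
  fgr <- fgr_fwd(tape, P, dec, config$strip_count)
  # regression head: GAP + 1x1 conv channel gate (no fully connected layer)
  g <- nn_gap(tape, fgr)
  gate <- nn_sigmoid(tape, nn_conv(tape, g, P("head.gate.w"),
                                   P("head.gate.b")))
  gated <- nn_scale_channels(tape, fgr, gate)
  coarse <- nn_conv(tape, gated, P("head.out.w"), P("head.out.b"))
  # enlarge to the input size, refine with a dilated convolution, rectify
  up <- nn_resample(tape, coarse, d[1], d[2])
  refined <- nn_conv(tape, up, P("head.dil.w"), P("head.dil.b"),
                     pad = 2L, dil = 2L)
  out <- nn_relu(tape, refined)
  list(tape = tape, out = out)
}

#' Run the counting network forward on one image
#'
#' @param model an `mfcnn_model` (see [build_model()]) or fitted [mfcnn]
#'   object.
#' @param image numeric matrix (grayscale, any size of at least 64x64) or
#'   an [annotated_scene].
#' @return A `density_prediction`: `map` (matrix, same size as the input)
#'   and `count` (its total mass).
#' @export
forward <- function(model, image) {
  if (inherits(model, "mfcnn")) model <- model$model
  if (!inherits(model, "mfcnn_model")) {
    stop_invalid("`model` must be an mfcnn_model or fitted mfcnn object")
  }
  if (inherits(image, "annotated_scene")) image <- image$image
  if (!is.matrix(image)) stop_invalid("`image` must be a numeric matrix")
  fg <- forward_graph(model$params, model$config, image)
  map <- fg$out$value[, , 1L] / model$config$output_scale
  structure(list(map = map, count = sum(map)), class = "density_prediction")
}

#' @export
print.density_prediction <- function(x, ...) {
  cat(sprintf("Density prediction: %dx%d map, count %.3f\n",
              nrow(x$map), ncol(x$map), x$count))
  invisible(x)
}

#' Fine-grained strip regression on a feature map
#'
#' Cuts a feature map into `strip_count` horizontal strips and,
#' independently, `strip_count` vertical strips (zero-padding when the
#' extent is not divisible, cropped after splicing), passes each strip
#' through a base block shared within its dimension, splices the strips
#' back in order, and fuses the width-enhanced and height-enhanced maps by
#' addition. `strip_split()`/`strip_splice()` expose the exact
#' cut-and-reassemble used, so `strip_splice(strip_split(x, k, d), d)`
#' restores `x` for any `k`.
#'
#' @param feature numeric (H, W, C) array (a matrix is promoted to one
#'   channel).
#' @param strip_count strips per dimension; must not exceed the spatial
#'   extent.
#' @param block function applied to each strip (default identity); shared
#'   across strips within a dimension.
#' @return Array of the same shape as `feature`.
#' @export
fine_grained_regress <- function(feature, strip_count, block = identity) {
  feature <- as_hwc(feature)
  d <- dim(feature)
  if (min(d[1], d[2]) < strip_count) {
    stop_invalid("strip_count (", strip_count, ") exceeds the feature map ",
                 "spatial extent (", d[1], "x", d[2], ")")
  }
  enhance <- function(margin) {
    strips <- strip_split(feature, strip_count, margin)
    out <- strip_splice(lapply(strips, block), margin)
    if (margin == 1L) out[seq_len(d[1]), , , drop = FALSE]
    else out[, seq_len(d[2]), , drop = FALSE]
  }
  enhance(1L) + enhance(2L)
}

#' @rdname fine_grained_regress
#' @param x numeric (H, W, C) array.
#' @param margin 1 to cut rows (horizontal strips), 2 to cut columns.
#' @export
strip_split <- function(x, strip_count, margin = 1L) {
  x <- as_hwc(x)
  d <- dim(x)
  n <- d[margin]
  size <- ceiling(n / strip_count)
  padded <- size * strip_count
  if (padded > n) {
    full <- if (margin == 1L) c(padded, d[2], d[3]) else c(d[1], padded, d[3])
    xp <- array(0, dim = full)
    xp[seq_len(d[1]), seq_len(d[2]), ] <- x
    x <- xp
  }
  lapply(strip_bounds(padded, strip_count), function(idx) {
    if (margin == 1L) x[idx, , , drop = FALSE] else x[, idx, , drop = FALSE]
  })
}

#' @rdname fine_grained_regress
#' @param strips list of arrays from `strip_split()`.
#' @export
strip_splice <- function(strips, margin = 1L) {
  if (margin == 1L) do.call(abind1, strips) else do.call(abind2, strips)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (id in names(params)) {
    g <- grads[[id]]
    if (is.null(g)) next
    if (is.null(state$m[[id]])) {
      state$m[[id]] <- g * 0
      state$v[[id]] <- g * 0
    }
    state$m[[id]] <- beta1 * state$m[[id]] + (1 - beta1) * g
    state$v[[id]] <- beta2 * state$v[[id]] + (1 - beta2) * g^2
    mhat <- state$m[[id]] / (1 - beta1^state$t)
    vhat <- state$v[[id]] / (1 - beta2^state$t)
    params[[id]] <- params[[id]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

batch_metrics <- function(params, config, pairs) {
  gt <- vapply(pairs, function(p) sum(p$density), numeric(1))
  pred <- vapply(pairs, function(p) {
    fg <- forward_graph(params, config, p$image)
    sum(fg$out$value) / config$output_scale
  }, numeric(1))
  c(mce = mce(gt, pred), rmse = rmse(gt, pred))
}

#' Train the counting network
#'
#' Minimises the pixel-wise squared error between predicted and
#' ground-truth density maps (both magnified by the network's
#' `output_scale`; the recorded loss is in those units, while MCE/RMSE are
#' in people) with Adam at a fixed learning rate, records
#' per-epoch training loss and validation MCE/RMSE, and returns the
#' weights of the epoch with the lowest validation MCE. Fully seeded: the
#' same model, data and configuration reproduce the same loss curve
#' bit-for-bit.
#'
#' @param model an `mfcnn_model` from [build_model()].
#' @param scenes list of training cases, each a list with `image` (matrix)
#'   and `density` (matrix of the same size; see
#'   [density_from_annotations()]).
#' @param tconfig a [training_config()].
#' @return A list: `model` (with the best epoch's weights), `history`
#'   (data frame: epoch, loss, mce, rmse), `best_epoch`.
#' @export
train_model <- function(model, scenes, tconfig = training_config()) {
  if (!inherits(model, "mfcnn_model")) {
    stop_invalid("`model` must come from build_model()")
  }
  if (length(scenes) == 0L) stop_invalid("empty training set")
  for (i in seq_along(scenes)) {
    s <- scenes[[i]]
    if (!all(dim(s$image) == dim(as.matrix(s$density)))) {
      stop_invalid("scene ", i, ": density map size does not match image")
    }
  }
  params <- model$params
  cfg <- model$config
  n <- length(scenes)
  with_seed(tconfig$seed, {
    n_val <- floor(n * tconfig$val_fraction)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(train_idx) == 0L) stop_invalid("validation split leaves no training scenes")
    eval_set <- if (n_val > 0) scenes[val_idx] else scenes[train_idx]
    state <- list(m = list(), v = list(), t = 0L)
    history <- vector("list", tconfig$epochs)
    best <- list(mce = Inf, params = params, epoch = NA_integer_)
    for (epoch in seq_len(tconfig$epochs)) {
      order_idx <- sample(train_idx)
      epoch_loss <- 0
      for (start in seq(1L, length(order_idx), by = tconfig$batch_size)) {
        batch <- order_idx[start:min(start + tconfig$batch_size - 1L,
                                     length(order_idx))]
        grads <- list()
        for (i in batch) {
          sc <- scenes[[i]]
          fg <- forward_graph(params, cfg, sc$image)
          gtmap <- array(as.matrix(sc$density) * cfg$output_scale,
                         dim = dim(fg$out$value))
          diffmap <- fg$out$value - gtmap
          epoch_loss <- epoch_loss + 0.5 * sum(diffmap^2)
          nn_backward(fg$tape, fg$out, diffmap / length(batch))
          for (id in names(fg$tape$pgrad)) {
            g <- fg$tape$pgrad[[id]]
            grads[[id]] <- if (is.null(grads[[id]])) g else grads[[id]] + g
          }
        }
        upd <- adam_step(params, grads, state, tconfig$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      met <- batch_metrics(params, cfg, eval_set)
      history[[epoch]] <- data.frame(epoch = epoch,
                                     loss = epoch_loss / length(train_idx),
                                     mce = met[["mce"]],
                                     rmse = met[["rmse"]])
      if (met[["mce"]] < best$mce) {
        best <- list(mce = met[["mce"]], params = params, epoch = epoch)
      }
    }
  })
  model$params <- best$params
  list(model = model,
       history = do.call(rbind, history),
       best_epoch = best$epoch)
}
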
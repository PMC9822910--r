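# Minimal reverse-mode autodiff tape over (H, W, C) arrays.
#
# Heavy kernels (convolution, resampling) live in src/conv.cpp; everything
# element-wise stays vectorised R. Nodes are environments appended to the
# tape in creation order; nn_backward() walks them in reverse, accumulating
# gradients into node$grad and, for parameter leaves, into tape$pgrad[[id]].

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- list()
  t$pgrad <- list()
  t
}

as_hwc <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop_invalid("tensors must be (H, W, C) arrays")
  x
}

new_node <- function(tape, value, parents = list(), backfn = NULL,
                     pid = NULL) {
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backfn <- backfn
  n$pid <- pid
  tape$nodes[[length(tape$nodes) + 1L]] <- n
  n
}

nn_input <- function(tape, x) new_node(tape, as_hwc(x))

nn_param <- function(tape, params, id) {
  new_node(tape, params[[id]], pid = id)
}

accumulate <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

nn_conv <- function(tape, x, w, b, stride = 1L, pad = 0L, dil = 1L) {
  out <- cpp_conv2d(x$value, w$value, as.numeric(b$value), stride, pad, dil)
  new_node(tape, out, parents = list(x, w, b), backfn = function(node) {
    gr <- cpp_conv2d_backward(x$value, w$value, node$grad, stride, pad, dil)
    accumulate(x, gr$gx)
    accumulate(w, gr$gw)
    accumulate(b, gr$gb)
  })
}

nn_relu <- function(tape, x) {
  mask <- x$value > 0
  new_node(tape, x$value * mask, parents = list(x), backfn = function(node) {
    accumulate(x, node$grad * mask)
  })
}

nn_sigmoid <- function(tape, x) {
  s <- 1 / (1 + exp(-x$value))
  new_node(tape, s, parents = list(x), backfn = function(node) {
    accumulate(x, node$grad * s * (1 - s))
  })
}

nn_add <- function(tape, x, y) {
  new_node(tape, x$value + y$value, parents = list(x, y),
           backfn = function(node) {
    accumulate(x, node$grad)
    accumulate(y, node$grad)
  })
}

nn_resample <- function(tape, x, out_h, out_w) {
  d <- dim(x$value)
  if (d[1] == out_h && d[2] == out_w) return(x)
  out <- cpp_resample_nearest(x$value, out_h, out_w)
  new_node(tape, out, parents = list(x), backfn = function(node) {
    accumulate(x, cpp_resample_nearest_backward(node$grad, d[1], d[2]))
  })
}

# Global average pool: (H, W, C) -> (1, 1, C).
nn_gap <- function(tape, x) {
  d <- dim(x$value)
  v <- array(apply(x$value, 3L, mean), dim = c(1L, 1L, d[3]))
  new_node(tape, v, parents = list(x), backfn = function(node) {
    g <- array(0, dim = d)
    per <- node$grad[1, 1, ] / (d[1] * d[2])
    for (c in seq_len(d[3])) g[, , c] <- per[c]
    accumulate(x, g)
  })
}

# Channel-wise gating: x (H, W, C) scaled by g (1, 1, C).
nn_scale_channels <- function(tape, x, g) {
  d <- dim(x$value)
  gv <- g$value[1, 1, ]
  out <- x$value * rep(gv, each = d[1] * d[2])
  new_node(tape, out, parents = list(x, g), backfn = function(node) {
    accumulate(x, node$grad * rep(gv, each = d[1] * d[2]))
    gg <- vapply(seq_len(d[3]),
                 function(c) sum(node$grad[, , c] * x$value[, , c]),
                 numeric(1))
    accumulate(g, array(gg, dim = c(1L, 1L, d[3])))
  })
}

# Zero-pad at the bottom/right so strips divide evenly; crop undoes it.
nn_pad_hw <- function(tape, x, ph, pw) {
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x$value)
  out <- array(0, dim = c(d[1] + ph, d[2] + pw, d[3]))
  out[seq_len(d[1]), seq_len(d[2]), ] <- x$value
  new_node(tape, out, parents = list(x), backfn = function(node) {
    accumulate(x, node$grad[seq_len(d[1]), seq_len(d[2]), , drop = FALSE])
  })
}

nn_crop <- function(tape, x, h, w) {
  d <- dim(x$value)
  if (d[1] == h && d[2] == w) return(x)
  out <- x$value[seq_len(h), seq_len(w), , drop = FALSE]
  new_node(tape, out, parents = list(x), backfn = function(node) {
    g <- array(0, dim = d)
    g[seq_len(h), seq_len(w), ] <- node$grad
    accumulate(x, g)
  })
}

# Slice a contiguous band of rows (margin = 1) or columns (margin = 2).
nn_slice <- function(tape, x, idx, margin) {
  d <- dim(x$value)
  out <- if (margin == 1L) x$value[idx, , , drop = FALSE]
         else x$value[, idx, , drop = FALSE]
  new_node(tape, out, parents = list(x), backfn = function(node) {
    g <- array(0, dim = d)
    if (margin == 1L) g[idx, , ] <- node$grad else g[, idx, ] <- node$grad
    accumulate(x, g)
  })
}

nn_concat <- function(tape, pieces, margin) {
  vals <- lapply(pieces, function(p) p$value)
  sizes <- vapply(vals, function(v) dim(v)[margin], integer(1))
  out <- if (margin == 1L) do.call(abind1, vals) else do.call(abind2, vals)
  new_node(tape, out, parents = pieces, backfn = function(node) {
    off <- 0L
    for (k in seq_along(pieces)) {
      idx <- off + seq_len(sizes[k])
      g <- if (margin == 1L) node$grad[idx, , , drop = FALSE]
           else node$grad[, idx, , drop = FALSE]
      accumulate(pieces[[k]], g)
      off <- off + sizes[k]
    }
  })
}

abind1 <- function(...) {
  pieces <- list(...)
  d <- dim(pieces[[1L]])
  out <- array(0, dim = c(sum(vapply(pieces, function(p) dim(p)[1], 0L)),
                          d[2], d[3]))
  off <- 0L
  for (p in pieces) {
    out[off + seq_len(dim(p)[1]), , ] <- p
    off <- off + dim(p)[1]
  }
  out
}

abind2 <- function(...) {
  pieces <- list(...)
  d <- dim(pieces[[1L]])
  out <- array(0, dim = c(d[1],
                          sum(vapply(pieces, function(p) dim(p)[2], 0L)),
                          d[3]))
  off <- 0L
  for (p in pieces) {
    out[, off + seq_len(dim(p)[2]), ] <- p
    off <- off + dim(p)[2]
  }
  out
}

# Reverse sweep from `out`, seeding with `seed_grad` (dL/d out).
nn_backward <- function(tape, out, seed_grad) {
  out$grad <- seed_grad
  for (i in rev(seq_along(tape$nodes))) {
    n <- tape$nodes[[i]]
    if (is.null(n$grad)) next
    if (!is.null(n$pid)) {
      if (is.null(tape$pgrad[[n$pid]])) tape$pgrad[[n$pid]] <- n$grad
      else tape$pgrad[[n$pid]] <- tape$pgrad[[n$pid]] + n$grad
    }
    if (!is.null(n$backfn)) n$backfn(n)
  }
  invisible(tape$pgrad)
}
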
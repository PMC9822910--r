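# Shared fixtures and independent oracles, built in code at test time.

# Scene with hand-placed heads on a blank image (any size; density-map
# tests use images smaller than the camera frames the generator makes).
blank_scene <- function(height, width, heads = data.frame(x = numeric(0),
                                                          y = numeric(0))) {
  annotated_scene(matrix(0, height, width), heads)
}

# Brute-force "filter the annotation map" oracle: direct convolution of the
# annotation grid with the (normalised) Gaussian kernel, zero-padded
# borders. Independent of the per-head implementation in the package.
brute_force_density <- function(scene, config = density_config()) {
  k <- edcrowd:::gaussian_kernel(config$kernel_size, config$sigma)
  r <- (config$kernel_size - 1L) %/% 2L
  ann <- annotation_map(scene)
  h <- nrow(ann); w <- ncol(ann)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (ann[i, j] == 0) next
      for (di in -r:r) {
        ii <- i + di
        if (ii < 1 || ii > h) next
        for (dj in -r:r) {
          jj <- j + dj
          if (jj < 1 || jj > w) next
          out[ii, jj] <- out[ii, jj] + ann[i, j] * k[di + r + 1, dj + r + 1]
        }
      }
    }
  }
  out
}

# Brute-force metric oracle: explicit accumulation loops.
brute_force_metrics <- function(gt, pred) {
  s_abs <- 0; s_sq <- 0
  for (i in seq_along(gt)) {
    s_abs <- s_abs + abs(gt[i] - pred[i])
    s_sq <- s_sq + (gt[i] - pred[i])^2
  }
  c(mce = s_abs / length(gt), rmse = sqrt(s_sq / length(gt)))
}

# report-time half-up rounding to 2 decimals
round_any <- function(x) edcrowd:::round_half_up(x, 2)

survey_hours <- function() {
  list(h24 = operating_hours("00:00", "24:00"),
       h10 = operating_hours("08:00", "18:00"))
}

weekly_cells_long <- function() {
  wk <- ed_weekly_counts()
  data.frame(area = rep(names(wk), each = nrow(wk)),
             day = rep(rownames(wk), times = ncol(wk)),
             count = unlist(wk, use.names = FALSE))
}
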
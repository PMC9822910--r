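#' Density-map configuration
#'
#' The Gaussian kernel used to turn point head annotations into density
#' maps: a truncated kernel of odd size `kernel_size` (default 15 px) and
#' standard deviation `sigma` (default 4 px).
#'
#' @param kernel_size odd positive kernel side length in pixels.
#' @param sigma Gaussian standard deviation in pixels.
#' @return A `density_config` object.
#' @export
density_config <- function(kernel_size = 15L, sigma = 4) {
  kernel_size <- check_count(kernel_size, "kernel_size", 1L)
  if (kernel_size %% 2L == 0L) stop_invalid("`kernel_size` must be odd")
  check_number(sigma, "sigma", 0, strict = TRUE)
  structure(list(kernel_size = kernel_size, sigma = sigma),
            class = "density_config")
}

gaussian_kernel <- function(kernel_size, sigma) {
  r <- (kernel_size - 1L) %/% 2L
  g <- dnorm(-r:r, sd = sigma)
  k <- outer(g, g)
  k / sum(k)
}

check_heads <- function(heads, height, width) {
  if (nrow(heads) == 0L) return(invisible(heads))
  bad <- which(heads$x < 0 | heads$x > width - 1 |
               heads$y < 0 | heads$y > height - 1)
  if (length(bad)) {
    stop_invalid("annotation out of bounds: (",
                 heads$x[bad[1]], ", ", heads$y[bad[1]], ") in a ",
                 width, "x", height, " image")
  }
  invisible(heads)
}

#' Binary annotation map from head points
#'
#' A grid of the image size with value 1 at each annotated head pixel and
#' 0 elsewhere; heads annotated at the same pixel accumulate, so the grid
#' always sums to the head count. Coordinates are 0-based with `x` the
#' column and `y` the row, origin at the top-left.
#'
#' @param scene an [annotated_scene].
#' @return Integer matrix of the image size.
#' @export
annotation_map <- function(scene) {
  stopifnot(inherits(scene, "annotated_scene"))
  h <- nrow(scene$image); w <- ncol(scene$image)
  check_heads(scene$heads, h, w)
  m <- matrix(0L, h, w)
  if (scene$count > 0) {
    idx <- cbind(round(scene$heads$y) + 1L, round(scene$heads$x) + 1L)
    for (i in seq_len(nrow(idx))) {
      m[idx[i, 1L], idx[i, 2L]] <- m[idx[i, 1L], idx[i, 2L]] + 1L
    }
  }
  m
}

#' Ground-truth density map from head annotations
#'
#' Each head contributes one truncated Gaussian kernel centred at its
#' pixel. Kernels clipped by the image border are renormalised to unit
#' mass, so the total pixel value of the density map equals the head count
#' exactly - including heads at corners and edges. (Plain Gaussian
#' filtering of the annotation map loses mass at the border; in the image
#' interior, at least `(kernel_size-1)/2` pixels from every edge, the two
#' procedures coincide.)
#'
#' @param scene an [annotated_scene].
#' @param config a [density_config()].
#' @return A `density_map`: a non-negative matrix of the image size whose
#'   sum equals `scene$count`, with attribute `source_count`.
#' @examples
#' sc <- generate_scene(5, 64, 64, seed = 1)
#' dm <- density_from_annotations(sc)
#' count_from_density(dm)  # 5
#' @export
density_from_annotations <- function(scene, config = density_config()) {
  stopifnot(inherits(scene, "annotated_scene"))
  if (!inherits(config, "density_config")) {
    stop_invalid("`config` must come from density_config()")
  }
  h <- nrow(scene$image); w <- ncol(scene$image)
  check_heads(scene$heads, h, w)
  k <- gaussian_kernel(config$kernel_size, config$sigma)
  r <- (config$kernel_size - 1L) %/% 2L
  m <- matrix(0, h, w)
  if (scene$count > 0) {
    cy <- round(scene$heads$y) + 1L
    cx <- round(scene$heads$x) + 1L
    for (i in seq_along(cx)) {
      rows <- max(1L, cy[i] - r):min(h, cy[i] + r)
      cols <- max(1L, cx[i] - r):min(w, cx[i] + r)
      kwin <- k[rows - cy[i] + r + 1L, cols - cx[i] + r + 1L, drop = FALSE]
      m[rows, cols] <- m[rows, cols] + kwin / sum(kwin)
    }
  }
  structure(m, class = c("density_map", "matrix"),
            source_count = scene$count)
}

#' Recover the people count from a density map
#'
#' The count is the total mass (sum of all pixel values) of the map.
#'
#' @param map a `density_map` or plain numeric matrix.
#' @return A single number.
#' @export
count_from_density <- function(map) {
  sum(unclass(map))
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("Density map %dx%d, mass %.4f (source count %s)\n",
              nrow(x), ncol(x), sum(unclass(x)),
              format(attr(x, "source_count"))))
  invisible(x)
}

#' Write / read a density map
#'
#' Density maps are serialised either as 32-bit floating-point TIFF
#' (lossless, `format = "tiff"`) or as headerless CSV (`format = "csv"`,
#' exact decimal text).
#'
#' @param map a `density_map` or numeric matrix.
#' @param path output path.
#' @param format `"tiff"` or `"csv"` (default guessed from the extension).
#' @return `write_density_map` returns `path` invisibly;
#'   `read_density_map` returns a `density_map` matrix.
#' @export
write_density_map <- function(map, path, format = c("auto", "tiff", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tiff"
  }
  m <- unclass(map)
  if (format == "tiff") {
    tiff::writeTIFF(m, path, bits.per.sample = 32L)
  } else {
    write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_density_map
#' @export
read_density_map <- function(path, format = c("auto", "tiff", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tiff"
  }
  m <- if (format == "tiff") {
    tiff::readTIFF(path)
  } else {
    as.matrix(read.csv(path, header = FALSE))
  }
  dimnames(m) <- NULL
  structure(m, class = c("density_map", "matrix"), source_count = NA)
}
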
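#' @useDynLib edcrowd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rpois rbinom rlnorm sd aov kruskal.test
#'   t.test shapiro.test dnorm predict coef residuals simulate filter
#' @importFrom utils read.csv write.csv head
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All exported stochastic functions route their
# randomness through this so no call mutates global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("edcrowd_invalid_argument", "error")))
}

check_number <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`", name, "` must be a single finite number")
  }
  if (strict && x <= lower) stop_invalid("`", name, "` must be > ", lower)
  if (!strict && x < lower) stop_invalid("`", name, "` must be >= ", lower)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != as.integer(x)) stop_invalid("`", name, "` must be an integer")
  invisible(as.integer(x))
}

# Half-up decimal rounding (R's round() is round-half-even); used only at
# report time, never in stored tables.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
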
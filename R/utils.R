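#' @importFrom rlang abort warn .data
#' @importFrom stats rnorm runif sd
NULL

# validation helper: abort with the offending field named, so callers can
# pinpoint which part of a spec is invalid
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    abort(sprintf("invalid `%s`: %s", field, msg), class = "nucmorph_validation_error")
  }
  invisible(TRUE)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards (keeps package functions from clobbering the
# user's RNG stream)
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# root-mean-square
rms <- function(x) sqrt(mean(x^2))

# linear interpolation of a periodic series sampled at uniform angles onto a
# new uniform angular grid of length n_out
resample_circular <- function(values, n_out) {
  n <- length(values)
  if (n == n_out) return(values)
  pos <- (seq_len(n_out) - 1) * n / n_out  # 0-based positions in input grid
  i0 <- floor(pos)
  t <- pos - i0
  a <- values[(i0 %% n) + 1L]
  b <- values[((i0 + 1L) %% n) + 1L]
  a * (1 - t) + b * t
}
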
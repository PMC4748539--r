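# Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic 32-bit sub-seed stream derived from a master seed.
sub_seed <- function(master, i) {
  (as.double(master) %% 2147483629 * 48271 + as.double(i) * 7919) %% 2147483629
}

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Quantize [0,1] intensities to the grid of a given bit depth, so that
# TIFF round trips are bit exact.
quantize <- function(x, bit_depth = 16L) {
  levels <- 2^bit_depth - 1
  round(x * levels) / levels
}

is_raster <- function(x) is.matrix(x) && is.numeric(x)

# Coerce EBImage Image objects (and logical matrices) back to plain numeric
# matrices so the operator contracts stay in base types.
as_raster <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.logical(x)) storage.mode(x) <- "double"
  as.matrix(x)
}

stop_if_not_raster <- function(x, what = "raster") {
  if (!is_raster(x)) stop(what, " must be a 2D numeric matrix", call. = FALSE)
  invisible(x)
}

# Beta draw parameterized by mean and standard deviation; sd = 0 (or a
# degenerate mean) returns the mean exactly. An infeasible sd is shrunk to
# 95% of the maximum attainable for that mean.
rbeta_meansd <- function(n, mean, sd) {
  m <- clamp01(mean)
  if (sd <= 0 || m <= 0 || m >= 1) return(rep(m, n))
  s_max <- sqrt(m * (1 - m))
  s <- min(sd, 0.95 * s_max)
  nu <- m * (1 - m) / s^2 - 1
  rbeta(n, m * nu, (1 - m) * nu)
}
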
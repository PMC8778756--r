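# Internal helpers shared across modules.

#' @useDynLib decellwatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards, so every stochastic operation is
# reproducible without clobbering the session RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Draw `n` independent sub-stream seeds from a master seed (kept within the
# 32-bit integer range R requires).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopifnot_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Bilinear resize of an H x W x 3 raster to `side` x `side`; returns the
# same storage convention as the input (8-bit integer or [0,1] double).
resize_raster <- function(raster, side) {
  eightbit <- is.integer(raster) || max(raster) > 1
  if (dim(raster)[1] == side && dim(raster)[2] == side) return(raster)
  x <- raster
  if (eightbit) x <- x / 255
  storage.mode(x) <- "double"
  x <- cpp_resize_bilinear(x, side, side)
  x <- pmin(pmax(x, 0), 1)
  if (eightbit) {
    x <- x * 255
    x[] <- round(x)
    storage.mode(x) <- "integer"
  }
  x
}

# Rec.601 luma on the 0-255 scale.
luminance <- function(raster) {
  x <- raster
  if (!is.integer(x) && max(x) <= 1) x <- x * 255
  0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
}

# Modal border colour of a frame: border pixels are binned (width 8 per
# channel), the modal bin located, and its member pixels averaged. Robust
# estimate of a uniform, noisy background.
estimate_background <- function(raster) {
  x <- raster
  if (!is.integer(x) && max(x) <= 1) x <- x * 255
  h <- dim(x)[1]; w <- dim(x)[2]
  border <- rbind(
    cbind(x[1, , 1], x[1, , 2], x[1, , 3]),
    cbind(x[h, , 1], x[h, , 2], x[h, , 3]),
    cbind(x[, 1, 1], x[, 1, 2], x[, 1, 3]),
    cbind(x[, w, 1], x[, w, 2], x[, w, 3]))
  key <- (border[, 1] %/% 8) * 1024 + (border[, 2] %/% 8) * 32 +
    border[, 3] %/% 8
  modal <- as.integer(names(which.max(table(key))))
  colMeans(border[key == modal, , drop = FALSE])
}
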
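# The optical "spectrometer": extract the heart pixels of every frame and
# reduce them to a per-cycle mean-luminance metric whose plateau marks the
# completion of decellularization.

#' Extract the heart mask of a frame
#'
#' Heart pixels are those whose Euclidean RGB distance from the estimated
#' background colour (modal border colour) exceeds `bg_tolerance`, reduced
#' to the largest connected component.
#'
#' @param frame A `decell_frame`, or a raw H x W x 3 raster.
#' @param bg_tolerance RGB distance threshold (default 30 on the 0-255
#'   scale).
#' @return Logical H x W matrix.
#' @export
extract_heart_mask <- function(frame, bg_tolerance = 30) {
  px <- if (inherits(frame, "decell_frame")) frame$pixels else frame
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("frame must be an H x W x 3 raster", call. = FALSE)
  x <- px
  if (!is.integer(x) && max(x) <= 1) x <- x * 255
  bg <- estimate_background(x)
  d2 <- (x[, , 1] - bg[1])^2 + (x[, , 2] - bg[2])^2 + (x[, , 3] - bg[3])^2
  fg <- d2 > bg_tolerance^2
  if (!any(fg))
    stop("no heart in view: no pixel exceeds the background tolerance",
         call. = FALSE)
  lab <- EBImage::bwlabel(fg)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Mean heart-pixel luminance of one frame
#'
#' Rec.601 luma (`0.299 R + 0.587 G + 0.114 B`) averaged over the masked
#' pixels, on the 0-255 scale.
#'
#' @param frame A `decell_frame` or H x W x 3 raster.
#' @param mask Logical matrix of the same spatial dimensions; must select at
#'   least one pixel.
#' @return A single luminance value.
#' @export
frame_metric <- function(frame, mask) {
  px <- if (inherits(frame, "decell_frame")) frame$pixels else frame
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (!all(dim(mask) == dim(px)[1:2]))
    stop("mask dimensions do not match the frame", call. = FALSE)
  mean(luminance(px)[mask])
}

#' Per-cycle spectrometer trace of a session
#'
#' For every acquisition cycle, averages [frame_metric()] over the cycle's
#' frames (heart mask re-estimated per frame). Frames in which no heart is
#' found are excluded and counted; a cycle losing more than half its frames
#' raises an error.
#'
#' @param session A `decell_session` with rendered frames.
#' @param bg_tolerance Passed to [extract_heart_mask()].
#' @return A data frame of class `spectrometer_trace` with columns
#'   `cycle`, `time_min`, `value`, `n_frames`.
#' @export
spectrometer_trace <- function(session, bg_tolerance = 30) {
  stopifnot(inherits(session, "decell_session"))
  if (!length(session$frames))
    stop("session has no rendered frames", call. = FALSE)
  cfg <- session$config
  out <- data.frame(cycle = seq_len(cfg$n_cycles) - 1L,
                    time_min = NA_real_, value = NA_real_,
                    n_frames = NA_integer_)
  k <- 0L
  for (c in seq_len(cfg$n_cycles)) {
    vals <- numeric(0)
    tmin <- NA_real_
    for (st in seq_len(cfg$steps_per_cycle)) {
      k <- k + 1L
      fr <- session$frames[[k]]
      tmin <- fr$time_min
      m <- tryCatch(extract_heart_mask(fr, bg_tolerance),
                    error = function(e) NULL)
      if (is.null(m)) next
      vals <- c(vals, frame_metric(fr, m))
    }
    if (length(vals) < cfg$steps_per_cycle / 2)
      stop(sprintf(
        "cycle %d: more than half of the frames have no detectable heart",
        c - 1L), call. = FALSE)
    out$time_min[c] <- tmin
    out$value[c] <- mean(vals)
    out$n_frames[c] <- length(vals)
  }
  class(out) <- c("spectrometer_trace", "data.frame")
  out
}

#' @export
print.spectrometer_trace <- function(x, ...) {
  cat(sprintf("<spectrometer_trace: %d cycles, value %.1f -> %.1f>\n",
              nrow(x), x$value[1], x$value[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more cycles\n", nrow(x) - 5L))
  invisible(x)
}

#' @export
plot.spectrometer_trace <- function(x, ...) {
  plot(x$time_min, x$value, type = "b", pch = 16, cex = 0.6,
       xlab = "time (min)", ylab = "mean heart-pixel luminance", ...)
}
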
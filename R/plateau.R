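# Plateau-onset detection by the consecutive-difference rule: a monitored
# series (analyte concentration or optical trace) has plateaued once the
# absolute difference between successive smoothed samples stays below a
# small fraction of the observed range for several samples in a row.

#' Plateau-detection parameters
#'
#' @param smooth_window Width of the centred moving average applied before
#'   differencing (odd, >= 1; edges truncated). Default 3.
#' @param eps_rel "Insignificant" difference threshold as a fraction of the
#'   smoothed series' range. Default 0.01.
#' @param m_consecutive Number of consecutive sub-threshold differences
#'   required. Default 3.
#' @return An object of class `plateau_params`.
#' @export
plateau_params <- function(smooth_window = 3L, eps_rel = 0.01,
                           m_consecutive = 3L) {
  if (smooth_window < 1 || smooth_window %% 2 == 0)
    stop("`smooth_window` must be odd and >= 1", call. = FALSE)
  if (eps_rel <= 0 || eps_rel >= 1)
    stop("`eps_rel` must be in (0, 1)", call. = FALSE)
  if (m_consecutive < 1)
    stop("`m_consecutive` must be >= 1", call. = FALSE)
  structure(list(smooth_window = as.integer(smooth_window),
                 eps_rel = eps_rel,
                 m_consecutive = as.integer(m_consecutive)),
            class = "plateau_params")
}

# Centred moving average with edge truncation.
smooth_ma <- function(x, window) {
  if (window == 1L) return(x)
  n <- length(x)
  h <- (window - 1L) %/% 2L
  vapply(seq_len(n),
         function(i) mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Detect the plateau onset of a series
#'
#' Smooths the series with a centred moving average, computes absolute
#' consecutive differences `d_i = |x_{i+1} - x_i|`, and reports the first
#' index `i` such that `d_j <= eps_rel * range(x)` for `m_consecutive`
#' successive `j` starting at `i`. A constant series plateaus at the first
#' sample (range 0, all differences 0).
#'
#' @param values Numeric series (length >= `smooth_window + m_consecutive
#'   + 1`).
#' @param times Sample times in minutes (same length as `values`).
#' @param params A [plateau_params()].
#' @return An object of class `plateau_result`: `onset_index` (1-based into
#'   the smoothed series, `NA` if no plateau), `onset_time` (minutes, `NA`
#'   if none), `diffs`, `threshold_abs` and the `smoothed` series.
#' @export
detect_plateau <- function(values, times = seq_along(values),
                           params = plateau_params()) {
  stopifnot(inherits(params, "plateau_params"))
  n <- length(values)
  if (length(times) != n)
    stop("`values` and `times` must have equal length", call. = FALSE)
  if (n < params$smooth_window + params$m_consecutive + 1L)
    stop(sprintf("series too short: need at least %d samples",
                 params$smooth_window + params$m_consecutive + 1L),
         call. = FALSE)
  xs <- smooth_ma(values, params$smooth_window)
  d <- abs(diff(xs))
  thr <- params$eps_rel * (max(xs) - min(xs))
  ok <- d <= thr
  m <- params$m_consecutive
  onset <- NA_integer_
  if (length(d) >= m) {
    run <- stats::filter(as.numeric(ok), rep(1, m), sides = 1)
    hits <- which(run == m)
    if (length(hits)) onset <- as.integer(hits[1] - m + 1L)
  }
  structure(list(onset_index = onset,
                 onset_time = if (is.na(onset)) NA_real_ else times[onset],
                 diffs = d, threshold_abs = thr, smoothed = xs,
                 params = params),
            class = "plateau_result")
}

#' @export
print.plateau_result <- function(x, ...) {
  if (is.na(x$onset_index))
    cat("<plateau_result: no plateau detected>\n")
  else
    cat(sprintf("<plateau_result: onset at index %d (t = %g min), |d| <= %.4g>\n",
                x$onset_index, x$onset_time, x$threshold_abs))
  invisible(x)
}

#' Consensus completion time across signals
#'
#' Decellularization is complete only once every available signal (DNA,
#' protein, optical trace) has plateaued, so the consensus is the latest
#' onset among the signals that have one. Returns `NA` (the "not yet
#' complete" signal) when no input has plateaued.
#'
#' @param ... `plateau_result` objects (any number >= 1).
#' @return Consensus onset time in minutes, or `NA_real_`.
#' @export
plateau_consensus <- function(...) {
  results <- list(...)
  if (!length(results)) stop("no plateau results given", call. = FALSE)
  onsets <- vapply(results, function(r) {
    stopifnot(inherits(r, "plateau_result"))
    r$onset_time
  }, numeric(1))
  if (all(is.na(onsets))) return(NA_real_)
  max(onsets, na.rm = TRUE)
}
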
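# The streaming completion metric: per-frame class predictions mapped to
# percent complete (class k of K -> 100 k / (K-1)), smoothed with a
# trailing rolling-window mean and reported once per cycle, plus the
# completion decision and optical-vs-analyte correlation.

#' Rolling-window completion trace
#'
#' Maps each frame's class to a percentage, takes a trailing (causal)
#' rolling mean over `window` frames (truncated at the start), and reports
#' the value at the end of every cycle. With the default window of one full
#' cycle the reported value is the mean over exactly that cycle's frames.
#'
#' @param predicted_classes Integer per-frame classes in
#'   `[0, n_classes - 1]`, in acquisition order.
#' @param frames_per_cycle Frames per cycle (cycle boundaries).
#' @param window Rolling-window width in frames (default
#'   `frames_per_cycle`).
#' @param n_classes Number of classes (default 11).
#' @param cycle_duration_min Minutes per cycle, used for the time axis.
#' @return A data frame of class `completion_trace` with columns `cycle`,
#'   `time_min`, `percent`.
#' @export
completion_trace <- function(predicted_classes, frames_per_cycle,
                             window = frames_per_cycle, n_classes = 11L,
                             cycle_duration_min = 12) {
  if (!length(predicted_classes)) stop("empty input", call. = FALSE)
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  if (any(predicted_classes < 0 | predicted_classes > n_classes - 1L))
    stop("classes out of range", call. = FALSE)
  if (length(predicted_classes) %% frames_per_cycle != 0)
    stop("frame count is not a whole number of cycles", call. = FALSE)
  pct <- predicted_classes * (100 / (n_classes - 1L))
  cs <- cumsum(pct)
  n <- length(pct)
  i <- seq_len(n)
  lo <- pmax(0L, i - window)
  roll <- (cs - c(0, cs)[lo + 1L]) / (i - lo)
  ends <- seq(frames_per_cycle, n, by = frames_per_cycle)
  out <- data.frame(cycle = seq_along(ends) - 1L,
                    time_min = (seq_along(ends) - 1L) * cycle_duration_min,
                    percent = pmin(pmax(roll[ends], 0), 100))
  attr(out, "window") <- window
  class(out) <- c("completion_trace", "data.frame")
  out
}

#' @export
print.completion_trace <- function(x, ...) {
  cat(sprintf("<completion_trace: %d cycles, %.1f%% -> %.1f%%>\n",
              nrow(x), x$percent[1], x$percent[nrow(x)]))
  invisible(x)
}

#' @export
plot.completion_trace <- function(x, ...) {
  plot(x$time_min, x$percent, type = "s", ylim = c(0, 100),
       xlab = "time (min)", ylab = "completion (%)", ...)
}

#' Decide whether decellularization is complete
#'
#' Complete once the completion percentage holds at or above `threshold`
#' for `hold_cycles` consecutive cycles (hysteresis against single-window
#' noise); reports the cycle at which the hold is first satisfied.
#'
#' @param trace A [completion_trace()].
#' @param hold_cycles Consecutive cycles required (default 2).
#' @param threshold Percent threshold (default 99.5).
#' @return List with `complete` (flag) and `cycle` (0-based completion
#'   cycle, or `NA`).
#' @export
is_complete <- function(trace, hold_cycles = 2L, threshold = 99.5) {
  stopifnot(inherits(trace, "completion_trace"))
  ok <- trace$percent >= threshold
  if (length(ok) >= hold_cycles) {
    run <- stats::filter(as.numeric(ok), rep(1, hold_cycles), sides = 1)
    hit <- which(run == hold_cycles)
    if (length(hit))
      return(list(complete = TRUE, cycle = trace$cycle[hit[1]]))
  }
  list(complete = FALSE, cycle = NA_integer_)
}

#' Rank correlation between two time-stamped traces
#'
#' Restricts both series to their overlapping time range, linearly
#' interpolates the denser one onto the sparser one's grid (never inventing
#' samples on the sparse side), and computes the Spearman rank correlation.
#'
#' @param times_a,values_a First series.
#' @param times_b,values_b Second series.
#' @return An object of class `correlation_report`: `coefficient`
#'   (`NA` with `degenerate = TRUE` when either series is constant),
#'   `n_points`, `method`.
#' @export
correlate_traces <- function(times_a, values_a, times_b, values_b) {
  lo <- max(min(times_a), min(times_b))
  hi <- min(max(times_a), max(times_b))
  if (lo >= hi) stop("series do not overlap in time", call. = FALSE)
  ina <- times_a >= lo & times_a <= hi
  inb <- times_b >= lo & times_b <= hi
  if (sum(ina) < 3 || sum(inb) < 3)
    stop("need at least 3 overlapping samples in each series",
         call. = FALSE)
  if (sum(ina) <= sum(inb)) {
    grid <- times_a[ina]; sparse <- values_a[ina]
    dense <- stats::approx(times_b, values_b, xout = grid)$y
  } else {
    grid <- times_b[inb]; sparse <- values_b[inb]
    dense <- stats::approx(times_a, values_a, xout = grid)$y
  }
  degenerate <- stats::sd(sparse) == 0 || stats::sd(dense) == 0
  coef <- if (degenerate) NA_real_ else
    stats::cor(sparse, dense, method = "spearman")
  structure(list(coefficient = coef, n_points = length(grid),
                 method = "spearman", degenerate = degenerate),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  if (x$degenerate)
    cat("<correlation_report: degenerate (constant series)>\n")
  else
    cat(sprintf("<correlation_report: rho = %.3f over %d points>\n",
                x$coefficient, x$n_points))
  invisible(x)
}

#' Monitor a session end to end
#'
#' Runs the whole monitoring pipeline on a session: spectrometer trace and
#' its plateau, analyte plateaus (when analytes are present), per-frame
#' classification (trained model, or the ground-truth oracle when
#' `use_oracle_labels = TRUE`), the rolling completion metric with its
#' completion decision, and correlations between the optical metrics and
#' the DNA curve.
#'
#' @param session A `decell_session` with rendered frames (frames optional
#'   on the oracle path).
#' @param model A trained `decell_cnn`, or `NULL`.
#' @param params [plateau_params()] shared by all plateau detections.
#' @param use_oracle_labels Substitute ground-truth per-frame labels for
#'   model predictions.
#' @param bg_tolerance Heart-extraction threshold.
#' @return An object of class `decell_report` with the traces, plateau
#'   results, completion decision, consensus time and correlations.
#' @export
monitor_session <- function(session, model = NULL,
                            params = plateau_params(),
                            use_oracle_labels = FALSE, bg_tolerance = 30) {
  stopifnot(inherits(session, "decell_session"))
  cfg <- session$config
  rep <- list(session_id = session$session_id)

  # a series too short for the detector simply has no onset yet
  safe_detect <- function(values, times) {
    tryCatch(detect_plateau(values, times, params), error = function(e)
      structure(list(onset_index = NA_integer_, onset_time = NA_real_,
                     diffs = abs(diff(values)), threshold_abs = NA_real_,
                     smoothed = values, params = params),
                class = "plateau_result"))
  }

  optical <- NULL
  if (length(session$frames)) {
    optical <- spectrometer_trace(session, bg_tolerance)
    rep$spectrometer <- optical
    rep$plateau_optical <- safe_detect(optical$value, optical$time_min)
  }

  if (!is.null(session$analytes)) {
    a <- session$analytes
    rep$plateau_dna <- safe_detect(a$dna_conc, a$times_min)
    rep$plateau_protein <- safe_detect(a$protein_conc, a$times_min)
  }

  onsets <- Filter(Negate(is.null),
                   rep[c("plateau_dna", "plateau_protein",
                         "plateau_optical")])
  if (length(onsets))
    rep$consensus_min <- do.call(plateau_consensus, unname(onsets))

  classes <- NULL
  if (use_oracle_labels) {
    cyc <- oracle_cycle_labels(session)
    classes <- rep(cyc, each = cfg$steps_per_cycle)
  } else if (!is.null(model) && length(session$frames)) {
    side <- model$config$input_side
    X <- matrix(0, side * side * 3L, length(session$frames))
    for (i in seq_along(session$frames)) {
      fr <- session$frames[[i]]
      m <- extract_heart_mask(fr, bg_tolerance)
      img <- crop_resize(fr, m, out_side = 200L)
      X[, i] <- as.numeric(resize_raster(img / 255, side))
    }
    classes <- predict(model, X, type = "class")
  }
  if (!is.null(classes)) {
    rep$completion <- completion_trace(classes, cfg$steps_per_cycle,
                                       cycle_duration_min =
                                         cfg$cycle_duration_min)
    rep$complete <- is_complete(rep$completion)
    if (!is.null(session$analytes))
      rep$cor_completion_dna <- tryCatch(correlate_traces(
        rep$completion$time_min, rep$completion$percent,
        session$analytes$times_min, session$analytes$dna_conc),
        error = function(e) NULL)  # too few overlapping samples
  }

  if (!is.null(optical) && !is.null(session$analytes))
    rep$cor_optical_dna <- tryCatch(correlate_traces(
      optical$time_min, optical$value,
      session$analytes$times_min, session$analytes$dna_conc),
      error = function(e) NULL)

  class(rep) <- "decell_report"
  rep
}

#' @export
print.decell_report <- function(x, ...) {
  cat(sprintf("<decell_report '%s'>\n", x$session_id))
  for (nm in c("plateau_dna", "plateau_protein", "plateau_optical")) {
    if (!is.null(x[[nm]]))
      cat(sprintf("  %-16s onset %s min\n", sub("plateau_", "", nm),
                  format(x[[nm]]$onset_time)))
  }
  if (!is.null(x$consensus_min))
    cat(sprintf("  consensus        %s min\n", format(x$consensus_min)))
  if (!is.null(x$complete))
    cat(sprintf("  completion       %s\n",
                if (x$complete$complete)
                  sprintf("complete at cycle %d", x$complete$cycle)
                else "not complete"))
  if (!is.null(x$cor_optical_dna) && !x$cor_optical_dna$degenerate)
    cat(sprintf("  optical~DNA rho  %.3f\n",
                x$cor_optical_dna$coefficient))
  invisible(x)
}
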
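# Synthetic decellularization sessions with known ground truth: a rotating
# heart-shaped blob whose colour washes out along a sigmoidal trajectory,
# plus saturating-kinetics DNA/protein release curves. Stands in for real
# acquisitions, which are not publicly deposited, and gives every test an
# oracle (per-angle masks, per-cycle washout state, true plateau time).

# Colour anchors (8-bit RGB). The heart interpolates linearly from dark red
# (native tissue) towards a pale tone near -- but reliably separable from --
# the uniform light-grey background, modelling the translucency of a fully
# decellularized scaffold.
HEART_COLOR_NATIVE <- c(120, 25, 30)
HEART_COLOR_DECELL <- c(172, 178, 186)
BACKGROUND_COLOR <- c(210, 215, 220)

#' Washout kinetics configuration
#'
#' First-order release kinetics for DNA and total protein,
#' `C(t) = C_max (1 - exp(-k t))`, plus the sigmoidal visual washout used to
#' render frames. The defaults are calibrated so that, with the default
#' plateau-detection parameters and the default 660-min session, the mean of
#' ten default DNA curves plateaus at ~540 min (any `rate_per_min` in
#' [0.0057, 0.0061] places the noiseless onset exactly at 540 min; the
#' midpoint 0.0059 is used, with `noise_sd_frac = 0.002` so the plateau
#' remains detectable in the short post-onset tail of the session). The
#' visual sigmoid starts with the washout already under way
#' (`s(0) ~ 0.14`), so the optical trace rises from the first cycle and its
#' only flat region is the terminal plateau (onset ~372 min by the default
#' detector on the noiseless trace).
#'
#' @param c_max_dna Asymptotic DNA concentration (ng/uL).
#' @param c_max_protein Asymptotic protein concentration (ug/uL).
#' @param rate_per_min First-order washout rate (1/min).
#' @param noise_sd_frac Gaussian noise SD as a fraction of `c_max`
#'   (must be < 0.2).
#' @param visual_mid_min Sigmoid midpoint of the visual washout (minutes).
#' @param visual_steepness Sigmoid steepness (1/min).
#' @return An object of class `kinetics_config`.
#' @export
kinetics_config <- function(c_max_dna = 60, c_max_protein = 2.5,
                            rate_per_min = 0.0059, noise_sd_frac = 0.002,
                            visual_mid_min = 150, visual_steepness = 0.012) {
  stopifnot_scalar(c_max_dna, "c_max_dna")
  stopifnot_scalar(c_max_protein, "c_max_protein")
  stopifnot_scalar(rate_per_min, "rate_per_min")
  stopifnot_scalar(noise_sd_frac, "noise_sd_frac", positive = FALSE)
  if (noise_sd_frac < 0 || noise_sd_frac >= 0.2)
    stop("`noise_sd_frac` must be in [0, 0.2)", call. = FALSE)
  stopifnot_scalar(visual_mid_min, "visual_mid_min")
  stopifnot_scalar(visual_steepness, "visual_steepness")
  structure(list(c_max_dna = c_max_dna, c_max_protein = c_max_protein,
                 rate_per_min = rate_per_min, noise_sd_frac = noise_sd_frac,
                 visual_mid_min = visual_mid_min,
                 visual_steepness = visual_steepness),
            class = "kinetics_config")
}

#' Motor schedule for one acquisition cycle
#'
#' One cycle sweeps the stepper 180 degrees clockwise and back
#' counter-clockwise in equal increments, one photo per step, for a total
#' angular travel of 360 degrees and zero net displacement.
#'
#' @param steps_per_cycle Even count >= 2 (default 400).
#' @return Numeric vector of angles (degrees) of length `steps_per_cycle`.
#' @export
schedule_cycle <- function(steps_per_cycle = 400L) {
  if (length(steps_per_cycle) != 1L || steps_per_cycle < 2 ||
      steps_per_cycle %% 2 != 0)
    stop("`steps_per_cycle` must be a single even count >= 2", call. = FALSE)
  half <- steps_per_cycle / 2
  inc <- 180 / half
  c(seq(inc, 180, by = inc), seq(180 - inc, 0, by = -inc))
}

#' Simulate DNA/protein release curves
#'
#' Samples `C_max (1 - exp(-k t))` every `interval_min` minutes with i.i.d.
#' Gaussian noise (SD = `noise_sd_frac * C_max`), clipped at zero.
#'
#' @param kinetics A [kinetics_config()].
#' @param interval_min Sampling interval (minutes, default 30).
#' @param duration_min Session duration (minutes); must be >= the interval.
#' @param heart_mass_g Heart mass carried into the series for later
#'   normalization.
#' @param seed Integer seed.
#' @return An [analyte_series()].
#' @export
simulate_analytes <- function(kinetics = kinetics_config(),
                              interval_min = 30, duration_min = 660,
                              heart_mass_g = 1.28, seed = 1L) {
  stopifnot(inherits(kinetics, "kinetics_config"))
  if (duration_min < interval_min)
    stop("`duration_min` must be >= `interval_min`", call. = FALSE)
  times <- seq(interval_min, duration_min, by = interval_min)
  base <- 1 - exp(-kinetics$rate_per_min * times)
  with_seed(seed, {
    dna <- kinetics$c_max_dna *
      pmax(0, base + stats::rnorm(length(times), 0, kinetics$noise_sd_frac))
    prot <- kinetics$c_max_protein *
      pmax(0, base + stats::rnorm(length(times), 0, kinetics$noise_sd_frac))
    analyte_series(times, dna, prot, heart_mass_g = heart_mass_g)
  })
}

# Heart-shaped blob mask at a given rotation angle: an ellipse-like shape
# (slightly tapered towards the apex) whose apparent width is compressed by
# max(|cos(angle)|, 0.35), as a 2-D stand-in for 3-D rotation. The mask
# depends on the angle only, never on the washout state.
render_heart_mask <- function(width, height, angle_deg) {
  compress <- max(abs(cos(angle_deg * pi / 180)), 0.35)
  a <- 0.28 * width * compress            # horizontal semi-axis
  b <- 0.33 * height                      # vertical semi-axis
  if (a >= width / 2 || b >= height / 2)
    stop("heart blob does not fit inside the frame", call. = FALSE)
  cx <- (width + 1) / 2
  cy <- (height + 1) / 2
  x <- matrix(seq_len(width), height, width, byrow = TRUE)
  y <- matrix(seq_len(height), height, width)
  # taper: narrower towards the bottom (apex), giving a heart-like outline
  taper <- 1 - 0.25 * pmax(0, (y - cy) / b)
  ((x - cx) / (a * taper))^2 + ((y - cy) / b)^2 <= 1
}

# Look up a ground-truth mask by (cycle, step) via the frame's angle.
#' Ground-truth heart mask for one frame
#' @param session A simulated `decell_session` with ground truth.
#' @param cycle,step 0-based indices.
#' @return Logical H x W matrix.
#' @export
gt_mask <- function(session, cycle, step) {
  stopifnot(!is.null(session$ground_truth$masks))
  angles <- schedule_cycle(session$config$steps_per_cycle)
  session$ground_truth$masks[[format(angles[step + 1L])]]
}

render_frame <- function(mask, s, noise_sd) {
  h <- nrow(mask); w <- ncol(mask)
  heart <- (1 - s) * HEART_COLOR_NATIVE + s * HEART_COLOR_DECELL
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(BACKGROUND_COLOR[ch], h, w)
    plane[mask] <- heart[ch]
    px[, , ch] <- plane
  }
  if (noise_sd > 0)
    px <- px + array(stats::rnorm(length(px), 0, noise_sd), dim(px))
  px <- pmin(pmax(px, 0), 255)
  storage.mode(px) <- "double"
  px[] <- round(px)
  storage.mode(px) <- "integer"
  px
}

#' Simulate a full decellularization session
#'
#' Renders the rotating-heart frame sequence (colour interpolating from dark
#' red to a pale near-background tone as the washout state `s` advances
#' along a logistic trajectory), generates the analyte series, and records
#' ground truth: per-cycle `s`, per-angle heart masks and the true plateau
#' time (the plateau onset of the noiseless DNA curve under default
#' detection parameters).
#'
#' @param config A [session_config()]; `config$seed` drives all randomness
#'   (analyte and pixel-noise streams are split deterministically).
#' @param kinetics A [kinetics_config()].
#' @param session_id Identifier for the session.
#' @param render If `FALSE`, skip frame rendering (analytes plus ground
#'   truth only) -- useful for oracle-label experiments at full scale.
#' @return A `decell_session` with `ground_truth`.
#' @export
simulate_session <- function(config = preset_config("default"),
                             kinetics = kinetics_config(),
                             session_id = sprintf("synthetic_%04d",
                                                  config$seed),
                             render = TRUE) {
  stopifnot(inherits(config, "session_config"),
            inherits(kinetics, "kinetics_config"))
  seeds <- derive_seeds(config$seed, 2L)
  duration <- config$n_cycles * config$cycle_duration_min
  # sessions shorter than one sampling interval have no analyte series
  analytes <- if (duration >= config$analyte_interval_min)
    simulate_analytes(kinetics, config$analyte_interval_min, duration,
                      config$heart_mass_g, seed = seeds[1]) else NULL

  cyc_t <- (seq_len(config$n_cycles) - 1L) * config$cycle_duration_min
  s <- stats::plogis(kinetics$visual_steepness *
                       (cyc_t - kinetics$visual_mid_min))

  # true plateau: noiseless kinetics under default detection parameters;
  # undefined (NA) when the session is too short to contain it
  tp_min <- NA_real_
  if (duration >= config$analyte_interval_min) {
    times <- seq(config$analyte_interval_min, duration,
                 by = config$analyte_interval_min)
    noiseless <- kinetics$c_max_dna *
      (1 - exp(-kinetics$rate_per_min * times))
    tp_min <- tryCatch(detect_plateau(noiseless, times)$onset_time,
                       error = function(e) NA_real_)
  }
  gt <- list(s = s, true_plateau_min = tp_min, masks = NULL)

  frames <- list()
  if (render) {
    angles <- schedule_cycle(config$steps_per_cycle)
    masks <- list()
    for (a in unique(angles))
      masks[[format(a)]] <- render_heart_mask(config$frame_width,
                                              config$frame_height, a)
    gt$masks <- masks
    frames <- vector("list", config$n_cycles * config$steps_per_cycle)
    k <- 0L
    with_seed(seeds[2], {
      for (c in seq_len(config$n_cycles) - 1L) {
        for (st in seq_len(config$steps_per_cycle) - 1L) {
          k <- k + 1L
          ang <- angles[st + 1L]
          px <- render_frame(masks[[format(ang)]], s[c + 1L],
                             config$pixel_noise_sd)
          frames[[k]] <- new_frame(px, c, st, ang,
                                   c * config$cycle_duration_min)
        }
      }
    })
  }
  decell_session(config, frames, analytes, session_id = session_id,
                 ground_truth = gt)
}

#' Ground-truth class labels for a simulated session
#'
#' Convenience oracle: weak labels derived from the simulator's true plateau
#' time via [split_collections()], one label per cycle.
#'
#' @param session A simulated session with ground truth.
#' @param n_classes Number of progress classes (default 11).
#' @return Integer vector of per-cycle labels (0-based classes).
#' @export
oracle_cycle_labels <- function(session, n_classes = 11L) {
  stopifnot(!is.null(session$ground_truth))
  pc <- ceiling(session$ground_truth$true_plateau_min /
                  session$config$cycle_duration_min)
  split_collections(session$config$n_cycles, pc, n_classes)
}
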
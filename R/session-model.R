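# Data model for decellularization sessions: configuration, frames grouped
# into acquisition cycles, analyte concentration series, and folder-based
# persistence (one folder per session, PNG frames plus CSV/JSON sidecars).

SESSION_FORMAT_VERSION <- 1L

#' Session configuration
#'
#' Describes one monitored decellularization run: the acquisition geometry
#' (steps per rotation cycle, frame size), its duration in cycles, the
#' analyte sampling cadence and the wet mass of the heart.
#'
#' @param n_cycles Number of acquisition cycles in the session.
#' @param steps_per_cycle Motor steps (= photos) per cycle; must be even and
#'   at least 2. The default 400 matches one full 360 degree excursion.
#' @param frame_width,frame_height Frame size in pixels (default 1280 x 720).
#' @param cycle_duration_min Minutes per cycle; cycle `c` (0-based) is
#'   time-stamped `c * cycle_duration_min`.
#' @param analyte_interval_min Minutes between analyte samples (default 30).
#' @param heart_mass_g Wet heart mass in grams used for mass normalization.
#' @param pixel_noise_sd Per-pixel Gaussian noise (8-bit units) applied by
#'   the simulator.
#' @param seed Integer seed controlling every stochastic element of a
#'   simulated session.
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_cycles = 55L, steps_per_cycle = 400L,
                           frame_width = 1280L, frame_height = 720L,
                           cycle_duration_min = 12, analyte_interval_min = 30,
                           heart_mass_g = 1.28, pixel_noise_sd = 2.5,
                           seed = 1L) {
  stopifnot_scalar(n_cycles, "n_cycles")
  stopifnot_scalar(steps_per_cycle, "steps_per_cycle")
  stopifnot_scalar(frame_width, "frame_width")
  stopifnot_scalar(frame_height, "frame_height")
  stopifnot_scalar(cycle_duration_min, "cycle_duration_min")
  stopifnot_scalar(analyte_interval_min, "analyte_interval_min")
  stopifnot_scalar(heart_mass_g, "heart_mass_g")
  stopifnot_scalar(pixel_noise_sd, "pixel_noise_sd", positive = FALSE)
  if (steps_per_cycle < 2 || steps_per_cycle %% 2 != 0)
    stop("`steps_per_cycle` must be even and >= 2", call. = FALSE)
  structure(list(
    n_cycles = as.integer(n_cycles),
    steps_per_cycle = as.integer(steps_per_cycle),
    frame_width = as.integer(frame_width),
    frame_height = as.integer(frame_height),
    cycle_duration_min = as.numeric(cycle_duration_min),
    analyte_interval_min = as.numeric(analyte_interval_min),
    heart_mass_g = as.numeric(heart_mass_g),
    pixel_noise_sd = as.numeric(pixel_noise_sd),
    seed = as.integer(seed)), class = "session_config")
}

#' Preset session configurations
#'
#' `"default"` is the full acquisition geometry (1280 x 720 frames, 400
#' steps per cycle). `"mini"` keeps the same session timeline but shrinks
#' frames to 160 x 120 and cycles to 20 steps for fast desk-scale runs.
#'
#' @param preset `"default"` or `"mini"`.
#' @param ... Overrides forwarded to [session_config()].
#' @return A `session_config`.
#' @export
preset_config <- function(preset = c("default", "mini"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "mini")
    args <- utils::modifyList(list(frame_width = 160L, frame_height = 120L,
                                   steps_per_cycle = 20L), args)
  do.call(session_config, args)
}

#' Analyte concentration series
#'
#' DNA and total-protein concentrations sampled from the recirculating
#' decellularization solution.
#'
#' @param times_min Strictly increasing sampling times (minutes).
#' @param dna_conc DNA concentrations (ng/uL), non-negative.
#' @param protein_conc Total protein concentrations (ug/uL), non-negative.
#' @param heart_mass_g Heart mass (g) to which values can be normalized.
#' @param mass_normalized Whether values are already divided by the mass.
#' @return An object of class `analyte_series`.
#' @export
analyte_series <- function(times_min, dna_conc, protein_conc,
                           heart_mass_g = 1.28, mass_normalized = FALSE) {
  n <- length(times_min)
  if (length(dna_conc) != n || length(protein_conc) != n)
    stop("analyte vectors must have equal length", call. = FALSE)
  if (n > 1 && any(diff(times_min) <= 0))
    stop("`times_min` must be strictly increasing", call. = FALSE)
  if (any(dna_conc < 0) || any(protein_conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  stopifnot_scalar(heart_mass_g, "heart_mass_g")
  structure(list(times_min = as.numeric(times_min),
                 dna_conc = as.numeric(dna_conc),
                 protein_conc = as.numeric(protein_conc),
                 heart_mass_g = as.numeric(heart_mass_g),
                 mass_normalized = isTRUE(mass_normalized)),
            class = "analyte_series")
}

#' Normalize an analyte series to unit heart mass
#'
#' Divides every concentration by the heart mass, as concentrations are
#' reported per gram of heart. Refuses to normalize twice.
#'
#' @param series An [analyte_series()].
#' @return The normalized series (`mass_normalized = TRUE`).
#' @export
normalize_to_mass <- function(series) {
  stopifnot(inherits(series, "analyte_series"))
  if (series$mass_normalized)
    stop("series is already mass-normalized", call. = FALSE)
  if (series$heart_mass_g <= 0)
    stop("heart mass must be > 0", call. = FALSE)
  series$dna_conc <- series$dna_conc / series$heart_mass_g
  series$protein_conc <- series$protein_conc / series$heart_mass_g
  series$mass_normalized <- TRUE
  series
}

new_frame <- function(pixels, cycle_index, step_index, angle_deg, time_min) {
  structure(list(pixels = pixels, cycle_index = as.integer(cycle_index),
                 step_index = as.integer(step_index),
                 angle_deg = as.numeric(angle_deg),
                 time_min = as.numeric(time_min)),
            class = "decell_frame")
}

#' Assemble a decellularization session
#'
#' @param config A [session_config()].
#' @param frames List of frames ordered by (cycle_index, step_index); may be
#'   empty for analyte-only sessions.
#' @param analytes An [analyte_series()], or `NULL`.
#' @param session_id Folder-safe identifier.
#' @param ground_truth Optional simulator ground truth (per-cycle washout
#'   state, per-angle masks, true plateau time).
#' @return An object of class `decell_session`.
#' @export
decell_session <- function(config, frames = list(), analytes = NULL,
                           session_id = "session", ground_truth = NULL) {
  stopifnot(inherits(config, "session_config"))
  if (length(frames)) {
    key <- vapply(frames, function(f)
      f$cycle_index * config$steps_per_cycle + f$step_index, numeric(1))
    frames <- frames[order(key)]
    expected <- config$n_cycles * config$steps_per_cycle
    if (length(frames) != expected)
      stop(sprintf("session has %d frames, expected %d", length(frames),
                   expected), call. = FALSE)
  }
  structure(list(config = config, frames = frames, analytes = analytes,
                 ground_truth = ground_truth,
                 session_id = as.character(session_id)),
            class = "decell_session")
}

#' @export
print.decell_session <- function(x, ...) {
  cat(sprintf("<decell_session '%s'>\n", x$session_id))
  cat(sprintf("  %d cycles x %d steps, frames %dx%d (%s rendered)\n",
              x$config$n_cycles, x$config$steps_per_cycle,
              x$config$frame_width, x$config$frame_height,
              if (length(x$frames)) length(x$frames) else "none"))
  if (!is.null(x$analytes))
    cat(sprintf("  analytes: %d samples every %g min%s\n",
                length(x$analytes$times_min), x$config$analyte_interval_min,
                if (x$analytes$mass_normalized) " (mass-normalized)" else ""))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: true plateau at %g min\n",
                x$ground_truth$true_plateau_min))
  invisible(x)
}

frame_index <- function(session, cycle, step) {
  cycle * session$config$steps_per_cycle + step + 1L
}

#' Fetch one frame of a session
#' @param session A `decell_session` with rendered frames.
#' @param cycle,step 0-based cycle and step indices.
#' @return A `decell_frame`.
#' @export
get_frame <- function(session, cycle, step) {
  session$frames[[frame_index(session, cycle, step)]]
}

write_frame_png <- function(pixels, path) {
  png::writePNG(pixels / 255, path)
}

read_frame_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  storage.mode(x) <- "double"
  x[] <- round(x * 255)
  storage.mode(x) <- "integer"
  x
}

#' Save a session to disk
#'
#' Writes `<root>/<session_id>/` containing `session.json`, `analytes.csv`,
#' one `cycle_<c>/` folder of PNG frames per cycle (zero-padded indices so
#' lexicographic order equals acquisition order), and, when ground truth is
#' present, `ground_truth.csv` plus per-frame mask PNGs under `masks/`.
#'
#' @param session A `decell_session`.
#' @param root Writable directory.
#' @param overwrite Overwrite an existing folder with the same session_id.
#' @param write_masks Write ground-truth mask PNGs (default `TRUE` when
#'   ground truth is present).
#' @return The session folder path, invisibly.
#' @export
save_session <- function(session, root, overwrite = FALSE,
                         write_masks = !is.null(session$ground_truth)) {
  stopifnot(inherits(session, "decell_session"))
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  folder <- file.path(root, session$session_id)
  if (dir.exists(folder)) {
    if (!overwrite)
      stop(sprintf("session folder '%s' already exists", folder),
           call. = FALSE)
    unlink(folder, recursive = TRUE)
  }
  dir.create(folder, recursive = TRUE)

  meta <- list(version = SESSION_FORMAT_VERSION,
               session_id = session$session_id,
               config = unclass(session$config))
  if (!is.null(session$ground_truth)) {
    meta$ground_truth <- list(
      file = "ground_truth.csv",
      true_plateau_min = session$ground_truth$true_plateau_min,
      masks = if (write_masks) "masks" else NULL)
  }
  jsonlite::write_json(meta, file.path(folder, "session.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(session$analytes)) {
    a <- session$analytes
    utils::write.csv(data.frame(time_min = a$times_min,
                                dna_conc = a$dna_conc,
                                protein_conc = a$protein_conc),
                     file.path(folder, "analytes.csv"), row.names = FALSE)
  }

  cfmt <- paste0("cycle_%0", max(3L, nchar(session$config$n_cycles)), "d")
  ffmt <- paste0("frame_%0", max(4L, nchar(session$config$steps_per_cycle)),
                 "d.png")
  for (fr in session$frames) {
    cdir <- file.path(folder, sprintf(cfmt, fr$cycle_index))
    if (!dir.exists(cdir)) dir.create(cdir)
    write_frame_png(fr$pixels, file.path(cdir, sprintf(ffmt, fr$step_index)))
  }

  gt <- session$ground_truth
  if (!is.null(gt)) {
    utils::write.csv(data.frame(
      cycle = seq_along(gt$s) - 1L,
      time_min = (seq_along(gt$s) - 1L) * session$config$cycle_duration_min,
      s = gt$s), file.path(folder, "ground_truth.csv"), row.names = FALSE)
    if (write_masks && length(session$frames)) {
      for (fr in session$frames) {
        mdir <- file.path(folder, "masks", sprintf(cfmt, fr$cycle_index))
        if (!dir.exists(mdir)) dir.create(mdir, recursive = TRUE)
        m <- gt_mask(session, fr$cycle_index, fr$step_index)
        png::writePNG(m * 1, file.path(mdir, sprintf(ffmt, fr$step_index)))
      }
    }
  }
  invisible(folder)
}

#' Load a session from disk
#'
#' Reconstructs a session saved by [save_session()] (or hand-assembled to the
#' same layout). Frame completeness is checked against the configuration; a
#' missing frame raises an integrity error naming its (cycle, step).
#'
#' @param folder Session folder.
#' @return A `decell_session`.
#' @export
load_session <- function(folder) {
  meta_path <- file.path(folder, "session.json")
  if (!file.exists(meta_path))
    stop(sprintf("no session.json in '%s'", folder), call. = FALSE)
  meta <- tryCatch(jsonlite::read_json(meta_path, simplifyVector = TRUE),
                   error = function(e)
                     stop(sprintf("malformed session.json: %s",
                                  conditionMessage(e)), call. = FALSE))
  cfg <- do.call(session_config, meta$config[names(meta$config) %in%
                                               names(formals(session_config))])

  analytes <- NULL
  csv <- file.path(folder, "analytes.csv")
  if (file.exists(csv)) {
    tab <- utils::read.csv(csv)
    analytes <- analyte_series(tab$time_min, tab$dna_conc, tab$protein_conc,
                               heart_mass_g = cfg$heart_mass_g)
  }

  cfmt <- paste0("cycle_%0", max(3L, nchar(cfg$n_cycles)), "d")
  ffmt <- paste0("frame_%0", max(4L, nchar(cfg$steps_per_cycle)), "d.png")
  angles <- schedule_cycle(cfg$steps_per_cycle)
  frames <- vector("list", cfg$n_cycles * cfg$steps_per_cycle)
  have_any <- FALSE
  missing <- character(0)
  k <- 0L
  for (c in seq_len(cfg$n_cycles) - 1L) {
    for (s in seq_len(cfg$steps_per_cycle) - 1L) {
      k <- k + 1L
      path <- file.path(folder, sprintf(cfmt, c), sprintf(ffmt, s))
      if (!file.exists(path)) {
        missing <- c(missing, sprintf("(cycle %d, step %d)", c, s))
        next
      }
      have_any <- TRUE
      px <- read_frame_png(path)
      if (dim(px)[1] != cfg$frame_height || dim(px)[2] != cfg$frame_width)
        stop(sprintf("frame (cycle %d, step %d) is %dx%d, expected %dx%d",
                     c, s, dim(px)[2], dim(px)[1], cfg$frame_width,
                     cfg$frame_height), call. = FALSE)
      frames[[k]] <- new_frame(px, c, s, angles[s + 1L],
                               c * cfg$cycle_duration_min)
    }
  }
  if (have_any && length(missing))
    stop(sprintf("session integrity error: missing frames %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!have_any) frames <- list()

  gt <- NULL
  if (!is.null(meta$ground_truth)) {
    gtab <- utils::read.csv(file.path(folder, meta$ground_truth$file))
    masks <- NULL
    if (!is.null(meta$ground_truth$masks) && length(frames)) {
      masks <- list()
      for (fr in frames) {
        key <- format(fr$angle_deg)
        if (is.null(masks[[key]])) {
          mp <- file.path(folder, "masks", sprintf(cfmt, fr$cycle_index),
                          sprintf(ffmt, fr$step_index))
          m <- png::readPNG(mp)
          if (length(dim(m)) == 3L) m <- m[, , 1]
          masks[[key]] <- m > 0.5
        }
      }
    }
    gt <- list(s = gtab$s,
               true_plateau_min = meta$ground_truth$true_plateau_min,
               masks = masks)
  }

  decell_session(cfg, frames, analytes, session_id = meta$session_id,
                 ground_truth = gt)
}
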
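# Weak labeling: turn a session plus its detected plateau into an 11-class
# progress dataset. Pre-plateau cycles are partitioned into ten contiguous,
# (near-)equal time segments (classes 0-9); everything from the plateau
# onwards is the final class. Frames inherit their cycle's class, are
# cropped to the heart, padded square and resized to 200 x 200.

#' Per-cycle weak class labels
#'
#' Cycles `[0, plateau_cycle)` are split into `n_classes - 1` contiguous
#' segments of equal size (any remainder `r` adds one cycle to each of the
#' first `r` segments); cycles `[plateau_cycle, n_cycles)` form the last
#' class.
#'
#' @param n_cycles Total cycles in the session.
#' @param plateau_cycle 0-based cycle index of the detected plateau onset;
#'   must satisfy `n_classes - 1 <= plateau_cycle < n_cycles`.
#' @param n_classes Number of classes (default 11).
#' @return Integer vector of length `n_cycles` with 0-based class labels.
#' @export
split_collections <- function(n_cycles, plateau_cycle, n_classes = 11L) {
  n_cycles <- as.integer(n_cycles)
  plateau_cycle <- as.integer(plateau_cycle)
  n_classes <- as.integer(n_classes)
  if (plateau_cycle <= 0 || plateau_cycle >= n_cycles)
    stop("`plateau_cycle` must lie strictly inside the session",
         call. = FALSE)
  k <- n_classes - 1L
  if (plateau_cycle < k)
    stop(sprintf(
      "plateau at cycle %d is too early for %d pre-plateau segments",
      plateau_cycle, k), call. = FALSE)
  base <- plateau_cycle %/% k
  r <- plateau_cycle %% k
  sizes <- rep(base, k) + c(rep(1L, r), rep(0L, k - r))
  c(rep(seq_len(k) - 1L, times = sizes),
    rep(k, n_cycles - plateau_cycle))
}

#' Crop a frame to its heart and resize
#'
#' Takes the tight bounding box of the mask, expands it by `margin` of its
#' size on every side, clamps to the frame, pads to a square with the
#' background colour (aspect ratio is never distorted) and bilinearly
#' resizes to `out_side`.
#'
#' @param frame A `decell_frame` or H x W x 3 raster.
#' @param mask Non-empty logical heart mask.
#' @param out_side Output side in pixels (default 200).
#' @param margin Fractional bounding-box expansion (default 0.1).
#' @param bg Background RGB (0-255) used for padding; estimated from the
#'   frame border when `NULL`.
#' @return An 8-bit integer `out_side` x `out_side` x 3 raster.
#' @export
crop_resize <- function(frame, mask, out_side = 200L, margin = 0.1,
                        bg = NULL) {
  px <- if (inherits(frame, "decell_frame")) frame$pixels else frame
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (!is.integer(px)) {
    x <- px
    if (max(x) <= 1) x <- x * 255
    storage.mode(x) <- "double"; x[] <- round(x)
    storage.mode(x) <- "integer"
    px <- x
  }
  h <- dim(px)[1]; w <- dim(px)[2]
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  mh <- rows[2] - rows[1] + 1L
  mw <- cols[2] - cols[1] + 1L
  r0 <- max(1L, rows[1] - as.integer(round(margin * mh)))
  r1 <- min(h, rows[2] + as.integer(round(margin * mh)))
  c0 <- max(1L, cols[1] - as.integer(round(margin * mw)))
  c1 <- min(w, cols[2] + as.integer(round(margin * mw)))
  crop <- px[r0:r1, c0:c1, , drop = FALSE]

  ch <- dim(crop)[1]; cw <- dim(crop)[2]
  side <- max(ch, cw)
  if (is.null(bg)) bg <- estimate_background(px)
  sq <- array(0L, c(side, side, 3L))
  for (k in 1:3) sq[, , k] <- as.integer(round(bg[k]))
  ro <- (side - ch) %/% 2L
  co <- (side - cw) %/% 2L
  sq[(ro + 1L):(ro + ch), (co + 1L):(co + cw), ] <- crop
  resize_raster(sq, out_side)
}

#' Randomly augment an image
#'
#' Horizontal flip with probability `flip_p`, rotation uniform in
#' `[-max_rot, max_rot]` degrees (bilinear, corners filled with the border
#' colour), and brightness scaling uniform in `brightness_range`, clipped to
#' the 8-bit range. Dimensions are preserved and the draw is deterministic
#' under `seed`.
#'
#' @param image H x W x 3 raster (8-bit integer or [0,1] double).
#' @param seed Integer seed.
#' @param flip_p Flip probability (default 0.5; 0 disables).
#' @param max_rot Maximum absolute rotation in degrees (default 15).
#' @param brightness_range Multiplicative brightness range (default
#'   `c(0.85, 1.15)`).
#' @return Raster of the same type and dimensions.
#' @export
augment <- function(image, seed, flip_p = 0.5, max_rot = 15,
                    brightness_range = c(0.85, 1.15)) {
  draws <- with_seed(seed, list(
    flip = stats::runif(1) < flip_p,
    angle = stats::runif(1, -max_rot, max_rot),
    scale = stats::runif(1, brightness_range[1], brightness_range[2])))
  apply_augment(image, draws$flip, draws$angle, draws$scale)
}

apply_augment <- function(image, flip, angle, scale) {
  eightbit <- is.integer(image) || max(image) > 1
  x <- image
  if (eightbit) x <- x / 255
  if (flip) x <- x[, dim(x)[2]:1, , drop = FALSE]
  if (angle != 0) {
    fill <- estimate_background(x) / 255
    x <- cpp_rotate_bilinear(x, angle, fill)
  }
  if (scale != 1) x <- x * scale
  x <- pmin(pmax(x, 0), 1)
  if (eightbit) {
    x <- x * 255
    storage.mode(x) <- "double"; x[] <- round(x)
    storage.mode(x) <- "integer"
  }
  x
}

new_dataset <- function(x, labels, source) {
  structure(list(x = x, labels = as.integer(labels), source = source),
            class = "decell_dataset")
}

#' @export
print.decell_dataset <- function(x, ...) {
  cat(sprintf("<decell_dataset: %d images %dx%d, %d classes>\n",
              length(x$labels), dim(x$x)[1], dim(x$x)[2],
              length(unique(x$labels))))
  invisible(x)
}

#' Build the labeled image dataset of a session
#'
#' Runs the full preprocessing chain on every frame: heart-mask extraction,
#' crop to the heart with margin, pad to square, resize to `out_side`
#' (200 x 200, the classifier's native input), then optional downscaling to
#' `store_side` to bound memory on desk-scale runs. Every frame inherits
#' the weak label of its cycle from [split_collections()].
#'
#' @param session A `decell_session` with rendered frames.
#' @param plateau_cycle 0-based plateau onset cycle (e.g. from
#'   [detect_plateau()] on the session's spectrometer trace).
#' @param n_classes Number of classes (default 11).
#' @param out_side Preprocessing resolution (default 200).
#' @param store_side Stored resolution (default `out_side`).
#' @param frames_per_cycle Evenly spaced frames to keep per cycle (default
#'   all). Subsampling mirrors real acquisitions, where far more frames are
#'   collected than are used for training.
#' @param bg_tolerance Heart-extraction threshold.
#' @return A `decell_dataset`: array `x` (`store_side` x `store_side` x 3 x
#'   N, values in [0,1]), integer `labels`, and a `source` data frame
#'   (session_id, cycle, step).
#' @export
build_dataset <- function(session, plateau_cycle, n_classes = 11L,
                          out_side = 200L, store_side = out_side,
                          frames_per_cycle = NULL, bg_tolerance = 30) {
  stopifnot(inherits(session, "decell_session"))
  if (!length(session$frames))
    stop("session has no rendered frames", call. = FALSE)
  cls <- split_collections(session$config$n_cycles, plateau_cycle, n_classes)
  keep <- seq_along(session$frames)
  spc <- session$config$steps_per_cycle
  if (!is.null(frames_per_cycle) && frames_per_cycle < spc) {
    steps <- unique(as.integer(round(seq(1L, spc,
                                         length.out = frames_per_cycle))))
    keep <- keep[((keep - 1L) %% spc + 1L) %in% steps]
  }
  frames <- session$frames[keep]
  n <- length(frames)
  x <- array(0, c(store_side, store_side, 3L, n))
  labels <- integer(n)
  src <- data.frame(session_id = rep(session$session_id, n),
                    cycle = integer(n), step = integer(n))
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    m <- extract_heart_mask(fr, bg_tolerance)
    img <- crop_resize(fr, m, out_side = out_side)
    if (store_side != out_side) img <- resize_raster(img, store_side)
    x[, , , i] <- img / 255
    labels[i] <- cls[fr$cycle_index + 1L]
    src$cycle[i] <- fr$cycle_index
    src$step[i] <- fr$step_index
  }
  new_dataset(x, labels, src)
}

#' Concatenate datasets
#' @param ... `decell_dataset` objects with matching image sides.
#' @return A single `decell_dataset`.
#' @export
combine_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]]) &&
      !inherits(ds[[1]], "decell_dataset")) ds <- ds[[1]]
  stopifnot(all(vapply(ds, inherits, logical(1), "decell_dataset")))
  side <- dim(ds[[1]]$x)[1]
  n <- sum(vapply(ds, function(d) length(d$labels), integer(1)))
  x <- array(0, c(side, side, 3L, n))
  labels <- integer(n)
  src <- do.call(rbind, lapply(ds, `[[`, "source"))
  at <- 0L
  for (d in ds) {
    k <- length(d$labels)
    x[, , , (at + 1L):(at + k)] <- d$x
    labels[(at + 1L):(at + k)] <- d$labels
    at <- at + k
  }
  new_dataset(x, labels, src)
}

#' Stratified train/validation/test split
#'
#' Splits a dataset by class into disjoint train/validation/test parts with
#' the given fractions (default 80/10/10), deterministically under `seed`.
#'
#' @param dataset A `decell_dataset`.
#' @param fractions Length-3 fractions summing to 1.
#' @param seed Integer seed.
#' @return An object of class `dataset_splits`: list with `train`, `val`,
#'   `test` (`decell_dataset` each) and the index vectors used.
#' @export
make_splits <- function(dataset, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(inherits(dataset, "decell_dataset"))
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    stop("`fractions` must be three numbers summing to 1", call. = FALSE)
  labs <- dataset$labels
  counts <- table(labs)
  if (any(counts < 3))
    stop("every class needs at least 3 images", call. = FALSE)
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in sort(unique(labs))) {
      members <- sample(which(labs == cl))
      n <- length(members)
      n_tr <- floor(fractions[1] * n)
      n_va <- floor(fractions[2] * n)
      if (n - n_tr - n_va < 1) n_tr <- n_tr - 1L
      idx$train <- c(idx$train, members[seq_len(n_tr)])
      idx$val <- c(idx$val, members[n_tr + seq_len(n_va)])
      idx$test <- c(idx$test, members[(n_tr + n_va + 1L):n])
    }
  })
  take <- function(i) new_dataset(dataset$x[, , , i, drop = FALSE],
                                  dataset$labels[i],
                                  dataset$source[i, , drop = FALSE])
  structure(list(train = take(idx$train), val = take(idx$val),
                 test = take(idx$test), indices = idx,
                 fractions = fractions),
            class = "dataset_splits")
}

#' @export
print.dataset_splits <- function(x, ...) {
  cat(sprintf("<dataset_splits: train %d / val %d / test %d images>\n",
              length(x$train$labels), length(x$val$labels),
              length(x$test$labels)))
  invisible(x)
}
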
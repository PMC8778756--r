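# Shared fixtures, built once per test run and cached. All synthetic, all
# generated in code.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A small rendered session: mini frames, 8 cycles. Too short to contain a
# plateau; used for rendering / spectrometer / persistence tests.
tiny_session <- function() {
  fixture("tiny", function()
    simulate_session(preset_config("mini", n_cycles = 8L, seed = 42L)))
}

# A noiseless variant for exact monotonicity checks.
tiny_noiseless <- function() {
  fixture("tiny0", function()
    simulate_session(preset_config("mini", n_cycles = 8L, seed = 43L,
                                   pixel_noise_sd = 0)))
}

# A full-length mini session whose optical plateau sits inside the session.
full_mini_session <- function() {
  fixture("full_mini", function()
    simulate_session(preset_config("mini", seed = 7L)))
}

# Spectrometer trace + detected optical plateau of the full mini session.
full_mini_optical <- function() {
  fixture("full_mini_optical", function() {
    s <- full_mini_session()
    tr <- spectrometer_trace(s)
    list(trace = tr, plateau = detect_plateau(tr$value, tr$time_min))
  })
}

# A frame that is uniform background everywhere (no heart in view).
background_frame <- function(h = 60L, w = 80L) {
  px <- array(0L, c(h, w, 3L))
  bg <- c(210L, 215L, 220L)
  for (k in 1:3) px[, , k] <- bg[k]
  px
}

# Independent plateau-onset oracle: exhaustive scan over all candidate run
# positions, sharing no code with detect_plateau beyond arithmetic.
brute_force_onset <- function(values, times, smooth_window = 3L,
                              eps_rel = 0.01, m = 3L) {
  n <- length(values)
  h <- (smooth_window - 1) %/% 2
  xs <- numeric(n)
  for (i in seq_len(n)) xs[i] <- mean(values[max(1, i - h):min(n, i + h)])
  thr <- eps_rel * (max(xs) - min(xs))
  for (i in seq_len(n - m)) {
    all_ok <- TRUE
    for (j in i:(i + m - 1)) {
      if (abs(xs[j + 1] - xs[j]) > thr) { all_ok <- FALSE; break }
    }
    if (all_ok) return(list(index = i, time = times[i]))
  }
  list(index = NA_integer_, time = NA_real_)
}
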
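test_that("session_config validates acquisition geometry", {
  expect_error(session_config(steps_per_cycle = 3L), "even")
  expect_error(session_config(steps_per_cycle = 0L), "> 0")
  expect_error(session_config(heart_mass_g = 0), "> 0")
  cfg <- session_config()
  expect_identical(cfg$steps_per_cycle, 400L)
  expect_identical(c(cfg$frame_width, cfg$frame_height), c(1280L, 720L))
  expect_equal(cfg$analyte_interval_min, 30)
})

test_that("analyte_series enforces its invariants", {
  expect_error(analyte_series(c(30, 60), c(1, 2, 3), c(1, 2, 3)), "length")
  expect_error(analyte_series(c(30, 30), c(1, 2), c(1, 2)), "increasing")
  expect_error(analyte_series(c(30, 60), c(-1, 2), c(1, 2)), "non-negative")
})

test_that("normalize_to_mass divides once and only once", {
  a <- analyte_series(c(30, 60), c(2, 4), c(1, 3), heart_mass_g = 2)
  n <- normalize_to_mass(a)
  expect_equal(n$dna_conc, c(1, 2))
  expect_equal(n$protein_conc, c(0.5, 1.5))
  expect_identical(n$times_min, a$times_min)
  expect_true(n$mass_normalized)
  expect_error(normalize_to_mass(n), "already")

  unit <- normalize_to_mass(
    analyte_series(c(30, 60), c(2, 4), c(1, 3), heart_mass_g = 1))
  expect_equal(unit$dna_conc, c(2, 4))
})

test_that("normalization is linear in the concentrations", {
  t <- c(30, 60, 90)
  a <- analyte_series(t, c(2, 4, 8), c(1, 2, 3), heart_mass_g = 2.5)
  b <- analyte_series(t, c(5, 1, 0), c(4, 4, 4), heart_mass_g = 2.5)
  ab <- analyte_series(t, a$dna_conc + b$dna_conc,
                       a$protein_conc + b$protein_conc, heart_mass_g = 2.5)
  na <- normalize_to_mass(a); nb <- normalize_to_mass(b)
  nab <- normalize_to_mass(ab)
  expect_equal(nab$dna_conc, na$dna_conc + nb$dna_conc)
  expect_equal(nab$protein_conc, na$protein_conc + nb$protein_conc)
})

test_that("save/load round-trips a session losslessly", {
  root <- withr::local_tempdir()
  s <- simulate_session(preset_config("mini", n_cycles = 2L,
                                      steps_per_cycle = 4L, seed = 5L),
                        session_id = "rt")
  folder <- save_session(s, root)

  pngs <- list.files(folder, pattern = "^frame_.*png$", recursive = TRUE)
  pngs <- pngs[!startsWith(pngs, "masks")]
  expect_length(pngs, 8L)
  expect_length(unique(dirname(pngs)), 2L)

  s2 <- load_session(folder)
  expect_identical(s2$session_id, "rt")
  expect_equal(unclass(s2$config), unclass(s$config))
  expect_equal(s2$analytes$dna_conc, s$analytes$dna_conc)
  expect_equal(s2$analytes$times_min, s$analytes$times_min)
  for (i in seq_along(s$frames))
    expect_identical(s2$frames[[i]]$pixels, s$frames[[i]]$pixels)
  expect_equal(s2$ground_truth$s, s$ground_truth$s)
  expect_identical(gt_mask(s2, 1, 2), gt_mask(s, 1, 2))

  expect_error(save_session(s, root), "exists")
  expect_silent(save_session(s, root, overwrite = TRUE))
})

test_that("frames saved at the default geometry decode to 1280x720x3", {
  root <- withr::local_tempdir()
  s <- simulate_session(session_config(n_cycles = 1L, steps_per_cycle = 2L,
                                       seed = 2L), session_id = "full")
  folder <- save_session(s, root, write_masks = FALSE)
  png_path <- list.files(folder, pattern = "frame_.*png$",
                         recursive = TRUE, full.names = TRUE)[1]
  decoded <- png::readPNG(png_path)
  expect_identical(dim(decoded), c(720L, 1280L, 3L))
})

test_that("a missing frame is reported as an integrity error", {
  root <- withr::local_tempdir()
  s <- simulate_session(preset_config("mini", n_cycles = 2L,
                                      steps_per_cycle = 4L, seed = 6L),
                        session_id = "gap")
  folder <- save_session(s, root, write_masks = FALSE)
  victim <- list.files(folder, pattern = "frame_.*png$", recursive = TRUE,
                       full.names = TRUE)[3]
  unlink(victim)
  expect_error(load_session(folder), "cycle 0, step 2")
})

test_that("non-monotone analyte times fail validation on load", {
  root <- withr::local_tempdir()
  s <- simulate_session(preset_config("mini", n_cycles = 5L,
                                      steps_per_cycle = 4L, seed = 8L),
                        session_id = "bad")
  folder <- save_session(s, root, write_masks = FALSE)
  tab <- utils::read.csv(file.path(folder, "analytes.csv"))
  tab$time_min[2] <- tab$time_min[1]
  utils::write.csv(tab, file.path(folder, "analytes.csv"),
                   row.names = FALSE)
  expect_error(load_session(folder), "increasing")
})

test_that("malformed session.json is a parse error", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "broken"))
  writeLines("{ not json", file.path(root, "broken", "session.json"))
  expect_error(load_session(file.path(root, "broken")), "malformed")
})
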
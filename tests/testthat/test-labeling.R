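test_that("split_collections partitions cycles into 11 ordered classes", {
  # even split: 110 cycles, plateau at 100
  cls <- split_collections(110L, 100L)
  expect_identical(sort(unique(cls)), 0:10)
  expect_equal(as.integer(table(cls)), rep(10L, 11L))

  # remainder rule: 25 cycles, plateau at 23
  cls2 <- split_collections(25L, 23L)
  expect_equal(as.integer(table(cls2)[as.character(0:9)]),
               c(3L, 3L, 3L, rep(2L, 7L)))
  expect_equal(sum(cls2 == 10L), 2L)

  # always exactly 11 distinct labels, non-decreasing in cycle order,
  # pre-plateau segment sizes differing by at most one
  for (case in list(c(55L, 32L), c(40L, 17L), c(200L, 199L), c(12L, 10L))) {
    cls <- split_collections(case[1], case[2])
    expect_length(unique(cls), 11L)
    expect_true(all(diff(cls) >= 0))
    sizes <- table(cls[cls < 10L])
    expect_lte(diff(range(sizes)), 1L)
    expect_equal(sum(cls == 10L), case[1] - case[2])
  }

  expect_error(split_collections(55L, 7L), "too early")
  expect_error(split_collections(55L, 55L), "inside")
})

test_that("crop_resize emits 200x200 inputs from raw frames", {
  full <- simulate_session(session_config(n_cycles = 1L,
                                          steps_per_cycle = 2L, seed = 21L))
  fr <- get_frame(full, 0, 0)
  expect_identical(dim(fr$pixels), c(720L, 1280L, 3L))
  m <- extract_heart_mask(fr)
  img <- crop_resize(fr, m)
  expect_identical(dim(img), c(200L, 200L, 3L))
  expect_true(is.integer(img))
  expect_error(crop_resize(fr, m & FALSE), "empty")
})

test_that("a centred square mask at zero margin is the identity path", {
  set.seed(5)
  px <- array(sample(0:255, 400 * 400 * 3, replace = TRUE),
              c(400L, 400L, 3L))
  storage.mode(px) <- "integer"
  mask <- matrix(FALSE, 400, 400)
  mask[101:300, 101:300] <- TRUE
  out <- crop_resize(px, mask, out_side = 200L, margin = 0)
  expect_identical(out, px[101:300, 101:300, ])
})

test_that("non-square masks are padded, never distorted", {
  # heart-coloured block of 100 rows x 50 cols on background
  px <- background_frame(160L, 160L)
  px[31:130, 51:100, 1] <- 120L
  px[31:130, 51:100, 2] <- 25L
  px[31:130, 51:100, 3] <- 30L
  mask <- matrix(FALSE, 160, 160)
  mask[31:130, 51:100] <- TRUE
  out <- crop_resize(px, mask, out_side = 200L, margin = 0)
  expect_identical(dim(out), c(200L, 200L, 3L))
  # the padded square is 100x100 with the 50-wide crop centred: the outer
  # quarters of each row are background, the middle half is heart-coloured
  expect_gt(mean(out[100, 1:20, 1]), 200)   # background red channel
  expect_lt(mean(out[100, 90:110, 2]), 40)  # heart green channel
  # aspect: the block's extent spans the full height but half the width
  dark <- out[, , 2] < 100
  expect_gt(sum(dark[, 100]) / 200, 0.95)
  expect_lt(sum(dark[100, ]) / 200, 0.6)
})

test_that("augmentation is seeded, bounded and optionally the identity", {
  s <- tiny_session()
  fr <- get_frame(s, 2, 2)
  img <- crop_resize(fr, extract_heart_mask(fr))

  # forced identity: flip off, rotation 0, brightness 1
  out <- augment(img, seed = 1L, flip_p = 0, max_rot = 0,
                 brightness_range = c(1, 1))
  expect_identical(out, img)

  # determinism
  a1 <- augment(img, seed = 17L)
  a2 <- augment(img, seed = 17L)
  expect_identical(a1, a2)
  expect_identical(dim(a1), dim(img))

  # brightness scaling on a constant-gray fixture
  gray <- array(100L, c(50L, 50L, 3L))
  storage.mode(gray) <- "integer"
  b <- augment(gray, seed = 1L, flip_p = 0, max_rot = 0,
               brightness_range = c(1.15, 1.15))
  expect_equal(mean(b), 115, tolerance = 0.01)
})

test_that("dataset building labels every kept frame by its cycle", {
  s <- tiny_session()  # 8 cycles; use a hand-set plateau at cycle 9? too few
  # tiny session is too short for 11 classes; check the error contract
  expect_error(build_dataset(s, 5L), "too early")

  full <- full_mini_session()
  opt <- full_mini_optical()
  ds <- build_dataset(full, opt$plateau$onset_index - 1L,
                      store_side = 32L, frames_per_cycle = 2L)
  expect_s3_class(ds, "decell_dataset")
  expect_equal(dim(ds$x), c(32L, 32L, 3L, 110L))
  expect_identical(sort(unique(ds$labels)), 0:10)
  # labels non-decreasing in cycle order
  expect_true(all(diff(ds$labels[order(ds$source$cycle)]) >= 0))
})

test_that("stratified splits are disjoint, covering and deterministic", {
  set.seed(2)
  n <- 1100L
  x <- array(stats::runif(8 * 8 * 3 * n), c(8L, 8L, 3L, n))
  labels <- rep(0:10, each = 100L)
  ds <- decellwatch:::new_dataset(x, labels,
                                  data.frame(session_id = "x",
                                             cycle = seq_len(n),
                                             step = 0L))
  sp <- make_splits(ds, seed = 4L)
  expect_length(sp$train$labels, 880L)
  expect_length(sp$val$labels, 110L)
  expect_length(sp$test$labels, 110L)
  expect_equal(as.integer(table(sp$train$labels)), rep(80L, 11L))
  expect_equal(as.integer(table(sp$test$labels)), rep(10L, 11L))

  all_idx <- c(sp$indices$train, sp$indices$val, sp$indices$test)
  expect_identical(sort(all_idx), seq_len(n))

  sp2 <- make_splits(ds, seed = 4L)
  expect_identical(sp$indices, sp2$indices)
  sp3 <- make_splits(ds, seed = 5L)
  expect_false(identical(sp$indices, sp3$indices))

  tiny <- decellwatch:::new_dataset(x[, , , 1:4, drop = FALSE],
                                    c(0L, 0L, 1L, 1L),
                                    data.frame(session_id = "x",
                                               cycle = 1:4, step = 0L))
  expect_error(make_splits(tiny), "at least 3")
})

test_that("bilinear resizing preserves constants and value order", {
  # identity when sides already match
  px <- array(sample(0:255, 300, replace = TRUE), c(10L, 10L, 3L))
  storage.mode(px) <- "integer"
  expect_identical(decellwatch:::resize_raster(px, 10L), px)

  # constant images stay constant under any rescale
  flat <- array(93L, c(40L, 40L, 3L))
  storage.mode(flat) <- "integer"
  for (side in c(13L, 40L, 80L)) {
    out <- decellwatch:::resize_raster(flat, side)
    expect_true(all(out == 93L))
    expect_identical(dim(out), c(side, side, 3L))
  }

  # a horizontal gradient stays monotone after up- and downscaling
  grad <- array(rep(seq(0, 1, length.out = 50), each = 50), c(50L, 50L, 3L))
  for (side in c(20L, 100L)) {
    out <- decellwatch:::resize_raster(grad, side)
    expect_true(all(diff(out[1, , 1]) >= 0))
    expect_equal(mean(out), mean(grad), tolerance = 0.01)
  }
})
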
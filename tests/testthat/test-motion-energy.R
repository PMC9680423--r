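make_toy_seq <- function(mk, dt = 0.05) {
  structure(list(markers = mk, side = "right", deviation_deg = 0,
                 n_frames = dim(mk)[3], duration = dt * (dim(mk)[3] - 1),
                 frame_dt = dt),
             class = "point_light_sequence")
}

blank_markers <- function(n_frames) {
  mk <- array(0, dim = c(15, 3, n_frames),
              dimnames = list(biomotion:::MARKER_NAMES, c("x", "y", "z"), NULL))
  mk[, "z", ] <- rep(seq(10, 150, length.out = 15), n_frames)
  mk
}

test_that("static sequences produce all-zero flow", {
  fl <- optic_flow(make_toy_seq(blank_markers(5)))
  expect_identical(fl$n_pairs, 4L)
  expect_true(all(fl$vx == 0) && all(fl$vy == 0))
})

test_that("a single moving marker produces flow only in its cell", {
  cfg <- bm_config()
  mk <- blank_markers(3)
  # marker 1 moves +2 cm/frame in world x
  mk[1, "x", ] <- c(0, 2, 4)
  seq <- make_toy_seq(mk)
  fl <- optic_flow(seq, cfg)
  expected_vx <- 2 * cfg$stimulus$px_per_cm / seq$frame_dt # px per second
  expect_equal(sum(fl$vx[, , 1] != 0), 1L)
  expect_equal(max(fl$vx[, , 1]), expected_vx, tolerance = 1e-9)
  expect_true(all(fl$vy[, , 1] == 0))
})

test_that("marker-based flow equals a brute-force per-cell displacement oracle", {
  cfg <- bm_config()
  seq <- kick_sequence("right", 9)
  fl <- optic_flow(seq, cfg)
  pr <- biomotion:::project_markers(seq, cfg)
  for (p in c(1, 30, 60, 89)) {
    cell <- biomotion:::px_to_cell(pr$x[, p], pr$y[, p], cfg)
    vx <- matrix(0, cfg$layer1$n_rows, cfg$layer1$n_cols)
    vy <- vx; cnt <- vx
    for (mki in 1:15) {
      r <- cell$row[mki]; c <- cell$col[mki]
      vx[r, c] <- vx[r, c] + (pr$x[mki, p + 1] - pr$x[mki, p]) / seq$frame_dt
      vy[r, c] <- vy[r, c] + (pr$y[mki, p + 1] - pr$y[mki, p]) / seq$frame_dt
      cnt[r, c] <- cnt[r, c] + 1
    }
    vx[cnt > 0] <- vx[cnt > 0] / cnt[cnt > 0]
    vy[cnt > 0] <- vy[cnt > 0] / cnt[cnt > 0]
    expect_equal(fl$vx[, , p], vx, tolerance = 1e-9)
    expect_equal(fl$vy[, , p], vy, tolerance = 1e-9)
  }
})

test_that("image-based flow recovers a translating dot", {
  mk <- blank_markers(4)
  px_per_cm <- bm_config()$stimulus$px_per_cm
  mk[1, "x", ] <- (0:3) * 2 / px_per_cm # 2 px/frame rightward
  img <- render_frames(make_toy_seq(mk))
  fl <- optic_flow(img)
  # one cell moves right at 2 px/frame = 40 px/s; allow centroid quantization
  expect_gt(max(fl$vx), 0)
  expect_equal(max(fl$vx), 2 / 0.05, tolerance = 0.3)
})

test_that("direction channels are half-rectified and mutually exclusive", {
  fl <- structure(list(
    vx = array(c(0, 3, -1), c(1, 1, 3)),
    vy = array(c(0, 0, 2), c(1, 1, 3)),
    dt = 0.05, n_pairs = 3L), class = "flow_field_series")
  act <- direction_activity(fl)
  expect_equal(act$right[1, 1, ], c(0, 3, 0))
  expect_equal(act$left[1, 1, ], c(0, 0, 1))
  # image y grows downward, so vy = +2 is downward motion
  expect_equal(act$down[1, 1, ], c(0, 0, 2))
  expect_equal(act$up[1, 1, ], c(0, 0, 0))

  # property: opposite channels never co-active, on random flows
  set.seed(42)
  for (i in 1:20) {
    rf <- structure(list(vx = array(rnorm(31 * 36), c(31, 36, 1)),
                         vy = array(rnorm(31 * 36), c(31, 36, 1)),
                         dt = 0.05, n_pairs = 1L), class = "flow_field_series")
    a <- direction_activity(rf)
    expect_true(all(a$right * a$left == 0))
    expect_true(all(a$up * a$down == 0))
    expect_true(all(a$right >= 0 & a$left >= 0 & a$up >= 0 & a$down >= 0))
  }
})

test_that("mirroring the stimulus swaps the left and right channel maps", {
  seq <- kick_sequence("right", 6)
  mir <- mirror_sequence(seq)
  a <- direction_activity(optic_flow(seq))
  b <- direction_activity(optic_flow(mir))
  flip <- function(x) x[, rev(seq_len(dim(x)[2])), , drop = FALSE]
  expect_equal(b$right, flip(a$left), tolerance = 1e-9)
  expect_equal(b$left, flip(a$right), tolerance = 1e-9)
  expect_equal(b$up, flip(a$up), tolerance = 1e-9)
})
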
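fake_activity <- function(right = 0, left = 0, up = 0, down = 0,
                          nr = 31, nc = 36) {
  z <- array(0, c(nr, nc, 1))
  mk <- function(v) if (is.array(v)) v else z + 0 * v + {
    a <- z; a[] <- 0; a
  }
  structure(list(right = if (length(right) > 1) right else z,
                 left = if (length(left) > 1) left else z,
                 up = if (length(up) > 1) up else z,
                 down = if (length(down) > 1) down else z,
                 dt = 0.05, n_pairs = 1L),
            class = "direction_activity")
}

test_that("opponent geometry yields 100 detectors with disjoint abutting subfields", {
  ocfg <- opponent_config()
  expect_identical(ocfg$n_features, 100L)
  types <- vapply(ocfg$detectors, `[[`, "", "type")
  expect_equal(unname(table(types)), rep(25L, 4), ignore_attr = TRUE)
  for (d in ocfg$detectors) {
    expect_length(intersect(d$cellsA, d$cellsB), 0)
    expect_true(all(c(d$cellsA, d$cellsB) >= 1 &
                      c(d$cellsA, d$cellsB) <= 31 * 36))
  }
})

test_that("opponent response is the square-rooted product of subfield maxima", {
  ocfg <- opponent_config()
  act <- fake_activity()
  # all-zero activity -> 0 for every detector
  expect_true(all(vapply(ocfg$detectors, function(d)
    opponent_response(act, d), 0) == 0))

  # plant 4 in subfield A's channel and 9 in subfield B's channel of one
  # h-expansion detector -> sqrt(4 * 9) = 6
  det <- ocfg$detectors[[which(vapply(ocfg$detectors, function(d)
    d$type == "h_expansion" && d$row == 3 && d$col == 3, TRUE))[1]]]
  left <- array(0, c(31, 36, 1)); right <- array(0, c(31, 36, 1))
  left[matrix(c(arrayInd(det$cellsA[5], c(31, 36)), 1), 1)] <- 4
  right[matrix(c(arrayInd(det$cellsB[7], c(31, 36)), 1), 1)] <- 9
  act2 <- fake_activity(right = right, left = left)
  expect_equal(opponent_response(act2, det), 6)

  # opponency requires both subfields: silence one -> 0
  act3 <- fake_activity(left = left)
  expect_equal(opponent_response(act3, det), 0)
})

test_that("max pooling gives spatial invariance within a subfield", {
  ocfg <- opponent_config()
  det <- ocfg$detectors[[1]]
  vals <- vapply(seq_along(det$cellsA), function(i) {
    left <- array(0, c(31, 36, 1)); right <- array(0, c(31, 36, 1))
    left[det$cellsA[i] + 0 * 31 * 36] <- 5 # move within subfield A
    right[det$cellsB[1]] <- 2
    opponent_response(fake_activity(right = right, left = left), det)
  }, 0)
  expect_true(all(abs(vals - vals[1]) < 1e-12))
})

test_that("uniform translation produces near-zero features", {
  # every marker translating right together: no opposing motion anywhere
  mk <- array(0, dim = c(15, 3, 5),
              dimnames = list(biomotion:::MARKER_NAMES, c("x", "y", "z"), NULL))
  mk[, "z", ] <- rep(seq(20, 140, length.out = 15), 5)
  for (f in 1:5) mk[, "x", f] <- seq(-20, 20, length.out = 15) + 2 * f
  toy <- structure(list(markers = mk, side = "right", deviation_deg = 0,
                        n_frames = 5L, duration = 0.2, frame_dt = 0.05),
                   class = "point_light_sequence")
  expect_true(all(featurize(toy) == 0))
})

test_that("an expanding dot pair activates h-expansion detectors (brute force)", {
  cfg <- bm_config()
  mk <- array(0, dim = c(15, 3, 3),
              dimnames = list(biomotion:::MARKER_NAMES, c("x", "y", "z"), NULL))
  mk[, "z", ] <- rep(seq(20, 140, length.out = 15), 3)
  # markers 1 and 2 at the same height, moving apart horizontally
  mk[1:2, "z", ] <- 80
  mk[1, "x", ] <- -c(2, 6, 10); mk[2, "x", ] <- c(2, 6, 10)
  toy <- structure(list(markers = mk, side = "right", deviation_deg = 0,
                        n_frames = 3L, duration = 0.1, frame_dt = 0.05),
                   class = "point_light_sequence")
  U <- featurize(toy, cfg)
  types <- vapply(opponent_config(cfg)$detectors, `[[`, "", "type")
  expect_gt(max(U[, types == "h_expansion"]), 0)
  expect_true(all(U[, types == "h_contraction"] == 0))

  # brute-force check of every feature against the definition
  act <- direction_activity(optic_flow(toy, cfg))
  ocfg <- opponent_config(cfg)
  for (j in seq_len(100)) {
    d <- ocfg$detectors[[j]]
    manual <- sqrt(max(act[[d$chA]][, , 1][d$cellsA]) *
                     max(act[[d$chB]][, , 1][d$cellsB]))
    expect_equal(unname(U[1, j]), unname(manual), tolerance = 1e-12)
  }
})

test_that("mirroring maps features onto mirror-position detectors exactly", {
  cfg <- bm_config()
  ocfg <- opponent_config(cfg)
  perm <- mirror_feature_permutation(ocfg)
  for (ang in c(0, 6, 14)) {
    seq <- kick_sequence("right", ang)
    U <- featurize(seq, cfg, ocfg)
    Um <- featurize(mirror_sequence(seq), cfg, ocfg)
    expect_equal(unname(Um), unname(U[, perm]), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})
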
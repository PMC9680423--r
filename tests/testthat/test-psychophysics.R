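test_that("noise-free trials decide deterministically and correctly", {
  m <- bm_test_model()
  m$cfg$layer3$delta <- 0
  for (side in c("right", "left")) {
    tr <- run_trial(m, 15, side, seed = 1)
    expect_identical(tr$decision, side)
    expect_true(tr$correct)
  }
  # same seed, same config -> identical decision (with noise on)
  m$cfg$layer3$delta <- 0.03
  d1 <- run_trial(m, 4, "right", seed = 7)$decision
  d2 <- run_trial(m, 4, "right", seed = 7)$decision
  expect_identical(d1, d2)
})

test_that("run_block matches per-trial error accounting", {
  m <- bm_test_model()
  blk <- run_block(m, 8, "right", n_trials = 20, seed = 3)
  expect_length(blk$decisions, 20)
  expect_equal(blk$error_pct, 100 * (1 - blk$n_correct / 20))
  expect_true(all(blk$decisions %in% c("right", "left")))
  # determinism: identical seeds give byte-identical blocks
  blk2 <- run_block(m, 8, "right", n_trials = 20, seed = 3)
  expect_identical(blk, blk2)
})

test_that("the psychometric fitter recovers known logistic parameters", {
  # Bernoulli observer simulated directly from a 2AFC logistic curve,
  # bypassing the neural model: threshold 8 deg, slope 0.15 per deg.
  set.seed(77)
  angles <- c(2, 4, 8, 15)
  n <- 240L
  p_true <- 0.5 + 0.5 * plogis(0.15 * (angles - 8))
  thr <- slp <- numeric(30)
  for (r in 1:30) {
    kc <- rbinom(length(angles), n, p_true)
    f <- fit_psychometric(angles, kc, rep(n, length(angles)))
    thr[r] <- f$threshold; slp[r] <- f$slope
  }
  # recovery within the fit's 95% sampling interval; the logistic-slope
  # MLE carries a small-sample upward bias, so the SE-of-mean interval
  # would test bias, not recovery
  ci_thr <- mean(thr) + c(-1, 1) * 1.96 * sd(thr)
  ci_slp <- mean(slp) + c(-1, 1) * 1.96 * sd(slp)
  expect_true(ci_thr[1] <= 8 && 8 <= ci_thr[2])
  expect_true(ci_slp[1] <= 0.15 && 0.15 <= ci_slp[2])
  expect_equal(mean(thr), 8, tolerance = 0.05)
})

test_that("a perfect observer is flagged floor-limited", {
  f <- fit_psychometric(c(2, 4, 8, 15), c(100, 100, 100, 100), rep(100, 4))
  expect_true(f$floor_limited)
  expect_lt(f$threshold, 2)
})

test_that("run_experiment reports mean and dispersion over repetitions", {
  m <- bm_test_model()
  m$cfg$layer3$delta <- 0.03
  ex <- run_experiment(m, n_trials = 15L, n_reps = 3L, seed = 5)
  expect_s3_class(ex, "bm_experiment")
  expect_length(ex$fits, 3)
  expect_true(is.finite(ex$threshold_mean) && is.finite(ex$slope_mean))
  expect_true(ex$threshold_sd >= 0)
  # determinism under the master seed
  ex2 <- run_experiment(m, n_trials = 15L, n_reps = 3L, seed = 5)
  expect_identical(ex$prop_correct, ex2$prop_correct)
  expect_equal(ex$threshold_mean, ex2$threshold_mean)
})

test_that("a 1x1x1 grid equals run_experiment directly", {
  m <- bm_test_model()
  cfg <- m$cfg
  g <- grid_search(cfg, delta = 0.03, tau = 0.0245, k = 4,
                   n_trials = 10L, n_reps = 2L, seed = 9, model = m)
  expect_identical(nrow(g), 1L)
  m2 <- m
  m2$cfg$layer3$delta <- 0.03
  ex <- run_experiment(m2, n_trials = 10L, n_reps = 2L, seed = g$seed[1])
  expect_equal(g$threshold_mean, ex$threshold_mean)
  expect_equal(g$slope_mean, ex$slope_mean)
})

test_that("cross-validation is stratified, above chance, and honest about leakage", {
  cv <- cross_validate(bm_config(), folds = 5, angles = 1:20, seed = 3)
  expect_identical(as.integer(cv$n), 3560L) # 40 sequences x 89 vectors
  expect_gt(cv$accuracy, 0.5)
  # resubstitution accuracy bounds the cross-validated accuracy
  m <- bm_test_model()
  cfg <- bm_config()
  feats <- list(); sides <- character()
  for (a in 1:20) for (s in c("right", "left")) {
    feats[[length(feats) + 1]] <- featurize(kick_sequence(s, a), cfg, m$ocfg)
    sides <- c(sides, s)
  }
  tpl <- fit_templates(feats, sides, cfg)
  hit <- 0L; n <- 0L
  for (i in seq_along(feats)) {
    r <- classify_risk(feats[[i]], tpl)
    hit <- hit + sum(r$side == sides[i]); n <- n + nrow(feats[[i]])
  }
  expect_gte(hit / n, cv$accuracy)
})

test_that("left and right blocks are statistically indistinguishable", {
  m <- bm_test_model()
  m$cfg$layer3$delta <- 0.03
  nR <- nL <- 0L
  for (s in 1:4) {
    nR <- nR + run_block(m, 8, "right", 30, seed = 100 + s)$n_correct
    nL <- nL + run_block(m, 8, "left", 30, seed = 200 + s)$n_correct
  }
  p <- stats::prop.test(c(nR, nL), c(120L, 120L))$p.value
  expect_gt(p, 0.001)
})
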
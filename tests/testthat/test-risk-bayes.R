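test_that("loss matrix has the goalkeeper asymmetry", {
  lam <- loss_matrix(beta = 0.5, gamma = 4)
  expect_identical(dim(lam), c(18L, 18L))
  expect_true(all(diag(lam) == 0))
  expect_true(all(lam[row(lam) != col(lam)] > 0))
  # truth stage 5 right (class 5): deciding the future stage 7 (class 7)
  # must cost less than deciding the past stage 3 (class 3)
  expect_lt(lam[5, 7], lam[5, 3])
  # equal temporal distance, past vs future
  expect_equal(lam[5, 7], 1)
  expect_equal(lam[5, 3], 1 + 0.5 * 2)
  # side confusions cost extra
  expect_gt(lam[5, 14], lam[5, 5 + 1])
})

test_that("risk classification matches a brute-force density oracle on random toys", {
  set.seed(101)
  for (rep in 1:20) {
    k <- sample(2:5, 1); d <- sample(2:4, 1)
    mu <- matrix(rnorm(k * d, sd = 2), k, d)
    sigmas <- replicate(k, random_pd(d), simplify = FALSE)
    priors <- as.vector(rexp(k)); priors <- priors / sum(priors)
    loss <- matrix(rexp(k * k), k); diag(loss) <- 0
    tpl <- toy_templates(mu, sigmas, priors)
    for (j in 1:5) {
      u <- rnorm(d, sd = 2)
      expect_identical(classify_risk(u, tpl, loss)$winner,
                       brute_force_risk(u, mu, sigmas, priors, loss))
    }
  }
})

test_that("0-1 loss with uniform priors reduces to maximum likelihood", {
  set.seed(202)
  k <- 4; d <- 3
  mu <- matrix(rnorm(k * d, sd = 3), k, d)
  sigmas <- replicate(k, random_pd(d), simplify = FALSE)
  priors <- rep(1 / k, k)
  loss01 <- matrix(1, k, k); diag(loss01) <- 0
  tpl <- toy_templates(mu, sigmas, priors)
  for (j in 1:100) {
    u <- matrix(rnorm(d, sd = 3), 1)
    ml <- which.max(biomotion:::log_likelihoods(u, tpl))
    expect_identical(classify_risk(u, tpl, loss01)$winner, ml)
  }
})

test_that("the decision is invariant to rescaling the prior-likelihood products", {
  set.seed(303)
  k <- 3; d <- 2
  mu <- matrix(rnorm(k * d), k, d)
  sigmas <- replicate(k, random_pd(d), simplify = FALSE)
  loss <- matrix(rexp(k * k), k); diag(loss) <- 0
  pr <- c(0.2, 0.3, 0.5)
  for (j in 1:20) {
    u <- rnorm(d)
    w1 <- classify_risk(u, toy_templates(mu, sigmas, pr), loss)$winner
    # scaling every prior by a positive constant scales all risk sums
    w2 <- classify_risk(u, toy_templates(mu, sigmas, pr * 7.3), loss)$winner
    expect_identical(w1, w2)
  }
})

test_that("template fitting pools stages correctly and covers frames 1-90", {
  m <- bm_test_model()
  tpl <- m$templates
  expect_identical(nrow(tpl$mu), 18L)
  expect_identical(tpl$d, 100L)
  sm <- tpl$stage_map
  expect_identical(nrow(sm), 18L)
  for (side in c("right", "left")) {
    rows <- sm[sm$side == side, ]
    expect_identical(rows$frame_lo, seq(1L, 81L, by = 10L))
    expect_identical(rows$frame_hi, seq(10L, 90L, by = 10L))
  }
  # 14 angles x 10 pairs per stage (9 pairs for stage 9)
  expect_identical(tpl$n_train, rep(c(rep(140L, 8), 126L), 2))
  # left templates are the mirror permutation of the right templates
  perm <- mirror_feature_permutation(m$ocfg)
  expect_equal(unname(tpl$mu[10:18, ]), unname(tpl$mu[1:9, perm]),
               tolerance = 1e-9)
})

test_that("mean estimation: a degenerate single-stage input returns the sample mean", {
  cfg <- bm_config()
  set.seed(9)
  U <- matrix(abs(rnorm(10 * 100)), 10, 100) # one stage of 10 frame pairs
  feats <- list(rbind(U, matrix(0, 79, 100)))
  # only stage 1 has data for the right side; other classes must error
  expect_error(fit_templates(feats, "right", cfg), "class")
})

test_that("the winning class has the strictly smallest risk on pipeline features", {
  m <- bm_test_model()
  U <- featurize(kick_sequence("right", 10), m$cfg, m$ocfg)
  res <- classify_risk(U, m$templates)
  for (i in seq_len(nrow(U))) {
    r <- res$risk[i, ]
    expect_true(all(r[res$winner[i]] <= r))
  }
  # gate fires at exactly one neuron with the configured amplitude
  expect_true(all(colSums(res$gate > 0) == 1))
  expect_equal(max(res$gate), m$cfg$classifier$gate_amplitude)
})

test_that("u = mu_k wins its own class for well-separated templates", {
  set.seed(404)
  k <- 4; d <- 3
  mu <- matrix(rnorm(k * d), k, d) * 10 # far apart
  sigmas <- replicate(k, diag(d), simplify = FALSE)
  tpl <- toy_templates(mu, sigmas, rep(1 / k, k))
  lam <- matrix(1, k, k) + 0.5 * pmax(0, outer(1:k, 1:k, `-`))
  diag(lam) <- 0
  for (j in 1:k)
    expect_identical(classify_risk(mu[j, ], tpl, lam)$winner, j)
})

test_that("non-finite features are rejected", {
  m <- bm_test_model()
  u <- rep(NA_real_, 100)
  expect_error(classify_risk(u, m$templates), "non-finite")
})
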
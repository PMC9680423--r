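# Shared fixtures, built once per test run.

.bm_helper_cache <- new.env(parent = emptyenv())

# Default trained model (templates fitted on 7-20 degrees, both sides).
bm_test_model <- function() {
  if (is.null(.bm_helper_cache$model))
    .bm_helper_cache$model <- train_model(bm_config())
  .bm_helper_cache$model
}

# Hand-built toy template set with k Gaussian classes in d dimensions.
# Mirrors the internal template_set layout so classify_risk accepts it.
toy_templates <- function(mu, sigmas, priors, gate_amplitude = 1) {
  k <- nrow(mu); d <- ncol(mu)
  chols <- lapply(sigmas, chol)
  structure(list(
    mu = mu, chols = chols,
    logdets = vapply(chols, function(R) 2 * sum(log(diag(R))), 0),
    priors = priors, loss = NULL, gate_amplitude = gate_amplitude, d = d
  ), class = "template_set")
}

# Independent brute-force evaluation of the minimum-average-risk rule:
# direct density arithmetic, no log-space tricks.
brute_force_risk <- function(u, mu, sigmas, priors, loss) {
  k <- nrow(mu)
  dens <- vapply(seq_len(k), function(j) {
    d <- length(u)
    S <- sigmas[[j]]
    x <- u - mu[j, ]
    exp(-0.5 * drop(t(x) %*% solve(S, x))) /
      sqrt((2 * pi)^d * det(S))
  }, 0)
  w <- dens * priors
  risks <- vapply(seq_len(k), function(i) sum(loss[, i] * w), 0)
  which.min(risks)
}

# Random positive-definite covariance.
random_pd <- function(d) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + diag(0.5, d)
}

# Mirror permutation of the 100-feature vector: detector column position
# j maps to 6 - j within each type, rows unchanged.
mirror_feature_permutation <- function(ocfg) {
  key <- vapply(ocfg$detectors, function(d)
    paste(d$type, d$row, d$col, sep = "."), "")
  mirrored <- vapply(ocfg$detectors, function(d)
    paste(d$type, d$row, 6L - d$col, sep = "."), "")
  match(mirrored, key)
}
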
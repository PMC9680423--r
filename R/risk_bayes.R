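# Risk-averse Bayesian gating of the optic-flow-pattern neurons.
#
# The 90-frame kick is divided into nine 10-frame stages per direction,
# giving an 18-class problem (classes 1..9 = rightward stages 1..9,
# classes 10..18 = leftward stages 1..9). Each class carries a Gaussian
# model N(mu_k, Sigma_k) over the opponent-motion feature space, fitted
# across training angles. Classification minimizes the average risk
#   r_i = sum_k lambda_ki p(u|omega_k) p(omega_k)
# with an asymmetric loss matrix in which misclassifying into a PAST stage
# costs more than into a FUTURE stage at equal temporal distance (the
# goalkeeper asymmetry), and side confusions cost most. The winning class
# receives the positive feed-forward gate G_i(t); all others receive 0.

N_STAGES <- 9L
N_CLASSES <- 18L

#' Stage index of a frame pair
#'
#' Frame pair `i` (frames `i` and `i+1`) belongs to stage `ceil(i / 10)`;
#' the final stage has 9 pairs because 90 frames yield 89 pairs.
#' @param pair frame-pair index (1-based).
#' @param stage_len frames per stage (default 10).
#' @return integer stage in 1..9.
#' @export
stage_of_pair <- function(pair, stage_len = 10L) {
  as.integer(ceiling(pair / stage_len))
}

class_index <- function(stage, side) {
  ifelse(side == "right", stage, N_STAGES + stage)
}

class_side <- function(class) ifelse(class <= N_STAGES, "right", "left")
class_stage <- function(class) ifelse(class <= N_STAGES, class, class - N_STAGES)

#' Asymmetric loss matrix for the risk-averse classifier
#'
#' `lambda[k, i]` is the penalty for assigning a pattern whose true class
#' is `k` to class `i` (the orientation in which the average risk of
#' deciding `i` is `r_i = sum_k lambda_ki p(u|omega_k) p(omega_k)`):
#' `lambda_ki = 1 + beta * max(0, stage(k) - stage(i)) + gamma * [side(k) != side(i)]`,
#' with zero diagonal. `beta > 0` makes past-directed decisions
#' (assigning the present to an already-elapsed stage) graver than
#' future-directed ones at equal temporal distance; `gamma` penalizes
#' left/right confusions.
#'
#' @param beta past-error growth per stage of temporal distance.
#' @param gamma additional penalty for a side mismatch.
#' @return 18 x 18 non-negative matrix with zero diagonal.
#' @export
loss_matrix <- function(beta = 0.5, gamma = 4) {
  stopifnot(beta >= 0, gamma >= 0)
  k <- seq_len(N_CLASSES)
  sk <- class_stage(k); dk <- class_side(k)
  lam <- outer(k, k, function(kk, ii) {
    1 + beta * pmax(0, sk[kk] - sk[ii]) + gamma * (dk[kk] != dk[ii])
  })
  diag(lam) <- 0
  lam
}

#' Fit the 18 Gaussian stage templates
#'
#' Pools, for every (side, stage) class, the feature vectors of that stage
#' across all training sequences of that side, and estimates the class
#' mean and a ridge-regularized sample covariance (denominator `n - 1`;
#' ridge `reg_eps` times the mean feature variance added to the diagonal,
#' or a diagonal-only covariance when `diagonal_only`).
#'
#' @param features list of feature matrices (`n_pairs x d`) from
#'   [featurize()], one per training sequence.
#' @param sides character vector, `"right"`/`"left"` per sequence.
#' @param cfg a [bm_config()]; uses the `classifier` block.
#' @return object of class `template_set`: means (18 x d), per-class
#'   Cholesky factors and log-determinants, priors, loss matrix, stage
#'   map, and the training manifest.
#' @export
fit_templates <- function(features, sides, cfg = bm_config()) {
  stopifnot(length(features) == length(sides), all(sides %in% c("right", "left")))
  cl <- cfg$classifier
  d <- ncol(features[[1]])
  if (!all(vapply(features, ncol, 1L) == d)) stop("inconsistent feature dimension")

  pooled <- vector("list", N_CLASSES)
  for (s in seq_along(features)) {
    U <- features[[s]]
    stage <- stage_of_pair(seq_len(nrow(U)), cl$stage_len)
    for (st in unique(stage)) {
      k <- class_index(st, sides[s])
      pooled[[k]] <- rbind(pooled[[k]], U[stage == st, , drop = FALSE])
    }
  }
  counts <- vapply(pooled, function(x) if (is.null(x)) 0L else nrow(x), 1L)
  if (any(counts < 2)) {
    bad <- which(counts < 2)[1]
    stop(sprintf("class %d (%s stage %d) has %d feature vector(s); need >= 2",
                 bad, class_side(bad), class_stage(bad), counts[bad]))
  }

  mu <- matrix(0, N_CLASSES, d)
  chols <- vector("list", N_CLASSES)
  logdets <- numeric(N_CLASSES)
  for (k in seq_len(N_CLASSES)) {
    X <- pooled[[k]]
    mu[k, ] <- colMeans(X)
    S <- cov(X)
    if (cl$diagonal_only) S <- diag(diag(S), d)
    ridge <- cl$reg_eps * mean(diag(S))
    if (ridge <= 0) ridge <- cl$reg_eps # all-zero class: fall back to eps
    S <- S + diag(ridge, d)
    R <- chol(S)
    chols[[k]] <- R
    logdets[k] <- 2 * sum(log(diag(R)))
  }
  priors <- cl$priors
  if (is.null(priors)) priors <- rep(1 / N_CLASSES, N_CLASSES)
  stopifnot(length(priors) == N_CLASSES, abs(sum(priors) - 1) < 1e-8)

  stage_map <- data.frame(
    class = seq_len(N_CLASSES),
    side = class_side(seq_len(N_CLASSES)),
    stage = class_stage(seq_len(N_CLASSES)),
    frame_lo = (class_stage(seq_len(N_CLASSES)) - 1L) * cl$stage_len + 1L,
    frame_hi = class_stage(seq_len(N_CLASSES)) * cl$stage_len
  )
  structure(list(
    mu = mu, chols = chols, logdets = logdets, priors = priors,
    loss = loss_matrix(cl$loss_beta, cl$loss_gamma),
    gate_amplitude = cl$gate_amplitude,
    stage_map = stage_map, d = d, n_train = counts,
    reg_eps = cl$reg_eps
  ), class = "template_set")
}

# Log-likelihood matrix: rows = samples of U, cols = classes. Works for
# any class count (toy problems in tests use 2-5 classes).
log_likelihoods <- function(U, tpl) {
  n <- nrow(U)
  n_cl <- nrow(tpl$mu)
  LL <- matrix(0, n, n_cl)
  const <- -0.5 * tpl$d * log(2 * pi)
  for (k in seq_len(n_cl)) {
    X <- sweep(U, 2, tpl$mu[k, ])
    Z <- forwardsolve(t(tpl$chols[[k]]), t(X))
    LL[, k] <- const - 0.5 * tpl$logdets[k] - 0.5 * colSums(Z^2)
  }
  LL
}

#' Minimum-average-risk classification of feature vectors
#'
#' Computes, for each class `i`, the weighted risk sum
#' `r_i = sum_k lambda[k, i] p(u|omega_k) p(omega_k)` and returns the
#' argmin. Likelihoods are evaluated in log space and the sums are
#' stabilized by factoring out the largest log term, which leaves the
#' argmin invariant (the decision rule is scale-invariant). Ties are
#' broken toward the lowest class index.
#'
#' @param u a single feature vector or a matrix (`n x d`) of them.
#' @param tpl a `template_set` from [fit_templates()].
#' @param loss optional loss matrix overriding the one stored in `tpl`.
#' @return list with `winner` (integer vector), `risk` (`n x 18` matrix of
#'   stabilized risk sums), `gate` (`18 x n` matrix: `gate_amplitude` at
#'   the winner, 0 elsewhere), and `side` of each winner.
#' @export
classify_risk <- function(u, tpl, loss = tpl$loss) {
  if (is.null(dim(u))) u <- matrix(u, 1)
  stop_if_not_finite(u, "feature vector u")
  if (ncol(u) != tpl$d) stop("feature dimension mismatch")
  n_cl <- nrow(tpl$mu)
  LL <- log_likelihoods(u, tpl)
  LP <- sweep(LL, 2, log(tpl$priors), `+`)
  m <- apply(LP, 1, max)
  W <- exp(LP - m) # n x n_cl, stabilized p(u|w_k)p(w_k) up to a row factor
  risk <- W %*% loss # risk[n, i] = sum_k W[n, k] * loss[k, i]
  winner <- max.col(-risk, ties.method = "first")
  gate <- matrix(0, n_cl, nrow(u))
  gate[cbind(winner, seq_len(nrow(u)))] <- tpl$gate_amplitude
  list(winner = winner, risk = risk, gate = gate,
       side = if (n_cl == N_CLASSES) class_side(winner) else rep(NA, nrow(u)))
}

#' Gate series for a whole sequence
#'
#' Classifies every frame-pair feature vector and returns the feed-forward
#' gate `G_i(t)` of the 18 optic-flow-pattern neurons, one column per
#' frame pair.
#' @inheritParams classify_risk
#' @param U feature matrix `n_pairs x d`.
#' @return `18 x n_pairs` gate matrix with attribute `winner`.
#' @export
gate_series <- function(U, tpl, loss = tpl$loss) {
  res <- classify_risk(U, tpl, loss)
  structure(res$gate, winner = res$winner)
}
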
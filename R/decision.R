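# Layer 4: two-neuron robust mutual-inhibition decision network.
#
# The summed activity of each side's optic-flow-pattern bank drives one
# decision neuron. The neuron whose input is excited first takes the
# T-equation (inhibited by k*N*D); the other takes the D-equation
# (inhibited by k*(N-1)*D + k*T, i.e. including auto-inhibition). With
# N = 2 the labelling is bookkeeping, but it is fixed deterministically
# ("first excited") and reported. Readout: the neuron with the larger
# activity at stimulus end wins.

#' Michaelis-Menten gain of the decision neurons
#'
#' `S(P) = M P^2 / (sigma_mm^2 + P^2)` for `P >= 0` and 0 otherwise;
#' `sigma_mm` is the information-threshold point where the gain reaches
#' half of its maximum `M`.
#'
#' @param P information threshold (any numeric vector).
#' @param M maximum of the gain.
#' @param sigma_mm half-maximum point (> 0).
#' @return numeric vector of gains in `[0, M)`.
#' @export
mm_gain <- function(P, M = 1, sigma_mm = 0.3) {
  stopifnot(M > 0, sigma_mm > 0)
  ifelse(P >= 0, M * P^2 / (sigma_mm^2 + P^2), 0)
}

#' Layer-4 parameter bundle
#' @param cfg a [bm_config()]; uses the `layer4` block.
#' @return list of parameters for [solve_decision()].
#' @export
decision_params <- function(cfg = bm_config()) {
  l4 <- cfg$layer4
  list(k = l4$k, tau = l4$tau, M = l4$M, sigma_mm = l4$sigma_mm,
       n_sub = l4$n_sub, robust = l4$robust, N = 2L)
}

# Pure-R reference integrator for a single trial; returns full traces.
# Kept deliberately independent of the C++ kernel for cross-checking.
solve_decision_r <- function(E_T, E_D, dt_in, params) {
  h <- dt_in / params$n_sub
  n <- length(E_T)
  drift <- function(A, P) {
    if (params$robust && P < 0) {
      if (A > 0) 0 else -A / params$tau
    } else {
      (-A + mm_gain(P, params$M, params$sigma_mm)) / params$tau
    }
  }
  f <- function(T, D, ET, ED) {
    PT <- ET - params$k * params$N * D
    PD <- ED - params$k * (params$N - 1) * D - params$k * T
    c(drift(T, PT), drift(D, PD))
  }
  Tt <- numeric(n * params$n_sub + 1); Dt <- Tt
  T <- 0; D <- 0; idx <- 1L
  for (i in seq_len(n)) {
    ET <- E_T[i]; ED <- E_D[i]
    for (s in seq_len(params$n_sub)) {
      k1 <- f(T, D, ET, ED)
      k2 <- f(T + h / 2 * k1[1], D + h / 2 * k1[2], ET, ED)
      k3 <- f(T + h / 2 * k2[1], D + h / 2 * k2[2], ET, ED)
      k4 <- f(T + h * k3[1], D + h * k3[2], ET, ED)
      T <- T + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
      D <- D + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      idx <- idx + 1L
      Tt[idx] <- T; Dt[idx] <- D
    }
  }
  list(T = Tt, D = Dt, dt = h)
}

#' Solve the two-neuron decision network
#'
#' Integrates the robust mutual-inhibition dynamics with fourth-order
#' Runge-Kutta, the external inputs zero-order held within each sample.
#' `E_right`/`E_left` are the summed activities of the side-specific
#' optic-flow-pattern banks, either vectors (one trial) or
#' `n_samples x n_trials` matrices (a trial block, integrated by the
#' compiled kernel).
#'
#' @param E_right,E_left bank inputs sampled every `dt_in` seconds.
#' @param dt_in input sampling interval (seconds).
#' @param params from [decision_params()].
#' @param engine `"cpp"` (default) or `"r"` (reference implementation;
#'   single trial only, also returns full traces).
#' @return for `engine = "cpp"`: list of per-trial vectors `winner`
#'   (`"right"`/`"left"`/`"undecided"`), `act_right`, `act_left`,
#'   `peak_right`, `peak_left` (times of peak activity, seconds),
#'   `t_label`. For `engine = "r"`: full `T`/`D` traces plus the same
#'   summary for the single trial.
#' @export
solve_decision <- function(E_right, E_left, dt_in, params = decision_params(),
                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  if (is.null(dim(E_right))) {
    E_right <- matrix(E_right); E_left <- matrix(E_left)
  }
  stop_if_not_finite(E_right, "E_right"); stop_if_not_finite(E_left, "E_left")
  if (engine == "r") {
    if (ncol(E_right) != 1) stop("engine='r' integrates a single trial")
    lab <- t_label_first_excited(E_right[, 1], E_left[, 1])
    ET <- if (lab == 1) E_right[, 1] else E_left[, 1]
    ED <- if (lab == 1) E_left[, 1] else E_right[, 1]
    tr <- solve_decision_r(ET, ED, dt_in, params)
    aR <- if (lab == 1) tr$T[length(tr$T)] else tr$D[length(tr$D)]
    aL <- if (lab == 1) tr$D[length(tr$D)] else tr$T[length(tr$T)]
    win <- decision_label(aR, aL)
    return(list(T = tr$T, D = tr$D, dt = tr$dt, t_label = lab,
                act_right = aR, act_left = aL, winner = win))
  }
  res <- solve_decision_block(E_right, E_left, dt_in, params$n_sub,
                              params$tau, params$k, params$M,
                              params$sigma_mm, params$N, params$robust)
  res$winner <- c("undecided", "right", "left")[res$winner + 1L]
  res
}

t_label_first_excited <- function(ER, EL, eps = 1e-9) {
  iR <- which(ER > eps)[1]; iL <- which(EL > eps)[1]
  if (is.na(iR) && is.na(iL)) return(1L)
  if (is.na(iL) || (!is.na(iR) && iR < iL)) return(1L)
  if (is.na(iR) || iL < iR) return(2L)
  if (ER[iR] >= EL[iL]) 1L else 2L
}

decision_label <- function(aR, aL, eps = 1e-9) {
  if (aR < eps && aL < eps) "undecided"
  else if (aR == aL) "undecided"
  else if (aR > aL) "right" else "left"
}
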
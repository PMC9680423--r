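# Layer 3: 18 laterally coupled optic-flow-pattern neurons.
#
# Leaky-integrator dynamics per neuron i:
#   tau_ofp dH_i/dt = -H_i + G_i(t) + sum_m w(i - m) f(H_m)
# integrated with forward Euler; the gate G is held constant within each
# frame interval (zero-order hold). The lateral kernel is asymmetric and
# confined to one side's bank of nine neurons: the immediate successor of
# an active neuron is excited (+w_e), every other same-side neuron is
# inhibited (-w_i), there is no self term beyond the intrinsic leak and no
# coupling across sides. f is a Heaviside step at theta_f.

#' Layer-3 parameter bundle
#'
#' The config stores `w_e`, `w_i` and `theta_f` as fractions of the gate
#' amplitude; here they are converted to absolute activity units, which
#' makes the layer exactly scale-homogeneous: doubling the gate amplitude
#' doubles every `H_i(t)`.
#' @param cfg a [bm_config()]; uses `layer3`, the gate amplitude and the
#'   stimulus timing.
#' @return list of parameters for [ofp_run()] / [ofp_step()].
#' @export
ofp_params <- function(cfg = bm_config()) {
  frame_dt <- cfg$stimulus$duration / (cfg$stimulus$n_frames - 1)
  dt <- frame_dt / cfg$layer3$n_sub
  if (dt >= cfg$layer3$tau_ofp) stop("Euler step must be < tau_ofp")
  g <- cfg$classifier$gate_amplitude
  list(tau_ofp = cfg$layer3$tau_ofp, w_e = cfg$layer3$w_e * g,
       w_i = cfg$layer3$w_i * g, theta_f = cfg$layer3$theta_f * g,
       dt = dt, n_sub = cfg$layer3$n_sub, delta = cfg$layer3$delta,
       frame_dt = frame_dt)
}

# Lateral input to every neuron given the thresholded activities f(H).
ofp_lateral <- function(fH, w_e, w_i) {
  lat <- numeric(18)
  for (bank in list(1:9, 10:18)) {
    f <- fH[bank]
    pred <- c(0, f[-9]) # f of the immediate predecessor within the bank
    tot <- sum(f)
    lat[bank] <- w_e * pred - w_i * (tot - f - pred)
  }
  lat
}

#' One forward-Euler update of the optic-flow-pattern layer
#'
#' @param H numeric(18) current activities.
#' @param g numeric(18) feed-forward gate (from [classify_risk()]).
#' @param params from [ofp_params()].
#' @return numeric(18) updated activities.
#' @export
ofp_step <- function(H, g, params) {
  stop_if_not_finite(H, "OFP state")
  fH <- as.numeric(H >= params$theta_f)
  H + params$dt / params$tau_ofp *
    (-H + g + ofp_lateral(fH, params$w_e, params$w_i))
}

#' Integrate the optic-flow-pattern bank over a gate sequence
#'
#' @param gates `18 x n_pairs` gate matrix from [gate_series()]; each
#'   column is held for one frame interval (`n_sub` Euler substeps).
#' @param params from [ofp_params()].
#' @param H0 initial activities (default 0).
#' @return matrix `18 x (n_pairs * n_sub)` of noise-free activities
#'   `H_i(t)` sampled after each Euler step, with attribute `dt`.
#' @export
ofp_run <- function(gates, params = ofp_params(), H0 = numeric(18)) {
  n_pairs <- ncol(gates)
  n_steps <- n_pairs * params$n_sub
  H <- matrix(0, 18, n_steps)
  h <- H0
  for (t in seq_len(n_steps)) {
    pair <- ((t - 1L) %/% params$n_sub) + 1L
    h <- ofp_step(h, gates[, pair], params)
    H[, t] <- h
  }
  attr(H, "dt") <- params$dt
  H
}

#' Internal Gaussian output noise of the optic-flow-pattern neurons
#'
#' The output passed to the decision layer is drawn from
#' `N(H_i(t), dt * delta^2)` independently per neuron and per sample; the
#' state recursion itself stays noise free. `delta = 0` returns the input
#' unchanged.
#'
#' @param H activity matrix (`18 x n_steps`) or vector.
#' @param delta noise standard-deviation parameter (>= 0).
#' @param dt sampling interval in seconds (defaults to `attr(H, "dt")`).
#' @param seed optional seed for reproducibility.
#' @return noisy copy of `H`.
#' @export
add_internal_noise <- function(H, delta, dt = attr(H, "dt"), seed = NULL) {
  if (delta < 0) stop("delta must be >= 0")
  if (is.null(dt)) stop("dt must be supplied when H carries no dt attribute")
  if (delta == 0) return(H)
  with_seed(seed, H + rnorm(length(H), sd = sqrt(dt) * delta))
}
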
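#' Default model configuration
#'
#' Returns the nested list of parameters controlling every layer of the
#' model and the psychophysics harness. Any element can be overridden by
#' passing replacement values in `...` using the same nesting, e.g.
#' `bm_config(layer4 = list(k = 8), layer3 = list(delta = 0.03))` replaces
#' only those fields and keeps all other defaults.
#'
#' Blocks:
#' \describe{
#'   \item{stimulus}{frame count (90), duration (4.5 s), rendering grid in
#'     pixels (128 wide x 112 high), dot radius, projection scale.}
#'   \item{layer1}{receptive-field grid: 36 columns x 31 rows.}
#'   \item{layer2}{opponent-detector assembly: 5 x 5 detectors per type,
#'     four types, 100 features.}
#'   \item{classifier}{stage length (10 frames), training angle range
#'     (7-20 degrees), loss-matrix shape (`beta` for past-directed penalty
#'     growth, `gamma` for side confusion), covariance ridge `reg_eps`
#'     (fraction of the mean variance), gate amplitude, priors.}
#'   \item{layer3}{optic-flow-pattern dynamics: `tau_ofp` = 0.150 s, lateral
#'     kernel weights `w_e` (excite the immediate successor) and `w_i`
#'     (inhibit all other same-side neurons), step-threshold `theta_f`,
#'     Euler substeps per frame interval, internal noise `delta`.}
#'   \item{layer4}{decision network: inhibitory gain `k`, time constant
#'     `tau`, Michaelis-Menten maximum `M` and half-point `sigma_mm`,
#'     Runge-Kutta substeps per layer-3 sample, `robust` variant flag,
#'     readout rule.}
#'   \item{psychophysics}{tested angles (2, 4, 8, 15 degrees), trials per
#'     block (120), repetitions (30).}
#' }
#'
#' The default `(k, tau, delta)` triple is the first subject group of the
#' packaged behavioural table (k = 4, tau = 0.0245 s, delta = 0.022).
#'
#' @param ... nested overrides, see Description.
#' @return a nested list with class `bm_config`.
#' @export
#' @examples
#' cfg <- bm_config(layer4 = list(k = 2))
#' cfg$layer4$k
bm_config <- function(...) {
  cfg <- list(
    stimulus = list(
      n_frames = 90L, duration = 4.5,
      grid_px = c(width = 128L, height = 112L),
      dot_radius = 1.5, px_per_cm = 0.6,
      center_px = c(x = 64, y = 111)
    ),
    layer1 = list(n_cols = 36L, n_rows = 31L),
    layer2 = list(assembly = c(5L, 5L)),
    classifier = list(
      stage_len = 10L, train_angles = 7:20,
      loss_beta = 0.5, loss_gamma = 4,
      reg_eps = 3, diagonal_only = FALSE,
      gate_amplitude = 0.01, priors = NULL # NULL -> uniform 1/18
    ),
    # w_e, w_i and theta_f are fractions of the gate amplitude, so the
    # layer-3 dynamics are exactly homogeneous in the activity scale.
    layer3 = list(
      tau_ofp = 0.150, w_e = 0.3, w_i = 0.05, theta_f = 0.5,
      n_sub = 10L, delta = 0.022
    ),
    # M and sigma_mm are in activity units and track the gate amplitude
    # (defaults: M = gate, sigma_mm = 0.3 * gate).
    layer4 = list(
      k = 4, tau = 0.0245, M = 0.01, sigma_mm = 0.003,
      n_sub = 5L, robust = TRUE, readout = "end"
    ),
    psychophysics = list(
      angles = c(2, 4, 8, 15), n_trials = 120L, n_reps = 30L,
      cv_unit = "vector"
    )
  )
  mods <- list(...)
  for (block in names(mods)) {
    if (!block %in% names(cfg)) stop("unknown config block: ", block)
    for (field in names(mods[[block]])) {
      if (!field %in% names(cfg[[block]]))
        stop("unknown config field: ", block, "$", field)
      cfg[[block]][[field]] <- mods[[block]][[field]]
    }
  }
  structure(cfg, class = "bm_config")
}

#' Read or write a configuration as JSON
#'
#' Plumbing for run manifests; requires the suggested jsonlite package.
#' @param cfg a `bm_config` list.
#' @param path file path.
#' @return `read_config` returns a `bm_config`; `write_config` its path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write config files")
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to read config files")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(bm_config, raw)
}
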
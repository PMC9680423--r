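# Synthetic point-light soccer-kick stimuli.
#
# The original motion capture behind the behavioural study is not publicly
# deposited, so sequences are produced by a parametric skeleton: keyframed
# joint angles with smooth (natural cubic spline) interpolation, forward
# kinematics for the swing leg and arms, and a planted support leg. The
# realism target is "discriminable by the feature hierarchy with human-like
# difficulty at small angles", not biomechanical fidelity.
#
# Conventions (fixed once, tested):
#   * world axes: x = viewer's right, y = depth into the screen (the kick
#     travels toward the viewer, i.e. -y), z = up (the vertical axis the
#     stimuli are yawed about);
#   * positive yaw deviates the ball direction toward the viewer's RIGHT
#     (counter-clockwise seen from above);
#   * a right-side stimulus at angle theta is the base kick yawed by
#     +theta; the left-side stimulus is its exact reflection through the
#     sagittal plane x = 0.

MARKER_NAMES <- c(
  "head", "neck", "pelvis",
  "shoulder_l", "shoulder_r", "elbow_l", "elbow_r", "wrist_l", "wrist_r",
  "hip_l", "hip_r", "knee_l", "knee_r", "ankle_l", "ankle_r"
)

# Natural-spline interpolation of keyframed values over normalized time.
keyframe_fun <- function(u_keys, values) {
  splinefun(u_keys, values, method = "natural")
}

# Band-limited capture jitter baked into the base kick (postural sway and
# marker-tracking noise of a motion capture). One fixed internal seed: the
# jitter is part of the base stimulus, identical in every call, and is
# rotated/mirrored together with the skeleton, so the generator's
# determinism, rotation and mirror properties hold exactly. The jitter is
# bilaterally mirror-symmetric (left markers carry the x-negated copy of
# the right markers' jitter; midline markers have no lateral jitter), so
# it adds within-stage feature variance - frame-to-frame flicker that a
# real capture has - without carrying any left/right information.
JITTER_SD_CM <- 1.6
JITTER_KNOTS <- 22L

jitter_knots_cache <- new.env(parent = emptyenv())

# Smooth jitter curves for the 9 independent markers (3 midline + 6 right
# side), evaluated at n_frames points: array 9 x 3 x n_frames.
base_jitter <- function(n_frames) {
  key <- as.character(n_frames)
  if (!is.null(jitter_knots_cache[[key]])) return(jitter_knots_cache[[key]])
  knots <- with_seed(20220901L,
                     array(rnorm(9 * 3 * JITTER_KNOTS, sd = JITTER_SD_CM),
                           dim = c(9, 3, JITTER_KNOTS)))
  uk <- seq(0, 1, length.out = JITTER_KNOTS)
  u <- seq(0, 1, length.out = n_frames)
  J <- array(0, dim = c(9, 3, n_frames))
  for (i in 1:9) for (d in 1:3)
    J[i, d, ] <- splinefun(uk, knots[i, d, ], method = "natural")(u)
  # midline markers (1-3): no lateral jitter
  J[1:3, 1, ] <- 0
  jitter_knots_cache[[key]] <- J
  J
}

# Base kick skeleton: 15 markers x 3 coords x n_frames, right-legged kick
# straight toward the viewer. Deterministic; units are centimetres.
#
# The base posture is deliberately sagittally symmetric in its LATERAL
# (x) structure: head, neck and pelvis stay on the midline, the two arms
# abduct and sway as an exact mirror pair with a COMMON depth (y) motion,
# and the necessarily asymmetric legs stay within ~20 cm of the midline.
# Consequence (see the methods vignette): at zero deviation the opponent-
# motion feature vectors of the two stimulus classes coincide, and class
# information enters only through the depth velocities that yaw rotation
# leaks into the horizontal flow channels, growing like sin(theta) - the
# graded small-angle difficulty the 2AFC task needs.
base_kick_markers <- function(n_frames) {
  u <- seq(0, 1, length.out = n_frames)
  deg <- pi / 180

  # swing-leg (right) hip flexion: immediate backswing, fast forward sweep
  alpha <- keyframe_fun(c(0, .15, .3, .55, .75, 1),
                        c(12, -10, -30, 25, 55, 45))(u) * deg
  # swing-knee flexion (0 = straight); lifts early, extends through contact
  beta <- keyframe_fun(c(0, .15, .3, .42, .55, .75, 1),
                       c(25, 40, 65, 85, 15, 10, 25))(u) * deg
  # mild adduction drift: the foot sweeps toward the midline
  addu <- keyframe_fun(c(0, .55, 1), c(2, -3, -4))(u) * deg
  # symmetric arm abduction (balance), rising from the first frame
  ab <- keyframe_fun(c(0, .12, .25, .42, .6, .8, 1),
                     c(12, 30, 38, 30, 50, 42, 45))(u) * deg
  # forearm abduction offset, out of phase with the upper arm
  abf <- keyframe_fun(c(0, .12, .25, .42, .6, .8, 1),
                      c(-4, 10, -6, 14, -4, 12, 6))(u) * deg
  # common fore-aft arm sway (both arms together, forward while leg is back)
  gam <- keyframe_fun(c(0, .15, .3, .55, .8, 1), c(-8, 8, 18, -10, -18, -12))(u) * deg
  # approach step and weight transfer: trunk depth sway, slight bob
  pel_y <- keyframe_fun(c(0, .12, .22, .3, .55, .75, 1),
                        c(10, 7, 4.5, 4, -6, -9, -8))(u)
  pel_dz <- keyframe_fun(c(0, .12, .42, .75, 1), c(1.5, 0, -2.5, -0.5, -1))(u)

  thigh <- 42; shank <- 40; uarm <- 30; farm <- 26

  m <- array(NA_real_, dim = c(15, 3, n_frames),
             dimnames = list(MARKER_NAMES, c("x", "y", "z"), NULL))

  m["head", , ] <- rbind(0, pel_y * 0.9, 168 + pel_dz * 0.5)
  m["neck", , ] <- rbind(0, pel_y * 0.8, 150 + pel_dz * 0.7)
  m["pelvis", , ] <- rbind(0, pel_y, 95 + pel_dz)
  m["hip_l", , ] <- rbind(-9, pel_y, 90 + pel_dz)
  m["hip_r", , ] <- rbind(9, pel_y, 90 + pel_dz)

  # support leg: planted (exactly static below the hip)
  m["knee_l", , ] <- rbind(-10, 1, 50)
  m["ankle_l", , ] <- rbind(-10, 2, 8)

  # swing leg forward kinematics; leg direction mostly sagittal
  leg_dir <- function(sag, add) {
    v <- rbind(sin(add) * cos(sag), -sin(sag), -cos(sag) * cos(add))
    v / rep(sqrt(colSums(v^2)), each = 3)
  }
  vt <- leg_dir(alpha, addu)
  vs <- leg_dir(alpha - beta, addu)
  m["knee_r", , ] <- m["hip_r", , ] + thigh * vt
  m["ankle_r", , ] <- m["knee_r", , ] + shank * vs

  # arms: exact mirror pair (same abduction, same depth sway)
  arm_dir <- function(side, abd, sag) {
    rbind(side * sin(abd), -cos(abd) * sin(sag), -cos(abd) * cos(sag))
  }
  for (s in c(-1, 1)) {
    sh <- if (s < 0) "shoulder_l" else "shoulder_r"
    el <- if (s < 0) "elbow_l" else "elbow_r"
    wr <- if (s < 0) "wrist_l" else "wrist_r"
    m[sh, , ] <- rbind(17 * s, pel_y * 0.8, 141 + pel_dz * 0.8)
    m[el, , ] <- m[sh, , ] + uarm * arm_dir(s, ab, gam)
    m[wr, , ] <- m[el, , ] + farm * arm_dir(s, ab + abf, gam + 15 * deg)
  }

  # capture jitter, bilaterally symmetric (see base_jitter)
  J <- base_jitter(n_frames)
  mid <- c("head", "neck", "pelvis")
  rgt <- c("shoulder_r", "elbow_r", "wrist_r", "hip_r", "knee_r", "ankle_r")
  lft <- c("shoulder_l", "elbow_l", "wrist_l", "hip_l", "knee_l", "ankle_l")
  m[mid, , ] <- m[mid, , ] + J[1:3, , ]
  m[rgt, , ] <- m[rgt, , ] + J[4:9, , ]
  Jl <- J[4:9, , , drop = FALSE]
  Jl[, 1, ] <- -Jl[, 1, ]
  m[lft, , ] <- m[lft, , ] + Jl

  m
}

#' Rotate marker trajectories about the vertical axis
#'
#' Positive angles rotate counter-clockwise seen from above, which deviates
#' a kick initially travelling toward the viewer to the viewer's right.
#'
#' @param markers array `15 x 3 x n_frames` (marker, xyz, frame).
#' @param angle_deg yaw angle in degrees.
#' @return rotated array of the same shape.
#' @export
yaw_markers <- function(markers, angle_deg) {
  a <- angle_deg * pi / 180
  out <- markers
  out[, "x", ] <- markers[, "x", ] * cos(a) - markers[, "y", ] * sin(a)
  out[, "y", ] <- markers[, "x", ] * sin(a) + markers[, "y", ] * cos(a)
  out
}

# Reflect markers through the sagittal plane x = 0, swapping paired
# left/right marker labels so labels stay anatomically consistent.
mirror_markers <- function(markers) {
  out <- markers
  out[, "x", ] <- -markers[, "x", ]
  swap <- function(a, b) {
    tmp <- out[a, , ]; out[a, , ] <<- out[b, , ]; out[b, , ] <<- tmp
  }
  for (base in c("shoulder", "elbow", "wrist", "hip", "knee", "ankle"))
    swap(paste0(base, "_l"), paste0(base, "_r"))
  out
}

#' Generate a synthetic point-light soccer-kick sequence
#'
#' Produces 15 labelled marker trajectories (head, neck, pelvis and
#' left/right shoulders, elbows, wrists, hips, knees, ankles) over
#' `n_frames` frames spanning `duration` seconds, yawed about the vertical
#' axis by `deviation_deg` toward `side`. The left-side sequence at any
#' angle is exactly the right-side sequence reflected through the sagittal
#' plane. The generator is fully deterministic; `seed` is accepted for
#' interface symmetry with the stochastic stages but has no effect.
#'
#' @param side `"right"` or `"left"` - the direction the ball deviates.
#' @param deviation_deg deviation angle in degrees, in `[0, 20]`.
#' @param n_frames number of frames (default 90).
#' @param duration sequence length in seconds (default 4.5).
#' @param seed ignored (the generator is deterministic); kept so that call
#'   sites can thread one seed through the whole pipeline.
#' @return an object of class `point_light_sequence`: list with `markers`
#'   (`15 x 3 x n_frames` array, cm), `side`, `deviation_deg`, `n_frames`,
#'   `duration`, and `frame_dt = duration / (n_frames - 1)`.
#' @export
#' @examples
#' seq <- kick_sequence("right", 9)
#' dim(seq$markers)
kick_sequence <- function(side = c("right", "left"), deviation_deg,
                          n_frames = 90L, duration = 4.5, seed = NULL) {
  side <- match.arg(side)
  if (!is.finite(deviation_deg) || deviation_deg < 0 || deviation_deg > 20)
    stop("deviation_deg must lie in [0, 20]")
  if (n_frames < 2) stop("n_frames must be >= 2")
  base <- base_kick_markers(n_frames)
  m <- yaw_markers(base, deviation_deg)
  if (side == "left") m <- mirror_markers(m)
  structure(
    list(markers = m, side = side, deviation_deg = deviation_deg,
         n_frames = as.integer(n_frames), duration = duration,
         frame_dt = duration / (n_frames - 1)),
    class = "point_light_sequence"
  )
}

#' Reflect a point-light sequence through the sagittal plane
#' @param seq a `point_light_sequence`.
#' @return the mirrored sequence, with `side` flipped.
#' @export
mirror_sequence <- function(seq) {
  seq$markers <- mirror_markers(seq$markers)
  seq$side <- if (seq$side == "right") "left" else "right"
  seq
}

#' @export
print.point_light_sequence <- function(x, ...) {
  cat(sprintf(
    "point-light kick: side=%s deviation=%.3g deg, %d frames / %.2f s (dt=%.1f ms)\n",
    x$side, x$deviation_deg, x$n_frames, x$duration, 1000 * x$frame_dt))
  invisible(x)
}

# ---- projection & rendering -------------------------------------------------

# Orthographic projection of markers onto the image plane (pixels).
# Returns list(x, y): 15 x n_frames matrices; image y grows downward.
project_markers <- function(seq, cfg = bm_config()) {
  st <- cfg$stimulus
  list(
    x = st$center_px[["x"]] + st$px_per_cm * seq$markers[, "x", ],
    y = st$center_px[["y"]] - st$px_per_cm * seq$markers[, "z", ]
  )
}

#' Render a point-light sequence to an image stack
#'
#' Orthographic projection of the markers onto a pixel grid, each marker
#' drawn as a disc. Rendering is plumbing for the optional image-based flow
#' backend; the default feature path works directly from marker geometry.
#'
#' @param seq a `point_light_sequence`.
#' @param cfg a [bm_config()]; uses the `stimulus` block (grid size in
#'   pixels, dot radius, projection scale).
#' @return array `height x width x n_frames` of 0/1 intensities, with
#'   attribute `centers` (the projected marker centres).
#' @export
render_frames <- function(seq, cfg = bm_config()) {
  st <- cfg$stimulus
  w <- st$grid_px[[1]]; h <- st$grid_px[[2]]
  pr <- project_markers(seq, cfg)
  if (any(pr$x < 1 | pr$x > w | pr$y < 1 | pr$y > h)) {
    warning("markers outside the rendering window were clipped")
  }
  img <- array(0, dim = c(h, w, seq$n_frames))
  r2 <- st$dot_radius^2
  rr <- ceiling(st$dot_radius)
  for (f in seq_len(seq$n_frames)) {
    for (m in 1:15) {
      cx <- pr$x[m, f]; cy <- pr$y[m, f]
      xs <- max(1, floor(cx - rr)):min(w, ceiling(cx + rr))
      ys <- max(1, floor(cy - rr)):min(h, ceiling(cy + rr))
      for (x in xs) for (y in ys)
        if ((x - cx)^2 + (y - cy)^2 <= r2) img[y, x, f] <- 1
    }
  }
  attr(img, "centers") <- pr
  attr(img, "frame_dt") <- seq$frame_dt
  img
}

#' Write or read a point-light sequence as tidy CSV
#'
#' Long format with columns `frame, marker, x, y, z` plus a header-encoded
#' metadata comment line.
#' @param seq a `point_light_sequence`.
#' @param path file path.
#' @return `read_sequence_csv` returns the reconstructed sequence;
#'   `write_sequence_csv` the path, invisibly.
#' @export
write_sequence_csv <- function(seq, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# side=%s deviation_deg=%.10g n_frames=%d duration=%.10g",
                     seq$side, seq$deviation_deg, seq$n_frames, seq$duration), con)
  d <- data.frame(
    frame = rep(seq_len(seq$n_frames), each = 15),
    marker = rep(MARKER_NAMES, seq$n_frames),
    x = as.vector(seq$markers[, "x", ]),
    y = as.vector(seq$markers[, "y", ]),
    z = as.vector(seq$markers[, "z", ])
  )
  write.csv(d, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- setNames(sub(".*=", "", meta), sub("=.*", "", meta))
  d <- read.csv(path, comment.char = "#")
  n_frames <- as.integer(kv[["n_frames"]])
  m <- array(NA_real_, dim = c(15, 3, n_frames),
             dimnames = list(MARKER_NAMES, c("x", "y", "z"), NULL))
  for (f in seq_len(n_frames)) {
    rows <- d[d$frame == f, ]
    rows <- rows[match(MARKER_NAMES, rows$marker), ]
    m[, , f] <- as.matrix(rows[, c("x", "y", "z")])
  }
  structure(
    list(markers = m, side = kv[["side"]],
         deviation_deg = as.numeric(kv[["deviation_deg"]]),
         n_frames = n_frames, duration = as.numeric(kv[["duration"]]),
         frame_dt = as.numeric(kv[["duration"]]) / (n_frames - 1)),
    class = "point_light_sequence"
  )
}
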
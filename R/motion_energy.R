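# Layer 1: local motion-energy detectors, approximated by frame-pair optic
# flow binned onto a 36 x 31 receptive-field grid with four direction
# channels. The default path computes flow exactly from marker
# displacements (the marker positions are known); an image-based backend
# matches rendered dot centroids between frames.
#
# Sign convention (single constant, tested): flow is stored in image
# coordinates where y grows downward; the "up" channel pools -vy so that
# "up" always means upward in the world.

# Map image pixel coordinates to receptive-field grid cells.
px_to_cell <- function(x_px, y_px, cfg) {
  w <- cfg$stimulus$grid_px[[1]]; h <- cfg$stimulus$grid_px[[2]]
  col <- pmin(cfg$layer1$n_cols, pmax(1L, 1L + floor(x_px / w * cfg$layer1$n_cols)))
  row <- pmin(cfg$layer1$n_rows, pmax(1L, 1L + floor(y_px / h * cfg$layer1$n_rows)))
  list(row = as.integer(row), col = as.integer(col))
}

#' Frame-pair optic flow on the receptive-field grid
#'
#' For a `point_light_sequence` (preferred, exact path) each marker's
#' image-plane displacement between consecutive frames is assigned to the
#' grid cell containing the marker in the earlier frame; displacements of
#' several markers sharing a cell are averaged. For a rendered image stack,
#' dot centroids are detected per frame and matched greedily to the nearest
#' centroid of the next frame before the same binning.
#'
#' @param x a `point_light_sequence` or the array returned by
#'   [render_frames()].
#' @param cfg a [bm_config()].
#' @return object of class `flow_field_series`: list with `vx`, `vy`
#'   (arrays `n_rows x n_cols x n_pairs`, pixels per second, image-y down)
#'   and `dt` (the frame interval in seconds).
#' @export
optic_flow <- function(x, cfg = bm_config()) {
  if (inherits(x, "point_light_sequence")) {
    pr <- project_markers(x, cfg)
    dt <- x$frame_dt
    xs <- pr$x; ys <- pr$y
  } else if (is.array(x) && length(dim(x)) == 3) {
    dt <- attr(x, "frame_dt")
    if (is.null(dt)) stop("image stack lacks a frame_dt attribute")
    cents <- lapply(seq_len(dim(x)[3]), function(f) dot_centroids(x[, , f]))
    n <- min(vapply(cents, nrow, 1L))
    if (n == 0) stop("no dots detected in at least one frame")
    # greedy nearest-neighbour matching against the first frame's ordering
    xs <- matrix(NA_real_, n, dim(x)[3]); ys <- xs
    xs[, 1] <- cents[[1]][seq_len(n), 1]; ys[, 1] <- cents[[1]][seq_len(n), 2]
    for (f in 2:dim(x)[3]) {
      prev <- cbind(xs[, f - 1], ys[, f - 1]); cur <- cents[[f]]
      taken <- rep(FALSE, nrow(cur))
      for (m in seq_len(n)) {
        d2 <- (cur[, 1] - prev[m, 1])^2 + (cur[, 2] - prev[m, 2])^2
        d2[taken] <- Inf
        j <- which.min(d2); taken[j] <- TRUE
        xs[m, f] <- cur[j, 1]; ys[m, f] <- cur[j, 2]
      }
    }
  } else stop("x must be a point_light_sequence or a rendered image stack")

  n_frames <- ncol(xs)
  if (n_frames < 2) stop("need at least two frames")
  n_pairs <- n_frames - 1L
  nr <- cfg$layer1$n_rows; nc <- cfg$layer1$n_cols
  vx <- array(0, c(nr, nc, n_pairs)); vy <- array(0, c(nr, nc, n_pairs))
  for (p in seq_len(n_pairs)) {
    cell <- px_to_cell(xs[, p], ys[, p], cfg)
    dx <- (xs[, p + 1] - xs[, p]) / dt
    dy <- (ys[, p + 1] - ys[, p]) / dt
    idx <- cbind(cell$row, cell$col)
    key <- paste(cell$row, cell$col)
    for (k in unique(key)) {
      sel <- key == k
      i <- idx[which(sel)[1], , drop = FALSE]
      vx[i[1], i[2], p] <- mean(dx[sel])
      vy[i[1], i[2], p] <- mean(dy[sel])
    }
  }
  structure(list(vx = vx, vy = vy, dt = dt, n_pairs = n_pairs),
            class = "flow_field_series")
}

# Connected-component dot centroids of a binary frame (4-connectivity).
dot_centroids <- function(img) {
  lab <- matrix(0L, nrow(img), ncol(img))
  nxt <- 0L
  on <- which(img > 0.5, arr.ind = TRUE)
  for (i in seq_len(nrow(on))) {
    r <- on[i, 1]; c <- on[i, 2]
    if (lab[r, c] > 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c)); lab[r, c] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= nrow(img) && cc >= 1 && cc <= ncol(img) &&
            img[rr, cc] > 0.5 && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  if (nxt == 0L) return(matrix(numeric(0), 0, 2))
  t(vapply(seq_len(nxt), function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    c(mean(px[, 2]), mean(px[, 1])) # (x, y)
  }, numeric(2)))
}

#' Direction-channel responses of the motion-energy layer
#'
#' Half-rectified projection of each cell's flow vector onto the four
#' cardinal directions. Opposite channels are mutually exclusive by
#' construction: at most one of right/left and one of up/down is non-zero
#' per cell.
#'
#' @param flow a `flow_field_series` from [optic_flow()].
#' @return object of class `direction_activity`: list of arrays
#'   `right`, `left`, `up`, `down`, each `n_rows x n_cols x n_pairs`,
#'   all non-negative.
#' @export
direction_activity <- function(flow) {
  stopifnot(inherits(flow, "flow_field_series"))
  structure(list(
    right = pmax(flow$vx, 0),
    left  = pmax(-flow$vx, 0),
    up    = pmax(-flow$vy, 0), # image y grows downward
    down  = pmax(flow$vy, 0),
    dt = flow$dt, n_pairs = flow$n_pairs
  ), class = "direction_activity")
}
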
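# Layer 2: opponent-motion detectors. Four types (horizontal/vertical x
# expansion/contraction), each deployed as a 5 x 5 assembly over the
# 36 x 31 motion-energy grid, for 100 features per frame pair. A detector
# pools one direction channel in each of its two abutting subfields with a
# maximum operator and outputs the square root of the product of the two
# maxima, so both subfields must be active for a non-zero response
# (opponency) and the response is invariant to position within a subfield.
#
# Geometry: detector receptive fields overlap and tile the grid on a
# 5 x 5 lattice. A horizontal-type detector spans 12 columns split into
# two abutting 6-column subfields (left|right), at column positions
# {1-12, 7-18, 13-24, 19-30, 25-36} and row bands
# {1-7, 7-13, 13-19, 19-25, 25-31}. A vertical-type detector spans 10
# rows split into two abutting 5-row subfields (top|bottom) at row
# positions {1-10, 6-15, 11-20, 16-25, 22-31} and column bands
# {1-8, 8-15, 15-22, 22-29, 29-36}. Both lattices are exactly symmetric
# under left-right reflection of the grid (column c -> 37 - c maps
# detector column position j onto position 6 - j with its two subfields
# exchanged), so reflecting the stimulus maps every detector onto its
# mirror-position twin of the same type. Overlap widens the reach of the
# opponency beyond a disjoint partition, which a sparse 15-dot stimulus
# needs: opposing motions up to ~6 columns apart are still paired.

# Channel pairs per type: subfield A is the left (h types) or top (v
# types) subfield.  Expansion = motion away from the detector centre,
# contraction = motion toward it.
OPPONENT_TYPES <- list(
  h_expansion   = c(A = "left",  B = "right"),
  h_contraction = c(A = "right", B = "left"),
  v_expansion   = c(A = "up",    B = "down"),
  v_contraction = c(A = "down",  B = "up")
)

# Subfield-pair lattices (start column/row of subfield A; both subfields
# have the given width and abut).
H_COL_STARTS <- c(1L, 7L, 13L, 19L, 25L) # A = s..s+5, B = s+6..s+11
H_ROW_BANDS <- rbind(c(1L, 7L), c(7L, 13L), c(13L, 19L), c(19L, 25L), c(25L, 31L))
V_ROW_STARTS <- c(1L, 6L, 11L, 16L, 22L) # A = s..s+4, B = s+5..s+9
V_COL_BANDS <- rbind(c(1L, 8L), c(8L, 15L), c(15L, 22L), c(22L, 29L), c(29L, 36L))

#' Opponent-detector geometry
#'
#' Precomputes, for each of the 100 detectors, the grid-cell index sets of
#' its two subfields and the direction channel pooled in each. The
#' returned table also fixes the feature ordering used by [featurize()]:
#' type-major (`h_expansion`, `h_contraction`, `v_expansion`,
#' `v_contraction`), then row-major within each 5 x 5 assembly.
#'
#' @param cfg a [bm_config()].
#' @return object of class `opponent_config`: list of 100 detector
#'   descriptors plus the grid dimensions.
#' @export
opponent_config <- function(cfg = bm_config()) {
  nr <- cfg$layer1$n_rows; nc <- cfg$layer1$n_cols
  stopifnot(nr == 31L, nc == 36L) # geometry below is for the default grid

  cell_id <- function(rows, cols) {
    as.vector(outer(rows, (cols - 1L) * nr, `+`)) # column-major cell ids
  }
  dets <- list()
  for (type in names(OPPONENT_TYPES)) {
    ch <- OPPONENT_TYPES[[type]]
    for (br in 1:5) for (bc in 1:5) {
      if (startsWith(type, "h")) {
        rows <- H_ROW_BANDS[br, 1]:H_ROW_BANDS[br, 2]
        s <- H_COL_STARTS[bc]
        cellsA <- cell_id(rows, s:(s + 5L))
        cellsB <- cell_id(rows, (s + 6L):(s + 11L))
      } else {
        cols <- V_COL_BANDS[bc, 1]:V_COL_BANDS[bc, 2]
        s <- V_ROW_STARTS[br]
        cellsA <- cell_id(s:(s + 4L), cols)
        cellsB <- cell_id((s + 5L):(s + 9L), cols)
      }
      dets[[length(dets) + 1L]] <- list(
        type = type, row = br, col = bc,
        cellsA = cellsA, cellsB = cellsB,
        chA = ch[["A"]], chB = ch[["B"]]
      )
    }
  }
  structure(list(detectors = dets, n_rows = nr, n_cols = nc,
                 n_features = length(dets)),
            class = "opponent_config")
}

#' Response of one opponent-motion detector
#'
#' `sqrt(max over subfield A of its channel x max over subfield B of its
#' channel)`; zero whenever either subfield is silent.
#'
#' @param act a `direction_activity` (single frame pair: pass `pair`).
#' @param detector one element of `opponent_config()$detectors`.
#' @param pair frame-pair index into `act`.
#' @return non-negative scalar.
#' @export
opponent_response <- function(act, detector, pair = 1L) {
  a <- act[[detector$chA]][, , pair][detector$cellsA]
  b <- act[[detector$chB]][, , pair][detector$cellsB]
  sqrt(max(a) * max(b))
}

#' Opponent-motion feature series u(t)
#'
#' Evaluates all 100 opponent detectors for every frame pair and returns
#' the feature matrix fed to the optic-flow-pattern layer.
#'
#' @param x a `point_light_sequence`, `flow_field_series` or
#'   `direction_activity`.
#' @param cfg a [bm_config()].
#' @param ocfg optionally a precomputed [opponent_config()].
#' @return matrix `n_pairs x 100` of non-negative responses, with
#'   attribute `dt`; column names encode `type.row.col`.
#' @export
featurize <- function(x, cfg = bm_config(), ocfg = opponent_config(cfg)) {
  if (inherits(x, "point_light_sequence")) x <- optic_flow(x, cfg)
  if (inherits(x, "flow_field_series")) x <- direction_activity(x)
  stopifnot(inherits(x, "direction_activity"))
  np <- x$n_pairs
  U <- matrix(0, np, ocfg$n_features)
  colnames(U) <- vapply(ocfg$detectors, function(d)
    paste(d$type, d$row, d$col, sep = "."), "")
  for (p in seq_len(np)) {
    ch <- lapply(x[c("right", "left", "up", "down")], function(a) a[, , p])
    U[p, ] <- vapply(ocfg$detectors, function(d) {
      sqrt(max(ch[[d$chA]][d$cellsA]) * max(ch[[d$chB]][d$cellsB]))
    }, numeric(1))
  }
  attr(U, "dt") <- x$dt
  U
}
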
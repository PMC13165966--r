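#' Serpentine scan grid
#'
#' Describes a rows x cols lateral scan with a fixed centre-to-centre stage
#' step, visited row by row with alternating direction starting from the
#' upper-left cell (the usual serpentine pattern of motorised x-y stages).
#' Tiles must overlap: `step < tile_side_px * pitch`.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param step centre-to-centre displacement in metres.
#' @param tile_side_px side of a (square) tile in pixels.
#' @param pitch pixel pitch in metres.
#' @return Object of class `scan_grid` with the visiting `order` (a
#'   two-column matrix of 0-based `(row, col)` indices) and the nominal
#'   `overlap` ratio `1 - step / (tile_side_px * pitch)`.
#' @export
scan_grid <- function(rows, cols, step, tile_side_px, pitch) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  stopifnot(rows >= 1L, cols >= 1L, tile_side_px >= 2L)
  .check_positive_scalar(step, "step")
  .check_positive_scalar(pitch, "pitch")
  side_m <- tile_side_px * pitch
  if (step >= side_m)
    stop(sprintf("step (%.3g m) must be smaller than the tile side (%.3g m): tiles must overlap",
                 step, side_m))
  ord <- serpentine_order(rows, cols)
  structure(
    list(rows = rows, cols = cols, step = step,
         tile_side_px = as.integer(tile_side_px), pitch = pitch,
         order = ord, overlap = 1 - step / side_m),
    class = "scan_grid"
  )
}

#' @export
print.scan_grid <- function(x, ...) {
  cat(sprintf(
    "<scan_grid> %d x %d serpentine, step %.3g mm, tile %d px, overlap %.1f%%\n",
    x$rows, x$cols, x$step * 1e3, x$tile_side_px, 100 * x$overlap))
  invisible(x)
}

#' Serpentine visiting order
#'
#' Row-by-row raster with alternating direction, starting at the upper-left
#' cell: even rows left-to-right, odd rows right-to-left.
#'
#' @param rows,cols grid dimensions.
#' @return Integer matrix, one `(row, col)` 0-based pair per visit.
#' @export
serpentine_order <- function(rows, cols) {
  out <- matrix(0L, rows * cols, 2, dimnames = list(NULL, c("row", "col")))
  k <- 1L
  for (r in 0:(rows - 1L)) {
    cs <- if (r %% 2L == 0L) 0:(cols - 1L) else (cols - 1L):0
    for (cc in cs) {
      out[k, ] <- c(r, cc)
      k <- k + 1L
    }
  }
  out
}

#' Single recorded hologram tile
#'
#' A nonnegative amplitude image plus acquisition metadata: grid indices,
#' stage position and axial plane.
#'
#' @param amplitude nonnegative numeric matrix.
#' @param pitch pixel pitch in metres.
#' @param z sensor distance in metres.
#' @param z_index 1-based index of the axial plane.
#' @param grid_row,grid_col 0-based scan grid indices.
#' @param stage_x,stage_y stage position in metres.
#' @return Object of class `hologram`.
#' @export
hologram <- function(amplitude, pitch, z, z_index = 1L,
                     grid_row = 0L, grid_col = 0L,
                     stage_x = 0, stage_y = 0) {
  if (!is.matrix(amplitude) || !is.numeric(amplitude))
    stop("'amplitude' must be a numeric matrix")
  if (any(!is.finite(amplitude)) || any(amplitude < 0))
    stop("'amplitude' must be finite and nonnegative")
  .check_positive_scalar(pitch, "pitch")
  structure(
    list(amplitude = amplitude, pitch = pitch, z = z,
         z_index = as.integer(z_index),
         grid_row = as.integer(grid_row), grid_col = as.integer(grid_col),
         stage_x = stage_x, stage_y = stage_y),
    class = "hologram"
  )
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf(
    "<hologram> %d x %d px @ (row %d, col %d), z[%d] = %.4g mm, pitch %.3g um\n",
    nrow(x$amplitude), ncol(x$amplitude), x$grid_row, x$grid_col,
    x$z_index, x$z * 1e3, x$pitch * 1e6))
  invisible(x)
}

#' @export
dim.hologram <- function(x) dim(x$amplitude)

#' Three-bar resolution-chart line width
#'
#' Line width in micrometres of a USAF-1951 chart element:
#' `500 / 2^(group + (element - 1)/6)` um (the chart's resolution is
#' `2^(group + (element - 1)/6)` line pairs per mm).
#'
#' @param group chart group number (integer, may be negative).
#' @param element element number, 1..6.
#' @return Line width in micrometres.
#' @export
usaf_linewidth <- function(group, element) {
  if (any(element < 1 | element > 6) || any(element != round(element)))
    stop("'element' must be an integer in 1..6")
  500 / 2^(group + (element - 1) / 6)
}

#' Draw a three-bar resolution target
#'
#' Renders selected chart elements onto a transmission map: background
#' transmission 1, bars 0 (amplitude target). Each element draws the
#' standard pattern in both orientations: three vertical bars of width `w`
#' and length `5 w` separated by gaps `w`, and, alongside, three horizontal
#' bars of the same geometry. `w = usaf_linewidth(group, element)` converted
#' to pixels at the given pitch (rounded to the nearest pixel).
#'
#' The returned map carries an `elements` attribute: one record per element
#' with its pixel line width and ready-made profile lines (one crossing the
#' vertical bars horizontally, one crossing the horizontal bars vertically)
#' for contrast analysis.
#'
#' @param canvas_px integer vector `c(rows, cols)`.
#' @param pitch pixel pitch in metres.
#' @param elements list of `list(group =, element =, at = c(row, col))`
#'   entries; `at` is the 1-based upper-left pixel of the element block.
#' @param phase_delay if nonzero, produce a phase target instead: complex
#'   map with unit modulus and phase `phase_delay` (radians) on the bars.
#' @return Transmission matrix (numeric in `[0, 1]`, or complex when
#'   `phase_delay != 0`) with attribute `elements`.
#' @export
generate_bar_target <- function(canvas_px, pitch, elements = list(),
                                phase_delay = 0) {
  nr <- as.integer(canvas_px[1]); nc <- as.integer(canvas_px[2])
  .check_positive_scalar(pitch, "pitch")
  bars <- matrix(FALSE, nr, nc)
  meta <- list()
  for (el in elements) {
    g <- el$group; e <- el$element
    w_um <- usaf_linewidth(g, e)
    w <- as.integer(round(w_um * 1e-6 / pitch))
    if (w < 2L)
      stop(sprintf(
        "element G%dE%d (%.2f um) maps to %d px at pitch %.3g um: need >= 2 px",
        g, e, w_um, w, pitch * 1e6))
    r0 <- as.integer(el$at[1]); c0 <- as.integer(el$at[2])
    # vertical bars: rows r0..r0+5w-1, cols r0 + {0, 2w, 4w}, width w
    # horizontal bars: offset 6w to the right, transposed geometry
    need_r <- r0 + 5L * w - 1L
    need_c <- c0 + 11L * w - 1L
    if (r0 < 1L || c0 < 1L || need_r > nr || need_c > nc)
      stop(sprintf("element G%dE%d does not fit on the canvas", g, e))
    for (k in 0:2) {
      cs <- c0 + 2L * k * w
      bars[r0:(r0 + 5L * w - 1L), cs:(cs + w - 1L)] <- TRUE
    }
    ch <- c0 + 6L * w
    for (k in 0:2) {
      rs <- r0 + 2L * k * w
      bars[rs:(rs + w - 1L), ch:(ch + 5L * w - 1L)] <- TRUE
    }
    mid_r <- r0 + as.integer(round(2.5 * w))
    mid_c <- ch + as.integer(round(2.5 * w))
    pad <- 2L * w
    meta[[length(meta) + 1L]] <- list(
      group = g, element = e, linewidth_px = w, linewidth_um = w_um,
      profile_v_bars = list(start = c(mid_r, max(1L, c0 - pad)),
                            end = c(mid_r, min(nc, c0 + 5L * w - 1L + pad))),
      profile_h_bars = list(start = c(max(1L, r0 - pad), mid_c),
                            end = c(min(nr, r0 + 5L * w - 1L + pad), mid_c))
    )
  }
  tmap <- matrix(1, nr, nc)
  if (phase_delay != 0) {
    tmap <- matrix(1 + 0i, nr, nc)
    tmap[bars] <- exp(1i * phase_delay)
  } else {
    tmap[bars] <- 0
  }
  attr(tmap, "elements") <- meta
  tmap
}

#' Smooth blob phantom
#'
#' Complex transmission map for testing retrieval: Gaussian absorption dips
#' (amplitude) and Gaussian phase bumps on a unit background. Deterministic
#' given the blob table.
#'
#' @param canvas_px `c(rows, cols)`.
#' @param blobs data frame with columns `row`, `col`, `sigma_px`,
#'   `absorption` (0..1) and `phase` (radians); one row per blob.
#' @return Complex matrix.
#' @export
blob_phantom <- function(canvas_px, blobs) {
  nr <- as.integer(canvas_px[1]); nc <- as.integer(canvas_px[2])
  amp <- matrix(1, nr, nc)
  phs <- matrix(0, nr, nc)
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(blobs))) {
    g <- exp(-((rr - blobs$row[i])^2 + (cc - blobs$col[i])^2) /
               (2 * blobs$sigma_px[i]^2))
    amp <- amp * (1 - blobs$absorption[i] * g)
    phs <- phs + blobs$phase[i] * g
  }
  amp * exp(1i * phs)
}

#' Simulate one in-line hologram
#'
#' Forward model for lensless in-line recording: unit plane-wave
#' illumination of the object transmission map, angular-spectrum propagation
#' over the object-to-sensor distance `z`, and recording of the field
#' amplitude `|U|`. Optional additive Gaussian amplitude noise, clipped at
#' zero; `noise_sigma = 0` is exactly deterministic.
#'
#' @param object_map complex (or numeric) transmission matrix.
#' @param config an [optical_config()] supplying wavelength and pitch.
#' @param z sensor distance in metres.
#' @param noise_sigma standard deviation of additive amplitude noise.
#' @param seed integer seed used when `noise_sigma > 0`.
#' @param z_index,grid_row,grid_col,stage_x,stage_y metadata passed through
#'   to the [hologram()].
#' @param band_limited propagation band-limiting mode, see [propagate()].
#' @return A [hologram()].
#' @export
simulate_hologram <- function(object_map, config, z, noise_sigma = 0,
                              seed = 1L, z_index = 1L,
                              grid_row = 0L, grid_col = 0L,
                              stage_x = 0, stage_y = 0,
                              band_limited = "auto") {
  stopifnot(inherits(config, "optical_config"))
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  f0 <- complex_field(as.matrix(object_map), config$pitch, config$wavelength, 0)
  amp <- Mod(propagate(f0, z, band_limited = band_limited)$values)
  if (noise_sigma > 0) {
    old <- .save_rng_state()
    on.exit(.restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    amp <- amp + matrix(stats::rnorm(length(amp), 0, noise_sigma),
                        nrow(amp), ncol(amp))
    amp[amp < 0] <- 0
  }
  hologram(amp, config$pitch, z, z_index = z_index,
           grid_row = grid_row, grid_col = grid_col,
           stage_x = stage_x, stage_y = stage_y)
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Simulate a multi-FOV, multi-depth scan
#'
#' Emulates serpentine x-y scanning of the sample at each of the configured
#' axial planes. The full object is propagated once per plane and each tile
#' is a window of that full-field hologram at the tile's stage offset --
#' physically equivalent to shifting the sample under fixed illumination,
#' and guaranteeing that adjacent tiles agree exactly on their geometric
#' overlap (the property pairwise registration relies on). The ground-truth
#' inter-tile pixel shift `step / pitch` is recorded in the manifest.
#'
#' `step` must be an integer multiple of the pitch (integer-pixel scanning,
#' as for a stage commanded in whole steps).
#'
#' @param object_map complex transmission map; must cover
#'   `tile_side_px + (rows-1 or cols-1) * step/pitch` pixels per axis.
#' @param grid a [scan_grid()].
#' @param config an [optical_config()]; all its `z_planes` are recorded.
#' @param noise_sigma,seed amplitude noise, as in [simulate_hologram()];
#'   each tile uses an independent substream derived from `seed`.
#' @param band_limited propagation mode, see [propagate()].
#' @return List with `holograms` (tiles in serpentine acquisition order,
#'   planes innermost), `manifest` (data frame: grid_row, grid_col,
#'   stage_x_mm, stage_y_mm, z_index, z_mm, shift_px), and
#'   `full_fields` (one full-field amplitude matrix per plane, the
#'   stitching oracle).
#' @export
simulate_scan <- function(object_map, grid, config, noise_sigma = 0,
                          seed = 1L, band_limited = "auto") {
  stopifnot(inherits(grid, "scan_grid"), inherits(config, "optical_config"))
  step_px <- grid$step / config$pitch
  if (abs(step_px - round(step_px)) > 1e-9)
    stop("grid step must be an integer multiple of the pixel pitch")
  step_px <- as.integer(round(step_px))
  side <- grid$tile_side_px
  need_r <- side + (grid$rows - 1L) * step_px
  need_c <- side + (grid$cols - 1L) * step_px
  om <- as.matrix(object_map)
  if (nrow(om) < need_r || ncol(om) < need_c)
    stop(sprintf("object too small: need at least %d x %d px, got %d x %d",
                 need_r, need_c, nrow(om), ncol(om)))

  f0 <- complex_field(om, config$pitch, config$wavelength, 0)
  full_fields <- lapply(config$z_planes, function(z)
    Mod(propagate(f0, z, band_limited = band_limited)$values))

  holos <- list()
  man <- list()
  tile_i <- 0L
  for (v in seq_len(nrow(grid$order))) {
    r <- grid$order[v, 1]; cc <- grid$order[v, 2]
    r0 <- r * step_px; c0 <- cc * step_px
    for (k in seq_along(config$z_planes)) {
      tile_i <- tile_i + 1L
      amp <- full_fields[[k]][(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side)]
      if (noise_sigma > 0) {
        old <- .save_rng_state()
        set.seed(as.integer(seed) + tile_i)
        amp <- amp + matrix(stats::rnorm(length(amp), 0, noise_sigma),
                            side, side)
        amp[amp < 0] <- 0
        .restore_rng_state(old)
      }
      holos[[tile_i]] <- hologram(
        amp, config$pitch, config$z_planes[k], z_index = k,
        grid_row = r, grid_col = cc,
        stage_x = cc * grid$step, stage_y = r * grid$step)
      man[[tile_i]] <- data.frame(
        grid_row = r, grid_col = cc,
        stage_x_mm = cc * grid$step * 1e3,
        stage_y_mm = r * grid$step * 1e3,
        z_index = k, z_mm = config$z_planes[k] * 1e3,
        shift_px = step_px)
    }
  }
  list(holograms = holos, manifest = do.call(rbind, man),
       full_fields = full_fields)
}
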
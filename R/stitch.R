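#' Adjacency topology of a scan lattice
#'
#' From the manifest of one z-plane, lists every 4-neighbour pair of tiles
#' (horizontal and vertical): `rows (cols-1) + cols (rows-1)` pairs for a
#' full rows x cols lattice.
#'
#' @param manifest data frame with integer columns `grid_row`, `grid_col`
#'   (0-based) describing one z-plane; one row per tile.
#' @return Data frame with columns `a`, `b` (row indices into `manifest`),
#'   `a_row`, `a_col`, `b_row`, `b_col` and `direction` (`"h"` when `b` is
#'   the right neighbour of `a`, `"v"` when below).
#' @export
build_topology <- function(manifest) {
  gr <- manifest$grid_row; gc <- manifest$grid_col
  if (anyDuplicated(paste(gr, gc)))
    stop("duplicate (grid_row, grid_col) cells in manifest")
  rows <- max(gr) + 1L; cols <- max(gc) + 1L
  want <- expand.grid(row = 0:(rows - 1L), col = 0:(cols - 1L))
  have <- paste(gr, gc)
  missing <- want[!(paste(want$row, want$col) %in% have), , drop = FALSE]
  if (nrow(missing) > 0)
    stop(sprintf("manifest lattice incomplete; missing cells: %s",
                 paste(sprintf("(%d,%d)", missing$row, missing$col),
                       collapse = ", ")))
  idx <- integer(rows * cols)
  idx[gr * cols + gc + 1L] <- seq_along(gr)
  pairs <- list()
  for (r in 0:(rows - 1L)) for (cc in 0:(cols - 1L)) {
    a <- idx[r * cols + cc + 1L]
    if (cc + 1L < cols) {
      b <- idx[r * cols + cc + 2L]
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = a, b = b, a_row = r, a_col = cc, b_row = r, b_col = cc + 1L,
        direction = "h")
    }
    if (r + 1L < rows) {
      b <- idx[(r + 1L) * cols + cc + 1L]
      pairs[[length(pairs) + 1L]] <- data.frame(
        a = a, b = b, a_row = r, a_col = cc, b_row = r + 1L, b_col = cc,
        direction = "v")
    }
  }
  if (length(pairs) == 0)
    return(data.frame(a = integer(), b = integer(), a_row = integer(),
                      a_col = integer(), b_row = integer(),
                      b_col = integer(), direction = character()))
  do.call(rbind, pairs)
}

#' Overlap regions of interest for an adjacent tile pair
#'
#' Computes matching ROI windows on the theoretical overlap strip of two
#' adjacent tiles, expanded by a search margin (a fraction of the tile
#' side) on each free edge to absorb stage positioning error, and clamped
#' to the tile. Both ROIs have equal size.
#'
#' @param dims_a,dims_b tile dimensions `c(rows, cols)` (must be equal).
#' @param direction `"h"` (B right of A) or `"v"` (B below A).
#' @param nominal_overlap overlap ratio in (0, 1).
#' @param margin search margin as a fraction of the tile side (default
#'   0.10, i.e. roughly +/-10%).
#' @return List with `a` and `b`, each `list(rows = c(lo, hi),
#'   cols = c(lo, hi))` 1-based inclusive bounds, plus 0-based pixel
#'   `offset_a`, `offset_b` of the ROI origins within their tiles.
#' @export
extract_overlap_rois <- function(dims_a, dims_b, direction,
                                 nominal_overlap, margin = 0.10) {
  if (!identical(as.integer(dims_a), as.integer(dims_b)))
    stop("adjacent tiles must have equal dimensions")
  if (nominal_overlap <= 0 || nominal_overlap >= 1)
    stop("'nominal_overlap' must be in (0, 1)")
  nr <- as.integer(dims_a[1]); nc <- as.integer(dims_a[2])
  side <- if (direction == "h") nc else nr
  ov <- as.integer(round(nominal_overlap * side))
  mg <- as.integer(round(margin * side))
  ext <- min(side, ov + mg)  # strip width after one-sided margin, clamped
  if (ext < 16L)
    stop(sprintf("overlap ROI only %d px wide (< 16 px): overlap too small",
                 ext))
  if (direction == "h") {
    a <- list(rows = c(1L, nr), cols = c(nc - ext + 1L, nc))
    b <- list(rows = c(1L, nr), cols = c(1L, ext))
  } else if (direction == "v") {
    a <- list(rows = c(nr - ext + 1L, nr), cols = c(1L, nc))
    b <- list(rows = c(1L, ext), cols = c(1L, nc))
  } else stop("'direction' must be \"h\" or \"v\"")
  list(a = a, b = b,
       offset_a = c(a$rows[1] - 1L, a$cols[1] - 1L),
       offset_b = c(b$rows[1] - 1L, b$cols[1] - 1L))
}

.crop_roi <- function(mat, roi) {
  mat[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2], drop = FALSE]
}

.empty_match_set <- function(name) {
  out <- list(correspondences = data.frame(
    ay = numeric(), ax = numeric(), by = numeric(), bx = numeric(),
    confidence = numeric()), matcher_name = name)
  class(out) <- "match_set"
  out
}

# Sums of M over all h x w windows (integral image), (nr-h+1) x (nc-w+1).
.window_sums <- function(m, h, w) {
  s <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed SAT
  s <- t(s)
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 1L, nc + 1L)
  pad[-1L, -1L] <- s
  r1 <- (h + 1L):(nr + 1L); r0 <- 1L:(nr - h + 1L)
  c1 <- (w + 1L):(nc + 1L); c0 <- 1L:(nc - w + 1L)
  pad[r1, c1, drop = FALSE] - pad[r0, c1, drop = FALSE] -
    pad[r1, c0, drop = FALSE] + pad[r0, c0, drop = FALSE]
}

#' Windowed normalized cross-correlation matcher
#'
#' Default classical matcher. Square templates are taken from ROI A on a
#' regular grid and each is located in ROI B by fast normalized
#' cross-correlation (FFT cross-correlation with integral-image local
#' normalization). Each template yields one correspondence whose NCC peak
#' value serves as the confidence; on simulated scans, templates lying in
#' the true geometric overlap match exactly (peak 1), and the few partial
#' templates produce outliers that the displacement voting discards.
#' Constant ROIs yield an empty match set.
#'
#' @param roi_a,roi_b equal-size numeric matrices.
#' @param patch_px template side in pixels (default 64, shrunk to fit).
#' @return A `match_set`: list with `correspondences` (data frame columns
#'   `ay, ax, by, bx, confidence`; points are 1-based ROI coordinates) and
#'   `matcher_name`.
#' @export
match_patches_ncc <- function(roi_a, roi_b, patch_px = 64L) {
  if (!all(dim(roi_a) == dim(roi_b))) stop("ROIs must have equal size")
  if (stats::sd(roi_a) == 0 || stats::sd(roi_b) == 0)
    return(.empty_match_set("ncc"))
  nr <- nrow(roi_a); nc <- ncol(roi_a)
  p <- min(patch_px, nr, nc)
  fb <- stats::fft(roi_b)
  s1 <- .window_sums(roi_b, p, p)
  s2 <- .window_sums(roi_b^2, p, p)
  npx <- p * p
  var_b <- pmax(s2 - s1^2 / npx, 0)
  rows0 <- unique(pmin(seq(1L, nr, by = p), nr - p + 1L))
  cols0 <- unique(pmin(seq(1L, nc, by = p), nc - p + 1L))
  recs <- list()
  for (r0 in rows0) for (c0 in cols0) {
    tmpl <- roi_a[r0:(r0 + p - 1L), c0:(c0 + p - 1L)]
    t0 <- tmpl - mean(tmpl)
    ss_t <- sum(t0^2)
    if (ss_t == 0) next
    t_pad <- matrix(0, nr, nc)
    t_pad[1:p, 1:p] <- t0
    cross <- Re(stats::fft(Conj(stats::fft(t_pad)) * fb,
                           inverse = TRUE)) / (nr * nc)
    cross <- cross[1:(nr - p + 1L), 1:(nc - p + 1L), drop = FALSE]
    denom <- sqrt(ss_t * var_b)
    floor_ <- sqrt(ss_t) * 1e-9
    ncc <- cross / pmax(denom, floor_)
    ncc[denom <= floor_] <- 0
    pk <- arrayInd(which.max(ncc), dim(ncc))
    half <- (p - 1) / 2
    recs[[length(recs) + 1L]] <- data.frame(
      ay = r0 + half, ax = c0 + half,
      by = pk[1] + half, bx = pk[2] + half,
      confidence = max(0, min(1, ncc[pk])))
  }
  if (length(recs) == 0) return(.empty_match_set("ncc"))
  out <- list(correspondences = do.call(rbind, recs), matcher_name = "ncc")
  class(out) <- "match_set"
  out
}

#' Patchwise phase-correlation matcher
#'
#' Alternative matcher: co-located patch pairs are registered by whitened
#' phase correlation; the (wrapped) peak height is the confidence. Faster
#' than [match_patches_ncc()] but less discriminative on smooth,
#' self-similar diffraction fringes; kept for fringe-rich content and as a
#' second implementation of the matcher contract.
#'
#' @inheritParams match_patches_ncc
#' @return A `match_set`.
#' @export
match_patches_phasecorr <- function(roi_a, roi_b, patch_px = 64L) {
  if (!all(dim(roi_a) == dim(roi_b))) stop("ROIs must have equal size")
  if (stats::sd(roi_a) == 0 || stats::sd(roi_b) == 0)
    return(.empty_match_set("phasecorr"))
  nr <- nrow(roi_a); nc <- ncol(roi_a)
  p <- min(patch_px, nr, nc)
  rows0 <- unique(pmin(seq(1L, nr, by = p), nr - p + 1L))
  cols0 <- unique(pmin(seq(1L, nc, by = p), nc - p + 1L))
  recs <- list()
  for (r0 in rows0) for (c0 in cols0) {
    pa <- roi_a[r0:(r0 + p - 1L), c0:(c0 + p - 1L)]
    pb <- roi_b[r0:(r0 + p - 1L), c0:(c0 + p - 1L)]
    if (stats::sd(pa) == 0 || stats::sd(pb) == 0) next
    d <- .phase_correlate(pa - mean(pa), pb - mean(pb))
    ctr <- c(r0 + (p - 1) / 2, c0 + (p - 1) / 2)
    recs[[length(recs) + 1L]] <- data.frame(
      ay = ctr[1] + d$dy, ax = ctr[2] + d$dx,
      by = ctr[1], bx = ctr[2], confidence = d$peak)
  }
  if (length(recs) == 0) return(.empty_match_set("phasecorr"))
  out <- list(correspondences = do.call(rbind, recs),
              matcher_name = "phasecorr")
  class(out) <- "match_set"
  out
}

# Phase correlation of two equal-size patches. Returns the displacement d
# such that content of B at p appears in A at p + d (wrapped to the
# centred range), and the normalized peak height.
.phase_correlate <- function(a, b) {
  fa <- stats::fft(a); fb <- stats::fft(b)
  cross <- fa * Conj(fb)
  m <- Mod(cross)
  cross <- cross / pmax(m, .Machine$double.eps)
  surf <- Re(stats::fft(cross, inverse = TRUE)) / length(a)
  pk <- which.max(surf)
  nr <- nrow(a); nc <- ncol(a)
  dy <- (pk - 1L) %% nr
  dx <- (pk - 1L) %/% nr
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  list(dy = dy, dx = dx, peak = min(1, max(0, surf[pk])))
}

#' Robust pair shift from a match set
#'
#' Turns the per-correspondence displacement vectors into one integer pair
#' shift: the component-wise median is taken as an initial estimate,
#' vectors farther than `max(3 MAD, 5) px` from it are discarded as
#' outliers, survivors are accumulated on a 2-D histogram with `bin_px`
#' bins, and the centre of the winning bin is returned (ties broken toward
#' the median).
#'
#' Displacements are `(point in A) - (point in B)` translated to the tile
#' frames via the ROI offsets, so the result is the position of tile B's
#' origin in tile A's pixel frame.
#'
#' @param matches a `match_set` from [match_patches_phasecorr()] (or any
#'   matcher honouring the same contract).
#' @param offset_a,offset_b 0-based ROI origins within the tiles, from
#'   [extract_overlap_rois()].
#' @param bin_px histogram bin width in pixels.
#' @return A `shift_estimate`: list with integer `dy`, `dx`, `votes`,
#'   `support_fraction` and `n_total`.
#' @export
estimate_pair_shift <- function(matches, offset_a = c(0L, 0L),
                                offset_b = c(0L, 0L), bin_px = 1L) {
  cm <- matches$correspondences
  n <- nrow(cm)
  if (n == 0) stop("empty match set: no correspondences to vote on")
  vy <- (cm$ay + offset_a[1]) - (cm$by + offset_b[1])
  vx <- (cm$ax + offset_a[2]) - (cm$bx + offset_b[2])
  med <- c(stats::median(vy), stats::median(vx))
  dist <- sqrt((vy - med[1])^2 + (vx - med[2])^2)
  radius <- max(3 * stats::median(dist), 5)
  keep <- dist <= radius
  vy <- vy[keep]; vx <- vx[keep]
  by_ <- round(vy / bin_px); bx_ <- round(vx / bin_px)
  key <- paste(by_, bx_)
  tab <- table(key)
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if (length(winners) > 1L) {
    cen <- do.call(rbind, lapply(strsplit(winners, " "), as.numeric)) * bin_px
    d2 <- (cen[, 1] - med[1])^2 + (cen[, 2] - med[2])^2
    winners <- winners[which.min(d2)]
  }
  w <- as.numeric(strsplit(winners, " ")[[1]]) * bin_px
  out <- list(dy = as.integer(round(w[1])), dx = as.integer(round(w[2])),
              votes = as.integer(top),
              support_fraction = as.integer(top) / n, n_total = n)
  class(out) <- "shift_estimate"
  out
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> (dy, dx) = (%d, %d), votes %d/%d (support %.2f)\n",
              x$dy, x$dx, x$votes, x$n_total, x$support_fraction))
  invisible(x)
}

#' Global alignment of tiles from pairwise shifts
#'
#' Places every tile in a common pixel frame by integer least squares over
#' all pairwise constraints `pos_b - pos_a = (dy, dx)`, anchoring the first
#' tile at (0, 0). Redundant loop constraints are reconciled by the
#' least-squares solve (each axis is an independent linear system on the
#' pair-constraint incidence matrix). Positions are then offset so the
#' canvas origin is (0, 0), and a per-pixel coverage count is built.
#'
#' @param shifts list of `shift_estimate`s, one per topology row.
#' @param topology data frame from [build_topology()] (columns `a`, `b`).
#' @param n_tiles number of tiles.
#' @param tile_dims tile dimensions `c(rows, cols)`.
#' @return A `mosaic_layout`: list with `positions` (n x 2 integer matrix
#'   of 0-based upper-left corners), `canvas` (`c(rows, cols)`),
#'   `coverage` (integer matrix) and `anchor_offset` (position of the
#'   anchor tile on the canvas).
#' @export
global_align <- function(shifts, topology, n_tiles, tile_dims) {
  stopifnot(length(shifts) == nrow(topology), n_tiles >= 1)
  # connectivity
  adj <- lapply(seq_len(n_tiles), function(i) integer())
  for (k in seq_len(nrow(topology))) {
    a <- topology$a[k]; b <- topology$b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n_tiles)
  queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- adj[[v]][!seen[adj[[v]]]]
    seen[nb] <- TRUE; queue <- c(queue, nb)
  }
  if (!all(seen))
    stop(sprintf("pair-shift graph is disconnected; unreachable tiles: %s",
                 paste(which(!seen), collapse = ", ")))
  pos <- matrix(0, n_tiles, 2)
  if (n_tiles > 1L) {
    np <- nrow(topology)
    A <- matrix(0, np, n_tiles - 1L)
    rhs_y <- numeric(np); rhs_x <- numeric(np)
    for (k in seq_len(np)) {
      a <- topology$a[k]; b <- topology$b[k]
      if (a != 1L) A[k, a - 1L] <- -1
      if (b != 1L) A[k, b - 1L] <- 1
      rhs_y[k] <- shifts[[k]]$dy; rhs_x[k] <- shifts[[k]]$dx
    }
    sol_y <- stats::lsfit(A, rhs_y, intercept = FALSE)$coefficients
    sol_x <- stats::lsfit(A, rhs_x, intercept = FALSE)$coefficients
    pos[-1L, 1] <- sol_y
    pos[-1L, 2] <- sol_x
  }
  pos <- round(pos)
  off <- apply(pos, 2, min)
  pos <- sweep(pos, 2, off)
  storage.mode(pos) <- "integer"
  canvas <- c(max(pos[, 1]) + tile_dims[1], max(pos[, 2]) + tile_dims[2])
  coverage <- matrix(0L, canvas[1], canvas[2])
  for (i in seq_len(n_tiles)) {
    rr <- (pos[i, 1] + 1L):(pos[i, 1] + tile_dims[1])
    cc <- (pos[i, 2] + 1L):(pos[i, 2] + tile_dims[2])
    coverage[rr, cc] <- coverage[rr, cc] + 1L
  }
  out <- list(positions = pos, canvas = as.integer(canvas),
              coverage = coverage, tile_dims = as.integer(tile_dims),
              anchor_offset = as.integer(-off))
  class(out) <- "mosaic_layout"
  out
}

#' @export
print.mosaic_layout <- function(x, ...) {
  cat(sprintf("<mosaic_layout> %d tile(s) on a %d x %d canvas\n",
              nrow(x$positions), x$canvas[1], x$canvas[2]))
  invisible(x)
}

#' Largest fully covered rectangle
#'
#' Finds the largest axis-aligned rectangle whose every pixel has coverage
#' >= 1 (the classic maximal-rectangle-in-binary-mask problem, solved by
#' per-row histograms of covered run heights), and crops the canvas to it.
#'
#' @param canvas numeric matrix.
#' @param coverage_mask integer matrix of per-pixel contributing-tile
#'   counts, same size as `canvas`.
#' @return List with `cropped` (submatrix) and `bounds`
#'   (`c(row_lo, row_hi, col_lo, col_hi)`, 1-based inclusive).
#' @export
auto_crop <- function(canvas, coverage_mask) {
  stopifnot(all(dim(canvas) == dim(coverage_mask)))
  cov <- coverage_mask >= 1L
  if (!any(cov)) stop("coverage mask is empty")
  nr <- nrow(cov); nc <- ncol(cov)
  heights <- integer(nc)
  best <- c(area = 0L, r0 = 0L, r1 = 0L, c0 = 0L, c1 = 0L)
  for (r in seq_len(nr)) {
    heights <- ifelse(cov[r, ], heights + 1L, 0L)
    # largest rectangle in histogram (monotonic stack)
    stack_c <- integer(0); stack_h <- integer(0)
    for (cc in seq_len(nc + 1L)) {
      h <- if (cc <= nc) heights[cc] else 0L
      start <- cc
      while (length(stack_h) && stack_h[length(stack_h)] > h) {
        top_c <- stack_c[length(stack_c)]
        top_h <- stack_h[length(stack_h)]
        stack_c <- stack_c[-length(stack_c)]
        stack_h <- stack_h[-length(stack_h)]
        area <- top_h * (cc - top_c)
        if (area > best["area"]) {
          best <- c(area = area, r0 = r - top_h + 1L, r1 = r,
                    c0 = top_c, c1 = cc - 1L)
        }
        start <- top_c
      }
      if (cc <= nc && (!length(stack_h) || stack_h[length(stack_h)] < h)) {
        stack_c <- c(stack_c, start); stack_h <- c(stack_h, h)
      }
    }
  }
  bounds <- as.integer(best[c("r0", "r1", "c0", "c1")])
  list(cropped = canvas[bounds[1]:bounds[2], bounds[3]:bounds[4],
                        drop = FALSE],
       bounds = bounds)
}

#' Feathering weight map
#'
#' Separable linear ramp rising from the tile edges to an interior plateau
#' of weight 1: `w(i) = min(i, n + 1 - i, plateau) / plateau` per axis
#' (1-based pixel index), so edge pixels keep a small positive weight and
#' the interior is flat.
#'
#' @param dims `c(rows, cols)`.
#' @param plateau ramp length in pixels (default 32, clamped to the tile).
#' @return Numeric weight matrix in `(0, 1]`.
#' @export
feather_weights <- function(dims, plateau = 32L) {
  ramp <- function(n) {
    p <- max(1L, min(as.integer(plateau), ceiling(n / 2)))
    i <- seq_len(n)
    pmin(pmin(i, n + 1L - i), p) / p
  }
  outer(ramp(dims[1]), ramp(dims[2]))
}

#' Weighted blending of placed tiles
#'
#' Accumulates `sum_i P_i W_i` and `sum_i W_i` over the canvas and divides:
#' `P(x, y) = sum P_i(x, y) W_i(x, y) / sum W_i(x, y)`. Where exactly one
#' tile contributes the tile's pixels are copied through unchanged.
#'
#' @param tiles list of equal-size numeric matrices, one per layout
#'   position.
#' @param layout a [global_align()] `mosaic_layout`.
#' @param weight_profile function `(dims) -> weight matrix`, by default
#'   [feather_weights()].
#' @return Numeric canvas matrix (0 outside coverage).
#' @export
blend <- function(tiles, layout, weight_profile = feather_weights) {
  stopifnot(inherits(layout, "mosaic_layout"),
            length(tiles) == nrow(layout$positions))
  td <- layout$tile_dims
  w <- weight_profile(td)
  if (any(w < 0) || !any(w > 0)) stop("weights must be >= 0 and > 0 somewhere")
  num <- matrix(0, layout$canvas[1], layout$canvas[2])
  den <- matrix(0, layout$canvas[1], layout$canvas[2])
  raw <- matrix(0, layout$canvas[1], layout$canvas[2])
  for (i in seq_along(tiles)) {
    t_i <- tiles[[i]]
    stopifnot(all(dim(t_i) == td))
    rr <- (layout$positions[i, 1] + 1L):(layout$positions[i, 1] + td[1])
    cc <- (layout$positions[i, 2] + 1L):(layout$positions[i, 2] + td[2])
    num[rr, cc] <- num[rr, cc] + t_i * w
    den[rr, cc] <- den[rr, cc] + w
    raw[rr, cc] <- raw[rr, cc] + t_i
  }
  inside <- layout$coverage >= 1L
  if (any(inside & den == 0))
    stop("zero total weight inside the coverage region")
  out <- matrix(0, layout$canvas[1], layout$canvas[2])
  multi <- inside & layout$coverage > 1L
  single <- inside & layout$coverage == 1L
  out[multi] <- num[multi] / den[multi]
  out[single] <- raw[single]
  out
}

#' Stitch one z-plane into an extended-FOV hologram
#'
#' Per-plane driver: builds the lattice topology from tile metadata,
#' extracts overlap ROIs for every adjacent pair, estimates each pair shift
#' with the pluggable matcher plus median/histogram voting (falling back to
#' the manifest-derived nominal shift when matching support is too low),
#' solves the global alignment, blends with feathering, and auto-crops.
#'
#' @param holos list of [hologram()]s of a single z-plane.
#' @param margin overlap-ROI search margin (fraction of tile side).
#' @param matcher matching function `(roi_a, roi_b) -> match_set`.
#' @param min_confidence correspondences below this confidence are dropped
#'   before voting.
#' @param min_support fall back to the nominal shift when the winning bin's
#'   support fraction is below this value.
#' @param bin_px histogram bin width for [estimate_pair_shift()].
#' @param crop_bounds optional precomputed crop bounds
#'   (`c(row_lo, row_hi, col_lo, col_hi)`) so several planes stay
#'   co-registered; computed by [auto_crop()] when `NULL`.
#' @param weight_profile blending weights, see [blend()].
#' @return List with `hologram` (stitched, cropped [hologram()]), `layout`,
#'   `shifts` (per-pair `shift_estimate`s + topology), `crop_bounds`, and
#'   `n_fallback` (pairs that used the nominal shift).
#' @export
stitch_plane <- function(holos, margin = 0.10,
                         matcher = match_patches_ncc,
                         min_confidence = 0.2, min_support = 0.2,
                         bin_px = 1L, crop_bounds = NULL,
                         weight_profile = feather_weights) {
  stopifnot(length(holos) >= 1L)
  zi <- unique(vapply(holos, function(h) h$z_index, integer(1)))
  if (length(zi) != 1L) stop("stitch_plane expects tiles of a single z-plane")
  man <- data.frame(
    grid_row = vapply(holos, function(h) h$grid_row, integer(1)),
    grid_col = vapply(holos, function(h) h$grid_col, integer(1)),
    stage_x = vapply(holos, function(h) h$stage_x, numeric(1)),
    stage_y = vapply(holos, function(h) h$stage_y, numeric(1)))
  topo <- build_topology(man)
  td <- dim(holos[[1]]$amplitude)
  pitch <- holos[[1]]$pitch
  shifts <- list()
  n_fallback <- 0L
  if (nrow(topo) > 0) for (k in seq_len(nrow(topo))) {
    a <- topo$a[k]; b <- topo$b[k]
    nominal <- c(
      round((man$stage_y[b] - man$stage_y[a]) / pitch),
      round((man$stage_x[b] - man$stage_x[a]) / pitch))
    side <- if (topo$direction[k] == "h") td[2] else td[1]
    step_px <- abs(nominal[if (topo$direction[k] == "h") 2L else 1L])
    overlap <- 1 - step_px / side
    est <- NULL
    if (overlap > 0 && overlap < 1) {
      rois <- extract_overlap_rois(td, td, topo$direction[k], overlap, margin)
      ms <- matcher(.crop_roi(holos[[a]]$amplitude, rois$a),
                    .crop_roi(holos[[b]]$amplitude, rois$b))
      cm <- ms$correspondences
      n_all <- nrow(cm)
      cm <- cm[cm$confidence >= min_confidence, , drop = FALSE]
      if (nrow(cm) > 0) {
        ms$correspondences <- cm
        est <- estimate_pair_shift(ms, rois$offset_a, rois$offset_b, bin_px)
        est$support_fraction <- est$votes / max(n_all, 1L)
        if (est$support_fraction < min_support) est <- NULL
      }
    }
    if (is.null(est)) {
      n_fallback <- n_fallback + 1L
      warning(sprintf(
        "pair (%d,%d)-(%d,%d): low matching support; using nominal shift (%d, %d)",
        topo$a_row[k], topo$a_col[k], topo$b_row[k], topo$b_col[k],
        nominal[1], nominal[2]))
      est <- structure(list(dy = as.integer(nominal[1]),
                            dx = as.integer(nominal[2]),
                            votes = 0L, support_fraction = 0,
                            n_total = 0L), class = "shift_estimate")
    }
    shifts[[k]] <- est
  }
  layout <- global_align(shifts, topo, length(holos), td)
  canvas <- blend(lapply(holos, `[[`, "amplitude"), layout, weight_profile)
  if (is.null(crop_bounds)) {
    cr <- auto_crop(canvas, layout$coverage)
    crop_bounds <- cr$bounds
    cropped <- cr$cropped
  } else {
    cropped <- canvas[crop_bounds[1]:crop_bounds[2],
                      crop_bounds[3]:crop_bounds[4], drop = FALSE]
  }
  list(
    hologram = hologram(cropped, pitch, holos[[1]]$z, z_index = zi),
    layout = layout,
    shifts = list(topology = topo, estimates = shifts),
    crop_bounds = crop_bounds,
    n_fallback = n_fallback)
}

#' Stitch every z-plane of a multi-depth scan
#'
#' Runs [stitch_plane()] on each z-plane and applies the reference plane's
#' crop bounds to all planes, so the stitched multi-depth stack stays
#' pixel-co-registered for phase retrieval.
#'
#' @param holos list of [hologram()]s covering all planes of one scan.
#' @param reference_index z-plane index whose crop bounds are reused.
#' @param ... passed to [stitch_plane()].
#' @return List with `planes` (per-plane [stitch_plane()] results, ordered
#'   by z-index) and `crop_bounds`.
#' @export
stitch_dataset <- function(holos, reference_index = 1L, ...) {
  zi <- vapply(holos, function(h) h$z_index, integer(1))
  planes_idx <- sort(unique(zi))
  stopifnot(reference_index %in% planes_idx)
  ref <- stitch_plane(holos[zi == reference_index], ...)
  out <- vector("list", length(planes_idx))
  for (k in seq_along(planes_idx)) {
    if (planes_idx[k] == reference_index) {
      out[[k]] <- ref
    } else {
      out[[k]] <- stitch_plane(holos[zi == planes_idx[k]],
                               crop_bounds = ref$crop_bounds, ...)
      if (!all(out[[k]]$layout$canvas == ref$layout$canvas))
        warning(sprintf(
          "plane %d canvas differs from reference; stack may be misregistered",
          planes_idx[k]))
    }
  }
  list(planes = out, crop_bounds = ref$crop_bounds)
}
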
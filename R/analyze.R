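#' Theoretical lateral resolution of a lensless in-line system
#'
#' `lambda sqrt(4 z^2 + L^2) / (2 L)`: the half-pitch resolvable given the
#' hologram extent L acting as the aperture at sensor distance z. Decreases
#' toward the diffraction limit `lambda / 2` as L grows (or z shrinks).
#'
#' @param wavelength wavelength in metres.
#' @param z object-to-sensor distance in metres (>= 0).
#' @param L hologram (FOV) side length in metres (> 0).
#' @return Resolution in metres.
#' @export
theoretical_resolution <- function(wavelength, z, L) {
  .check_positive_scalar(wavelength, "wavelength")
  .check_positive_scalar(L, "L")
  if (z < 0) stop("'z' must be >= 0")
  wavelength * sqrt(4 * z^2 + L^2) / (2 * L)
}

#' Effective numerical aperture of a single hologram
#'
#' Half the hologram extent over the sensor distance, as a sine:
#' `NA = (L/2) / sqrt(z^2 + (L/2)^2)`.
#'
#' @param L hologram side length in metres (>= 0).
#' @param z object-to-sensor distance in metres (> 0).
#' @return Numerical aperture in `[0, 1)`.
#' @export
effective_na <- function(L, z) {
  if (L < 0) stop("'L' must be >= 0")
  .check_positive_scalar(z, "z")
  (L / 2) / sqrt(z^2 + (L / 2)^2)
}

#' Depth of field
#'
#' `lambda / NA^2`: the axial range over which the reconstruction stays
#' effectively in focus. Used to choose the inter-plane spacing of the
#' multi-depth recording (spacing should exceed it).
#'
#' @param wavelength wavelength in metres.
#' @param na numerical aperture (> 0).
#' @return Depth of field in metres.
#' @export
depth_of_field <- function(wavelength, na) {
  .check_positive_scalar(wavelength, "wavelength")
  .check_positive_scalar(na, "na")
  wavelength / na^2
}

#' Scan overlap ratio and stitched area gain
#'
#' `overlap_ratio`: fraction of a tile shared with its neighbour,
#' `1 - step / tile_fov`. `area_gain`: fold increase of imaging area after
#' stitching, `(L_stitched / L_single)^2`.
#'
#' @param step centre-to-centre stage displacement in metres.
#' @param tile_fov single-tile FOV side in metres.
#' @return Overlap ratio in (0, 1).
#' @export
overlap_ratio <- function(step, tile_fov) {
  .check_positive_scalar(step, "step")
  .check_positive_scalar(tile_fov, "tile_fov")
  if (step >= tile_fov) stop("step must be smaller than the tile FOV (no overlap)")
  1 - step / tile_fov
}

#' @param L_single,L_stitched FOV side lengths in metres.
#' @rdname overlap_ratio
#' @export
area_gain <- function(L_single, L_stitched) {
  .check_positive_scalar(L_single, "L_single")
  .check_positive_scalar(L_stitched, "L_stitched")
  (L_stitched / L_single)^2
}

#' Fringe contrast along a line profile
#'
#' Samples the image along a straight line crossing a three-bar element,
#' lightly smooths it (3-sample moving mean), and detects bright peaks and
#' dark troughs as (plateau-aware) local extrema. The three-bar geometry
#' then selects the fringe features: the 3 deepest troughs are the bars and
#' the 2 highest peaks between the outer bars are the gaps; the Michelson
#' contrast `(I_max - I_min) / (I_max + I_min)` of their mean levels is
#' reported. Fewer than 3 troughs or 2 interior peaks raises an error
#' (never silently padded). A constant profile is degenerate and reported
#' as contrast 0, not resolved.
#'
#' @param image numeric matrix (amplitude by default; pass intensity if
#'   preferred -- the formula is the same).
#' @param line `list(start = c(row, col), end = c(row, col))`, 1-based.
#' @param element optional `(group, element)` label carried through.
#' @param threshold resolution decision threshold, see [is_resolved()].
#' @return A `contrast_report`: list with `profile`, `i_max`, `i_min`,
#'   `contrast`, `resolved`, `threshold`, `element`.
#' @export
line_profile_contrast <- function(image, line, element = NULL,
                                  threshold = 0.10) {
  p0 <- as.numeric(line$start); p1 <- as.numeric(line$end)
  n <- max(abs(p1 - p0)) + 1
  if (n < 8) stop("profile too short")
  rr <- round(seq(p0[1], p1[1], length.out = n))
  cc <- round(seq(p0[2], p1[2], length.out = n))
  if (any(rr < 1 | rr > nrow(image) | cc < 1 | cc > ncol(image)))
    stop("profile line leaves the image")
  prof <- image[cbind(rr, cc)]
  if (max(prof) == min(prof)) {
    rep_ <- list(profile = prof, i_max = prof[1], i_min = prof[1],
                 contrast = 0, resolved = FALSE, threshold = threshold,
                 element = element)
    class(rep_) <- "contrast_report"
    return(rep_)
  }
  sm <- stats::filter(prof, rep(1 / 3, 3), sides = 2)
  sm[1] <- prof[1]; sm[length(prof)] <- prof[length(prof)]
  sm <- as.numeric(sm)
  ext <- .plateau_extrema(sm)
  mins <- ext$kind == -1L; maxs <- ext$kind == 1L
  if (sum(mins) < 3L)
    stop(sprintf("only %d troughs on the profile; a three-bar element needs 3",
                 sum(mins)))
  bar_i <- which(mins)[order(ext$value[mins])[1:3]]
  span <- range(ext$pos[bar_i])
  gap_i <- which(maxs & ext$pos > span[1] & ext$pos < span[2])
  if (length(gap_i) < 2L)
    stop(sprintf("only %d gap peaks between the outer bars; need 2",
                 length(gap_i)))
  gap_i <- gap_i[order(ext$value[gap_i], decreasing = TRUE)[1:2]]
  i_max <- mean(ext$value[gap_i])
  i_min <- mean(ext$value[bar_i])
  contrast <- (i_max - i_min) / (i_max + i_min)
  contrast <- max(0, min(1, contrast))
  rep_ <- list(profile = prof, i_max = i_max, i_min = i_min,
               contrast = contrast,
               resolved = is_resolved(contrast, threshold),
               threshold = threshold, element = element)
  class(rep_) <- "contrast_report"
  rep_
}

#' @export
print.contrast_report <- function(x, ...) {
  lbl <- if (!is.null(x$element))
    sprintf("G%dE%d ", x$element[1], x$element[2]) else ""
  cat(sprintf("<contrast_report> %scontrast %.3f (Imax %.3g, Imin %.3g): %s\n",
              lbl, x$contrast, x$i_max, x$i_min,
              if (x$resolved) "resolved" else "not resolved"))
  invisible(x)
}

# Plateau-aware local extrema: collapse the signal into runs of equal
# value, then a run is a peak (kind +1) / trough (-1) if both neighbouring
# runs are lower / higher. Endpoints count as extrema of their slope side.
# Returns values, kinds and sample positions (run centres).
.plateau_extrema <- function(x) {
  r <- rle(x)
  v <- r$values
  ends <- cumsum(r$lengths)
  pos <- ends - (r$lengths - 1) / 2
  m <- length(v)
  if (m < 2)
    return(list(value = numeric(), kind = integer(), pos = numeric()))
  kind <- integer(m)
  for (i in seq_len(m)) {
    lo_l <- if (i > 1) v[i - 1] < v[i] else TRUE
    hi_l <- if (i > 1) v[i - 1] > v[i] else TRUE
    lo_r <- if (i < m) v[i + 1] < v[i] else TRUE
    hi_r <- if (i < m) v[i + 1] > v[i] else TRUE
    if (lo_l && lo_r) kind[i] <- 1L
    if (hi_l && hi_r) kind[i] <- -1L
  }
  keep <- kind != 0L
  list(value = v[keep], kind = kind[keep], pos = pos[keep])
}

#' MTF10 resolution decision
#'
#' A fringe pattern counts as resolved when its contrast reaches the
#' threshold; the default 0.10 is the usual MTF10 criterion ("modulation of
#' about 10% marks the resolution limit"). The boundary is inclusive.
#'
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param threshold decision threshold (default 0.10).
#' @return Logical.
#' @export
is_resolved <- function(contrast, threshold = 0.10) {
  if (contrast < 0 || contrast > 1) stop("'contrast' must be in [0, 1]")
  contrast >= threshold
}

#' Contrast analysis of every chart element on a reconstruction
#'
#' Convenience wrapper: evaluates [line_profile_contrast()] along each
#' element's stored profile lines (from [generate_bar_target()]'s
#' `elements` attribute) on a reconstructed amplitude image, averaging the
#' two orientations.
#'
#' @param image reconstructed amplitude matrix, same frame as the target.
#' @param elements the `elements` attribute of [generate_bar_target()].
#' @param threshold resolution threshold, see [is_resolved()].
#' @return Data frame: group, element, linewidth_um, contrast, resolved.
#' @export
analyze_bar_elements <- function(image, elements, threshold = 0.10) {
  rows <- lapply(elements, function(el) {
    c1 <- line_profile_contrast(image, el$profile_v_bars,
                                element = c(el$group, el$element), threshold)
    c2 <- line_profile_contrast(image, el$profile_h_bars,
                                element = c(el$group, el$element), threshold)
    contrast <- mean(c(c1$contrast, c2$contrast))
    data.frame(group = el$group, element = el$element,
               linewidth_um = el$linewidth_um, contrast = contrast,
               resolved = is_resolved(max(0, min(1, contrast)), threshold))
  })
  do.call(rbind, rows)
}
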
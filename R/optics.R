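#' Sampled complex wavefield
#'
#' Container for a 2-D sampled scalar wavefront: a complex-valued matrix
#' together with the physical sampling pitch, the illumination wavelength
#' and the axial position of the sampling plane relative to the object.
#' All lengths are SI metres.
#'
#' @param values complex (or numeric) matrix of field samples.
#' @param pitch sampling pitch in metres per pixel (> 0).
#' @param wavelength illumination wavelength in metres (> 0).
#' @param z axial position of the plane in metres (any real).
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, pitch, wavelength, z = 0) {
  if (!is.matrix(values)) stop("'values' must be a matrix")
  storage.mode(values) <- "complex"
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("field values must be finite (no NA/NaN/Inf)")
  .check_positive_scalar(pitch, "pitch")
  .check_positive_scalar(wavelength, "wavelength")
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z))
    stop("'z' must be a finite scalar")
  structure(
    list(values = values, pitch = pitch, wavelength = wavelength, z = z),
    class = "complex_field"
  )
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf(
    "<complex_field> %d x %d px, pitch %.3g um, lambda %.4g nm, z = %.4g mm\n",
    nrow(x$values), ncol(x$values), x$pitch * 1e6, x$wavelength * 1e9,
    x$z * 1e3
  ))
  invisible(x)
}

#' @export
dim.complex_field <- function(x) dim(x$values)

#' Optical system configuration
#'
#' Bundles the wavelength, pixel pitch and the ordered sensor distances
#' z_1 < z_2 < ... < z_K used for multi-depth recording, together with the
#' index of the reference (reconstruction) plane and, optionally, the side
#' length of the field of view.
#'
#' @param wavelength wavelength in metres.
#' @param pitch pixel pitch in metres.
#' @param z_planes strictly increasing numeric vector of sensor distances
#'   in metres (length K >= 1; K >= 2 is required for phase retrieval).
#' @param reference_plane_index integer in `1..K`; the plane at which the
#'   retrieved wavefront is reported.
#' @param fov_side optional field-of-view side length in metres. When an
#'   image is attached this equals (side in pixels) x pitch.
#' @return An object of class `optical_config`.
#' @export
optical_config <- function(wavelength, pitch, z_planes,
                           reference_plane_index = 1L, fov_side = NULL) {
  .check_positive_scalar(wavelength, "wavelength")
  .check_positive_scalar(pitch, "pitch")
  if (!is.numeric(z_planes) || length(z_planes) < 1L || any(!is.finite(z_planes)))
    stop("'z_planes' must be a finite numeric vector")
  if (is.unsorted(z_planes, strictly = TRUE))
    stop("'z_planes' must be strictly increasing")
  k <- length(z_planes)
  r <- as.integer(reference_plane_index)
  if (r < 1L || r > k)
    stop(sprintf("reference_plane_index must be in 1..%d", k))
  if (!is.null(fov_side)) .check_positive_scalar(fov_side, "fov_side")
  structure(
    list(wavelength = wavelength, pitch = pitch, z_planes = z_planes,
         reference_plane_index = r, fov_side = fov_side),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf(
    "<optical_config> lambda %.4g nm, pitch %.3g um, %d plane(s) z = [%s] mm, ref plane %d\n",
    x$wavelength * 1e9, x$pitch * 1e6, length(x$z_planes),
    paste(signif(x$z_planes * 1e3, 6), collapse = ", "),
    x$reference_plane_index
  ))
  invisible(x)
}

.check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name))
  invisible(TRUE)
}

# FFT sample frequencies (cycles per metre), zero frequency first,
# matching the layout of stats::fft output.
.fft_freq <- function(n, pitch) {
  idx <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2):1))
  if (n == 1L) idx <- 0
  idx / (n * pitch)
}

#' Angular-spectrum transfer function
#'
#' Exact free-space transfer function for scalar diffraction,
#' `exp(i 2 pi dz sqrt(1/lambda^2 - fx^2 - fy^2))` at propagating spatial
#' frequencies and exactly zero on the evanescent domain
#' (`fx^2 + fy^2 > 1/lambda^2`). Frequencies are laid out with the zero
#' frequency at the array origin, matching [stats::fft()].
#'
#' With `band_limited = TRUE` the kernel is additionally restricted to the
#' alias-free local-frequency band `|f| <= 1 / (lambda sqrt((2 dz df)^2 + 1))`
#' per axis (df the frequency sampling step), which keeps long-distance
#' propagation free of wrap-around artifacts when `|dz|` exceeds the plain
#' sampling bound `N pitch^2 / lambda`.
#'
#' @param shape integer vector `c(rows, cols)`.
#' @param pitch sampling pitch in metres.
#' @param wavelength wavelength in metres.
#' @param dz propagation distance in metres (any sign).
#' @param band_limited logical; apply the band-limiting window.
#' @return Complex matrix of dimension `shape`.
#' @export
angular_spectrum_kernel <- function(shape, pitch, wavelength, dz,
                                    band_limited = FALSE) {
  .check_positive_scalar(pitch, "pitch")
  .check_positive_scalar(wavelength, "wavelength")
  if (!is.numeric(dz) || length(dz) != 1L || !is.finite(dz))
    stop("'dz' must be a finite scalar")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  fy <- .fft_freq(nr, pitch)
  fx <- .fft_freq(nc, pitch)
  fy2 <- matrix(fy^2, nr, nc)
  fx2 <- matrix(fx^2, nr, nc, byrow = TRUE)
  arg <- 1 / wavelength^2 - fy2 - fx2
  prop <- arg > 0
  kern <- matrix(0 + 0i, nr, nc)
  kern[prop] <- exp(2i * pi * dz * sqrt(arg[prop]))
  if (band_limited && dz != 0) {
    fy_lim <- 1 / (wavelength * sqrt((2 * dz / (nr * pitch))^2 + 1))
    fx_lim <- 1 / (wavelength * sqrt((2 * dz / (nc * pitch))^2 + 1))
    mask <- outer(abs(fy) <= fy_lim, abs(fx) <= fx_lim, `&`)
    kern[!mask] <- 0 + 0i
  }
  kern
}

#' Alias-free propagation bound
#'
#' Largest |dz| for which the plain angular-spectrum kernel is sampled
#' without aliasing: `N pitch^2 / wavelength`, N the smaller image side.
#'
#' @param shape integer vector `c(rows, cols)`.
#' @param pitch pitch in metres.
#' @param wavelength wavelength in metres.
#' @return Distance in metres.
#' @export
asm_sampling_limit <- function(shape, pitch, wavelength) {
  min(shape[1], shape[2]) * pitch^2 / wavelength
}

#' Free-space propagation by the angular spectrum method
#'
#' Propagates a sampled wavefield by `dz` metres: FFT, multiplication by the
#' angular-spectrum transfer function, inverse FFT. Exact (non-paraxial)
#' scalar propagation; evanescent components are discarded.
#'
#' `band_limited = "auto"` (default) switches to the band-limited transfer
#' function whenever `|dz|` exceeds the plain sampling bound
#' `N pitch^2 / lambda`; `"off"` keeps the plain kernel and emits a warning
#' instead; `"on"` always band-limits.
#'
#' @param field a [complex_field()].
#' @param dz axial step in metres; positive moves away from the object.
#' @param band_limited one of `"auto"`, `"on"`, `"off"`.
#' @return A [complex_field()] at `z + dz`.
#' @export
propagate <- function(field, dz, band_limited = c("auto", "on", "off")) {
  stopifnot(inherits(field, "complex_field"))
  band_limited <- match.arg(band_limited)
  if (dz == 0) return(field)
  d <- dim(field$values)
  limit <- asm_sampling_limit(d, field$pitch, field$wavelength)
  bl <- switch(band_limited,
    auto = abs(dz) > limit,
    on = TRUE,
    off = FALSE)
  if (!bl && abs(dz) > limit && band_limited == "off")
    warning(sprintf(
      "|dz| = %.3g m exceeds the alias-free bound %.3g m; kernel will alias",
      abs(dz), limit))
  kern <- angular_spectrum_kernel(d, field$pitch, field$wavelength, dz,
                                  band_limited = bl)
  spec <- stats::fft(field$values) * kern
  out <- stats::fft(spec, inverse = TRUE) / length(spec)
  complex_field(out, field$pitch, field$wavelength, field$z + dz)
}

#' Scale an amplitude image to unit maximum
#'
#' Divides a nonnegative image by its maximum so that `max(out) == 1`.
#' The minimum is not forced to zero; the zero background of amplitude
#' holograms is preserved. Idempotent.
#'
#' @param image nonnegative numeric matrix, not all zero.
#' @return Numeric matrix with values in `[0, 1]`.
#' @export
normalize_amplitude <- function(image) {
  if (!is.numeric(image)) stop("'image' must be numeric")
  if (any(!is.finite(image))) stop("'image' must be finite")
  if (any(image < 0)) stop("'image' must be nonnegative")
  m <- max(image)
  if (m == 0) stop("cannot normalize an all-zero image")
  image / m
}
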
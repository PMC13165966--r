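#' Co-registered multi-depth hologram stack
#'
#' Holds K same-size amplitude holograms recorded at strictly increasing
#' sensor distances, with the recording geometry and the index of the
#' reference (reconstruction) plane.
#'
#' @param holograms list of K nonnegative amplitude matrices (equal size).
#' @param z_planes strictly increasing sensor distances in metres,
#'   length K >= 2.
#' @param pitch pixel pitch in metres.
#' @param wavelength wavelength in metres.
#' @param reference_index index of the reference plane (1..K).
#' @return Object of class `multi_depth_stack`.
#' @export
multi_depth_stack <- function(holograms, z_planes, pitch, wavelength,
                              reference_index = ceiling(length(z_planes) / 2)) {
  k <- length(z_planes)
  if (k < 2L) stop("multi-depth retrieval needs at least 2 planes")
  if (length(holograms) != k)
    stop("length(holograms) must equal length(z_planes)")
  if (is.unsorted(z_planes, strictly = TRUE))
    stop("'z_planes' must be strictly increasing")
  d <- dim(holograms[[1]])
  for (h in holograms) {
    if (!is.matrix(h) || !all(dim(h) == d))
      stop("all holograms must be same-size matrices (co-registered stack)")
    if (any(!is.finite(h)) || any(h < 0))
      stop("hologram amplitudes must be finite and nonnegative")
  }
  r <- as.integer(reference_index)
  if (r < 1L || r > k) stop(sprintf("reference_index must be in 1..%d", k))
  .check_positive_scalar(pitch, "pitch")
  .check_positive_scalar(wavelength, "wavelength")
  structure(
    list(holograms = holograms, z_planes = z_planes, pitch = pitch,
         wavelength = wavelength, reference_index = r),
    class = "multi_depth_stack"
  )
}

#' @export
print.multi_depth_stack <- function(x, ...) {
  cat(sprintf(
    "<multi_depth_stack> %d planes of %d x %d px, z = [%s] mm, ref %d\n",
    length(x$z_planes), nrow(x$holograms[[1]]), ncol(x$holograms[[1]]),
    paste(signif(x$z_planes * 1e3, 6), collapse = ", "), x$reference_index))
  invisible(x)
}

#' Amplitude constraint (modulus replacement)
#'
#' The projection step of iterative retrieval: the propagated field's
#' modulus is replaced with the measured hologram amplitude while its phase
#' is retained. Pixels where the input field is exactly zero have undefined
#' phase and are assigned phase 0.
#'
#' @param field a [complex_field()].
#' @param measured nonnegative amplitude matrix of the same size.
#' @return A [complex_field()] with `Mod(values) == measured`.
#' @export
amplitude_constraint <- function(field, measured) {
  stopifnot(inherits(field, "complex_field"))
  if (!all(dim(field$values) == dim(measured)))
    stop("field and measured amplitude differ in shape")
  if (any(measured < 0)) stop("measured amplitude must be nonnegative")
  m <- Mod(field$values)
  unit <- field$values / m
  unit[m == 0] <- 1 + 0i  # phase 0 where the field vanishes
  complex_field(measured * unit, field$pitch, field$wavelength, field$z)
}

#' RMSE between two normalized amplitude images
#'
#' Both images are first scaled to unit maximum ([normalize_amplitude()]),
#' then `sqrt(mean((a - b)^2))` is returned. Symmetric and nonnegative.
#'
#' @param a,b nonnegative matrices of equal size, neither all zero.
#' @return Scalar RMSE.
#' @export
amplitude_rmse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("images differ in shape")
  an <- normalize_amplitude(a)
  bn <- normalize_amplitude(b)
  sqrt(mean((an - bn)^2))
}

# Plane visiting order for one sweep: r -> K -> 1 -> r.
.sweep_path <- function(k, r) {
  c(if (r < k) (r + 1L):k,
    if (k > 1L) (k - 1L):1L,
    if (r > 1L) 2L:r)
}

#' Multi-depth amplitude-constrained phase retrieval
#'
#' Iterative twin-image-suppressing retrieval from K co-registered
#' holograms at different sensor depths. The field is initialised at the
#' reference plane with the measured amplitude and zero phase
#' (`H_r exp(i 0)`), then each iteration performs one full sweep
#' `r -> r+1 -> ... -> K -> K-1 -> ... -> 1 -> 2 -> ... -> r`, propagating
#' between consecutive planes with the angular spectrum method and
#' replacing the modulus with the measured amplitude at every visited
#' plane. After each sweep the RMSE between the measured reference
#' amplitude and the modulus of the field arriving back at the reference
#' plane is recorded (images normalized first), together with its
#' iteration-to-iteration difference dRMSE. The loop stops at `iterations`
#' sweeps or as soon as `|dRMSE| < tol`.
#'
#' The returned field is `H_r exp(i phi_f)`: measured reference amplitude
#' carrying the retrieved phase. The algorithm contains no randomness and
#' is bitwise reproducible.
#'
#' @param stack a [multi_depth_stack()].
#' @param iterations sweep cap (default 10).
#' @param tol stop when `|dRMSE|` falls below this (default 1e-6).
#' @param init_phase optional initial phase matrix at the reference plane
#'   (default zero).
#' @param band_limited propagation mode, see [propagate()].
#' @return List with `field` (a [complex_field()] at the reference plane)
#'   and `trace` (class `convergence_trace`: `rmse`, `delta_rmse` --
#'   `delta_rmse[1]` is `NA` -- and `iterations_run`).
#' @export
multi_depth_retrieve <- function(stack, iterations = 10L, tol = 1e-6,
                                 init_phase = NULL, band_limited = "auto") {
  stopifnot(inherits(stack, "multi_depth_stack"), iterations >= 1L)
  k <- length(stack$z_planes)
  r <- stack$reference_index
  h_ref <- stack$holograms[[r]]
  if (is.null(init_phase)) init_phase <- matrix(0, nrow(h_ref), ncol(h_ref))
  field <- complex_field(h_ref * exp(1i * init_phase), stack$pitch,
                         stack$wavelength, stack$z_planes[r])
  path <- .sweep_path(k, r)
  rmse <- numeric(0)
  it <- 0L
  while (it < iterations) {
    it <- it + 1L
    for (j in path) {
      field <- propagate(field, stack$z_planes[j] - field$z,
                         band_limited = band_limited)
      if (j == r && j == path[length(path)])
        rmse[it] <- amplitude_rmse(h_ref, Mod(field$values))
      field <- amplitude_constraint(field, stack$holograms[[j]])
    }
    if (it >= 2L && abs(rmse[it] - rmse[it - 1L]) < tol) break
  }
  delta <- c(NA_real_, diff(rmse))
  trace <- structure(
    list(rmse = rmse, delta_rmse = delta, iterations_run = it),
    class = "convergence_trace")
  list(field = field, trace = trace)
}

#' @export
print.convergence_trace <- function(x, ...) {
  cat(sprintf("<convergence_trace> %d iteration(s); final RMSE %.3g\n",
              x$iterations_run, x$rmse[x$iterations_run]))
  invisible(x)
}

#' Object-plane reconstruction
#'
#' Back-propagates a field at the reference plane to the object plane
#' (`dz = -z`) with the angular spectrum method; amplitude and phase images
#' follow as `Mod()` / `Arg()` of the result.
#'
#' @param field a [complex_field()] with `z > 0` (at the sensor plane).
#' @param band_limited propagation mode, see [propagate()].
#' @return A [complex_field()] at `z = 0`.
#' @export
reconstruct_object <- function(field, band_limited = "auto") {
  stopifnot(inherits(field, "complex_field"))
  propagate(field, -field$z, band_limited = band_limited)
}
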
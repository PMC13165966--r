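# Shared fixtures, built once per test run and cached. All synthetic, all
# seeded; the desk-scale scan is the "stated world" the acceptance criteria
# run on (3 x 3 grid, 256 px tiles, 115 px step ~ 55% overlap, 5 planes
# from 4 mm with 0.25 mm spacing, He-Ne illumination, 2 um pixels).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

desk_objects <- function() fixture("desk_objects", function() {
  config_objects(desk_config())
})

# Noiseless desk-scale scan of the demo object (bar elements + blobs).
desk_scan <- function() fixture("desk_scan", function() {
  co <- desk_objects()
  obj <- demo_object(c(486L, 486L), co$optics$pitch)
  scan <- simulate_scan(obj, co$grid, co$optics, noise_sigma = 0)
  list(co = co, obj = obj, elements = attr(obj, "elements"), scan = scan)
})

desk_stitched <- function() fixture("desk_stitched", function() {
  d <- desk_scan()
  st <- stitch_dataset(d$scan$holograms,
                       reference_index = d$co$optics$reference_plane_index)
  c(d, list(st = st))
})

desk_retrieval <- function() fixture("desk_retrieval", function() {
  d <- desk_stitched()
  amps <- lapply(d$st$planes, function(p) p$hologram$amplitude)
  stack <- multi_depth_stack(amps, d$co$optics$z_planes, d$co$optics$pitch,
                             d$co$optics$wavelength,
                             reference_index = d$co$optics$reference_plane_index)
  ret <- multi_depth_retrieve(stack, iterations = 10)
  c(d, list(amps = amps, stack = stack, ret = ret))
})

# Tiny 4-plane blob stack for retrieval unit tests: 64 px, distances within
# the plain sampling bound (~0.40 mm) so propagation is exactly unitary and
# the stack is perfectly self-consistent.
tiny_stack <- function() fixture("tiny_stack", function() {
  blobs <- data.frame(row = c(22, 44), col = c(40, 24),
                      sigma_px = c(6, 4), absorption = c(0.5, 0.3),
                      phase = c(0.9, -0.6))
  obj <- blob_phantom(c(64L, 64L), blobs)
  pitch <- 2e-6; lambda <- 632.8e-9
  z <- c(0.20, 0.25, 0.30, 0.35) * 1e-3
  f0 <- complex_field(obj, pitch, lambda, 0)
  fields <- lapply(z, function(zz) propagate(f0, zz))
  holos <- lapply(fields, function(f) Mod(f$values))
  list(obj = obj, pitch = pitch, lambda = lambda, z = z,
       fields = fields,
       stack = multi_depth_stack(holos, z, pitch, lambda,
                                 reference_index = 2L))
})

# Small noiseless 2 x 2 scan (96 px tiles, 32 px step) for stitching units.
small_scan <- function() fixture("small_scan", function() {
  pitch <- 2e-6; lambda <- 632.8e-9
  optics <- optical_config(lambda, pitch, c(0.8e-3, 1.0e-3),
                           reference_plane_index = 1L)
  grid <- scan_grid(2, 2, 32 * pitch, 96L, pitch)
  blobs <- data.frame(row = c(40, 80, 64, 30), col = c(40, 90, 70, 100),
                      sigma_px = c(9, 7, 5, 6),
                      absorption = c(0.6, 0.5, 0.4, 0.55),
                      phase = c(0.7, -0.4, 0.5, 0.3))
  obj <- blob_phantom(c(128L, 128L), blobs)
  scan <- simulate_scan(obj, grid, optics, noise_sigma = 0)
  list(optics = optics, grid = grid, obj = obj, scan = scan,
       # 32 px templates keep most of the grid inside the true overlap
       matcher = function(a, b) match_patches_ncc(a, b, patch_px = 32L))
})

rms <- function(x) sqrt(mean(Mod(x)^2))
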
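#' Demo object for the synthetic pipeline
#'
#' A transmission map combining three three-bar chart elements (well above,
#' near, and close to the desk-scale resolution limit) with a cluster of
#' absorbing/phase-delaying blobs, sized to cover a full scan extent.
#'
#' @param canvas_px `c(rows, cols)`; element and blob positions scale with
#'   the canvas (>= ~180 px needed to fit the coarsest element).
#' @param pitch pixel pitch in metres.
#' @return Complex transmission matrix with the bar-target `elements`
#'   attribute (see [generate_bar_target()]).
#' @export
demo_object <- function(canvas_px = c(486L, 486L), pitch = 2e-6) {
  nr <- as.integer(canvas_px[1]); nc <- as.integer(canvas_px[2])
  at <- function(fr, fc) c(round(fr * (nr - 1)) + 1L, round(fc * (nc - 1)) + 1L)
  elements <- list(
    list(group = 4, element = 4, at = at(0.142, 0.122)),  # 22.1 um -> 11 px
    list(group = 5, element = 2, at = at(0.410, 0.122)),  # 13.9 um -> 7 px
    list(group = 6, element = 2, at = at(0.617, 0.122)))  # 7.0 um -> 4 px
  bars <- generate_bar_target(canvas_px, pitch, elements)
  s <- min(nr, nc) / 486
  blobs <- data.frame(
    row = round(c(0.25, 0.37, 0.66, 0.80) * nr),
    col = round(c(0.68, 0.82, 0.74, 0.62) * nc),
    sigma_px = pmax(3, round(c(18, 12, 24, 10) * s)),
    absorption = c(0.5, 0.7, 0.35, 0.6),
    phase = c(0.8, -0.5, 0.4, 1.0))
  obj <- as.complex(bars) * blob_phantom(canvas_px, blobs)
  obj <- matrix(obj, nr, nc)
  attr(obj, "elements") <- attr(bars, "elements")
  obj
}

#' Load a recorded scan from a manifest
#'
#' Reads every tile referenced by the manifest, attaches its metadata and
#' validates that each z-plane forms a complete rows x cols lattice,
#' aborting with the missing `(row, col, z)` otherwise.
#'
#' @param manifest_path CSV manifest (see [read_manifest()]).
#' @param pitch pixel pitch in metres.
#' @param as `"amplitude"` or `"intensity"`, see [read_hologram()].
#' @return List of [hologram()]s.
#' @export
load_scan <- function(manifest_path, pitch, as = "amplitude") {
  man <- read_manifest(manifest_path)
  rows <- max(man$grid_row) + 1L; cols <- max(man$grid_col) + 1L
  for (k in sort(unique(man$z_index))) {
    sub <- man[man$z_index == k, ]
    want <- expand.grid(row = 0:(rows - 1L), col = 0:(cols - 1L))
    have <- paste(sub$grid_row, sub$grid_col)
    gone <- want[!(paste(want$row, want$col) %in% have), , drop = FALSE]
    if (nrow(gone))
      stop(sprintf("manifest missing tile(s): %s",
                   paste(sprintf("(row %d, col %d, z %d)",
                                 gone$row, gone$col, k), collapse = ", ")))
  }
  lapply(seq_len(nrow(man)), function(i)
    read_hologram(man$file[i], as = as, pitch = pitch,
                  z = man$z_mm[i] * 1e-3, z_index = man$z_index[i],
                  grid_row = man$grid_row[i], grid_col = man$grid_col[i],
                  stage_x = man$stage_x_mm[i] * 1e-3,
                  stage_y = man$stage_y_mm[i] * 1e-3))
}

#' End-to-end pipeline driver
#'
#' simulate (or load) -> stitch every z-plane -> multi-depth retrieve ->
#' reconstruct -> analyze. Writes all artifacts under `out_dir`: tile
#' images + manifest (when simulating), stitched planes, the retrieved
#' field, object-plane amplitude/phase, the convergence trace, a contrast
#' report and a run log listing every parameter actually used. Fully
#' deterministic given `seed`.
#'
#' @param config configuration list ([desk_config()] by default; see
#'   [load_config()]).
#' @param out_dir artifact directory (created if needed).
#' @param seed integer seed for the simulated noise.
#' @param manifest_path optional recorded-scan manifest; when `NULL` a
#'   synthetic scan of [demo_object()] is generated.
#' @param write_tiles write the simulated tiles + manifest to disk.
#' @return Invisibly, a list with the stitched planes, retrieval result,
#'   reconstruction, element report and artifact paths.
#' @export
run_pipeline <- function(config = desk_config(), out_dir, seed = 1L,
                         manifest_path = NULL, write_tiles = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- config_objects(config)
  optics <- co$optics; grid <- co$grid
  elements <- NULL
  if (is.null(manifest_path)) {
    step_px <- as.integer(round(grid$step / optics$pitch))
    need <- grid$tile_side_px + (max(grid$rows, grid$cols) - 1L) * step_px
    obj <- demo_object(c(need, need), optics$pitch)
    elements <- attr(obj, "elements")
    scan <- simulate_scan(obj, grid, optics,
                          noise_sigma = config$noise_sigma, seed = seed,
                          band_limited = config$band_limited)
    holos <- scan$holograms
    if (write_tiles) {
      man <- scan$manifest
      man$file <- sprintf("tile_r%d_c%d_z%d.tsv", man$grid_row,
                          man$grid_col, man$z_index)
      for (i in seq_along(holos))
        write_hologram(holos[[i]], file.path(out_dir, man$file[i]))
      write_manifest(man[c("file", "grid_row", "grid_col", "stage_x_mm",
                           "stage_y_mm", "z_index", "z_mm")],
                     file.path(out_dir, "manifest.csv"))
    }
  } else {
    holos <- load_scan(manifest_path, optics$pitch)
    obj <- NULL
  }

  stitched <- stitch_dataset(holos,
                             reference_index = optics$reference_plane_index,
                             margin = config$margin)
  amps <- lapply(stitched$planes, function(p) p$hologram$amplitude)
  for (k in seq_along(amps))
    write_hologram(amps[[k]], file.path(out_dir, sprintf("stitched_z%d.tsv", k)))

  stack <- multi_depth_stack(amps, optics$z_planes, optics$pitch,
                             optics$wavelength,
                             reference_index = optics$reference_plane_index)
  ret <- multi_depth_retrieve(stack, iterations = config$iterations,
                              tol = config$tol,
                              band_limited = config$band_limited)
  write_field(ret$field, file.path(out_dir, "field_ref"))

  recon <- reconstruct_object(ret$field, band_limited = config$band_limited)
  write_hologram(Mod(recon$values), file.path(out_dir, "recon_amplitude.tsv"))
  write_hologram(Arg(recon$values) + pi, file.path(out_dir, "recon_phase.tsv"))

  report <- NULL
  if (!is.null(elements)) {
    # reconstruction frame: object pixels shifted by the crop origin
    cb <- stitched$crop_bounds
    shifted <- .shift_elements(elements, -(cb[1] - 1L), -(cb[3] - 1L))
    report <- analyze_bar_elements(Mod(recon$values), shifted)
    utils::write.csv(report, file.path(out_dir, "contrast_report.csv"),
                     row.names = FALSE)
  }

  jsonlite::write_json(
    list(config = config, seed = seed,
         crop_bounds = stitched$crop_bounds,
         rmse = ret$trace$rmse, delta_rmse = ret$trace$delta_rmse,
         iterations_run = ret$trace$iterations_run,
         n_fallback = sum(vapply(stitched$planes, `[[`, 0L, "n_fallback")),
         parameters = list(margin = config$margin, bin_px = 1,
                           weight_profile = "feather(plateau=32)",
                           sweep = "ref->K->1->ref", tol = config$tol)),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  invisible(list(stitched = stitched, retrieval = ret, reconstruction = recon,
                 report = report, out_dir = out_dir))
}

# Translate element profile lines into the cropped/reconstructed frame.
.shift_elements <- function(elements, dr, dc) {
  lapply(elements, function(el) {
    el$profile_v_bars$start <- el$profile_v_bars$start + c(dr, dc)
    el$profile_v_bars$end <- el$profile_v_bars$end + c(dr, dc)
    el$profile_h_bars$start <- el$profile_h_bars$start + c(dr, dc)
    el$profile_h_bars$end <- el$profile_h_bars$end + c(dr, dc)
    el
  })
}
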
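#' Write a hologram image
#'
#' Two plain-text on-disk formats are supported, chosen by extension:
#' `.tsv` -- lossless float matrix, tab-separated, the interchange default;
#' `.pgm` -- ASCII (P2) 16-bit greyscale for viewers, quantized to 65535
#' levels after scaling to unit maximum (lossy, intended for inspection).
#'
#' @param holo a [hologram()] or a plain numeric matrix.
#' @param path output path ending in `.tsv` or `.pgm`.
#' @param intensity write `amplitude^2` instead of amplitude (the reader's
#'   `as` flag undoes this with a square root).
#' @return `path`, invisibly.
#' @export
write_hologram <- function(holo, path, intensity = FALSE) {
  amp <- if (inherits(holo, "hologram")) holo$amplitude else holo
  if (intensity) amp <- amp^2
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    utils::write.table(format(amp, digits = 17, trim = TRUE, scientific = TRUE),
                       path, sep = "\t", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else if (ext == "pgm") {
    q <- round(65535 * amp / max(amp))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)), "65535"), con)
    utils::write.table(q, con, sep = " ", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else stop("unsupported image format: .", ext, " (use .tsv or .pgm)")
  invisible(path)
}

#' Read a hologram image
#'
#' Counterpart of [write_hologram()]. PGM pixel values are scaled to
#' `[0, 1]` by the file's maximum level; TSV floats are taken verbatim.
#' With `as = "intensity"` the stored image is treated as `|U|^2` and a
#' square root is applied, covering sensors calibrated either way.
#'
#' @param path `.tsv` or `.pgm` file.
#' @param as `"amplitude"` (default) or `"intensity"`.
#' @param pitch,z,z_index,grid_row,grid_col,stage_x,stage_y metadata for
#'   the returned [hologram()] (usually joined from a manifest row).
#' @return A [hologram()].
#' @export
read_hologram <- function(path, as = c("amplitude", "intensity"),
                          pitch = 1e-6, z = 0, z_index = 1L,
                          grid_row = 0L, grid_col = 0L,
                          stage_x = 0, stage_y = 0) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "tsv") {
    amp <- as.matrix(utils::read.table(path, sep = "\t",
                                       colClasses = "numeric"))
  } else if (ext == "pgm") {
    tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    if (tok[1] != "P2") stop("only ASCII (P2) PGM is supported: ", path)
    nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
    maxval <- as.numeric(tok[4])
    px <- suppressWarnings(as.numeric(tok[-(1:4)]))
    if (length(px) != nr * nc || any(is.na(px))) stop("corrupt PGM: ", path)
    amp <- matrix(px, nr, nc, byrow = TRUE) / maxval
  } else stop("unsupported image format: .", ext)
  dimnames(amp) <- NULL
  if (as == "intensity") amp <- sqrt(amp)
  hologram(amp, pitch = pitch, z = z, z_index = z_index,
           grid_row = grid_row, grid_col = grid_col,
           stage_x = stage_x, stage_y = stage_y)
}

#' Write / read a scan manifest
#'
#' CSV with one row per recorded tile: `file, grid_row, grid_col,
#' stage_x_mm, stage_y_mm, z_index, z_mm`. Stage units are millimetres in
#' the file and converted to SI metres on ingest.
#'
#' @param manifest data frame with the columns above.
#' @param path CSV path.
#' @return `path` / the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_files verify that every referenced image file exists.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "grid_row", "grid_col", "stage_x_mm", "stage_y_mm",
            "z_index", "z_mm")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("manifest lacks columns: ", paste(miss, collapse = ", "))
  key <- paste(man$grid_row, man$grid_col, man$z_index)
  if (anyDuplicated(key)) stop("manifest has duplicate (row, col, z) entries")
  if (check_files) {
    base <- dirname(path)
    paths <- ifelse(grepl("^/", man$file), man$file, file.path(base, man$file))
    gone <- !file.exists(paths)
    if (any(gone)) stop("manifest references missing files: ",
                        paste(man$file[gone], collapse = ", "))
    man$file <- paths
  }
  man
}

#' Default optical / pipeline configuration
#'
#' `default_config()` mirrors the reference bench: He-Ne illumination
#' (632.8 nm), 2 um pixels, 3552 px tiles, five sensor planes from 114 mm
#' with 1 mm spacing, reference plane 3, a 7 x 7 serpentine scan with 3 mm
#' steps, 10 retrieval iterations and a 10% registration margin.
#'
#' `desk_config()` is a scaled-down geometry for simulation and testing:
#' 256 px tiles, five planes from 4 mm with 0.25 mm spacing, a 3 x 3 scan
#' with 0.23 mm steps (115 px, ~55% overlap). Axial distances are reduced
#' so free-space propagation stays close to the plain sampling bound at
#' this tile size.
#'
#' @return Named list of configuration values (human units: nm, um, mm).
#' @export
default_config <- function() {
  list(
    wavelength_nm = 632.8,
    pitch_um = 2,
    z1_mm = 114,
    z_spacing_mm = 1,
    n_planes = 5L,
    reference_plane = 3L,
    iterations = 10L,
    tol = 1e-6,
    margin = 0.10,
    grid_rows = 7L,
    grid_cols = 7L,
    tile_px = 3552L,
    step_mm = 3,
    noise_sigma = 0,
    band_limited = "auto"
  )
}

#' @rdname default_config
#' @export
desk_config <- function() {
  cfg <- default_config()
  cfg$z1_mm <- 4
  cfg$z_spacing_mm <- 0.25
  cfg$grid_rows <- 3L
  cfg$grid_cols <- 3L
  cfg$tile_px <- 256L
  cfg$step_mm <- 0.23
  cfg
}

#' Load a configuration file
#'
#' JSON configuration with the keys of [default_config()]; missing keys
#' take the defaults, unknown keys are rejected. `z_spacing_mm` may be a
#' scalar or a vector of `n_planes - 1` spacings (anything else errors).
#' An empty file (or `{}`) yields the defaults.
#'
#' @param path JSON file.
#' @return Fully resolved configuration list.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  user <- if (nchar(trimws(txt)) == 0) list()
          else jsonlite::fromJSON(txt, simplifyVector = TRUE)
  cfg <- default_config()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  sp <- cfg$z_spacing_mm
  if (!(length(sp) == 1L || length(sp) == cfg$n_planes - 1L))
    stop(sprintf(
      "z_spacing_mm must be a scalar or have length n_planes - 1 = %d, got %d",
      cfg$n_planes - 1L, length(sp)))
  cfg
}

#' @rdname load_config
#' @param config configuration list.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Expand a configuration into core objects
#'
#' @param cfg list from [load_config()] / [desk_config()].
#' @return List with `optics` (an [optical_config()]) and `grid`
#'   (a [scan_grid()]).
#' @export
config_objects <- function(cfg) {
  sp <- cfg$z_spacing_mm
  if (length(sp) == 1L) sp <- rep(sp, cfg$n_planes - 1L)
  z_mm <- cfg$z1_mm + c(0, cumsum(sp))
  optics <- optical_config(
    wavelength = cfg$wavelength_nm * 1e-9,
    pitch = cfg$pitch_um * 1e-6,
    z_planes = z_mm * 1e-3,
    reference_plane_index = cfg$reference_plane,
    fov_side = cfg$tile_px * cfg$pitch_um * 1e-6)
  grid <- scan_grid(cfg$grid_rows, cfg$grid_cols, cfg$step_mm * 1e-3,
                    cfg$tile_px, cfg$pitch_um * 1e-6)
  list(optics = optics, grid = grid)
}

#' Write / read a complex field
#'
#' Stored as two float TSV matrices (`<stem>_real.tsv`, `<stem>_imag.tsv`)
#' plus a JSON sidecar (`<stem>.json`) carrying wavelength, pitch and z in
#' human units -- all open, text-only formats.
#'
#' @param field a [complex_field()].
#' @param stem path stem (no extension).
#' @return `stem` / the [complex_field()].
#' @export
write_field <- function(field, stem) {
  stopifnot(inherits(field, "complex_field"))
  write_hologram(Re(field$values), paste0(stem, "_real.tsv"))
  write_hologram(Im(field$values), paste0(stem, "_imag.tsv"))
  jsonlite::write_json(
    list(wavelength_nm = field$wavelength * 1e9, pitch_um = field$pitch * 1e6,
         z_mm = field$z * 1e3, dim = dim(field$values)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname write_field
#' @export
read_field <- function(stem) {
  meta <- jsonlite::fromJSON(paste0(stem, ".json"))
  re <- as.matrix(utils::read.table(paste0(stem, "_real.tsv"), sep = "\t"))
  im <- as.matrix(utils::read.table(paste0(stem, "_imag.tsv"), sep = "\t"))
  dimnames(re) <- dimnames(im) <- NULL
  complex_field(re + 1i * im, meta$pitch_um * 1e-6, meta$wavelength_nm * 1e-9,
                meta$z_mm * 1e-3)
}
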
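#' Read and write emission spectra as CSV
#'
#' Plain CSV with columns `wavelength_nm`, `intensity` and (if available)
#' `excitation_nm`.
#'
#' @param spectrum Spectrum tibble.
#' @param path File path.
#' @return `read_spectrum()` returns the spectrum tibble;
#'   `write_spectrum()` returns `path` invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  check_spectrum(spectrum)
  utils::write.csv(spectrum, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  check_spectrum(out)
  out
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a hyperspectral cube as multi-page TIFF with JSON sidecar
#'
#' One 32-bit float TIFF page per wavelength channel plus a
#' `<path>.json` sidecar carrying `excitation_nm`, `wavelengths_nm`, the
#' intensity `scale_factor` (TIFF pages store `value / scale_factor` in
#' `[0, 1]`) and an `integer_counts` flag. Integer photon-count cubes below
#' 2^23 round-trip bit-exactly (values are re-scaled and rounded on read).
#'
#' @param img A `spectral_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_spectral_cube <- function(img, path) {
  stopifnot(inherits(img, "spectral_image"))
  scale_factor <- max(img$cube, 1)
  integer_counts <- all(img$cube == round(img$cube))
  pages <- purrr::map(seq_along(img$wavelengths_nm),
                      function(k) img$cube[, , k] / scale_factor)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(
    list(excitation_nm = img$excitation_nm,
         wavelengths_nm = img$wavelengths_nm,
         scale_factor = scale_factor, integer_counts = integer_counts),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_spectral_cube
#' @return `read_spectral_cube()` returns the `spectral_image`.
#' @export
read_spectral_cube <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side)) {
    abort(paste0("Missing JSON sidecar: ", side))
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$excitation_nm) || is.null(meta$wavelengths_nm)) {
    abort("Sidecar must provide `excitation_nm` and `wavelengths_nm`.")
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(meta$wavelengths_nm)) {
    abort(sprintf("Sidecar lists %d wavelengths but the TIFF has %d pages.",
                  length(meta$wavelengths_nm), length(pages)))
  }
  scale_factor <- meta$scale_factor %||% 1
  cube <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) cube[, , k] <- pages[[k]] * scale_factor
  if (isTRUE(meta$integer_counts)) cube <- round(cube)
  spectral_image(cube, meta$wavelengths_nm, meta$excitation_nm)
}

#' Write a FLIM decay cube to HDF5
#'
#' Layout: dataset `/decays` of shape `(ny, nx, L)` photon counts with
#' attributes `Ts_ns`, `L` and `channel` on the dataset.
#'
#' @param img A `flim_image`.
#' @param path Output `.h5` path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_flim_cube <- function(img, path) {
  stopifnot(inherits(img, "flim_image"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(img$decays, path, "decays")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, "decays")
  on.exit(rhdf5::H5Dclose(did), add = TRUE, after = FALSE)
  rhdf5::h5writeAttribute(img$Ts, did, "Ts_ns")
  rhdf5::h5writeAttribute(as.integer(img$L), did, "L")
  rhdf5::h5writeAttribute(img$channel, did, "channel")
  invisible(path)
}

#' @rdname write_flim_cube
#' @return `read_flim_cube()` returns the `flim_image`; invariants
#'   (attribute consistency, non-negative counts, positive `Ts`) are
#'   validated on read.
#' @export
read_flim_cube <- function(path) {
  decays <- rhdf5::h5read(path, "decays", read.attributes = TRUE)
  at <- attributes(decays)
  for (field in c("Ts_ns", "L", "channel")) {
    if (is.null(at[[field]])) {
      abort(paste0("FLIM cube is missing the `", field, "` attribute."))
    }
  }
  if (as.integer(at$L) != dim(decays)[3]) {
    abort("`L` attribute does not match the decay axis length.")
  }
  if (at$Ts_ns <= 0) abort("`Ts_ns` must be > 0.")
  flim_image(array(as.numeric(decays), dim = dim(decays)),
             Ts = as.numeric(at$Ts_ns), channel = as.character(at$channel))
}

#' Write a phasor histogram as CSV
#'
#' Long-format CSV of occupied bins: `g_mid`, `s_mid`, `count`.
#'
#' @param hist A `phasor_histogram`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_phasor_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "phasor_histogram"))
  occ <- which(hist$counts > 0, arr.ind = TRUE)
  utils::write.csv(
    tibble(g_mid = hist$g_mid[occ[, 1]], s_mid = hist$s_mid[occ[, 2]],
           count = hist$counts[occ]),
    path, row.names = FALSE)
  invisible(path)
}
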
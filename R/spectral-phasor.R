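#' First-harmonic spectral phasor of an emission spectrum
#'
#' Maps a spectrum to its first Fourier harmonic over the wavelength axis:
#' `g = sum(I * cos(2 pi (lambda - lambda0) / span)) / sum(I)` and the sine
#' analogue for `s`, with `lambda0` the axis start and `span` the axis
#' extent. Non-negative spectra always map inside the unit circle. The total
#' intensity is carried as `weight` so that mixtures combine by
#' intensity-weighted averaging.
#'
#' @param spectrum Tibble with `wavelength_nm`, `intensity` (all >= 0, sum
#'   > 0).
#' @return One-row tibble `g`, `s`, `weight`.
#' @examples
#' sp <- tibble::tibble(wavelength_nm = seq(380, 790, 10),
#'                      intensity = c(1, rep(0, 41)))
#' spectral_phasor_transform(sp) # delta at axis start: (1, 0)
#' @export
spectral_phasor_transform <- function(spectrum) {
  check_spectrum(spectrum)
  intens <- spectrum$intensity
  if (any(intens < 0)) abort("Spectral phasors require non-negative intensities.")
  total <- sum(intens)
  if (total <= 0) abort("Cannot transform a zero-sum spectrum.")
  lambda <- spectrum$wavelength_nm
  phase <- 2 * pi * (lambda - lambda[1]) / (lambda[length(lambda)] - lambda[1])
  tibble(g = sum(intens * cos(phase)) / total,
         s = sum(intens * sin(phase)) / total,
         weight = total)
}

#' Per-pixel spectral phasor map and histogram of an image cube
#'
#' Transforms every non-empty pixel of a hyperspectral cube to its spectral
#' phasor and bins the phasors into a 2D histogram over the unit square.
#' All-zero pixels are excluded and counted in the histogram metadata.
#'
#' @param img A `spectral_image`.
#' @param bins Number of histogram bins per axis.
#' @return A list: `pixels` (tibble `x`, `y`, `g`, `s`, `weight`) and
#'   `histogram` (a `phasor_histogram`).
#' @export
phasor_image <- function(img, bins = 128) {
  stopifnot(inherits(img, "spectral_image"))
  d <- dim(img$cube)
  flat <- matrix(img$cube, nrow = d[1] * d[2])
  totals <- rowSums(flat)
  keep <- totals > 0
  if (!any(keep)) abort("Every pixel of the cube is zero.")
  lambda <- img$wavelengths_nm
  phase <- 2 * pi * (lambda - lambda[1]) / (lambda[length(lambda)] - lambda[1])
  g <- as.vector(flat %*% cos(phase)) / totals
  s <- as.vector(flat %*% sin(phase)) / totals
  idx <- which(keep)
  pixels <- tibble(
    y = ((idx - 1) %% d[1]) + 1,
    x = ((idx - 1) %/% d[1]) + 1,
    g = g[keep], s = s[keep], weight = totals[keep]
  )
  hist <- phasor_histogram(pixels, bins = bins,
                           metadata = list(excitation_nm = img$excitation_nm,
                                           harmonic = 1,
                                           n_zero_pixels = sum(!keep)))
  list(pixels = pixels, histogram = hist)
}

#' Build a 2D phasor histogram
#'
#' Bins phasor points (spectral or FLIM) on a regular grid over
#' `[-1, 1] x [-1, 1]`. One count per contributing point.
#'
#' @param points Data frame with `g` and `s` columns (optionally `weight`).
#' @param bins Bins per axis.
#' @param range Common axis range `c(lo, hi)` for g and s.
#' @param metadata Named list stored with the histogram.
#' @return A `phasor_histogram`: list with `counts` (bins x bins matrix,
#'   g on rows), `g_mid`, `s_mid`, `breaks`, `metadata`.
#' @export
phasor_histogram <- function(points, bins = 128, range = c(-1, 1),
                             metadata = list()) {
  if (!is.data.frame(points) || !all(c("g", "s") %in% names(points))) {
    abort("`points` needs `g` and `s` columns.")
  }
  breaks <- seq(range[1], range[2], length.out = bins + 1)
  gi <- findInterval(points$g, breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  si <- findInterval(points$s, breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, bins, bins)
  for (k in seq_along(gi)) counts[gi[k], si[k]] <- counts[gi[k], si[k]] + 1L
  mid <- (head(breaks, -1) + tail(breaks, -1)) / 2
  structure(list(counts = counts, g_mid = mid, s_mid = mid, breaks = breaks,
                 metadata = metadata),
            class = "phasor_histogram")
}

#' @export
print.phasor_histogram <- function(x, ...) {
  cat(sprintf("<phasor_histogram> %d x %d bins, %d counts\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Add phasor histograms bin-wise
#'
#' Pools the histograms of several samples of one tissue type. All inputs
#' must share identical binning.
#'
#' @param histos List of `phasor_histogram` objects.
#' @return A `phasor_histogram` whose counts are the bin-wise sum.
#' @export
aggregate_histograms <- function(histos) {
  if (length(histos) == 0) abort("`histos` must not be empty.")
  purrr::walk(histos, function(h) {
    if (!inherits(h, "phasor_histogram")) {
      abort("All elements must be `phasor_histogram` objects.")
    }
  })
  ref <- histos[[1]]
  for (h in histos[-1]) {
    if (!isTRUE(all.equal(h$breaks, ref$breaks)) ||
        !all(dim(h$counts) == dim(ref$counts))) {
      abort("Histogram binning mismatch; cannot aggregate.")
    }
  }
  out <- ref
  out$counts <- Reduce(`+`, purrr::map(histos, "counts"))
  out
}

#' Reference phasor of a Gaussian emission band
#'
#' Phasor position of a Gaussian spectrum with the given peak wavelength and
#' spectral width (FWHM), evaluated on the NIR detection axis (380--790 nm,
#' 10 nm channels). Used for fluorophore fingerprints (e.g. NADH at 495 nm,
#' FAD at 535 nm) and for the reference grid.
#'
#' @param center_nm Peak emission wavelength (within the axis).
#' @param width_nm Spectral width (FWHM) in nm, > 0.
#' @param axis Wavelength axis, default the NIR detection axis.
#' @return One-row tibble `g`, `s`, `weight`.
#' @export
fingerprint_phasor <- function(center_nm, width_nm, axis = nir_axis()) {
  if (center_nm < min(axis) || center_nm > max(axis)) {
    abort("`center_nm` must lie within the wavelength axis.")
  }
  if (width_nm <= 0) abort("`width_nm` must be > 0.")
  sp <- tibble(wavelength_nm = axis,
               intensity = gaussian_profile(axis, center_nm, width_nm, 1))
  spectral_phasor_transform(sp)
}

#' Reference grid of the spectral phasor plot
#'
#' Phasor positions of Gaussian bands on the lattice of peak wavelengths
#' 380--790 nm (10 nm steps) by spectral widths 20--100 nm (20 nm steps),
#' covering the possible emission maxima of the detection range.
#'
#' @return A tibble `peak_nm`, `width_nm`, `g`, `s` (42 x 5 = 210 nodes).
#' @export
build_wavelength_grid <- function() {
  nodes <- tidyr::expand_grid(peak_nm = seq(380, 790, by = 10),
                              width_nm = seq(20, 100, by = 20))
  ph <- purrr::map2(nodes$peak_nm, nodes$width_nm, fingerprint_phasor)
  mutate(nodes,
         g = purrr::map_dbl(ph, "g"),
         s = purrr::map_dbl(ph, "s"))
}

#' Invert a spectral phasor phase to a peak wavelength
#'
#' Maps the phase angle of a phasor point linearly back onto the wavelength
#' axis. Exact for narrow symmetric bands; approximate for wide ones.
#'
#' @param p One-row data frame with `g`, `s` (e.g. from
#'   [spectral_phasor_transform()]), or a numeric `c(g, s)` pair.
#' @param axis Wavelength axis the phasor was computed on.
#' @return Peak wavelength in nm.
#' @export
invert_phase_to_wavelength <- function(p, axis = nir_axis()) {
  gs <- if (is.data.frame(p)) c(p$g[1], p$s[1]) else p[1:2]
  phase <- atan2(gs[2], gs[1])
  if (phase < -1e-9) phase <- phase + 2 * pi
  phase <- max(phase, 0)
  lambda0 <- axis[1]
  span <- axis[length(axis)] - lambda0
  lambda <- lambda0 + span * phase / (2 * pi)
  if (lambda > max(axis) + 1e-9) {
    abort("Phasor phase maps outside the wavelength axis.")
  }
  lambda
}
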
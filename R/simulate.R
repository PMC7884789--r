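#' Simulate an emission spectrum for one tissue preset
#'
#' Evaluates the preset's Gaussian fluorophore components on the emission
#' axis of the requested excitation (deep-UV: 300--550 nm at 1 nm; NIR:
#' 380--790 nm at 10 nm) and optionally adds photon-counting noise.
#'
#' With `noise_scale > 0` the intensities are drawn as
#' `rpois(I / noise_scale) * noise_scale`, i.e. Poisson counting noise whose
#' relative magnitude grows with `noise_scale`; `noise_scale = 0` returns the
#' exact component sum.
#'
#' @param preset A [tissue_preset()].
#' @param excitation Excitation wavelength in nm: 275, 810 or 890.
#' @param noise_scale Non-negative noise scale (0 = noiseless).
#' @param seed Optional integer seed for reproducible noise.
#' @return A tibble with columns `wavelength_nm`, `intensity`,
#'   `excitation_nm`.
#' @examples
#' sp <- simulate_emission_spectrum(tissue_preset("control"), 275)
#' sp$wavelength_nm[which.max(sp$intensity)] # tryptophan peak near 340 nm
#' @export
simulate_emission_spectrum <- function(preset, excitation, noise_scale = 0,
                                       seed = NULL) {
  stopifnot(inherits(preset, "tissue_preset"))
  assert_excitation(excitation)
  if (!is.numeric(noise_scale) || length(noise_scale) != 1 || noise_scale < 0) {
    abort("`noise_scale` must be a single non-negative number.")
  }
  comps <- preset_components(preset, excitation)
  sp <- eval_components(comps, emission_axis_for(excitation))
  if (noise_scale > 0) {
    sp <- with_seed_or_not(seed, rpois(length(sp$intensity),
                                       sp$intensity / noise_scale) * noise_scale)
    sp <- tibble(wavelength_nm = emission_axis_for(excitation), intensity = sp)
  }
  mutate(sp, excitation_nm = excitation)
}

eval_components <- function(components, axis) {
  intensity <- rep(0, length(axis))
  for (i in seq_len(nrow(components))) {
    intensity <- intensity + gaussian_profile(
      axis, components$center_nm[i], components$fwhm_nm[i],
      components$amplitude[i])
  }
  tibble(wavelength_nm = axis, intensity = intensity)
}

#' Simulate a hyperspectral emission image cube
#'
#' Every pixel is an independent Poisson draw around the preset's emission
#' spectrum scaled so that the expected photon total per pixel equals
#' `photons_per_pixel`.
#'
#' @inheritParams simulate_emission_spectrum
#' @param shape Integer `(ny, nx)` image shape.
#' @param photons_per_pixel Expected photons per pixel (> 0).
#' @param seed Integer seed; identical seeds give bit-identical cubes.
#' @return A `spectral_image`: list with `cube` (ny x nx x n_channels counts),
#'   `wavelengths_nm`, `excitation_nm`.
#' @examples
#' img <- simulate_spectral_image(tissue_preset("grade2"), 890, c(8, 8),
#'                                1e5, seed = 1)
#' dim(img$cube)
#' @export
simulate_spectral_image <- function(preset, excitation, shape,
                                    photons_per_pixel, seed = NULL) {
  stopifnot(inherits(preset, "tissue_preset"))
  assert_excitation(excitation)
  if (length(shape) != 2 || any(shape < 1)) {
    abort("`shape` must be two positive integers (ny, nx).")
  }
  if (!is.numeric(photons_per_pixel) || photons_per_pixel <= 0) {
    abort("`photons_per_pixel` must be > 0.")
  }
  axis <- emission_axis_for(excitation)
  sp <- eval_components(preset_components(preset, excitation), axis)
  p <- sp$intensity / sum(sp$intensity) * photons_per_pixel
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2])
  counts <- with_seed_or_not(seed,
    rpois(ny * nx * length(axis), rep(p, each = ny * nx)))
  spectral_image(array(counts, dim = c(ny, nx, length(axis))), axis, excitation)
}

#' Construct a spectral image object
#'
#' @param cube Numeric array `(ny, nx, n_channels)` of non-negative counts.
#' @param wavelengths_nm Channel wavelengths, strictly increasing, one per
#'   cube page.
#' @param excitation_nm Excitation wavelength in nm.
#' @return A `spectral_image` object.
#' @export
spectral_image <- function(cube, wavelengths_nm, excitation_nm) {
  if (length(dim(cube)) != 3) abort("`cube` must be a 3D array (ny, nx, channel).")
  if (dim(cube)[3] != length(wavelengths_nm)) {
    abort("Number of cube pages must match `wavelengths_nm`.")
  }
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    abort("`wavelengths_nm` must be strictly increasing.")
  }
  if (any(cube < 0)) abort("`cube` must contain non-negative intensities.")
  structure(list(cube = cube, wavelengths_nm = as.numeric(wavelengths_nm),
                 excitation_nm = excitation_nm),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("<spectral_image> %d x %d pixels, %d channels (%g-%g nm), excitation %g nm\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm),
              x$excitation_nm))
  invisible(x)
}

#' Mean emission spectrum of a spectral image
#'
#' @param img A `spectral_image`.
#' @return A tibble `wavelength_nm`, `intensity`, `excitation_nm` (pixel
#'   average per channel).
#' @export
mean_spectrum <- function(img) {
  stopifnot(inherits(img, "spectral_image"))
  tibble(wavelength_nm = img$wavelengths_nm,
         intensity = apply(img$cube, 3, mean),
         excitation_nm = img$excitation_nm)
}

# Draw per-pixel long-lifetime intensity fractions from a preset-style
# llif description: beta(mean, spread), uniform(min, max) or fixed(value).
draw_llif <- function(llif, n) {
  switch(llif$family,
    beta = {
      m <- llif$mean; s <- llif$spread
      k <- m * (1 - m) / s^2 - 1
      if (k <= 0) abort("llif spread too large for a beta distribution.")
      rbeta(n, m * k, (1 - m) * k)
    },
    uniform = runif(n, llif$min, llif$max),
    fixed = rep(llif$value, n),
    abort("Unknown llif family.")
  )
}

#' Simulate a FLIM photon-decay image
#'
#' Each pixel decay is a two-component exponential mixture at the preset's
#' channel lifetimes. The per-pixel mixing fraction `f` is the *intensity*
#' fraction of the long-lived component (the LLIF): the expected decay is
#' `photons_per_pixel * (f * eL(t) + (1 - f) * eS(t))` with `eL`, `eS`
#' area-normalised exponentials sampled on `t = 0, Ts, ..., (L-1) Ts`.
#' Counts are Poisson-distributed unless `poisson = FALSE`, which returns the
#' noiseless expectation.
#'
#' @inheritParams simulate_spectral_image
#' @param channel `"NADH"` or `"FAD"` detection channel.
#' @param L Number of time bins (>= 64).
#' @param Ts Sampling period in ns (> 0).
#' @param llif Optional override of the preset's LLIF distribution: a list
#'   with `family` `"beta"` (`mean`, `spread`), `"uniform"` (`min`, `max`) or
#'   `"fixed"` (`value`).
#' @param poisson Add Poisson photon noise (default `TRUE`).
#' @return A [flim_image()].
#' @examples
#' img <- simulate_flim_image(tissue_preset("control"), "FAD", c(4, 4),
#'                            photons_per_pixel = 1e4, seed = 1)
#' img$L
#' @export
simulate_flim_image <- function(preset, channel, shape, L = 256L,
                                Ts = 12.5 / 256, photons_per_pixel,
                                seed = NULL, llif = NULL, poisson = TRUE) {
  stopifnot(inherits(preset, "tissue_preset"))
  if (L < 64) abort("`L` must be at least 64 time bins.")
  if (Ts <= 0) abort("`Ts` must be > 0 ns.")
  if (length(shape) != 2 || any(shape < 1)) {
    abort("`shape` must be two positive integers (ny, nx).")
  }
  if (!is.numeric(photons_per_pixel) || photons_per_pixel <= 0) {
    abort("`photons_per_pixel` must be > 0.")
  }
  taus <- preset_lifetimes(preset, channel)
  llif <- llif %||% preset$llif
  ny <- as.integer(shape[1]); nx <- as.integer(shape[2]); npix <- ny * nx
  t <- (seq_len(L) - 1) * Ts
  el <- exp(-t / taus["tau_long"]);  el <- el / sum(el)
  es <- exp(-t / taus["tau_short"]); es <- es / sum(es)
  decays <- with_seed_or_not(seed, {
    f <- draw_llif(llif, npix)
    expected <- photons_per_pixel * (outer(f, el) + outer(1 - f, es))
    if (poisson) {
      matrix(rpois(npix * L, expected), nrow = npix)
    } else {
      expected
    }
  })
  flim_image(array(decays, dim = c(ny, nx, L)), Ts = Ts, channel = channel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an excitation--emission matrix (EEM)
#'
#' Emission spectra are generated on the deep-UV emission axis for each
#' excitation wavelength, with every fluorophore's amplitude modulated by a
#' Gaussian excitation-efficiency profile (relative to 275 nm excitation).
#' Tryptophan and collagen profiles peak in the 270--280 nm range; NADH is
#' excited most efficiently near 340 nm.
#'
#' @inheritParams simulate_emission_spectrum
#' @param excitations Excitation wavelengths in nm, all within 270--340.
#' @return An [build_eem()] object (tibble `excitation_nm`, `wavelength_nm`,
#'   `intensity`, class `eem`).
#' @examples
#' eem <- simulate_eem(tissue_preset("control"), seq(270, 340, by = 10))
#' dplyr::n_distinct(eem$excitation_nm)
#' @export
simulate_eem <- function(preset, excitations = seq(270, 340, by = 10)) {
  stopifnot(inherits(preset, "tissue_preset"))
  if (length(excitations) == 0) abort("`excitations` must not be empty.")
  if (any(excitations < 270 | excitations > 340)) {
    abort("All `excitations` must lie within 270-340 nm.")
  }
  prof <- preset$excitation_profiles
  eff <- function(exc) {
    raw <- exp(-((exc - prof$exc_peak_nm)^2) / (2 * prof$exc_sigma_nm^2))
    ref <- exp(-((275 - prof$exc_peak_nm)^2) / (2 * prof$exc_sigma_nm^2))
    setNames(raw / ref, prof$fluorophore)
  }
  rows <- purrr::map(excitations, function(exc) {
    scale <- eff(exc)
    comps <- mutate(preset$duv,
                    amplitude = .data$amplitude * scale[.data$fluorophore])
    eval_components(comps, duv_axis()) %>% mutate(excitation_nm = exc)
  })
  build_eem(bind_rows(rows))
}

#' Simulate a labelled cohort of tissue samples
#'
#' Generates, for each sample: a deep-UV emission spectrum (with mild
#' inter-sample amplitude variability and counting noise), NIR spectral cubes
#' at 810 and 890 nm, FLIM decay cubes for the NADH and FAD channels, and a
#' collagen feature point (`shg_int`, `coll_peak`, `coll_int`) drawn around
#' the preset's generating means.
#'
#' @param n_control,n_g1,n_g2 Per-label sample counts (>= 0, not all zero).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param spectral_shape,flim_shape Image shapes for spectral and FLIM cubes.
#' @param photons_spectral,photons_flim Expected photons per pixel.
#' @param L,Ts FLIM time-base (bins, sampling period in ns).
#' @return A `cohort`: list with `samples` (tibble of labelled list-columns
#'   `duv_spectrum`, `nir810`, `nir890`, `flim_nadh`, `flim_fad`),
#'   `features` (tibble `sample_id`, `label`, `shg_int`, `coll_peak`,
#'   `coll_int`) and `seed`.
#' @examples
#' co <- simulate_cohort(2, 1, 1, seed = 7, flim_shape = c(4, 4),
#'                       photons_flim = 1e4)
#' table(co$features$label)
#' @export
simulate_cohort <- function(n_control, n_g1, n_g2, seed,
                            spectral_shape = c(8, 8), flim_shape = c(16, 16),
                            photons_spectral = 1e5, photons_flim = 1e5,
                            L = 256L, Ts = 12.5 / 256) {
  counts <- c(control = n_control, grade1 = n_g1, grade2 = n_g2)
  if (any(counts < 0)) abort("Sample counts must be non-negative.")
  if (sum(counts) == 0) abort("At least one sample must be requested.")
  labels <- rep(names(counts), counts)
  presets <- lapply(c(control = "control", grade1 = "grade1",
                      grade2 = "grade2"), tissue_preset)
  with_seed_or_not(seed, {
    samples <- purrr::map(seq_along(labels), function(i) {
      preset <- presets[[labels[i]]]
      # mild per-sample amplitude variability on every component
      jitter_preset <- preset
      for (blk in c("duv", "nir810", "nir890")) {
        k <- exp(rnorm(nrow(jitter_preset[[blk]]), 0, 0.05))
        jitter_preset[[blk]]$amplitude <- jitter_preset[[blk]]$amplitude * k
        jitter_preset[[blk]]$area <- jitter_preset[[blk]]$area * k
      }
      feat <- pmax(rnorm(3, preset$feature_targets, preset$feature_spread), 0)
      list(
        label = labels[i],
        duv_spectrum = simulate_emission_spectrum(jitter_preset, 275,
                                                  noise_scale = 1e-3),
        nir810 = simulate_spectral_image(jitter_preset, 810, spectral_shape,
                                         photons_spectral),
        nir890 = simulate_spectral_image(jitter_preset, 890, spectral_shape,
                                         photons_spectral),
        flim_nadh = simulate_flim_image(preset, "NADH", flim_shape, L = L,
                                        Ts = Ts,
                                        photons_per_pixel = photons_flim),
        flim_fad = simulate_flim_image(preset, "FAD", flim_shape, L = L,
                                       Ts = Ts,
                                       photons_per_pixel = photons_flim),
        features = setNames(feat, names(preset$feature_targets))
      )
    })
    sample_id <- sprintf("S%02d", seq_along(labels))
    structure(
      list(
        samples = tibble(
          sample_id = sample_id,
          label = labels,
          duv_spectrum = purrr::map(samples, "duv_spectrum"),
          nir810 = purrr::map(samples, "nir810"),
          nir890 = purrr::map(samples, "nir890"),
          flim_nadh = purrr::map(samples, "flim_nadh"),
          flim_fad = purrr::map(samples, "flim_fad")
        ),
        features = tibble(
          sample_id = sample_id,
          label = labels,
          shg_int = purrr::map_dbl(samples, ~ .x$features["shg_int"]),
          coll_peak = purrr::map_dbl(samples, ~ .x$features["coll_peak"]),
          coll_int = purrr::map_dbl(samples, ~ .x$features["coll_int"])
        ),
        seed = seed
      ),
      class = "cohort"
    )
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort>", nrow(x$samples), "samples:",
      paste(names(table(x$samples$label)), table(x$samples$label),
            sep = "=", collapse = ", "),
      "| seed", x$seed, "\n")
  invisible(x)
}
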
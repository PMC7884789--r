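# shared fixtures built in code

default_timebase <- function() list(L = 256L, Ts = 12.5 / 256)

# noiseless decay sampled on the package time grid, intensity-fraction mix
mixture_decay <- function(f, tau_long, tau_short, L = 256L, Ts = 12.5 / 256,
                          photons = 1) {
  t <- (seq_len(L) - 1) * Ts
  el <- exp(-t / tau_long); el <- el / sum(el)
  es <- exp(-t / tau_short); es <- es / sum(es)
  photons * (f * el + (1 - f) * es)
}

# spectrum_fit-shaped object with prescribed integral proportions, for
# ratio arithmetic tests
fake_fit <- function(int_props, excitation_nm) {
  n <- length(int_props)
  components <- tibble::tibble(
    fluorophore = names(int_props),
    center_nm = seq(400, 700, length.out = n),
    fwhm_nm = rep(40, n),
    amplitude = unname(int_props),
    area = unname(int_props),
    int_prop = unname(int_props)
  )
  structure(list(components = components, residual_norm = 0,
                 converged = TRUE, excitation_nm = excitation_nm,
                 spectrum = tibble::tibble(wavelength_nm = 1:2,
                                           intensity = c(1, 1))),
            class = "spectrum_fit")
}

# Gaussian spectrum tibble on a given axis
gaussian_spectrum <- function(center, fwhm, axis, amplitude = 1,
                              excitation_nm = 890) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  tibble::tibble(
    wavelength_nm = axis,
    intensity = amplitude * exp(-((axis - center)^2) / (2 * sigma^2)),
    excitation_nm = excitation_nm
  )
}

nir_axis_fix <- function() seq(380, 790, by = 10)
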
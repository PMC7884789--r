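#' Normalise an emission spectrum to unit maximum
#'
#' @param spectrum Tibble with `wavelength_nm` and `intensity` columns.
#' @return The spectrum with `intensity` divided by its maximum (NFI scale).
#' @export
normalize_spectrum <- function(spectrum) {
  check_spectrum(spectrum)
  m <- max(spectrum$intensity)
  if (m <= 0) abort("Cannot normalise an all-zero spectrum.")
  mutate(spectrum, intensity = .data$intensity / m)
}

check_spectrum <- function(spectrum) {
  if (!is.data.frame(spectrum) ||
      !all(c("wavelength_nm", "intensity") %in% names(spectrum))) {
    abort("A spectrum needs `wavelength_nm` and `intensity` columns.")
  }
  if (is.unsorted(spectrum$wavelength_nm, strictly = TRUE)) {
    abort("`wavelength_nm` must be strictly increasing.")
  }
  invisible(spectrum)
}

spectrum_excitation <- function(spectrum) {
  if (!"excitation_nm" %in% names(spectrum)) {
    abort("Spectrum is missing an `excitation_nm` column.")
  }
  exc <- unique(spectrum$excitation_nm)
  if (length(exc) != 1) abort("Spectrum has mixed excitation wavelengths.")
  exc
}

#' Fit a spectrum as a constrained sum of fluorophore Gaussians
#'
#' Bounded (trust-region Levenberg--Marquardt) least squares over the centre,
#' bandwidth (FWHM) and non-negative amplitude of one Gaussian per bank
#' fluorophore at the spectrum's excitation. Bounds are the bank windows;
#' bandwidth lower bounds are clipped at one channel width to keep components
#' non-singular; a bank entry whose centre window collapses to a point (deep-UV
#' NADH at 430 nm) is held fixed. Each restart perturbs the starting centres
#' and widths inside their windows and seeds the amplitudes with a clipped
#' linear solve; the best restart is kept.
#'
#' The integral proportion of component *c* is `100 * area_c / sum(areas)`
#' with the analytic Gaussian area `amplitude * sigma * sqrt(2 pi)`, so
#' proportions always total 100 for a successful fit.
#'
#' @param spectrum Tibble with `wavelength_nm`, `intensity`,
#'   `excitation_nm`.
#' @param bank A fluorophore bank, see [default_bank()].
#' @param restarts Number of seeded multi-starts (>= 1).
#' @param seed Integer seed controlling the restart jitter.
#' @return A `spectrum_fit` object: `components` tibble (`fluorophore`,
#'   `center_nm`, `fwhm_nm`, `amplitude`, `area`, `int_prop`),
#'   `residual_norm`, `converged`, `excitation_nm`, and the input `spectrum`.
#' @examples
#' sp <- simulate_emission_spectrum(tissue_preset("control"), 275)
#' fit <- fit_spectrum(sp)
#' tidy(fit)
#' @export
fit_spectrum <- function(spectrum, bank = default_bank(), restarts = 5,
                         seed = 1) {
  check_spectrum(spectrum)
  exc <- spectrum_excitation(spectrum)
  bank <- bank_for_excitation(bank, exc)
  axis <- spectrum$wavelength_nm
  y <- spectrum$intensity
  channel_width <- stats::median(diff(axis))

  n <- nrow(bank)
  lower_c <- bank$center_min; upper_c <- bank$center_max
  lower_w <- pmax(bank$fwhm_min, channel_width)
  upper_w <- pmax(bank$fwhm_max, lower_w)
  fixed_center <- upper_c - lower_c < 1e-12

  # The model is linear in the amplitudes, so the shape search uses variable
  # projection: the optimiser moves only the free centres and widths while
  # the amplitudes are re-solved by a zero-clipped linear fit at every
  # residual evaluation.  A bounded full-parameter polish then enforces the
  # non-negative amplitude formulation exactly.
  n_free_c <- sum(!fixed_center)
  basis_of <- function(centers, widths) {
    vapply(seq_len(n),
           function(i) gaussian_profile(axis, centers[i], widths[i], 1),
           numeric(length(axis)))
  }
  amps_for <- function(B) {
    a <- tryCatch(stats::lm.fit(B, y)$coefficients, error = function(e) NULL)
    if (is.null(a)) a <- rep(max(y) / n, n)
    a[is.na(a)] <- 0
    pmax(a, 0)
  }
  shapes_of <- function(par) {
    centers <- lower_c
    centers[!fixed_center] <- par[seq_len(n_free_c)]
    list(centers = centers, widths = par[n_free_c + seq_len(n)])
  }
  vp_resid <- function(par) {
    p <- shapes_of(par)
    B <- basis_of(p$centers, p$widths)
    as.vector(B %*% amps_for(B)) - y
  }
  vp_lower <- c(lower_c[!fixed_center], lower_w)
  vp_upper <- c(upper_c[!fixed_center], upper_w)

  best <- NULL
  with_seed_or_not(seed, {
    for (r in seq_len(restarts)) {
      if (r == 1) {
        centers0 <- (lower_c + upper_c) / 2
        widths0 <- (lower_w + upper_w) / 2
      } else {
        centers0 <- runif(n, lower_c, upper_c)
        widths0 <- runif(n, lower_w, upper_w)
      }
      ans <- tryCatch(
        minpack.lm::nls.lm(
          par = c(centers0[!fixed_center], widths0),
          lower = vp_lower, upper = vp_upper, fn = vp_resid,
          control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-12,
                                               ptol = 1e-12)),
        error = function(e) NULL)
      if (is.null(ans)) next
      rn <- sqrt(sum(ans$fvec^2))
      if (is.null(best) || rn < best$rn) {
        best <- list(ans = ans, rn = rn)
      }
    }
  })
  if (is.null(best)) {
    abort("Spectral fit failed to converge in every restart.")
  }

  # full-parameter polish: bounded LM over (centres, widths, amplitudes)
  sh <- shapes_of(best$ans$par)
  amps <- amps_for(basis_of(sh$centers, sh$widths))
  full_resid <- function(par) {
    p <- shapes_of(par[seq_len(n_free_c + n)])
    a <- par[n_free_c + n + seq_len(n)]
    as.vector(basis_of(p$centers, p$widths) %*% a) - y
  }
  polish <- tryCatch(
    minpack.lm::nls.lm(
      par = c(best$ans$par, amps),
      lower = c(vp_lower, rep(0, n)), upper = c(vp_upper, rep(Inf, n)),
      fn = full_resid,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)),
    error = function(e) NULL)
  if (!is.null(polish) && sqrt(sum(polish$fvec^2)) <= best$rn) {
    sh <- shapes_of(polish$par[seq_len(n_free_c + n)])
    amps <- polish$par[n_free_c + n + seq_len(n)]
    best <- list(ans = polish, rn = sqrt(sum(polish$fvec^2)))
  }
  converged <- best$ans$info %in% 1:4
  if (!converged) {
    warn("Spectral fit did not formally converge; result flagged.")
  }
  p <- list(centers = sh$centers, widths = sh$widths, amps = amps)
  components <- tibble(
    fluorophore = bank$fluorophore,
    center_nm = p$centers,
    fwhm_nm = p$widths,
    amplitude = p$amps,
    area = gaussian_area(p$widths, p$amps)
  ) %>%
    mutate(int_prop = 100 * .data$area / sum(.data$area))

  structure(
    list(components = components, residual_norm = best$rn,
         converged = converged, excitation_nm = exc, spectrum = spectrum),
    class = "spectrum_fit"
  )
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf("<spectrum_fit> excitation %g nm, residual norm %.4g%s\n",
              x$excitation_nm, x$residual_norm,
              if (x$converged) "" else " (NOT converged)"))
  print(x$components)
  invisible(x)
}

#' @rdname fit_spectrum
#' @param x A `spectrum_fit`.
#' @param ... Unused.
#' @export
tidy.spectrum_fit <- function(x, ...) x$components

#' @rdname fit_spectrum
#' @export
glance.spectrum_fit <- function(x, ...) {
  tibble(excitation_nm = x$excitation_nm, n_components = nrow(x$components),
         residual_norm = x$residual_norm, converged = x$converged)
}

int_prop_of <- function(fit, fluorophore) {
  i <- match(fluorophore, fit$components$fluorophore)
  if (is.na(i)) 0 else fit$components$int_prop[i]
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Deep-UV molecular ratios
#'
#' Ratios of integral proportions from a 275 nm spectrum fit:
#' tryptophan/tyrosine, tryptophan/NADH and tryptophan/collagen. A zero
#' denominator yields `NA` (undefined ratio) rather than an error.
#'
#' @param fit A `spectrum_fit` of a 275 nm spectrum.
#' @return One-row tibble `tryp_tyr`, `tryp_nadh`, `tryp_coll`.
#' @export
duv_ratios <- function(fit) {
  stopifnot(inherits(fit, "spectrum_fit"))
  if (fit$excitation_nm != 275) {
    abort("Deep-UV ratios require a 275 nm spectrum fit.")
  }
  tryp <- int_prop_of(fit, "tryptophan")
  tibble(
    tryp_tyr = safe_ratio(tryp, int_prop_of(fit, "tyrosine")),
    tryp_nadh = safe_ratio(tryp, int_prop_of(fit, "nadh")),
    tryp_coll = safe_ratio(tryp, int_prop_of(fit, "collagen"))
  )
}

#' NIR metabolic ratios
#'
#' From an 810 nm spectrum fit: the optical redox ratio
#' `FAD / (NADH_free + NADH_bound + FAD)`, the porphyrin/NADH ratio `PN`,
#' and the lipopigment/porphyrin ratio `LP = Lipo / (PorphI + PorphII)`.
#' `caption_variant = TRUE` switches LP to the alternative
#' `(PorphI + PorphII) / (Lipo + PorphI + PorphII)` form.
#' Zero denominators yield `NA`.
#'
#' @param fit A `spectrum_fit` of an 810 nm spectrum.
#' @param caption_variant Use the alternative LP definition.
#' @return One-row tibble `redox`, `pn`, `lp`.
#' @export
nir_ratios <- function(fit, caption_variant = FALSE) {
  stopifnot(inherits(fit, "spectrum_fit"))
  if (fit$excitation_nm != 810) {
    abort("NIR metabolic ratios require an 810 nm spectrum fit.")
  }
  fad <- int_prop_of(fit, "fad")
  nadh <- int_prop_of(fit, "nadh_free") + int_prop_of(fit, "nadh_bound")
  porph <- int_prop_of(fit, "porphyrins_i") + int_prop_of(fit, "porphyrins_ii")
  lipo <- int_prop_of(fit, "lipopigments")
  tibble(
    redox = safe_ratio(fad, nadh + fad),
    pn = safe_ratio(porph, nadh),
    lp = if (caption_variant) safe_ratio(porph, lipo + porph)
         else safe_ratio(lipo, porph)
  )
}

#' Collagen feature triple for 3D discrimination
#'
#' Combines a deep-UV (275 nm) fit and an 890 nm fit of the same sample into
#' the three collagen-derived coordinates used by the ellipsoid classifier:
#' `shg_int` (SHG integral proportion at 890 nm, %), `coll_peak` (fitted
#' collagen component peak height after unit-maximum normalisation of the
#' fitted deep-UV curve, x100) and `coll_int` (deep-UV collagen integral
#' proportion, %).
#'
#' @param fit_duv A 275 nm `spectrum_fit`.
#' @param fit_nir890 An 890 nm `spectrum_fit`.
#' @return One-row tibble `shg_int`, `coll_peak`, `coll_int`.
#' @export
collagen_features <- function(fit_duv, fit_nir890) {
  if (missing(fit_duv) || missing(fit_nir890) ||
      !inherits(fit_duv, "spectrum_fit") ||
      !inherits(fit_nir890, "spectrum_fit")) {
    abort("Both a deep-UV and an 890 nm spectrum fit are required.")
  }
  if (fit_duv$excitation_nm != 275 || fit_nir890$excitation_nm != 890) {
    abort("Expected fits at 275 nm and 890 nm excitation.")
  }
  comps <- fit_duv$components
  total <- eval_components(comps, fit_duv$spectrum$wavelength_nm)$intensity
  peak_height <- comps$amplitude[match("collagen", comps$fluorophore)]
  tibble(
    shg_int = int_prop_of(fit_nir890, "shg"),
    coll_peak = 100 * peak_height / max(total),
    coll_int = int_prop_of(fit_duv, "collagen")
  )
}

#' Assemble an excitation--emission matrix
#'
#' Stacks emission spectra recorded at several excitation wavelengths into a
#' long-format EEM, ordered by excitation. All spectra must share the same
#' emission axis.
#'
#' @param spectra A tibble with columns `excitation_nm`, `wavelength_nm`,
#'   `intensity` (rows from several spectra bound together).
#' @return The same data, sorted, with class `eem`.
#' @export
build_eem <- function(spectra) {
  if (!is.data.frame(spectra) || nrow(spectra) == 0 ||
      !all(c("excitation_nm", "wavelength_nm", "intensity") %in%
           names(spectra))) {
    abort("`spectra` needs `excitation_nm`, `wavelength_nm`, `intensity`.")
  }
  axes <- spectra %>%
    group_by(.data$excitation_nm) %>%
    summarise(axis = paste(.data$wavelength_nm, collapse = ","),
              .groups = "drop")
  if (length(unique(axes$axis)) != 1) {
    abort("All spectra in an EEM must share one emission axis.")
  }
  out <- arrange(as_tibble(spectra), .data$excitation_nm, .data$wavelength_nm)
  class(out) <- c("eem", class(out))
  out
}

#' @export
print.eem <- function(x, ...) {
  cat(sprintf("<eem> %d excitations x %d emission channels\n",
              length(unique(x$excitation_nm)),
              length(unique(x$wavelength_nm))))
  NextMethod()
}
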
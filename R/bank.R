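#' Fluorophore Gaussian fitting bank
#'
#' Returns the constraint windows used to decompose tissue emission spectra
#' into endogenous fluorophore contributions. Each fluorophore is modelled as
#' a Gaussian whose peak wavelength and spectral bandwidth (FWHM) are bounded
#' to a literature window, per excitation wavelength:
#'
#' * deep-UV excitation (275 nm): tyrosine, tryptophan, collagen crosslinks
#'   and NADH;
#' * two-photon NIR excitation (810 nm): free NADH, protein-bound NADH, FAD,
#'   lipopigments and two porphyrin bands;
#' * two-photon NIR excitation (890 nm): as 810 nm except that protein-bound
#'   NADH is replaced by the second-harmonic generation (SHG) line of
#'   fibrillar collagen near 445 nm.
#'
#' The NADH entry in the deep-UV block has a fixed centre (430 nm) with only
#' its bandwidth free.
#'
#' @return A tibble with columns `fluorophore`, `excitation_nm`,
#'   `center_min`, `center_max`, `fwhm_min`, `fwhm_max` (all nm).
#' @examples
#' default_bank() |> dplyr::filter(excitation_nm == 275)
#' @export
default_bank <- function() {
  duv <- tibble(
    fluorophore = c("tyrosine", "tryptophan", "collagen", "nadh"),
    excitation_nm = 275,
    center_min = c(301, 335, 380, 430),
    center_max = c(311, 345, 420, 430),
    fwhm_min   = c(0, 0, 0, 0),
    fwhm_max   = c(50, 10, 50, 60)
  )
  nir_core <- tibble(
    fluorophore = c("nadh_free", "fad", "lipopigments",
                    "porphyrins_i", "porphyrins_ii"),
    center_min = c(460, 520, 570, 615, 675),
    center_max = c(470, 530, 600, 630, 690),
    fwhm_min   = c(45, 30, 0, 0, 0),
    fwhm_max   = c(50, 50, 180, 10, 10)
  )
  nir810 <- bind_rows(
    tibble(fluorophore = "nadh_bound", center_min = 443, center_max = 445,
           fwhm_min = 40, fwhm_max = 48),
    nir_core
  ) %>% mutate(excitation_nm = 810)
  nir890 <- bind_rows(
    tibble(fluorophore = "shg", center_min = 440, center_max = 450,
           fwhm_min = 0, fwhm_max = 5),
    nir_core
  ) %>% mutate(excitation_nm = 890)
  bind_rows(duv, nir810, nir890) %>%
    select("fluorophore", "excitation_nm", "center_min", "center_max",
           "fwhm_min", "fwhm_max")
}

bank_for_excitation <- function(bank, excitation) {
  out <- filter(bank, .data$excitation_nm == excitation)
  if (nrow(out) == 0) {
    abort(paste0("No fluorophore bank entries for excitation ", excitation,
                 " nm."))
  }
  out
}
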
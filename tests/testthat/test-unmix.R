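test_that("normalisation rescales to unit maximum and nothing else", {
  sp <- tibble::tibble(wavelength_nm = 1:5, intensity = rep(5, 5))
  expect_equal(normalize_spectrum(sp)$intensity, rep(1, 5))

  sp2 <- gaussian_spectrum(500, 60, nir_axis_fix(), amplitude = 3)
  n1 <- normalize_spectrum(sp2)
  expect_equal(normalize_spectrum(n1), n1) # idempotent
  expect_equal(which.max(n1$intensity), which.max(sp2$intensity))

  expect_error(normalize_spectrum(dplyr::mutate(sp, intensity = 0)))
})

test_that("a single-component spectrum unmixes to 100% of that fluorophore", {
  axis <- seq(300, 550, 1)
  sp <- gaussian_spectrum(340, 8, axis, amplitude = 100, excitation_nm = 275)
  fit <- fit_spectrum(sp)
  props <- setNames(fit$components$int_prop, fit$components$fluorophore)
  expect_gt(props[["tryptophan"]], 99.5)
  expect_lt(sum(props) - props[["tryptophan"]], 0.5)
  expect_equal(sum(props), 100, tolerance = 1e-6)
})

test_that("noiseless bank mixtures refit to the generating parameters", {
  # known area split 60/20/15/5 (tryptophan/collagen/tyrosine/NADH)
  axis <- seq(300, 550, 1)
  truth <- tibble::tibble(
    fluorophore = c("tryptophan", "collagen", "tyrosine", "nadh"),
    center_nm = c(341, 405, 308, 430),
    fwhm_nm = c(9, 45, 28, 52),
    area = c(60, 20, 15, 5)
  )
  sig <- truth$fwhm_nm / (2 * sqrt(2 * log(2)))
  amp <- truth$area / (sig * sqrt(2 * pi))
  intensity <- rowSums(mapply(
    function(c0, s0, a0) a0 * exp(-((axis - c0)^2) / (2 * s0^2)),
    truth$center_nm, sig, amp))
  sp <- tibble::tibble(wavelength_nm = axis, intensity = intensity,
                       excitation_nm = 275)
  fit <- fit_spectrum(sp)
  comp <- dplyr::left_join(fit$components, truth, by = "fluorophore",
                           suffix = c("", "_true"))
  expect_lt(max(abs(comp$center_nm - comp$center_nm_true)), 1)   # <= 1 nm
  expect_lt(max(abs(comp$int_prop - comp$area_true)), 1)         # <= 1 point
  expect_equal(sum(fit$components$int_prop), 100, tolerance = 0.1)
})

test_that("preset spectra at 890 nm recover the per-grade SHG ordering", {
  shg_of <- function(tt) {
    fit <- fit_spectrum(simulate_emission_spectrum(tissue_preset(tt), 890))
    fit$components$int_prop[fit$components$fluorophore == "shg"]
  }
  shg <- c(shg_of("control"), shg_of("grade1"), shg_of("grade2"))
  expect_true(all(diff(shg) > 0))
})

test_that("molecular ratios are pure integral-proportion arithmetic", {
  fit <- fake_fit(c(tryptophan = 60, collagen = 20, tyrosine = 15, nadh = 5),
                  275)
  r <- duv_ratios(fit)
  expect_equal(r$tryp_coll, 3.0)
  expect_equal(r$tryp_tyr, 4.0)
  expect_equal(r$tryp_nadh, 12.0)

  sym <- duv_ratios(fake_fit(c(tryptophan = 50, tyrosine = 50,
                               collagen = 1, nadh = 1), 275))
  expect_equal(sym$tryp_tyr, 1.0)

  nir <- nir_ratios(fake_fit(c(fad = 25, nadh_free = 50, nadh_bound = 25,
                               lipopigments = 10, porphyrins_i = 10,
                               porphyrins_ii = 10), 810))
  expect_equal(nir$redox, 0.25)
  expect_equal(nir$pn, 20 / 75)

  pn <- nir_ratios(fake_fit(c(porphyrins_i = 10, porphyrins_ii = 10,
                              nadh_free = 30, nadh_bound = 10, fad = 5,
                              lipopigments = 40), 810))
  expect_equal(pn$pn, 0.5)
  expect_equal(pn$lp, 2.0)
  expect_equal(nir_ratios(fake_fit(
    c(porphyrins_i = 10, porphyrins_ii = 10, nadh_free = 30,
      nadh_bound = 10, fad = 5, lipopigments = 40), 810),
    caption_variant = TRUE)$lp, 20 / 60)

  # zero denominator flags NA, no error
  zero <- duv_ratios(fake_fit(c(tryptophan = 100, collagen = 0,
                                tyrosine = 0, nadh = 0), 275))
  expect_true(is.na(zero$tryp_coll))

  expect_error(duv_ratios(fake_fit(c(fad = 1), 810)))
  expect_error(nir_ratios(fake_fit(c(tryptophan = 1), 275)))
})

test_that("per-grade molecular ratios reproduce the tissue trends", {
  fits275 <- lapply(c("control", "grade1", "grade2"), function(tt) {
    fit_spectrum(simulate_emission_spectrum(tissue_preset(tt), 275))
  })
  tc <- sapply(fits275, function(f) duv_ratios(f)$tryp_coll)
  tn <- sapply(fits275, function(f) duv_ratios(f)$tryp_nadh)
  expect_true(all(diff(tc) < 0)) # tryptophan/collagen falls with grade
  expect_true(all(diff(tn) < 0)) # tryptophan/NADH falls with grade

  fits810 <- lapply(c("control", "grade2"), function(tt) {
    fit_spectrum(simulate_emission_spectrum(tissue_preset(tt), 810))
  })
  pn <- sapply(fits810, function(f) nir_ratios(f)$pn)
  expect_gt(pn[1], pn[2]) # porphyrin/NADH higher in control
})

test_that("ratios and collagen features are scale invariant", {
  ctrl <- tissue_preset("control")
  sp <- simulate_emission_spectrum(ctrl, 275)
  sp890 <- simulate_emission_spectrum(ctrl, 890)
  f1 <- fit_spectrum(sp); f2 <- fit_spectrum(dplyr::mutate(sp, intensity = intensity * 7.3))
  g1 <- fit_spectrum(sp890); g2 <- fit_spectrum(dplyr::mutate(sp890, intensity = intensity * 7.3))
  expect_equal(duv_ratios(f1), duv_ratios(f2), tolerance = 1e-6)
  expect_equal(collagen_features(f1, g1), collagen_features(f2, g2),
               tolerance = 1e-6)
})

test_that("collagen features read the right quantities from the fits", {
  ctrl <- tissue_preset("control")
  fit_duv <- fit_spectrum(simulate_emission_spectrum(ctrl, 275))
  fit_890 <- fit_spectrum(simulate_emission_spectrum(ctrl, 890))
  feats <- collagen_features(fit_duv, fit_890)
  expect_equal(feats$coll_int,
               fit_duv$components$int_prop[
                 fit_duv$components$fluorophore == "collagen"])
  expect_equal(feats$shg_int,
               fit_890$components$int_prop[
                 fit_890$components$fluorophore == "shg"])
  expect_true(all(unlist(feats) >= 0 & unlist(feats) <= 100))

  # zero collagen amplitude: coll_peak and coll_int vanish
  axis <- seq(300, 550, 1)
  sp_tryp <- gaussian_spectrum(340, 8, axis, 50, excitation_nm = 275)
  fit0 <- fit_spectrum(sp_tryp)
  z <- collagen_features(fit0, fit_890)
  expect_lt(z$coll_int, 0.5)
  expect_lt(z$coll_peak, 0.5)

  expect_error(collagen_features(fit_duv, fit_duv))
  expect_error(collagen_features(fit_890, fit_890))
})

test_that("EEM assembly validates and orders its rows", {
  ctrl <- tissue_preset("control")
  rows <- lapply(c(310, 270, 290), function(e) {
    dplyr::mutate(gaussian_spectrum(340, 10, seq(300, 550, 1),
                                    excitation_nm = NULL),
                  excitation_nm = e)
  })
  eem <- build_eem(dplyr::bind_rows(rows))
  expect_equal(unique(eem$excitation_nm), c(270, 290, 310))
  # permutation invariance
  eem2 <- build_eem(dplyr::bind_rows(rows[c(2, 3, 1)]))
  expect_equal(as.data.frame(eem), as.data.frame(eem2))

  one <- build_eem(rows[[1]])
  expect_equal(nrow(one), length(seq(300, 550, 1)))

  bad <- dplyr::bind_rows(rows[[1]],
                          dplyr::mutate(gaussian_spectrum(340, 10,
                                                          seq(300, 549, 1)),
                                        excitation_nm = 280))
  expect_error(build_eem(bad))
})

test_that("fit residuals shrink as counting noise shrinks", {
  ctrl <- tissue_preset("control")
  resid_at <- function(noise_scale, seeds) {
    sapply(seeds, function(s) {
      sp <- simulate_emission_spectrum(ctrl, 890, noise_scale = noise_scale,
                                       seed = s)
      suppressWarnings(fit_spectrum(sp, restarts = 2))$residual_norm
    })
  }
  seeds <- 1:20
  noisy <- resid_at(0.05, seeds)
  quiet <- resid_at(0.005, seeds)
  expect_gt(mean(noisy), mean(quiet))
})
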
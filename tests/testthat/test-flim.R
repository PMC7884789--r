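test_that("spatial binning sums blocks and conserves photons exactly", {
  ones <- flim_image(array(1, dim = c(512, 512, 4)), Ts = 0.05,
                     channel = "NADH")
  binned <- bin_flim_image(ones, 32)
  expect_equal(dim(binned$decays), c(16, 16, 4))
  expect_true(all(binned$decays == 1024))

  withr::with_seed(9, {
    img <- flim_image(array(rpois(8 * 8 * 64, 5), dim = c(8, 8, 64)),
                      Ts = 0.05, channel = "FAD")
    b <- bin_flim_image(img, 4)
    expect_equal(sum(b$decays), sum(img$decays))
    # block content check on one block
    expect_equal(b$decays[1, 1, ], apply(img$decays[1:4, 1:4, ], 3, sum))
  })
  expect_identical(bin_flim_image(ones, 1), ones)
  expect_error(bin_flim_image(ones, 30))
})

test_that("the decay phasor transform matches the universal-circle theory", {
  tb <- default_timebase()
  omega <- flim_omega(tb$L, tb$Ts)
  expect_equal(omega, 2 * pi / 12.5, tolerance = 1e-12)

  t <- (seq_len(tb$L) - 1) * tb$Ts
  for (tau in c(0.55, 1.2, 2.19)) {
    p <- decay_to_phasor(exp(-t / tau), tb$Ts)
    # on the universal circle, and tau recoverable as s/(omega g)
    expect_lt(abs((p$g - 0.5)^2 + p$s^2 - 0.25), 5e-4)
    expect_equal(lifetime_from_point(p, omega), tau, tolerance = 2e-3)
  }

  # omega tau = 1 lands at the circle apex (0.5, 0.5)
  p1 <- decay_to_phasor(exp(-t / (1 / omega)), tb$Ts)
  expect_equal(c(p1$g, p1$s), c(0.5, 0.5), tolerance = 1e-3)

  # mixture phasor is the intensity-weighted mean of the pure phasors
  dmix <- mixture_decay(0.5, 2.1, 0.55)
  long <- mixture_decay(1, 2.1, 0.55); short <- mixture_decay(0, 2.1, 0.55)
  pm <- decay_to_phasor(dmix, tb$Ts)
  pl <- decay_to_phasor(long, tb$Ts); ps <- decay_to_phasor(short, tb$Ts)
  expect_equal(pm$g, 0.5 * pl$g + 0.5 * ps$g, tolerance = 1e-12)
  expect_equal(pm$s, 0.5 * pl$s + 0.5 * ps$s, tolerance = 1e-12)

  expect_error(decay_to_phasor(numeric(0), tb$Ts))
  expect_error(decay_to_phasor(rep(0, 64), tb$Ts))
})

test_that("simulated decay phasors stay inside the universal circle", {
  tb <- default_timebase()
  img <- simulate_flim_image(tissue_preset("grade1"), "NADH", c(8, 8),
                             photons_per_pixel = 1e5, seed = 21)
  ph <- flim_phasors(img)
  expect_true(all((ph$g - 0.5)^2 + ph$s^2 <= 0.25 + 3e-3))
})

test_that("line fitting and circle intersection recover pure lifetimes", {
  tb <- default_timebase()
  omega <- flim_omega(tb$L, tb$Ts)
  t <- (seq_len(tb$L) - 1) * tb$Ts

  pts <- dplyr::bind_rows(decay_to_phasor(exp(-t / 0.55), tb$Ts),
                          decay_to_phasor(exp(-t / 2.1), tb$Ts))
  line <- fit_phasor_line(pts)
  comp <- lifetime_components(line, omega)
  expect_equal(comp$tau_short, 0.55, tolerance = 0.01)
  expect_equal(comp$tau_long, 2.10, tolerance = 0.01)
  # intersection points satisfy the circle equation to 1e-9
  expect_true(all(abs((comp$points$g - 0.5)^2 + comp$points$s^2 - 0.25) <
                    1e-9))

  # order invariance of the two-point fit
  line2 <- fit_phasor_line(pts[2:1, ])
  expect_equal(line$slope, line2$slope)
  expect_equal(line$intercept, line2$intercept)

  # histogram route: two mono-exponential pixel clusters
  clusters <- dplyr::bind_rows(
    pts[rep(1, 40), ], pts[rep(2, 40), ])
  h <- phasor_histogram(clusters)
  comp_h <- lifetime_components(fit_phasor_line(h), omega)
  expect_equal(comp_h$tau_short, 0.55, tolerance = 0.02)
  expect_equal(comp_h$tau_long, 2.10, tolerance = 0.02)

  # degenerate: all mass at one point
  expect_error(fit_phasor_line(pts[c(1, 1), ]))

  # tangent line s = 0.5 touches at the apex; tau there is 1/omega
  tangent <- structure(list(slope = 0, intercept = 0.5),
                       class = "phasor_line")
  expect_warning(tp <- intersect_universal_circle(tangent))
  expect_equal(c(tp$g, tp$s), c(0.5, 0.5))
  expect_equal(lifetime_from_point(tp, omega), 1 / omega)
  # non-intersecting line
  off <- structure(list(slope = 0, intercept = 0.9), class = "phasor_line")
  expect_error(intersect_universal_circle(off))
})

test_that("LLIF equals the long-component intensity fraction", {
  tb <- default_timebase()
  omega <- flim_omega(tb$L, tb$Ts)
  t <- (seq_len(tb$L) - 1) * tb$Ts
  pl <- decay_to_phasor(exp(-t / 2.1), tb$Ts)
  ps <- decay_to_phasor(exp(-t / 0.55), tb$Ts)
  comp <- lifetime_components(fit_phasor_line(dplyr::bind_rows(ps, pl)),
                              omega)

  # exact chord mixtures: LLIF = f to machine precision
  fs <- seq(0.1, 0.9, by = 0.1)
  chord <- tibble::tibble(
    g = comp$points$g[1] + fs * diff(comp$points$g),
    s = comp$points$s[1] + fs * diff(comp$points$s))
  expect_equal(llif_project(chord, comp)$llif, fs, tolerance = 1e-6)

  # endpoints and midpoint
  ends <- llif_project(comp$points, comp)
  expect_equal(ends$llif, c(0, 1))
  mid <- llif_project(tibble::tibble(g = mean(comp$points$g),
                                     s = mean(comp$points$s)), comp)
  expect_equal(mid$llif, 0.5)

  # noiseless decay mixtures across f: within 0.02 of the generating f
  mix_ph <- dplyr::bind_rows(lapply(fs, function(f) {
    decay_to_phasor(mixture_decay(f, 2.1, 0.55), tb$Ts)
  }))
  expect_lt(max(abs(llif_project(mix_ph, comp)$llif - fs)), 0.02)
})

test_that("bi-exponential fits recover generating lifetimes", {
  tb <- default_timebase()
  # noiseless single exponential: main lifetime within 0.1%
  pure <- mixture_decay(1, 2.19, 0.4, photons = 1e6)
  fit <- fit_biexponential(pure, tb$Ts)
  main_tau <- if (fit$A2 >= fit$A1) fit$tau2 else fit$tau1
  expect_equal(main_tau, 2.19, tolerance = 1e-3)

  # Poisson mixture at the control FAD lifetimes, 1e6 photons
  withr::with_seed(17, {
    y <- rpois(tb$L, mixture_decay(0.4, 2.1, 0.55, photons = 1e6))
  })
  fit2 <- fit_biexponential(y, tb$Ts)
  expect_equal(fit2$tau1, 0.55, tolerance = 0.05)
  expect_equal(fit2$tau2, 2.10, tolerance = 0.05)
  expect_true(fit2$accepted)

  # acceptance rate on correctly specified simulations
  accepted <- withr::with_seed(23, {
    vapply(1:20, function(i) {
      y <- rpois(tb$L, mixture_decay(0.3, 2.19, 0.4, photons = 1e6))
      fit_biexponential(y, tb$Ts)$accepted
    }, logical(1))
  })
  expect_gte(mean(accepted), 0.9)

  # the chi-squared window is enforced
  bad <- fit2
  bad$chi2_reduced <- 1.5
  expect_false(accept_fit(bad))
  low <- fit2
  low$chi2_reduced <- 0.5
  expect_false(accept_fit(low))
  expect_error(fit_biexponential(rep(1, 64), tb$Ts, min_photons = 1000))
})

test_that("cohort FLIM analysis pools the line and orders LLIF by grade", {
  tb <- default_timebase()
  make_set <- function(tt, n, seed) {
    lapply(seq_len(n), function(i) {
      simulate_flim_image(tissue_preset(tt), "NADH", c(8, 8),
                          photons_per_pixel = 1e5, seed = seed + i)
    })
  }
  images <- list(control = make_set("control", 2, 100),
                 grade1 = make_set("grade1", 2, 200),
                 grade2 = make_set("grade2", 2, 300))
  res <- analyze_flim_cohort(images, channel = "NADH")
  means <- setNames(res$llif$mean_llif, res$llif$type)
  expect_lt(means[["control"]], means[["grade1"]])
  expect_lt(means[["grade1"]], means[["grade2"]])

  # single-type pool equals the per-type analysis
  solo <- analyze_flim_cohort(images["control"], channel = "NADH")
  ph <- dplyr::bind_rows(lapply(images$control, flim_phasors))
  comp <- lifetime_components(fit_phasor_line(phasor_histogram(ph)),
                              flim_omega(tb$L, tb$Ts))
  expect_equal(solo$components$tau_long, comp$tau_long)

  # a 3x3 mosaic analysed jointly equals its 9 tiles analysed jointly
  tiles <- make_set("grade1", 9, 400)
  mosaic_decays <- array(0, dim = c(24, 24, tb$L))
  for (k in seq_len(9)) {
    r <- ((k - 1) %% 3) * 8 + 1:8
    c <- ((k - 1) %/% 3) * 8 + 1:8
    mosaic_decays[r, c, ] <- tiles[[k]]$decays
  }
  mosaic <- flim_image(mosaic_decays, Ts = tb$Ts, channel = "NADH")
  h_tiles <- phasor_histogram(dplyr::bind_rows(lapply(tiles, flim_phasors)))
  h_mosaic <- phasor_histogram(flim_phasors(mosaic))
  expect_equal(h_mosaic$counts, h_tiles$counts)

  expect_error(analyze_flim_cohort(list(), channel = "NADH"))
  expect_error(analyze_flim_cohort(list(control = list()), channel = "NADH"))
})
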
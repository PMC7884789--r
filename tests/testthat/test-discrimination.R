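test_that("the 60% ellipsoid uses the chi-squared(3) scaling", {
  withr::with_seed(31, {
    pts <- tibble::tibble(shg_int = rnorm(100, 10), coll_peak = rnorm(100, 20),
                          coll_int = rnorm(100, 30))
  })
  e <- fit_ellipsoid(pts, mass = 0.60)
  expect_equal(e$scale, qchisq(0.60, 3), tolerance = 1e-12)
  expect_equal(e$scale, 2.946, tolerance = 1e-3)

  # large-sample fit recovers mean and covariance of a unit Gaussian
  withr::with_seed(32, {
    big <- tibble::tibble(shg_int = rnorm(1e5), coll_peak = rnorm(1e5),
                          coll_int = rnorm(1e5))
  })
  eb <- fit_ellipsoid(big)
  expect_lt(max(abs(eb$mean)), 0.05)
  expect_lt(max(abs(eb$covariance - diag(3))), 0.05)

  expect_error(fit_ellipsoid(pts[1:3, ]))
  flat <- dplyr::mutate(pts, coll_int = shg_int + coll_peak)
  expect_error(fit_ellipsoid(flat))
  expect_error(fit_ellipsoid(pts, mass = 0))
})

test_that("membership is Mahalanobis-based, boundary inclusive, affine equivariant", {
  withr::with_seed(33, {
    pts <- tibble::tibble(shg_int = rnorm(200, 5, 2),
                          coll_peak = rnorm(200, 8, 3),
                          coll_int = rnorm(200, 12, 1))
  })
  e <- fit_ellipsoid(pts)
  expect_true(ellipsoid_contains(e, tibble::tibble(
    shg_int = e$mean[1], coll_peak = e$mean[2], coll_int = e$mean[3])))

  # a point placed exactly on the boundary is inside
  dir <- c(1, 0, 0)
  lam <- sqrt(e$scale / mahalanobis(matrix(e$mean + dir, 1), e$mean,
                                    e$covariance))
  boundary <- e$mean + lam * dir
  expect_true(ellipsoid_contains(e, matrix(boundary, 1)))
  expect_false(ellipsoid_contains(e, matrix(e$mean + 1.0001 * lam * dir, 1)))

  # affine transform: membership is preserved under y = A x + b
  A <- matrix(c(2, 0.3, 0, 0.1, 1.5, 0.2, 0, 0, 0.8), 3, 3)
  b <- c(5, -2, 7)
  m <- as.matrix(pts)
  tm <- t(A %*% t(m) + b)
  colnames(tm) <- colnames(m)
  et <- fit_ellipsoid(tibble::as_tibble(tm))
  inside0 <- ellipsoid_contains(e, m)
  inside1 <- ellipsoid_contains(et, tm)
  expect_equal(inside0, inside1)
})

test_that("a fitted ellipsoid holds its nominal probability mass", {
  sigma <- matrix(c(4, 1, 0.5, 1, 3, 0.8, 0.5, 0.8, 2), 3, 3)
  ch <- chol(sigma)
  draw <- function(n) {
    m <- matrix(rnorm(n * 3), n, 3) %*% ch
    m <- sweep(m, 2, c(10, 20, 30), "+")
    colnames(m) <- c("shg_int", "coll_peak", "coll_int")
    m
  }
  withr::with_seed(34, {
    train <- draw(1e5)
    test <- draw(1e5)
  })
  e <- fit_ellipsoid(tibble::as_tibble(train), mass = 0.60)
  inside <- mean(ellipsoid_contains(e, test))
  expect_equal(inside, 0.60, tolerance = 0.01)
})

test_that("Monte-Carlo overlap behaves on analytic cases", {
  withr::with_seed(35, {
    pts <- tibble::tibble(shg_int = rnorm(500, 10, 2),
                          coll_peak = rnorm(500, 10, 2),
                          coll_int = rnorm(500, 10, 2))
  })
  e <- fit_ellipsoid(pts)
  expect_equal(ellipsoid_overlap_volume(e, e, n_mc = 2e4, seed = 1), 1)

  far <- e
  far$mean <- e$mean + 500
  expect_equal(ellipsoid_overlap_volume(e, far, n_mc = 2e4, seed = 1), 0)

  # concentric ellipsoid with doubled linear scale: volume ratio 1/8
  bigger <- e
  bigger$covariance <- 4 * e$covariance
  ov <- ellipsoid_overlap_volume(e, bigger, n_mc = 2e5, seed = 2)
  expect_equal(ov, 1 / 8, tolerance = 0.02)
  expect_error(ellipsoid_overlap_volume(e, e, n_mc = 100))
})

test_that("the gated classification rules follow the diagnosis thresholds", {
  make_cloud <- function(center, n = 30, sd = 0.8, seed = 1) {
    withr::with_seed(seed, tibble::tibble(
      shg_int = rnorm(n, center[1], sd),
      coll_peak = rnorm(n, center[2], sd),
      coll_int = rnorm(n, center[3], sd)))
  }
  ellipsoids <- list(
    control = fit_ellipsoid(make_cloud(c(1.5, 6, 12), seed = 1)),
    grade1 = fit_ellipsoid(make_cloud(c(12, 24, 38), seed = 2)),
    grade2 = fit_ellipsoid(make_cloud(c(35, 45, 50), seed = 3)))

  at <- function(shg, peak, coll) {
    tibble::tibble(shg_int = shg, coll_peak = peak, coll_int = coll)
  }
  # inside grade2, SHG 30 -> tumor; inside control, SHG 1 -> control
  expect_equal(classify_control_tumor(at(35, 45, 50), ellipsoids), "tumor")
  expect_equal(classify_control_tumor(at(1.5, 6, 12), ellipsoids), "control")
  # inside no ellipsoid -> indeterminate
  expect_equal(classify_control_tumor(at(100, 100, 100), ellipsoids),
               "indeterminate")
  # inside control but SHG above the gate -> indeterminate
  shifted <- ellipsoids
  shifted$control <- fit_ellipsoid(make_cloud(c(3, 6, 12), seed = 4))
  expect_equal(classify_control_tumor(at(3, 6, 12), shifted),
               "indeterminate")

  expect_equal(classify_grade(at(12, 24, 38), ellipsoids), "grade1")
  expect_equal(classify_grade(at(35, 45, 50), ellipsoids), "grade2")
  # the grade I gate is inclusive at 22
  g1_edge <- ellipsoids
  g1_edge$grade1 <- fit_ellipsoid(make_cloud(c(22, 24, 38), seed = 5))
  expect_equal(classify_grade(at(22, 24, 38), g1_edge), "grade1")
  expect_equal(classify_grade(at(1.5, 6, 12), ellipsoids), "indeterminate")
})

test_that("sensitivity and specificity are the standard confusion ratios", {
  expect_equal(
    sensitivity_specificity(tibble::tibble(tp = 15, fp = 0, tn = 1, fn = 0)),
    tibble::tibble(se = 1, sp = 1))
  expect_equal(
    sensitivity_specificity(tibble::tibble(tp = 15, fp = 1, tn = 9, fn = 0)),
    tibble::tibble(se = 1, sp = 0.9))
  expect_equal(
    sensitivity_specificity(tibble::tibble(tp = 1, fp = 1, tn = 1, fn = 1)),
    tibble::tibble(se = 0.5, sp = 0.5))
  und <- sensitivity_specificity(tibble::tibble(tp = 0, fp = 1, tn = 1,
                                                fn = 0))
  expect_true(is.na(und$se))

  counts <- confusion_counts(c(TRUE, TRUE, FALSE, FALSE),
                             c("tumor", "indeterminate", "control",
                               "indeterminate"),
                             positive = "tumor", negative = "control")
  # conservative mode: indeterminates count against their own class
  expect_equal(as.numeric(counts), c(1, 1, 1, 1))
  excl <- confusion_counts(c(TRUE, TRUE, FALSE, FALSE),
                           c("tumor", "indeterminate", "control",
                             "indeterminate"),
                           positive = "tumor", negative = "control",
                           indeterminate = "exclude")
  expect_equal(as.numeric(excl), c(1, 0, 1, 0))
})

test_that("threshold rules reproduce the diagnostic table", {
  f <- tibble::tibble(shg_int = 30, coll_peak = 40, coll_int = 30)
  v <- threshold_rules(f, bound_nadh_tau = 1.7, bound_fad_tau = 1.2)
  verdicts <- setNames(v$rules$verdict, v$rules$rule)
  expect_equal(verdicts[["coll_int"]], "tumor")
  expect_equal(verdicts[["shg_int"]], "grade2")
  expect_equal(verdicts[["bound_nadh_tau"]], "grade2")
  expect_equal(verdicts[["bound_fad_tau"]], "grade2")
  expect_equal(v$majority$control_tumor, "tumor")
  expect_equal(v$majority$grade, "grade2")

  ctrl <- threshold_rules(
    tibble::tibble(shg_int = 1, coll_peak = 5, coll_int = 10),
    bound_nadh_tau = 2.19, bound_fad_tau = 0.55)
  expect_true(all(ctrl$rules$verdict == "control"))
  expect_equal(ctrl$majority$control_tumor, "control")

  mid <- threshold_rules(
    tibble::tibble(shg_int = 10, coll_peak = 25, coll_int = 40),
    bound_nadh_tau = 2.0, bound_fad_tau = 0.8)
  expect_equal(setNames(mid$rules$verdict, mid$rules$rule)[["shg_int"]],
               "grade1")
  expect_equal(mid$majority$grade, "grade1")
})

test_that("well-separated cohorts are recovered perfectly; mixing degrades", {
  co <- simulate_cohort(10, 7, 8, seed = 41, spectral_shape = c(2, 2),
                        flim_shape = c(2, 2), photons_flim = 1e4,
                        photons_spectral = 1e4)
  res <- discriminate_cohort(co$features, indeterminate = "exclude")
  expect_equal(res$control_tumor$se, 1)
  expect_equal(res$control_tumor$sp, 1)
  expect_equal(res$grade$se, 1)
  expect_equal(res$grade$sp, 1)
  expect_lt(max(res$overlap), 0.01)

  # classification result is invariant to the row order of the features
  perm <- withr::with_seed(42, sample(nrow(co$features)))
  res_p <- discriminate_cohort(co$features[perm, ],
                               indeterminate = "exclude")
  expect_equal(res_p$control_tumor$counts, res$control_tumor$counts)
  expect_equal(res_p$grade$counts, res$grade$counts)

  # collapse the class separation: errors must appear
  blurred <- co$features
  withr::with_seed(43, {
    blurred$shg_int <- rnorm(nrow(blurred), 10, 8)
    blurred$coll_peak <- rnorm(nrow(blurred), 25, 15)
    blurred$coll_int <- rnorm(nrow(blurred), 30, 15)
  })
  res_b <- discriminate_cohort(blurred, indeterminate = "exclude")
  expect_lt(min(res_b$control_tumor$se, res_b$control_tumor$sp,
                res_b$grade$se, res_b$grade$sp, na.rm = TRUE), 1)
})
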
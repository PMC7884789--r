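#' Construct a FLIM decay image
#'
#' A FLIM image stores one TCSPC photon-decay histogram per pixel together
#' with its time base: `L` time bins of width `Ts` nanoseconds.
#'
#' @param decays Array `(ny, nx, L)` of non-negative photon counts.
#' @param Ts Sampling period in ns (> 0).
#' @param channel Detection channel label, `"NADH"` or `"FAD"`.
#' @return A `flim_image` object with fields `decays`, `Ts`, `L`, `channel`.
#' @export
flim_image <- function(decays, Ts, channel) {
  if (length(dim(decays)) != 3) {
    abort("`decays` must be a 3D array (ny, nx, time).")
  }
  if (any(decays < 0)) abort("Photon counts must be non-negative.")
  if (!is.numeric(Ts) || Ts <= 0) abort("`Ts` must be > 0 ns.")
  if (!channel %in% c("NADH", "FAD")) {
    abort("`channel` must be \"NADH\" or \"FAD\".")
  }
  structure(list(decays = decays, Ts = Ts, L = dim(decays)[3],
                 channel = channel),
            class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$decays)
  cat(sprintf("<flim_image> %s channel, %d x %d pixels, L = %d, Ts = %.6g ns (window %.4g ns)\n",
              x$channel, d[1], d[2], x$L, x$Ts, x$L * x$Ts))
  invisible(x)
}

#' Spatially bin a FLIM image
#'
#' Sums the decay curves of each `factor x factor` pixel block into one
#' decay, e.g. reducing a 512 x 512 image to 16 x 16 super-pixels of
#' 1024 summed decays each. Total photons are conserved exactly.
#'
#' @param img A `flim_image`.
#' @param factor Integer binning factor; image sides must be divisible by it.
#' @return A `flim_image` with shape `(ny/factor, nx/factor, L)`.
#' @export
bin_flim_image <- function(img, factor = 32L) {
  stopifnot(inherits(img, "flim_image"))
  factor <- as.integer(factor)
  d <- dim(img$decays)
  if (factor < 1) abort("`factor` must be a positive integer.")
  if (factor == 1L) return(img)
  if (d[1] %% factor != 0 || d[2] %% factor != 0) {
    abort("Image shape must be divisible by the binning factor.")
  }
  ny <- d[1] %/% factor; nx <- d[2] %/% factor
  # reshape (factor, ny, factor, nx, L) and sum over the two factor axes
  a <- array(img$decays, dim = c(factor, ny, factor, nx, d[3]))
  binned <- apply(a, c(2, 4, 5), sum)
  flim_image(array(binned, dim = c(ny, nx, d[3])), Ts = img$Ts,
             channel = img$channel)
}

#' Phasor transform of a photon decay
#'
#' First-harmonic phasor of a decay histogram at the fundamental angular
#' frequency `omega = 2 pi / (L * Ts)`:
#' `g = sum(I cos(omega t)) / sum(I)`, `s = sum(I sin(omega t)) / sum(I)`.
#' Photon-bin centre timestamps `t = (n + 1/2) Ts` and the sinc factor
#' `(omega Ts / 2) / sin(omega Ts / 2)` correct for the finite bin width so
#' that mono-exponential decays land on the universal circle
#' (centre (0.5, 0), radius 0.5) rather than slightly inside it.
#' `m` carries the decay's intensity integral (total counts) for
#' intensity-weighted pooling.
#'
#' @param decay Numeric vector of photon counts (sum > 0).
#' @param Ts Sampling period in ns.
#' @param L Signal length; defaults to `length(decay)`.
#' @return One-row tibble `g`, `s`, `m`.
#' @export
decay_to_phasor <- function(decay, Ts, L = length(decay)) {
  if (length(decay) == 0 || sum(decay) <= 0) {
    abort("Cannot transform an empty decay.")
  }
  ph <- phasor_rows(matrix(decay, nrow = 1), Ts, L)
  tibble(g = ph$g, s = ph$s, m = ph$m)
}

# vectorised phasor transform: one decay per row
phasor_rows <- function(mat, Ts, L = ncol(mat)) {
  omega <- 2 * pi / (L * Ts)
  t_mid <- (seq_len(L) - 0.5) * Ts
  totals <- rowSums(mat)
  corr <- (omega * Ts / 2) / sin(omega * Ts / 2)
  list(g = corr * as.vector(mat %*% cos(omega * t_mid)) / totals,
       s = corr * as.vector(mat %*% sin(omega * t_mid)) / totals,
       m = totals)
}

#' Angular frequency of a FLIM time base
#'
#' @param L Signal length (time bins).
#' @param Ts Sampling period in ns.
#' @return `omega = 2 pi / (L * Ts)` in rad/ns.
#' @export
flim_omega <- function(L, Ts) 2 * pi / (L * Ts)

#' Per-pixel phasors of a FLIM image
#'
#' @param img A `flim_image`.
#' @return Tibble `x`, `y`, `g`, `s`, `m` over pixels with at least one
#'   photon.
#' @export
flim_phasors <- function(img) {
  stopifnot(inherits(img, "flim_image"))
  d <- dim(img$decays)
  flat <- matrix(img$decays, nrow = d[1] * d[2])
  keep <- rowSums(flat) > 0
  if (!any(keep)) abort("Every pixel of the FLIM image is empty.")
  ph <- phasor_rows(flat[keep, , drop = FALSE], img$Ts, img$L)
  idx <- which(keep)
  tibble(y = ((idx - 1) %% d[1]) + 1,
         x = ((idx - 1) %/% d[1]) + 1,
         g = ph$g, s = ph$s, m = ph$m)
}

#' Fit the phasor chord line
#'
#' Count-weighted total-least-squares line through the dense region of a
#' phasor histogram: bins holding at least `density_frac` of the maximum bin
#' count enter a weighted principal-component fit. For a two-lifetime
#' system the phasors of all mixtures lie on the chord joining the two pure
#' component phasors, so this line carries the component information.
#'
#' @param x A `phasor_histogram`, or a data frame of phasor points
#'   (`g`, `s`, optional `m` weights) which is used directly.
#' @param density_frac Occupancy threshold as a fraction of the maximum bin
#'   count (histogram method).
#' @return A `phasor_line`: list with `slope` and `intercept`
#'   (`s = slope * g + intercept`).
#' @export
fit_phasor_line <- function(x, density_frac = 0.5) {
  UseMethod("fit_phasor_line")
}

#' @export
fit_phasor_line.phasor_histogram <- function(x, density_frac = 0.5) {
  occupied <- which(x$counts > 0, arr.ind = TRUE)
  if (nrow(occupied) < 2) {
    abort("Phasor line undefined: fewer than two occupied bins.")
  }
  thresh <- density_frac * max(x$counts)
  keep <- which(x$counts >= thresh, arr.ind = TRUE)
  if (nrow(keep) < 2) keep <- occupied
  tls_line(g = x$g_mid[keep[, 1]], s = x$s_mid[keep[, 2]],
           w = x$counts[keep])
}

#' @export
fit_phasor_line.data.frame <- function(x, density_frac = 0.5) {
  if (!all(c("g", "s") %in% names(x))) {
    abort("`x` needs `g` and `s` columns.")
  }
  if (nrow(x) < 2) abort("Phasor line undefined: fewer than two points.")
  w <- if ("m" %in% names(x)) x$m else rep(1, nrow(x))
  tls_line(x$g, x$s, w)
}

tls_line <- function(g, s, w) {
  w <- w / sum(w)
  mg <- sum(w * g); ms <- sum(w * s)
  cgg <- sum(w * (g - mg)^2); css <- sum(w * (s - ms)^2)
  cgs <- sum(w * (g - mg) * (s - ms))
  if (cgg + css < 1e-24) {
    abort("Phasor line undefined: all mass at a single point.")
  }
  ev <- eigen(matrix(c(cgg, cgs, cgs, css), 2, 2), symmetric = TRUE)
  v <- ev$vectors[, 1]
  if (abs(v[1]) < 1e-12) {
    abort("Degenerate (vertical) phasor line; cannot express as slope/intercept.")
  }
  slope <- v[2] / v[1]
  structure(list(slope = slope, intercept = ms - slope * mg),
            class = "phasor_line")
}

#' @export
print.phasor_line <- function(x, ...) {
  cat(sprintf("<phasor_line> s = %.5f g + %.5f\n", x$slope, x$intercept))
  invisible(x)
}

#' Intersect a phasor line with the universal circle
#'
#' Solves `(g - 0.5)^2 + s^2 = 0.25` along `s = slope * g + intercept`.
#' The two intersection points are the phasors of the two pure
#' mono-exponential components of the mixture.
#'
#' @param line A `phasor_line`.
#' @param tol Discriminant tolerance below which the line is treated as
#'   tangent (single flagged solution).
#' @return Tibble of intersection points `g`, `s` (one row if tangent, with
#'   attribute `tangent = TRUE`).
#' @export
intersect_universal_circle <- function(line, tol = 1e-12) {
  stopifnot(inherits(line, "phasor_line"))
  a <- line$slope; b <- line$intercept
  A <- 1 + a^2; B <- 2 * a * b - 1; C <- b^2
  disc <- B^2 - 4 * A * C
  if (disc < -tol) {
    abort("The phasor line does not intersect the universal circle.")
  }
  if (disc <= tol) {
    gg <- -B / (2 * A)
    out <- tibble(g = gg, s = a * gg + b)
    attr(out, "tangent") <- TRUE
    warn("Phasor line is tangent to the universal circle; single solution.")
    return(out)
  }
  gg <- c((-B - sqrt(disc)) / (2 * A), (-B + sqrt(disc)) / (2 * A))
  tibble(g = gg, s = a * gg + b)
}

#' Lifetime of a point on the universal circle
#'
#' For a mono-exponential phasor, `tau = s / (omega * g)`.
#'
#' @param p One-row data frame with `g`, `s`, or numeric `c(g, s)`.
#' @param omega Angular frequency in rad/ns, see [flim_omega()].
#' @return Lifetime in ns.
#' @export
lifetime_from_point <- function(p, omega) {
  gs <- if (is.data.frame(p)) cbind(p$g, p$s) else matrix(p[1:2], 1)
  as.vector(gs[, 2] / (omega * gs[, 1]))
}

#' Extract the two component lifetimes from a phasor line
#'
#' Combines [intersect_universal_circle()] and [lifetime_from_point()] into
#' the short/long lifetime pair of a two-component system.
#'
#' @param line A `phasor_line`.
#' @param omega Angular frequency in rad/ns.
#' @return A `lifetime_components` object: `tau_short`, `tau_long` (ns),
#'   `line`, and `points` (tibble `g`, `s`, `tau_ns`, ordered short then
#'   long).
#' @export
lifetime_components <- function(line, omega) {
  pts <- intersect_universal_circle(line)
  if (nrow(pts) < 2) {
    abort("Tangent line: two distinct component lifetimes are undefined.")
  }
  taus <- lifetime_from_point(pts, omega)
  ord <- order(taus)
  pts <- pts[ord, ]
  taus <- taus[ord]
  structure(list(tau_short = taus[1], tau_long = taus[2], line = line,
                 omega = omega,
                 points = mutate(pts, tau_ns = taus)),
            class = "lifetime_components")
}

#' @export
print.lifetime_components <- function(x, ...) {
  cat(sprintf("<lifetime_components> tau_short = %.4g ns, tau_long = %.4g ns\n",
              x$tau_short, x$tau_long))
  invisible(x)
}

#' @rdname lifetime_components
#' @param x A `lifetime_components`.
#' @param ... Unused.
#' @export
tidy.lifetime_components <- function(x, ...) x$points

#' Long-lifetime intensity fraction (LLIF) of phasor points
#'
#' Projects each phasor orthogonally onto the component chord and expresses
#' it as the normalised coordinate from the short-lifetime intersection
#' towards the long-lifetime intersection, clipped to `[0, 1]`. By phasor
#' linearity this coordinate equals the fraction of the emitted intensity
#' contributed by the long-lived component.
#'
#' @param phasors Tibble with `g`, `s` (e.g. from [flim_phasors()]).
#' @param components A `lifetime_components` with two distinct intersections.
#' @return The input tibble with an added `llif` column.
#' @export
llif_project <- function(phasors, components) {
  stopifnot(inherits(components, "lifetime_components"))
  pts <- components$points
  d <- c(pts$g[2] - pts$g[1], pts$s[2] - pts$s[1])
  len2 <- sum(d^2)
  if (len2 < 1e-20) abort("Coincident intersections: LLIF undefined.")
  tcoord <- ((phasors$g - pts$g[1]) * d[1] +
             (phasors$s - pts$s[1]) * d[2]) / len2
  mutate(phasors, llif = pmin(pmax(tcoord, 0), 1))
}

#' Histogram of LLIF values
#'
#' @param llif Numeric vector of fractions in `[0, 1]` (or a tibble from
#'   [llif_project()]).
#' @param bins Number of bins over `[0, 1]`.
#' @param weights Optional per-value weights (e.g. decay intensity `m`);
#'   default unweighted counts.
#' @param channel Optional channel label used to name the components: the
#'   long-lived component is protein-bound NADH on the NADH channel and free
#'   FAD on the FAD channel.
#' @return Tibble `bin_mid`, `count` with class `llif_histogram` and
#'   attributes `channel`, `component_labels`.
#' @export
llif_histogram <- function(llif, bins = 50, weights = NULL, channel = NULL) {
  if (is.data.frame(llif)) llif <- llif$llif
  if (any(llif < 0 | llif > 1)) abort("LLIF values must lie in [0, 1].")
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- findInterval(llif, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  w <- weights %||% rep(1, length(llif))
  counts <- vapply(seq_len(bins), function(b) sum(w[idx == b]), numeric(1))
  out <- tibble(bin_mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
                count = counts)
  attr(out, "channel") <- channel
  attr(out, "component_labels") <- component_labels(channel)
  class(out) <- c("llif_histogram", class(out))
  out
}

component_labels <- function(channel) {
  if (is.null(channel)) return(c(short = "short", long = "long"))
  switch(channel,
         NADH = c(short = "free NADH", long = "protein-bound NADH"),
         FAD = c(short = "protein-bound FAD", long = "free FAD"),
         c(short = "short", long = "long"))
}

#' Poisson-weighted bi-exponential decay fit
#'
#' Fits `A1 exp(-t / tau1) + A2 exp(-t / tau2) + B` to a (typically
#' ROI-summed) decay by weighted least squares with Poisson weights
#' (`sigma_i = sqrt(max(count_i, 1))`). The fit is accepted when the reduced
#' chi-squared lies in `chi2_window` and every weighted residual stays
#' within `residual_bound` of zero.
#'
#' @param decay Photon counts (total >= `min_photons`).
#' @param Ts Sampling period in ns.
#' @param min_photons Minimum photon floor for a meaningful fit.
#' @param chi2_window Acceptance window for reduced chi-squared.
#' @param residual_bound Acceptance bound on absolute weighted residuals.
#' @return A `biexp_fit`: amplitudes `A1`, `A2`, lifetimes `tau1 < tau2`
#'   (ns), `background`, `chi2_reduced`, `max_abs_weighted_residual`,
#'   `accepted`, `converged`, plus the fitted curve.
#' @examples
#' t <- (0:255) * 12.5 / 256
#' y <- rpois(256, 4e3 * (0.3 * exp(-t / 2.19) + 0.7 * exp(-t / 0.4)))
#' fit <- fit_biexponential(y, Ts = 12.5 / 256)
#' glance(fit)
#' @export
fit_biexponential <- function(decay, Ts, min_photons = 1000,
                              chi2_window = c(0.8, 1.2), residual_bound = 4) {
  if (sum(decay) < min_photons) {
    abort(sprintf("Decay has fewer than %g photons; fit would be unreliable.",
                  min_photons))
  }
  L <- length(decay)
  t <- (seq_len(L) - 1) * Ts
  sigma <- sqrt(pmax(decay, 1))
  model <- function(par) {
    par[1] * exp(-t / par[2]) + par[3] * exp(-t / par[4]) + par[5]
  }
  resid_fn <- function(par) (model(par) - decay) / sigma
  tau_bar <- max(sum(decay * t) / sum(decay), Ts)
  amp0 <- max(decay)
  start <- c(A1 = amp0 * 0.6, tau1 = tau_bar / 2, A2 = amp0 * 0.4,
             tau2 = tau_bar * 2, B = max(min(decay), 1e-3))
  lower <- c(0, Ts / 10, 0, Ts / 10, 0)
  upper <- c(Inf, 100, Inf, 100, Inf)
  ans <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(ans)) {
    return(structure(list(A1 = NA_real_, A2 = NA_real_, tau1 = NA_real_,
                          tau2 = NA_real_, background = NA_real_,
                          chi2_reduced = NA_real_,
                          max_abs_weighted_residual = NA_real_,
                          accepted = FALSE, converged = FALSE,
                          fitted = rep(NA_real_, L), decay = decay, Ts = Ts,
                          chi2_window = chi2_window,
                          residual_bound = residual_bound),
                     class = "biexp_fit"))
  }
  par <- ans$par
  # order components so tau1 is the short lifetime
  if (par[2] > par[4]) par <- par[c(3, 4, 1, 2, 5)]
  wres <- resid_fn(par)
  chi2 <- sum(wres^2) / (L - 5)
  fit <- structure(
    list(A1 = unname(par[1]), A2 = unname(par[3]), tau1 = unname(par[2]),
         tau2 = unname(par[4]), background = unname(par[5]),
         chi2_reduced = chi2, max_abs_weighted_residual = max(abs(wres)),
         accepted = NA, converged = ans$info %in% 1:4,
         fitted = model(par), decay = decay, Ts = Ts,
         chi2_window = chi2_window, residual_bound = residual_bound),
    class = "biexp_fit")
  fit$accepted <- accept_fit(fit, chi2_window, residual_bound)
  fit
}

#' Acceptance test for a bi-exponential fit
#'
#' @param fit A `biexp_fit`.
#' @param chi2_window Reduced chi-squared acceptance window.
#' @param residual_bound Bound on absolute weighted residuals.
#' @return `TRUE` iff the fit converged, its reduced chi-squared lies inside
#'   the window and all weighted residuals are within the bound.
#' @export
accept_fit <- function(fit, chi2_window = c(0.8, 1.2), residual_bound = 4) {
  stopifnot(inherits(fit, "biexp_fit"))
  isTRUE(fit$converged) && !is.na(fit$chi2_reduced) &&
    fit$chi2_reduced >= chi2_window[1] && fit$chi2_reduced <= chi2_window[2] &&
    fit$max_abs_weighted_residual <= residual_bound
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("<biexp_fit> tau = (%.4g, %.4g) ns, chi2_red = %.3f, %s\n",
              x$tau1, x$tau2, x$chi2_reduced,
              if (isTRUE(x$accepted)) "accepted" else "rejected"))
  invisible(x)
}

#' @rdname fit_biexponential
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble(term = c("A1", "tau1", "A2", "tau2", "background"),
         estimate = c(x$A1, x$tau1, x$A2, x$tau2, x$background))
}

#' @rdname fit_biexponential
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble(tau1 = x$tau1, tau2 = x$tau2,
         chi2_reduced = x$chi2_reduced,
         max_abs_weighted_residual = x$max_abs_weighted_residual,
         accepted = x$accepted, converged = x$converged)
}

#' Pooled FLIM phasor analysis of a labelled image set
#'
#' Implements the shared-line protocol: the phasors of *all* images of every
#' tissue type are pooled into one global histogram per molecule, the chord
#' line is fitted once on that pooled histogram, the component lifetimes are
#' read from its universal-circle intersections, and each tissue type's LLIF
#' histogram is computed against that shared line. Mosaics are simply
#' several images of the same sample; their phasors aggregate before
#' analysis.
#'
#' @param images Named list (one entry per tissue type) of lists of
#'   `flim_image` objects, all on the same channel and time base.
#' @param channel Detection channel the images belong to.
#' @param bin_factor Spatial binning applied to each image first.
#' @param bins Phasor histogram bins per axis.
#' @param density_frac Line-fit occupancy threshold, see
#'   [fit_phasor_line()].
#' @param llif_bins Bins of the LLIF histograms.
#' @param llif_weighted Weight LLIF counts by decay intensity `m`.
#' @return A `flim_cohort_analysis`: list with `channel`, `components`
#'   (shared [lifetime_components()]), `llif` (tibble `type`, `mean_llif`,
#'   `n_pixels`) and `histograms` (tibble `type`, `bin_mid`, `count`).
#' @export
analyze_flim_cohort <- function(images, channel, bin_factor = 1, bins = 128,
                                density_frac = 0.5, llif_bins = 50,
                                llif_weighted = FALSE) {
  if (length(images) == 0 || is.null(names(images)) ||
      any(!nzchar(names(images)))) {
    abort("`images` must be a non-empty named list (one entry per type).")
  }
  purrr::walk(images, function(set) {
    if (length(set) == 0) abort("Every tissue type needs at least one image.")
  })
  first <- images[[1]][[1]]
  omega <- flim_omega(first$L, first$Ts)
  type_phasors <- purrr::map(images, function(set) {
    bind_rows(purrr::map(set, function(img) {
      stopifnot(inherits(img, "flim_image"))
      if (img$L != first$L || abs(img$Ts - first$Ts) > 1e-12) {
        abort("All images must share one (L, Ts) time base.")
      }
      if (img$channel != channel) {
        abort("Image channel does not match the requested channel.")
      }
      flim_phasors(bin_flim_image(img, bin_factor))
    }))
  })
  pooled <- bind_rows(type_phasors)
  hist <- phasor_histogram(pooled, bins = bins,
                           metadata = list(channel = channel, pooled = TRUE))
  line <- fit_phasor_line(hist, density_frac = density_frac)
  components <- lifetime_components(line, omega)
  projected <- purrr::map(type_phasors, llif_project, components = components)
  llif_tbl <- bind_rows(purrr::imap(projected, function(p, type) {
    tibble(type = type, mean_llif = mean(p$llif), n_pixels = nrow(p))
  }))
  histograms <- bind_rows(purrr::imap(projected, function(p, type) {
    h <- llif_histogram(p$llif, bins = llif_bins,
                        weights = if (llif_weighted) p$m else NULL,
                        channel = channel)
    mutate(as_tibble(h), type = type)
  })) %>% select("type", "bin_mid", "count")
  structure(list(channel = channel, components = components,
                 pooled_histogram = hist, llif = llif_tbl,
                 histograms = histograms),
            class = "flim_cohort_analysis")
}

#' @export
print.flim_cohort_analysis <- function(x, ...) {
  cat(sprintf("<flim_cohort_analysis> %s channel: tau = (%.3g, %.3g) ns\n",
              x$channel, x$components$tau_short, x$components$tau_long))
  print(x$llif)
  invisible(x)
}
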
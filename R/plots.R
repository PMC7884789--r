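#' Plot a fitted emission spectrum
#'
#' Data, total fitted curve and individual fluorophore components.
#'
#' @param object A `spectrum_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spectrum_fit <- function(object, ...) {
  axis <- object$spectrum$wavelength_nm
  comp_curves <- bind_rows(purrr::map(
    seq_len(nrow(object$components)), function(i) {
      ci <- object$components[i, ]
      tibble(wavelength_nm = axis,
             intensity = gaussian_profile(axis, ci$center_nm, ci$fwhm_nm,
                                          ci$amplitude),
             fluorophore = ci$fluorophore)
    }))
  total <- eval_components(object$components, axis)
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(.data$wavelength_nm, .data$intensity)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(data = comp_curves,
                       ggplot2::aes(colour = .data$fluorophore)) +
    ggplot2::geom_line(data = total, linewidth = 0.8) +
    ggplot2::labs(x = "emission wavelength (nm)", y = "intensity",
                  title = sprintf("Gaussian unmixing, %g nm excitation",
                                  object$excitation_nm))
}

#' Plot a phasor histogram
#'
#' Occupied bins on the (g, s) plane; for FLIM phasors the universal
#' semicircle is drawn as reference.
#'
#' @param object A `phasor_histogram`.
#' @param universal_circle Draw the universal semicircle.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.phasor_histogram <- function(object, universal_circle = TRUE, ...) {
  occ <- which(object$counts > 0, arr.ind = TRUE)
  df <- tibble(g = object$g_mid[occ[, 1]], s = object$s_mid[occ[, 2]],
               count = object$counts[occ])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$g, .data$s,
                                        fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "G", y = "S")
  if (universal_circle) {
    th <- seq(0, pi, length.out = 200)
    p <- p + ggplot2::geom_path(
      data = tibble(g = 0.5 + 0.5 * cos(th), s = 0.5 * sin(th)),
      ggplot2::aes(.data$g, .data$s), inherit.aes = FALSE,
      linetype = "dashed")
  }
  p
}

#' Plot an excitation--emission matrix
#'
#' @param object An `eem`.
#' @param ... Unused.
#' @return A ggplot raster of intensity over excitation x emission.
#' @export
autoplot.eem <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$wavelength_nm,
                                       .data$excitation_nm,
                                       fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::labs(x = "emission wavelength (nm)",
                  y = "excitation wavelength (nm)")
}

#' Plot an LLIF histogram
#'
#' @param object An `llif_histogram`.
#' @param ... Unused.
#' @return A ggplot bar chart over the LLIF axis.
#' @export
autoplot.llif_histogram <- function(object, ...) {
  labels <- attr(object, "component_labels")
  ggplot2::ggplot(object, ggplot2::aes(.data$bin_mid, .data$count)) +
    ggplot2::geom_col(width = 1 / nrow(object)) +
    ggplot2::labs(
      x = sprintf("long lifetime intensity fraction (0 = %s, 1 = %s)",
                  labels[["short"]], labels[["long"]]),
      y = "pixels")
}

#' Pairwise feature-space view of a discrimination result
#'
#' Scatter of the three collagen features per tissue label over the three
#' coordinate pairs, with the fitted ellipsoids' 2D shadows (projected
#' mean +/- Mahalanobis contour).
#'
#' @param object A `discrimination_result`.
#' @param ... Unused.
#' @return A ggplot object faceted by coordinate pair.
#' @export
autoplot.discrimination_result <- function(object, ...) {
  pairs <- list(c("shg_int", "coll_peak"), c("shg_int", "coll_int"),
                c("coll_peak", "coll_int"))
  pts <- bind_rows(purrr::map(pairs, function(pr) {
    tibble(panel = paste(pr, collapse = " vs "),
           x = object$verdicts[[pr[1]]], y = object$verdicts[[pr[2]]],
           label = object$verdicts$label)
  }))
  th <- seq(0, 2 * pi, length.out = 120)
  shadows <- bind_rows(purrr::imap(object$ellipsoids, function(e, lab) {
    bind_rows(purrr::map(pairs, function(pr) {
      i <- match(pr, c("shg_int", "coll_peak", "coll_int"))
      cv <- e$covariance[i, i]
      eg <- eigen(cv, symmetric = TRUE)
      r <- sqrt(e$scale)
      xy <- t(eg$vectors %*% (r * t(cbind(sqrt(eg$values[1]) * cos(th),
                                          sqrt(eg$values[2]) * sin(th)))))
      tibble(panel = paste(pr, collapse = " vs "),
             x = xy[, 1] + e$mean[i[1]], y = xy[, 2] + e$mean[i[2]],
             label = lab)
    }))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y,
                                    colour = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_path(data = shadows) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL)
}
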
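#' Default analysis configuration
#'
#' All tunable constants of the pipeline in one serialisable list. The
#' defaults are the study constants: bi-exponential acceptance window
#' 0.8--1.2 with +/-4 residual bounds, 60% ellipsoid mass, SHG gates 2.5
#' and 22, collagen gate 28, and 32x spatial binning of 512 x 512 FLIM
#' tiles (scaled here to the simulated tile size).
#'
#' @param ... Named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return A `run_config` list.
#' @export
default_config <- function(...) {
  config <- list(
    seed = 1L,
    cohort = list(n_control = 10L, n_g1 = 7L, n_g2 = 8L,
                  spectral_shape = c(8L, 8L), flim_shape = c(16L, 16L),
                  photons_spectral = 1e5, photons_flim = 1e5),
    fit = list(restarts = 5L),
    flim = list(L = 256L, Ts = 12.5 / 256, bin_factor = 1L,
                chi2_window = c(0.8, 1.2), residual_bound = 4,
                min_photons = 1000),
    discrimination = list(mass = 0.60, shg_thresholds = c(2.5, 22),
                          coll_int_threshold = 28,
                          indeterminate = "exclude", n_mc = 1e5)
  )
  overrides <- list(...)
  if (length(overrides)) config <- modifyList(config, overrides)
  validate_config(config)
  config
}

validate_config <- function(config) {
  d <- config$discrimination
  if (d$mass <= 0 || d$mass >= 1) {
    abort("Config invalid: ellipsoid mass must lie in (0, 1).")
  }
  if (length(d$shg_thresholds) != 2 ||
      d$shg_thresholds[1] >= d$shg_thresholds[2]) {
    abort("Config invalid: SHG thresholds must be increasing (control, grade).")
  }
  f <- config$flim
  if (f$L < 64 || f$Ts <= 0) abort("Config invalid: FLIM time base.")
  if (f$chi2_window[1] >= f$chi2_window[2]) {
    abort("Config invalid: chi-squared window.")
  }
  invisible(config)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates a labelled cohort, unmixes the per-sample spectra (deep-UV,
#' 810 nm and 890 nm mean spectra), computes molecular ratios and collagen
#' features, runs the 3D ellipsoid discrimination on the cohort feature
#' points, and performs the pooled FLIM phasor/LLIF analysis and ROI
#' bi-exponential NADH fits per tissue type.
#'
#' @param config A [default_config()] list.
#' @return A `pipeline_report` list with elements `seed`, `config`,
#'   `ratios` (per-sample tibble), `features_from_spectra`,
#'   `discrimination` (Se/Sp and overlap for both tests), `flim` (per-type
#'   component lifetimes and LLIF means per channel), `biexp`
#'   (per-type bound-NADH lifetimes), and `threshold_verdicts`.
#' @examples
#' \donttest{
#' report <- run_pipeline(default_config(
#'   cohort = list(n_control = 3L, n_g1 = 3L, n_g2 = 3L,
#'                 flim_shape = c(8L, 8L), photons_flim = 1e4)))
#' report$discrimination$control_tumor
#' }
#' @export
run_pipeline <- function(config = default_config()) {
  validate_config(config)
  co <- config$cohort
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }
  message("pipeline: simulating cohort")
  cohort <- stage("simulate", simulate_cohort(
    co$n_control, co$n_g1, co$n_g2, seed = config$seed,
    spectral_shape = co$spectral_shape, flim_shape = co$flim_shape,
    photons_spectral = co$photons_spectral, photons_flim = co$photons_flim,
    L = config$flim$L, Ts = config$flim$Ts))

  message("pipeline: unmixing spectra")
  unmix <- stage("unmix", {
    purrr::map(seq_len(nrow(cohort$samples)), function(i) {
      row <- cohort$samples[i, ]
      fit_duv <- fit_spectrum(row$duv_spectrum[[1]],
                              restarts = config$fit$restarts)
      fit_810 <- fit_spectrum(mean_spectrum(row$nir810[[1]]),
                              restarts = config$fit$restarts)
      fit_890 <- fit_spectrum(mean_spectrum(row$nir890[[1]]),
                              restarts = config$fit$restarts)
      list(
        ratios = dplyr::bind_cols(
          tibble(sample_id = row$sample_id, label = row$label),
          duv_ratios(fit_duv), nir_ratios(fit_810)),
        features = dplyr::bind_cols(
          tibble(sample_id = row$sample_id, label = row$label),
          collagen_features(fit_duv, fit_890))
      )
    })
  })
  ratios <- bind_rows(purrr::map(unmix, "ratios"))
  features_from_spectra <- bind_rows(purrr::map(unmix, "features"))

  message("pipeline: 3D ellipsoid discrimination")
  disc <- stage("discriminate", discriminate_cohort(
    cohort$features, mass = config$discrimination$mass,
    shg_thresholds = config$discrimination$shg_thresholds,
    indeterminate = config$discrimination$indeterminate,
    n_mc = config$discrimination$n_mc, seed = config$seed))

  message("pipeline: FLIM phasor analysis")
  flim_summaries <- stage("flim", {
    purrr::map(c(NADH = "NADH", FAD = "FAD"), function(ch) {
      col <- if (ch == "NADH") "flim_nadh" else "flim_fad"
      sets <- split(cohort$samples[[col]], cohort$samples$label)
      sets <- sets[purrr::map_int(sets, length) > 0]
      pooled <- analyze_flim_cohort(sets, channel = ch,
                                    bin_factor = config$flim$bin_factor)
      # per-type component lifetimes from per-type lines
      per_type <- purrr::imap(sets, function(set, type) {
        ph <- bind_rows(purrr::map(set, flim_phasors))
        comp <- lifetime_components(
          fit_phasor_line(phasor_histogram(ph)),
          flim_omega(config$flim$L, config$flim$Ts))
        tibble(type = type, tau_short_ns = comp$tau_short,
               tau_long_ns = comp$tau_long)
      })
      list(pooled = pooled, per_type_lifetimes = bind_rows(per_type))
    })
  })

  message("pipeline: bi-exponential NADH fits")
  biexp <- stage("biexp", {
    bind_rows(purrr::map(seq_len(nrow(cohort$samples)), function(i) {
      img <- cohort$samples$flim_nadh[[i]]
      roi <- apply(img$decays, 3, sum) # whole-image ROI sum
      fit <- fit_biexponential(roi, Ts = img$Ts,
                               min_photons = config$flim$min_photons,
                               chi2_window = config$flim$chi2_window,
                               residual_bound = config$flim$residual_bound)
      dplyr::bind_cols(tibble(sample_id = cohort$samples$sample_id[i],
                              label = cohort$samples$label[i]),
                       glance(fit))
    }))
  })
  bound_nadh <- biexp %>%
    filter(.data$accepted) %>%
    group_by(.data$label) %>%
    summarise(bound_nadh_tau_ns = mean(.data$tau2), .groups = "drop")

  threshold_verdicts <- purrr::map(
    split(cohort$features, cohort$features$sample_id),
    function(row) {
      nadh_tau <- bound_nadh$bound_nadh_tau_ns[
        match(row$label, bound_nadh$label)]
      fad_short <- flim_summaries$FAD$per_type_lifetimes$tau_short_ns[
        match(row$label, flim_summaries$FAD$per_type_lifetimes$type)]
      if (is.na(nadh_tau) || is.na(fad_short)) return(NULL)
      v <- threshold_rules(row, bound_nadh_tau = nadh_tau,
                           bound_fad_tau = fad_short)
      mutate(v$rules, sample_id = row$sample_id, label = row$label)
    })
  threshold_verdicts <- bind_rows(purrr::compact(threshold_verdicts))

  structure(
    list(seed = config$seed, config = config, cohort_labels = cohort$features,
         ratios = ratios, features_from_spectra = features_from_spectra,
         discrimination = list(
           control_tumor = as.list(sensitivity_specificity(
             disc$control_tumor$counts)),
           grade = as.list(sensitivity_specificity(disc$grade$counts)),
           overlap = disc$overlap,
           detail = disc),
         flim = purrr::map(flim_summaries, function(fs) {
           list(shared_lifetimes = c(tau_short_ns = fs$pooled$components$tau_short,
                                     tau_long_ns = fs$pooled$components$tau_long),
                per_type_lifetimes = fs$per_type_lifetimes,
                llif = fs$pooled$llif)
         }),
         biexp = list(per_sample = biexp, bound_nadh = bound_nadh),
         threshold_verdicts = threshold_verdicts),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed", x$seed, "\n")
  cat(sprintf("  control vs tumor Se/Sp: %.3f / %.3f\n",
              x$discrimination$control_tumor$se,
              x$discrimination$control_tumor$sp))
  cat(sprintf("  grade I vs II Se/Sp:    %.3f / %.3f\n",
              x$discrimination$grade$se, x$discrimination$grade$sp))
  cat("  bound-NADH lifetimes (ns):\n")
  print(x$biexp$bound_nadh)
  invisible(x)
}

#' Serialise a pipeline report to JSON
#'
#' Writes the scalar and tabular summaries of a report (not the raw cohort)
#' to a JSON file.
#'
#' @param report A `pipeline_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pipeline_report"))
  out <- list(
    seed = report$seed,
    discrimination = list(
      control_tumor = report$discrimination$control_tumor,
      grade = report$discrimination$grade,
      overlap = as.list(report$discrimination$overlap)),
    flim = purrr::map(report$flim, function(f) {
      list(shared_lifetimes = as.list(f$shared_lifetimes),
           per_type_lifetimes = f$per_type_lifetimes,
           llif = f$llif)
    }),
    bound_nadh = report$biexp$bound_nadh,
    ratios = report$ratios
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
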
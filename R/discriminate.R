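#' Fit a Gaussian probability-mass ellipsoid to feature points
#'
#' Approximates a 3D scatter cloud by the Gaussian ellipsoid holding `mass`
#' of the probability: mean = sample mean, covariance = sample covariance,
#' and squared-Mahalanobis radius equal to the chi-squared(3) quantile at
#' `mass` (for 60% mass, about 2.946) - the unique scaling for which a
#' Gaussian's mass inside the Mahalanobis ellipsoid equals `mass`.
#'
#' @param points Data frame with `shg_int`, `coll_peak`, `coll_int` columns
#'   (at least 4 points, not coplanar).
#' @param mass Probability mass the ellipsoid should cover, in (0, 1).
#' @return An `ellipsoid3d`: list with `mean` (3-vector), `covariance`
#'   (3 x 3), `scale` (Mahalanobis-squared threshold), `mass`, `n`.
#' @export
fit_ellipsoid <- function(points, mass = 0.60) {
  m <- feature_matrix(points)
  if (nrow(m) < 4) abort("At least 4 feature points are required.")
  if (!is.numeric(mass) || mass <= 0 || mass >= 1) {
    abort("`mass` must lie strictly between 0 and 1.")
  }
  center <- colMeans(m)
  covariance <- cov(m)
  if (!all(is.finite(covariance)) ||
      abs(det(covariance)) < 1e-12 * prod(pmax(diag(covariance), 1e-12))) {
    abort("Singular covariance: the points are (nearly) coplanar.")
  }
  structure(list(mean = center, covariance = covariance,
                 scale = qchisq(mass, df = 3), mass = mass, n = nrow(m)),
            class = "ellipsoid3d")
}

feature_matrix <- function(points) {
  cols <- c("shg_int", "coll_peak", "coll_int")
  if (is.matrix(points)) {
    if (ncol(points) != 3) abort("Feature matrix must have 3 columns.")
    colnames(points) <- cols
    return(points)
  }
  if (!all(cols %in% names(points))) {
    abort("Feature points need `shg_int`, `coll_peak`, `coll_int` columns.")
  }
  m <- as.matrix(points[, cols])
  if (!all(is.finite(m))) abort("Feature coordinates must be finite.")
  m
}

#' @export
print.ellipsoid3d <- function(x, ...) {
  cat(sprintf("<ellipsoid3d> %.0f%% mass, n = %d, centre (%.2f, %.2f, %.2f)\n",
              100 * x$mass, x$n, x$mean[1], x$mean[2], x$mean[3]))
  invisible(x)
}

#' Ellipsoid membership test
#'
#' A point belongs to the ellipsoid iff its squared Mahalanobis distance
#' from the centre is at most the ellipsoid scale (boundary inclusive).
#'
#' @param e An `ellipsoid3d`.
#' @param points Feature points (data frame or 3-column matrix).
#' @return Logical vector, one entry per point.
#' @export
ellipsoid_contains <- function(e, points) {
  stopifnot(inherits(e, "ellipsoid3d"))
  m <- feature_matrix(points)
  mahalanobis(m, e$mean, e$covariance) <= e$scale
}

#' Monte-Carlo overlap fraction of two ellipsoids
#'
#' Estimates `|e1 intersect e2| / |e1 union e2|` by uniform sampling in the
#' joint bounding box of the two ellipsoids.
#'
#' @param e1,e2 `ellipsoid3d` objects.
#' @param n_mc Number of Monte-Carlo samples (>= 1e4).
#' @param seed Integer seed.
#' @return Overlap fraction in `[0, 1]`.
#' @export
ellipsoid_overlap_volume <- function(e1, e2, n_mc = 1e5, seed = 1) {
  stopifnot(inherits(e1, "ellipsoid3d"), inherits(e2, "ellipsoid3d"))
  if (n_mc < 1e4) abort("`n_mc` must be at least 10^4.")
  box <- function(e) {
    half <- sqrt(e$scale * diag(e$covariance))
    rbind(e$mean - half, e$mean + half)
  }
  b1 <- box(e1); b2 <- box(e2)
  lo <- pmin(b1[1, ], b2[1, ]); hi <- pmax(b1[2, ], b2[2, ])
  with_seed_or_not(seed, {
    pts <- cbind(runif(n_mc, lo[1], hi[1]), runif(n_mc, lo[2], hi[2]),
                 runif(n_mc, lo[3], hi[3]))
    in1 <- ellipsoid_contains(e1, pts)
    in2 <- ellipsoid_contains(e2, pts)
    n_union <- sum(in1 | in2)
    if (n_union == 0) return(0)
    sum(in1 & in2) / n_union
  })
}

#' Control-versus-tumor classification of a feature point
#'
#' The diagnosis rule: a point inside the grade I or grade II ellipsoid with
#' `shg_int` strictly above `shg_threshold` is tumor; a point inside the
#' control ellipsoid with `shg_int` at or below the threshold is control;
#' anything else is indeterminate.
#'
#' @param points Feature points.
#' @param ellipsoids Named list with `control`, `grade1`, `grade2`
#'   `ellipsoid3d` entries.
#' @param shg_threshold SHG integral-proportion gate (%, default 2.5).
#' @return Character vector `"control"`, `"tumor"` or `"indeterminate"`.
#' @export
classify_control_tumor <- function(points, ellipsoids, shg_threshold = 2.5) {
  check_ellipsoid_set(ellipsoids)
  m <- feature_matrix(points)
  in_tumor <- ellipsoid_contains(ellipsoids$grade1, m) |
    ellipsoid_contains(ellipsoids$grade2, m)
  in_control <- ellipsoid_contains(ellipsoids$control, m)
  shg <- m[, "shg_int"]
  dplyr::case_when(
    in_tumor & shg > shg_threshold ~ "tumor",
    in_control & shg <= shg_threshold ~ "control",
    .default = "indeterminate"
  )
}

#' Grade I versus grade II classification of a feature point
#'
#' A point inside the grade I ellipsoid with `shg_int` lower than or equal
#' to `shg_threshold` is grade I; inside the grade II ellipsoid with
#' `shg_int` strictly above the threshold it is grade II; otherwise
#' indeterminate.
#'
#' @inheritParams classify_control_tumor
#' @param shg_threshold SHG integral-proportion gate (%, default 22).
#' @return Character vector `"grade1"`, `"grade2"` or `"indeterminate"`.
#' @export
classify_grade <- function(points, ellipsoids, shg_threshold = 22) {
  check_ellipsoid_set(ellipsoids)
  m <- feature_matrix(points)
  in_g1 <- ellipsoid_contains(ellipsoids$grade1, m)
  in_g2 <- ellipsoid_contains(ellipsoids$grade2, m)
  shg <- m[, "shg_int"]
  dplyr::case_when(
    in_g1 & shg <= shg_threshold ~ "grade1",
    in_g2 & shg > shg_threshold ~ "grade2",
    .default = "indeterminate"
  )
}

check_ellipsoid_set <- function(ellipsoids) {
  need <- c("control", "grade1", "grade2")
  if (!is.list(ellipsoids) || !all(need %in% names(ellipsoids))) {
    abort("`ellipsoids` must name `control`, `grade1` and `grade2` fits.")
  }
  purrr::walk(ellipsoids[need], function(e) {
    if (!inherits(e, "ellipsoid3d")) abort("Ellipsoids must be `ellipsoid3d`.")
  })
  invisible(ellipsoids)
}

#' Confusion counts for a binary discrimination test
#'
#' @param truth Logical vector: `TRUE` where the point truly belongs to the
#'   positive class.
#' @param predicted Character verdicts; `positive` / `negative` name the
#'   verdict labels of the two classes.
#' @param positive,negative Verdict labels counted as the positive and
#'   negative calls.
#' @param indeterminate How to count verdicts that are neither: `"error"`
#'   (an indeterminate positive point becomes a false negative and vice
#'   versa - conservative default) or `"exclude"` (dropped from the
#'   denominators).
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, predicted, positive, negative,
                             indeterminate = c("error", "exclude")) {
  indeterminate <- match.arg(indeterminate)
  stopifnot(length(truth) == length(predicted))
  undecided <- !(predicted %in% c(positive, negative))
  if (indeterminate == "exclude") {
    truth <- truth[!undecided]
    predicted <- predicted[!undecided]
  } else {
    # an undecided point counts against its own class
    predicted[undecided & truth] <- negative
    predicted[undecided & !truth] <- positive
  }
  tibble(tp = sum(truth & predicted == positive),
         fp = sum(!truth & predicted == positive),
         tn = sum(!truth & predicted == negative),
         fn = sum(truth & predicted == negative))
}

#' Sensitivity and specificity from confusion counts
#'
#' `Se = TP / (TP + FN)`; `Sp = TN / (TN + FP)`. Zero denominators give
#' `NA` (undefined) rather than an error.
#'
#' @param counts One-row data frame with `tp`, `fp`, `tn`, `fn`.
#' @return One-row tibble `se`, `sp`.
#' @export
sensitivity_specificity <- function(counts) {
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(counts)))
  tibble(
    se = if (counts$tp + counts$fn > 0) counts$tp / (counts$tp + counts$fn)
         else NA_real_,
    sp = if (counts$tn + counts$fp > 0) counts$tn / (counts$tn + counts$fp)
         else NA_real_
  )
}

#' Run both ellipsoid discrimination tests on a labelled feature table
#'
#' Fits a 60%-mass Gaussian ellipsoid per tissue type and evaluates, under
#' resubstitution, (1) the control-versus-tumor test (SHG gate at
#' `shg_thresholds[1]`) on all points and (2) the grade I-versus-grade II
#' test (gate at `shg_thresholds[2]`) on the tumor points, reporting
#' sensitivity and specificity for each together with the Monte-Carlo
#' overlap between the control and tumor ellipsoids.
#'
#' @param features Tibble with `label` (`"control"`, `"grade1"`,
#'   `"grade2"`), `shg_int`, `coll_peak`, `coll_int`; e.g. the `features`
#'   element of [simulate_cohort()].
#' @param mass Ellipsoid probability mass.
#' @param shg_thresholds SHG gates for the two tests (control/tumor, grade).
#' @param indeterminate Handling of gate-indeterminate points, see
#'   [confusion_counts()].
#' @param n_mc,seed Monte-Carlo settings for the overlap estimate.
#' @return A `discrimination_result`: list with `ellipsoids`, `verdicts`
#'   (per-point tibble), `control_tumor` and `grade` (each with `counts`,
#'   `se`, `sp`), and `overlap` (control vs grade1 / grade2).
#' @examples
#' co <- simulate_cohort(10, 7, 8, seed = 1, flim_shape = c(4, 4),
#'                       photons_flim = 1e4)
#' res <- discriminate_cohort(co$features, indeterminate = "exclude")
#' glance(res)
#' @export
discriminate_cohort <- function(features, mass = 0.60,
                                shg_thresholds = c(2.5, 22),
                                indeterminate = c("error", "exclude"),
                                n_mc = 1e5, seed = 1) {
  indeterminate <- match.arg(indeterminate)
  if (!"label" %in% names(features)) abort("`features` needs a `label` column.")
  labs <- c("control", "grade1", "grade2")
  if (!all(features$label %in% labs)) {
    abort("Labels must be control / grade1 / grade2.")
  }
  ellipsoids <- purrr::map(setNames(labs, labs), function(l) {
    fit_ellipsoid(filter(features, .data$label == l), mass = mass)
  })
  verdict_ct <- classify_control_tumor(features, ellipsoids,
                                       shg_threshold = shg_thresholds[1])
  verdict_gr <- classify_grade(features, ellipsoids,
                               shg_threshold = shg_thresholds[2])
  verdicts <- features %>%
    mutate(verdict_control_tumor = verdict_ct, verdict_grade = verdict_gr)

  ct_counts <- confusion_counts(features$label != "control", verdict_ct,
                                positive = "tumor", negative = "control",
                                indeterminate = indeterminate)
  tumor <- features$label != "control"
  gr_counts <- confusion_counts(features$label[tumor] == "grade2",
                                verdict_gr[tumor],
                                positive = "grade2", negative = "grade1",
                                indeterminate = indeterminate)
  overlap <- c(
    control_grade1 = ellipsoid_overlap_volume(ellipsoids$control,
                                              ellipsoids$grade1,
                                              n_mc = n_mc, seed = seed),
    control_grade2 = ellipsoid_overlap_volume(ellipsoids$control,
                                              ellipsoids$grade2,
                                              n_mc = n_mc, seed = seed)
  )
  structure(
    list(ellipsoids = ellipsoids, verdicts = verdicts,
         control_tumor = c(list(counts = ct_counts),
                           as.list(sensitivity_specificity(ct_counts))),
         grade = c(list(counts = gr_counts),
                   as.list(sensitivity_specificity(gr_counts))),
         overlap = overlap, mass = mass, shg_thresholds = shg_thresholds,
         indeterminate = indeterminate),
    class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat("<discrimination_result>\n")
  cat(sprintf("  control vs tumor:   Se = %.3f, Sp = %.3f\n",
              x$control_tumor$se, x$control_tumor$sp))
  cat(sprintf("  grade I vs grade II: Se = %.3f, Sp = %.3f\n",
              x$grade$se, x$grade$sp))
  cat(sprintf("  control-tumor overlap: %.3g / %.3g\n",
              x$overlap[1], x$overlap[2]))
  invisible(x)
}

#' @rdname discriminate_cohort
#' @param x A `discrimination_result`.
#' @param ... Unused.
#' @export
tidy.discrimination_result <- function(x, ...) x$verdicts

#' @rdname discriminate_cohort
#' @export
glance.discrimination_result <- function(x, ...) {
  tibble(se_control_tumor = x$control_tumor$se,
         sp_control_tumor = x$control_tumor$sp,
         se_grade = x$grade$se, sp_grade = x$grade$sp,
         overlap_control_grade1 = x$overlap[["control_grade1"]],
         overlap_control_grade2 = x$overlap[["control_grade2"]])
}

#' Threshold-rule verdicts for one measurement
#'
#' Applies the four independent diagnostic threshold rules:
#'
#' * collagen integral proportion: `coll_int > 28` is tumor, otherwise
#'   control;
#' * SHG integral proportion: `< 2.5` control, `2.5--22` grade I, `> 22`
#'   grade II;
#' * protein-bound NADH lifetime: `> 2.1` ns control, `1.9--2.1` ns grade I,
#'   `< 1.9` ns grade II;
#' * protein-bound FAD lifetime: `< 0.7` ns control, `0.7--1` ns grade I,
#'   `> 1` ns grade II;
#'
#' plus a majority-vote summary over the four verdicts (graded verdicts
#' count as tumor for the control/tumor vote; the grade vote is the
#' majority of the three graded rules; ties are indeterminate).
#'
#' @param features One-row data frame with `shg_int`, `coll_peak`,
#'   `coll_int` (only `shg_int` and `coll_int` are used by the rules).
#' @param bound_nadh_tau Protein-bound NADH lifetime (ns).
#' @param bound_fad_tau Protein-bound FAD lifetime (ns).
#' @return A list with `rules` (tibble `rule`, `verdict`) and `majority`
#'   (list `control_tumor`, `grade`).
#' @export
threshold_rules <- function(features, bound_nadh_tau, bound_fad_tau) {
  m <- feature_matrix(features)
  if (nrow(m) != 1) abort("`threshold_rules()` scores one measurement.")
  if (!is.finite(bound_nadh_tau) || !is.finite(bound_fad_tau)) {
    abort("Lifetimes must be finite.")
  }
  shg <- m[1, "shg_int"]; coll <- m[1, "coll_int"]
  rules <- tibble(
    rule = c("coll_int", "shg_int", "bound_nadh_tau", "bound_fad_tau"),
    verdict = c(
      if (coll > 28) "tumor" else "control",
      if (shg < 2.5) "control" else if (shg <= 22) "grade1" else "grade2",
      if (bound_nadh_tau > 2.1) "control"
      else if (bound_nadh_tau >= 1.9) "grade1" else "grade2",
      if (bound_fad_tau < 0.7) "control"
      else if (bound_fad_tau <= 1) "grade1" else "grade2"
    )
  )
  tumor_votes <- sum(rules$verdict != "control")
  control_votes <- sum(rules$verdict == "control")
  ct <- if (tumor_votes > control_votes) "tumor"
        else if (control_votes > tumor_votes) "control" else "indeterminate"
  graded <- rules$verdict[rules$verdict %in% c("grade1", "grade2")]
  gr <- if (length(graded) == 0) NA_character_
        else if (sum(graded == "grade2") > sum(graded == "grade1")) "grade2"
        else if (sum(graded == "grade1") > sum(graded == "grade2")) "grade1"
        else "indeterminate"
  list(rules = rules, majority = list(control_tumor = ct, grade = gr))
}
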
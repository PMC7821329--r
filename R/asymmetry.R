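#' Root asymmetry and gravitropism statistics
#'
#' Quantifies the asymmetric distribution of a reporter signal between the
#' upper and lower sides of a gravistimulated root (profile measurement,
#' lower/upper ratios, treated/control fold changes, region intensities) and
#' summarises root-tip deviation-angle experiments (means, SEMs, equal-
#' variance two-sample comparisons, dose-response tables).
#'
#' @name asymmetry
NULL

#' Measure an intensity profile along a polyline
#'
#' The image is sampled at 1-pixel steps along the polyline with bilinear
#' interpolation; at each step the value is the mean over `width` pixels
#' perpendicular to the line.
#'
#' @param image A [calibrated_image()].
#' @param line 2-column (x, y) matrix of vertices in um.
#' @param width Averaging width in pixels (default 1).
#' @return Data frame with `position_um` (arc length along the line) and
#'   `intensity`.
#' @export
measure_profile <- function(image, line, width = 1L) {
  stopifnot(inherits(image, "calibrated_image"))
  ps <- image$pixel_size
  path <- sample_polyline(as.matrix(line), step_um = ps)
  assert_in_bounds(path$points_um, dim(image$pixels), ps)
  offs <- (seq_len(width) - (width + 1) / 2)
  cols_px <- um_to_px(path$points_um[, 1], ps)
  rows_px <- um_to_px(path$points_um[, 2], ps)
  vals <- vapply(offs, function(o) {
    interp_bilinear(image$pixels, cols_px + o * path$normals[, 1],
                    rows_px + o * path$normals[, 2])
  }, numeric(length(cols_px)))
  vals <- matrix(vals, nrow = length(cols_px))
  data.frame(position_um = path$s_um, intensity = rowMeans(vals))
}

#' Paired upper/lower intensity profiles
#'
#' @param upper,lower Profiles (data frames from [measure_profile()]) or
#'   plain numeric intensity vectors.
#' @return A `sided_profile`: list with `upper`, `lower`, `mean_upper`,
#'   `mean_lower`.
#' @export
sided_profile <- function(upper, lower) {
  get_int <- function(p) if (is.data.frame(p)) p$intensity else as.numeric(p)
  u <- get_int(upper); l <- get_int(lower)
  if (length(u) == 0L || length(l) == 0L)
    stop("profiles must be non-empty")
  structure(list(upper = u, lower = l,
                 mean_upper = mean(u), mean_lower = mean(l)),
            class = "sided_profile")
}

#' Lower/upper signal ratio
#'
#' @param profile_pair A [sided_profile()].
#' @return An `asymmetry_result`: list with `ratio_lower_upper`,
#'   `mean_upper`, `mean_lower`.
#' @export
sided_ratio <- function(profile_pair) {
  stopifnot(inherits(profile_pair, "sided_profile"))
  if (profile_pair$mean_upper <= 0)
    stop("upper-side mean must be > 0 to form the ratio")
  if (profile_pair$mean_lower <= 0)
    stop("lower-side mean must be > 0 to form the ratio")
  structure(list(ratio_lower_upper =
                   profile_pair$mean_lower / profile_pair$mean_upper,
                 mean_upper = profile_pair$mean_upper,
                 mean_lower = profile_pair$mean_lower),
            class = "asymmetry_result")
}

#' Treated/control fold change
#'
#' @param treated,control Summary intensities (AU); `control` must be > 0.
#' @return Dimensionless fold `treated / control`.
#' @export
fold_change <- function(treated, control) {
  if (!is.numeric(treated) || !is.numeric(control))
    stop("inputs must be numeric")
  if (control <= 0) stop("control must be > 0")
  treated / control
}

#' Mean intensity over a polygonal region
#'
#' @param image A [calibrated_image()].
#' @param region Either a logical mask matching the image, or a 2-column
#'   (x, y) matrix of polygon vertices in um (pixels whose centres fall
#'   inside the polygon are used).
#' @param label Optional region label (e.g. `"QC+CC"`).
#' @return A `region_intensity`: list with `region_label`, `mean`,
#'   `n_pixels`.
#' @export
region_intensity <- function(image, region, label = "custom") {
  stopifnot(inherits(image, "calibrated_image"))
  px <- image$pixels
  if (is.logical(region) && is.matrix(region)) {
    stopifnot(identical(dim(region), dim(px)))
    mask <- region
  } else {
    poly <- as.matrix(region)
    if (ncol(poly) != 2L || nrow(poly) < 3L)
      stop("polygon needs >= 3 (x, y) vertices")
    ps <- image$pixel_size
    cc <- rep(seq_len(ncol(px)), each = nrow(px))
    rr <- rep(seq_len(nrow(px)), times = ncol(px))
    inside <- pracma::inpolygon(px_to_um(cc, ps), px_to_um(rr, ps),
                                poly[, 1], poly[, 2])
    mask <- matrix(inside, nrow(px), ncol(px))
  }
  n <- sum(mask)
  if (n == 0L) stop("empty region: no pixels inside the mask/polygon")
  structure(list(region_label = label, mean = mean(px[mask]),
                 n_pixels = as.integer(n)),
            class = "region_intensity")
}

#' Summary statistics of root-tip deviation angles
#'
#' Angles are deviations from the vertical growth vector in degrees; by
#' default summaries are taken on absolute deviations, matching how
#' unsigned deviated angles are usually charted.
#'
#' @param angles Numeric vector of angles (degrees); n >= 1.
#' @param absolute Summarise `abs(angles)` (default TRUE).
#' @return List with `mean_deg`, `sem_deg` (`NA` when n = 1), `n`.
#' @export
angle_stats <- function(angles, absolute = TRUE) {
  if (length(angles) < 1L || any(!is.finite(angles)))
    stop("angles must be a non-empty finite vector")
  a <- if (absolute) abs(angles) else angles
  n <- length(a)
  list(mean_deg = mean(a),
       sem_deg = if (n > 1L) stats::sd(a) / sqrt(n) else NA_real_,
       n = n)
}

#' Two-tailed equal-variance two-sample comparison
#'
#' Student's t-test assuming equal variances, the comparison used for all
#' group contrasts in this workflow.
#'
#' @param a,b Numeric measurement vectors, n >= 2 each.
#' @return List with `statistic`, `p_value`, `df`, `mean_a`, `mean_b`.
#' @export
compare_conditions <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("need n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero pooled variance: comparison undefined")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Dose-response table with monotonicity flag
#'
#' @param doses Numeric vector of doses (must be unique).
#' @param means Numeric vector of mean responses, one per dose.
#' @param sems Optional standard errors.
#' @return A `dose_response` data frame ordered by dose, with attributes
#'   `monotone` (TRUE when the means are non-increasing or non-decreasing in
#'   dose) and `direction` (`"decreasing"`, `"increasing"`, `"flat"` or
#'   `"none"`).
#' @export
dose_response <- function(doses, means, sems = NULL) {
  if (length(doses) < 2L) stop("need >= 2 doses")
  if (anyDuplicated(doses)) stop("duplicate doses")
  if (length(means) != length(doses)) stop("one mean per dose required")
  ord <- order(doses)
  out <- data.frame(dose = doses[ord], mean_response = means[ord])
  if (!is.null(sems)) out$sem <- sems[ord]
  d <- diff(out$mean_response)
  monotone <- all(d <= 0) || all(d >= 0)
  direction <- if (!monotone) "none"
    else if (all(d == 0)) "flat"
    else if (all(d <= 0)) "decreasing" else "increasing"
  attr(out, "monotone") <- monotone
  attr(out, "direction") <- direction
  class(out) <- c("dose_response", "data.frame")
  out
}
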
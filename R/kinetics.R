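#' FRAP and kymograph lifetime analysis
#'
#' Dynamics perpendicular to the membrane plane: normalisation and
#' single-exponential fitting of fluorescence-recovery-after-photobleaching
#' (FRAP) curves into mobile and stable fractions, and residence-lifetime
#' measurement of membrane puncta from position-time kymographs.
#'
#' @name kinetics
NULL

#' FRAP recovery curve
#'
#' @param times Sample times in s, increasing; the bleach is at `t = 0` and
#'   at least one pre-bleach sample (`t < 0`) must be present.
#' @param intensity Fluorescence (AU, or normalised units).
#' @param prebleach_level Pre-bleach plateau (AU); computed from the `t < 0`
#'   samples when `NULL`.
#' @param background Camera background (AU), default 0.
#' @param normalized Whether the curve is already normalised.
#' @return A `frap_curve` object.
#' @export
frap_curve <- function(times, intensity, prebleach_level = NULL,
                       background = 0, normalized = FALSE) {
  stopifnot(length(times) == length(intensity))
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (!any(times < 0)) stop("need at least one pre-bleach (t < 0) sample")
  if (is.null(prebleach_level)) prebleach_level <- mean(intensity[times < 0])
  structure(list(times = as.numeric(times),
                 intensity = as.numeric(intensity),
                 prebleach_level = prebleach_level,
                 background = background, normalized = normalized),
            class = "frap_curve")
}

#' Normalise a FRAP curve to its pre-bleach plateau
#'
#' `normalized = (I - background) / (prebleach - background)`, so the
#' pre-bleach plateau maps to 1 and the background to 0. Idempotent on
#' already-normalised curves.
#'
#' @param raw A [frap_curve()].
#' @return A normalised `frap_curve` (background 0, prebleach_level 1).
#' @export
normalize_frap <- function(raw) {
  stopifnot(inherits(raw, "frap_curve"))
  pre <- raw$prebleach_level
  bg <- raw$background
  if (pre <= bg)
    stop("prebleach level must exceed background: cannot normalise")
  frap_curve(times = raw$times,
             intensity = (raw$intensity - bg) / (pre - bg),
             prebleach_level = 1, background = 0, normalized = TRUE)
}

#' Average replicate FRAP curves
#'
#' FRAP parameters are conventionally estimated from the mean recovery over
#' replicate cells rather than from single noisy traces; this averages
#' curves sampled on a common time base.
#'
#' @param curves List of [frap_curve()]s with identical `times`.
#' @return A `frap_curve` with the pointwise mean intensity; normalisation
#'   state is inherited when shared by all inputs.
#' @export
average_frap_curves <- function(curves) {
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "frap_curve")))
  tt <- curves[[1]]$times
  for (crv in curves)
    if (!isTRUE(all.equal(crv$times, tt)))
      stop("curves must share a common time base")
  inten <- rowMeans(vapply(curves, `[[`, numeric(length(tt)), "intensity"))
  frap_curve(times = tt, intensity = inten,
             prebleach_level = mean(vapply(curves, `[[`, numeric(1),
                                           "prebleach_level")),
             background = mean(vapply(curves, `[[`, numeric(1),
                                      "background")),
             normalized = all(vapply(curves, function(crv)
               isTRUE(crv$normalized), logical(1))))
}

#' Fit the single-exponential FRAP recovery model
#'
#' Least-squares fit of `I(t) = I0 + (Iinf - I0) * (1 - exp(-k t))` to the
#' post-bleach samples of a normalised curve. The mobile fraction is the
#' recovered amplitude relative to the bleached amplitude,
#' `(Iinf - I0) / (1 - I0)`, and `stable_fraction = 1 - mobile_fraction`
#' exactly.
#'
#' @param curve A normalised [frap_curve()] (see [normalize_frap()]) with at
#'   least 8 post-bleach samples.
#' @return A `frap_fit`: list with `mobile_fraction`, `stable_fraction`,
#'   `rate_k` (1/s), `I0`, `Iinf`, `residual_rms`, `converged`.
#' @export
fit_frap <- function(curve) {
  stopifnot(inherits(curve, "frap_curve"))
  if (!isTRUE(curve$normalized))
    curve <- normalize_frap(curve)
  post <- curve$times >= 0
  tt <- curve$times[post]
  yy <- curve$intensity[post]
  if (length(tt) < 8L) stop("need >= 8 post-bleach samples")
  i0_start <- mean(yy[seq_len(min(3L, length(yy)))])
  iinf_start <- mean(yy[tt >= stats::quantile(tt, 0.8)])
  if (diff(range(yy)) < 1e-12) {
    # flat post-bleach curve: no recovery, rate unidentifiable
    fit <- list(I0 = yy[1], Iinf = yy[1], k = 0)
    mobile <- 0
    rms <- 0
    converged <- TRUE
  } else {
    half_t <- tt[which.min(abs(yy - (i0_start + iinf_start) / 2))]
    k_start <- if (half_t > 0) log(2) / half_t else 1
    start <- list(I0 = i0_start, Iinf = iinf_start,
                  k = max(k_start, 1e-3))
    nls_fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ I0 + (Iinf - I0) * (1 - exp(-k * tt)),
                        start = start,
                        lower = c(I0 = -0.2, Iinf = 0, k = 0),
                        upper = c(I0 = 1.2, Iinf = 1.5, k = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e)
        stop(sprintf(paste0("FRAP fit did not converge (%s); starting ",
                            "values: I0 = %.3g, Iinf = %.3g, k = %.3g"),
                     conditionMessage(e), start$I0, start$Iinf, start$k)))
    cf <- stats::coef(nls_fit)
    fit <- list(I0 = unname(cf["I0"]), Iinf = unname(cf["Iinf"]),
                k = unname(cf["k"]))
    mobile <- (fit$Iinf - fit$I0) / (1 - fit$I0)
    rms <- sqrt(mean(stats::resid(nls_fit)^2))
    converged <- TRUE
  }
  mobile <- min(max(mobile, 0), 1)
  structure(list(mobile_fraction = mobile,
                 stable_fraction = 1 - mobile,
                 rate_k = fit$k, I0 = fit$I0, Iinf = fit$Iinf,
                 residual_rms = rms, converged = converged),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf("<frap_fit> mobile = %.3f, stable = %.3f, k = %.4g /s (rms %.3g)\n",
              x$mobile_fraction, x$stable_fraction, x$rate_k,
              x$residual_rms))
  invisible(x)
}

#' Position-time kymograph
#'
#' @param array Numeric matrix, rows = positions along the sampled line,
#'   columns = frames.
#' @param frame_interval s per frame (column).
#' @param pixel_size um per row.
#' @return A `kymograph` object.
#' @export
kymograph <- function(array, frame_interval, pixel_size) {
  stopifnot(is.matrix(array))
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(array = array, frame_interval = frame_interval,
                 pixel_size = pixel_size),
            class = "kymograph")
}

#' Extract a kymograph from a time-lapse stack
#'
#' Samples the stack along a polyline at 1-pixel steps; at each position the
#' value is the maximum over `width` pixels perpendicular to the line, and
#' positions over frames form the kymograph.
#'
#' @param stack An [image_stack()].
#' @param line 2-column (x, y) matrix of polyline vertices in um.
#' @param width Averaging width in pixels perpendicular to the line (odd,
#'   default 1); the maximum across the width is taken.
#' @return A [kymograph()].
#' @export
extract_kymograph <- function(stack, line, width = 1L) {
  stopifnot(inherits(stack, "image_stack"))
  ps <- stack$pixel_size
  path <- sample_polyline(as.matrix(line), step_um = ps)
  assert_in_bounds(path$points_um, dim(stack$frames[[1]]), ps)
  offs <- (seq_len(width) - (width + 1) / 2)  # px offsets across the line
  cols_px <- um_to_px(path$points_um[, 1], ps)
  rows_px <- um_to_px(path$points_um[, 2], ps)
  arr <- vapply(stack$frames, function(fr) {
    vals <- vapply(offs, function(o) {
      interp_bilinear(fr, cols_px + o * path$normals[, 1],
                      rows_px + o * path$normals[, 2])
    }, numeric(length(cols_px)))
    vals <- matrix(vals, nrow = length(cols_px))
    apply(vals, 1, max)
  }, numeric(length(cols_px)))
  kymograph(matrix(arr, nrow = length(cols_px)),
            frame_interval = stack$frame_interval, pixel_size = ps)
}

#' Measure particle residence lifetimes from a kymograph
#'
#' Each contiguous supra-threshold run within a spatial row becomes one
#' lifetime record with `duration = run length * frame_interval` (inclusive
#' frame count). Runs touching the first or last frame are flagged censored:
#' their full residence time is unobserved. Runs in the same row are split at
#' sub-threshold gaps of >= 1 frame.
#'
#' @param kymo A [kymograph()].
#' @param intensity_threshold Intensity above which a particle is present
#'   (AU); must exceed the background.
#' @param min_frames Minimum run length in frames (default 1).
#' @return Data frame with `row`, `start_frame`, `end_frame`, `duration_s`,
#'   `censored`.
#' @export
measure_lifetimes <- function(kymo, intensity_threshold, min_frames = 1L) {
  stopifnot(inherits(kymo, "kymograph"))
  arr <- kymo$array
  nfr <- ncol(arr)
  recs <- list()
  for (r in seq_len(nrow(arr))) {
    above <- arr[r, ] > intensity_threshold
    if (!any(above)) next
    rl <- rle(above)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (k in which(rl$values & rl$lengths >= min_frames)) {
      recs[[length(recs) + 1L]] <- data.frame(
        row = r, start_frame = starts[k], end_frame = ends[k],
        duration_s = rl$lengths[k] * kymo$frame_interval,
        censored = starts[k] == 1L || ends[k] == nfr)
    }
  }
  if (length(recs) == 0L)
    return(data.frame(row = integer(0), start_frame = integer(0),
                      end_frame = integer(0), duration_s = numeric(0),
                      censored = logical(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Summarise residence lifetimes
#'
#' @param records Lifetime records from [measure_lifetimes()].
#' @param policy `"exclude_censored"` (default: summary statistics over
#'   uncensored records only) or `"include_all"`.
#' @return List with `mean_s`, `median_s`, `n`, `n_censored`, `policy`.
#' @export
summarize_lifetimes <- function(records,
                                policy = c("exclude_censored",
                                           "include_all")) {
  policy <- match.arg(policy)
  n_cens <- sum(records$censored)
  use <- if (policy == "exclude_censored") !records$censored
         else rep(TRUE, nrow(records))
  if (!any(use))
    stop("no uncensored lifetime records to summarise")
  d <- records$duration_s[use]
  list(mean_s = mean(d), median_s = stats::median(d), n = length(d),
       n_censored = as.integer(n_cens), policy = policy)
}
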
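#' Single-particle tracking and diffusion analysis
#'
#' Spot detection with sub-pixel centroids, intensity classification, greedy
#' nearest-neighbour linking, time-averaged mean-squared displacement (MSD)
#' and diffusion-coefficient estimation from the short-lag MSD slope
#' (`MSD = 4 D t` in 2-D, plus a localisation-noise intercept).
#'
#' @name spt
NULL

#' Particle trajectory
#'
#' @param detections Data frame with columns `frame` (strictly increasing
#'   integer), `x_um`, `y_um` and optionally `intensity_AU`.
#' @param frame_interval s between consecutive frames.
#' @return A `trajectory` (a data frame with a `frame_interval` attribute).
#' @export
trajectory <- function(detections, frame_interval) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x_um", "y_um") %in% names(detections)))
  if (is.unsorted(detections$frame, strictly = TRUE))
    stop("frame indices must be strictly increasing")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(detections, frame_interval = frame_interval,
            class = c("trajectory", "data.frame"))
}

#' Detect fluorescent spots in one frame
#'
#' Local maxima above `background + snr_min * noise` (background = median,
#' noise = MAD of the frame) are refined to sub-pixel centroids by
#' background-subtracted intensity weighting over the spot window; the
#' spot's total intensity is the background-subtracted sum over that window.
#'
#' @param frame A [calibrated_image()].
#' @param expected_radius Approximate spot radius in um.
#' @param snr_min Minimum peak signal-to-noise ratio (default 3).
#' @return Data frame with `x_um`, `y_um`, `intensity_AU`, `peak_AU`; empty
#'   when no spot qualifies.
#' @export
detect_spots <- function(frame, expected_radius, snr_min = 3) {
  stopifnot(inherits(frame, "calibrated_image"))
  px <- frame$pixels
  ps <- frame$pixel_size
  r <- max(1L, ceiling(expected_radius / ps - 1e-9))
  w <- 3L * r                      # intensity (flux) window half-width
  wc <- 2L * r                     # tighter centroid window: less pull from
                                   # neighbouring spots
  bg <- stats::median(px)
  noise <- stats::mad(px)
  thr <- bg + snr_min * noise
  cand <- which(px > thr)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      intensity_AU = numeric(0), peak_AU = numeric(0))
  if (length(cand) == 0L) return(empty)
  nr <- nrow(px); nc <- ncol(px)
  rows <- ((cand - 1L) %% nr) + 1L
  cols <- ((cand - 1L) %/% nr) + 1L
  ord <- order(px[cand], decreasing = TRUE)
  taken <- matrix(FALSE, nr, nc)
  out <- list()
  for (k in ord) {
    ri <- rows[k]; ci <- cols[k]
    if (taken[ri, ci]) next
    rr <- max(1L, ri - 1L):min(nr, ri + 1L)
    cc <- max(1L, ci - 1L):min(nc, ci + 1L)
    if (px[ri, ci] < max(px[rr, cc])) next    # not a local maximum
    rr <- max(1L, ri - w):min(nr, ri + w)
    cc <- max(1L, ci - w):min(nc, ci + w)
    win <- px[rr, cc, drop = FALSE] - bg
    win[win < 0] <- 0
    tot <- sum(win)
    if (tot <= 0) next
    rrc <- max(1L, ri - wc):min(nr, ri + wc)
    ccc <- max(1L, ci - wc):min(nc, ci + wc)
    wcent <- px[rrc, ccc, drop = FALSE] - bg
    wcent[wcent < 0] <- 0
    cy <- sum(rrc * rowSums(wcent)) / sum(wcent)
    cx <- sum(ccc * colSums(wcent)) / sum(wcent)
    # suppress only within ~1 radius so nearby genuine peaks survive
    sr <- max(1L, ri - r):min(nr, ri + r)
    sc <- max(1L, ci - r):min(nc, ci + r)
    taken[sr, sc] <- TRUE
    out[[length(out) + 1L]] <- c(cx, cy, tot, px[ri, ci])
  }
  if (length(out) == 0L) return(empty)
  m <- do.call(rbind, out)
  data.frame(x_um = px_to_um(m[, 1], ps), y_um = px_to_um(m[, 2], ps),
             intensity_AU = m[, 3], peak_AU = m[, 4])
}

#' Classify spot intensity into the three brightness populations
#'
#' Boundaries: low `< 5e3` AU, medium `[5e3, 15e3]` AU (both boundaries
#' inclusive), high `> 15e3` AU.
#'
#' @param intensity Numeric vector of total spot intensities (AU), >= 0.
#' @param low_cut,high_cut Class boundaries in AU.
#' @return Factor with levels `low`, `medium`, `high`.
#' @export
classify_intensity <- function(intensity, low_cut = 5e3, high_cut = 15e3) {
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be non-negative and finite")
  cls <- ifelse(intensity < low_cut, "low",
                ifelse(intensity <= high_cut, "medium", "high"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbour linking: candidate (track end, detection) pairs
#' within `max_disp` um and at most `max_gap` missing frames are accepted in
#' order of increasing distance; each detection is used at most once, and
#' unmatched detections seed new tracks.
#'
#' @param detections Data frame with `frame`, `x_um`, `y_um` and optional
#'   `intensity_AU`, covering all frames.
#' @param max_disp Maximum link displacement (um).
#' @param max_gap Maximum number of missing frames bridged (default 0).
#' @param frame_interval s per frame, attached to the returned tracks.
#' @return List of `trajectory` objects.
#' @export
link_trajectories <- function(detections, max_disp, max_gap = 0L,
                              frame_interval = 0.1) {
  stopifnot(is.data.frame(detections),
            all(c("frame", "x_um", "y_um") %in% names(detections)))
  if (!"intensity_AU" %in% names(detections))
    detections$intensity_AU <- NA_real_
  if (nrow(detections) == 0L) return(list())
  detections <- detections[order(detections$frame), , drop = FALSE]
  frames <- sort(unique(detections$frame))
  # active track state
  tr_rows <- list()          # list of integer row indices into `detections`
  last_x <- numeric(0); last_y <- numeric(0); last_f <- integer(0)
  open <- integer(0)         # indices of open tracks
  for (f in frames) {
    det_idx <- which(detections$frame == f)
    open <- open[f - last_f[open] <= max_gap + 1L]
    assigned_det <- rep(FALSE, length(det_idx))
    if (length(open) > 0L && length(det_idx) > 0L) {
      dx <- outer(last_x[open], detections$x_um[det_idx], "-")
      dy <- outer(last_y[open], detections$y_um[det_idx], "-")
      d <- sqrt(dx^2 + dy^2)
      cand <- which(d <= max_disp, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        used_tr <- rep(FALSE, length(open))
        for (q in seq_len(nrow(cand))) {
          ti <- cand[q, 1]; di <- cand[q, 2]
          if (used_tr[ti] || assigned_det[di]) next
          used_tr[ti] <- TRUE; assigned_det[di] <- TRUE
          tid <- open[ti]
          tr_rows[[tid]] <- c(tr_rows[[tid]], det_idx[di])
          last_x[tid] <- detections$x_um[det_idx[di]]
          last_y[tid] <- detections$y_um[det_idx[di]]
          last_f[tid] <- f
        }
      }
    }
    for (di in which(!assigned_det)) {
      tid <- length(tr_rows) + 1L
      tr_rows[[tid]] <- det_idx[di]
      last_x[tid] <- detections$x_um[det_idx[di]]
      last_y[tid] <- detections$y_um[det_idx[di]]
      last_f[tid] <- f
      open <- c(open, tid)
    }
    open <- unique(c(open, which(last_f == f)))
  }
  lapply(seq_along(tr_rows), function(tid) {
    d <- detections[tr_rows[[tid]],
                    c("frame", "x_um", "y_um", "intensity_AU")]
    rownames(d) <- NULL
    tr <- trajectory(d, frame_interval)
    attr(tr, "track_id") <- tid
    tr
  })
}

#' Time-averaged mean-squared displacement over an ensemble of tracks
#'
#' For each track, the time-averaged squared displacement at lag `l` is the
#' mean over all frame pairs `(t, t + l)` present in the track; the ensemble
#' MSD at each lag is the mean of per-track values and the SE is their
#' standard deviation across tracks divided by `sqrt(n_tracks)`.
#'
#' @param tracks List of `trajectory` objects.
#' @param n_lags Number of lags to evaluate; defaults to half the longest
#'   track.
#' @param min_length Minimum track length in frames (default 5); shorter
#'   tracks are dropped.
#' @return An `msd_curve`: list with `lags_s`, `msd_um2`, `se_um2`,
#'   `n_tracks`, `n_pairs`, `frame_interval`.
#' @export
compute_msd <- function(tracks, n_lags = NULL, min_length = 5L) {
  tracks <- Filter(function(tr) nrow(tr) >= min_length, tracks)
  if (length(tracks) == 0L)
    stop(sprintf("no tracks with >= %d frames", min_length))
  dt <- attr(tracks[[1]], "frame_interval")
  max_len <- max(vapply(tracks, nrow, integer(1)))
  if (is.null(n_lags)) n_lags <- max(1L, (max_len - 1L) %/% 2L)
  per_track <- vapply(tracks, function(tr) {
    msd <- rep(NA_real_, n_lags)
    fr <- tr$frame
    for (l in seq_len(n_lags)) {
      j <- match(fr + l, fr)
      ok <- !is.na(j)
      if (!any(ok)) next
      msd[l] <- mean((tr$x_um[which(ok)] - tr$x_um[j[ok]])^2 +
                       (tr$y_um[which(ok)] - tr$y_um[j[ok]])^2)
    }
    msd
  }, numeric(n_lags))
  per_track <- matrix(per_track, nrow = n_lags)
  msd <- apply(per_track, 1, mean, na.rm = TRUE)
  ntr <- apply(per_track, 1, function(z) sum(!is.na(z)))
  se <- apply(per_track, 1, stats::sd, na.rm = TRUE) / sqrt(pmax(ntr, 1))
  structure(list(lags_s = seq_len(n_lags) * dt, msd_um2 = as.numeric(msd),
                 se_um2 = as.numeric(se), n_tracks = as.integer(ntr),
                 n_pairs = NULL, frame_interval = dt),
            class = "msd_curve")
}

#' Fit a diffusion coefficient to the short-lag MSD
#'
#' Weighted least-squares line through the first `n_fit_lags` lags of the
#' MSD curve (weights `1/se^2` where defined); in 2-D the slope is `4 D` and
#' the intercept absorbs static localisation noise (`4 sigma^2`). A negative
#' fitted slope is clipped to `D = 0` and flagged.
#'
#' @param curve An `msd_curve` from [compute_msd()].
#' @param n_fit_lags Number of lags fitted (default 4, the usual short-lag
#'   bias-variance compromise; never more than the curve provides).
#' @return A `diffusion_estimate`: list with `D` (um^2/s), `intercept`
#'   (um^2), `fit_lags_s`, `r_squared`, `clipped`.
#' @export
fit_diffusion <- function(curve, n_fit_lags = 4L) {
  stopifnot(inherits(curve, "msd_curve"))
  if (length(curve$lags_s) < n_fit_lags)
    stop(sprintf("MSD curve has %d lags, need >= %d",
                 length(curve$lags_s), n_fit_lags))
  i <- seq_len(n_fit_lags)
  x <- curve$lags_s[i]; y <- curve$msd_um2[i]; se <- curve$se_um2[i]
  wts <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(i))
  fit <- stats::lm(y ~ x, weights = wts)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  clipped <- slope < 0
  D <- if (clipped) 0 else slope / 4
  ss_tot <- sum(wts * (y - stats::weighted.mean(y, wts))^2)
  r2 <- if (ss_tot > 0) 1 - sum(wts * stats::resid(fit)^2) / ss_tot else NA_real_
  structure(list(D = D, intercept = intercept, fit_lags_s = range(x),
                 r_squared = r2, clipped = clipped, slope = slope),
            class = "diffusion_estimate")
}

#' Frequency distribution of diffusion coefficients
#'
#' @param D Numeric vector of per-ROI diffusion coefficients (um^2/s), or a
#'   list of `diffusion_estimate` objects.
#' @param breaks Histogram bin edges (um^2/s); default 20 equal bins over the
#'   data range.
#' @return Data frame with `bin_low`, `bin_high`, `count`, `frequency`
#'   (summing to 1).
#' @export
diffusion_distribution <- function(D, breaks = NULL) {
  if (is.list(D) && inherits(D[[1]], "diffusion_estimate"))
    D <- vapply(D, `[[`, numeric(1), "D")
  if (length(D) < 1L) stop("need at least one estimate")
  if (is.null(breaks)) {
    rng <- range(D)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(rng[1], 1e-3)
    breaks <- seq(rng[1], rng[2], length.out = 21L)
  }
  h <- graphics::hist(D, breaks = breaks, plot = FALSE,
                      include.lowest = TRUE, right = FALSE)
  data.frame(bin_low = utils::head(h$breaks, -1),
             bin_high = utils::tail(h$breaks, -1),
             count = h$counts,
             frequency = h$counts / sum(h$counts))
}
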
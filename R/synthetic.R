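#' Synthetic ground-truth generators
#'
#' Seeded generators that emulate the statistical structure each analysis
#' stage assumes: membrane intensity fields with clusters of controlled area
#' distribution, mixtures of Brownian and immobile particle trajectories,
#' single-exponential FRAP recovery curves, kymographs of puncta with
#' exponential lifetimes, and two-sided root intensity fields with an imposed
#' lower/upper fold difference. Each generator is a pure function of its spec
#' (including the seed): the same spec always yields bit-identical output, and
#' every generator returns the planted ground truth next to the data.
#'
#' @name synthetic
NULL

validate_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  as.integer(seed)
}

## ---------------------------------------------------------------------------
## Cluster fields

#' Specification of a synthetic clustered membrane field
#'
#' @param image_shape Integer vector `c(rows, cols)` in pixels.
#' @param pixel_size um per pixel.
#' @param n_clusters Number of clusters to plant (>= 0).
#' @param area_distribution Named distribution of cluster areas in um^2.
#'   Either `list(type = "uniform", min =, max =)`,
#'   `list(type = "lognormal", meanlog =, sdlog =)`, or
#'   `list(type = "mixture", weights =, mins =, maxs =)` where each component
#'   is uniform on `[mins[i], maxs[i])` and drawn with probability
#'   `weights[i]`. The default mixture reproduces a strongly condensed field:
#'   31% tiny (<0.2 um^2), 61% small (0.2-0.6), 6% medium (0.6-1), 2% long
#'   (>1 um^2) islands.
#' @param cluster_peak_intensity Peak intensity of a cluster above background
#'   (AU).
#' @param background_intensity Membrane background level (AU).
#' @param noise_poisson_scale Scale of Poisson shot noise: pixel values are
#'   drawn as `rpois(I / scale) * scale`; 0 disables shot noise.
#' @param noise_gaussian_sd Additive Gaussian read-noise sd (AU); 0 disables.
#' @param membrane_geometry `list(type = "full")` (whole field is membrane
#'   surface) or `list(type = "band", center_row =, width_px =)` for a
#'   horizontal membrane band.
#' @param seed Integer seed.
#' @return A validated `cluster_field_spec`.
#' @export
cluster_field_spec <- function(image_shape = c(512L, 512L),
                               pixel_size = 0.05,
                               n_clusters = 150L,
                               area_distribution = list(
                                 type = "mixture",
                                 weights = c(0.31, 0.61, 0.06, 0.02),
                                 mins = c(0.05, 0.2, 0.6, 1.0),
                                 maxs = c(0.2, 0.6, 1.0, 1.6)),
                               cluster_peak_intensity = 2000,
                               background_intensity = 200,
                               noise_poisson_scale = 0,
                               noise_gaussian_sd = 20,
                               membrane_geometry = list(type = "full"),
                               seed = 1L) {
  stopifnot(length(image_shape) == 2L, all(image_shape >= 8))
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (n_clusters < 0) stop("n_clusters must be >= 0")
  if (cluster_peak_intensity < 0 || background_intensity < 0)
    stop("intensities must be >= 0")
  if (noise_poisson_scale < 0 || noise_gaussian_sd < 0)
    stop("noise parameters must be >= 0")
  if (!membrane_geometry$type %in% c("full", "band"))
    stop("membrane_geometry$type must be 'full' or 'band'")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size,
                 n_clusters = as.integer(n_clusters),
                 area_distribution = area_distribution,
                 cluster_peak_intensity = cluster_peak_intensity,
                 background_intensity = background_intensity,
                 noise_poisson_scale = noise_poisson_scale,
                 noise_gaussian_sd = noise_gaussian_sd,
                 membrane_geometry = membrane_geometry,
                 seed = validate_seed(seed)),
            class = "cluster_field_spec")
}

draw_areas <- function(dist, n) {
  if (n == 0L) return(numeric(0))
  switch(dist$type,
    uniform = stats::runif(n, dist$min, dist$max),
    lognormal = stats::rlnorm(n, dist$meanlog, dist$sdlog),
    mixture = {
      k <- sample.int(length(dist$weights), n, replace = TRUE,
                      prob = dist$weights)
      stats::runif(n, dist$mins[k], dist$maxs[k])
    },
    stop("unknown area distribution type: ", dist$type))
}

#' Generate a clustered membrane intensity field with ground truth
#'
#' Clusters are rendered as Gaussian-profiled blobs whose area is defined at
#' half-maximum, so that a detector thresholding halfway between background
#' and peak recovers the planted area: a blob of area `a` um^2 has
#' `sigma = sqrt(a / (2 * pi * log(2)))`. Blobs are placed by rejection
#' sampling so that no two clusters merge above half-maximum; shot and read
#' noise are applied after rendering.
#'
#' @param spec A [cluster_field_spec()].
#' @return List with `image` (a [calibrated_image()]) and `truth`, a
#'   data frame with one row per planted cluster: `label`, `x_um`, `y_um`,
#'   `area_um2`, `size_class`, `sigma_px`.
#' @export
generate_cluster_image <- function(spec) {
  stopifnot(inherits(spec, "cluster_field_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    ps <- spec$pixel_size
    if (spec$membrane_geometry$type == "band") {
      r0 <- max(1L, spec$membrane_geometry$center_row -
                  spec$membrane_geometry$width_px %/% 2L)
      r1 <- min(nr, r0 + spec$membrane_geometry$width_px - 1L)
    } else {
      r0 <- 1L; r1 <- nr
    }
    px <- matrix(0, nr, nc)
    px[r0:r1, ] <- spec$background_intensity

    n <- spec$n_clusters
    truth <- data.frame(label = integer(0), x_um = numeric(0),
                        y_um = numeric(0), area_um2 = numeric(0),
                        size_class = character(0), sigma_px = numeric(0),
                        stringsAsFactors = FALSE)
    if (n > 0L) {
      areas <- draw_areas(spec$area_distribution, n)
      # place large blobs first: they have the tightest spacing constraints
      areas <- areas[order(areas, decreasing = TRUE)]
      sigma_um <- sqrt(areas / (2 * pi * log(2)))
      sigma_px <- sigma_um / ps
      # placement: keep centres far enough apart that blobs stay disjoint at
      # the half-maximum contour (tails < 5% of peak at the midpoint)
      margin <- 3 * sigma_px + 2
      cx <- numeric(n); cy <- numeric(n)
      placed <- 0L
      attempts <- 0L
      max_attempts <- 400L * n
      while (placed < n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop(sprintf(paste0(
            "could not place %d non-overlapping clusters in a %d x %d px ",
            "field after %d attempts: cluster density too high"),
            n, nr, nc, max_attempts))
        i <- placed + 1L
        m <- margin[i]
        if (2 * m >= nc - 1 || 2 * m >= (r1 - r0 - 1))
          stop(sprintf(
            "cluster of sigma %.1f px does not fit the membrane region",
            sigma_px[i]))
        x <- stats::runif(1, 1 + m, nc - m)
        y <- stats::runif(1, r0 + m, r1 - m)
        ok <- TRUE
        if (placed > 0L) {
          j <- seq_len(placed)
          d2 <- (cx[j] - x)^2 + (cy[j] - y)^2
          ok <- all(d2 >= (2.6 * (sigma_px[j] + sigma_px[i]))^2)
        }
        if (ok) {
          placed <- i
          cx[i] <- x; cy[i] <- y
        }
      }
      for (i in seq_len(n)) {
        w <- ceiling(4 * sigma_px[i])
        rows <- max(1L, floor(cy[i]) - w):min(nr, ceiling(cy[i]) + w)
        cols <- max(1L, floor(cx[i]) - w):min(nc, ceiling(cx[i]) + w)
        dy <- rows - cy[i]
        dx <- cols - cx[i]
        g <- exp(-outer(dy^2, dx^2, "+") / (2 * sigma_px[i]^2))
        px[rows, cols] <- px[rows, cols] + spec$cluster_peak_intensity * g
      }
      truth <- data.frame(label = seq_len(n),
                          x_um = px_to_um(cx, ps),
                          y_um = px_to_um(cy, ps),
                          area_um2 = areas,
                          size_class = as.character(classify_cluster_size(areas)),
                          sigma_px = sigma_px,
                          stringsAsFactors = FALSE)
    }
    if (spec$noise_poisson_scale > 0) {
      sc <- spec$noise_poisson_scale
      px[] <- stats::rpois(length(px), px / sc) * sc
    }
    if (spec$noise_gaussian_sd > 0)
      px[] <- px + stats::rnorm(length(px), 0, spec$noise_gaussian_sd)
    px[px < 0] <- 0
    list(image = calibrated_image(px, ps), truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Trajectories

#' Specification of a synthetic particle-trajectory field
#'
#' @param n_tracks Number of particles.
#' @param frame_interval s between frames.
#' @param n_frames Frames per track.
#' @param D_free Diffusion coefficient of the mobile population (um^2/s).
#' @param immobile_fraction Probability that a track is immobile, in `[0, 1]`.
#' @param localization_sd Localisation noise sd per axis (um).
#' @param intensity_means Named mean spot intensities (AU) for the two
#'   mobility populations, `c(free = , immobile = )`; brighter immobile spots
#'   mirror the inverse intensity-mobility relationship seen for oligomerised
#'   membrane proteins.
#' @param intensity_sd Spot intensity sd (AU).
#' @param field_size Side of the square field (um); trajectories reflect at
#'   the boundary so the Brownian MSD is preserved.
#' @param seed Integer seed.
#' @return A validated `trajectory_field_spec`.
#' @export
trajectory_field_spec <- function(n_tracks = 100L,
                                  frame_interval = 0.1,
                                  n_frames = 60L,
                                  D_free = 0.05,
                                  immobile_fraction = 0,
                                  localization_sd = 0.02,
                                  intensity_means = c(free = 3000,
                                                      immobile = 20000),
                                  intensity_sd = 200,
                                  field_size = 20,
                                  seed = 1L) {
  if (immobile_fraction < 0 || immobile_fraction > 1)
    stop("immobile_fraction must lie in [0, 1]")
  if (D_free < 0) stop("D_free must be >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (localization_sd < 0) stop("localization_sd must be >= 0")
  if (n_frames < 2) stop("n_frames must be >= 2")
  structure(list(n_tracks = as.integer(n_tracks),
                 frame_interval = frame_interval,
                 n_frames = as.integer(n_frames),
                 D_free = D_free,
                 immobile_fraction = immobile_fraction,
                 localization_sd = localization_sd,
                 intensity_means = intensity_means,
                 intensity_sd = intensity_sd,
                 field_size = field_size,
                 seed = validate_seed(seed)),
            class = "trajectory_field_spec")
}

reflect_into <- function(x, lo, hi) {
  # fold coordinates back into [lo, hi] (reflecting boundary)
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  y <- ifelse(y > span, 2 * span - y, y)
  y + lo
}

#' Generate labelled Brownian/immobile trajectories
#'
#' Free tracks take 2-D Brownian steps with per-axis variance
#' `2 * D_free * frame_interval`; immobile tracks stay at their anchor point.
#' Both are observed with additive Gaussian localisation noise. The returned
#' tracks carry their true mobility label and per-detection intensities.
#'
#' @param spec A [trajectory_field_spec()].
#' @return List of `trajectory` objects (see [trajectory()]), each with a
#'   `mobility` attribute of `"free"` or `"immobile"`.
#' @export
generate_trajectories <- function(spec) {
  stopifnot(inherits(spec, "trajectory_field_spec"))
  withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_tracks), function(id) {
      immobile <- stats::runif(1) < spec$immobile_fraction
      nfr <- spec$n_frames
      x0 <- stats::runif(1, 0, spec$field_size)
      y0 <- stats::runif(1, 0, spec$field_size)
      if (immobile || spec$D_free == 0) {
        x <- rep(x0, nfr); y <- rep(y0, nfr)
      } else {
        step_sd <- sqrt(2 * spec$D_free * spec$frame_interval)
        x <- x0 + cumsum(c(0, stats::rnorm(nfr - 1, 0, step_sd)))
        y <- y0 + cumsum(c(0, stats::rnorm(nfr - 1, 0, step_sd)))
        x <- reflect_into(x, 0, spec$field_size)
        y <- reflect_into(y, 0, spec$field_size)
      }
      if (spec$localization_sd > 0) {
        x <- x + stats::rnorm(nfr, 0, spec$localization_sd)
        y <- y + stats::rnorm(nfr, 0, spec$localization_sd)
      }
      mob <- if (immobile) "immobile" else "free"
      inten <- stats::rnorm(nfr, spec$intensity_means[[mob]],
                            spec$intensity_sd)
      tr <- trajectory(data.frame(frame = seq_len(nfr),
                                  x_um = x, y_um = y,
                                  intensity_AU = pmax(inten, 0)),
                       frame_interval = spec$frame_interval)
      attr(tr, "track_id") <- id
      attr(tr, "mobility") <- mob
      tr
    })
  })
}

#' Render trajectories into a synthetic time-lapse stack
#'
#' Draws each detection as a Gaussian spot of total intensity equal to the
#' detection's intensity, over a uniform background with optional Gaussian
#' noise. Used to exercise spot detection and linking against known tracks.
#'
#' @param tracks List of `trajectory` objects (from [generate_trajectories()]).
#' @param field_size Side of the square field (um).
#' @param pixel_size um per pixel of the rendered stack.
#' @param psf_sigma_um Gaussian spot sd (um).
#' @param background Background level (AU).
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param seed Integer seed for the noise.
#' @return An [image_stack()].
#' @export
render_trajectory_stack <- function(tracks, field_size, pixel_size = 0.1,
                                    psf_sigma_um = 0.15, background = 100,
                                    noise_sd = 0, seed = 1L) {
  stopifnot(length(tracks) > 0L)
  dt <- attr(tracks[[1]], "frame_interval")
  nfr <- max(vapply(tracks, function(tr) max(tr$frame), integer(1)))
  npx <- ceiling(field_size / pixel_size)
  sig <- psf_sigma_um / pixel_size
  w <- ceiling(4 * sig)
  withr::with_seed(validate_seed(seed), {
    frames <- lapply(seq_len(nfr), function(f) {
      px <- matrix(background, npx, npx)
      for (tr in tracks) {
        i <- match(f, tr$frame)
        if (is.na(i)) next
        cx <- um_to_px(tr$x_um[i], pixel_size)
        cy <- um_to_px(tr$y_um[i], pixel_size)
        rows <- max(1L, floor(cy) - w):min(npx, ceiling(cy) + w)
        cols <- max(1L, floor(cx) - w):min(npx, ceiling(cx) + w)
        g <- exp(-outer((rows - cy)^2, (cols - cx)^2, "+") / (2 * sig^2))
        px[rows, cols] <- px[rows, cols] +
          tr$intensity_AU[i] * g / (2 * pi * sig^2)
      }
      if (noise_sd > 0)
        px <- pmax(px + stats::rnorm(length(px), 0, noise_sd), 0)
      px
    })
    image_stack(frames, pixel_size = pixel_size, frame_interval = dt)
  })
}

## ---------------------------------------------------------------------------
## FRAP

#' Specification of a synthetic FRAP experiment
#'
#' @param prebleach_level Pre-bleach fluorescence plateau (AU).
#' @param bleach_depth Fraction of signal removed by the bleach, in `(0, 1]`.
#' @param mobile_fraction Fraction of molecules free to exchange, `[0, 1]`.
#' @param rate_k Recovery rate constant (1/s), >= 0.
#' @param duration Post-bleach observation time (s).
#' @param sample_interval Sampling interval (s).
#' @param n_prebleach Number of pre-bleach samples.
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param seed Integer seed.
#' @return A validated `frap_spec`.
#' @export
frap_spec <- function(prebleach_level = 1000,
                      bleach_depth = 0.8,
                      mobile_fraction = 0.7,
                      rate_k = 0.2,
                      duration = 60,
                      sample_interval = 0.5,
                      n_prebleach = 5L,
                      noise_sd = 0,
                      seed = 1L) {
  if (mobile_fraction < 0 || mobile_fraction > 1)
    stop("mobile_fraction must lie in [0, 1]")
  if (rate_k < 0) stop("rate_k must be >= 0")
  if (bleach_depth <= 0 || bleach_depth > 1)
    stop("bleach_depth must lie in (0, 1]")
  if (duration <= 0 || sample_interval <= 0)
    stop("duration and sample_interval must be > 0")
  structure(list(prebleach_level = prebleach_level,
                 bleach_depth = bleach_depth,
                 mobile_fraction = mobile_fraction,
                 rate_k = rate_k, duration = duration,
                 sample_interval = sample_interval,
                 n_prebleach = as.integer(n_prebleach),
                 noise_sd = noise_sd,
                 seed = validate_seed(seed)),
            class = "frap_spec")
}

#' Generate a single-exponential FRAP recovery curve
#'
#' The noise-free expectation follows the model fitted by [fit_frap()]:
#' normalised recovery `i(t) = i0 + mobile * (1 - i0) * (1 - exp(-k t))`
#' with `i0 = 1 - bleach_depth`, scaled by the pre-bleach level.
#'
#' @param spec A [frap_spec()].
#' @return A [frap_curve()] whose `true_params` attribute stores the planted
#'   `mobile_fraction`, `rate_k`, `bleach_depth` and `prebleach_level`.
#' @export
generate_frap_curve <- function(spec) {
  stopifnot(inherits(spec, "frap_spec"))
  withr::with_seed(spec$seed, {
    t_pre <- -rev(seq_len(spec$n_prebleach)) * spec$sample_interval
    t_post <- seq(0, spec$duration, by = spec$sample_interval)
    i0 <- 1 - spec$bleach_depth
    norm <- c(rep(1, spec$n_prebleach),
              i0 + spec$mobile_fraction * (1 - i0) *
                (1 - exp(-spec$rate_k * t_post)))
    inten <- norm * spec$prebleach_level
    if (spec$noise_sd > 0)
      inten <- inten + stats::rnorm(length(inten), 0, spec$noise_sd)
    crv <- frap_curve(times = c(t_pre, t_post), intensity = inten,
                      prebleach_level = spec$prebleach_level, background = 0)
    attr(crv, "true_params") <- list(mobile_fraction = spec$mobile_fraction,
                                     rate_k = spec$rate_k,
                                     bleach_depth = spec$bleach_depth,
                                     prebleach_level = spec$prebleach_level)
    crv
  })
}

## ---------------------------------------------------------------------------
## Kymographs

#' Specification of a synthetic kymograph of membrane puncta
#'
#' @param duration Movie duration (s).
#' @param frame_interval s per frame.
#' @param n_particles Number of puncta; each occupies its own spatial row.
#' @param mean_lifetime Mean of the exponential residence lifetime (s).
#' @param particle_intensity Intensity of a punctum above background (AU).
#' @param background Background level (AU).
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param n_rows Number of spatial rows; defaults to `max(n_particles, 16)`.
#' @param seed Integer seed.
#' @return A validated `kymograph_spec`.
#' @export
kymograph_spec <- function(duration = 90,
                           frame_interval = 0.3,
                           n_particles = 50L,
                           mean_lifetime = 8,
                           particle_intensity = 1000,
                           background = 100,
                           noise_sd = 0,
                           n_rows = NULL,
                           seed = 1L) {
  if (duration <= 0) stop("duration must be > 0")
  if (mean_lifetime <= 0) stop("mean_lifetime must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (is.null(n_rows)) n_rows <- max(n_particles, 16L)
  if (n_rows < n_particles)
    stop("n_rows must be >= n_particles (one particle per row)")
  structure(list(duration = duration, frame_interval = frame_interval,
                 n_particles = as.integer(n_particles),
                 mean_lifetime = mean_lifetime,
                 particle_intensity = particle_intensity,
                 background = background, noise_sd = noise_sd,
                 n_rows = as.integer(n_rows),
                 seed = validate_seed(seed)),
            class = "kymograph_spec")
}

#' Generate a kymograph with known residence lifetimes
#'
#' Each particle occupies one spatial row over a contiguous span of frames.
#' Nucleation frames are uniform over frames 2..n (a run starting in the first
#' frame would be indistinguishable from one predating acquisition); spans are
#' truncated at the movie end. A span touching the first or last frame is
#' flagged censored in the ground truth, matching the censoring rule of
#' [measure_lifetimes()].
#'
#' @param spec A [kymograph_spec()].
#' @return List with `kymograph` (a [kymograph()]) and `truth`, a data frame
#'   with `row`, `start_frame`, `end_frame`, `lifetime_s` (true, untruncated,
#'   frame-quantised), `observed_s` (span visible in the movie) and
#'   `censored`.
#' @export
generate_kymograph <- function(spec) {
  stopifnot(inherits(spec, "kymograph_spec"))
  withr::with_seed(spec$seed, {
    nfr <- max(2L, round(spec$duration / spec$frame_interval))
    arr <- matrix(spec$background, spec$n_rows, nfr)
    n <- spec$n_particles
    truth <- data.frame(row = integer(0), start_frame = integer(0),
                        end_frame = integer(0), lifetime_s = numeric(0),
                        observed_s = numeric(0), censored = logical(0))
    if (n > 0L) {
      rows <- sample.int(spec$n_rows, n)
      start <- sample(2:nfr, n, replace = TRUE)
      life_frames <- pmax(1L, as.integer(
        ceiling(stats::rexp(n, 1 / spec$mean_lifetime) /
                  spec$frame_interval)))
      end_true <- start + life_frames - 1L
      end_obs <- pmin(end_true, nfr)
      censored <- end_true > nfr | end_obs == nfr | start == 1L
      for (i in seq_len(n))
        arr[rows[i], start[i]:end_obs[i]] <-
          arr[rows[i], start[i]:end_obs[i]] + spec$particle_intensity
      truth <- data.frame(row = rows, start_frame = start,
                          end_frame = end_obs,
                          lifetime_s = life_frames * spec$frame_interval,
                          observed_s = (end_obs - start + 1L) *
                            spec$frame_interval,
                          censored = censored)
      truth <- truth[order(truth$row), , drop = FALSE]
      rownames(truth) <- NULL
    }
    if (spec$noise_sd > 0)
      arr[] <- pmax(arr + stats::rnorm(length(arr), 0, spec$noise_sd), 0)
    list(kymograph = kymograph(arr, frame_interval = spec$frame_interval,
                               pixel_size = 0.1),
         truth = truth)
  })
}

## ---------------------------------------------------------------------------
## Asymmetric root fields

#' Specification of a two-sided root intensity field
#'
#' Emulates the upper/lower epidermis signal of a gravistimulated root: two
#' parallel horizontal bands whose noise-free mean intensities differ by a
#' controlled fold.
#'
#' @param image_shape `c(rows, cols)` pixels.
#' @param pixel_size um per pixel.
#' @param upper_level Mean intensity of the upper band (AU).
#' @param lower_fold Lower band level = `lower_fold * upper_level`; > 0.
#' @param band_width_px Width of each band in pixels.
#' @param noise_sd Additive Gaussian noise sd (AU).
#' @param seed Integer seed.
#' @return A validated `asymmetry_field_spec`.
#' @export
asymmetry_field_spec <- function(image_shape = c(200L, 400L),
                                 pixel_size = 0.2,
                                 upper_level = 500,
                                 lower_fold = 2,
                                 band_width_px = 30L,
                                 noise_sd = 25,
                                 seed = 1L) {
  if (lower_fold <= 0) stop("lower_fold must be > 0")
  if (upper_level < 0) stop("upper_level must be >= 0")
  if (2L * band_width_px > image_shape[1])
    stop("bands do not fit the image")
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, upper_level = upper_level,
                 lower_fold = lower_fold,
                 band_width_px = as.integer(band_width_px),
                 noise_sd = noise_sd, seed = validate_seed(seed)),
            class = "asymmetry_field_spec")
}

#' Generate a two-sided root field with a known lower/upper ratio
#'
#' @param spec An [asymmetry_field_spec()].
#' @return List with `image` (a [calibrated_image()]), `true_ratio`
#'   (= `lower_fold`), and `bands`, the row ranges of the upper and lower
#'   bands.
#' @export
generate_asymmetric_root <- function(spec) {
  stopifnot(inherits(spec, "asymmetry_field_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    px <- matrix(0, nr, nc)
    w <- spec$band_width_px
    gap <- nr - 2L * w
    upper_rows <- seq_len(w) + gap %/% 3L
    lower_rows <- seq(nr - w + 1L, nr) - gap %/% 3L
    px[upper_rows, ] <- spec$upper_level
    px[lower_rows, ] <- spec$lower_fold * spec$upper_level
    if (spec$noise_sd > 0)
      px[] <- pmax(px + stats::rnorm(length(px), 0, spec$noise_sd), 0)
    list(image = calibrated_image(px, spec$pixel_size),
         true_ratio = spec$lower_fold,
         bands = list(upper_rows = upper_rows, lower_rows = lower_rows))
  })
}
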
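render_gaussian_frame <- function(centers_px, total_AU, sigma_px = 1.5,
                                  dim_px = 80, bg = 100, pixel_size = 0.1) {
  px <- matrix(bg, dim_px, dim_px)
  for (i in seq_len(nrow(centers_px))) {
    cx <- centers_px[i, 1]; cy <- centers_px[i, 2]
    px <- px + total_AU[i] *
      exp(-outer((1:dim_px - cy)^2, (1:dim_px - cx)^2, "+") /
            (2 * sigma_px^2)) / (2 * pi * sigma_px^2)
  }
  calibrated_image(px, pixel_size)
}

test_that("spot detection finds planted spots with sub-pixel accuracy", {
  blank <- calibrated_image(matrix(100, 50, 50), 0.1)
  expect_equal(nrow(detect_spots(blank, 0.15)), 0)

  one <- render_gaussian_frame(cbind(25.3, 24.7), 8000)
  sp <- detect_spots(one, expected_radius = 0.15)
  expect_equal(nrow(sp), 1)
  expect_lt(abs(sp$x_um / 0.1 + 0.5 - 25.3), 0.1)   # within 0.1 px
  expect_lt(abs(sp$y_um / 0.1 + 0.5 - 24.7), 0.1)
  expect_equal(sp$intensity_AU, 8000, tolerance = 0.01)

  # 20 spots at >= 4-radius separation: all found, none invented
  set.seed(43)
  n <- 0; cx <- numeric(0); cy <- numeric(0)
  while (n < 20) {
    x <- runif(1, 10, 140); y <- runif(1, 10, 140)
    if (n == 0 || all(sqrt((cx - x)^2 + (cy - y)^2) >= 4 * 1.5 + 1)) {
      n <- n + 1; cx[n] <- x; cy[n] <- y
    }
  }
  many <- render_gaussian_frame(cbind(cx, cy), rep(8000, 20), dim_px = 150)
  sp20 <- detect_spots(many, 0.15)
  expect_equal(nrow(sp20), 20)
  # neighbours 4 radii away pull measured centroids slightly; each planted
  # spot must still have a detection well under the spot spacing
  d <- sqrt(outer(sp20$x_um / 0.1 + 0.5, cx, "-")^2 +
              outer(sp20$y_um / 0.1 + 0.5, cy, "-")^2)
  expect_lt(max(apply(d, 2, min)), 2)
})

test_that("intensity classes follow the published boundaries", {
  expect_equal(as.character(classify_intensity(3e3)), "low")
  expect_equal(as.character(classify_intensity(12e3)), "medium")
  expect_equal(as.character(classify_intensity(20e3)), "high")
  # boundary convention: 5e3 and 15e3 are medium
  expect_equal(as.character(classify_intensity(c(5e3, 15e3))),
               c("medium", "medium"))
  expect_error(classify_intensity(-1), "non-negative")
})

test_that("greedy linking joins detections within reach and splits beyond it", {
  two_close <- data.frame(frame = c(1, 2), x_um = c(1, 1.1),
                          y_um = c(1, 1))
  lk <- link_trajectories(two_close, max_disp = 0.5)
  expect_equal(length(lk), 1)
  expect_equal(nrow(lk[[1]]), 2)

  two_far <- data.frame(frame = c(1, 2), x_um = c(1, 2), y_um = c(1, 1))
  lk2 <- link_trajectories(two_far, max_disp = 0.5)
  expect_equal(length(lk2), 2)
  expect_true(all(vapply(lk2, nrow, integer(1)) == 1))

  # gap bridging
  gap <- data.frame(frame = c(1, 3), x_um = c(1, 1.05), y_um = c(1, 1))
  expect_equal(length(link_trajectories(gap, 0.5, max_gap = 1)), 1)
  expect_equal(length(link_trajectories(gap, 0.5, max_gap = 0)), 2)
})

test_that("linking recovers ground-truth tracks on rendered low-density movies", {
  spec <- trajectory_field_spec(n_tracks = 8, D_free = 0.05, n_frames = 12,
                                localization_sd = 0, field_size = 25,
                                intensity_means = c(free = 8000,
                                                    immobile = 8000),
                                intensity_sd = 0, seed = 47)
  tracks <- generate_trajectories(spec)
  stack <- render_trajectory_stack(tracks, field_size = 25, noise_sd = 0)
  det <- do.call(rbind, lapply(seq_along(stack$frames), function(f) {
    s <- detect_spots(calibrated_image(stack$frames[[f]],
                                       stack$pixel_size), 0.15)
    if (nrow(s)) cbind(frame = f, s) else NULL
  }))
  linked <- link_trajectories(det, max_disp = 0.5,
                              frame_interval = spec$frame_interval)
  full <- Filter(function(tr) nrow(tr) == 12, linked)
  # count links that agree with the truth
  good <- 0; total <- 0
  for (tr in tracks) {
    # nearest linked track by first-frame position
    d0 <- vapply(full, function(lt)
      sqrt((lt$x_um[1] - tr$x_um[1])^2 + (lt$y_um[1] - tr$y_um[1])^2),
      numeric(1))
    if (length(d0) == 0) next
    lt <- full[[which.min(d0)]]
    match_d <- sqrt((lt$x_um - tr$x_um)^2 + (lt$y_um - tr$y_um)^2)
    good <- good + sum(match_d < 0.2)
    total <- total + length(match_d)
  }
  expect_gte(total, 0.8 * 8 * 12)
  expect_gte(good / total, 0.95)
})

test_that("MSD matches closed forms for stationary and ballistic motion", {
  dt <- 0.1
  still <- trajectory(data.frame(frame = 1:30, x_um = 1, y_um = 2), dt)
  msd0 <- compute_msd(list(still), n_lags = 10)
  expect_true(all(msd0$msd_um2 == 0))

  step <- 0.1
  ball <- trajectory(data.frame(frame = 1:30, x_um = (0:29) * step,
                                y_um = 0), dt)
  msdb <- compute_msd(list(ball), n_lags = 8)
  expect_equal(msdb$msd_um2, (step * (1:8))^2)
})

test_that("MSD is invariant under time reversal and matches brute force", {
  set.seed(53)
  xy <- apply(matrix(rnorm(2 * 40, 0, 0.1), ncol = 2), 2, cumsum)
  fwd <- trajectory(data.frame(frame = 1:40, x_um = xy[, 1],
                               y_um = xy[, 2]), 0.1)
  rev_tr <- trajectory(data.frame(frame = 1:40, x_um = rev(xy[, 1]),
                                  y_um = rev(xy[, 2])), 0.1)
  m1 <- compute_msd(list(fwd), n_lags = 12)
  m2 <- compute_msd(list(rev_tr), n_lags = 12)
  expect_equal(m1$msd_um2, m2$msd_um2)
  expect_equal(m1$msd_um2, brute_msd(1:40, xy[, 1], xy[, 2], 12))
})

test_that("diffusion fitting is exact on analytic MSD lines", {
  dt <- 0.1
  lags <- (1:10) * dt
  line <- structure(list(lags_s = lags, msd_um2 = 4 * 0.025 * lags,
                         se_um2 = rep(0, 10), n_tracks = rep(100L, 10),
                         frame_interval = dt), class = "msd_curve")
  est <- fit_diffusion(line)
  expect_equal(est$D, 0.025)
  expect_equal(est$intercept, 0, tolerance = 1e-12)

  offset <- line
  offset$msd_um2 <- 4 * 0.025 * lags + 4 * 0.02^2
  est2 <- fit_diffusion(offset)
  expect_equal(est2$D, 0.025)
  expect_equal(est2$intercept, 0.0016)

  neg <- line
  neg$msd_um2 <- 0.01 - 0.001 * lags
  est3 <- fit_diffusion(neg)
  expect_equal(est3$D, 0)
  expect_true(est3$clipped)
})

test_that("ensemble diffusion recovery from simulated Brownian motion", {
  tracks <- generate_trajectories(trajectory_field_spec(
    n_tracks = 500, n_frames = 60, frame_interval = 0.1, D_free = 0.05,
    immobile_fraction = 0, localization_sd = 0.02, seed = 59))
  est <- fit_diffusion(compute_msd(tracks, n_lags = 10))
  expect_lt(abs(est$D - 0.05) / 0.05, 0.10)
})

test_that("diffusion histograms are normalised and separate two populations", {
  single <- diffusion_distribution(0.05)
  expect_equal(sum(single$frequency), 1)
  ident <- diffusion_distribution(rep(0.02, 5))
  expect_equal(max(ident$frequency), 1)

  spec <- trajectory_field_spec(n_tracks = 120, immobile_fraction = 0.5,
                                D_free = 0.08, localization_sd = 0.01,
                                seed = 61)
  tracks <- generate_trajectories(spec)
  D <- vapply(tracks, function(tr)
    fit_diffusion(compute_msd(list(tr), n_lags = 6))$D, numeric(1))
  h <- diffusion_distribution(D, breaks = seq(0, 0.2, by = 0.02))
  expect_equal(sum(h$frequency), 1)
  # bimodal: mass near 0 (immobile) and around D_free
  expect_gt(h$frequency[1], 0.25)
  expect_gt(sum(h$frequency[h$bin_low >= 0.04 & h$bin_low < 0.14]), 0.25)
})

test_that("bright immobile particles fit slower than dim mobile ones", {
  spec <- trajectory_field_spec(n_tracks = 100, immobile_fraction = 0.4,
                                D_free = 0.08, localization_sd = 0.01,
                                intensity_means = c(free = 3000,
                                                    immobile = 20000),
                                intensity_sd = 300, seed = 67)
  tracks <- generate_trajectories(spec)
  D <- vapply(tracks, function(tr)
    fit_diffusion(compute_msd(list(tr), n_lags = 6))$D, numeric(1))
  cls <- classify_intensity(vapply(tracks, function(tr)
    mean(tr$intensity_AU), numeric(1)))
  expect_lt(mean(D[cls == "high"]), mean(D[cls == "low"]))
})
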
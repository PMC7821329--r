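test_that("FRAP normalisation maps plateau to 1 and background to 0", {
  tt <- seq(-2, 30, by = 0.5)
  flat <- frap_curve(tt, rep(800, length(tt)), prebleach_level = 800,
                     background = 50)
  norm <- normalize_frap(flat)
  expect_true(all(abs(norm$intensity - 1) < 1e-12))

  at_bg <- frap_curve(tt, rep(50, length(tt)), prebleach_level = 800,
                      background = 50)
  expect_true(all(normalize_frap(at_bg)$intensity == 0))

  # idempotent on already-normalised curves
  spec <- frap_spec(mobile_fraction = 0.6, rate_k = 0.3, noise_sd = 0)
  crv <- normalize_frap(generate_frap_curve(spec))
  again <- normalize_frap(crv)
  expect_equal(again$intensity, crv$intensity)

  # normalised bleach depth equals the spec's bleach_depth
  post0 <- crv$intensity[crv$times == 0]
  expect_equal(1 - post0, spec$bleach_depth, tolerance = 1e-12)

  bad <- frap_curve(tt, rep(50, length(tt)), prebleach_level = 40,
                    background = 50)
  expect_error(normalize_frap(bad), "background")
})

test_that("FRAP fit recovers boundary and planted parameter cases", {
  full <- generate_frap_curve(frap_spec(mobile_fraction = 1, rate_k = 0.4,
                                        noise_sd = 0))
  fit_full <- fit_frap(normalize_frap(full))
  expect_equal(fit_full$mobile_fraction, 1, tolerance = 1e-3)

  none <- generate_frap_curve(frap_spec(mobile_fraction = 0, noise_sd = 0))
  fit_none <- fit_frap(normalize_frap(none))
  expect_equal(fit_none$mobile_fraction, 0)

  crv <- generate_frap_curve(frap_spec(mobile_fraction = 0.7, rate_k = 0.2,
                                       noise_sd = 0))
  fit <- fit_frap(normalize_frap(crv))
  expect_lt(abs(fit$mobile_fraction - 0.7) / 0.7, 0.01)
  expect_lt(abs(fit$rate_k - 0.2) / 0.2, 0.01)
  expect_equal(fit$mobile_fraction + fit$stable_fraction, 1)

  short <- frap_curve(c(-1, seq(0, 3, by = 0.5)),
                      c(1, rep(0.5, 7)))
  expect_error(fit_frap(short), ">= 8")
})

test_that("FRAP recovery holds over a (mobile, k) grid, noise-free and noisy", {
  grid <- expand.grid(mobile = c(0.2, 0.5, 0.9), k = c(0.05, 0.2, 0.5))
  err_m <- err_k <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    m <- grid$mobile[i]; k <- grid$k[i]
    crv <- generate_frap_curve(frap_spec(mobile_fraction = m, rate_k = k,
                                         duration = 100,
                                         sample_interval = 0.25,
                                         noise_sd = 0, seed = 71 + i))
    fit <- fit_frap(normalize_frap(crv))
    expect_lt(abs(fit$mobile_fraction - m) / m, 0.01)
    expect_lt(abs(fit$rate_k - k) / k, 0.01)
    expect_equal(fit$mobile_fraction + fit$stable_fraction, 1)

    # noisy recovery is assessed on the mean of replicate cells, as FRAP
    # parameters are estimated in practice (per-trace noise 5% of plateau)
    reps <- lapply(1:20, function(r) generate_frap_curve(frap_spec(
      mobile_fraction = m, rate_k = k, duration = 100,
      sample_interval = 0.25, prebleach_level = 1000, noise_sd = 50,
      seed = 171 + 40 * i + r)))
    nfit <- fit_frap(normalize_frap(average_frap_curves(reps)))
    err_m[i] <- (nfit$mobile_fraction - m) / m
    err_k[i] <- (nfit$rate_k - k) / k
  }
  # grid-wide root-mean-square recovery error under noise
  expect_lt(sqrt(mean(err_m^2)), 0.05)
  expect_lt(sqrt(mean(err_k^2)), 0.05)
})

test_that("averaging replicate FRAP curves preserves the time base", {
  reps <- lapply(1:4, function(r) generate_frap_curve(frap_spec(
    noise_sd = 30, seed = r)))
  avg <- average_frap_curves(reps)
  expect_equal(avg$times, reps[[1]]$times)
  expect_equal(avg$intensity,
               rowMeans(sapply(reps, `[[`, "intensity")))
  short <- generate_frap_curve(frap_spec(duration = 30, seed = 1))
  expect_error(average_frap_curves(list(reps[[1]], short)), "time base")
})

test_that("kymograph extraction reproduces simple and generated patterns", {
  const_stack <- image_stack(replicate(10, matrix(42, 30, 30),
                                       simplify = FALSE),
                             pixel_size = 0.1, frame_interval = 0.3)
  line <- rbind(c(0.5, 1.5), c(2.5, 1.5))
  kymo <- extract_kymograph(const_stack, line)
  expect_true(all(kymo$array == 42))
  expect_equal(ncol(kymo$array), 10)

  # a static bright spot on the line -> one continuous horizontal streak
  frames <- replicate(10, matrix(0, 30, 30), simplify = FALSE)
  for (f in seq_along(frames)) frames[[f]][15, 10] <- 500
  spot_stack <- image_stack(frames, pixel_size = 0.1, frame_interval = 0.3)
  kline <- rbind(c(0.05, 1.45), c(2.95, 1.45))
  kymo2 <- extract_kymograph(spot_stack, kline)
  hits <- which(kymo2$array > 250, arr.ind = TRUE)
  expect_equal(sort(unique(hits[, 2])), 1:10)        # present in every frame
  expect_equal(length(unique(hits[, 1])), 1)         # a single row

  expect_error(extract_kymograph(const_stack,
                                 rbind(c(-1, 1), c(5, 1))), "bounds")
})

test_that("generated kymographs round-trip through a rendered stack", {
  spec <- kymograph_spec(n_particles = 6, n_rows = 12, noise_sd = 0,
                         seed = 73)
  sim <- generate_kymograph(spec)
  arr <- sim$kymograph$array
  stack <- image_stack(lapply(seq_len(ncol(arr)), function(f)
    matrix(arr[, f], nrow(arr), 25)), pixel_size = 0.1,
    frame_interval = spec$frame_interval)
  line <- rbind(c(1.25, 0.05), c(1.25, (nrow(arr) - 0.5) * 0.1))
  kymo <- extract_kymograph(stack, line)
  expect_equal(dim(kymo$array), dim(arr))
  expect_lt(max(abs(kymo$array - arr)), 1e-9)
})

test_that("lifetimes are measured with the inclusive frame-count convention", {
  arr <- matrix(0, 3, 80)
  arr[2, 1:70] <- 1000                    # 70 frames from the movie start
  kymo <- kymograph(arr, frame_interval = 0.3, pixel_size = 0.1)
  rec <- measure_lifetimes(kymo, intensity_threshold = 500)
  expect_equal(rec$duration_s, 70 * 0.3)  # 21 s
  expect_true(rec$censored)               # touches the first frame

  arr2 <- matrix(0, 2, 50)
  arr2[1, 10:29] <- 1000                  # interior run: 20 frames
  arr2[2, 40:50] <- 1000                  # alive at movie end
  kymo2 <- kymograph(arr2, frame_interval = 0.3, pixel_size = 0.1)
  rec2 <- measure_lifetimes(kymo2, 500)
  expect_equal(rec2$duration_s[1], 6)
  expect_false(rec2$censored[1])
  expect_true(rec2$censored[2])

  # runs in one row split at a single sub-threshold frame
  arr3 <- matrix(0, 1, 30)
  arr3[1, c(5:10, 12:20)] <- 1000
  rec3 <- measure_lifetimes(kymograph(arr3, 0.3, 0.1), 500)
  expect_equal(nrow(rec3), 2)
  expect_equal(rec3$duration_s, c(6, 9) * 0.3)
})

test_that("supra-threshold frames are conserved between kymograph and records", {
  spec <- kymograph_spec(n_particles = 40, n_rows = 40, noise_sd = 0,
                         seed = 79)
  sim <- generate_kymograph(spec)
  thr <- spec$background + spec$particle_intensity / 2
  rec <- measure_lifetimes(sim$kymograph, thr)
  expect_equal(sum(rec$end_frame - rec$start_frame + 1),
               sum(sim$kymograph$array > thr))
  # all durations are integer multiples of the frame interval
  mult <- rec$duration_s / sim$kymograph$frame_interval
  expect_equal(mult, round(mult))
})

test_that("lifetime summaries respect the censoring policy", {
  rec <- data.frame(row = 1:3, start_frame = 1, end_frame = 2,
                    duration_s = c(3, 5, 7), censored = FALSE)
  expect_equal(summarize_lifetimes(rec)$mean_s, 5)

  rec2 <- rbind(rec, data.frame(row = 4, start_frame = 1, end_frame = 2,
                                duration_s = 99, censored = TRUE))
  s2 <- summarize_lifetimes(rec2)
  expect_equal(s2$mean_s, 5)
  expect_equal(s2$n_censored, 1)
  expect_error(summarize_lifetimes(rec2[4, ]), "uncensored")

  # exponential sampling theory: n = 500 at mean 10 s within 2 SE
  set.seed(83)
  d <- rexp(500, 1 / 10)
  rec3 <- data.frame(row = seq_along(d), start_frame = 1, end_frame = 2,
                     duration_s = d, censored = FALSE)
  s3 <- summarize_lifetimes(rec3)
  expect_lt(abs(s3$mean_s - 10), 2 * 10 / sqrt(500))
})
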
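make_square_image <- function(side = 10, value = 1000, bg = 0,
                              dim_px = 40, pixel_size = 0.05) {
  px <- matrix(bg, dim_px, dim_px)
  px[11:(10 + side), 11:(10 + side)] <- value
  calibrated_image(px, pixel_size)
}

test_that("segmentation recovers simple geometry and rejects degenerate input", {
  img <- make_square_image()
  mask <- segment_membrane(img)
  expect_equal(sum(mask), 100)
  expect_true(attr(mask, "threshold") > 0 && attr(mask, "threshold") < 1000)

  blank <- calibrated_image(matrix(5, 20, 20), 0.05)
  expect_error(segment_membrane(blank), "constant")
  # blank image with a fixed threshold above background -> empty mask
  expect_equal(sum(segment_membrane(blank, method = "fixed",
                                    threshold = 10)), 0)
})

test_that("segmentation covers planted above-threshold pixels on noise-free fields", {
  spec <- cluster_field_spec(n_clusters = 40, noise_gaussian_sd = 0,
                             seed = 13)
  sim <- generate_cluster_image(spec)
  mask <- segment_membrane(sim$image)
  halfmax <- spec$background_intensity + spec$cluster_peak_intensity / 2
  planted <- sim$image$pixels >= halfmax
  expect_gte(sum(mask & planted) / sum(planted), 0.95)
})

test_that("detect_clusters measures areas and centroids in physical units", {
  img <- make_square_image()
  rec <- detect_clusters(img, segment_membrane(img))
  expect_equal(nrow(rec), 1)
  # 0.25 um^2; the subpixel half-max boundary rounds the square's corners
  # slightly under bilinear interpolation
  expect_equal(rec$area_um2, 100 * 0.05^2, tolerance = 0.005)
  expect_equal(rec$size_class, "small")
  expect_equal(rec$centroid_x_um, (mean(11:20) - 0.5) * 0.05)

  empty <- detect_clusters(img, matrix(FALSE, 40, 40))
  expect_equal(nrow(empty), 0)
})

test_that("detected areas track planted areas on a noise-free field", {
  spec <- cluster_field_spec(n_clusters = 50, noise_gaussian_sd = 0,
                             seed = 17)
  sim <- generate_cluster_image(spec)
  rec <- detect_clusters(sim$image, segment_membrane(sim$image))
  expect_equal(nrow(rec), 50)
  d <- sqrt(outer(sim$truth$x_um, rec$centroid_x_um, "-")^2 +
              outer(sim$truth$y_um, rec$centroid_y_um, "-")^2)
  nn <- apply(d, 1, which.min)
  relerr <- abs(rec$area_um2[nn] - sim$truth$area_um2) / sim$truth$area_um2
  expect_true(all(relerr <= 0.15))
})

test_that("size classification follows the four left-closed bins", {
  expect_equal(as.character(classify_cluster_size(0.1)), "tiny")
  expect_equal(as.character(classify_cluster_size(0.5)), "small")
  expect_equal(as.character(classify_cluster_size(1.5)), "long")
  # boundary convention: left-closed, right-open
  expect_equal(as.character(classify_cluster_size(c(0.2, 0.6, 1.0))),
               c("small", "medium", "long"))
  expect_equal(as.character(classify_cluster_size(0.2 - 1e-9)), "tiny")
  expect_error(classify_cluster_size(0), "positive")
  expect_error(classify_cluster_size(-1), "positive")
  # monotone step function of area
  areas <- sort(runif(50, 0.01, 2))
  codes <- as.integer(classify_cluster_size(areas))
  expect_true(all(diff(codes) >= 0))
})

test_that("size_distribution returns consistent counts and frequencies", {
  rec <- data.frame(size_class = rep("long", 10))
  sd1 <- size_distribution(rec)
  expect_equal(unname(sd1$frequencies["long"]), 1)
  expect_equal(sd1$n_total, 10)

  rec4 <- data.frame(size_class = cluster_size_levels())
  sd4 <- size_distribution(rec4)
  expect_equal(unname(sd4$frequencies), rep(0.25, 4))
  expect_equal(sum(sd4$frequencies), 1)

  sd0 <- size_distribution(data.frame(size_class = character(0)))
  expect_false(sd0$defined)
  expect_true(all(is.na(sd0$frequencies)))
})

test_that("cluster spacing equals the brute-force all-pairs computation", {
  two <- data.frame(centroid_x_um = c(0, 1), centroid_y_um = c(0, 0))
  expect_equal(cluster_spacing(two)$mean_um, 1)

  # regular grid with pitch p
  g <- expand.grid(x = (0:4) * 0.7, y = (0:4) * 0.7)
  grid_rec <- data.frame(centroid_x_um = g$x, centroid_y_um = g$y)
  expect_equal(cluster_spacing(grid_rec)$mean_um, 0.7)

  set.seed(31)
  rnd <- data.frame(centroid_x_um = runif(40, 0, 10),
                    centroid_y_um = runif(40, 0, 10))
  expect_equal(cluster_spacing(rnd)$nn_dist_um,
               brute_nn_distances(rnd$centroid_x_um, rnd$centroid_y_um))
  expect_error(cluster_spacing(two[1, , drop = FALSE]), "at least 2")
})

test_that("clustering index is a scale-invariant dispersion measure", {
  expect_equal(clustering_index(rep(5, 100))$index, 0)
  # equal halves at 0 and 2 AU: mean 1, sd 1 -> CV 1 (population sd differs
  # from sample sd by sqrt(n/(n-1)); use a large n and tolerance)
  x <- rep(c(0, 2), each = 5000)
  expect_equal(clustering_index(x)$index, 1, tolerance = 1e-3)
  # rescaling invariance
  set.seed(7); y <- rgamma(500, 2, 1)
  expect_equal(clustering_index(y)$index, clustering_index(17.3 * y)$index)
  expect_error(clustering_index(rep(0, 10)), "zero mean")
  expect_error(clustering_index(5), ">= 2")
})

test_that("clustered fields score a higher index than uniform fields", {
  spec_c <- cluster_field_spec(n_clusters = 80, noise_gaussian_sd = 10,
                               seed = 19)
  sim_c <- generate_cluster_image(spec_c)
  uniform <- withr::with_seed(19, {
    m <- mean(sim_c$image$pixels)
    calibrated_image(pmax(matrix(rnorm(512 * 512, m, 10), 512, 512), 0),
                     0.05)
  })
  idx_c <- clustering_index(as.vector(sim_c$image$pixels))$index
  idx_u <- clustering_index(as.vector(uniform$pixels))$index
  expect_gt(idx_c, idx_u)
})

test_that("outside_confidence behaves at its null, centre and extremes", {
  set.seed(23)
  mock <- rlnorm(10000, 0, 0.5)
  # treated at the mock median -> 0%
  res0 <- outside_confidence(rep(median(mock), 100), mock)
  expect_equal(res0$percentage, 0)
  # treated far above the interval -> 100%
  shifted <- mock + 10 * sd(mock)
  expect_equal(outside_confidence(shifted, mock)$percentage, 100)
  # null draw -> close to the 5% baseline
  treated <- rlnorm(10000, 0, 0.5)
  resn <- outside_confidence(treated, mock)
  expect_lt(abs(resn$percentage - 5), 1.5)
  expect_lt(resn$interval[1], resn$interval[2])
  expect_error(outside_confidence(treated, mock[1:10]), "40")
})

test_that("colocalisation statistics hit their analytic anchors", {
  set.seed(29)
  pxA <- matrix(rgamma(64 * 64, 2, 0.01), 64, 64)
  imgA <- calibrated_image(pxA, 0.05)
  maskA <- pxA > median(pxA)
  same <- colocalise(imgA, imgA, maskA, maskA)
  expect_equal(same$pearson_r, 1)

  # identical convex clusters: every centroid falls in its own cluster
  blobs <- generate_cluster_image(cluster_field_spec(
    n_clusters = 25, noise_gaussian_sd = 0, seed = 29))
  bmask <- segment_membrane(blobs$image)
  self <- colocalise(blobs$image, blobs$image, bmask, bmask)
  expect_equal(self$object_overlap_fraction, 1)

  # disjoint masks -> zero object overlap
  maskL <- maskR <- matrix(FALSE, 64, 64)
  maskL[, 1:30] <- maskA[, 1:30]
  maskR[, 35:64] <- maskA[, 35:64]
  disj <- colocalise(imgA, imgA, maskL, maskR)
  expect_equal(disj$object_overlap_fraction, 0)

  # independent noise -> r near 0 within a few / sqrt(n)
  pxB <- matrix(rgamma(64 * 64, 2, 0.01), 64, 64)
  indep <- colocalise(imgA, calibrated_image(pxB, 0.05),
                      matrix(TRUE, 64, 64), matrix(TRUE, 64, 64))
  expect_lt(abs(indep$pearson_r), 3 / sqrt(64 * 64))
  expect_error(colocalise(imgA, calibrated_image(pxB[1:32, ], 0.05),
                          maskA, maskA[1:32, ]), "shape")
})

test_that("area conservation holds under the threshold area policy", {
  spec <- cluster_field_spec(n_clusters = 30, seed = 37)
  sim <- generate_cluster_image(spec)
  mask <- segment_membrane(sim$image)
  rec <- detect_clusters(sim$image, mask, area_policy = "threshold")
  expect_equal(sum(rec$area_um2), sum(mask) * sim$image$pixel_size^2)
})

test_that("8-connected labelling matches the flood-fill oracle", {
  set.seed(41)
  for (dens in c(0.2, 0.4, 0.6)) {
    mask <- matrix(runif(64 * 64) < dens, 64, 64)
    ours <- memclust:::label_components8(mask)
    oracle <- flood_fill_label8(mask)
    expect_identical(canonical_labels(ours), canonical_labels(oracle))
  }
})
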
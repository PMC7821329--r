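#' Membrane cluster detection and condensation statistics
#'
#' Operations for quantifying the lateral condensation of a membrane protein
#' signal into discrete islands: segmentation, connected-component cluster
#' detection, the four-bin size classification, size-class frequency tables,
#' nearest-neighbour spacing, a per-cell clustering (dispersion) index, the
#' outside-95%-confidence statistic against a mock group, and colocalisation.
#'
#' @name cluster_quant
NULL

#' Segment membrane signal from background
#'
#' Default policy is an Otsu bimodal split of the intensity histogram,
#' computed per image so no hand-tuned cutoff is needed; the chosen threshold
#' is attached to the returned mask for auditability.
#'
#' @param image A [calibrated_image()].
#' @param method `"otsu"` (default), `"quantile"` (threshold at
#'   `probs` quantile) or `"fixed"` (threshold given in `threshold`).
#' @param threshold Fixed threshold (AU), for `method = "fixed"`.
#' @param probs Quantile for `method = "quantile"` (default 0.5).
#' @return Logical matrix of membrane pixels with attributes `threshold`
#'   (AU) and `method`.
#' @export
segment_membrane <- function(image, method = c("otsu", "quantile", "fixed"),
                             threshold = NULL, probs = 0.5) {
  stopifnot(inherits(image, "calibrated_image"))
  method <- match.arg(method)
  px <- image$pixels
  rng <- range(px)
  if (method != "fixed" && diff(rng) == 0)
    stop("degenerate input: constant image, no threshold can be computed")
  thr <- switch(method,
    otsu = {
      scaled <- (px - rng[1]) / diff(rng)
      rng[1] + diff(rng) *
        EBImage::otsu(EBImage::Image(scaled), range = c(0, 1))
    },
    quantile = stats::quantile(px, probs, names = FALSE),
    fixed = {
      if (is.null(threshold)) stop("method 'fixed' requires `threshold`")
      threshold
    })
  mask <- px > thr
  attr(mask, "threshold") <- as.numeric(thr)
  attr(mask, "method") <- method
  mask
}

#' Detect clusters as connected components
#'
#' Labels the mask with 8-connectivity and returns one record per component:
#' area in um^2, geometric centroid in um, mean and total intensity, and the
#' four-bin size class.
#'
#' Two area policies are available. `"halfmax"` (default) measures each
#' cluster's area at its full-width-at-half-maximum: the area of the region
#' at or above `background + (peak - background) / 2`, with the background
#' estimated as the median intensity outside the mask. The super-level region
#' is measured on an 8x bilinearly upsampled grid over the cluster's bounding
#' box, so the area is not quantised to whole pixels (whole-pixel counting
#' misestimates small clusters by up to the half-perimeter in pixels). This
#' makes the area independent of where the global segmentation threshold
#' happens to fall on the cluster's intensity profile. `"threshold"` counts
#' every masked pixel of the component, so that record areas sum exactly to
#' `masked pixel count * pixel_size^2`.
#'
#' @param image A [calibrated_image()].
#' @param mask Logical membrane mask from [segment_membrane()].
#' @param min_pixels Minimum component size in pixels (default 1).
#' @param area_policy `"halfmax"` (default) or `"threshold"`, see Details.
#' @return Data frame with columns `label`, `area_um2`, `centroid_x_um`,
#'   `centroid_y_um`, `mean_intensity`, `total_intensity`, `size_class`;
#'   empty mask yields a zero-row frame.
#' @export
detect_clusters <- function(image, mask, min_pixels = 1L,
                            area_policy = c("halfmax", "threshold")) {
  stopifnot(inherits(image, "calibrated_image"))
  stopifnot(identical(dim(mask), dim(image$pixels)))
  area_policy <- match.arg(area_policy)
  ps <- image$pixel_size
  lab <- label_components8(mask)
  empty <- data.frame(label = integer(0), area_um2 = numeric(0),
                      centroid_x_um = numeric(0), centroid_y_um = numeric(0),
                      mean_intensity = numeric(0),
                      total_intensity = numeric(0),
                      size_class = character(0), stringsAsFactors = FALSE)
  if (max(lab) == 0L) return(empty)
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  inten <- image$pixels[idx]
  npix <- as.vector(table(l))
  keep <- npix >= min_pixels
  sum_r <- rowsum(as.numeric(rows), l)[, 1]
  sum_c <- rowsum(as.numeric(cols), l)[, 1]
  sum_i <- rowsum(inten, l)[, 1]
  ids <- sort(unique(l))
  area_px <- if (area_policy == "halfmax") {
    bg <- if (all(mask)) 0 else stats::median(image$pixels[!mask])
    peak <- vapply(split(inten, l), max, numeric(1))
    halfmax <- bg + (peak - bg) / 2
    px_img <- image$pixels
    nr <- nrow(px_img); nc <- ncol(px_img)
    sub <- 1 / 8   # subpixel sampling step
    vapply(seq_along(ids), function(k) {
      sel <- l == ids[k]
      r0 <- max(1, min(rows[sel]) - 1L); r1 <- min(nr, max(rows[sel]) + 1L)
      c0 <- max(1, min(cols[sel]) - 1L); c1 <- min(nc, max(cols[sel]) + 1L)
      # midpoint rule over subcells spanning the bounding box (+half-pixel
      # rim), so axis-aligned half-max boundaries are not double-counted
      gr <- seq(r0 - 0.5 + sub / 2, r1 + 0.5 - sub / 2, by = sub)
      gc <- seq(c0 - 0.5 + sub / 2, c1 + 0.5 - sub / 2, by = sub)
      gg_r <- rep(gr, times = length(gc))
      gg_c <- rep(gc, each = length(gr))
      vals <- interp_bilinear(px_img, gg_c, gg_r)
      # attribute subpixels to this component via the nearest pixel's label
      own <- lab[cbind(round(gg_r), round(gg_c))]
      sum(vals >= halfmax[k] & (own == ids[k] | own == 0L)) * sub^2
    }, numeric(1))
  } else npix
  out <- data.frame(label = ids,
                    area_um2 = area_px * ps^2,
                    centroid_x_um = px_to_um(sum_c / npix, ps),
                    centroid_y_um = px_to_um(sum_r / npix, ps),
                    mean_intensity = sum_i / npix,
                    total_intensity = sum_i,
                    stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]
  out$size_class <- as.character(classify_cluster_size(out$area_um2))
  rownames(out) <- NULL
  out
}

#' Classify cluster area into the four island size classes
#'
#' Bins (left-closed, right-open): tiny `(0, 0.2)`, small `[0.2, 0.6)`,
#' medium `[0.6, 1)`, long `[1, Inf)` um^2.
#'
#' @param area Numeric vector of areas (um^2), all > 0.
#' @return Factor with levels `tiny`, `small`, `medium`, `long`.
#' @export
classify_cluster_size <- function(area) {
  if (length(area) == 0L)
    return(factor(character(0), levels = cluster_size_levels()))
  if (any(!is.finite(area)) || any(area <= 0))
    stop("cluster areas must be positive and finite")
  cut(area, breaks = c(0, 0.2, 0.6, 1, Inf), right = FALSE,
      labels = cluster_size_levels())
}

#' @rdname classify_cluster_size
#' @export
cluster_size_levels <- function() c("tiny", "small", "medium", "long")

#' Size-class frequency distribution
#'
#' @param records Cluster records from [detect_clusters()] (or any data frame
#'   with a `size_class` column).
#' @return A `cluster_size_distribution`: list with `counts` and `frequencies`
#'   (named by class) and `n_total`. For empty input the frequencies are `NA`
#'   and `defined` is `FALSE`.
#' @export
size_distribution <- function(records) {
  cls <- factor(records$size_class, levels = cluster_size_levels())
  counts <- table(cls)
  n <- sum(counts)
  freq <- if (n > 0) as.numeric(counts) / n else rep(NA_real_, length(counts))
  structure(list(counts = stats::setNames(as.integer(counts), names(counts)),
                 frequencies = stats::setNames(freq, names(counts)),
                 n_total = as.integer(n), defined = n > 0),
            class = "cluster_size_distribution")
}

#' @export
print.cluster_size_distribution <- function(x, ...) {
  cat(sprintf("<cluster_size_distribution> n = %d\n", x$n_total))
  print(rbind(count = x$counts, frequency = round(x$frequencies, 3)))
  invisible(x)
}

#' Nearest-neighbour spacing between clusters
#'
#' @param records Cluster records with `centroid_x_um`, `centroid_y_um`
#'   (>= 2 rows).
#' @return List with `nn_dist_um` (per-cluster nearest-neighbour centroid
#'   distance) and `mean_um`.
#' @export
cluster_spacing <- function(records) {
  if (nrow(records) < 2L)
    stop("cluster_spacing requires at least 2 clusters")
  d <- as.matrix(stats::dist(records[, c("centroid_x_um", "centroid_y_um")]))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  list(nn_dist_um = as.numeric(nn), mean_um = mean(nn))
}

#' Per-cell clustering index
#'
#' A dispersion statistic of the membrane-pixel intensities of one cell: a
#' more condensed (hyperclustered) signal concentrates intensity into fewer
#' pixels and widens the intensity distribution, raising the index, while a
#' uniform membrane gives 0. The default estimator is the coefficient of
#' variation (sd/mean), which is invariant to uniform intensity rescaling;
#' Gini and variance/mean (index-of-dispersion) estimators are selectable.
#'
#' @param membrane_intensities Numeric vector of membrane-pixel intensities
#'   (AU) for one cell; length >= 2, mean > 0.
#' @param estimator `"cv"` (default), `"gini"` or `"dispersion"`.
#' @return A `clustering_index_result`: list with `index`, `n_pixels`,
#'   `estimator`.
#' @export
clustering_index <- function(membrane_intensities,
                             estimator = c("cv", "gini", "dispersion")) {
  estimator <- match.arg(estimator)
  x <- as.numeric(membrane_intensities)
  if (length(x) < 2L) stop("clustering_index requires >= 2 pixels")
  if (anyNA(x) || any(x < 0)) stop("intensities must be non-negative")
  m <- mean(x)
  if (m <= 0) stop("zero mean intensity: clustering index undefined")
  idx <- switch(estimator,
    cv = stats::sd(x) / m,
    gini = mean(abs(outer(x, x, "-"))) / (2 * m),
    dispersion = stats::var(x) / m)
  structure(list(index = idx, n_pixels = length(x), estimator = estimator),
            class = "clustering_index_result")
}

#' Percentage of treated values outside the mock 95% confidence interval
#'
#' The mock interval is by default the empirical 2.5-97.5 percentile range of
#' the pooled mock values (intensity distributions are typically skewed, so a
#' value interval rather than mean +/- 1.96 sd); under the null where treated
#' values follow the mock distribution the statistic sits at the 5% baseline.
#'
#' @param treated Numeric vector of treated-sample values (AU).
#' @param mock Numeric vector of mock-group values (AU); length >= 40 so the
#'   empirical 2.5/97.5 percentiles are defined.
#' @param level Confidence level (default 0.95).
#' @param method `"percentile"` (default, empirical interval) or
#'   `"parametric"` (mean +/- z sd).
#' @return An `outside_confidence_result`: list with `percentage` (0-100),
#'   `interval` (low, high in AU), `n_mock`, `n_treated`, `level`, `method`.
#' @export
outside_confidence <- function(treated, mock, level = 0.95,
                               method = c("percentile", "parametric")) {
  method <- match.arg(method)
  min_mock <- 40L
  if (length(mock) < min_mock)
    stop(sprintf("mock sample too small: need >= %d values to define the %g%% interval",
                 min_mock, 100 * level))
  if (length(treated) < 1L) stop("treated sample is empty")
  a <- (1 - level) / 2
  int <- switch(method,
    percentile = stats::quantile(mock, c(a, 1 - a), names = FALSE),
    parametric = mean(mock) + stats::qnorm(c(a, 1 - a)) * stats::sd(mock))
  pct <- 100 * mean(treated < int[1] | treated > int[2])
  structure(list(percentage = pct,
                 interval = c(low = int[1], high = int[2]),
                 n_mock = length(mock), n_treated = length(treated),
                 level = level, method = method),
            class = "outside_confidence_result")
}

#' @export
print.outside_confidence_result <- function(x, ...) {
  cat(sprintf("<outside_confidence> %.2f%% of %d treated values outside [%.4g, %.4g] AU (mock n = %d)\n",
              x$percentage, x$n_treated, x$interval[1], x$interval[2],
              x$n_mock))
  invisible(x)
}

#' Colocalisation of two channels
#'
#' Pearson correlation of the two channels over the union of the masks, plus
#' an object-based overlap: the fraction of clusters in channel A whose
#' centroid falls inside the channel-B mask.
#'
#' @param imageA,imageB [calibrated_image()]s with identical shape and
#'   calibration.
#' @param maskA,maskB Logical masks for the two channels.
#' @return A `colocalisation_result`: list with `pearson_r` and
#'   `object_overlap_fraction`.
#' @export
colocalise <- function(imageA, imageB, maskA, maskB) {
  stopifnot(inherits(imageA, "calibrated_image"),
            inherits(imageB, "calibrated_image"))
  if (!identical(dim(imageA$pixels), dim(imageB$pixels)))
    stop("images must have identical shapes")
  if (!isTRUE(all.equal(imageA$pixel_size, imageB$pixel_size)))
    stop("images must share the same calibration")
  stopifnot(identical(dim(maskA), dim(imageA$pixels)),
            identical(dim(maskB), dim(imageB$pixels)))
  un <- maskA | maskB
  r <- if (sum(un) >= 2L) {
    a <- imageA$pixels[un]; b <- imageB$pixels[un]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
    else stats::cor(a, b)
  } else NA_real_
  recA <- detect_clusters(imageA, maskA)
  overlap <- if (nrow(recA) == 0L) NA_real_ else {
    cpx <- round(um_to_px(recA$centroid_x_um, imageA$pixel_size))
    rpx <- round(um_to_px(recA$centroid_y_um, imageA$pixel_size))
    cpx <- pmin(pmax(cpx, 1L), ncol(maskB))
    rpx <- pmin(pmax(rpx, 1L), nrow(maskB))
    mean(maskB[cbind(rpx, cpx)])
  }
  structure(list(pearson_r = r, object_overlap_fraction = overlap),
            class = "colocalisation_result")
}
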
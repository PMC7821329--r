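#' Image I/O and reproducible pipeline execution
#'
#' TIFF reading/writing with attached physical calibration, CSV/JSON table
#' output with unit-bearing column names, and a YAML-configured pipeline
#' runner that records a manifest sufficient to re-execute deterministic
#' stages bit-identically.
#'
#' @name io
NULL

#' Load a calibrated TIFF image or stack
#'
#' Intensities are read as stored integer counts (1 AU = 1 count); a
#' single-page file yields a [calibrated_image()], a multi-page file an
#' [image_stack()] (which requires `frame_interval`).
#'
#' @param path TIFF file path.
#' @param pixel_size um per pixel; TIFF files carry no reliable physical
#'   calibration here, so it must be supplied.
#' @param frame_interval s per frame, required for multi-page files.
#' @return A `calibrated_image` or `image_stack`.
#' @export
load_image <- function(path, pixel_size, frame_interval = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(pixel_size) || is.null(pixel_size))
    stop("missing calibration: `pixel_size` (um/pixel) is required")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  pages <- lapply(pages, function(p) {
    m <- as.matrix(p)
    storage.mode(m) <- "double"
    m
  })
  if (length(pages) == 1L)
    return(calibrated_image(pages[[1]], pixel_size))
  if (is.null(frame_interval))
    stop("multi-page TIFF: `frame_interval` (s) is required")
  image_stack(pages, pixel_size = pixel_size,
              frame_interval = frame_interval)
}

#' Write a calibrated image or stack as 16-bit TIFF
#'
#' Values are stored as integer counts (1 AU = 1 count), clamped to
#' `[0, 65535]`; integer-AU images round-trip exactly through
#' [load_image()].
#'
#' @param x A [calibrated_image()] or [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(x, path) {
  to_page <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  pages <- if (inherits(x, "calibrated_image")) list(to_page(x$pixels))
    else if (inherits(x, "image_stack")) lapply(x$frames, to_page)
    else stop("x must be a calibrated_image or image_stack")
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in order over seeded synthetic inputs and
#' writes CSV/JSON outputs plus a run manifest (`manifest.json`: config
#' snapshot, output checksums, package version, timestamp, seed). Identical
#' config and seed reproduce identical outputs. On stage failure the run
#' aborts with the failing stage named and a `FAILED` marker file next to the
#' partial outputs.
#'
#' @param config A YAML file path or a list with elements `seed` and
#'   `stages` (character vector from `"simulate_clusters"`, `"clusters"`,
#'   `"spt"`, `"frap"`, `"lifetime"`, `"asym"`), plus optional per-stage
#'   parameter lists of the same names as the spec constructors.
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$seed)) stop("config must name a `seed`")
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop("config must name at least one stage")
  known <- c("simulate_clusters", "clusters", "spt", "frap", "lifetime",
             "asym")
  bad <- setdiff(config$stages, known)
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- validate_seed(config$seed)
  spec_args <- function(name) c(config[[name]], list(seed = seed))
  outputs <- character(0)
  emit_csv <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.csv(df, p, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  emit_json <- function(x, file) {
    p <- file.path(out_dir, file)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <<- c(outputs, p)
    p
  }
  state <- new.env(parent = emptyenv())
  run_stage <- function(stage) {
    switch(stage,
      simulate_clusters = {
        spec <- do.call(cluster_field_spec, spec_args("cluster_field"))
        sim <- generate_cluster_image(spec)
        state$cluster_image <- sim$image
        p <- file.path(out_dir, "cluster_field.tif")
        write_image(sim$image, p); outputs <<- c(outputs, p)
        emit_csv(sim$truth, "cluster_truth.csv")
        emit_json(unclass(spec), "cluster_field_spec.json")
      },
      clusters = {
        img <- state$cluster_image
        if (is.null(img)) {
          sim <- generate_cluster_image(
            do.call(cluster_field_spec, spec_args("cluster_field")))
          img <- sim$image
        }
        mask <- segment_membrane(img)
        rec <- detect_clusters(img, mask)
        emit_csv(data.frame(label = rec$label, area_um2 = rec$area_um2,
                            class = rec$size_class,
                            centroid_x_um = rec$centroid_x_um,
                            centroid_y_um = rec$centroid_y_um,
                            mean_AU = rec$mean_intensity,
                            total_AU = rec$total_intensity),
                 "clusters.csv")
        dist <- size_distribution(rec)
        ci <- clustering_index(img$pixels[mask])
        emit_json(list(threshold_AU = attr(mask, "threshold"),
                       n_clusters = dist$n_total,
                       frequencies = as.list(dist$frequencies),
                       clustering_index = ci$index),
                  "cluster_summary.json")
      },
      spt = {
        spec <- do.call(trajectory_field_spec, spec_args("trajectory_field"))
        tracks <- generate_trajectories(spec)
        tab <- do.call(rbind, lapply(tracks, function(tr)
          data.frame(track_id = attr(tr, "track_id"), frame = tr$frame,
                     x_um = tr$x_um, y_um = tr$y_um,
                     intensity_AU = tr$intensity_AU,
                     mobility = attr(tr, "mobility"))))
        emit_csv(tab, "tracks.csv")
        msd <- compute_msd(tracks)
        emit_csv(data.frame(lag_s = msd$lags_s, msd_um2 = msd$msd_um2,
                            se_um2 = msd$se_um2, n_tracks = msd$n_tracks),
                 "msd.csv")
        est <- fit_diffusion(msd)
        emit_json(list(D_um2_per_s = est$D, intercept_um2 = est$intercept,
                       r_squared = est$r_squared, clipped = est$clipped),
                  "diffusion.json")
      },
      frap = {
        spec <- do.call(frap_spec, spec_args("frap"))
        crv <- generate_frap_curve(spec)
        emit_csv(data.frame(t_s = crv$times, intensity_AU = crv$intensity),
                 "frap_curve.csv")
        fit <- fit_frap(normalize_frap(crv))
        emit_json(list(mobile_fraction = fit$mobile_fraction,
                       stable_fraction = fit$stable_fraction,
                       rate_k_per_s = fit$rate_k,
                       residual_rms = fit$residual_rms),
                  "frap_fit.json")
      },
      lifetime = {
        spec <- do.call(kymograph_spec, spec_args("kymograph"))
        sim <- generate_kymograph(spec)
        thr <- spec$background + spec$particle_intensity / 2
        rec <- measure_lifetimes(sim$kymograph, thr)
        emit_csv(rec, "lifetimes.csv")
        s <- summarize_lifetimes(rec)
        emit_json(list(mean_s = s$mean_s, median_s = s$median_s, n = s$n,
                       n_censored = s$n_censored), "lifetime_summary.json")
      },
      asym = {
        spec <- do.call(asymmetry_field_spec, spec_args("asymmetry_field"))
        sim <- generate_asymmetric_root(spec)
        prof_u <- colMeans(sim$image$pixels[sim$bands$upper_rows, ])
        prof_l <- colMeans(sim$image$pixels[sim$bands$lower_rows, ])
        res <- sided_ratio(sided_profile(prof_u, prof_l))
        emit_json(list(ratio_lower_upper = res$ratio_lower_upper,
                       mean_upper_AU = res$mean_upper,
                       mean_lower_AU = res$mean_lower,
                       true_ratio = sim$true_ratio), "asymmetry.json")
      })
  }
  for (stage in config$stages) {
    ok <- tryCatch({ run_stage(stage); TRUE }, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", stage,
                         conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  manifest <- list(
    config = config,
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs)),
    package_version = as.character(utils::packageVersion("memclust")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
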
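# Internal geometry / labelling helpers shared across modules.

# 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that touch
# only diagonally are merged afterwards with a union-find pass.
label_components8 <- function(mask) {
  stopifnot(is.matrix(mask))
  lab <- EBImage::imageData(EBImage::bwlabel(mask != 0))
  n <- max(lab)
  if (n == 0L) return(lab)
  parent <- seq_len(n)
  find_root <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  merge_pairs <- function(a, b) {
    idx <- which(a > 0 & b > 0 & a != b)
    for (k in idx) {
      ra <- find_root(a[k]); rb <- find_root(b[k])
      if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    }
  }
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr > 1L && nc > 1L) {
    merge_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right diagonal
    merge_pairs(lab[-1, -nc], lab[-nr, -1])   # up-right diagonal
  }
  roots <- vapply(seq_len(n), find_root, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Bilinear interpolation at fractional pixel coordinates (col_px, row_px),
# pixel centres at integer coordinates. Coordinates are clamped to the image.
interp_bilinear <- function(px, col_px, row_px) {
  nr <- nrow(px); nc <- ncol(px)
  c0 <- pmin(pmax(col_px, 1), nc)
  r0 <- pmin(pmax(row_px, 1), nr)
  cf <- floor(c0); rf <- floor(r0)
  cf <- pmin(cf, nc - 1L); rf <- pmin(rf, nr - 1L)
  cf <- pmax(cf, 1L); rf <- pmax(rf, 1L)
  dc <- c0 - cf; dr <- r0 - rf
  i11 <- px[cbind(rf, cf)]
  i12 <- px[cbind(rf, cf + 1)]
  i21 <- px[cbind(rf + 1, cf)]
  i22 <- px[cbind(rf + 1, cf + 1)]
  i11 * (1 - dr) * (1 - dc) + i12 * (1 - dr) * dc +
    i21 * dr * (1 - dc) + i22 * dr * dc
}

# Resample a polyline (vertices in um, columns x,y) at a fixed step (um).
# Returns positions along the path, interpolated points and unit normals.
sample_polyline <- function(vertices, step_um) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 2L)
    stop("`line` must be a 2-column (x, y) matrix with >= 2 vertices")
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) {
    keep <- c(TRUE, seg_len > 0)
    vertices <- vertices[keep, , drop = FALSE]
    if (nrow(vertices) < 2L) stop("degenerate polyline")
    seg <- diff(vertices); seg_len <- sqrt(rowSums(seg^2))
  }
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, total, by = step_um)
  if (s[length(s)] < total) s <- c(s, total)
  seg_idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE),
                  nrow(seg))
  frac <- (s - cum[seg_idx]) / seg_len[seg_idx]
  pts <- vertices[seg_idx, , drop = FALSE] +
    seg[seg_idx, , drop = FALSE] * frac
  tang <- seg[seg_idx, , drop = FALSE] / seg_len[seg_idx]
  normal <- cbind(-tang[, 2], tang[, 1])
  list(s_um = s, points_um = pts, normals = normal)
}

# um <-> fractional pixel coordinate conversion (pixel centres at integers).
um_to_px <- function(u, pixel_size) u / pixel_size + 0.5
px_to_um <- function(p, pixel_size) (p - 0.5) * pixel_size

# Check that physical points fall inside the image bounds.
assert_in_bounds <- function(points_um, image_dim, pixel_size, what = "polyline") {
  xmax <- image_dim[2] * pixel_size
  ymax <- image_dim[1] * pixel_size
  if (any(points_um[, 1] < 0) || any(points_um[, 1] > xmax) ||
      any(points_um[, 2] < 0) || any(points_um[, 2] > ymax))
    stop(sprintf("%s extends outside the image bounds (%g x %g um)",
                 what, xmax, ymax))
  invisible(TRUE)
}
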
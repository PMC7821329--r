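# Independent oracles used to cross-check the implementation.

# Brute-force 8-connected component labelling by explicit flood fill.
flood_fill_label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- cur
    while (length(queue) > 0L) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1] + dr; c <- p[2] + dc
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Canonical form for comparing labelings up to label permutation: the label
# image relabelled by first pixel occurrence in column-major order.
canonical_labels <- function(lab) {
  ids <- unique(lab[lab > 0])
  match(lab, ids) * (lab > 0)
}

# Pooled-variance two-sample t statistic and p, from the textbook formula.
hand_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = tstat, p_value = 2 * pt(-abs(tstat), df), df = df)
}

# All-pairs nearest-neighbour distances (O(n^2), no dist() shortcut).
brute_nn_distances <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    min(sqrt((x[-i] - x[i])^2 + (y[-i] - y[i])^2))
  }, numeric(1))
}

# Expand a trajectory into per-lag squared displacements by direct
# enumeration of all frame pairs.
brute_msd <- function(frames, x, y, n_lags) {
  vapply(seq_len(n_lags), function(l) {
    acc <- c()
    for (i in seq_along(frames)) {
      j <- which(frames == frames[i] + l)
      if (length(j) == 1L)
        acc <- c(acc, (x[j] - x[i])^2 + (y[j] - y[i])^2)
    }
    if (length(acc) == 0L) NA_real_ else mean(acc)
  }, numeric(1))
}
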
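# Independent brute-force oracle for the correlation maps: per candidate,
# build the four mirror templates explicitly from first principles and
# compute the sample Pearson correlation with stats::cor on the vectors.
brute_force_maps <- function(px, xs, ys, n) {
  h <- (n - 1L) %/% 2L
  mirror_lr <- function(m) m[, ncol(m):1, drop = FALSE]
  mirror_tb <- function(m) m[nrow(m):1, , drop = FALSE]
  cx <- matrix(NA_real_, length(ys), length(xs))
  cy <- matrix(NA_real_, length(ys), length(xs))
  for (j in seq_along(xs)) {
    for (i in seq_along(ys)) {
      roi <- px[(ys[i] - h):(ys[i] + h), (xs[j] - h):(xs[j] + h)]
      mid <- h + 1L
      tl <- cbind(roi[, 1:mid], mirror_lr(roi[, 1:(mid - 1), drop = FALSE]))
      tr <- cbind(mirror_lr(roi[, (mid + 1):n, drop = FALSE]), roi[, mid:n])
      tt <- rbind(roi[1:mid, ], mirror_tb(roi[1:(mid - 1), , drop = FALSE]))
      tb <- rbind(mirror_tb(roi[(mid + 1):n, , drop = FALSE]), roi[mid:n, ])
      cx[i, j] <- cor(as.vector(tl), as.vector(tr))
      cy[i, j] <- cor(as.vector(tt), as.vector(tb))
    }
  }
  list(corr_x = cx, corr_y = cy)
}

# Euclidean localization error of a particle_loc against a scene's truth.
scene_error <- function(loc, scene) {
  if (!isTRUE(loc$converged)) return(NA_real_)
  sqrt((loc$x - scene$truth$center[["x"]])^2 +
       (loc$y - scene$truth$center[["y"]])^2)
}

# Mean error and failure count of a locator over seeded randomized trials.
trial_errors <- function(n, radius, snr, method = "csym", pattern = "rings",
                         seed_offset = 0L, ...) {
  vapply(seq_len(n), function(i) {
    scene <- make_trial(radius, snr, pattern = pattern, seed = i + seed_offset)
    scene_error(locate_particle(scene, method, ...), scene)
  }, numeric(1))
}
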
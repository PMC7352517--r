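# Independent oracles used across the suite.

# Analytic circularity of an ellipse of given aspect ratio via the
# Ramanujan perimeter approximation.
ellipse_circularity <- function(aspect_ratio, area = 1) {
  a <- sqrt(area * aspect_ratio / pi)
  b <- sqrt(area / (pi * aspect_ratio))
  p <- pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
  4 * pi * area / p^2
}

# Furth MSD, restated independently of the package.
furth_msd <- function(t, mu, P, n_d = 2) {
  2 * n_d * mu * (t - P * (1 - exp(-t / P)))
}

# Brute-force per-step speeds from a trajectory table: plain loops, no
# dplyr, used to cross-check the vectorized implementation.
brute_force_speeds <- function(tracks) {
  out <- numeric(0)
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    tr <- tr[order(tr$t_min), ]
    for (k in 2:nrow(tr)) {
      d <- sqrt((tr$x_um[k] - tr$x_um[k - 1])^2 +
                (tr$y_um[k] - tr$y_um[k - 1])^2)
      out <- c(out, d / (tr$t_min[k] - tr$t_min[k - 1]))
    }
  }
  out
}

# Greedy matching of detections to ground-truth spots within a radius;
# returns recall and precision.
match_spots <- function(truth, detected, radius_um) {
  if (nrow(detected) == 0) {
    return(list(recall = 0, precision = if (nrow(truth) == 0) 1 else 0))
  }
  d2 <- outer(truth$x_um, detected$x_um, "-")^2 +
        outer(truth$y_um, detected$y_um, "-")^2
  list(
    recall = mean(apply(d2, 1, min) <= radius_um^2),
    precision = mean(apply(d2, 2, min) <= radius_um^2)
  )
}

# Rasterized disk mask of radius r pixels.
disk_mask <- function(r, pad = 10) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  m <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, "+") <= r^2
  m
}
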
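# Fixtures built in code: hourglass masks, random rigid transforms, and
# independent brute-force oracles kept deliberately separate from the
# package's own implementations.

default_meta <- function(mm_per_px = 0.2, angle = 30)
  acquisition_meta(fps = 15, bpm = 60, imaging_angle_deg = angle,
                   mm_per_px = mm_per_px, center_px = c(20, 100))

# rasterize an hourglass (two opposed triangles joined at a neck) into a
# logical image mask; neck extent is exact for odd w_neck at angle 0/90
hourglass_mask <- function(H = 120, W = 120, neck = c(60, 60), angle_deg = 0,
                           length_px = 60, w_neck = 5, w_max = 19) {
  th <- angle_deg * pi / 180
  e1 <- c(sin(th), cos(th)); e2 <- c(cos(th), -sin(th))
  voff <- if (w_neck %% 2 == 0) 0.5 else 0
  rr <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  u <- (rr - neck[1]) * e1[1] + (cc - neck[2]) * e1[2]
  v <- (rr - neck[1]) * e2[1] + (cc - neck[2]) * e2[2] - voff
  hw <- (w_neck - 1) / 2 + ((w_max - 1) / 2 - (w_neck - 1) / 2) *
    abs(u) / (length_px / 2)
  abs(u) <= length_px / 2 & abs(v) <= hw
}

# independent exhaustive width-profile oracle on aligned (u, v) points:
# plain loops, no shared code with find_vc
brute_force_vcw <- function(aligned, interior_fraction = 0.1) {
  u <- round(aligned[, 1]); v <- aligned[, 2]
  span <- max(u) - min(u)
  lo <- min(u) + interior_fraction * span
  hi <- max(u) - interior_fraction * span
  best <- Inf
  for (b in sort(unique(u))) {
    if (b < lo || b > hi) next
    vb <- v[u == b]
    h <- max(vb) - min(vb) + 1
    if (h < best) best <- h
  }
  best
}

random_rigid <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))  # random unit quaternion
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  m <- diag(4); m[1:3, 1:3] <- R; m[1:3, 4] <- stats::runif(3, -50, 50)
  m
}

# flat RGB array helper
rgb_image <- function(H, W, rgb = c(0L, 0L, 0L)) {
  a <- array(0L, c(H, W, 3))
  for (ch in 1:3) a[, , ch] <- rgb[ch]
  a
}
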
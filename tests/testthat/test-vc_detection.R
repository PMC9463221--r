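test_that("PCA recovers axes and centroid of an axis-aligned rectangle", {
  m <- matrix(FALSE, 60, 30)
  m[11:50, 11:20] <- TRUE  # 40 rows x 10 cols
  pca <- pca_axes(m)
  expect_equal(pca$centroid_px, c(30.5, 15.5))
  expect_equal(abs(sum(pca$major_axis * c(1, 0))), 1, tolerance = 1e-12)
  expect_equal(pca$major_axis, c(1, 0))  # sign rule: col = 0 -> row >= 0
  expect_gte(pca$moments[1], pca$moments[2])
  expect_equal(sum(pca$major_axis * pca$minor_axis), 0, tolerance = 1e-12)
  expect_false(pca$degenerate)
})

test_that("PCA recovers the orientation of a rotated ellipse within 1 degree", {
  for (ang in c(30, 10, 55, 80)) {
    th <- ang * pi / 180
    e1 <- c(sin(th), cos(th)); e2 <- c(cos(th), -sin(th))
    m <- matrix(FALSE, 160, 160)
    rr <- matrix(seq_len(160), 160, 160)
    cc <- matrix(seq_len(160), 160, 160, byrow = TRUE)
    u <- (rr - 80) * e1[1] + (cc - 80) * e1[2]
    v <- (rr - 80) * e2[1] + (cc - 80) * e2[2]
    m[(u / 50)^2 + (v / 15)^2 <= 1] <- TRUE  # semi-axes 50 / 15 px
    pca <- pca_axes(m)
    got <- atan2(pca$major_axis[1], pca$major_axis[2]) * 180 / pi
    expect_lt(min(abs(got - ang), abs(got - ang + 180), abs(got - ang - 180)), 1)
  }
})

test_that("an isotropic square is flagged degenerate but still usable", {
  m <- matrix(FALSE, 20, 20); m[5:14, 5:14] <- TRUE
  pca <- pca_axes(m)
  expect_true(pca$degenerate)
  expect_equal(pca$moments[[1]], pca$moments[[2]])
  expect_gte(pca$major_axis[2], 0)
  expect_error(pca_axes(matrix(FALSE, 5, 5)), class = "vclocate_degenerate")
})

test_that("axis alignment is rigid: centroid to origin, distances preserved", {
  set.seed(21)
  m <- hourglass_mask(angle_deg = 37)
  pca <- pca_axes(m)
  pts <- which(m, arr.ind = TRUE)
  al <- align_to_axis(m, pca)
  expect_equal(colMeans(al), c(u = 0, v = 0), tolerance = 1e-9)
  i <- sample(nrow(pts), 20); j <- sample(nrow(pts), 20)
  d_img <- sqrt(rowSums((pts[i, ] - pts[j, ])^2))
  d_ax <- sqrt(rowSums((al[i, ] - al[j, ])^2))
  expect_equal(d_ax, d_img, tolerance = 1e-9)

  # an axis-aligned rectangle maps to itself centered at the origin
  r <- matrix(FALSE, 40, 20); r[6:35, 6:15] <- TRUE
  pr <- pca_axes(r)
  ar <- align_to_axis(r, pr)
  expect_equal(sort(unique(ar[, 1])), seq(-14.5, 14.5), tolerance = 1e-12)
  expect_equal(sort(unique(ar[, 2])), seq(-4.5, 4.5), tolerance = 1e-12)
})

test_that("find_vc matches the exhaustive width-profile oracle on a known neck", {
  # two 21-px-tall triangles joined by a 5-px neck at u = 12, on u in 0..24
  pts <- do.call(rbind, lapply(0:24, function(u) {
    h <- 5 + 2 * round(8 * abs(u - 12) / 12)  # 5 at the neck, 21 at the ends
    cbind(u = u, v = seq(-(h - 1) / 2, (h - 1) / 2))
  }))
  vc <- find_vc(pts, interior_fraction = 0.1)
  expect_equal(vc$vcw_px, 5)
  expect_equal(unname(vc$vc_axis), c(12, 0))
  expect_equal(vc$vcw_px, brute_force_vcw(pts, 0.1))

  # neck minor-extent spanning [3, 7] -> midpoint 5
  pts2 <- do.call(rbind, lapply(-10:10, function(u) {
    if (u == 0) cbind(u = u, v = 3:7)
    else cbind(u = u, v = seq(-abs(u) - 4, abs(u) + 10))
  }))
  vc2 <- find_vc(pts2)
  expect_equal(unname(vc2$vc_axis), c(0, 5))
})

test_that("constant-height profiles tie-break to the bin nearest u = 0", {
  pts <- do.call(rbind, lapply(-10:13, function(u) cbind(u = u, v = -3:3)))
  vc <- find_vc(pts, interior_fraction = 0.1)
  expect_equal(vc$vcw_px, 7)
  expect_equal(unname(vc$vc_axis[1]), 0)
  # short jets whose interior search range is empty raise a retake condition
  expect_error(find_vc(cbind(u = c(0, 10), v = c(0, 0)), 0.4),
               class = "vclocate_jet_too_short")
})

test_that("VCW equals the brute-force minimum on randomized hourglasses", {
  set.seed(101)
  for (rep in 1:25) {
    w_neck <- sample(3:9, 1)
    m <- hourglass_mask(H = 140, W = 140,
                        neck = c(sample(55:85, 1), sample(55:85, 1)),
                        angle_deg = stats::runif(1, 0, 180),
                        length_px = sample(40:70, 1),
                        w_neck = w_neck,
                        w_max = w_neck + sample(10:16, 1))
    pca <- pca_axes(m)
    al <- align_to_axis(m, pca)
    expect_equal(find_vc(al)$vcw_px, brute_force_vcw(al))
  }
})

test_that("the inverse PCA map returns the VC to image coordinates", {
  m <- hourglass_mask(neck = c(60, 62), angle_deg = 25)
  pca <- pca_axes(m)
  al <- align_to_axis(m, pca)
  vc <- vc_to_image(find_vc(al), pca)
  # (0, 0) in axis coords is the centroid
  expect_equal(vc_to_image(c(0, 0), pca), pca$centroid_px, tolerance = 1e-12)
  # round trip point -> axis -> image is exact
  p <- which(m, arr.ind = TRUE)[10, ]
  d <- p - pca$centroid_px
  uv <- c(sum(d * pca$major_axis), sum(d * pca$minor_axis))
  expect_equal(vc_to_image(uv, pca), as.numeric(p), tolerance = 1e-9)
  # detected VC lands on the constructed neck
  expect_lt(sqrt(sum((vc$vc_px - c(60, 62))^2)), 1.5)
})

test_that("detection is rotation invariant to within 1.5 px of the neck", {
  for (ang in seq(10, 80, by = 10)) {
    m <- hourglass_mask(H = 140, W = 140, neck = c(70, 70), angle_deg = ang,
                        length_px = 60, w_neck = 5, w_max = 19)
    pca <- pca_axes(m)
    vc <- vc_to_image(find_vc(align_to_axis(m, pca)), pca)
    expect_lt(sqrt(sum((vc$vc_px - c(70, 70))^2)), 1.5)
  }
})

test_that("masks symmetric about the major axis place the VC on that axis", {
  m <- hourglass_mask(neck = c(60, 60), angle_deg = 0)
  vc <- find_vc(align_to_axis(m, pca_axes(m)))
  expect_lt(abs(vc$vc_axis[2]), 0.51)
})
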
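test_that("grayscale removal blacks out achromatic pixels only", {
  img <- rgb_image(2, 2)
  img[1, 1, ] <- c(100L, 100L, 100L)   # pure gray
  img[1, 2, ] <- c(255L, 255L, 0L)     # saturated yellow
  img[2, 1, ] <- c(60L, 50L, 45L)      # spread 15 <= tol
  img[2, 2, ] <- c(90L, 50L, 45L)      # spread 45 > tol
  out <- remove_bmode(img, gray_tol = 20)
  expect_equal(out[1, 1, ], c(0L, 0L, 0L))
  expect_equal(out[1, 2, ], c(255L, 255L, 0L))
  expect_equal(out[2, 1, ], c(0L, 0L, 0L))
  expect_equal(out[2, 2, ], c(90L, 50L, 45L))
})

test_that("chromatic pixel count survives grayscale removal exactly", {
  set.seed(42)
  H <- 40; W <- 40
  g <- matrix(sample(0:120, H * W, replace = TRUE), H, W)
  img <- array(0L, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- g  # perfectly gray speckle
  idx <- sample(H * W, 37)
  img[, , 1][idx] <- pmin(255L, g[idx] + 60L)  # spread 60 > tol
  out <- remove_bmode(img, gray_tol = 20)
  # brute-force per-pixel count of surviving (non-black) pixels
  nonblack <- 0
  for (i in seq_len(H)) for (j in seq_len(W))
    if (any(out[i, j, ] != 0)) nonblack <- nonblack + 1
  expect_equal(nonblack, 37)
})

test_that("cool-flow suppression removes blue-dominant pixels", {
  img <- rgb_image(1, 3)
  img[1, 1, ] <- c(0L, 0L, 255L)
  img[1, 2, ] <- c(255L, 0L, 0L)
  img[1, 3, ] <- c(10L, 10L, 200L)
  out <- suppress_cool(img)
  expect_equal(out[1, 1, ], c(0L, 0L, 0L))
  expect_equal(out[1, 2, ], c(255L, 0L, 0L))
  expect_equal(out[1, 3, ], c(0L, 0L, 0L))
  # boundary: R == B is warm, kept
  img2 <- rgb_image(1, 1, c(100L, 0L, 100L))
  expect_equal(suppress_cool(img2), img2)
})

test_that("the two color filters are idempotent and commute", {
  set.seed(7)
  img <- array(sample(0:255, 30 * 30 * 3, replace = TRUE), c(30, 30, 3))
  a <- remove_bmode(img); b <- suppress_cool(img)
  expect_identical(remove_bmode(a), a)
  expect_identical(suppress_cool(b), b)
  expect_identical(suppress_cool(remove_bmode(img)),
                   remove_bmode(suppress_cool(img)))
})

test_that("MIP compounding keeps the brightest full RGB triple per pixel", {
  set.seed(3)
  f1 <- array(sample(0:255, 20 * 20 * 3, replace = TRUE), c(20, 20, 3))
  black <- rgb_image(20, 20)
  expect_identical(mip_compound(list(f1)), f1)
  expect_identical(mip_compound(list(f1, black)), f1)
  expect_identical(mip_compound(list(black, f1)), f1)
  expect_identical(mip_compound(list(f1, f1)), mip_compound(list(f1)))

  # disjoint blobs: each output pixel copied verbatim from its argmax frame
  a <- rgb_image(10, 10); b <- rgb_image(10, 10)
  a[2:4, 2:4, 1] <- 200L; a[2:4, 2:4, 2] <- 180L
  b[6:8, 6:8, 1] <- 150L; b[6:8, 6:8, 2] <- 250L
  out <- mip_compound(list(a, b))
  lum <- function(im, i, j) 0.299 * im[i, j, 1] + 0.587 * im[i, j, 2] +
    0.114 * im[i, j, 3]
  for (i in 1:10) for (j in 1:10) {
    src <- if (lum(a, i, j) >= lum(b, i, j)) a else b  # earliest wins ties
    expect_equal(out[i, j, ], src[i, j, ])
  }
  # dominance: output luminance >= every input's, pixelwise
  for (im in list(a, b))
    expect_true(all(vclocate:::luminance(out) >= vclocate:::luminance(im)))

  expect_error(mip_compound(list()), "empty")
  expect_error(mip_compound(list(a, rgb_image(5, 5))), "dimensions")
})

test_that("grayscale conversion follows Rec.601 luminance", {
  img <- rgb_image(1, 3)
  img[1, 2, ] <- c(255L, 255L, 255L)
  img[1, 3, ] <- c(255L, 255L, 0L)
  g <- to_grayscale(img)
  expect_equal(g[1, 1], 0L)
  expect_equal(g[1, 2], 255L)
  expect_equal(g[1, 3], 226L)  # round(0.299*255 + 0.587*255)
})

test_that("thresholding is strict and antitone in the threshold", {
  g <- matrix(c(149L, 150L, 151L, 0L), 2, 2)
  m150 <- threshold_segment(g, 150)
  expect_equal(as.vector(m150), c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(attr(m150, "threshold_used"), 150)
  expect_false(any(threshold_segment(matrix(0L, 4, 4))))

  set.seed(9)
  g2 <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  m130 <- threshold_segment(g2, 130); m150b <- threshold_segment(g2, 150)
  expect_true(all(m130[m150b]))            # mask(150) subset of mask(130)
  expect_true(all(m130[g2 > 130 & g2 <= 150]))
})

test_that("largest island keeps one 8-connected component", {
  m <- matrix(FALSE, 30, 30)
  m[5:14, 5:14] <- TRUE        # 100 px
  m[20:24, 20:27] <- TRUE      # 40 px
  jet <- largest_island(m)
  expect_s3_class(jet, "jet_mask")
  expect_equal(jet$component_area_px, 100)
  expect_true(all(which(jet$mask) %in% which(m)))
  expect_false(any(jet$mask[20:24, 20:27]))

  # single blob unchanged
  single <- matrix(FALSE, 10, 10); single[3:6, 3:6] <- TRUE
  expect_equal(largest_island(single)$mask, single)

  # a diagonal chain is one component (8-connectivity)
  diagm <- matrix(FALSE, 10, 10)
  for (i in 1:6) diagm[i, i] <- TRUE
  diagm[8:9, 1] <- TRUE  # 2-px rival
  expect_equal(largest_island(diagm)$component_area_px, 6)

  expect_error(largest_island(matrix(FALSE, 5, 5)), class = "vclocate_no_jet")
  expect_error(largest_island(matrix(FALSE, 5, 5)), class = "vclocate_retake")
})

test_that("island area ties break on the top-left bounding box corner", {
  m <- matrix(FALSE, 20, 20)
  m[10:12, 15:17] <- TRUE  # 9 px, corner (10, 15)
  m[2:4, 2:4] <- TRUE      # 9 px, corner (2, 2) - wins
  jet <- largest_island(m)
  expect_true(all(jet$mask[2:4, 2:4]))
  expect_false(any(jet$mask[10:12, 15:17]))
})
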
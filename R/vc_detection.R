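#' Vena contracta detection on the segmented jet
#'
#' The jet mask is aligned to its own principal axes; the jet height (minor
#' extent) is profiled along the major axis, and the interior minimum of that
#' profile is the vena contracta: its value is the vena contracta width (VCW)
#' and its midpoint is the VC location, mapped back to image pixels by the
#' inverse PCA transform.
#'
#' @name vc_detection
NULL

#' Principal axes of a jet mask
#'
#' Computes the centroid of the on-pixels and the eigen-decomposition of
#' their 2x2 coordinate covariance (population form, divisor n). The major
#' axis is the eigenvector of the larger eigenvalue, with its sign fixed so
#' the column component is >= 0 (ties: row component >= 0); the minor axis is
#' treated the same way. Isotropic masks (equal moments) are usable but
#' flagged `degenerate`.
#'
#' @param jet a [largest_island()] result, or a logical mask.
#' @return a list of class `"pca_frame"`: `centroid_px` (row, col),
#'   `major_axis`, `minor_axis` (unit (row, col) vectors), `moments`
#'   (lambda_major, lambda_minor in px^2), `degenerate`.
#' @export
pca_axes <- function(jet) {
  mask <- if (inherits(jet, "jet_mask")) jet$mask else jet
  pts <- which(mask, arr.ind = TRUE)  # columns: row, col
  if (nrow(pts) < 2)
    stop(vc_condition("degenerate jet: fewer than 2 pixels", "vclocate_degenerate"))
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  cov2 <- crossprod(d) / nrow(pts)
  e <- eigen(cov2, symmetric = TRUE)
  fix_sign <- function(v) {
    if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) -v else v
  }
  major <- fix_sign(e$vectors[, 1])
  minor <- fix_sign(e$vectors[, 2])
  lam <- e$values
  structure(list(centroid_px = as.numeric(ctr),
                 major_axis = major, minor_axis = minor,
                 moments = c(lambda_major = lam[1], lambda_minor = lam[2]),
                 degenerate = isTRUE(all.equal(lam[1], lam[2])) || lam[2] == 0),
            class = "pca_frame")
}

#' @export
print.pca_frame <- function(x, ...) {
  cat(sprintf("PCA frame: centroid (%.2f, %.2f) px, major axis (%.3f, %.3f), moments %.1f / %.1f px^2%s\n",
              x$centroid_px[1], x$centroid_px[2],
              x$major_axis[1], x$major_axis[2],
              x$moments[1], x$moments[2],
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Map jet pixels into principal-axis coordinates
#'
#' A rigid map: each on-pixel p becomes (u, v) = ((p - centroid) . major,
#' (p - centroid) . minor), so the jet lies along the u axis. Pairwise
#' distances are preserved exactly.
#'
#' @param jet a [largest_island()] result or logical mask.
#' @param pca the [pca_axes()] of the same mask.
#' @return N x 2 numeric matrix with columns `u` (major) and `v` (minor).
#' @export
align_to_axis <- function(jet, pca) {
  mask <- if (inherits(jet, "jet_mask")) jet$mask else jet
  pts <- which(mask, arr.ind = TRUE)
  d <- sweep(pts, 2, pca$centroid_px)
  out <- cbind(u = d %*% pca$major_axis, v = d %*% pca$minor_axis)
  colnames(out) <- c("u", "v")
  out
}

#' Find the vena contracta on the axis-aligned jet
#'
#' Pixels are binned by rounded major-axis coordinate u; the jet height at u
#' is the minor-axis extent `max(v) - min(v) + 1` of that bin. Because the
#' jet tapers to a point at its tips, the raw profile minimum always sits at
#' an end; the search therefore excludes `interior_fraction` of the occupied
#' u-range at each end and takes the minimum of the remaining profile. That
#' minimum height is the vena contracta width; ties go to the bin nearest
#' u = 0 (then the smaller u), and the VC is placed at the bin's midpoint of
#' minor extent.
#'
#' @param aligned N x 2 (u, v) matrix from [align_to_axis()].
#' @param interior_fraction fraction of the u-range excluded at each end
#'   (default 0.1; must be < 0.5).
#' @return a list of class `"vc_result2d"`: `vcw_px`, `vc_axis` (u*, v
#'   midpoint), and `profile` (data.frame u, height of the searched bins).
#' @export
find_vc <- function(aligned, interior_fraction = 0.1) {
  stopifnot(nrow(aligned) >= 1,
            interior_fraction >= 0, interior_fraction < 0.5)
  u <- round(aligned[, 1])
  v <- aligned[, 2]
  lo_all <- min(u); hi_all <- max(u)
  span <- hi_all - lo_all
  lo <- lo_all + interior_fraction * span
  hi <- hi_all - interior_fraction * span
  keep <- u >= lo & u <= hi
  if (!any(keep))
    stop(vc_condition("jet too short: no interior bins to search",
                      "vclocate_jet_too_short"))
  uk <- u[keep]; vk <- v[keep]
  bins <- sort(unique(uk))
  vmin <- vapply(bins, function(b) min(vk[uk == b]), numeric(1))
  vmax <- vapply(bins, function(b) max(vk[uk == b]), numeric(1))
  h <- vmax - vmin + 1
  m <- min(h)
  cand <- which(h == m)
  cand <- cand[order(abs(bins[cand]), bins[cand])][1]
  structure(list(vcw_px = m,
                 vc_axis = c(u = bins[cand], v = (vmin[cand] + vmax[cand]) / 2),
                 profile = data.frame(u = bins, height = h)),
            class = "vc_result2d")
}

#' Map an axis-coordinate VC back to image pixels
#'
#' Applies the inverse of the PCA alignment:
#' `vc_px = centroid + u* major + v* minor`.
#'
#' @param vc_axis a [find_vc()] result (or a length-2 (u, v) vector).
#' @param pca the [pca_axes()] used for alignment.
#' @return the input with an added `vc_px` (row, col) field (class
#'   `"vc_result2d"`).
#' @export
vc_to_image <- function(vc_axis, pca) {
  uv <- if (inherits(vc_axis, "vc_result2d")) vc_axis$vc_axis else vc_axis
  p <- pca$centroid_px + uv[1] * pca$major_axis + uv[2] * pca$minor_axis
  if (inherits(vc_axis, "vc_result2d")) {
    vc_axis$vc_px <- as.numeric(p)
    vc_axis
  } else {
    as.numeric(p)
  }
}

#' @export
print.vc_result2d <- function(x, ...) {
  cat(sprintf("Vena contracta (2D): width %.2f px at axis coords (u=%.1f, v=%.1f)",
              x$vcw_px, x$vc_axis[1], x$vc_axis[2]))
  if (!is.null(x$vc_px))
    cat(sprintf(", image pixel (%.2f, %.2f)", x$vc_px[1], x$vc_px[2]))
  cat("\n")
  invisible(x)
}
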
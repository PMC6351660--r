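# Radial "rake" infiltration profiling: tumor ROI geometry, normalized
# infiltration fraction (0 at the stromal margin, 1 at the centroid),
# concentric decile grids, per-deposit profiles and profile comparison.

boundary_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  inner <- pad[2:(nr + 1L), 2:(nc + 1L)] &
    pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
    pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}

#' Tumor region of interest with radial geometry
#'
#' Wraps a binary tumor mask together with its pixel centroid and boundary,
#' the geometry used by the radial infiltration coordinate. The boundary is
#' the set of mask pixels with a 4-neighbor outside the mask, ordered by
#' polar angle about the centroid (a closed contour for star-shaped ROIs;
#' a flag records when the centroid falls outside the mask).
#'
#' @param mask Logical matrix (TRUE inside the tumor cross-section).
#' @param pixel_size Pixel size `c(row, col)` in mm (default `c(0.1, 0.1)`).
#' @return An object of class `tumor_roi` with `mask`, `centroid`
#'   (row, col), `boundary` (ordered matrix of row, col), `pixel_size`,
#'   `area_px`, `area_mm2` and `star_shaped`.
#' @export
tumor_roi <- function(mask, pixel_size = c(0.1, 0.1)) {
  if (!is.logical(mask) || !is.matrix(mask) || !any(mask))
    stop("'mask' must be a nonempty logical matrix")
  pixel_size <- rep(as.numeric(pixel_size), length.out = 2L)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(mean(idx[, 1L]), mean(idx[, 2L]))
  bp <- boundary_pixels(mask)
  th <- atan2(bp[, 1L] - centroid[1L], bp[, 2L] - centroid[2L])
  o <- order(th)
  boundary <- bp[o, , drop = FALSE]
  colnames(boundary) <- c("row", "col")
  cr <- round(centroid)
  star <- cr[1L] >= 1 && cr[1L] <= nrow(mask) &&
    cr[2L] >= 1 && cr[2L] <= ncol(mask) && mask[cr[1L], cr[2L]]
  structure(
    list(mask = mask, centroid = centroid, boundary = boundary,
         pixel_size = pixel_size, area_px = nrow(idx),
         area_mm2 = nrow(idx) * pixel_size[1L] * pixel_size[2L],
         star_shaped = star,
         boundary_theta = th[o],
         boundary_r = sqrt((bp[o, 1L] - centroid[1L])^2 +
                             (bp[o, 2L] - centroid[2L])^2)),
    class = "tumor_roi")
}

#' @export
print.tumor_roi <- function(x, ...) {
  cat(sprintf("Tumor ROI: %d px (%.3g mm^2), centroid (%.1f, %.1f)\n",
              x$area_px, x$area_mm2, x$centroid[1L], x$centroid[2L]))
  invisible(x)
}

#' Segment a tumor cross-section from an intensity image
#'
#' Automatic delineation for synthetic or well-contrasted images: Otsu
#' thresholding, largest connected foreground component, hole filling.
#' Alternatively passes a supplied mask through unchanged (computing its
#' centroid and boundary).
#'
#' @param reference_image Numeric intensity matrix (e.g. the first-echo MGE
#'   image, or an inverted histology channel).
#' @param method `"otsu"` (default) or `"provided-mask"`.
#' @param mask Logical matrix, required when `method = "provided-mask"`.
#' @param pixel_size Pixel size `c(row, col)` in mm.
#' @return A [tumor_roi()].
#' @export
segment_tumor_roi <- function(reference_image,
                              method = c("otsu", "provided-mask"),
                              mask = NULL, pixel_size = c(0.1, 0.1)) {
  method <- match.arg(method)
  if (method == "provided-mask") {
    if (is.null(mask)) stop("'mask' is required for method = 'provided-mask'")
    return(tumor_roi(mask, pixel_size))
  }
  if (!is.matrix(reference_image) || !is.numeric(reference_image) ||
      !any(is.finite(reference_image)))
    stop("'reference_image' must be a numeric matrix")
  rng <- range(reference_image, finite = TRUE)
  if (rng[2L] <= rng[1L]) stop("no foreground found: image is constant")
  norm <- (reference_image - rng[1L]) / (rng[2L] - rng[1L])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > thr
  if (!any(fg)) stop("no foreground found above the automatic threshold")
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  main <- which.max(tabulate(lab[lab > 0L]))
  comp <- lab == main
  filled <- EBImage::fillHull(EBImage::Image(comp * 1)) > 0
  tumor_roi(matrix(as.logical(filled), nrow(comp), ncol(comp)), pixel_size)
}

# Boundary distance D(theta) from the centroid, by linear interpolation of
# the boundary's polar radius with wrap-around.
ray_boundary_distance <- function(roi, theta) {
  th <- roi$boundary_theta
  r <- roi$boundary_r
  if (length(th) < 3L) return(rep(max(r), length(theta)))
  th3 <- c(th - 2 * pi, th, th + 2 * pi)
  r3 <- c(r, r, r)
  stats::approx(th3, r3, xout = theta, ties = mean)$y
}

#' Radial infiltration fraction of points in a tumor ROI
#'
#' Normalized depth coordinate of a point: a ray is cast from the ROI
#' centroid through the point to its first boundary intersection at distance
#' `D`, and the fraction is `1 - d / D` where `d` is the point's distance
#' from the centroid. The fraction is 0 at the stromal margin and 1 at the
#' centroid, and is clipped to `[0, 1]` against pixelation of the boundary.
#'
#' @param points Numeric matrix or data frame of point coordinates with
#'   columns (row, col) in pixels; a length-2 vector is taken as one point.
#' @param roi A [tumor_roi()].
#' @param normalization `"ray"` (default, centroid-ray geometry) or `"edt"`
#'   (Euclidean distance from the boundary scaled by its ROI maximum; more
#'   robust for strongly non-convex ROIs).
#' @return Numeric vector of infiltration fractions in `[0, 1]`.
#' @export
infiltration_fraction <- function(points, roi,
                                  normalization = c("ray", "edt")) {
  normalization <- match.arg(normalization)
  if (!inherits(roi, "tumor_roi")) stop("'roi' must be a tumor_roi")
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("'points' must have two columns (row, col)")
  pr <- round(points[, 1L]); pc <- round(points[, 2L])
  inside <- pr >= 1 & pr <= nrow(roi$mask) & pc >= 1 & pc <= ncol(roi$mask)
  inside[inside] <- roi$mask[cbind(pr[inside], pc[inside])]
  if (!all(inside))
    stop(sum(!inside), " point(s) fall outside the tumor ROI")
  if (normalization == "edt") {
    dm <- EBImage::distmap(EBImage::Image(roi$mask * 1))
    dm <- matrix(as.numeric(dm), nrow(roi$mask), ncol(roi$mask))
    f <- dm[cbind(pr, pc)] / max(dm)
    return(pmin(pmax(f, 0), 1))
  }
  dr <- points[, 1L] - roi$centroid[1L]
  dc <- points[, 2L] - roi$centroid[2L]
  d <- sqrt(dr^2 + dc^2)
  D <- ray_boundary_distance(roi, atan2(dr, dc))
  f <- 1 - d / pmax(D, .Machine$double.eps)
  pmin(pmax(f, 0), 1)
}

#' Concentric radial decile grid over a tumor ROI
#'
#' Labels every ROI pixel with its infiltration bin: bin `k` covers
#' fractions `[(k-1)/n, k/n)`, with the last bin closed at 1, reproducing a
#' concentric "rake" ring pattern from the margin (bin 1) to the core
#' (bin `n`).
#'
#' @param roi A [tumor_roi()].
#' @param n_bins Number of bins (default 10; must be >= 1).
#' @param normalization Passed to [infiltration_fraction()].
#' @return An object of class `radial_grid` with `n_bins`, `bin_edges`,
#'   integer `region_labels` image (0 outside the ROI), and per-bin pixel
#'   counts and areas (`area_px`, `area_mm2`).
#' @export
make_radial_grid <- function(roi, n_bins = 10,
                             normalization = c("ray", "edt")) {
  normalization <- match.arg(normalization)
  if (!inherits(roi, "tumor_roi")) stop("'roi' must be a tumor_roi")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  if (roi$area_px < n_bins)
    stop("degenerate ROI: fewer pixels than bins")
  idx <- which(roi$mask, arr.ind = TRUE)
  f <- infiltration_fraction(idx, roi, normalization)
  bin <- pmin(floor(f * n_bins) + 1L, n_bins)
  labels <- matrix(0L, nrow(roi$mask), ncol(roi$mask))
  labels[idx] <- bin
  area_px <- tabulate(bin, nbins = n_bins)
  structure(
    list(n_bins = n_bins, bin_edges = seq(0, 1, length.out = n_bins + 1L),
         region_labels = labels, area_px = area_px,
         area_mm2 = area_px * roi$pixel_size[1L] * roi$pixel_size[2L],
         normalization = normalization),
    class = "radial_grid")
}

#' Radial infiltration profile of clusters or deposits
#'
#' Assigns each cluster to an infiltration bin by its centroid and returns
#' per-bin counts together with the raw per-deposit infiltration fractions.
#' Clusters whose centroid falls outside the ROI are dropped with a warning.
#'
#' @param clusters A `cluster_set` (from [label_clusters()] or
#'   [count_pb_deposits()]), or a two-column matrix of centroid (row, col)
#'   coordinates in pixels.
#' @param grid A [make_radial_grid()].
#' @param roi The [tumor_roi()] the grid was built on.
#' @param modality Free-text tag (e.g. `"FeMRI"` or `"PB"`).
#' @return An object of class `radial_profile` with `counts` (per bin),
#'   `per_deposit_infiltration`, `modality`, `n_bins`, `bin_edges` and
#'   `area_per_bin_mm2`. `sum(counts)` equals the number of profiled
#'   deposits.
#' @export
infiltration_profile <- function(clusters, grid, roi, modality = "") {
  if (!inherits(grid, "radial_grid")) stop("'grid' must be a radial_grid")
  if (!inherits(roi, "tumor_roi")) stop("'roi' must be a tumor_roi")
  cen <- if (inherits(clusters, "cluster_set"))
    cbind(clusters$clusters$row, clusters$clusters$col)
  else as.matrix(clusters)
  if (nrow(cen) > 0L) {
    pr <- round(cen[, 1L]); pc <- round(cen[, 2L])
    inside <- pr >= 1 & pr <= nrow(roi$mask) & pc >= 1 & pc <= ncol(roi$mask)
    inside[inside] <- roi$mask[cbind(pr[inside], pc[inside])]
    if (!all(inside)) {
      warning(sum(!inside), " cluster centroid(s) outside the ROI dropped")
      cen <- cen[inside, , drop = FALSE]
    }
  }
  if (nrow(cen) == 0L) {
    f <- numeric(0)
    counts <- integer(grid$n_bins)
  } else {
    f <- infiltration_fraction(cen, roi, grid$normalization)
    bin <- pmin(floor(f * grid$n_bins) + 1L, grid$n_bins)
    counts <- tabulate(bin, nbins = grid$n_bins)
  }
  structure(
    list(counts = counts, per_deposit_infiltration = f,
         modality = modality, n_bins = grid$n_bins,
         bin_edges = grid$bin_edges, area_per_bin_mm2 = grid$area_mm2),
    class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial profile%s: %d deposits over %d bins\n",
              if (nzchar(x$modality)) paste0(" [", x$modality, "]") else "",
              sum(x$counts), x$n_bins))
  cat("  counts (margin -> core):", paste(x$counts, collapse = " "), "\n")
  invisible(x)
}

#' Compare two radial infiltration profiles (two-sample KS test)
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on the raw per-deposit
#' infiltration fractions of the two profiles (not on the binned counts).
#'
#' @param a,b `radial_profile` objects with at least one deposit each.
#' @return List with `statistic` (D) and `p_value`.
#' @export
compare_profiles <- function(a, b) {
  if (!inherits(a, "radial_profile") || !inherits(b, "radial_profile"))
    stop("'a' and 'b' must be radial_profile objects")
  xa <- a$per_deposit_infiltration
  xb <- b$per_deposit_infiltration
  if (length(xa) == 0L || length(xb) == 0L)
    stop("both profiles must contain at least one deposit")
  kt <- suppressWarnings(stats::ks.test(xa, xb, alternative = "two.sided"))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
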
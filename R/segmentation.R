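# Binary stratification of iron maps and connected-component cluster
# labeling ("Analyze Particles"-style counting of high-iron pixel clusters).

#' Binary high-iron mask from an iron map
#'
#' Stratifies the iron map inside a region of interest into high- and
#' low-iron pixels. The default rule thresholds at the midpoint of the
#' concentration range (`(min + max) / 2` over valid ROI pixels); the
#' alternative rule uses the median of the pixel values. Comparison is
#' strictly greater-than, so a constant map yields an empty mask.
#'
#' @param iron An `iron_map`, or a plain numeric matrix of concentrations.
#' @param roi Logical matrix delimiting the region the threshold is computed
#'   over; `NULL` (default) uses the whole image.
#' @param rule `"range-midpoint"` (default) or `"value-median"`.
#' @return An object of class `binary_mask` with the logical `mask`
#'   (FALSE everywhere outside `roi`), the `roi`, and `threshold_used` (mM).
#' @export
high_iron_mask <- function(iron, roi = NULL,
                           rule = c("range-midpoint", "value-median")) {
  rule <- match.arg(rule)
  if (inherits(iron, "iron_map")) {
    conc <- iron$concentration
    valid <- iron$valid
  } else if (is.matrix(iron) && is.numeric(iron)) {
    conc <- iron
    valid <- is.finite(iron)
  } else stop("'iron' must be an iron_map or a numeric matrix")
  if (is.null(roi)) roi <- matrix(TRUE, nrow(conc), ncol(conc))
  if (!is.logical(roi) || !identical(dim(roi), dim(conc)))
    stop("'roi' must be a logical matrix matching the iron map dimensions")
  sel <- roi & valid & is.finite(conc)
  if (!any(sel))
    stop("ROI is empty or contains no valid iron-map pixels")
  v <- conc[sel]
  thr <- switch(rule,
                "range-midpoint" = (min(v) + max(v)) / 2,
                "value-median" = stats::median(v))
  mask <- sel & conc > thr
  mask[is.na(mask)] <- FALSE
  structure(list(mask = mask, roi = roi, threshold_used = thr, rule = rule),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("Binary mask: %d x %d, %d positive pixels (threshold %.4g)\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$threshold_used))
  invisible(x)
}

# Two-pass union-find connected-component labeling on a logical matrix.
# Raster scan (row-major); final labels are contiguous from 1 in raster
# order of each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  n_lab <- 0L
  find_root <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      nb <- integer(0)
      if (cc > 1L && mask[r, cc - 1L]) nb <- c(nb, lab[r, cc - 1L])
      if (r > 1L && mask[r - 1L, cc]) nb <- c(nb, lab[r - 1L, cc])
      if (connectivity == 8L && r > 1L) {
        if (cc > 1L && mask[r - 1L, cc - 1L]) nb <- c(nb, lab[r - 1L, cc - 1L])
        if (cc < nc && mask[r - 1L, cc + 1L]) nb <- c(nb, lab[r - 1L, cc + 1L])
      }
      if (length(nb) == 0L) {
        n_lab <- n_lab + 1L
        parent[n_lab] <- n_lab
        lab[r, cc] <- n_lab
      } else {
        roots <- unique(vapply(nb, find_root, integer(1)))
        keep <- min(roots)
        lab[r, cc] <- keep
        for (rt in roots) parent[rt] <- keep
      }
    }
  }
  if (n_lab == 0L) return(lab)
  root_of <- vapply(seq_len(n_lab), find_root, integer(1))
  # relabel roots in raster order of first occurrence
  remap <- integer(n_lab)
  nxt <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      l <- lab[r, cc]
      if (l == 0L) next
      rt <- root_of[l]
      if (remap[rt] == 0L) {
        nxt <- nxt + 1L
        remap[rt] <- nxt
      }
      lab[r, cc] <- remap[rt]
    }
  }
  lab
}

#' Label and measure connected high-iron clusters
#'
#' Connected-component labeling of a binary mask under 4- or 8-connectivity,
#' discarding components smaller than `min_size` pixels. Labeling is
#' deterministic: components are numbered 1, 2, ... in raster-scan order of
#' their first pixel.
#'
#' @param mask A `binary_mask` or a logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @param min_size Minimum component area in pixels (default 1).
#' @param pixel_size Optional pixel size `c(row, col)` in mm, used to report
#'   cluster areas in mm^2.
#' @param values Optional numeric matrix (e.g. iron concentrations) whose
#'   per-cluster mean is reported as `mean_value`.
#' @return An object of class `cluster_set`: integer `labels` image
#'   (0 = background) and a `clusters` data frame with columns `id`, `row`,
#'   `col` (centroid, pixels), `area_px`, and optionally `area_mm2` and
#'   `mean_value`.
#' @export
label_clusters <- function(mask, connectivity = 8, min_size = 1,
                           pixel_size = NULL, values = NULL) {
  if (inherits(mask, "binary_mask")) mask <- mask$mask
  if (!is.logical(mask) || !is.matrix(mask))
    stop("'mask' must be a logical matrix or a binary_mask")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("'connectivity' must be 4 or 8")
  if (min_size < 1) stop("'min_size' must be >= 1 pixel")
  lab <- label_components(mask, connectivity)
  n <- max(lab)
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    keep <- which(areas >= min_size)
    if (length(keep) < n) {
      remap <- integer(n)
      remap[keep] <- seq_along(keep)
      lab[lab > 0L] <- remap[lab[lab > 0L]]
      areas <- areas[keep]
    }
    n <- length(keep)
  }
  if (n == 0L) {
    clusters <- data.frame(id = integer(0), row = numeric(0),
                           col = numeric(0), area_px = integer(0))
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    rr <- (idx - 1L) %% nrow(lab) + 1L
    cc <- (idx - 1L) %/% nrow(lab) + 1L
    clusters <- data.frame(
      id = seq_len(n),
      row = as.numeric(tapply(rr, l, mean)),
      col = as.numeric(tapply(cc, l, mean)),
      area_px = as.integer(tabulate(l, nbins = n)))
    if (!is.null(values)) {
      if (!identical(dim(values), dim(mask)))
        stop("'values' must match the mask dimensions")
      clusters$mean_value <- as.numeric(tapply(values[idx], l, mean))
    }
  }
  if (!is.null(pixel_size)) {
    pixel_size <- rep(as.numeric(pixel_size), length.out = 2L)
    clusters$area_mm2 <- clusters$area_px * pixel_size[1L] * pixel_size[2L]
  }
  structure(list(labels = lab, clusters = clusters,
                 connectivity = connectivity, min_size = min_size),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d clusters (connectivity %d, min size %g px)\n",
              nrow(x$clusters), x$connectivity, x$min_size))
  invisible(x)
}

#' Number of clusters in a cluster set
#' @param x A `cluster_set`.
#' @return Integer cluster count.
#' @export
n_clusters <- function(x) {
  stopifnot(inherits(x, "cluster_set"))
  nrow(x$clusters)
}
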
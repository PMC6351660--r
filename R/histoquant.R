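# Histology quantification: Prussian-blue deposit detection on RGB
# brightfield sections, single-channel cell detection on multiplexed IF
# fields, centroid-proximity co-positivity, and fractional populations.

#' RGB brightfield histology image
#'
#' @param rgb Numeric array `[row, col, 3]` of channel values on a 0-255
#'   scale (values in `[0, 1]` are rescaled).
#' @param microns_per_pixel Spatial sampling in um per pixel (> 0).
#' @param stain Stain descriptor; default `"prussian_blue_nfr"` (Prussian
#'   blue iron stain with nuclear-fast-red counter-stain).
#' @return An object of class `histology_image`.
#' @export
histology_image <- function(rgb, microns_per_pixel,
                            stain = "prussian_blue_nfr") {
  if (!is.array(rgb) || length(dim(rgb)) != 3L || dim(rgb)[3L] != 3L)
    stop("'rgb' must be a [row, col, 3] array")
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("'microns_per_pixel' must be positive")
  if (max(rgb) <= 1) rgb <- rgb * 255
  structure(list(rgb = rgb, microns_per_pixel = microns_per_pixel,
                 stain = stain),
            class = "histology_image")
}

#' Prussian-blue positive pixel mask
#'
#' Blue-dominance rule for ferric-iron staining: a pixel is positive iff its
#' blue channel exceeds both the red and the green channel by at least
#' `delta`. The pink nuclear-fast-red counter-stain (red > blue) and
#' unstained tissue are negative. Optional white-balance normalisation
#' rescales each channel so that its 99th percentile maps to 255 before the
#' rule is applied.
#'
#' @param img A [histology_image()].
#' @param delta Minimum blue excess, channel units on the 0-255 scale
#'   (default 30).
#' @param white_balance Logical; apply the per-channel normalisation first.
#' @return A `binary_mask` (threshold slot carries `delta`).
#' @export
pb_positive_mask <- function(img, delta = 30, white_balance = FALSE) {
  if (!inherits(img, "histology_image")) {
    if (is.array(img) && length(dim(img)) == 3L && dim(img)[3L] == 3L)
      img <- histology_image(img, microns_per_pixel = 1)
    else stop("'img' must be a histology_image or an RGB array")
  }
  rgb <- img$rgb
  if (white_balance) {
    for (k in 1:3) {
      q <- stats::quantile(rgb[, , k], 0.99, names = FALSE)
      if (q > 0) rgb[, , k] <- pmin(rgb[, , k] * 255 / q, 255)
    }
  }
  d <- dim(rgb)
  r <- matrix(rgb[, , 1L], d[1L], d[2L])
  g <- matrix(rgb[, , 2L], d[1L], d[2L])
  b <- matrix(rgb[, , 3L], d[1L], d[2L])
  mask <- (b - r >= delta) & (b - g >= delta)
  structure(list(mask = mask,
                 roi = matrix(TRUE, nrow(mask), ncol(mask)),
                 threshold_used = delta, rule = "blue-dominance"),
            class = "binary_mask")
}

#' Count Prussian-blue deposits in a positivity mask
#'
#' Connected-component counting of stain-positive pixels with a physical
#' minimum deposit area; thin wrapper over [label_clusters()] reporting
#' areas in um^2.
#'
#' @param mask A `binary_mask` (e.g. from [pb_positive_mask()]) or logical
#'   matrix.
#' @param microns_per_pixel Spatial sampling in um per pixel.
#' @param min_area Minimum deposit area in um^2 (default 20).
#' @param connectivity Neighbour connectivity, 4 or 8 (default 8).
#' @return A `cluster_set`; the `clusters` table gains an `area_um2` column.
#' @export
count_pb_deposits <- function(mask, microns_per_pixel, min_area = 20,
                              connectivity = 8) {
  if (!is.numeric(microns_per_pixel) || microns_per_pixel <= 0)
    stop("'microns_per_pixel' must be positive")
  px_area <- microns_per_pixel^2
  min_size <- max(1L, ceiling(min_area / px_area))
  cs <- label_clusters(mask, connectivity = connectivity,
                       min_size = min_size)
  cs$clusters$area_um2 <- cs$clusters$area_px * px_area
  cs
}

#' Detect cells on a single fluorescence channel
#'
#' Intensity threshold, connected-component labeling and a physical size
#' filter; returns centroids in micron coordinates.
#'
#' @param channel Numeric intensity matrix (single channel).
#' @param threshold Intensity above which pixels count as signal.
#' @param min_area Minimum object area in um^2 (default 25).
#' @param microns_per_pixel Spatial sampling in um per pixel.
#' @return Data frame with columns `x_um`, `y_um` (centroid: x along
#'   columns, y along rows), `row`, `col` (pixels) and `area_um2`; zero rows
#'   when nothing is detected.
#' @export
detect_cells_channel <- function(channel, threshold, min_area = 25,
                                 microns_per_pixel = 1) {
  if (!is.matrix(channel) || !is.numeric(channel))
    stop("'channel' must be a numeric matrix")
  px_area <- microns_per_pixel^2
  min_size <- max(1L, ceiling(min_area / px_area))
  cs <- label_clusters(channel > threshold, connectivity = 8,
                       min_size = min_size)
  cl <- cs$clusters
  data.frame(x_um = cl$col * microns_per_pixel,
             y_um = cl$row * microns_per_pixel,
             row = cl$row, col = cl$col,
             area_um2 = cl$area_px * px_area)
}

# Greedy one-to-one matching of two centroid sets within 'radius' um.
# Candidate pairs are ordered by distance, then by raster order of the
# first set, then of the second; each object is used at most once.
# Returns a logical vector: which rows of 'from' found a partner.
greedy_match <- function(from, to, radius) {
  nf <- nrow(from); nt <- nrow(to)
  if (nf == 0L || nt == 0L) return(rep(FALSE, nf))
  dx <- outer(from$x_um, to$x_um, "-")
  dy <- outer(from$y_um, to$y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(rep(FALSE, nf))
  o <- order(d[cand], cand[, 1L], cand[, 2L])
  cand <- cand[o, , drop = FALSE]
  used_f <- rep(FALSE, nf); used_t <- rep(FALSE, nt)
  for (i in seq_len(nrow(cand))) {
    a <- cand[i, 1L]; b <- cand[i, 2L]
    if (!used_f[a] && !used_t[b]) {
      used_f[a] <- TRUE
      used_t[b] <- TRUE
    }
  }
  used_f
}

#' Exhaustive co-positivity counts of iron-positive cells
#'
#' Matches each iron-positive object to the AIF1, CD206 and CSF1R channels
#' by greedy nearest-neighbour centroid proximity (one-to-one within
#' `radius`), then tabulates the exhaustive marker combinations of the
#' iron-positive cells. Combination categories are exclusive:
#' `iron_AIF1` counts iron+AIF1+CD206- cells, `iron_CD206` counts
#' iron+CD206+AIF1- cells and `iron_AIF1_CD206` the double positives, so the
#' three categories partition the iron+ cells carrying at least one
#' polarization marker (and analogously for the CSF1R-positive triplet).
#'
#' @param centroids_by_marker Named list of centroid data frames (as
#'   returned by [detect_cells_channel()], needing columns `x_um`, `y_um`)
#'   with entries `iron`, `AIF1`, `CD206` and `CSF1R`.
#' @param radius Matching radius in um (default 10, about one cell
#'   diameter).
#' @return An object of class `copositivity_table`: named integer counts
#'   `n_AIF1`, `n_CD206`, `n_CSF1R`, `n_iron`, `iron_AIF1`, `iron_CD206`,
#'   `iron_AIF1_CD206`, `iron_CSF1R_AIF1`, `iron_CSF1R_CD206`,
#'   `iron_CSF1R_AIF1_CD206`.
#' @export
match_copositive <- function(centroids_by_marker, radius = 10) {
  need <- c("iron", "AIF1", "CD206", "CSF1R")
  if (!all(need %in% names(centroids_by_marker)))
    stop("'centroids_by_marker' must contain entries: ",
         paste(need, collapse = ", "))
  if (!is.numeric(radius) || radius <= 0) stop("'radius' must be > 0")
  iron <- centroids_by_marker$iron
  markers <- c("AIF1", "CD206", "CSF1R")
  pos <- matrix(FALSE, nrow(iron), 3L, dimnames = list(NULL, markers))
  for (m in markers)
    pos[, m] <- greedy_match(iron, centroids_by_marker[[m]], radius)
  a <- pos[, "AIF1"]; c2 <- pos[, "CD206"]; s <- pos[, "CSF1R"]
  counts <- c(
    n_AIF1 = nrow(centroids_by_marker$AIF1),
    n_CD206 = nrow(centroids_by_marker$CD206),
    n_CSF1R = nrow(centroids_by_marker$CSF1R),
    n_iron = nrow(iron),
    iron_AIF1 = sum(a & !c2),
    iron_CD206 = sum(c2 & !a),
    iron_AIF1_CD206 = sum(a & c2),
    iron_CSF1R_AIF1 = sum(s & a & !c2),
    iron_CSF1R_CD206 = sum(s & c2 & !a),
    iron_CSF1R_AIF1_CD206 = sum(s & a & c2))
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "copositivity_table")
}

#' @export
print.copositivity_table <- function(x, ...) {
  cat("Co-positivity counts:\n")
  for (nm in names(unclass(x))) cat(sprintf("  %-22s %d\n", nm, x[[nm]]))
  invisible(x)
}

#' Fractional macrophage populations from co-positivity counts
#'
#' Polarization triplet: each of iron+AIF1+, iron+CD206+ and
#' iron+AIF1+CD206+ divided by their sum. CSF1R triplet: each of
#' iron+CSF1R+AIF1+, iron+CSF1R+CD206+ and iron+CSF1R+AIF1+CD206+ divided by
#' their sum. A zero denominator leaves the corresponding triplet undefined
#' (`NA`), not zero.
#'
#' @param t A `copositivity_table` from [match_copositive()].
#' @return An object of class `fractional_populations` with elements
#'   `polarization` (named fractions `AIF1`, `CD206`, `AIF1_CD206`),
#'   `csf1r` (named fractions over the CSF1R+ triplet) and the two
#'   denominators.
#' @export
fractional_populations <- function(t) {
  if (!inherits(t, "copositivity_table"))
    stop("'t' must be a copositivity_table")
  tri <- c(t$iron_AIF1, t$iron_CD206, t$iron_AIF1_CD206)
  den1 <- sum(tri)
  pol <- if (den1 > 0) tri / den1 else rep(NA_real_, 3L)
  names(pol) <- c("AIF1", "CD206", "AIF1_CD206")
  tri2 <- c(t$iron_CSF1R_AIF1, t$iron_CSF1R_CD206, t$iron_CSF1R_AIF1_CD206)
  den2 <- sum(tri2)
  csf <- if (den2 > 0) tri2 / den2 else rep(NA_real_, 3L)
  names(csf) <- c("CSF1R_AIF1", "CSF1R_CD206", "CSF1R_AIF1_CD206")
  structure(list(polarization = pol, csf1r = csf,
                 denominator_polarization = den1,
                 denominator_csf1r = den2),
            class = "fractional_populations")
}

#' @export
print.fractional_populations <- function(x, ...) {
  cat("Fractional populations (polarization triplet, n =",
      x$denominator_polarization, "):\n")
  print(round(x$polarization, 3))
  cat("CSF1R+ triplet (n =", x$denominator_csf1r, "):\n")
  print(round(x$csf1r, 3))
  invisible(x)
}
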
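# End-to-end convenience wrappers: raw rendering -> cluster counts and
# radial infiltration profiles, for each imaging modality.

#' FeMRI analysis of an MGE rendering or stack
#'
#' Full iron-MRI pipeline: pixel-wise T2* fitting, calibration to an iron
#' map, tumor ROI segmentation from the first-echo image, binary
#' stratification at the concentration-range midpoint inside the ROI, and
#' connected-cluster counting.
#'
#' @param x An `mge_render` (from [render_mge()]) or an [mge_stack()].
#' @param cal Iron calibration; defaults to the rendering's own calibration
#'   when `x` is an `mge_render`.
#' @param noise_floor Echo-train truncation floor; defaults to three times
#'   the rendering's noise SD.
#' @param rule Threshold rule for [high_iron_mask()].
#' @param connectivity,min_size Cluster labeling parameters.
#' @param roi Optional [tumor_roi()] to use instead of automatic
#'   segmentation.
#' @return List with `count`, `clusters` (a `cluster_set`), `iron`
#'   (the `iron_map`), `roi` and `mask`.
#' @export
analyze_femri <- function(x, cal = NULL, noise_floor = NULL,
                          rule = "range-midpoint", connectivity = 8,
                          min_size = 1, roi = NULL) {
  if (inherits(x, "mge_render")) {
    if (is.null(cal)) cal <- x$calibration
    if (is.null(noise_floor)) noise_floor <- 3 * x$noise$sigma * x$s0
    stack <- x$stack
  } else if (inherits(x, "mge_stack")) {
    stack <- x
    if (is.null(cal)) stop("'cal' is required for a plain mge_stack")
    if (is.null(noise_floor)) noise_floor <- 0
  } else stop("'x' must be an mge_render or an mge_stack")
  rmap <- fit_t2star_map(stack, noise_floor = noise_floor)
  iron <- apply_calibration(rmap, cal)
  if (is.null(roi))
    roi <- segment_tumor_roi(matrix(stack$data[1L, , ],
                                    dim(stack$data)[2L], dim(stack$data)[3L]),
                             pixel_size = stack$params$pixel_size)
  hi <- high_iron_mask(iron, roi = roi$mask, rule = rule)
  cs <- label_clusters(hi, connectivity = connectivity, min_size = min_size,
                       pixel_size = stack$params$pixel_size,
                       values = iron$concentration)
  list(count = n_clusters(cs), clusters = cs, iron = iron, roi = roi,
       mask = hi)
}

#' Prussian-blue analysis of a histology rendering or image
#'
#' Blue-dominance positivity masking followed by deposit counting, plus
#' tumor ROI segmentation from the inverted green channel (tissue and
#' deposits are darker in green than the slide background).
#'
#' @param x A `pb_render` (from [render_pb_histology()]) or a
#'   [histology_image()].
#' @param delta Blue-dominance margin for [pb_positive_mask()].
#' @param min_area Minimum deposit area in um^2.
#' @param segment_roi Logical; also segment the tumor ROI (default TRUE).
#' @return List with `count`, `clusters`, `mask` and (optionally) `roi`.
#' @export
analyze_pb <- function(x, delta = 30, min_area = 20, segment_roi = TRUE) {
  img <- if (inherits(x, "pb_render")) x$image
  else if (inherits(x, "histology_image")) x
  else stop("'x' must be a pb_render or a histology_image")
  mask <- pb_positive_mask(img, delta = delta)
  cs <- count_pb_deposits(mask, img$microns_per_pixel, min_area = min_area)
  out <- list(count = n_clusters(cs), clusters = cs, mask = mask)
  if (segment_roi) {
    mm <- img$microns_per_pixel / 1000
    out$roi <- segment_tumor_roi(255 - img$rgb[, , 2L],
                                 pixel_size = c(mm, mm))
  }
  out
}

#' Radial infiltration profile from a modality analysis
#'
#' @param analysis Result of [analyze_femri()] or [analyze_pb()] (must
#'   contain `clusters` and `roi`).
#' @param n_bins Number of infiltration deciles (default 10).
#' @param modality Tag stored on the profile.
#' @return A `radial_profile`.
#' @export
profile_analysis <- function(analysis, n_bins = 10, modality = "") {
  if (is.null(analysis$roi))
    stop("analysis carries no ROI; rerun with ROI segmentation enabled")
  grid <- make_radial_grid(analysis$roi, n_bins = n_bins)
  suppressWarnings(
    infiltration_profile(analysis$clusters, grid, analysis$roi,
                         modality = modality))
}

#' Quantify a rendered immunofluorescence field
#'
#' Runs channel-wise cell detection on the AIF1, CD206, CSF1R and
#' registered PB channels of an [render_if_field()] output and tabulates
#' iron co-positivity.
#'
#' @param field An `if_field`.
#' @param threshold Detection intensity threshold (channels are rendered on
#'   a 0-255-like scale; default 100).
#' @param min_area Minimum cell area in um^2.
#' @param radius Co-positivity matching radius in um.
#' @return A `copositivity_table`.
#' @export
quantify_if_field <- function(field, threshold = 100, min_area = 25,
                              radius = 10) {
  if (!inherits(field, "if_field")) stop("'field' must be an if_field")
  det <- function(ch) detect_cells_channel(
    ch, threshold = threshold, min_area = min_area,
    microns_per_pixel = field$microns_per_pixel)
  match_copositive(
    list(iron = det(field$channels$PB),
         AIF1 = det(field$channels$AIF1),
         CD206 = det(field$channels$CD206),
         CSF1R = det(field$channels$CSF1R)),
    radius = radius)
}
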
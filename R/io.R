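# Readers and writers for the standard interchange formats: NIfTI and
# multi-page TIFF stacks with a JSON sidecar for echo metadata, CSV tables
# for clusters/profiles, JSON for calibrations and test results.

read_sidecar <- function(path) {
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(meta$echo_times_ms))
    stop("sidecar '", path, "' lacks 'echo_times_ms'")
  acquisition_params(
    echo_times = meta$echo_times_ms,
    repetition_time = meta$repetition_time_ms %||% 1200,
    flip_angle = meta$flip_angle_deg %||% 60,
    pixel_size = meta$pixel_size_mm %||% c(0.1, 0.1),
    slice_thickness = meta$slice_thickness_mm %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a multi-gradient-echo stack from NIfTI or multi-page TIFF
#'
#' NIfTI input carries the echo train on the 4th axis; multi-page TIFF
#' carries one echo per page. Echo times and geometry come from a JSON
#' sidecar (fields `echo_times_ms`, optional `repetition_time_ms`,
#' `flip_angle_deg`, `pixel_size_mm`, `slice_thickness_mm`) or an explicit
#' [acquisition_params()].
#'
#' @param path Image file (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @param params An [acquisition_params()]; if `NULL`, read from `sidecar`.
#' @param sidecar Path to the JSON sidecar; defaults to `path` with its
#'   extension replaced by `.json`.
#' @return An [mge_stack()].
#' @export
read_mge_stack <- function(path, params = NULL, sidecar = NULL) {
  if (is.null(params)) {
    if (is.null(sidecar))
      sidecar <- paste0(sub("\\.(nii\\.gz|nii|tiff?|png)$", "", path),
                        ".json")
    params <- read_sidecar(sidecar)
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 4L && dim(arr)[3L] == 1L)
      arr <- arr[, , 1L, , drop = TRUE]
    if (length(dim(arr)) != 3L)
      stop("expected a row x col x echo NIfTI volume")
    dat <- aperm(arr, c(3L, 1L, 2L))
  } else if (grepl("\\.tiff?$", path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dat <- array(0, dim = c(length(pages), nrow(pages[[1L]]),
                            ncol(pages[[1L]])))
    for (j in seq_along(pages)) dat[j, , ] <- pages[[j]]
  } else stop("unsupported stack format: ", path)
  mge_stack(dat, params)
}

#' Write an MGE stack as NIfTI plus JSON sidecar
#'
#' @param stack An [mge_stack()].
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly (the sidecar lands next to it).
#' @export
write_mge_stack <- function(stack, path) {
  stopifnot(inherits(stack, "mge_stack"))
  arr <- aperm(stack$data, c(2L, 3L, 1L))
  dim(arr) <- c(dim(arr)[1:2], 1L, dim(arr)[3L])
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  p <- stack$params
  jsonlite::write_json(
    list(echo_times_ms = p$echo_times,
         repetition_time_ms = p$repetition_time,
         flip_angle_deg = p$flip_angle,
         pixel_size_mm = p$pixel_size,
         slice_thickness_mm = p$slice_thickness),
    paste0(sub("\\.(nii\\.gz|nii)$", "", path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an iron map (or any per-pixel matrix) as single-plane NIfTI
#'
#' @param map An `iron_map`, `relaxometry_map` (its `r2star` plane) or a
#'   numeric matrix.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(map, path) {
  m <- if (inherits(map, "iron_map")) {
    x <- map$concentration
    x[!map$valid] <- NA_real_
    x
  } else if (inherits(map, "relaxometry_map")) map$r2star
  else map
  RNifti::writeNifti(RNifti::asNifti(m), path)
  invisible(path)
}

#' Read a single-plane NIfTI map as a matrix
#' @param path NIfTI file.
#' @return Numeric matrix.
#' @export
read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  matrix(arr, dim(arr)[1L], dim(arr)[2L])
}

#' Write a binary mask or label image as TIFF
#'
#' Binary masks are written as 0/1; label images are scaled by their
#' maximum label (8-bit TIFF is a visualisation format here, the CSV tables
#' carry the quantitative output).
#' @param x A `binary_mask`, logical matrix or integer label matrix.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(x, path) {
  if (inherits(x, "binary_mask")) x <- x$mask
  m <- if (is.logical(x)) x * 1 else x / max(1, max(x))
  tiff::writeTIFF(m, path)
  invisible(path)
}

#' Write a cluster table as CSV
#'
#' Columns `id, row, col, area_px` plus `area_mm2` / `area_um2` /
#' `mean_conc_mM` when available.
#' @param cs A `cluster_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clusters_csv <- function(cs, path) {
  stopifnot(inherits(cs, "cluster_set"))
  tab <- cs$clusters
  if (!is.null(tab$mean_value)) {
    tab$mean_conc_mM <- tab$mean_value
    tab$mean_value <- NULL
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a radial profile as CSV
#'
#' Columns `bin, lo_pct, hi_pct, count, area_mm2` (percent infiltration
#' edges from margin to core).
#' @param profile A `radial_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  nb <- profile$n_bins
  tab <- data.frame(bin = seq_len(nb),
                    lo_pct = 100 * profile$bin_edges[-(nb + 1L)],
                    hi_pct = 100 * profile$bin_edges[-1L],
                    count = profile$counts,
                    area_mm2 = profile$area_per_bin_mm2)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an iron calibration as JSON
#'
#' @param cal An `iron_calibration`.
#' @param path JSON path.
#' @return `path` (write) or the reconstructed `iron_calibration` (read),
#'   invisibly for the writer.
#' @export
write_calibration_json <- function(cal, path) {
  stopifnot(inherits(cal, "iron_calibration"))
  jsonlite::write_json(
    list(slope = cal$slope, intercept = cal$intercept,
         r_squared = cal$r_squared, standards = cal$standards),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = j$slope, intercept = j$intercept,
                 r_squared = j$r_squared,
                 standards = as.data.frame(j$standards)),
            class = "iron_calibration")
}

#' Read an RGB histology image (TIFF or PNG)
#'
#' @param path Image path.
#' @param microns_per_pixel Spatial sampling in um per pixel.
#' @return A [histology_image()].
#' @export
read_histology_image <- function(path, microns_per_pixel) {
  arr <- if (grepl("\\.png$", path)) png::readPNG(path)
  else tiff::readTIFF(path)
  if (length(dim(arr)) != 3L || dim(arr)[3L] < 3L)
    stop("expected an RGB image: ", path)
  histology_image(arr[, , 1:3, drop = FALSE] * 255, microns_per_pixel)
}

#' Write an RGB histology image as TIFF or PNG
#' @param img A [histology_image()].
#' @param path Output path (`.tif` or `.png`).
#' @return `path`, invisibly.
#' @export
write_histology_image <- function(img, path) {
  stopifnot(inherits(img, "histology_image"))
  arr <- pmin(pmax(img$rgb / 255, 0), 1)
  if (grepl("\\.png$", path)) png::writePNG(arr, path)
  else tiff::writeTIFF(arr, path)
  invisible(path)
}
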
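# Seeded synthetic ground truth: tumor cross-sections with margin-decaying
# iron deposit fields, paired MGE / Prussian-blue / immunofluorescence
# renderings, and control-vs-treated cohorts.
#
# Every generator is a pure function of (configuration, seed); passing
# seed = NULL continues from the current RNG state, which is how
# simulate_cohort() derives per-animal randomness from a single seed.

#' Tumor cross-section geometry for synthetic phantoms
#'
#' A star-shaped region described in polar form about its center:
#' `R(theta) = radius_mm * (1 + sum_j amp[j] * cos(harmonics[j] * theta +
#' phase[j]))`. A disc has no harmonics; a smooth "blob" perturbs the disc
#' with low-order harmonics.
#'
#' @param radius_mm Mean radius in mm.
#' @param amp,harmonics,phase Equal-length vectors of harmonic amplitudes
#'   (each < 0.5 in total), integer orders and phases.
#' @return An object of class `roi_geometry`.
#' @export
roi_geometry <- function(radius_mm = 2, amp = numeric(0),
                         harmonics = integer(0), phase = numeric(0)) {
  if (radius_mm <= 0) stop("'radius_mm' must be positive")
  if (length(amp) != length(harmonics) || length(amp) != length(phase))
    stop("'amp', 'harmonics' and 'phase' must have equal length")
  if (sum(abs(amp)) >= 0.5)
    stop("total harmonic amplitude must stay below 0.5")
  structure(list(radius_mm = radius_mm, amp = amp,
                 harmonics = as.integer(harmonics), phase = phase),
            class = "roi_geometry")
}

#' Random smooth-blob geometry
#'
#' @param radius_mm Mean radius in mm.
#' @param roughness Total harmonic amplitude (default 0.12).
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#' @return An `roi_geometry` with random order-2..4 harmonics.
#' @export
random_blob_geometry <- function(radius_mm = 2, roughness = 0.12,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  k <- 2:4
  a <- stats::runif(3)
  a <- roughness * a / sum(a)
  roi_geometry(radius_mm, amp = a, harmonics = k,
               phase = stats::runif(3, 0, 2 * pi))
}

# Polar radius of the geometry at angle theta (vectorised).
geometry_radius <- function(geom, theta) {
  r <- rep(geom$radius_mm, length(theta))
  for (j in seq_along(geom$amp))
    r <- r + geom$radius_mm * geom$amp[j] *
      cos(geom$harmonics[j] * theta + geom$phase[j])
  r
}

#' Area of a synthetic ROI geometry (mm^2)
#' @param geom An `roi_geometry`.
#' @return Cross-section area in mm^2 (polar quadrature).
#' @export
geometry_area <- function(geom) {
  th <- seq(0, 2 * pi, length.out = 4097L)[-1L]
  mean(geometry_radius(geom, th)^2) * pi
}

#' Sample a margin-decaying iron deposit field
#'
#' Inhomogeneous Poisson placement of deposits over the tumor cross-section
#' with intensity `lambda(f) = lambda0 * exp(-f / tau)`, where `f` is the
#' infiltration fraction (0 at the margin, 1 at the center) -- deposits
#' concentrate at the stromal margin and thin out toward the core.
#' Implemented by thinning a homogeneous Poisson field of intensity
#' `lambda0`. Deposit radii are gamma distributed, iron concentrations
#' lognormal, and the three macrophage marker states are independent
#' Bernoulli draws per deposit.
#'
#' @param geometry An [roi_geometry()].
#' @param lambda0 Margin-level deposit intensity, deposits per mm^2 (> 0).
#' @param tau Infiltration decay scale of the density, in infiltration
#'   fraction units (> 0); large `tau` approaches a uniform field.
#' @param marker_probs Named probabilities `c(AIF1=, CD206=, CSF1R=)` of
#'   each marker being positive on a deposit.
#' @param size_shape,size_scale Gamma shape/scale of deposit radii in um
#'   (default mean 4 * 12.5 = 50 um).
#' @param conc_meanlog,conc_sdlog Lognormal parameters of deposit iron
#'   concentration in mM (default median 2 mM).
#' @param background_t2star Background tissue T2* in ms.
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#' @return An object of class `synthetic_truth` with the `geometry`, the
#'   `deposits` data frame (`x_mm`, `y_mm` about the center, exact
#'   infiltration fraction `f`, `radius_um`, `conc_mM`, `AIF1`, `CD206`,
#'   `CSF1R`), the density parameters and `area_mm2`.
#' @export
sample_deposits <- function(geometry, lambda0 = 2, tau = 0.25,
                            marker_probs = c(AIF1 = 0.55, CD206 = 0.6,
                                             CSF1R = 0.7),
                            size_shape = 4, size_scale = 12.5,
                            conc_meanlog = log(2), conc_sdlog = 0.15,
                            background_t2star = 50, seed = NULL) {
  if (!inherits(geometry, "roi_geometry"))
    stop("'geometry' must be an roi_geometry")
  if (lambda0 <= 0) stop("'lambda0' must be > 0")
  if (tau <= 0) stop("'tau' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  area <- geometry_area(geometry)
  n0 <- stats::rpois(1L, lambda0 * area)
  rmax <- geometry$radius_mm * (1 + sum(abs(geometry$amp)))
  xs <- numeric(0); ys <- numeric(0); fs <- numeric(0)
  got <- 0L
  while (got < n0) {
    m <- max(4L * (n0 - got), 16L)
    x <- stats::runif(m, -rmax, rmax)
    y <- stats::runif(m, -rmax, rmax)
    r <- sqrt(x^2 + y^2)
    th <- atan2(y, x)
    R <- geometry_radius(geometry, th)
    ok <- r <= R
    take <- which(ok)[seq_len(min(sum(ok), n0 - got))]
    xs <- c(xs, x[take]); ys <- c(ys, y[take])
    fs <- c(fs, 1 - r[take] / R[take])
    got <- got + length(take)
  }
  keep <- stats::runif(n0) < exp(-fs / tau)
  n <- sum(keep)
  deposits <- data.frame(
    x_mm = xs[keep], y_mm = ys[keep], f = fs[keep],
    radius_um = stats::rgamma(n, shape = size_shape, scale = size_scale),
    conc_mM = stats::rlnorm(n, conc_meanlog, conc_sdlog),
    AIF1 = stats::runif(n) < marker_probs[["AIF1"]],
    CD206 = stats::runif(n) < marker_probs[["CD206"]],
    CSF1R = stats::runif(n) < marker_probs[["CSF1R"]])
  structure(
    list(geometry = geometry, deposits = deposits, lambda0 = lambda0,
         tau = tau, marker_probs = marker_probs,
         background_t2star = background_t2star, area_mm2 = area,
         seed = seed),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "Synthetic truth: %d deposits over %.3g mm^2 (lambda0 %.3g /mm^2, tau %.3g)\n",
    nrow(x$deposits), x$area_mm2, x$lambda0, x$tau))
  invisible(x)
}

#' Synthetic iron calibration standards
#'
#' Table of aqueous-standard measurements following an exact linear
#' `R2* = slope * concentration + intercept` relation, optionally with
#' Gaussian measurement noise on R2*.
#'
#' @param concentrations Standard concentrations in mM.
#' @param slope,intercept True line (s^-1 per mM, s^-1).
#' @param sigma Gaussian noise SD on R2* in s^-1 (default 0, exact).
#' @param seed Optional integer seed.
#' @return Data frame with columns `concentration` and `r2star`.
#' @export
synthetic_iron_standards <- function(concentrations = seq(0, 2.5, by = 0.5),
                                     slope = 30, intercept = 20,
                                     sigma = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r2 <- intercept + slope * concentrations
  if (sigma > 0) r2 <- r2 + stats::rnorm(length(r2), 0, sigma)
  data.frame(concentration = concentrations, r2star = r2)
}

#' Default synthetic iron calibration
#'
#' Calibration fitted to the noiseless default standards (slope 30 s^-1/mM,
#' intercept 20 s^-1, the baseline tissue relaxation rate).
#' @return An `iron_calibration`.
#' @export
default_iron_calibration <- function() {
  fit_iron_calibration(synthetic_iron_standards())
}

# Pixel raster covering the geometry plus a margin. Returns pixel-center
# coordinates (x along columns, y along rows) and the ROI mask.
raster_grid <- function(geometry, pixel_mm, margin_mm = 0.4) {
  rmax <- geometry$radius_mm * (1 + sum(abs(geometry$amp))) + margin_mm
  half <- ceiling(rmax / pixel_mm)
  coords <- (seq_len(2L * half + 1L) - half - 1L) * pixel_mm
  xg <- matrix(coords, 2L * half + 1L, 2L * half + 1L, byrow = TRUE)
  yg <- matrix(coords, 2L * half + 1L, 2L * half + 1L)
  r <- sqrt(xg^2 + yg^2)
  th <- atan2(yg, xg)
  mask <- r <= geometry_radius(geometry, th)
  list(x = xg, y = yg, coords = coords, mask = mask, pixel_mm = pixel_mm)
}

# Paint per-pixel deposit concentration onto a raster grid. Each deposit
# marks the pixels whose centers fall within its radius and always at least
# its nearest pixel; overlaps keep the larger concentration.
paint_deposits <- function(grid, deposits, value = deposits$conc_mM) {
  img <- matrix(0, nrow(grid$x), ncol(grid$x))
  if (nrow(deposits) == 0L) return(img)
  pix <- grid$pixel_mm
  coords <- grid$coords
  n_side <- length(coords)
  for (i in seq_len(nrow(deposits))) {
    x <- deposits$x_mm[i]; y <- deposits$y_mm[i]
    rad <- deposits$radius_um[i] / 1000
    ci <- which.min(abs(coords - x))
    ri <- which.min(abs(coords - y))
    w <- ceiling(rad / pix) + 1L
    rs <- max(1L, ri - w):min(n_side, ri + w)
    cs <- max(1L, ci - w):min(n_side, ci + w)
    dx <- matrix(coords[cs] - x, length(rs), length(cs), byrow = TRUE)
    dy <- matrix(coords[rs] - y, length(rs), length(cs))
    hit <- dx^2 + dy^2 <= rad^2
    hit[ri - rs[1L] + 1L, ci - cs[1L] + 1L] <- TRUE  # nearest pixel always
    img[rs, cs][hit] <- pmax(img[rs, cs][hit], value[i])
  }
  img
}

#' Render a multi-gradient-echo stack from a synthetic truth
#'
#' Forward model of the iron-MRI pipeline: per-pixel R2* is
#' `intercept + slope * concentration` on deposit pixels and
#' `1000 / background_t2star` on the remaining tumor tissue; the signal at
#' each echo follows the monoexponential decay with amplitude `s0`, is zero
#' outside the tumor, and receives additive Gaussian or Rician magnitude
#' noise.
#'
#' @param truth A [sample_deposits()] ground truth.
#' @param cal An `iron_calibration` (default [default_iron_calibration()]).
#' @param acq An [acquisition_params()]; the first pixel-size component sets
#'   the raster spacing.
#' @param noise List with `model` (`"gaussian"` or `"rician"`) and `sigma`
#'   (SD as a fraction of `s0`).
#' @param s0 Signal amplitude at TE = 0.
#' @param margin_mm Dark margin around the tumor in mm.
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#' @return An object of class `mge_render`: the `stack` (an [mge_stack()]),
#'   `truth_conc` (planted per-pixel concentration), `roi_mask`, the raster
#'   `coords` (mm, pixel centers) and the `truth`.
#' @export
render_mge <- function(truth, cal = default_iron_calibration(),
                       acq = acquisition_params(pixel_size = c(0.05, 0.05)),
                       noise = list(model = "gaussian", sigma = 0.02),
                       s0 = 1000, margin_mm = 0.4, seed = NULL) {
  if (!inherits(truth, "synthetic_truth"))
    stop("'truth' must be a synthetic_truth")
  if (!is.null(seed)) set.seed(seed)
  grid <- raster_grid(truth$geometry, acq$pixel_size[1L], margin_mm)
  conc <- paint_deposits(grid, truth$deposits)
  conc[!grid$mask] <- 0
  r2 <- matrix(1000 / truth$background_t2star, nrow(conc), ncol(conc))
  dep <- conc > 0
  r2[dep] <- cal$intercept + cal$slope * conc[dep]
  te <- acq$echo_times
  ne <- length(te)
  nr <- nrow(conc); nc <- ncol(conc)
  dat <- array(0, dim = c(ne, nr, nc))
  for (j in seq_len(ne)) {
    plane <- s0 * exp(-te[j] * r2 / 1000)
    plane[!grid$mask] <- 0
    dat[j, , ] <- plane
  }
  sg <- noise$sigma * s0
  if (sg > 0) {
    n <- length(dat)
    if (identical(noise$model, "rician")) {
      dat <- sqrt((dat + stats::rnorm(n, 0, sg))^2 +
                    stats::rnorm(n, 0, sg)^2)
    } else {
      dat <- dat + stats::rnorm(n, 0, sg)
      dim(dat) <- c(ne, nr, nc)
    }
    dim(dat) <- c(ne, nr, nc)
  }
  structure(
    list(stack = mge_stack(dat, acq), truth_conc = conc,
         roi_mask = grid$mask, coords = grid$coords, truth = truth,
         calibration = cal, noise = noise, s0 = s0),
    class = "mge_render")
}

#' Render Prussian-blue histology from a synthetic truth
#'
#' Pre-registered histological twin of [render_mge()]: the same deposit
#' coordinates are rendered as blue blobs over a pink nuclear-fast-red
#' tissue background (white outside the cross-section), with Gaussian
#' texture noise on all channels.
#'
#' @param truth A [sample_deposits()] ground truth.
#' @param microns_per_pixel Rendering resolution in um per pixel.
#' @param margin_mm White margin around the section in mm.
#' @param noise_sd Channel noise SD (0-255 scale).
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#' @return An object of class `pb_render`: the `image`
#'   (a [histology_image()]), `roi_mask`, raster `coords` (mm) and `truth`.
#' @export
render_pb_histology <- function(truth, microns_per_pixel = 8,
                                margin_mm = 0.4, noise_sd = 6,
                                seed = NULL) {
  if (!inherits(truth, "synthetic_truth"))
    stop("'truth' must be a synthetic_truth")
  if (!is.null(seed)) set.seed(seed)
  grid <- raster_grid(truth$geometry, microns_per_pixel / 1000, margin_mm)
  nr <- nrow(grid$mask); nc <- ncol(grid$mask)
  dep <- paint_deposits(grid, truth$deposits) > 0
  dep[!grid$mask] <- FALSE
  rgb <- array(0, dim = c(nr, nc, 3L))
  base <- list(bg = c(246, 245, 244), tissue = c(231, 151, 172),
               deposit = c(45, 65, 178))
  for (k in 1:3) {
    ch <- matrix(base$bg[k], nr, nc)
    ch[grid$mask] <- base$tissue[k]
    ch[dep] <- base$deposit[k]
    ch <- ch + stats::rnorm(nr * nc, 0, noise_sd)
    rgb[, , k] <- pmin(pmax(ch, 0), 255)
  }
  structure(
    list(image = histology_image(rgb, microns_per_pixel),
         roi_mask = grid$mask, coords = grid$coords, truth = truth),
    class = "pb_render")
}

#' Render a multiplexed immunofluorescence field
#'
#' Square field centered on an iron deposit, populated with cells whose
#' marker states are independent Bernoulli draws; each channel (AIF1,
#' CD206, CSF1R, DAPI, and the registered Prussian-blue channel `PB`)
#' shows a bright disc for every cell positive for that marker over a dim
#' noisy background. The central cell is always iron positive.
#'
#' @param marker_probs Named probabilities `c(AIF1=, CD206=, CSF1R=)`.
#' @param p_iron Probability that a non-central cell is iron positive.
#' @param n_cells_mean Poisson mean of the cell count (min 1).
#' @param field_size Field edge length in um (default 200).
#' @param microns_per_pixel Rendering resolution (default 2).
#' @param cell_radius_um Cell disc radius in um.
#' @param min_separation_um Minimum distance between cell centers.
#' @param intensity,background Foreground/background channel levels.
#' @param noise_sd Channel Gaussian noise SD.
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#' @return An object of class `if_field`: named `channels` (matrices
#'   `AIF1`, `CD206`, `CSF1R`, `DAPI`, `PB`), `microns_per_pixel`,
#'   `field_size` and the per-cell `truth` data frame.
#' @export
render_if_field <- function(marker_probs = c(AIF1 = 0.55, CD206 = 0.6,
                                             CSF1R = 0.7),
                            p_iron = 0.8, n_cells_mean = 12,
                            field_size = 200, microns_per_pixel = 2,
                            cell_radius_um = 5, min_separation_um = 15,
                            intensity = 200, background = 10,
                            noise_sd = 5, seed = NULL) {
  if (field_size <= 0) stop("'field_size' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- max(1L, stats::rpois(1L, n_cells_mean))
  ctr <- field_size / 2
  xs <- ctr; ys <- ctr
  pad <- cell_radius_um + 2
  tries <- 0L
  while (length(xs) < n && tries < 4000L) {
    tries <- tries + 1L
    x <- stats::runif(1L, pad, field_size - pad)
    y <- stats::runif(1L, pad, field_size - pad)
    if (all((x - xs)^2 + (y - ys)^2 >= min_separation_um^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  n <- length(xs)
  truth <- data.frame(
    x_um = xs, y_um = ys,
    iron = c(TRUE, stats::runif(n - 1L) < p_iron),
    AIF1 = stats::runif(n) < marker_probs[["AIF1"]],
    CD206 = stats::runif(n) < marker_probs[["CD206"]],
    CSF1R = stats::runif(n) < marker_probs[["CSF1R"]])
  side <- round(field_size / microns_per_pixel)
  cx <- (seq_len(side) - 0.5) * microns_per_pixel
  render_channel <- function(on) {
    ch <- matrix(background, side, side)
    for (i in which(on)) {
      cs <- which(abs(cx - xs[i]) <= cell_radius_um + microns_per_pixel)
      rs <- which(abs(cx - ys[i]) <= cell_radius_um + microns_per_pixel)
      dx <- matrix(cx[cs] - xs[i], length(rs), length(cs), byrow = TRUE)
      dy <- matrix(cx[rs] - ys[i], length(rs), length(cs))
      hit <- dx^2 + dy^2 <= cell_radius_um^2
      ch[rs, cs][hit] <- intensity
    }
    pmax(ch + stats::rnorm(side * side, 0, noise_sd), 0)
  }
  channels <- list(
    AIF1 = render_channel(truth$AIF1),
    CD206 = render_channel(truth$CD206),
    CSF1R = render_channel(truth$CSF1R),
    DAPI = render_channel(rep(TRUE, n)),
    PB = render_channel(truth$iron))
  structure(
    list(channels = channels, microns_per_pixel = microns_per_pixel,
         field_size = field_size, truth = truth),
    class = "if_field")
}

#' Cohort simulation configuration
#'
#' Study design of a simulated two-arm CSF1R-inhibitor trial: a control arm
#' with margin deposit intensity `lambda0` and a treated arm at
#' `treatment_factor * lambda0` (the drug inhibits deposit accumulation,
#' not per-deposit iron load). Tumor radii are lognormal and shared between
#' arms, so deposit totals scale with cross-section area and correlate with
#' volume.
#'
#' @param n_per_group Animals per arm (>= 2).
#' @param treatment_factor Multiplier on `lambda0` in (0, 1].
#' @param lambda0 Control-arm margin intensity, deposits per mm^2.
#' @param tau Infiltration decay scale of the deposit density.
#' @param tumor_radius_meanlog,tumor_radius_sdlog Lognormal parameters of
#'   the tumor cross-section radius in mm.
#' @param blob_roughness Harmonic roughness of each tumor outline.
#' @param modality Renderings to produce: any of `"mge"`, `"pb"`.
#' @param acq [acquisition_params()] for MGE rendering.
#' @param calibration `iron_calibration` used by the MGE forward model.
#' @param noise MGE noise model list (`model`, `sigma`).
#' @param microns_per_pixel Prussian-blue rendering resolution.
#' @param seed Integer seed for the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 8, treatment_factor = 0.37,
                          lambda0 = 2, tau = 0.25,
                          tumor_radius_meanlog = log(3),
                          tumor_radius_sdlog = 0.1,
                          blob_roughness = 0.1,
                          modality = "mge",
                          acq = acquisition_params(pixel_size = c(0.1, 0.1)),
                          calibration = default_iron_calibration(),
                          noise = list(model = "gaussian", sigma = 0.02),
                          microns_per_pixel = 8, seed = 1) {
  if (n_per_group < 2) stop("'n_per_group' must be >= 2")
  if (treatment_factor <= 0 || treatment_factor > 1)
    stop("'treatment_factor' must be in (0, 1]")
  if (!all(modality %in% c("mge", "pb")))
    stop("'modality' entries must be 'mge' and/or 'pb'")
  structure(
    list(n_per_group = as.integer(n_per_group),
         treatment_factor = treatment_factor, lambda0 = lambda0, tau = tau,
         tumor_radius_meanlog = tumor_radius_meanlog,
         tumor_radius_sdlog = tumor_radius_sdlog,
         blob_roughness = blob_roughness, modality = modality,
         acq = acq, calibration = calibration, noise = noise,
         microns_per_pixel = microns_per_pixel, seed = seed),
    class = "cohort_config")
}

#' Simulate a control-vs-treated imaging cohort
#'
#' Draws one synthetic tumor per animal (random outline and radius, deposit
#' field at the arm's intensity) and renders the requested modalities.
#' Fully deterministic given the config seed.
#'
#' @param cfg A [cohort_config()].
#' @return An object of class `cohort`: list `animals` (each with `id`,
#'   `group`, `volume_mm3`, `truth`, and renders `mge` / `pb` as
#'   configured) plus the `config`.
#' @export
simulate_cohort <- function(cfg) {
  if (!inherits(cfg, "cohort_config")) stop("'cfg' must be a cohort_config")
  set.seed(cfg$seed)
  groups <- rep(c("control", "treated"), each = cfg$n_per_group)
  lambda <- ifelse(groups == "treated",
                   cfg$treatment_factor * cfg$lambda0, cfg$lambda0)
  animals <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    radius <- stats::rlnorm(1L, cfg$tumor_radius_meanlog,
                            cfg$tumor_radius_sdlog)
    geom <- random_blob_geometry(radius, cfg$blob_roughness, seed = NULL)
    truth <- sample_deposits(geom, lambda0 = lambda[i], tau = cfg$tau,
                             seed = NULL)
    a <- list(id = sprintf("%s_%02d", groups[i],
                           ((i - 1L) %% cfg$n_per_group) + 1L),
              group = groups[i],
              volume_mm3 = 4 / 3 * pi * radius^3,
              truth = truth)
    if ("mge" %in% cfg$modality)
      a$mge <- render_mge(truth, cal = cfg$calibration, acq = cfg$acq,
                          noise = cfg$noise, seed = NULL)
    if ("pb" %in% cfg$modality)
      a$pb <- render_pb_histology(truth,
                                  microns_per_pixel = cfg$microns_per_pixel,
                                  seed = NULL)
    animals[[i]] <- a
  }
  structure(list(animals = animals, config = cfg), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  g <- vapply(x$animals, `[[`, character(1), "group")
  cat(sprintf(
    "Simulated cohort: %d control + %d treated (treatment factor %.3g)\n",
    sum(g == "control"), sum(g == "treated"),
    x$config$treatment_factor))
  invisible(x)
}
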
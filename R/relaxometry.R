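# T2*/R2* relaxometry: forward MGE signal model, pixel-wise monoexponential
# fitting, iron calibration from standards, and parametric iron maps.
#
# Unit conventions used throughout: echo times and T2* in ms, R2* in s^-1
# (so r2star = 1000 / t2star), iron concentration in mM.

#' Acquisition parameters for a multi-gradient-echo (MGE) series
#'
#' Bundles the echo train and geometry metadata of a 2D MGE relaxometry
#' acquisition. Repetition time and flip angle are carried as metadata only;
#' steady-state weighting is absorbed into the fitted amplitude `S0`.
#'
#' @param echo_times Strictly increasing vector of at least 3 positive echo
#'   times in ms. Default is a 16-echo train at 3 ms spacing (3, 6, ..., 48).
#' @param repetition_time Repetition time in ms (metadata only).
#' @param flip_angle Excitation flip angle in degrees (metadata only).
#' @param pixel_size In-plane pixel size `c(row, col)` in mm.
#' @param slice_thickness Slice thickness in mm.
#' @return An object of class `acquisition_params`.
#' @export
acquisition_params <- function(echo_times = seq(3, 48, by = 3),
                               repetition_time = 1200,
                               flip_angle = 60,
                               pixel_size = c(0.1, 0.1),
                               slice_thickness = 1) {
  echo_times <- as.numeric(echo_times)
  if (length(echo_times) < 3L)
    stop("'echo_times' must contain at least 3 echoes")
  if (any(!is.finite(echo_times)) || any(echo_times <= 0))
    stop("'echo_times' must be positive and finite")
  if (any(diff(echo_times) <= 0))
    stop("'echo_times' must be strictly increasing")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- rep(pixel_size, 2L)
  if (length(pixel_size) != 2L || any(pixel_size <= 0))
    stop("'pixel_size' must be two positive values (row, col) in mm")
  structure(
    list(echo_times = echo_times,
         repetition_time = repetition_time,
         flip_angle = flip_angle,
         pixel_size = pixel_size,
         slice_thickness = slice_thickness),
    class = "acquisition_params")
}

#' Multi-gradient-echo image stack
#'
#' @param data Numeric array of nonnegative finite intensities indexed
#'   `[echo, row, col]`.
#' @param params An [acquisition_params()] object; the number of echo planes
#'   must equal `length(params$echo_times)`.
#' @return An object of class `mge_stack`.
#' @export
mge_stack <- function(data, params) {
  if (!inherits(params, "acquisition_params"))
    stop("'params' must be an acquisition_params object")
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array indexed [echo, row, col]")
  if (dim(data)[1L] != length(params$echo_times))
    stop("number of echo planes (", dim(data)[1L],
         ") does not match length(echo_times) (",
         length(params$echo_times), ")")
  if (any(!is.finite(data)))
    stop("all stack intensities must be finite")
  structure(list(data = data, params = params), class = "mge_stack")
}

#' @export
print.mge_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("MGE stack: %d echoes, %d x %d pixels, TE %.3g..%.3g ms\n",
              d[1], d[2], d[3],
              min(x$params$echo_times), max(x$params$echo_times)))
  invisible(x)
}

#' Forward monoexponential MGE signal model
#'
#' Evaluates `S(TE) = S0 * exp(-TE / T2*)` at each echo time. `t2star = Inf`
#' gives the no-decay limit (constant signal).
#'
#' @param s0 Zero-echo signal amplitude (>= 0).
#' @param t2star Effective transverse relaxation time in ms; positive or
#'   infinite.
#' @param echo_times Echo times in ms.
#' @return Numeric vector of signal intensities, one per echo; monotone
#'   nonincreasing.
#' @export
mge_signal <- function(s0, t2star, echo_times) {
  if (!is.numeric(s0) || length(s0) != 1L || is.na(s0) || s0 < 0)
    stop("'s0' must be a single nonnegative number")
  if (!is.numeric(t2star) || length(t2star) != 1L || is.na(t2star) ||
      (is.finite(t2star) && t2star <= 0))
    stop("'t2star' must be positive (ms) or Inf")
  echo_times <- as.numeric(echo_times)
  if (any(!is.finite(echo_times)) || any(echo_times < 0))
    stop("'echo_times' must be nonnegative and finite")
  if (is.infinite(t2star)) rep(s0, length(echo_times))
  else s0 * exp(-echo_times / t2star)
}

# Truncate an echo train at the first sample <= noise_floor; returns the
# logical vector of retained (usable) echoes.
usable_echoes <- function(signal, noise_floor) {
  bad <- signal <= noise_floor
  if (any(bad)) {
    first_bad <- which(bad)[1L]
    seq_along(signal) < first_bad
  } else rep(TRUE, length(signal))
}

sentinel_fit <- function() {
  list(s0 = NA_real_, t2star = Inf, r2star = 0, fit_ok = FALSE,
       residual = NA_real_, n_used = 0L)
}

#' Fit a monoexponential decay to a single pixel's echo train
#'
#' Log-linear least squares on `log S` vs `TE`, restricted to the echoes that
#' survive the noise-floor truncation rule: the train is cut at the first
#' sample at or below `noise_floor` and at least 3 echoes must remain.
#' A non-decaying fit (nonnegative log-domain slope) or an unusable train
#' yields `fit_ok = FALSE` with `r2star` clamped to 0 and `t2star = Inf`.
#'
#' @param signal Numeric vector of intensities, one per echo.
#' @param echo_times Echo times in ms (same length as `signal`).
#' @param noise_floor Intensity below which samples are treated as noise
#'   (>= 0). Default 0.
#' @param weighting `"signal"` (default) weights each echo by its squared
#'   signal, the usual first-order variance correction for log-transformed
#'   Gaussian noise; `"none"` is ordinary unweighted log-linear least
#'   squares. Noiseless data are recovered exactly under either choice.
#' @return List with elements `s0`, `t2star` (ms), `r2star` (s^-1),
#'   `fit_ok`, `residual` (log-domain sum of squared residuals) and `n_used`.
#' @export
fit_t2star_pixel <- function(signal, echo_times, noise_floor = 0,
                             weighting = c("signal", "none")) {
  weighting <- match.arg(weighting)
  signal <- as.numeric(signal)
  echo_times <- as.numeric(echo_times)
  if (length(signal) != length(echo_times))
    stop("'signal' length must equal the number of echo times")
  if (!is.numeric(noise_floor) || length(noise_floor) != 1L || noise_floor < 0)
    stop("'noise_floor' must be a single nonnegative number")
  use <- usable_echoes(signal, noise_floor)
  n <- sum(use)
  if (n < 3L) return(sentinel_fit())
  x <- echo_times[use]
  y <- log(signal[use])
  w <- if (weighting == "signal") signal[use]^2 else rep(1, n)
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x * x); sxy <- sum(w * x * y)
  denom <- sxx - sx * sx / sw
  if (denom <= 0) return(sentinel_fit())
  slope <- (sxy - sx * sy / sw) / denom
  icpt <- (sy - slope * sx) / sw
  if (slope >= 0) return(sentinel_fit())
  res <- sum(w * (y - (icpt + slope * x))^2)
  t2 <- -1 / slope
  list(s0 = exp(icpt), t2star = t2, r2star = 1000 / t2, fit_ok = TRUE,
       residual = res, n_used = n)
}

#' Pixel-wise T2*/R2* mapping of an MGE stack
#'
#' Applies [fit_t2star_pixel()] independently to every pixel of the stack
#' (vectorised over pixels; results are identical to the per-pixel routine).
#'
#' @param stack An [mge_stack()].
#' @param noise_floor Intensity truncation floor, as in [fit_t2star_pixel()].
#' @param weighting Passed to the per-pixel fit; see [fit_t2star_pixel()].
#' @return An object of class `relaxometry_map` with per-pixel matrices
#'   `s0`, `t2star` (ms), `r2star` (s^-1), `fit_ok`, `residual`, `n_used`,
#'   and the acquisition `params`. Pixels that cannot be fitted carry the
#'   sentinel values `s0 = NA`, `t2star = Inf`, `r2star = 0`.
#' @export
fit_t2star_map <- function(stack, noise_floor = 0,
                           weighting = c("signal", "none")) {
  weighting <- match.arg(weighting)
  if (!inherits(stack, "mge_stack"))
    stop("'stack' must be an mge_stack object")
  if (!is.numeric(noise_floor) || length(noise_floor) != 1L || noise_floor < 0)
    stop("'noise_floor' must be a single nonnegative number")
  te <- stack$params$echo_times
  ne <- length(te)
  nr <- dim(stack$data)[2L]; nc <- dim(stack$data)[3L]
  np <- nr * nc
  # pixels x echoes matrix
  S <- matrix(aperm(stack$data, c(2L, 3L, 1L)), nrow = np, ncol = ne)
  # truncation: echo j usable iff all echoes 1..j exceed the floor
  use <- matrix(FALSE, np, ne)
  alive <- rep(TRUE, np)
  for (j in seq_len(ne)) {
    alive <- alive & (S[, j] > noise_floor)
    use[, j] <- alive
  }
  n_used <- rowSums(use)
  W <- if (weighting == "signal") S * S * use else 1 * use
  Y <- ifelse(use, log(pmax(S, .Machine$double.xmin)), 0)
  tex <- matrix(te, np, ne, byrow = TRUE)
  sw <- rowSums(W)
  sx <- rowSums(W * tex)
  sy <- rowSums(W * Y)
  sxx <- rowSums(W * tex * tex)
  sxy <- rowSums(W * tex * Y)
  sw[sw == 0] <- NA_real_
  denom <- sxx - sx * sx / sw
  slope <- (sxy - sx * sy / sw) / denom
  icpt <- (sy - slope * sx) / sw
  ok <- n_used >= 3L & is.finite(slope) & slope < 0 &
    is.finite(denom) & denom > 0
  yhat <- matrix(icpt, np, ne) + slope * tex
  res <- rowSums(W * (Y - yhat)^2)
  s0 <- ifelse(ok, exp(icpt), NA_real_)
  t2 <- ifelse(ok, -1 / slope, Inf)
  r2 <- ifelse(ok, 1000 * pmax(-slope, 0), 0)
  structure(
    list(s0 = matrix(s0, nr, nc),
         t2star = matrix(t2, nr, nc),
         r2star = matrix(r2, nr, nc),
         fit_ok = matrix(ok, nr, nc),
         residual = matrix(ifelse(ok, res, NA_real_), nr, nc),
         n_used = matrix(as.integer(n_used), nr, nc),
         params = stack$params),
    class = "relaxometry_map")
}

#' @export
print.relaxometry_map <- function(x, ...) {
  cat(sprintf("Relaxometry map: %d x %d pixels, %d fitted (%.1f%%)\n",
              nrow(x$r2star), ncol(x$r2star), sum(x$fit_ok),
              100 * mean(x$fit_ok)))
  if (any(x$fit_ok))
    cat(sprintf("  T2* median %.3g ms, R2* median %.3g s^-1 (fitted pixels)\n",
                stats::median(x$t2star[x$fit_ok]),
                stats::median(x$r2star[x$fit_ok])))
  invisible(x)
}

#' Linear iron calibration from relaxometry standards
#'
#' Ordinary least-squares fit of the linear relation
#' `R2* = slope * concentration + intercept` to measurements of aqueous iron
#' standards of known concentration, as used to convert R2* maps to
#' parametric iron-concentration maps.
#'
#' @param standards Data frame with columns `concentration` (mM) and
#'   `r2star` (s^-1); at least two distinct concentrations are required.
#' @return An object of class `iron_calibration` with `slope` (s^-1 per mM),
#'   `intercept` (s^-1, the baseline tissue/solvent relaxation rate),
#'   `r_squared`, and the `standards` table.
#' @export
fit_iron_calibration <- function(standards) {
  if (!is.data.frame(standards) ||
      !all(c("concentration", "r2star") %in% names(standards)))
    stop("'standards' must be a data frame with columns 'concentration' and 'r2star'")
  conc <- as.numeric(standards$concentration)
  r2 <- as.numeric(standards$r2star)
  if (length(conc) < 2L || length(unique(conc)) < 2L)
    stop("at least two distinct standard concentrations are required")
  fit <- stats::lm(r2 ~ conc)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive; got ", format(slope))
  ssr <- sum(stats::residuals(fit)^2)
  sst <- sum((r2 - mean(r2))^2)
  r_squared <- if (sst > 0) 1 - ssr / sst else 1
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         standards = data.frame(concentration = conc, r2star = r2)),
    class = "iron_calibration")
}

#' @export
print.iron_calibration <- function(x, ...) {
  cat(sprintf(
    "Iron calibration: R2* = %.4g * [Fe] + %.4g  (R^2 = %.4f, n = %d)\n",
    x$slope, x$intercept, x$r_squared, nrow(x$standards)))
  invisible(x)
}

#' Convert a relaxometry map to a parametric iron-concentration map
#'
#' Inverts the linear calibration per pixel:
#' `concentration = (r2star - intercept) / slope`. Negative concentrations
#' (pixels relaxing more slowly than the calibration baseline) are clamped
#' to 0; validity follows the relaxometry `fit_ok` flag.
#'
#' @param rmap A `relaxometry_map` from [fit_t2star_map()].
#' @param cal An `iron_calibration` from [fit_iron_calibration()].
#' @return An object of class `iron_map` with matrices `concentration` (mM)
#'   and `valid`, plus the calibration as `provenance` and the pixel size.
#' @export
apply_calibration <- function(rmap, cal) {
  if (!inherits(rmap, "relaxometry_map"))
    stop("'rmap' must be a relaxometry_map object")
  if (!inherits(cal, "iron_calibration"))
    stop("'cal' must be an iron_calibration object")
  conc <- (rmap$r2star - cal$intercept) / cal$slope
  conc <- pmax(conc, 0)
  conc[!rmap$fit_ok] <- NA_real_
  structure(
    list(concentration = conc, valid = rmap$fit_ok, provenance = cal,
         pixel_size = rmap$params$pixel_size),
    class = "iron_map")
}

#' @export
print.iron_map <- function(x, ...) {
  cat(sprintf("Iron map: %d x %d pixels, %d valid\n",
              nrow(x$concentration), ncol(x$concentration), sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  concentration range %.3g..%.3g mM (valid pixels)\n",
                min(x$concentration[x$valid]), max(x$concentration[x$valid])))
  invisible(x)
}
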
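# Cohort-level statistics: treatment-effect ratios with bootstrap CIs,
# cluster-burden vs tumor-volume correlation, per-decile group comparisons.

#' Treated-to-control ratio with percentile bootstrap CI
#'
#' `ratio = mean(treated) / mean(control)`, with a seeded percentile
#' bootstrap (animals resampled with replacement within each group).
#'
#' @param control_counts,treated_counts Nonempty numeric vectors of
#'   per-animal cluster or deposit counts.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param conf Confidence level (default 0.95).
#' @param seed Optional integer seed; `NULL` continues the RNG stream.
#' @return List with `ratio`, `ci_low`, `ci_high`, `percent_of_control`
#'   (100 * ratio) and the group means.
#' @export
treatment_ratio <- function(control_counts, treated_counts, n_boot = 1000,
                            conf = 0.95, seed = NULL) {
  control_counts <- as.numeric(control_counts)
  treated_counts <- as.numeric(treated_counts)
  if (length(control_counts) == 0L || length(treated_counts) == 0L)
    stop("both groups must be nonempty")
  mc <- mean(control_counts)
  if (mc <= 0) stop("control mean must be > 0 for a defined ratio")
  mt <- mean(treated_counts)
  if (!is.null(seed)) set.seed(seed)
  boot <- numeric(n_boot)
  nc <- length(control_counts); nt <- length(treated_counts)
  for (b in seq_len(n_boot)) {
    bc <- mean(control_counts[sample.int(nc, nc, replace = TRUE)])
    bt <- mean(treated_counts[sample.int(nt, nt, replace = TRUE)])
    boot[b] <- if (bc > 0) bt / bc else NA_real_
  }
  alpha <- (1 - conf) / 2
  qs <- stats::quantile(boot, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(ratio = mt / mc, ci_low = qs[1L], ci_high = qs[2L],
       percent_of_control = 100 * mt / mc,
       mean_control = mc, mean_treated = mt, n_boot = n_boot)
}

#' Pearson correlation of cluster burden with tumor volume
#'
#' Pearson r with two-sided p-value from the t transform on n - 2 degrees
#' of freedom.
#'
#' @param counts Per-animal cluster/deposit counts (n >= 3).
#' @param volumes Per-animal tumor volumes in mm^3.
#' @return List with `r`, `r_squared`, `p_value` and `n`.
#' @export
correlate_counts_volume <- function(counts, volumes) {
  counts <- as.numeric(counts); volumes <- as.numeric(volumes)
  if (length(counts) != length(volumes))
    stop("'counts' and 'volumes' must have equal length")
  if (length(counts) < 3L) stop("at least 3 animals are required")
  if (stats::sd(counts) == 0 || stats::sd(volumes) == 0)
    stop("degenerate input: zero variance in counts or volumes")
  ct <- stats::cor.test(counts, volumes, method = "pearson",
                        alternative = "two.sided")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_value = ct$p.value, n = length(counts))
}

#' Per-decile comparison of infiltration profiles between groups
#'
#' Per-bin group means and SEMs with Welch t statistics and Holm-adjusted
#' two-sided p-values. Bins where both groups are constant get p = 1 when
#' the means agree and p = 0 when they differ.
#'
#' @param profiles_control,profiles_treated Lists of `radial_profile`
#'   objects (>= 2 per group, identical `n_bins`).
#' @return Data frame with columns `bin`, `lo`, `hi` (infiltration fraction
#'   edges), `mean_control`, `sem_control`, `mean_treated`, `sem_treated`,
#'   `t`, `p`, `p_adj`.
#' @export
profile_group_comparison <- function(profiles_control, profiles_treated) {
  as_mat <- function(ps, label) {
    if (length(ps) < 2L) stop("need >= 2 profiles in the ", label, " group")
    nb <- unique(vapply(ps, function(p) p$n_bins, integer(1)))
    if (length(nb) != 1L) stop("profiles disagree on n_bins")
    do.call(rbind, lapply(ps, function(p) p$counts))
  }
  mc <- as_mat(profiles_control, "control")
  mt <- as_mat(profiles_treated, "treated")
  if (ncol(mc) != ncol(mt))
    stop("control and treated profiles disagree on n_bins")
  nb <- ncol(mc)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  tt <- numeric(nb); pv <- numeric(nb)
  for (k in seq_len(nb)) {
    a <- mc[, k]; b <- mt[, k]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      tt[k] <- if (mean(a) == mean(b)) 0 else Inf
      pv[k] <- if (mean(a) == mean(b)) 1 else 0
    } else {
      w <- stats::t.test(a, b, var.equal = FALSE)
      tt[k] <- unname(w$statistic)
      pv[k] <- w$p.value
    }
  }
  edges <- profiles_control[[1L]]$bin_edges
  data.frame(bin = seq_len(nb), lo = edges[-(nb + 1L)], hi = edges[-1L],
             mean_control = colMeans(mc), sem_control = apply(mc, 2L, sem),
             mean_treated = colMeans(mt), sem_treated = apply(mt, 2L, sem),
             t = tt, p = pv, p_adj = stats::p.adjust(pv, method = "holm"))
}

#' Summarise a simulated cohort end to end
#'
#' Runs the modality pipeline on every animal of a [simulate_cohort()]
#' result and assembles per-animal counts, the treatment ratio and the
#' count-volume correlation.
#'
#' @param cohort A `cohort`.
#' @param modality `"mge"` or `"pb"` (must have been rendered).
#' @param n_boot Bootstrap resamples for the treatment ratio.
#' @param ... Passed to [analyze_femri()] or [analyze_pb()].
#' @return An object of class `cohort_summary`: per-animal data frame
#'   `animals` (id, group, count, volume_mm3), `ratio`
#'   (see [treatment_ratio()]) and `correlation`
#'   (see [correlate_counts_volume()]; pooled over both arms).
#' @export
summarize_cohort <- function(cohort, modality = c("mge", "pb"),
                             n_boot = 1000, ...) {
  modality <- match.arg(modality)
  if (!inherits(cohort, "cohort")) stop("'cohort' must be a cohort")
  rows <- lapply(cohort$animals, function(a) {
    if (is.null(a[[modality]]))
      stop("modality '", modality, "' was not rendered for this cohort")
    count <- if (modality == "mge") analyze_femri(a$mge, ...)$count
    else analyze_pb(a$pb, segment_roi = FALSE, ...)$count
    data.frame(id = a$id, group = a$group, count = count,
               volume_mm3 = a$volume_mm3)
  })
  tab <- do.call(rbind, rows)
  ctrl <- tab$count[tab$group == "control"]
  trt <- tab$count[tab$group == "treated"]
  structure(
    list(animals = tab,
         ratio = treatment_ratio(ctrl, trt, n_boot = n_boot),
         correlation = correlate_counts_volume(tab$count, tab$volume_mm3)),
    class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "Cohort summary: treated = %.1f%% of control (95%% CI %.1f-%.1f%%)\n",
    x$ratio$percent_of_control, 100 * x$ratio$ci_low, 100 * x$ratio$ci_high))
  cat(sprintf("  count-volume correlation r = %.3f (R^2 = %.3f, p = %.3g)\n",
              x$correlation$r, x$correlation$r_squared,
              x$correlation$p_value))
  invisible(x)
}
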
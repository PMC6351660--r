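# Ground-truth generators and renderings: determinism, the planted radial
# law, and round trips through the measurement pipelines.

test_that("generators are pure functions of (config, seed)", {
  g <- roi_geometry(2)
  t1 <- sample_deposits(g, lambda0 = 5, tau = 0.3, seed = 11)
  t2 <- sample_deposits(g, lambda0 = 5, tau = 0.3, seed = 11)
  expect_identical(t1, t2)
  r1 <- render_mge(t1, seed = 12)
  r2 <- render_mge(t1, seed = 12)
  expect_identical(r1$stack$data, r2$stack$data)
  p1 <- render_pb_histology(t1, seed = 13)
  p2 <- render_pb_histology(t1, seed = 13)
  expect_identical(p1$image$rgb, p2$image$rgb)
  cfg <- cohort_config(n_per_group = 2, lambda0 = 1,
                       tumor_radius_meanlog = log(1.5), seed = 5)
  expect_identical(simulate_cohort(cfg)$animals[[1]]$truth,
                   simulate_cohort(cfg)$animals[[1]]$truth)
})

test_that("deposit totals follow the inhomogeneous Poisson mean", {
  g <- roi_geometry(1.5)
  area <- geometry_area(g)
  expect_equal(area, pi * 1.5^2, tolerance = 1e-6)
  tau <- 0.25
  lambda0 <- 6
  # E[N] = lambda0 * area * E[exp(-f/tau)] under area-uniform f:
  # on a disc, f = 1 - r/R has density 2(1-f)
  integrand <- function(f) exp(-f / tau) * 2 * (1 - f)
  expected <- lambda0 * area * stats::integrate(integrand, 0, 1)$value
  set.seed(61)
  counts <- vapply(1:500, function(k)
    nrow(sample_deposits(g, lambda0, tau, seed = NULL)$deposits),
    numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # near-uniform limit: per-decile counts proportional to annulus areas
  set.seed(62)
  bins <- integer(10)
  for (k in 1:60) {
    tr <- sample_deposits(g, lambda0 = 8, tau = 1e6, seed = NULL)
    bins <- bins + tabulate(pmin(floor(tr$deposits$f * 10) + 1L, 10L), 10L)
  }
  analytic <- rev(diff(seq(0, 1, by = 0.1)^2))
  expect_lt(max(abs(bins / sum(bins) - analytic)), 0.02)
  # vanishing intensity: essentially no deposits
  set.seed(63)
  expect_lt(nrow(sample_deposits(g, lambda0 = 1e-4, tau = 1, seed = NULL)$deposits), 2)
})

test_that("noiseless MGE render inverts exactly through the pipeline", {
  set.seed(21)
  truth <- sample_deposits(roi_geometry(1.2), lambda0 = 4, tau = 0.3,
                           seed = NULL)
  cal <- default_iron_calibration()
  mr <- render_mge(truth, cal = cal,
                   acq = acquisition_params(pixel_size = c(0.05, 0.05)),
                   noise = list(model = "gaussian", sigma = 0), seed = NULL)
  rmap <- fit_t2star_map(mr$stack, noise_floor = 0)
  iron <- apply_calibration(rmap, cal)
  inroi <- mr$roi_mask
  # planted concentration recovered exactly at every tumor pixel
  expect_true(all(rmap$fit_ok[inroi]))
  expect_equal(iron$concentration[inroi], mr$truth_conc[inroi],
               tolerance = 1e-8)
  # background tissue fits the background T2*
  bg <- inroi & mr$truth_conc == 0
  expect_equal(unique(round(rmap$t2star[bg], 6)),
               truth$background_t2star)
  # zero-deposit truth renders a uniform decaying stack
  t0 <- sample_deposits(roi_geometry(1.2), lambda0 = 1e-6, tau = 1,
                        seed = 1)
  expect_equal(nrow(t0$deposits), 0)
  m0 <- render_mge(t0, cal = cal, noise = list(model = "gaussian",
                                               sigma = 0), seed = 1)
  v <- m0$stack$data[5, , ][m0$roi_mask]
  expect_equal(max(v) - min(v), 0)
})

test_that("PB rendering is detected deposit-for-deposit when disjoint", {
  set.seed(33)
  ok_all <- TRUE
  for (k in 1:15) {
    truth <- sample_deposits(roi_geometry(1.5), lambda0 = 3, tau = 0.35,
                             seed = NULL)
    pb <- render_pb_histology(truth, seed = NULL)
    det <- analyze_pb(pb, segment_roi = FALSE)
    # deposits can merge when closer than their radii; require near-exact
    expect_lte(det$count, nrow(truth$deposits))
    expect_gte(det$count, floor(0.8 * nrow(truth$deposits)))
  }
  # zero deposits -> no positive pixel at default delta
  t0 <- sample_deposits(roi_geometry(1), lambda0 = 1e-6, tau = 1, seed = 2)
  p0 <- render_pb_histology(t0, seed = 2)
  expect_equal(sum(pb_positive_mask(p0$image)$mask), 0)
  # single planted deposit -> exactly one detection
  t1 <- t0
  t1$deposits <- data.frame(x_mm = 0.2, y_mm = -0.1, f = 0.5,
                            radius_um = 60, conc_mM = 2,
                            AIF1 = TRUE, CD206 = FALSE, CSF1R = TRUE)
  p1 <- render_pb_histology(t1, seed = 3)
  expect_equal(analyze_pb(p1, segment_roi = FALSE)$count, 1)
})

test_that("paired renderings share the planted deposit coordinates", {
  truth <- sample_deposits(roi_geometry(1.5), lambda0 = 5, tau = 0.3,
                           seed = 71)
  mr <- render_mge(truth, noise = list(model = "gaussian", sigma = 0),
                   seed = 72)
  pb <- render_pb_histology(truth, seed = 73)
  expect_identical(mr$truth, pb$truth)
  # each planted deposit marks pixels in both renderings near its location
  for (i in seq_len(min(5, nrow(truth$deposits)))) {
    d <- truth$deposits[i, ]
    ri <- which.min(abs(mr$coords - d$y_mm))
    ci <- which.min(abs(mr$coords - d$x_mm))
    expect_gt(mr$truth_conc[ri, ci], 0)
    rj <- which.min(abs(pb$coords - d$y_mm))
    cj <- which.min(abs(pb$coords - d$x_mm))
    expect_true(pb_positive_mask(pb$image)$mask[rj, cj])
  }
})

test_that("IF fields carry the configured marker structure", {
  # all probabilities zero: only iron and DAPI signal
  f0 <- render_if_field(marker_probs = c(AIF1 = 0, CD206 = 0, CSF1R = 0),
                        p_iron = 1, seed = 51)
  expect_equal(nrow(detect_cells_channel(f0$channels$AIF1, 100,
                                         microns_per_pixel = 2)), 0)
  expect_gt(nrow(detect_cells_channel(f0$channels$DAPI, 100,
                                      microns_per_pixel = 2)), 0)
  # certain AIF1: the polarization fraction concentrates on AIF1
  f1 <- render_if_field(marker_probs = c(AIF1 = 1, CD206 = 0, CSF1R = 0),
                        p_iron = 1, seed = 52)
  tab <- quantify_if_field(f1)
  fp <- fractional_populations(tab)
  expect_equal(unname(fp$polarization["AIF1"]), 1)
  expect_equal(tab$iron_CD206, 0)
})

test_that("cohorts scale deposit burden by the treatment factor", {
  cfg <- cohort_config(n_per_group = 6, treatment_factor = 0.5,
                       lambda0 = 8, tau = 0.25,
                       tumor_radius_meanlog = log(1.6),
                       tumor_radius_sdlog = 0.05,
                       modality = character(0), seed = 31)
  coh <- simulate_cohort(cfg)
  g <- vapply(coh$animals, `[[`, character(1), "group")
  n <- vapply(coh$animals, function(a) nrow(a$truth$deposits), numeric(1))
  expect_equal(sort(unique(g)), c("control", "treated"))
  ratio <- mean(n[g == "treated"]) / mean(n[g == "control"])
  expect_gt(ratio, 0.3); expect_lt(ratio, 0.8)
  # null effect: the two arms are exchangeable
  cfg1 <- cohort_config(n_per_group = 10, treatment_factor = 1,
                        lambda0 = 8, tumor_radius_meanlog = log(1.6),
                        modality = character(0), seed = 32)
  coh1 <- simulate_cohort(cfg1)
  g1 <- vapply(coh1$animals, `[[`, character(1), "group")
  n1 <- vapply(coh1$animals, function(a) nrow(a$truth$deposits), numeric(1))
  r1 <- mean(n1[g1 == "treated"]) / mean(n1[g1 == "control"])
  expect_gt(r1, 0.75); expect_lt(r1, 1.33)
})
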
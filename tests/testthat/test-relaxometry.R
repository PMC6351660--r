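# Forward signal model, pixel-wise fitting, calibration, iron maps.

te16 <- seq(3, 48, by = 3)

test_that("forward MGE signal model matches element-wise exponentials", {
  expect_equal(mge_signal(1000, Inf, c(3, 6, 9)), c(1000, 1000, 1000))
  expect_equal(mge_signal(100, 3, 3), 100 * exp(-1))
  s <- mge_signal(1000, 12, te16)
  expect_equal(s, vapply(te16, function(t) 1000 * exp(-t / 12), numeric(1)))
  expect_true(all(diff(s) <= 0))
  expect_error(mge_signal(1000, -5, te16), "t2star")
  expect_error(mge_signal(1000, 0, te16), "t2star")
  expect_error(mge_signal(-1, 12, te16), "s0")
})

test_that("noiseless round trip recovers s0 and t2star exactly", {
  for (t2 in c(1.5, 12, 85, 640)) {
    f <- fit_t2star_pixel(mge_signal(1000, t2, te16), te16, 0)
    expect_true(f$fit_ok)
    expect_equal(f$t2star, t2, tolerance = 1e-9)
    expect_equal(f$s0, 1000, tolerance = 1e-9)
    expect_equal(f$r2star, 1000 / t2, tolerance = 1e-9)
  }
  f <- fit_t2star_pixel(mge_signal(1000, 12, te16), te16, 0,
                        weighting = "none")
  expect_equal(f$t2star, 12, tolerance = 1e-9)
  expect_equal(f$r2star, 1000 / 12, tolerance = 1e-6)
})

test_that("degenerate echo trains yield the sentinel, not an exception", {
  # constant (non-decaying) signal
  f <- fit_t2star_pixel(rep(500, 16), te16, 0)
  expect_false(f$fit_ok)
  expect_identical(f$r2star, 0)
  expect_identical(f$t2star, Inf)
  # all echoes below the floor
  f2 <- fit_t2star_pixel(rep(5, 16), te16, noise_floor = 10)
  expect_false(f2$fit_ok)
  expect_identical(f2$n_used, 0L)
  # increasing signal
  f3 <- fit_t2star_pixel(seq(100, 250, by = 10), te16, 0)
  expect_false(f3$fit_ok)
})

test_that("noise-floor rule truncates at the first sub-floor sample", {
  s <- mge_signal(1000, 12, te16)
  s[10] <- 0.5                     # dropout mid-train
  f <- fit_t2star_pixel(s, te16, noise_floor = 1)
  expect_identical(f$n_used, 9L)   # echoes after the dropout are discarded
  expect_equal(f$t2star, 12, tolerance = 1e-9)
  # fewer than 3 usable echoes -> sentinel
  s2 <- mge_signal(1000, 12, te16)
  s2[3:16] <- 0
  expect_false(fit_t2star_pixel(s2, te16, noise_floor = 0.1)$fit_ok)
})

test_that("median T2* error stays below 5% at 2% Gaussian noise", {
  set.seed(421)
  n <- 1000
  truth_t2 <- 12
  s0 <- 1000
  sigma <- 0.02 * s0
  clean <- mge_signal(s0, truth_t2, te16)
  sig <- matrix(rep(clean, each = n), n, length(te16)) +
    rnorm(n * length(te16), 0, sigma)
  floor_ <- 3 * sigma
  est <- vapply(seq_len(n), function(i)
    fit_t2star_pixel(sig[i, ], te16, floor_)$t2star, numeric(1))
  expect_lt(median(abs(est - truth_t2) / truth_t2), 0.05)
  # independent oracle: dense grid search over (s0-profiled) t2star
  grid <- exp(seq(log(2), log(60), length.out = 500))
  est_oracle <- oracle_grid_t2star(sig, te16, grid)
  expect_lt(median(abs(est_oracle - truth_t2) / truth_t2), 0.05)
  # the two estimators agree on the bulk of pixels
  expect_lt(median(abs(est - est_oracle) / truth_t2), 0.05)
})

test_that("map fitting equals the per-pixel fit and recovers phantoms", {
  acq <- acquisition_params(echo_times = te16, pixel_size = c(0.05, 0.05))
  t2s <- matrix(c(10, 20, 30, 40), 2, 2)
  dat <- array(0, dim = c(16, 2, 2))
  for (r in 1:2) for (cc in 1:2)
    dat[, r, cc] <- mge_signal(1000, t2s[r, cc], te16)
  rmap <- fit_t2star_map(mge_stack(dat, acq), 0)
  expect_true(all(rmap$fit_ok))
  expect_equal(rmap$t2star, t2s, tolerance = 1e-9)
  expect_equal(rmap$r2star * rmap$t2star,
               matrix(1000, 2, 2), tolerance = 1e-9)
  # all-zero stack: nothing fits
  z <- fit_t2star_map(mge_stack(array(0, dim = c(16, 3, 3)), acq), 0)
  expect_false(any(z$fit_ok))
  expect_true(all(z$r2star == 0))
  # noisy stack: vectorised map equals the scalar reference pixel by pixel
  set.seed(99)
  noisy <- dat + array(rnorm(length(dat), 0, 15), dim = dim(dat))
  m2 <- fit_t2star_map(mge_stack(noisy, acq), noise_floor = 45)
  for (r in 1:2) for (cc in 1:2) {
    ref <- fit_t2star_pixel(noisy[, r, cc], te16, 45)
    expect_equal(m2$t2star[r, cc], ref$t2star, tolerance = 1e-12)
    expect_equal(m2$fit_ok[r, cc], ref$fit_ok)
  }
  # echo-count mismatch is a structural error
  expect_error(mge_stack(array(1, dim = c(5, 2, 2)), acq), "echo")
})

test_that("iron calibration matches the closed-form least-squares line", {
  cal <- fit_iron_calibration(
    data.frame(concentration = c(0, 1), r2star = c(20, 50)))
  expect_equal(cal$slope, 30)
  expect_equal(cal$intercept, 20)
  expect_equal(cal$r_squared, 1)
  # collinear points
  cc <- seq(0, 2, by = 0.5)
  cal2 <- fit_iron_calibration(
    data.frame(concentration = cc, r2star = 20 + 30 * cc))
  expect_equal(cal2$r_squared, 1)
  # noisy standards against the normal-equations oracle
  set.seed(7)
  conc <- runif(20, 0, 3)
  r2 <- 20 + 30 * conc + rnorm(20, 0, 2)
  cal3 <- fit_iron_calibration(data.frame(concentration = conc, r2star = r2))
  orc <- oracle_lsq_line(conc, r2)
  expect_equal(cal3$slope, orc$slope, tolerance = 1e-9)
  expect_equal(cal3$intercept, orc$intercept, tolerance = 1e-9)
  # degenerate design
  expect_error(fit_iron_calibration(
    data.frame(concentration = c(1, 1, 1), r2star = c(40, 50, 60))),
    "distinct")
})

test_that("calibration maps R2* to concentration with clamping", {
  acq <- acquisition_params(echo_times = te16)
  cal <- fit_iron_calibration(
    data.frame(concentration = c(0, 1), r2star = c(20, 50)))
  # r2star 50 -> 1 mM; r2star == intercept -> 0; slow pixels clamp to 0
  t2s <- 1000 / c(50, 20, 10)
  dat <- array(0, dim = c(16, 1, 3))
  for (k in 1:3) dat[, 1, k] <- mge_signal(1000, t2s[k], te16)
  iron <- apply_calibration(fit_t2star_map(mge_stack(dat, acq), 0), cal)
  expect_equal(iron$concentration[1, ], c(1, 0, 0), tolerance = 1e-9)
  expect_true(all(iron$valid))
  # inverse transform recovers r2star where concentration was positive
  expect_equal(cal$intercept + cal$slope * iron$concentration[1, 1], 50,
               tolerance = 1e-9)
})
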
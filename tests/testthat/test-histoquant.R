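# Prussian-blue masking, deposit counting, IF cell detection,
# co-positivity and fractional populations.

test_that("blue-dominance rule separates PB deposits from counter-stain", {
  px <- function(r, g, b) {
    a <- array(0, dim = c(1, 1, 3)); a[1, 1, ] <- c(r, g, b)
    histology_image(a, microns_per_pixel = 1)
  }
  expect_true(pb_positive_mask(px(0, 0, 255), delta = 30)$mask[1, 1])
  # pink nuclear-fast-red counter-stain
  expect_false(pb_positive_mask(px(230, 150, 170), delta = 30)$mask[1, 1])
  # white slide background
  expect_false(pb_positive_mask(px(246, 245, 244), delta = 30)$mask[1, 1])
  # blue must exceed BOTH red and green by delta
  expect_false(pb_positive_mask(px(0, 235, 255), delta = 30)$mask[1, 1])
  expect_true(pb_positive_mask(px(100, 100, 130), delta = 30)$mask[1, 1])
  expect_false(pb_positive_mask(px(100, 100, 129), delta = 30)$mask[1, 1])
  expect_error(pb_positive_mask(matrix(1, 5, 5)), "RGB|histology")
})

test_that("pb mask is monotone in delta", {
  set.seed(2)
  arr <- array(runif(20 * 20 * 3, 0, 255), dim = c(20, 20, 3))
  img <- histology_image(arr, 1)
  m1 <- pb_positive_mask(img, delta = 10)$mask
  m2 <- pb_positive_mask(img, delta = 40)$mask
  expect_true(all(m1[m2]))               # larger delta -> subset
  expect_true(sum(m2) <= sum(m1))
})

test_that("deposit counting applies the physical size filter", {
  e <- count_pb_deposits(matrix(FALSE, 10, 10), 1)
  expect_equal(n_clusters(e), 0)
  m <- matrix(FALSE, 20, 20)
  m[3:7, 3:7] <- TRUE          # 25 px = 25 um^2 at 1 um/px
  cs <- count_pb_deposits(m, microns_per_pixel = 1, min_area = 20)
  expect_equal(n_clusters(cs), 1)
  expect_equal(cs$clusters$area_um2, 25)
  # a 4-px blob falls below the 20 um^2 floor
  m2 <- m; m2[12:13, 12:13] <- TRUE
  expect_equal(n_clusters(count_pb_deposits(m2, 1, min_area = 20)), 1)
  # at 8 um/px one pixel is already 64 um^2
  expect_equal(n_clusters(count_pb_deposits(m2, 8, min_area = 20)), 2)
})

test_that("channel cell detection finds disjoint bright discs", {
  expect_equal(nrow(detect_cells_channel(matrix(0, 50, 50), 100)), 0)
  ch <- matrix(5, 60, 60)
  ch[disc_mask(60, c(15, 20), 4)] <- 200
  ch[disc_mask(60, c(45, 40), 4)] <- 200
  cells <- detect_cells_channel(ch, threshold = 100, min_area = 25,
                                microns_per_pixel = 2)
  expect_equal(nrow(cells), 2)
  expect_equal(cells$row, c(15, 45), tolerance = 0.5)
  expect_equal(cells$col, c(20, 40), tolerance = 0.5)
  expect_equal(cells$x_um, c(40, 80), tolerance = 1)
})

test_that("synthetic IF fields are detected against the planted cells", {
  set.seed(41)
  hits <- 0; n_tot <- 0
  for (k in 1:20) {
    fld <- render_if_field(seed = NULL)
    det <- detect_cells_channel(fld$channels$DAPI, threshold = 100,
                                min_area = 25,
                                microns_per_pixel = fld$microns_per_pixel)
    truth <- fld$truth
    n_tot <- n_tot + nrow(truth)
    matched <- oracle_match_once(
      truth, data.frame(x_um = det$x_um, y_um = det$y_um), radius = 5)
    hits <- hits + sum(matched)
  }
  expect_gte(hits / n_tot, 0.95)
})

test_that("co-positivity matching equals the brute-force oracle", {
  # identical lists: every iron cell pairs up
  pts <- data.frame(x_um = c(10, 50, 90), y_um = c(10, 50, 90))
  t1 <- match_copositive(list(iron = pts, AIF1 = pts,
                              CD206 = pts[0, ], CSF1R = pts[0, ]),
                         radius = 10)
  expect_equal(t1$iron_AIF1, 3)
  expect_equal(t1$iron_CD206, 0)
  expect_equal(t1$n_iron, 3)
  # empty iron list: all combinations zero
  t0 <- match_copositive(list(iron = pts[0, ], AIF1 = pts,
                              CD206 = pts, CSF1R = pts), radius = 10)
  expect_equal(t0$iron_AIF1 + t0$iron_CD206 + t0$iron_AIF1_CD206, 0)
  # random constellations against the oracle
  set.seed(8)
  for (k in 1:40) {
    rp <- function(n) data.frame(x_um = runif(n, 0, 60),
                                 y_um = runif(n, 0, 60))
    iron <- rp(sample(0:8, 1))
    lst <- list(iron = iron, AIF1 = rp(sample(0:8, 1)),
                CD206 = rp(sample(0:8, 1)), CSF1R = rp(sample(0:8, 1)))
    tt <- match_copositive(lst, radius = 12)
    oa <- oracle_match_once(iron, lst$AIF1, 12)
    oc <- oracle_match_once(iron, lst$CD206, 12)
    os <- oracle_match_once(iron, lst$CSF1R, 12)
    expect_equal(tt$iron_AIF1, sum(oa & !oc))
    expect_equal(tt$iron_CD206, sum(oc & !oa))
    expect_equal(tt$iron_AIF1_CD206, sum(oa & oc))
    expect_equal(tt$iron_CSF1R_AIF1_CD206, sum(os & oa & oc))
    # combination counts never exceed constituent counts
    expect_lte(tt$iron_AIF1 + tt$iron_AIF1_CD206, tt$n_AIF1)
    expect_lte(tt$iron_CD206 + tt$iron_AIF1_CD206, tt$n_CD206)
    expect_lte(tt$iron_AIF1 + tt$iron_CD206 + tt$iron_AIF1_CD206,
               tt$n_iron)
  }
})

test_that("fractional populations partition and handle zero denominators", {
  mk <- function(a, c2, ac, sa = 0, sc = 0, sac = 0)
    structure(list(n_AIF1 = 9L, n_CD206 = 9L, n_CSF1R = 9L, n_iron = 9L,
                   iron_AIF1 = a, iron_CD206 = c2, iron_AIF1_CD206 = ac,
                   iron_CSF1R_AIF1 = sa, iron_CSF1R_CD206 = sc,
                   iron_CSF1R_AIF1_CD206 = sac),
              class = "copositivity_table")
  fp <- fractional_populations(mk(1, 1, 0))
  expect_equal(unname(fp$polarization), c(0.5, 0.5, 0))
  # zero denominator: undefined, not zero
  fp0 <- fractional_populations(mk(0, 0, 0))
  expect_true(all(is.na(fp0$polarization)))
  # random tables: triplets sum to one and match hand arithmetic
  set.seed(14)
  for (k in 1:20) {
    v <- sample(0:9, 6, replace = TRUE)
    fp2 <- fractional_populations(mk(v[1], v[2], v[3], v[4], v[5], v[6]))
    if (sum(v[1:3]) > 0) {
      expect_equal(sum(fp2$polarization), 1)
      expect_equal(unname(fp2$polarization[2]), v[2] / sum(v[1:3]))
    }
    if (sum(v[4:6]) > 0) expect_equal(sum(fp2$csf1r), 1)
  }
})
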
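test_that("rotation converts to arc length on a 50 mm sphere", {
  expect_identical(rotation_to_mm(0), 0)
  expect_equal(rotation_to_mm(1), 50 * pi / 180)
  expect_equal(rotation_to_mm(-2), -2 * 50 * pi / 180)
  expect_equal(rotation_to_mm(pi / 2, units = "radians"), 50 * pi / 2)
  expect_equal(rotation_to_mm(1, radius_mm = 100), 100 * pi / 180)
})

test_that("framewise displacement sums absolute parameter changes", {
  zero <- matrix(0, 5, 6)
  fd0 <- framewise_displacement(zero)
  expect_equal(fd0$fd_series, rep(0, 5))
  expect_equal(fd0$mean_fd, 0)
  expect_false(fd0$excluded)

  # one +1 mm step in x between volumes 1 and 2
  m <- matrix(0, 4, 6)
  m[2:4, 1] <- 1
  fd <- framewise_displacement(m)
  expect_equal(fd$fd_series, c(0, 1, 0, 0))
  expect_equal(fd$mean_fd, 0.25)

  # one +1 degree pitch step contributes the arc length
  m2 <- matrix(0, 4, 6)
  m2[3:4, 4] <- 1
  fd2 <- framewise_displacement(m2)
  expect_equal(fd2$fd_series[3], 50 * pi / 180)

  expect_error(framewise_displacement(matrix(0, 5, 5)), "6 columns")
})

test_that("FD depends only on differences and exclusion is monotone", {
  set.seed(42)
  for (i in 1:20) {
    m <- matrix(cumsum(rnorm(30 * 6, 0, 0.1)), 30, 6)
    shift <- matrix(rep(rnorm(6, 0, 5), each = 30), 30, 6)
    expect_equal(framewise_displacement(m)$fd_series,
                 framewise_displacement(m + shift)$fd_series)
    base <- framewise_displacement(m)
    for (c_scale in c(1, 2, 10)) {
      sc <- framewise_displacement(m * c_scale)
      if (base$excluded) expect_true(sc$excluded)
    }
  }
})

test_that("exclusion thresholds flag exactly the crossing traces", {
  # slow ramp keeps mean FD tiny so only the translation rule can fire
  over_trans <- matrix(0, 30, 6); over_trans[, 2] <- seq(0, 3.01, length = 30)
  expect_true(framewise_displacement(over_trans)$excluded)
  expect_match(framewise_displacement(over_trans)$exclusion_reason,
               "translation")
  at_trans <- matrix(0, 30, 6); at_trans[, 2] <- seq(0, 3, length = 30)
  expect_false(framewise_displacement(at_trans)$excluded)

  # oscillating 0.7 mm in x: mean FD = 0.7 * 9/10 = 0.63 > 0.5 while the
  # maximum translation stays far below 3 mm
  wiggle <- matrix(0, 10, 6); wiggle[, 1] <- rep(c(0, 0.7), 5)
  expect_true(all(abs(wiggle[, 1]) <= 3))
  fd <- framewise_displacement(wiggle)
  expect_true(fd$excluded)
  expect_match(fd$exclusion_reason, "mean FD")
})

test_that("nuisance design has the documented column structure", {
  set.seed(7)
  m <- matrix(cumsum(rnorm(235 * 6, 0, 0.05)), 235, 6)
  d <- build_nuisance_design(m, tr = 2)
  expect_length(d$columns$motion, 24)
  # filter column count equals direct enumeration of out-of-band components
  k <- 1:234
  f <- k / (2 * 235 * 2)
  expect_length(d$columns$filter, sum(f < 0.01 | f > 0.08))
  expect_equal(ncol(d$x), 1 + 24 + length(d$columns$filter))

  # the lag columns are the one-volume-back copies, zero-padded
  expect_equal(unname(d$x[, "m1_lag"]), c(0, m[-235, 1]))
  expect_equal(unname(d$x[, "m3_sq"]), m[, 3]^2)

  # band covering everything -> no filter columns
  d_all <- build_nuisance_design(m, tr = 2, band = c(0, 0.25))
  expect_length(d_all$columns$filter, 0)

  # tissue signals appended
  d_t <- build_nuisance_design(m, tissue = cbind(global = rnorm(235)),
                               tr = 2)
  expect_equal(ncol(d_t$x), ncol(d$x) + 1)

  expect_error(build_nuisance_design(m[1:40, ], tr = 2), "underdetermined")
})

test_that("cleaning returns residuals orthogonal to the design", {
  set.seed(8)
  t_len <- 120
  m <- matrix(cumsum(rnorm(t_len * 6, 0, 0.05)), t_len, 6)
  d <- build_nuisance_design(m, tr = 2)
  y <- roi_timeseries(matrix(rnorm(t_len * 4), t_len, 4), tr_seconds = 2)
  clean <- clean_timeseries(y, d)
  expect_lt(max(abs(crossprod(d$x, clean$data))), 1e-8)

  # a series equal to a design column is annihilated
  y2 <- roi_timeseries(cbind(d$x[, "m1"], d$x[, "dct1"]), tr_seconds = 2)
  clean2 <- clean_timeseries(y2, d)
  expect_lt(max(abs(clean2$data)), 1e-8)

  # idempotence
  twice <- clean_timeseries(clean, d)
  expect_equal(twice$data, clean$data, tolerance = 1e-10)

  # a rank-deficient design warns but completes
  dd <- cbind(d$x, d$x[, 2])
  expect_warning(clean_timeseries(y, dd), "rank-deficient")
})

test_that("joint cleaning band-passes: out-of-band power < 1% of total", {
  set.seed(9)
  t_len <- 235; tr <- 2
  m <- matrix(cumsum(rnorm(t_len * 6, 0, 0.02)), t_len, 6)
  d <- build_nuisance_design(m, tr = tr)
  y <- roi_timeseries(matrix(rnorm(t_len * 3), t_len, 3), tr_seconds = tr)
  clean <- clean_timeseries(y, d)
  # allow one periodogram bin (1 / (T * TR) Hz) beyond each band edge:
  # bins straddling the edge are inside the filter's own resolution
  bin <- 1 / (t_len * tr)
  for (j in 1:3) {
    sp <- stats::spec.pgram(stats::ts(clean$data[, j], deltat = tr),
                            taper = 0.1, plot = FALSE, detrend = FALSE)
    inband <- sp$freq >= 0.01 - bin & sp$freq <= 0.08 + bin
    expect_lt(sum(sp$spec[!inband]) / sum(sp$spec), 0.01)
  }
})

test_that("ROI extraction averages voxels by label and round-trips", {
  # one label covering everything -> global mean
  img <- array(rnorm(3 * 3 * 2 * 10), c(3, 3, 2, 10))
  atlas1 <- array(1L, c(3, 3, 2))
  expect_error(extract_roi_timeseries(img, atlas1, 2), "at least 2 regions")

  # two labels, one of them two voxels -> (a + b) / 2
  atlas <- array(1L, c(3, 3, 2))
  atlas[1, 1, 1] <- 2L; atlas[2, 1, 1] <- 2L
  ts2 <- extract_roi_timeseries(img, atlas, 2)
  expect_equal(ts2$data[, 2],
               (img[1, 1, 1, ] + img[2, 1, 1, ]) / 2)

  # painting a known per-label series recovers it exactly
  truth <- matrix(rnorm(10 * 3), 10, 3)
  atlas3 <- array(rep(1:3, length.out = 27), c(3, 3, 3))
  img3 <- array(0, c(3, 3, 3, 10))
  for (v in 1:27) {
    ijk <- arrayInd(v, c(3, 3, 3))
    img3[ijk[1], ijk[2], ijk[3], ] <- truth[, atlas3[v]]
  }
  got <- extract_roi_timeseries(img3, atlas3, 2)
  expect_equal(unname(got$data), truth)

  # missing label errors with its id
  atlas_bad <- atlas3; atlas_bad[atlas_bad == 2L] <- 1L
  expect_error(extract_roi_timeseries(img3, atlas_bad, 2), "2")
  expect_error(extract_roi_timeseries(img3, atlas3[1:2, , ], 2), "grid")
})
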
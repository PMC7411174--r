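test_that("Gaussian smoothing is identity at fwhm 0 and preserves constants", {
  arr <- array(rnorm(6 * 6 * 6), dim = c(6, 6, 6))
  expect_identical(smooth_gaussian(arr, 0), arr)
  const <- array(3.7, dim = c(8, 8, 4))
  sm <- smooth_gaussian(const, fwhm = 4, voxel_size = 2)
  expect_equal(sm, const, tolerance = 1e-12)
  expect_error(smooth_gaussian(arr, -1), "fwhm")
})

test_that("smoothing a delta reproduces the separable Gaussian kernel", {
  d <- c(11, 11, 11)
  arr <- array(0, dim = d)
  arr[6, 6, 6] <- 1
  fwhm <- 4; vox <- 2
  sm <- smooth_gaussian(arr, fwhm, vox)
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / vox
  # kernel evaluated directly at the offsets
  kern <- function(k) exp(-k^2 / (2 * sigma^2))
  expect_equal(sm[7, 6, 6] / sm[6, 6, 6], kern(1) / kern(0),
               tolerance = 1e-10)
  expect_equal(sm[6, 8, 6] / sm[6, 6, 6], kern(2) / kern(0),
               tolerance = 1e-10)
  expect_equal(sm[7, 7, 7] / sm[6, 6, 6], (kern(1) / kern(0))^3,
               tolerance = 1e-10)
  # anisotropic voxels handled per axis
  sma <- smooth_gaussian(arr, fwhm, c(2, 4, 4))
  s2 <- fwhm / (2 * sqrt(2 * log(2))) / 4
  expect_equal(sma[6, 7, 6] / sma[6, 6, 6], exp(-1 / (2 * s2^2)),
               tolerance = 1e-10)
})

test_that("whole-brain mask segmentation recovers the phantom brain", {
  s <- clean_subject()
  mean_e1 <- apply(s$dual_echo$echo1, 1:3, mean)
  wb <- compute_wb_mask(mean_e1)
  recovered <- sum(wb & s$masks$wb) / sum(s$masks$wb)
  expect_gte(recovered, 0.99)
  expect_error(compute_wb_mask(array(0, dim = c(4, 4, 4))), "threshold")
  # threshold 0 keeps every strictly positive voxel (largest component)
  v <- array(0, dim = c(8, 8, 8)); v[2:4, 2:4, 2:4] <- 1
  expect_equal(sum(compute_wb_mask(v, threshold_frac = 0)), 27)
})

test_that("surround subtraction matches hand computation and cancels drift", {
  x <- rep(c(102, 100), 6)  # control, label, ...
  dm <- surround_subtract(x, "control")
  expect_equal(dm$values, rep(2, 12))
  expect_equal(dm$kind, "perfusion-weighted")

  # label-first sign convention
  dml <- surround_subtract(rep(c(100, 102), 6), "label")
  expect_equal(dml$values, rep(2, 12))

  # linear drift leaves interior values unchanged; endpoints deviate
  d <- 0.37
  xd <- x + d * seq_along(x)
  dmd <- surround_subtract(xd, "control")
  expect_equal(dmd$values[2:11], rep(2, 10), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(dmd$values[1], 2)))

  expect_equal(surround_subtract(rep(5, 10))$values, rep(0, 10))
  expect_error(surround_subtract(c(1, 2)), "3 time points")
})

test_that("surround subtraction equals the brute-force loop on short series", {
  set.seed(11)
  for (n in 3:12) {
    for (first in c("control", "label")) {
      x <- rnorm(n)
      expect_equal(surround_subtract(x, first)$values,
                   surround_subtract_loop(x, first), tolerance = 1e-12)
    }
  }
})

test_that("surround operators are linear and agree between 1D and 4D paths", {
  set.seed(12)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(surround_subtract(a + b)$values,
               surround_subtract(a)$values + surround_subtract(b)$values,
               tolerance = 1e-12)
  expect_equal(surround_add(a + b)$values,
               surround_add(a)$values + surround_add(b)$values,
               tolerance = 1e-12)
  arr <- array(rnorm(2 * 2 * 2 * 10), dim = c(2, 2, 2, 10))
  d4 <- surround_subtract(arr, "control")
  expect_equal(d4$values[1, 2, 1, ],
               surround_subtract(arr[1, 2, 1, ], "control")$values,
               tolerance = 1e-12)
})

test_that("surround addition removes the control/label alternation", {
  x <- rep(c(102, 100), 6)
  b <- surround_add(x)
  expect_equal(b$values[2:11], rep(101, 10))
  expect_equal(surround_add(rep(7, 8))$values, rep(7, 8))
  # a step survives with at most one-sample blur
  st <- c(rep(0, 6), rep(10, 6))
  bs <- surround_add(st)$values
  expect_equal(bs[1:5], rep(0, 5))
  expect_equal(bs[8:12], rep(10, 5))
  expect_true(all(bs >= 0 & bs <= 10))
})

test_that("ROI time courses are unweighted mask means", {
  arr <- array(0, dim = c(3, 3, 1, 4))
  arr[1, 1, 1, ] <- 1:4
  arr[2, 1, 1, ] <- 5:8
  ps <- new_processed_series(arr, "bold", 4)
  m1 <- array(FALSE, dim = c(3, 3, 1)); m1[1, 1, 1] <- TRUE
  expect_equal(roi_time_course(ps, m1)$values, 1:4)
  m2 <- m1; m2[2, 1, 1] <- TRUE
  expect_equal(roi_time_course(ps, m2)$values, (1:4 + 5:8) / 2)
  expect_error(roi_time_course(ps, array(FALSE, dim = c(3, 3, 1))), "empty")
})

test_that("epoch averaging uses half-open windows and ignores the middle", {
  tl <- acquisition_timeline(tr = 4, n_volumes = 150L,
                             ra_window = c(0, 240), hc_window = c(360, 600))
  t_acq <- (0:149) * 4
  x <- ifelse(t_acq < 240, 1, ifelse(t_acq >= 360, 2, 99))
  em <- epoch_average(new_processed_series(x, "bold", 4), tl)
  expect_equal(em$s_ra, 1)
  expect_equal(em$s_hc, 2)

  # transition values never leak into either epoch
  x2 <- x; x2[t_acq >= 240 & t_acq < 360] <- -1e6
  em2 <- epoch_average(new_processed_series(x2, "bold", 4), tl)
  expect_equal(em2$s_ra, em$s_ra)
  expect_equal(em2$s_hc, em$s_hc)

  # a volume at exactly t0 of the next window is excluded from RA
  expect_equal(em$n_ra, 60)  # volumes 0..59 (t = 0..236); t = 240 excluded

  const <- epoch_average(new_processed_series(rep(5, 150), "bold", 4), tl)
  expect_equal(const$s_ra, const$s_hc)

  tl_bad <- acquisition_timeline(tr = 4, n_volumes = 150L,
                                 ra_window = c(0, 4), hc_window = c(360, 600))
  expect_error(
    epoch_average(new_processed_series(x, "bold", 4), tl_bad), "2 volumes")
})
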
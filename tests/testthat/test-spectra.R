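make_ps <- function(peaks, n_row = 4, n_col = 4) {
  n <- n_row * n_col
  pixels <- data.frame(pixel = seq_len(n),
                       row = rep(seq_len(n_row) - 1L, each = n_col),
                       col = rep(seq_len(n_col) - 1L, times = n_row))
  pixel_spectra(pixels, peaks)
}

test_that("peak reduction applies a strict intensity threshold then top-n", {
  ps <- make_ps(data.frame(pixel = 1, mz = c(400, 500, 600),
                           intensity = c(50, 150, 300)))
  red <- reduce_peaks(ps, top_n = 3000, min_intensity = 100)
  expect_equal(red$peaks$intensity, c(150, 300))
  # intensity exactly at the threshold is removed
  ps2 <- make_ps(data.frame(pixel = 1, mz = 400, intensity = 100))
  expect_equal(nrow(reduce_peaks(ps2)$peaks), 0)
  # top_n keeps the most intense, output re-sorted by m/z
  ps3 <- make_ps(data.frame(pixel = 1, mz = 5:1 * 100,
                            intensity = c(10, 50, 30, 40, 20)))
  red3 <- reduce_peaks(ps3, top_n = 2, min_intensity = 0)
  expect_equal(red3$peaks$mz, c(200, 400))
  expect_equal(red3$peaks$intensity, c(40, 50))
})

test_that("reduction ties at the top-n boundary keep the lower m/z peak", {
  ps <- make_ps(data.frame(pixel = 1, mz = c(300, 500, 700),
                           intensity = c(10, 8, 8)))
  red <- reduce_peaks(ps, top_n = 2, min_intensity = 0)
  expect_equal(red$peaks$mz, c(300, 500))
  # same intensities listed in reverse m/z order give the same answer
  ps_rev <- make_ps(data.frame(pixel = 1, mz = c(700, 500, 300),
                               intensity = c(8, 8, 10)))
  expect_equal(reduce_peaks(ps_rev, top_n = 2, min_intensity = 0)$peaks$mz,
               c(300, 500))
})

test_that("peak reduction is idempotent", {
  set.seed(42)
  ps <- make_ps(data.frame(pixel = rep(1:16, each = 20),
                           mz = runif(320, 100, 900),
                           intensity = rexp(320, 1 / 200)))
  once <- reduce_peaks(ps, top_n = 10, min_intensity = 50)
  twice <- reduce_peaks(once, top_n = 10, min_intensity = 50)
  expect_identical(once$peaks, twice$peaks)
})

test_that("target binning uses half-open bins with origin at zero", {
  ps <- make_ps(data.frame(pixel = c(1, 2), mz = c(700.01, 700.03),
                           intensity = c(1, 1)))
  expect_equal(nrow(build_target_list(ps, mz_bin = 0.04)), 1)
  ps2 <- make_ps(data.frame(pixel = c(1, 2), mz = c(700.03, 700.05),
                            intensity = c(1, 1)))
  expect_equal(nrow(build_target_list(ps2, mz_bin = 0.04)), 2)
})

test_that("target centres are the intensity-weighted means of member peaks", {
  ps <- make_ps(data.frame(pixel = c(1, 2, 3),
                           mz = c(700.010, 700.020, 700.030),
                           intensity = c(1, 1, 2)))
  tl <- build_target_list(ps, mz_bin = 0.04)
  expect_equal(nrow(tl), 1)
  expect_equal(tl$mz_center, 700.0225)
  expect_warning(build_target_list(make_ps(data.frame(
    pixel = integer(), mz = numeric(), intensity = numeric()))),
    "no peaks")
})

test_that("drift time, when present, partitions the bins", {
  ps <- make_ps(data.frame(pixel = c(1, 2), mz = c(700.01, 700.01),
                           intensity = c(1, 1), drift = c(50, 250)))
  tl <- build_target_list(ps, mz_bin = 0.04, drift_bin = 100)
  expect_equal(nrow(tl), 2)
})

test_that("re-binning assigns to the nearest target, lower m/z on ties", {
  tl <- build_target_list(make_ps(data.frame(
    pixel = c(1, 1), mz = c(700.02, 700.10), intensity = c(1, 1))),
    mz_bin = 0.04)
  expect_equal(tl$mz_center, c(700.02, 700.10))
  # exact centre
  ps <- make_ps(data.frame(pixel = 1, mz = 700.10, intensity = 5))
  img <- rebin_to_targets(ps, tl)
  expect_equal(unname(img$matrix[1, ]), c(0, 5))
  # exact midpoint 700.06 goes to the lower-m/z target
  ps_mid <- make_ps(data.frame(pixel = 1, mz = 700.06, intensity = 3))
  img_mid <- rebin_to_targets(ps_mid, tl)
  expect_equal(unname(img_mid$matrix[1, ]), c(3, 0))
  # empty pixels give all-zero rows
  expect_true(all(img$matrix[2:16, ] == 0))
})

test_that("re-binning conserves assigned intensity and counts drops", {
  set.seed(7)
  ps <- make_ps(data.frame(pixel = rep(1:16, each = 10),
                           mz = runif(160, 400, 900),
                           intensity = rexp(160, 1 / 100)))
  tl <- build_target_list(ps, mz_bin = 0.04)
  img <- rebin_to_targets(ps, tl)
  expect_equal(img$n_dropped, 0)
  per_pixel <- tapply(ps$peaks$intensity, ps$peaks$pixel, sum)
  expect_equal(unname(rowSums(img$matrix)[as.integer(names(per_pixel))]),
               as.numeric(per_pixel))
  # a far-away peak is dropped, not forced into a bin
  ps_far <- make_ps(data.frame(pixel = 1, mz = 200, intensity = 1))
  img_far <- rebin_to_targets(ps_far, tl)
  expect_equal(img_far$n_dropped, 1)
  expect_true(all(img_far$matrix == 0))
})

test_that("lock-mass correction lands the standard on the reference", {
  ref <- 753.6134
  mk <- function(shift_ppm) {
    f <- 1 + shift_ppm * 1e-6
    make_ps(data.frame(pixel = rep(1:4, each = 2),
                       mz = rep(c(600.0, ref) * f, 4),
                       intensity = rep(c(100, 5000), 4)))
  }
  up <- lock_mass_correct(mk(20), ref, search_window = 50)
  down <- lock_mass_correct(mk(-20), ref, search_window = 50)
  std_up <- up$peaks$mz[which.min(abs(up$peaks$mz - ref))]
  std_down <- down$peaks$mz[which.min(abs(down$peaks$mz - ref))]
  expect_lt(abs(std_up - std_down) / ref * 1e6, 0.1)
  expect_equal(std_up, ref, tolerance = 1e-9)
  expect_equal(up$metadata$lockmass_shift_ppm, 20, tolerance = 1e-3)
  # identity when already calibrated
  same <- lock_mass_correct(mk(0), ref, search_window = 50)
  expect_equal(same$peaks$mz, mk(0)$peaks$mz)
  # warning and no change when the standard is absent
  no_std <- make_ps(data.frame(pixel = 1, mz = 400, intensity = 10))
  expect_warning(out <- lock_mass_correct(no_std, ref), "no peak")
  expect_equal(out$peaks$mz, 400)
})
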
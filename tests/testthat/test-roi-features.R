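mini_image <- function(values, n_col = 2) {
  # values: pixels x ions matrix; grid is one row of pixels per matrix row
  n_px <- nrow(values)
  tl <- structure(data.frame(bin_id = paste0("t_", seq_len(ncol(values))),
                             mz_center = 500 + seq_len(ncol(values)),
                             drift_center = NA_real_),
                  mz_bin = 0.04, class = c("TargetList", "data.frame"))
  colnames(values) <- tl$bin_id
  structure(list(matrix = values,
                 pixels = data.frame(pixel = seq_len(n_px),
                                     row = (seq_len(n_px) - 1L) %/% n_col,
                                     col = (seq_len(n_px) - 1L) %% n_col),
                 target_list = tl, metadata = list(), provenance = ""),
            class = "BinnedImage")
}

roi_df <- function(...) roi_set(data.frame(...))

test_that("feature extraction averages ROI member pixels", {
  img <- mini_image(matrix(c(4, 6, 8, 10), 2, 2), n_col = 2)
  rois <- roi_df(roi_id = c("a", "a", "s"), row = c(0, 0, 0),
                 col = c(0, 1, 0), tissue = "marrow",
                 kind = c("lROI", "lROI", "sROI"))
  fm <- extract_features(img, rois)
  expect_equal(unname(fm$values["a", ]), c(5, 9))     # mean of the two pixels
  expect_equal(unname(fm$values["s", ]), c(4, 8))     # single pixel identity
  bad <- roi_df(roi_id = "x", row = 9, col = 9, tissue = "marrow",
                kind = "sROI")
  expect_error(extract_features(img, bad), "x")
})

test_that("TIC normalization scales rows to unit sum and is idempotent", {
  fm <- feature_matrix(matrix(c(2, 3, 5, 20, 30, 50), 2, 3, byrow = TRUE,
                              dimnames = list(NULL, c("a", "b", "c"))),
                       data.frame(roi_id = c("r1", "r2"), tissue = "m",
                                  kind = "lROI"))
  out <- tic_normalize(fm)
  expect_equal(unname(out$values[1, ]), c(0.2, 0.3, 0.5))
  # rows that are scalar multiples coincide after TIC
  expect_equal(out$values[1, ], out$values[2, ])
  expect_equal(tic_normalize(out)$values, out$values)
  zero <- feature_matrix(matrix(0, 2, 2, dimnames = list(NULL, c("a", "b"))),
                         data.frame(roi_id = c("r1", "r2"), tissue = "m",
                                    kind = "lROI"))
  expect_warning(tic_normalize(zero), "all-zero")
})

test_that("matrix-ion filter applies the two-sigma interval inequality", {
  # ion 1: matrix 950/1050 (mean 1000, sd 50), tissue 100/300 (mean 200,
  # sd 100): 900 > 400 -> excluded. ion 2: matrix 600/1400 (sd 400),
  # tissue 400/600 (sd 100): 200 > 700 false -> kept
  vals <- rbind(c(950, 600), c(1050, 1400), c(100, 400), c(300, 600))
  colnames(vals) <- c("ion1", "ion2")
  fm <- feature_matrix(vals, data.frame(
    roi_id = paste0("r", 1:4), tissue = c("matrix", "matrix", "gp", "gp"),
    kind = c("matrix", "matrix", "lROI", "lROI")))
  out <- matrix_ion_filter(fm)
  expect_equal(colnames(out$values), "ion2")
  expect_equal(out$excluded$bin_id, "ion1")
  # fewer than 2 ROIs on one side is an error
  fm3 <- feature_matrix(vals[-1, , drop = FALSE], data.frame(
    roi_id = paste0("r", 2:4), tissue = c("matrix", "gp", "gp"),
    kind = c("matrix", "lROI", "lROI")))
  expect_error(matrix_ion_filter(fm3), ">= 2")
})

test_that("matrix-ion filter never removes tissue-dominant ions", {
  set.seed(31)
  for (rep in 1:20) {
    vals <- matrix(rexp(8 * 6, 1 / 100), 8, 6,
                   dimnames = list(NULL, paste0("i", 1:6)))
    fm <- feature_matrix(vals, data.frame(
      roi_id = paste0("r", 1:8),
      tissue = rep(c("matrix", "gp"), each = 4),
      kind = rep(c("matrix", "lROI"), each = 4)))
    out <- matrix_ion_filter(fm)
    mu_m <- colMeans(vals[1:4, ]); mu_t <- colMeans(vals[5:8, ])
    dominant <- colnames(vals)[mu_t >= mu_m]
    expect_true(all(dominant %in% colnames(out$values)))
  }
})

test_that("log scaling matches log2(x + pseudocount) and flips the flag", {
  fm <- feature_matrix(matrix(c(0, 3), 2, 1, dimnames = list(NULL, "a")),
                       data.frame(roi_id = c("r1", "r2"), tissue = "m",
                                  kind = "lROI"))
  out <- log_scale(fm, pseudocount = 1)
  expect_equal(unname(out$values[, 1]), c(0, 2))
  expect_equal(out$scale, "log2")
  # monotonicity on an arbitrary column
  x <- matrix(sort(runif(10, 0, 50)), 10, 1, dimnames = list(NULL, "a"))
  fmx <- feature_matrix(x, data.frame(roi_id = paste0("r", 1:10),
                                      tissue = "m", kind = "lROI"))
  expect_false(is.unsorted(log_scale(fmx)$values[, 1]))
  expect_error(log_scale(out), "linear")
})

test_that("z-scoring centres columns by their population SD", {
  fm <- feature_matrix(matrix(c(0, 0, 4, 4, 1, 1, 1, 1), 4, 2,
                              dimnames = list(NULL, c("a", "b"))),
                       data.frame(roi_id = paste0("r", 1:4), tissue = "m",
                                  kind = "lROI"), scale = "log2")
  expect_warning(out <- zscore_columns(fm), "zero-variance")
  expect_equal(unname(out$values[, "a"]), c(-1, -1, 1, 1))
  expect_equal(unname(out$values[, "b"]), rep(0, 4))
  # means 0 and population SDs 1 for non-degenerate columns
  set.seed(5)
  big <- feature_matrix(matrix(rnorm(60), 10, 6,
                               dimnames = list(NULL, paste0("i", 1:6))),
                        data.frame(roi_id = paste0("r", 1:10), tissue = "m",
                                   kind = "lROI"), scale = "log2")
  z <- zscore_columns(big)$values
  expect_equal(unname(colMeans(z)), rep(0, 6))
  expect_equal(unname(sqrt(colMeans(sweep(z, 2, colMeans(z))^2))), rep(1, 6))
  one_row <- feature_matrix(matrix(1, 1, 2, dimnames = list(NULL,
                                                            c("a", "b"))),
                            data.frame(roi_id = "r1", tissue = "m",
                                       kind = "lROI"))
  expect_error(zscore_columns(one_row), ">= 2")
})

test_that("the canonical preprocessing order is recorded in provenance", {
  out <- generate_phantom(phantom_spec(grid_shape = c(20, 10),
                                       lipid_panel = tiny_panel(),
                                       standard_spec = NULL, seed = 8))
  img <- rebin_to_targets(reduce_peaks(out$spectra, min_intensity = 10),
                          build_target_list(out$spectra))
  rois <- auto_rois(out$spectra$pixels, n_per_region = 2, size = 5,
                    n_matrix = 2, seed = 4)
  fm <- preprocess_features(img, rois)
  expect_equal(fm$scale, "log2")
  steps <- fm$provenance
  expect_lt(grep("extract_features", steps), grep("tic_normalize", steps))
  expect_lt(grep("tic_normalize", steps), grep("matrix_ion_filter", steps))
  expect_lt(grep("matrix_ion_filter", steps), grep("log_scale", steps))
})
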
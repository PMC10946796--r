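test_that("Pareto scaling divides centred columns by the root of their SD", {
  X <- cbind(a = c(0, 0, 4, 4), b = c(1, 1, 1, 1))
  sc <- pareto_scale(X)
  expect_equal(unname(sc$X[, "a"]), c(-1.4142, -1.4142, 1.4142, 1.4142),
               tolerance = 1e-4)
  expect_equal(unname(sc$X[, "b"]), rep(0, 4))
  expect_equal(sc$flagged, "b")
  # after scaling, each column's SD is the square root of the original SD
  set.seed(2)
  Y <- matrix(rnorm(50, sd = 4), 10, 5)
  scy <- pareto_scale(Y)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(apply(scy$X, 2, pop_sd), sqrt(apply(Y, 2, pop_sd)),
               tolerance = 1e-12)
})

test_that("PCA reproduces a full singular decomposition on small data", {
  set.seed(9)
  X <- matrix(rnorm(30), 6, 5)
  m <- fit_pca(X, n_components = 3)
  # oracle: svd of the same Pareto-scaled matrix
  sc <- pareto_scale(X)
  sv <- svd(sc$X)
  for (k in 1:3) {
    expect_equal(abs(m$scores[, k]), abs(sv$u[, k] * sv$d[k]),
                 tolerance = 1e-8)
    expect_equal(abs(m$loadings[, k]), abs(sv$v[, k]), tolerance = 1e-8)
  }
  expect_equal(m$explained_variance_pct,
               (sv$d^2 / sum(sv$d^2) * 100)[1:3], tolerance = 1e-8)
  # scores equal projections of the scaled data
  expect_equal(m$scores, sc$X %*% m$loadings, tolerance = 1e-8)
  expect_error(fit_pca(X, n_components = 6), "n_components")
})

test_that("explained variances are non-increasing and one-dimensional data
           load onto a single component", {
  set.seed(10)
  t <- rnorm(8)
  X <- outer(t, c(1, -2, 0.5)) # rank one
  m <- fit_pca(X, n_components = 2)
  expect_equal(m$explained_variance_pct[1], 100, tolerance = 1e-8)
  Y <- matrix(rnorm(60), 10, 6)
  my <- fit_pca(Y, n_components = 5)
  expect_true(all(diff(my$explained_variance_pct) <= 1e-12))
  expect_lte(sum(my$explained_variance_pct), 100 + 1e-8)
})

test_that("a single discriminating ion dominates the S-plot", {
  set.seed(3)
  X <- matrix(rnorm(20 * 6, sd = 1e-4), 20, 6,
              dimnames = list(NULL, paste0("i", 1:6)))
  X[, 4] <- rep(c(0, 5), each = 10)
  m <- fit_oplsda(X, rep(c("WT", "KO"), each = 10), n_orth = 0,
                  positive_class = "KO")
  expect_equal(abs(m$splot_corr[["i4"]]), 1, tolerance = 1e-6)
  expect_true(all(abs(m$splot_corr[-4]) < 0.8))
  # the KO group was coded positive, and ion 4 is high in KO
  expect_gt(mean(m$t_pred[11:20]), 0)
  expect_gt(m$splot_cov[["i4"]], 0)
})

test_that("with no orthogonal components OPLS equals one-component PLS", {
  set.seed(14)
  for (rep in 1:5) {
    X <- matrix(rnorm(48), 8, 6)
    y <- rep(c(-1, 1), 4)
    m <- fit_oplsda(X, ifelse(y > 0, "B", "A"), n_orth = 0,
                    positive_class = "B")
    oracle <- nipals_pls1_oracle(pareto_scale(X)$X, y, n_comp = 1)
    # equal up to sign
    d <- min(max(abs(m$t_pred - oracle$scores[, 1])),
             max(abs(m$t_pred + oracle$scores[, 1])))
    expect_lt(d, 1e-8)
  }
})

test_that("orthogonal scores are orthogonal to the predictive score", {
  set.seed(15)
  X <- matrix(rnorm(12 * 20), 12, 20)
  y <- rep(c("A", "B"), each = 6)
  m <- fit_oplsda(X, y, n_orth = 2)
  for (k in seq_len(ncol(m$t_orth))) {
    expect_lt(abs(sum(m$t_orth[, k] * m$t_pred)), 1e-10)
  }
  expect_error(fit_oplsda(X, rep("A", 12)), "two groups")
  expect_error(fit_oplsda(X, y, n_orth = 50), "rank")
})

test_that("S-plot covariance and correlation share signs and |corr| <= 1", {
  set.seed(16)
  X <- matrix(rnorm(10 * 8), 10, 8)
  X[, 1] <- X[, 1] + rep(c(0, 2), each = 5)
  m <- fit_oplsda(X, rep(c("A", "B"), each = 5))
  nz <- abs(m$splot_cov) > 1e-12
  expect_true(all(sign(m$splot_cov[nz]) == sign(m$splot_corr[nz])))
  expect_true(all(abs(m$splot_corr) <= 1 + 1e-12))
})

test_that("OPLS with orthogonal removal explains no less Y-variance than
           plain PLS with the same total component count", {
  set.seed(17)
  for (rep in 1:5) {
    X <- matrix(rnorm(12 * 10), 12, 10)
    y <- rep(c(-1, 1), each = 6)
    X[, 1:3] <- X[, 1:3] + outer(y, c(1, 0.5, 0.25))
    m <- fit_oplsda(X, ifelse(y > 0, "B", "A"), n_orth = 1,
                    positive_class = "B")
    oracle <- nipals_pls1_oracle(pareto_scale(X)$X, y, n_comp = 2)
    expect_gte(m$r2y, oracle$r2y - 1e-8)
  }
})

test_that("panel selection applies the absolute threshold with directions", {
  m <- structure(list(
    splot_cov = c(i1 = 0.05, i2 = -0.06, i3 = 0.01),
    splot_corr = c(i1 = 0.9, i2 = -0.8, i3 = 0.2),
    w_pred = c(i1 = 0.7, i2 = -0.7, i3 = 0.1),
    groups = rep(c("WT", "KO"), 3), positive_class = "KO"
  ), class = "OplsModel")
  p <- select_panel(m, stat = "cov", threshold = 0.04)
  expect_setequal(p$bin_id, c("i1", "i2"))
  expect_equal(p$direction[p$bin_id == "i1"], "KO")
  expect_equal(p$direction[p$bin_id == "i2"], "WT")
  # threshold above every |cov| gives an empty panel
  expect_equal(nrow(suppressMessages(
    select_panel(m, "cov", threshold = 1))), 0)
  # monotone: raising the threshold never adds ions
  ths <- c(0.005, 0.02, 0.045, 0.055, 0.1)
  sizes <- vapply(ths, function(th) nrow(suppressMessages(
    select_panel(m, "cov", threshold = th))), 0L)
  expect_true(all(diff(sizes) <= 0))
  # explicit post-hoc exclusions are honoured and logged
  ex <- select_panel(m, "cov", threshold = 0.04, exclude = "i1")
  expect_equal(ex$bin_id, "i2")
  expect_equal(attr(ex, "excluded"), "i1")
})

test_that("panel merging is a union with overlap bookkeeping", {
  mk <- function(ids, src) structure(
    data.frame(bin_id = ids, direction = "KO", cov = 1, corr = 1, stat = 1,
               source = src, stringsAsFactors = FALSE),
    class = c("DiffPanel", "data.frame"))
  a <- mk(c("x", "y", "z"), "A"); b <- mk(c("u", "v", "w", "q"), "B")
  expect_equal(nrow(merge_panels(list(a, b))), 7)
  expect_equal(nrow(merge_panels(list(a, a))), 3)
  # panels sized like the study's tissue panels: 96 and 80 sharing 69
  p1 <- mk(sprintf("ion%03d", 1:96), "juvenile")
  p2 <- mk(sprintf("ion%03d", c(1:69, 97:107)), "adult")
  merged <- merge_panels(list(p1, p2))
  expect_equal(nrow(merged), 107)
  expect_equal(attr(merged, "overlap")[1, 2], 69L)
})

test_that("clustering merges identical profiles first and ignores column
           order", {
  set.seed(20)
  vals <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(NULL, paste0("i", 1:6)))
  vals[2, ] <- vals[1, ]    # duplicate ROI profile
  fm <- feature_matrix(vals, data.frame(roi_id = paste0("r", 1:5),
                                        tissue = c("a", "a", "b", "b", "b"),
                                        kind = "lROI"), scale = "log2")
  hc <- hierarchical_cluster(fm, k = 2)
  first <- hc$row_hclust$merge[1, ]
  expect_setequal(-first, c(1, 2))
  expect_equal(hc$row_hclust$height[1], 0, tolerance = 1e-12)
  perm <- fm
  perm$values <- perm$values[, c(4, 1, 6, 2, 5, 3)]
  hc2 <- hierarchical_cluster(perm, k = 2)
  expect_equal(hc2$row_hclust$height, hc$row_hclust$height,
               tolerance = 1e-12)
  expect_equal(hc2$row_clusters, hc$row_clusters)
  expect_error(hierarchical_cluster(
    feature_matrix(vals[1, , drop = FALSE],
                   data.frame(roi_id = "r1", tissue = "a", kind = "lROI"),
                   scale = "log2")), ">= 2")
})
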
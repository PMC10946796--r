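zone_fm <- function(wt, ko, zone = "resting") {
  vals <- rbind(wt, ko)
  if (is.null(colnames(vals))) colnames(vals) <- paste0("i", seq_len(ncol(vals)))
  rois <- data.frame(
    roi_id = paste0("r", seq_len(nrow(vals))),
    tissue = "growth_plate", zone = zone,
    genotype = rep(c("WT", "KO"), c(nrow(wt), nrow(ko))),
    kind = "lROI")
  feature_matrix(vals, rois, scale = "log2")
}

test_that("identical groups give zero differences and unit fold change", {
  base <- matrix(rep(c(5, 7, 9), each = 4), 4, 3)
  res <- zone_ttest(zone_fm(base, base), zone = "resting")
  expect_equal(res$mean_diff, rep(0, 3))
  expect_equal(res$fold_change, rep(1, 3))
  expect_equal(res$q, rep(1, 3))
  expect_equal(res$flag, rep("zero_variance", 3))
})

test_that("a 0.585 log2 mean difference is a 1.5-fold change", {
  set.seed(41)
  wt <- matrix(rnorm(40, 10, 1e-6), 10, 4)
  ko <- wt + 0.585
  res <- zone_ttest(zone_fm(wt, ko), zone = "resting")
  expect_equal(res$fold_change, rep(2^0.585, 4), tolerance = 1e-4)
  expect_equal(res$fold_change[1], 1.5, tolerance = 1e-3)
  expect_true(all(res$direction == "up_in_KO"))
})

test_that("per-ion statistics agree with the t.test oracle", {
  set.seed(42)
  wt <- matrix(rnorm(5 * 6, 10), 5, 6)
  ko <- matrix(rnorm(7 * 6, 10.5), 7, 6)
  res <- zone_ttest(zone_fm(wt, ko), zone = "resting")
  for (j in 1:6) {
    or <- t.test(ko[, j], wt[, j])           # Welch, two-sided
    expect_equal(res$t_stat[j], unname(or$statistic), tolerance = 1e-10)
    expect_equal(res$p[j], or$p.value, tolerance = 1e-10)
    expect_equal(res$mean_diff[j], mean(ko[, j]) - mean(wt[, j]))
  }
  pooled <- zone_ttest(zone_fm(wt, ko), zone = "resting", var_equal = TRUE)
  or2 <- t.test(ko[, 1], wt[, 1], var.equal = TRUE)
  expect_equal(pooled$p[1], or2$p.value, tolerance = 1e-10)
  expect_error(zone_ttest(zone_fm(wt[1, , drop = FALSE], ko),
                          zone = "resting"), ">= 2")
})

test_that("q-values agree with a brute-force BH step-up oracle", {
  set.seed(43)
  for (rep in 1:25) {
    wt <- matrix(rnorm(6 * 40, 10), 6, 40)
    ko <- matrix(rnorm(6 * 40, 10), 6, 40)
    ko[, 1:4] <- ko[, 1:4] + 1
    res <- zone_ttest(zone_fm(wt, ko), zone = "resting")
    expect_equal(res$q, bh_oracle(res$p), tolerance = 1e-12)
    expect_true(all(res$q >= res$p))
  }
  # the textbook staircase: (0.01, 0.02, 0.03, 0.04) all adjust to 0.04
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
})

test_that("significant sets honour the q cut and fold-change gate", {
  res <- structure(data.frame(
    bin_id = c("i1", "i2", "i3"), mean_diff = c(1, -1, 0.1),
    t_stat = c(5, -5, 5), p = c(0.001, 0.001, 0.001),
    q = c(0.01, 0.01, 0.01), fold_change = 2^c(1, 1, 0.1),
    direction = c("up_in_KO", "down_in_KO", "up_in_KO"), flag = ""),
    zone = "resting", class = c("ZoneTestResult", "data.frame"))
  sets <- significant_sets(res, q_cut = 0.05, fc_cut = 1.5)
  expect_equal(sets$up, "i1")
  expect_equal(sets$down, "i2")
  no_gate <- significant_sets(res, q_cut = 0.05)
  expect_setequal(no_gate$up, c("i1", "i3"))
  res$q <- rep(1, 3)
  empty <- significant_sets(res, q_cut = 0.05)
  expect_length(empty$up, 0)
  expect_length(empty$down, 0)
})

test_that("cross-zone overlap computes common sets and membership patterns", {
  sets <- list(resting = c("a", "b", "c"), proliferating = c("b", "c"),
               hypertrophic = c("b", "c", "d"))
  cz <- cross_zone_overlap(sets)
  expect_setequal(cz$common, c("b", "c"))
  expect_setequal(cz$union, c("a", "b", "c", "d"))
  expect_equal(cz$pairwise["resting", "hypertrophic"], 2L)
  patt <- cz$membership$pattern[cz$membership$ion == "b"]
  expect_equal(patt, "resting&proliferating&hypertrophic")
  disjoint <- cross_zone_overlap(list(z1 = "a", z2 = "b"))
  expect_length(disjoint$common, 0)
})

test_that("overlap unions satisfy inclusion-exclusion on random sets", {
  set.seed(44)
  for (rep in 1:20) {
    pool <- sprintf("ion%02d", 1:15)
    sets <- list(a = sample(pool, 6), b = sample(pool, 5),
                 c = sample(pool, 7))
    cz <- cross_zone_overlap(sets)
    incl_excl <- length(sets$a) + length(sets$b) + length(sets$c) -
      length(intersect(sets$a, sets$b)) -
      length(intersect(sets$a, sets$c)) -
      length(intersect(sets$b, sets$c)) +
      length(Reduce(intersect, sets))
    expect_equal(length(cz$union), incl_excl)
  }
})

test_that("volcano tables carry finite transformed coordinates", {
  set.seed(45)
  wt <- matrix(rnorm(5 * 8, 10), 5, 8)
  ko <- matrix(rnorm(5 * 8, 10), 5, 8)
  res <- zone_ttest(zone_fm(wt, ko), zone = "resting")
  v <- volcano_table(res)
  expect_equal(nrow(v), 8)
  expect_true(all(is.finite(v$neg_log10_q)))
  expect_equal(v$log2_fc, res$mean_diff)
  # the reference points of the plot annotations
  expect_equal(log2(1.5), 0.585, tolerance = 1e-3)
  expect_equal(-log10(0.05), 1.301, tolerance = 1e-3)
  res$q[1] <- 0
  expect_true(is.finite(volcano_table(res)$neg_log10_q[1]))
})

test_that("replicate-level aggregation collapses pseudo-replicates", {
  set.seed(46)
  vals <- matrix(rnorm(12 * 3, 10), 12, 3,
                 dimnames = list(NULL, paste0("i", 1:3)))
  rois <- data.frame(
    roi_id = paste0("r", 1:12), tissue = "growth_plate", zone = "resting",
    genotype = rep(c("WT", "KO"), each = 6),
    replicate = rep(rep(1:3, each = 2), 2), kind = "lROI")
  fm <- feature_matrix(vals, rois, scale = "log2")
  agg <- zone_ttest(fm, zone = "resting", aggregate_replicates = TRUE)
  expect_equal(attr(agg, "n_per_group"), c(3, 3))
})
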
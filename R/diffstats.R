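# Zone-wise univariate differential testing with FDR control, fold-change
# gating, and cross-zone set logic (volcano tables and Venn-style overlaps).

#' Zone-wise multiple t-test between genotypes
#'
#' Per-ion unpaired two-sided t-test (Welch by default, pooled-variance
#' optional) comparing the two genotype groups among the ROIs of one
#' growth-plate zone, on log2-scale data. P-values are Benjamini-Hochberg
#' adjusted across ions within the zone. The mean difference (KO - WT in log2
#' units) gives the fold change `2^|mean_diff|` with direction from its sign.
#' ROIs are the replication unit, as exported from the imaging software; note
#' they are pseudo-replicates within animals — aggregate per replicate first
#' (`aggregate_replicates = TRUE`) for an animal-level analysis.
#'
#' @param fm Log2-scale [feature_matrix()] whose ROI metadata carries `zone`
#'   and `genotype`.
#' @param zone Zone label to test (`"resting"`, `"proliferating"`,
#'   `"hypertrophic"`), or `NULL` to use every row.
#' @param groups Length-2 character vector `(reference, test)`; mean_diff is
#'   test minus reference. Default `c("WT", "KO")`.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param fdr_method Multiple-testing correction, default `"BH"`.
#' @param aggregate_replicates Average ROIs within each `replicate` before
#'   testing.
#' @return `ZoneTestResult`: data.frame with one row per ion (`bin_id`,
#'   `mean_diff`, `t_stat`, `p`, `q`, `fold_change`, `direction`, `flag`) and
#'   attributes `zone`, `n_per_group`.
#' @export
zone_ttest <- function(fm, zone = NULL, groups = c("WT", "KO"),
                       var_equal = FALSE, fdr_method = "BH",
                       aggregate_replicates = FALSE) {
  stopifnot(inherits(fm, "FeatureMatrix"), length(groups) == 2)
  if (fm$scale != "log2") stop("zone_ttest expects a log2-scale matrix")
  keep <- if (is.null(zone)) rep(TRUE, nrow(fm$values)) else
    !is.na(fm$rois$zone) & fm$rois$zone == zone
  vals <- fm$values[keep, , drop = FALSE]
  meta <- fm$rois[keep, , drop = FALSE]
  if (aggregate_replicates) {
    key <- paste(meta$genotype, meta$replicate)
    vals <- do.call(rbind, lapply(split(seq_len(nrow(vals)), key),
                                  function(i) colMeans(vals[i, , drop = FALSE])))
    meta <- data.frame(genotype = sub(" .*", "", rownames(vals)),
                       stringsAsFactors = FALSE)
  }
  a <- vals[meta$genotype == groups[1], , drop = FALSE]
  b <- vals[meta$genotype == groups[2], , drop = FALSE]
  if (nrow(a) < 2 || nrow(b) < 2) {
    stop("zone_ttest needs >= 2 ROIs per genotype in zone '", zone, "'")
  }
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2, stats::var); vb <- apply(b, 2, stats::var)
  mean_diff <- mb - ma
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t_stat <- mean_diff / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  flag <- rep("", length(p))
  degenerate <- !is.finite(t_stat)
  if (any(degenerate)) {
    # zero variance in both groups: no evidence either way
    p[degenerate & mean_diff == 0] <- 1
    t_stat[degenerate & mean_diff == 0] <- 0
    flag[degenerate] <- "zero_variance"
    p[is.na(p)] <- 1
  }
  q <- stats::p.adjust(p, method = fdr_method)
  res <- data.frame(
    bin_id = colnames(vals),
    mean_diff = mean_diff,
    t_stat = t_stat,
    p = p,
    q = q,
    fold_change = 2^abs(mean_diff),
    direction = ifelse(mean_diff > 0, paste0("up_in_", groups[2]),
                       ifelse(mean_diff < 0, paste0("down_in_", groups[2]),
                              "unchanged")),
    flag = flag,
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  structure(res, zone = zone %||% "all",
            n_per_group = c(na, nb), groups = groups,
            fdr_method = fdr_method,
            class = c("ZoneTestResult", "data.frame"))
}

#' Significant up/down ion sets
#'
#' Splits a zone test result into significantly up- and down-regulated ion
#' sets at an FDR cut, with an optional fold-change gate on top.
#'
#' @param res A `ZoneTestResult`.
#' @param q_cut FDR threshold (0 < q_cut < 1), default 0.05.
#' @param fc_cut Optional minimum fold change (ratio, e.g. 1.5), or `NULL`.
#' @return List with character vectors `up` and `down` (bin ids).
#' @export
significant_sets <- function(res, q_cut = 0.05, fc_cut = NULL) {
  stopifnot(inherits(res, "ZoneTestResult"), q_cut > 0, q_cut < 1)
  sig <- res$q < q_cut
  if (!is.null(fc_cut)) sig <- sig & res$fold_change > fc_cut
  list(up = res$bin_id[sig & res$mean_diff > 0],
       down = res$bin_id[sig & res$mean_diff < 0])
}

#' Cross-zone overlap summary
#'
#' Computes all pairwise and triple intersections of per-zone significant-ion
#' sets (the Venn-diagram semantics of the per-zone volcano analyses) and a
#' per-ion membership bit-pattern table.
#'
#' @param sets Named list (one element per zone) of character vectors.
#' @return `CrossZoneSummary`: list with `common` (ions in every zone),
#'   `union`, `pairwise` (count matrix), and `membership` (data.frame of
#'   per-ion zone membership flags and the pattern string).
#' @export
cross_zone_overlap <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2, !is.null(names(sets)))
  zones <- names(sets)
  all_ions <- sort(unique(unlist(sets)))
  memb <- vapply(sets, function(s) all_ions %in% s,
                 logical(length(all_ions)))
  if (length(all_ions) == 1L) memb <- matrix(memb, nrow = 1,
                                             dimnames = list(NULL, zones))
  membership <- data.frame(ion = all_ions, memb,
                           pattern = apply(memb, 1, function(r)
                             paste(zones[r], collapse = "&")),
                           stringsAsFactors = FALSE)
  k <- length(zones)
  pw <- matrix(0L, k, k, dimnames = list(zones, zones))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    pw[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  }
  structure(list(
    common = all_ions[rowSums(memb) == k],
    union = all_ions,
    pairwise = pw,
    membership = membership,
    sets = sets
  ), class = "CrossZoneSummary")
}

#' Volcano-plot table
#'
#' One row per ion with the signed log2 fold change and `-log10(q)`;
#' zero q-values are capped at `q_floor` so every row is finite.
#'
#' @param res A `ZoneTestResult`.
#' @param q_floor Cap applied to `q` before taking logs (default 1e-300).
#' @return data.frame `bin_id`, `log2_fc`, `neg_log10_q`, `q`, `fold_change`,
#'   `direction`.
#' @export
volcano_table <- function(res, q_floor = 1e-300) {
  stopifnot(inherits(res, "ZoneTestResult"))
  data.frame(
    bin_id = res$bin_id,
    log2_fc = res$mean_diff,
    neg_log10_q = -log10(pmax(res$q, q_floor)),
    q = res$q,
    fold_change = res$fold_change,
    direction = res$direction,
    stringsAsFactors = FALSE
  )
}
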
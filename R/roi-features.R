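# ROI definitions, feature-matrix extraction, normalization, and the
# matrix-ion (DHB background) exclusion filter.

#' ROI set
#'
#' Validated table of regions of interest. Each ROI is a labelled set of grid
#' pixels acting as one statistical observation: single-pixel sROIs, 10-pixel
#' (or 5-pixel, for small tissues) lROIs, and off-tissue matrix ROIs used by
#' the background filter.
#'
#' @param df data.frame with columns `roi_id`, `row`, `col`, `tissue`, `kind`
#'   (`sROI`, `lROI` or `matrix`) and optionally `zone`, `bone`, `replicate`,
#'   `genotype`; one row per member pixel.
#' @return Object of classes `RoiSet`/`data.frame`.
#' @export
roi_set <- function(df) {
  need <- c("roi_id", "row", "col", "tissue", "kind")
  stopifnot(all(need %in% names(df)))
  for (opt in c("zone", "bone", "replicate", "genotype")) {
    if (!opt %in% names(df)) df[[opt]] <- NA
  }
  sizes <- table(df$roi_id)
  kinds <- tapply(df$kind, df$roi_id, function(k) k[1])
  bad <- names(sizes)[kinds[names(sizes)] == "sROI" & sizes != 1]
  if (length(bad)) {
    stop("sROI with more than one pixel: ", paste(bad, collapse = ", "))
  }
  mat_rois <- unique(df$roi_id[df$kind == "matrix"])
  if (length(mat_rois)) {
    on_tissue <- df$roi_id %in% mat_rois & df$tissue != "matrix"
    if (any(on_tissue)) stop("matrix ROI contains on-tissue pixels")
  }
  structure(df, class = c("RoiSet", "data.frame"))
}

#' Draw ROIs automatically on a phantom region map
#'
#' Samples non-overlapping lROIs of `size` pixels within each tissue region
#' (growth-plate zones kept separate, labelled with their zone), plus
#' `n_matrix` matrix ROIs from the off-tissue band. A convenience for
#' simulated data; real analyses supply ROI label files.
#'
#' @param pixels data.frame with `row`, `col`, `region` (as produced by the
#'   phantom generator).
#' @param n_per_region lROIs per region.
#' @param size Pixels per lROI.
#' @param n_matrix Off-tissue matrix ROIs.
#' @param genotype Genotype label attached to every ROI.
#' @param replicate Replicate (sample) id attached to every ROI.
#' @param seed RNG seed.
#' @return An [roi_set()].
#' @export
auto_rois <- function(pixels, n_per_region = 4, size = 10, n_matrix = 4,
                      genotype = NA, replicate = 1, seed = 1) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  stopifnot(all(c("row", "col", "region") %in% names(pixels)))
  out <- list()
  for (reg in unique(pixels$region)) {
    px <- pixels[pixels$region == reg, , drop = FALSE]
    n_roi <- if (reg == "off_tissue") n_matrix else n_per_region
    need <- n_roi * size
    if (nrow(px) < need) {
      stop("region ", reg, " has ", nrow(px), " pixels; need ", need)
    }
    pick <- px[sample(nrow(px), need), , drop = FALSE]
    tissue <- region_to_tissue(reg)
    zone <- region_to_zone(reg)
    kind <- if (reg == "off_tissue") "matrix" else "lROI"
    out[[reg]] <- data.frame(
      roi_id = sprintf("%s_r%s_%02d", reg, replicate,
                       rep(seq_len(n_roi), each = size)),
      row = pick$row, col = pick$col,
      tissue = tissue, zone = zone, bone = NA,
      replicate = replicate, genotype = genotype, kind = kind,
      stringsAsFactors = FALSE
    )
  }
  roi_set(do.call(rbind, out))
}

#' Feature matrix
#'
#' ROI-by-ion intensity table with ROI metadata, a linear/log2 scale flag, a
#' record of excluded ions, and an append-only provenance log.
#'
#' @param values Numeric matrix, ROIs x ions; column names are bin ids.
#' @param rois data.frame of per-ROI metadata (one row per ROI, aligned with
#'   `values`); must contain `roi_id`, `tissue`, `kind`.
#' @param scale `"linear"` or `"log2"`.
#' @param excluded data.frame of removed ions (`bin_id`, `reason`).
#' @param provenance Character vector of processing-log entries.
#' @return Object of class `FeatureMatrix`.
#' @export
feature_matrix <- function(values, rois, scale = "linear",
                           excluded = data.frame(bin_id = character(),
                                                 reason = character()),
                           provenance = character()) {
  stopifnot(is.matrix(values), nrow(values) == nrow(rois),
            scale %in% c("linear", "log2"),
            all(c("roi_id", "tissue", "kind") %in% names(rois)))
  if (scale == "linear" && nrow(values) && any(values < 0)) {
    stop("negative intensities in a linear-scale feature matrix")
  }
  structure(list(values = values, rois = rois, scale = scale,
                 excluded = excluded, provenance = provenance),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf("FeatureMatrix: %d ROIs x %d ions (%s scale, %d excluded)\n",
              nrow(x$values), ncol(x$values), x$scale, nrow(x$excluded)))
  invisible(x)
}

#' Extract an ROI-by-ion feature matrix from a binned image
#'
#' Each ROI becomes one row holding, per target, the mean intensity over the
#' ROI's member pixels.
#'
#' @param img A `BinnedImage` from [rebin_to_targets()].
#' @param rois An [roi_set()]; every referenced pixel must exist on the grid.
#' @return A linear-scale [feature_matrix()].
#' @export
extract_features <- function(img, rois) {
  stopifnot(inherits(img, "BinnedImage"), inherits(rois, "RoiSet"))
  px_key <- paste(img$pixels$row, img$pixels$col)
  roi_key <- paste(rois$row, rois$col)
  idx <- match(roi_key, px_key)
  if (anyNA(idx)) {
    bad <- unique(rois$roi_id[is.na(idx)])
    stop("ROI(s) reference pixels missing from the grid: ",
         paste(bad, collapse = ", "))
  }
  roi_ids <- unique(rois$roi_id)
  vals <- matrix(0, length(roi_ids), ncol(img$matrix),
                 dimnames = list(roi_ids, colnames(img$matrix)))
  meta <- rois[!duplicated(rois$roi_id),
               setdiff(names(rois), c("row", "col")), drop = FALSE]
  meta <- as.data.frame(meta)[match(roi_ids, meta$roi_id), , drop = FALSE]
  rownames(meta) <- NULL
  for (i in seq_along(roi_ids)) {
    rows <- idx[rois$roi_id == roi_ids[i]]
    vals[i, ] <- colMeans(img$matrix[rows, , drop = FALSE])
  }
  feature_matrix(vals, meta, scale = "linear",
                 provenance = sprintf("extract_features: %d ROIs",
                                      length(roi_ids)))
}

#' Total-ion-count normalization
#'
#' Divides each ROI row by its row sum so rows sum to one; removes
#' per-observation acquisition-scale effects. All-zero rows are left as zeros
#' with a warning.
#'
#' @param fm Linear-scale [feature_matrix()].
#' @return TIC-normalized `FeatureMatrix`.
#' @export
tic_normalize <- function(fm) {
  stopifnot(inherits(fm, "FeatureMatrix"), fm$scale == "linear")
  rs <- rowSums(fm$values)
  zero <- rs == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero ROI row(s) left unnormalized")
    rs[zero] <- 1
  }
  fm$values <- fm$values / rs
  fm$provenance <- c(fm$provenance, "tic_normalize")
  fm
}

#' Matrix-ion exclusion filter
#'
#' Removes ions dominated by the chemical matrix (DHB) background: an ion is
#' excluded iff its mean intensity over matrix ROIs minus two SDs still
#' exceeds its mean over all tissue ROIs plus two SDs. SD is the population
#' standard deviation. Never removes an ion whose tissue mean exceeds its
#' matrix mean.
#'
#' @param fm Linear-scale [feature_matrix()] whose rows include at least two
#'   ROIs with `kind == "matrix"` and two tissue ROIs.
#' @return Filtered `FeatureMatrix`; dropped ions recorded in `$excluded`
#'   together with both intervals.
#' @export
matrix_ion_filter <- function(fm) {
  stopifnot(inherits(fm, "FeatureMatrix"), fm$scale == "linear")
  is_matrix <- fm$rois$kind == "matrix"
  if (sum(is_matrix) < 2 || sum(!is_matrix) < 2) {
    stop("matrix_ion_filter needs >= 2 matrix ROIs and >= 2 tissue ROIs")
  }
  pop_sd <- function(m) sqrt(colMeans(sweep(m, 2, colMeans(m))^2))
  mm <- fm$values[is_matrix, , drop = FALSE]
  tm <- fm$values[!is_matrix, , drop = FALSE]
  mu_m <- colMeans(mm); sd_m <- pop_sd(mm)
  mu_t <- colMeans(tm); sd_t <- pop_sd(tm)
  drop <- (mu_m - 2 * sd_m) > (mu_t + 2 * sd_t)
  if (any(drop)) {
    fm$excluded <- rbind(fm$excluded, data.frame(
      bin_id = colnames(fm$values)[drop],
      reason = sprintf("matrix_ion: matrix %.4g-2*%.4g > tissue %.4g+2*%.4g",
                       mu_m[drop], sd_m[drop], mu_t[drop], sd_t[drop]),
      stringsAsFactors = FALSE
    ))
    fm$values <- fm$values[, !drop, drop = FALSE]
  }
  fm$provenance <- c(fm$provenance,
                     sprintf("matrix_ion_filter: %d ion(s) excluded",
                             sum(drop)))
  fm
}

#' Log2 scaling with a pseudocount
#'
#' Replaces each value by `log2(prescale * value + pseudocount)` and flips the
#' scale flag. The pipeline applies this to TIC-normalized proportions with
#' `prescale = 1e4`, so a pseudocount of one intensity unit avoids `log(0)`
#' without swamping real signal.
#'
#' @param fm Linear-scale [feature_matrix()].
#' @param pseudocount Added before taking logs (default 1).
#' @param prescale Multiplier applied before the pseudocount (default 1).
#' @return Log2-scale `FeatureMatrix`.
#' @export
log_scale <- function(fm, pseudocount = 1, prescale = 1) {
  stopifnot(inherits(fm, "FeatureMatrix"), fm$scale == "linear")
  if (any(fm$values < 0)) stop("negative values; cannot log-scale")
  fm$values <- log2(prescale * fm$values + pseudocount)
  fm$scale <- "log2"
  fm$provenance <- c(fm$provenance,
                     sprintf("log_scale: pseudocount %g, prescale %g",
                             pseudocount, prescale))
  fm
}

#' Column z-scoring
#'
#' Centres each ion column and divides by its population SD; zero-variance
#' columns are set to zero with a warning.
#'
#' @param fm A [feature_matrix()] with at least two rows.
#' @return `FeatureMatrix` of z-scores (scale flag unchanged: z-scores are
#'   relative to whatever scale entered).
#' @export
zscore_columns <- function(fm) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  if (nrow(fm$values) < 2) stop("zscore_columns needs >= 2 rows")
  mu <- colMeans(fm$values)
  ctr <- sweep(fm$values, 2, mu)
  sd <- sqrt(colMeans(ctr^2))
  zero <- sd == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance column(s) set to 0")
    sd[zero] <- 1
  }
  fm$values <- sweep(ctr, 2, sd, "/")
  fm$provenance <- c(fm$provenance, "zscore_columns")
  fm
}

#' Canonical ROI-level preprocessing chain
#'
#' Applies the enforced processing order: extract features, TIC-normalize,
#' matrix-ion filter, log2 scale (on proportions prescaled by 1e4). The order
#' is recorded in provenance.
#'
#' @param img A `BinnedImage`.
#' @param rois An [roi_set()].
#' @param filter_matrix Apply [matrix_ion_filter()] (default TRUE).
#' @param pseudocount,prescale Passed to [log_scale()].
#' @return Log2-scale [feature_matrix()].
#' @export
preprocess_features <- function(img, rois, filter_matrix = TRUE,
                                pseudocount = 1, prescale = 1e4) {
  fm <- extract_features(img, rois)
  fm <- tic_normalize(fm)
  if (filter_matrix) fm <- matrix_ion_filter(fm)
  log_scale(fm, pseudocount = pseudocount, prescale = prescale)
}
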
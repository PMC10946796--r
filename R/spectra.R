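# Pixel-resolved peak lists and the HDI-style processing steps: peak-list
# reduction, shared target-list binning, re-binning, and lock-mass correction.

#' Pixel spectrum set
#'
#' Container for pixel-resolved MS1 peak lists: one acquired sample, one peak
#' list per ablation pixel. Stored long-format for vectorised processing.
#'
#' @param pixels data.frame with columns `pixel` (1-based index), `row`, `col`
#'   (0-based grid coordinates) and optionally `region`.
#' @param peaks data.frame with columns `pixel`, `mz`, `intensity` and
#'   optionally `drift`; sorted by pixel then m/z on construction.
#' @param metadata list; typically `sample_id`, `genotype`, `acquisition`.
#' @return Object of class `PixelSpectrumSet`.
#' @export
pixel_spectra <- function(pixels, peaks, metadata = list()) {
  stopifnot(all(c("pixel", "row", "col") %in% names(pixels)),
            all(c("pixel", "mz", "intensity") %in% names(peaks)))
  if (anyDuplicated(pixels[, c("row", "col")])) {
    stop("pixel coordinates must be unique")
  }
  if (nrow(peaks)) {
    stopifnot(all(peaks$mz > 0), all(peaks$intensity >= 0),
              all(peaks$pixel %in% pixels$pixel))
    peaks <- peaks[order(peaks$pixel, peaks$mz), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(pixels = pixels, peaks = peaks, metadata = metadata),
            class = "PixelSpectrumSet")
}

#' @export
print.PixelSpectrumSet <- function(x, ...) {
  cat(sprintf("PixelSpectrumSet: %d pixels, %d peaks, sample '%s'\n",
              nrow(x$pixels), nrow(x$peaks),
              x$metadata$sample_id %||% "<unnamed>"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduce peak lists to the most intense ions
#'
#' Per pixel, removes peaks with intensity at or below `min_intensity`
#' (threshold is strict: an intensity of exactly `min_intensity` is removed),
#' then keeps at most the `top_n` most intense peaks. Ties at the `top_n`
#' boundary are resolved in favour of the lower-m/z peak. Idempotent for fixed
#' arguments.
#'
#' @param ps A `PixelSpectrumSet`.
#' @param top_n Maximum peaks retained per pixel (default 3000).
#' @param min_intensity Intensity threshold (default 100, strict `>`).
#' @return Reduced `PixelSpectrumSet`, peak lists re-sorted by m/z.
#' @export
reduce_peaks <- function(ps, top_n = 3000, min_intensity = 100) {
  stopifnot(inherits(ps, "PixelSpectrumSet"), top_n >= 1, min_intensity >= 0)
  pk <- ps$peaks
  if (!nrow(pk)) return(ps)
  pk <- pk[pk$intensity > min_intensity, , drop = FALSE]
  if (nrow(pk)) {
    ord <- order(pk$pixel, -pk$intensity, pk$mz)
    pk <- pk[ord, , drop = FALSE]
    rank_in_pixel <- stats::ave(seq_len(nrow(pk)), pk$pixel,
                                FUN = seq_along)
    pk <- pk[rank_in_pixel <= top_n, , drop = FALSE]
  }
  pixel_spectra(ps$pixels, pk, ps$metadata)
}

#' Build a shared target list by m/z (and drift) binning
#'
#' Partitions all observed peaks across all pixels into half-open bins
#' `[k * mz_bin, (k+1) * mz_bin)` with origin at zero, crossed with drift-time
#' bins of width `drift_bin` when drift is present. Each non-empty bin becomes
#' one target whose centre is the intensity-weighted mean of its member peaks.
#'
#' A consolidation pass then merges adjacent targets whose centres lie closer
#' than `merge_within` (default half a bin): a single ion population whose
#' mass error straddles a bin boundary would otherwise shear into two
#' low-intensity targets.
#'
#' @param ps A `PixelSpectrumSet` (typically after [reduce_peaks()]).
#' @param mz_bin m/z bin width in Da (default 0.04).
#' @param drift_bin Drift-time bin width (default 100); ignored when the data
#'   carry no drift column.
#' @param merge_within Consolidate adjacent targets closer than this (Da);
#'   `0` disables consolidation.
#' @return A `TargetList`: data.frame `bin_id`, `mz_center`, `drift_center`
#'   (NA without drift), sorted by drift then m/z, with the bin widths kept as
#'   attributes.
#' @export
build_target_list <- function(ps, mz_bin = 0.04, drift_bin = 100,
                              merge_within = mz_bin / 2) {
  stopifnot(inherits(ps, "PixelSpectrumSet"), mz_bin > 0)
  pk <- ps$peaks
  if (!nrow(pk)) {
    warning("no peaks anywhere; empty target list")
    tl <- data.frame(bin_id = character(), mz_center = numeric(),
                     drift_center = numeric())
    return(structure(tl, mz_bin = mz_bin, drift_bin = drift_bin,
                     class = c("TargetList", "data.frame")))
  }
  kmz <- floor(pk$mz / mz_bin)
  has_drift <- "drift" %in% names(pk) && !all(is.na(pk$drift))
  kdr <- if (has_drift) floor(pk$drift / drift_bin) else rep(0L, nrow(pk))
  key <- paste(kdr, kmz)
  w <- pk$intensity
  # weighted means; fall back to plain mean inside all-zero-intensity bins
  sw <- tapply(w, key, sum)
  mzc <- tapply(pk$mz * w, key, sum) / sw
  zero <- !is.na(sw) & sw == 0
  if (any(zero)) mzc[zero] <- tapply(pk$mz, key, mean)[zero]
  drc <- if (has_drift) {
    d <- tapply(pk$drift * w, key, sum) / sw
    if (any(zero)) d[zero] <- tapply(pk$drift, key, mean)[zero]
    d
  } else rep(NA_real_, length(mzc))
  kd <- as.numeric(vapply(strsplit(names(mzc), " "), `[`, "", 1))
  ord <- order(kd, as.numeric(mzc))
  kd <- kd[ord]
  mzc <- as.numeric(mzc)[ord]
  drc <- as.numeric(drc)[ord]
  wts <- as.numeric(sw)[ord]
  wts[wts == 0] <- 1
  if (merge_within > 0 && length(mzc) > 1) {
    # greedy left-to-right merge of boundary-split targets per drift group
    cl <- integer(length(mzc))
    cl[1] <- 1L
    cur_mz <- mzc[1]; cur_w <- wts[1]
    for (i in 2:length(mzc)) {
      if (kd[i] == kd[i - 1] &&
          mzc[i] - cur_mz < merge_within * (1 - 1e-9)) {
        cl[i] <- cl[i - 1]
        cur_mz <- (cur_mz * cur_w + mzc[i] * wts[i]) / (cur_w + wts[i])
        cur_w <- cur_w + wts[i]
      } else {
        cl[i] <- cl[i - 1] + 1L
        cur_mz <- mzc[i]; cur_w <- wts[i]
      }
    }
    mzc <- as.numeric(tapply(mzc * wts, cl, sum) / tapply(wts, cl, sum))
    drc <- as.numeric(tapply(drc * wts, cl, sum) / tapply(wts, cl, sum))
  }
  tl <- data.frame(
    bin_id = sprintf("t_%05d", seq_along(mzc)),
    mz_center = mzc,
    drift_center = drc,
    stringsAsFactors = FALSE
  )
  structure(tl, mz_bin = mz_bin, drift_bin = drift_bin,
            class = c("TargetList", "data.frame"))
}

#' Re-bin pixel peaks onto a shared target list
#'
#' Assigns every peak to the nearest target (by m/z, within the same drift bin
#' when both sides carry drift); peaks farther than the acceptance half-width
#' from any target are dropped and counted in provenance. Intensities of peaks
#' co-assigned to one target in one pixel are summed, so total assigned
#' intensity per pixel is conserved. A peak exactly equidistant between two
#' targets goes to the lower-m/z one.
#'
#' @param ps A `PixelSpectrumSet`.
#' @param tl A `TargetList` from [build_target_list()].
#' @param tolerance Acceptance half-width in Da around each target centre;
#'   default one full `mz_bin` of the target list (binning jitter can push a
#'   peak beyond half a bin from the intensity-weighted centre).
#' @return A `BinnedImage`: list with `matrix` (pixels x targets), `pixels`,
#'   `target_list`, `provenance`.
#' @export
rebin_to_targets <- function(ps, tl, tolerance = NULL) {
  stopifnot(inherits(ps, "PixelSpectrumSet"), nrow(tl) > 0)
  if (is.null(tolerance)) tolerance <- attr(tl, "mz_bin") %||% 0.04
  pk <- ps$peaks
  n_px <- nrow(ps$pixels)
  n_t <- nrow(tl)
  mat <- matrix(0, n_px, n_t,
                dimnames = list(NULL, tl$bin_id))
  dropped <- 0L
  if (nrow(pk)) {
    has_drift <- "drift" %in% names(pk) && !all(is.na(pk$drift)) &&
      !all(is.na(tl$drift_center))
    drift_bin <- attr(tl, "drift_bin") %||% 100
    groups <- if (has_drift) {
      split(seq_len(nrow(pk)), floor(pk$drift / drift_bin))
    } else list(all = seq_len(nrow(pk)))
    t_groups <- if (has_drift) {
      split(seq_len(n_t), floor(tl$drift_center / drift_bin))
    } else list(all = seq_len(n_t))
    for (g in names(groups)) {
      rows <- groups[[g]]
      t_idx <- t_groups[[g]]
      if (is.null(t_idx)) { dropped <- dropped + length(rows); next }
      centers <- tl$mz_center[t_idx]
      mz <- pk$mz[rows]
      left <- findInterval(mz, centers)
      li <- pmax(left, 1L)
      ri <- pmin(left + 1L, length(centers))
      dl <- abs(mz - centers[li])
      dr <- abs(mz - centers[ri])
      nearest <- ifelse(dl <= dr, li, ri)       # tie -> lower m/z
      dist <- pmin(dl, dr)
      ok <- dist <= tolerance
      dropped <- dropped + sum(!ok)
      if (any(ok)) {
        i <- pk$pixel[rows][ok]
        j <- t_idx[nearest[ok]]
        flat <- (j - 1L) * n_px + i
        add <- tapply(pk$intensity[rows][ok], flat, sum)
        mat[as.integer(names(add))] <- mat[as.integer(names(add))] + add
      }
    }
  }
  prov <- sprintf(
    "rebin_to_targets: %d targets, tolerance %.4g Da, %d peaks dropped",
    n_t, tolerance, dropped)
  structure(list(matrix = mat, pixels = ps$pixels, target_list = tl,
                 metadata = ps$metadata, provenance = prov,
                 n_dropped = dropped),
            class = "BinnedImage")
}

#' Lock-mass correction against an internal standard
#'
#' Finds the most intense peak within `search_window` ppm of `reference_mz` in
#' the sample-mean spectrum and applies the multiplicative factor
#' `reference_mz / observed_mz` to every m/z in the sample, recording the ppm
#' shift. Applied per sample (one `PixelSpectrumSet`), not per pixel.
#'
#' @param ps A `PixelSpectrumSet`.
#' @param reference_mz True m/z of the standard, e.g. 753.6134 for the
#'   protonated deuterated PC(15:0/18:1) spike.
#' @param search_window Half-width of the search window in ppm (default 50).
#' @return Corrected `PixelSpectrumSet` with `lockmass_shift_ppm` and
#'   `lockmass_factor` in its metadata; unchanged (with a warning) when no
#'   peak lies in the window.
#' @export
lock_mass_correct <- function(ps, reference_mz = 753.6134,
                              search_window = 50) {
  stopifnot(inherits(ps, "PixelSpectrumSet"), reference_mz > 0,
            search_window > 0)
  pk <- ps$peaks
  lo <- reference_mz * (1 - search_window * 1e-6)
  hi <- reference_mz * (1 + search_window * 1e-6)
  inw <- which(pk$mz >= lo & pk$mz <= hi)
  if (!length(inw)) {
    warning("lock_mass_correct: no peak within ", search_window,
            " ppm of ", reference_mz, "; sample left uncorrected")
    ps$metadata$lockmass_shift_ppm <- NA_real_
    return(ps)
  }
  # sample-mean spectrum inside the window: 2-ppm sub-bins of summed intensity
  off_ppm <- (pk$mz[inw] - reference_mz) / reference_mz * 1e6
  sub <- floor(off_ppm / 2)
  tot <- tapply(pk$intensity[inw], sub, sum)
  best <- names(tot)[which.max(tot)]
  sel <- inw[sub == as.numeric(best)]
  observed <- sum(pk$mz[sel] * pk$intensity[sel]) / sum(pk$intensity[sel])
  factor <- reference_mz / observed
  pk$mz <- pk$mz * factor
  out <- pixel_spectra(ps$pixels, pk, ps$metadata)
  out$metadata$lockmass_factor <- factor
  out$metadata$lockmass_shift_ppm <- (observed - reference_mz) /
    reference_mz * 1e6
  out
}
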
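# Adduct- and isotope-aware matching of observed ions to a lipid reference
# library within a ppm tolerance, with tiered confidence scoring and
# LC-MS consensus m/z binning.

#' Match observed target ions to a lipid library
#'
#' Every (target, lipid, adduct) combination whose theoretical m/z lies within
#' `tolerance` ppm of the observed target centre is emitted as a hit; one
#' target may receive multiple hits. The adduct space is [adduct_forms()]:
#' protonated, sodiated, potassiated, dehydrated, and their carbon-13 isotope
#' partners.
#'
#' @param targets A `TargetList` (or data.frame with `bin_id`, `mz_center`).
#' @param library Lipid library data.frame with `name`, `neutral_mass` and the
#'   database-evidence flags `manual_id`, `lipidmatch_hit`,
#'   `lipidmatch_score_high`, `lipidblast_hit` (see [generate_library()] or
#'   [read_library_csv()]).
#' @param tolerance Match tolerance in ppm (default 100, chosen for
#'   multi-session MALDI calibration drift).
#' @return data.frame of hits sorted by |ppm error|: `bin_id`, `observed_mz`,
#'   `lipid`, `adduct`, `theoretical_mz`, `ppm_error`, plus the library's
#'   evidence flags. Empty (with a warning) for an empty library.
#' @export
match_ions <- function(targets, library, tolerance = 100) {
  stopifnot(tolerance > 0, all(c("bin_id", "mz_center") %in% names(targets)))
  if (!nrow(library)) {
    warning("match_ions: empty library")
    return(data.frame(bin_id = character(), observed_mz = numeric(),
                      lipid = character(), adduct = character(),
                      theoretical_mz = numeric(), ppm_error = numeric()))
  }
  ad <- adduct_forms()
  # library ion table: lipid x adduct
  lib_idx <- rep(seq_len(nrow(library)), times = nrow(ad))
  ad_idx <- rep(seq_len(nrow(ad)), each = nrow(library))
  theo <- library$neutral_mass[lib_idx] + ad$mass_delta[ad_idx]
  ord <- order(theo)
  theo <- theo[ord]; lib_idx <- lib_idx[ord]; ad_idx <- ad_idx[ord]

  hits <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    mz <- targets$mz_center[i]
    lo <- mz / (1 + tolerance * 1e-6)
    hi <- mz / (1 - tolerance * 1e-6)
    j0 <- findInterval(lo, theo) + 1L
    j1 <- findInterval(hi, theo)
    if (j1 < j0) next
    j <- j0:j1
    pe <- (mz - theo[j]) / theo[j] * 1e6
    keep <- abs(pe) <= tolerance
    if (!any(keep)) next
    j <- j[keep]; pe <- pe[keep]
    hits[[i]] <- data.frame(
      bin_id = targets$bin_id[i], observed_mz = mz,
      lipid = library$name[lib_idx[j]],
      adduct = ad$adduct[ad_idx[j]],
      theoretical_mz = theo[j], ppm_error = pe,
      manual_id = library$manual_id[lib_idx[j]],
      lipidmatch_hit = library$lipidmatch_hit[lib_idx[j]],
      lipidmatch_score_high = library$lipidmatch_score_high[lib_idx[j]],
      lipidblast_hit = library$lipidblast_hit[lib_idx[j]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(bin_id = character(), observed_mz = numeric(),
                      lipid = character(), adduct = character(),
                      theoretical_mz = numeric(), ppm_error = numeric(),
                      manual_id = logical(), lipidmatch_hit = logical(),
                      lipidmatch_score_high = logical(),
                      lipidblast_hit = logical())
  } else {
    out <- out[order(abs(out$ppm_error)), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Tiered confidence scoring of annotation hits
#'
#' Assigns each hit a confidence tier: `i` — manually annotated ID; `ii` —
#' putative ID supported by both LipidMatch and LipidBlast; `iii` — a highly
#' scored LipidMatch ID without LipidBlast support; `iv` — low-confidence,
#' to be excluded, with reasons: low LipidMatch score, an odd total number of
#' fatty-acyl carbons, or an implausible adduct combination (a salt-adduct
#' isotope stack where only singly charged protonated series are expected).
#'
#' @param hits Hit table from [match_ions()].
#' @return `hits` with added `tier` and `reasons` columns; tier-iv rows carry
#'   at least one reason.
#' @export
score_tiers <- function(hits) {
  n <- nrow(hits)
  tier <- character(n); reasons <- character(n)
  for (i in seq_len(n)) {
    rs <- character()
    parsed <- tryCatch(parse_shorthand(hits$lipid[i]),
                       error = function(e) NULL)
    odd <- !is.null(parsed) && isTRUE(parsed$odd_chain)
    if (isTRUE(hits$manual_id[i])) {
      tier[i] <- "i"
    } else if (isTRUE(hits$lipidmatch_hit[i]) &&
               isTRUE(hits$lipidblast_hit[i]) && !odd) {
      tier[i] <- "ii"
    } else if (isTRUE(hits$lipidmatch_hit[i]) &&
               isTRUE(hits$lipidmatch_score_high[i]) &&
               !isTRUE(hits$lipidblast_hit[i]) && !odd) {
      tier[i] <- "iii"
    } else {
      tier[i] <- "iv"
      if (!isTRUE(hits$lipidmatch_score_high[i])) rs <- c(rs, "low_score")
      if (odd) rs <- c(rs, "odd_chain")
      if (grepl("^M\\+(Na|K)\\+13C$", hits$adduct[i])) {
        rs <- c(rs, "implausible_adduct")
      }
      if (!length(rs)) rs <- "no_database_support"
    }
    if (tier[i] != "iv" && odd) {
      # odd-chain flags downgrade any non-manual ID
      tier[i] <- "iv"; rs <- c(rs, "odd_chain")
    }
    reasons[i] <- paste(rs, collapse = ";")
  }
  hits$tier <- tier
  hits$reasons <- reasons
  hits
}

#' Build an m/z-only consensus library by binning
#'
#' Collapses LC-MS/MS MS1 m/z values (retention time discarded) into half-open
#' bins of `bin_width` m/z and assigns each lipid record to its bin;
#' multi-member bins are flagged ambiguous.
#'
#' @param ms1_mz Numeric vector of MS1 m/z values, aligned with `records`.
#' @param records data.frame of lipid records (same length).
#' @param bin_width Bin width in m/z (default 0.2).
#' @return data.frame, one row per non-empty bin: `bin_lo`, `bin_center`,
#'   `n_members`, `ambiguous`, `members` (semicolon-joined names).
#' @export
build_consensus_library <- function(ms1_mz, records, bin_width = 0.2) {
  stopifnot(bin_width > 0, length(ms1_mz) == nrow(records))
  if (!length(ms1_mz)) {
    return(data.frame(bin_lo = numeric(), bin_center = numeric(),
                      n_members = integer(), ambiguous = logical(),
                      members = character()))
  }
  k <- floor(ms1_mz / bin_width)
  bins <- sort(unique(k))
  out <- data.frame(
    bin_lo = bins * bin_width,
    bin_center = bins * bin_width + bin_width / 2,
    n_members = as.integer(table(factor(k, levels = bins))),
    stringsAsFactors = FALSE
  )
  out$ambiguous <- out$n_members > 1
  out$members <- vapply(bins, function(b)
    paste(records$name[k == b], collapse = ";"), "")
  out
}

#' Score annotation performance against a phantom ground truth
#'
#' Compares tiered hits with a phantom truth table: a true positive is a hit
#' whose (bin, lipid, adduct) agrees with the planted ion assigned to that
#' bin.
#'
#' @param hits Hit table from [match_ions()] / [score_tiers()].
#' @param truth Phantom truth table (see [generate_phantom()]).
#' @param targets `TargetList` used for matching.
#' @param tolerance ppm tolerance used to pair targets with planted ions.
#' @return List with `sensitivity`, `precision`, `n_true`, `n_hits`.
#' @export
annotation_performance <- function(hits, truth, targets, tolerance = 100) {
  # pair each planted ion with the nearest target centre within tolerance
  truth$bin_id <- NA_character_
  for (i in seq_len(nrow(truth))) {
    d <- abs(targets$mz_center - truth$theoretical_mz[i]) /
      truth$theoretical_mz[i] * 1e6
    j <- which.min(d)
    if (length(j) && d[j] <= tolerance) truth$bin_id[i] <- targets$bin_id[j]
  }
  truth <- truth[!is.na(truth$bin_id), , drop = FALSE]
  truth_key <- paste(truth$bin_id, truth$lipid, truth$adduct)
  hit_key <- paste(hits$bin_id, hits$lipid, hits$adduct)
  tp <- sum(truth_key %in% hit_key)
  list(
    sensitivity = if (nrow(truth)) tp / nrow(truth) else NA_real_,
    precision = if (nrow(hits)) sum(hit_key %in% truth_key) / nrow(hits)
                else NA_real_,
    n_true = nrow(truth), n_hits = nrow(hits)
  )
}
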
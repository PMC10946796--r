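# End-to-end orchestration of the two study designs: the healthy-tissue atlas
# (tissue-vs-rest OPLS-DA panels, clustering, annotation) and the KO-vs-WT
# growth-plate contrast (lock mass, whole-growth-plate OPLS-DA, zone-wise
# t-tests, Venn overlap, annotation). Runs are seeded and fully provenance-
# logged; outputs are plain CSV plus a JSON-lines log.

#' Build a run configuration
#'
#' Collects all pipeline parameters with their standard defaults: peak-list
#' reduction keeps the top 3000 peaks above intensity 100; target binning uses
#' a 0.04-Da m/z window and 100-unit drift window; lock mass is the
#' protonated deuterated PC(15:0/18:1) spike at m/z 753.6134 with a 50-ppm
#' search window; panels use the S-plot covariance at threshold 0.04;
#' zone tests use q < 0.05 with a 1.5 fold-change gate; annotation tolerance
#' is 100 ppm.
#'
#' @param design `"atlas"` or `"genotype_contrast"`.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed driving simulation and any randomized step.
#' @param spectra,rois,library Optional input paths (imzML/tabular, ROI CSV,
#'   library CSV). When `spectra` is `NULL` the run simulates its inputs from
#'   `phantom` (a [phantom_spec()]-argument list).
#' @param ... Parameter overrides (see Details in the function body).
#' @return List of class `RunConfig`.
#' @export
run_config <- function(design = c("atlas", "genotype_contrast"),
                       out_dir, seed, spectra = NULL, rois = NULL,
                       library = NULL, ...) {
  design <- match.arg(design)
  cfg <- list(
    design = design, out_dir = out_dir, seed = as.integer(seed),
    spectra = spectra, rois = rois, library = library,
    # simulation
    grid_shape = c(48, 48), n_wt = 2, n_ko = 2, n_samples = 3,
    panel_args = list(), decoys = 25, mz_shift_ppm_sd = 15,
    # processing
    top_n = 3000, min_intensity = 100, mz_bin = 0.04, drift_bin = 100,
    lockmass_ref = 753.6134, lockmass_window = 50, lockmass = TRUE,
    filter_matrix = TRUE, pseudocount = 1, prescale = 1e4,
    # modelling
    n_components = 3, n_orth = 1, panel_stat = "cov",
    panel_threshold = 0.04, q_cut = 0.05, fc_cut = 1.5, ppm_tol = 100,
    n_rois_per_region = 4, roi_size = 10, n_matrix_rois = 4
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (p in c("spectra", "rois", "library")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("config path does not exist: ", p, " = ", cfg[[p]])
    }
  }
  structure(cfg, class = "RunConfig")
}

# config as logged: parameters only, no filesystem paths, so that runs into
# different directories produce bit-identical provenance
config_record <- function(cfg) {
  rec <- unclass(cfg)
  rec$out_dir <- NULL
  rec[!vapply(rec, is.null, TRUE)]
}

provenance_logger <- function(path) {
  unlink(path)
  function(stage, params = list(), warnings = character()) {
    rec <- list(stage = stage, params = params, warnings = warnings)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = path, append = TRUE, sep = "")
  }
}

pool_spectra <- function(sets) {
  offset <- 0L
  pixels <- list(); peaks <- list()
  for (i in seq_along(sets)) {
    ps <- sets[[i]]
    px <- ps$pixels; pk <- ps$peaks
    px$pixel <- px$pixel + offset
    # keep coordinates unique across samples by offsetting rows
    row_off <- if (i > 1) max(vapply(pixels, function(p) max(p$row), 0)) + 1L
      else 0L
    px$row <- px$row + row_off
    pk$pixel <- pk$pixel + offset
    pixels[[i]] <- px; peaks[[i]] <- pk
    offset <- offset + nrow(ps$pixels)
  }
  common <- Reduce(intersect, lapply(pixels, names))
  pixel_spectra(do.call(rbind, lapply(pixels, `[`, common)),
                do.call(rbind, peaks),
                metadata = list(sample_id = "pooled"))
}

simulate_inputs <- function(cfg) {
  panel_args <- cfg$panel_args
  panel_args$seed <- panel_args$seed %||% cfg$seed
  panel <- do.call(make_lipid_panel, panel_args)
  base_args <- list(grid_shape = cfg$grid_shape, lipid_panel = panel,
                    seed = cfg$seed)
  if (cfg$design == "atlas") {
    # pipeline-development design: no spiked standard, ion mobility on
    base_args$standard_spec <- NULL
    spec <- do.call(phantom_spec, base_args)
    samples <- lapply(seq_len(cfg$n_samples), function(i) {
      s <- spec
      s$seed <- (spec$seed * 131L + i) %% .Machine$integer.max
      s$sample_id <- sprintf("S%02d", i)
      generate_phantom(s)
    })
    truth <- samples[[1]]$truth
  } else {
    spec <- do.call(phantom_spec, base_args)
    genos <- c(rep("WT", cfg$n_wt), rep("KO", cfg$n_ko))
    # per-sample calibration shifts, corrected later by the lock mass
    old <- set_local_seed(cfg$seed + 17L)
    shifts <- stats::rnorm(length(genos), 0, cfg$mz_shift_ppm_sd)
    restore_seed(old)
    samples <- vector("list", length(genos))
    for (i in seq_along(genos)) {
      s <- spec
      s$genotype <- genos[i]
      s$sample_id <- sprintf("%s_%02d", genos[i], i)
      s$seed <- (spec$seed * 131L + i) %% .Machine$integer.max
      s$mz_shift_ppm <- shifts[i]
      samples[[i]] <- generate_phantom(s)
    }
    truth <- samples[[1]]$truth
  }
  library <- generate_library(spec, decoys = cfg$decoys)
  list(spec = spec, samples = samples, truth = truth, library = library)
}

# shared front end: reduce (+ lock mass), pooled target list, per-sample
# re-binning, ROI extraction, canonical normalization chain
ingest_and_bin <- function(cfg, sim, log, lockmass = FALSE) {
  reduced <- lapply(sim$samples, function(s)
    reduce_peaks(s$spectra, cfg$top_n, cfg$min_intensity))
  log("reduce_peaks", list(top_n = cfg$top_n,
                           min_intensity = cfg$min_intensity))
  if (lockmass) {
    reduced <- lapply(reduced, lock_mass_correct,
                      reference_mz = cfg$lockmass_ref,
                      search_window = cfg$lockmass_window)
    log("lock_mass_correct", list(
      reference_mz = cfg$lockmass_ref, window_ppm = cfg$lockmass_window,
      shifts_ppm = vapply(reduced, function(p)
        p$metadata$lockmass_shift_ppm %||% NA_real_, 0.0)))
  }
  tl <- build_target_list(pool_spectra(reduced), cfg$mz_bin, cfg$drift_bin)
  log("build_target_list", list(mz_bin = cfg$mz_bin,
                                drift_bin = cfg$drift_bin,
                                n_targets = nrow(tl)))
  fms <- vector("list", length(reduced))
  for (i in seq_along(reduced)) {
    img <- rebin_to_targets(reduced[[i]], tl)
    rois <- auto_rois(reduced[[i]]$pixels,
                      n_per_region = cfg$n_rois_per_region,
                      size = cfg$roi_size, n_matrix = cfg$n_matrix_rois,
                      genotype = reduced[[i]]$metadata$genotype,
                      replicate = i, seed = cfg$seed + 1000L + i)
    fms[[i]] <- extract_features(img, rois)
  }
  log("extract_features", list(n_samples = length(fms)))
  values <- do.call(rbind, lapply(fms, `[[`, "values"))
  rois <- do.call(rbind, lapply(fms, `[[`, "rois"))
  rownames(rois) <- NULL
  fm <- feature_matrix(values, rois, scale = "linear")
  fm <- tic_normalize(fm)
  if (cfg$filter_matrix) fm <- suppressWarnings(matrix_ion_filter(fm))
  fm <- log_scale(fm, cfg$pseudocount, cfg$prescale)
  log("normalize", list(tic = TRUE, matrix_filter = cfg$filter_matrix,
                        excluded = nrow(fm$excluded),
                        pseudocount = cfg$pseudocount,
                        prescale = cfg$prescale))
  list(fm = fm, tl = tl)
}

write_outputs <- function(out, dir) {
  for (nm in names(out)) {
    utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  file.path(dir, paste0(names(out), ".csv"))
}

#' Run the healthy-atlas tissue analysis
#'
#' Executes ingest, peak reduction, shared target binning, ROI feature
#' extraction, TIC normalization, matrix-ion filtering, log scaling, PCA,
#' each-tissue-vs-rest OPLS-DA (plus the growth-plate-vs-articular cartilage
#' contrast), panel merging, panel-restricted hierarchical clustering and
#' lipid annotation; writes every figure table as CSV together with a
#' JSON-lines provenance log.
#'
#' @param cfg A [run_config()] with `design = "atlas"`.
#' @return List with the feature matrix, PCA model, per-contrast panels,
#'   merged panel, clustering, annotation table, ground truth, and
#'   `output_files` (paths written).
#' @export
run_atlas <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"), cfg$design == "atlas")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- provenance_logger(file.path(cfg$out_dir, "provenance.jsonl"))
  log("config", config_record(cfg))

  sim <- simulate_inputs(cfg)
  log("simulate", list(seed = cfg$seed, n_samples = length(sim$samples),
                       n_lipids = nrow(sim$spec$lipid_panel)))
  ib <- ingest_and_bin(cfg, sim, log, lockmass = FALSE)
  fm <- ib$fm

  tissue_fm <- fm
  keep <- tissue_fm$rois$kind != "matrix"
  tissue_fm$values <- tissue_fm$values[keep, , drop = FALSE]
  tissue_fm$rois <- tissue_fm$rois[keep, , drop = FALSE]

  pca <- fit_pca(tissue_fm$values, n_components = cfg$n_components)
  log("pca", list(explained_pct = pca$explained_variance_pct))

  tissues <- sort(unique(tissue_fm$rois$tissue))
  contrasts <- lapply(tissues, function(t) c(t, "rest"))
  names(contrasts) <- paste0(tissues, "_vs_rest")
  panels <- list()
  for (nm in names(contrasts)) {
    t <- contrasts[[nm]][1]
    y <- ifelse(tissue_fm$rois$tissue == t, t, "rest")
    m <- fit_oplsda(tissue_fm$values, y, n_orth = cfg$n_orth,
                    positive_class = t)
    panels[[nm]] <- select_panel(m, stat = cfg$panel_stat,
                                 threshold = cfg$panel_threshold,
                                 contrast = nm)
  }
  if (all(c("growth_plate", "articular_cartilage") %in% tissues)) {
    sub <- tissue_fm$rois$tissue %in% c("growth_plate",
                                        "articular_cartilage")
    m <- fit_oplsda(tissue_fm$values[sub, , drop = FALSE],
                    tissue_fm$rois$tissue[sub], n_orth = cfg$n_orth,
                    positive_class = "growth_plate")
    panels[["gp_vs_articular"]] <- select_panel(
      m, stat = cfg$panel_stat, threshold = cfg$panel_threshold,
      contrast = "gp_vs_articular")
  }
  merged <- merge_panels(panels)
  log("panels", list(sizes = vapply(panels, nrow, 0L),
                     merged = nrow(merged)))

  hc <- hierarchical_cluster(tissue_fm, panel = merged)
  log("hierarchical_cluster", list(k = hc$k, metric = hc$metric,
                                   linkage = hc$linkage))

  hits <- score_tiers(match_ions(
    ib$tl[ib$tl$bin_id %in% merged$bin_id, , drop = FALSE],
    sim$library, tolerance = cfg$ppm_tol))
  log("annotate", list(ppm = cfg$ppm_tol, n_hits = nrow(hits)))

  out_tabs <- list(
    feature_matrix = cbind(fm$rois, as.data.frame(fm$values)),
    excluded_ions = fm$excluded,
    pca_scores = data.frame(fm$rois[keep, c("roi_id", "tissue")],
                            pca$scores),
    splot_table = do.call(rbind, lapply(names(panels), function(nm)
      data.frame(contrast = nm, as.data.frame(panels[[nm]])))),
    merged_panel = as.data.frame(merged),
    heatmap_matrix = data.frame(roi_id = rownames(hc$heatmap), hc$heatmap),
    row_clusters = data.frame(roi_id = names(hc$row_clusters),
                              cluster = hc$row_clusters,
                              tissue = hc$rois$tissue[
                                match(names(hc$row_clusters),
                                      hc$rois$roi_id)]),
    annotation = hits,
    ground_truth = sim$truth
  )
  files <- write_outputs(out_tabs, cfg$out_dir)
  log("write_outputs", list(files = basename(files)))

  list(fm = fm, pca = pca, panels = panels, merged_panel = merged,
       clustering = hc, annotation = hits, truth = sim$truth,
       target_list = ib$tl, library = sim$library,
       output_files = c(files, file.path(cfg$out_dir, "provenance.jsonl")))
}

#' Run the KO-vs-WT growth-plate contrast
#'
#' Executes ingest, reduction, per-sample lock-mass correction against the
#' internal standard, shared target binning, ROI features, normalizations,
#' whole-growth-plate OPLS-DA panel selection, per-zone Welch t-tests with
#' BH q-values and fold changes, volcano tables, the cross-zone overlap
#' summary, and annotation of significant ions.
#'
#' @param cfg A [run_config()] with `design = "genotype_contrast"`.
#' @return List with the feature matrix, OPLS model and panel, per-zone test
#'   results and volcano tables, up/down sets, cross-zone summaries,
#'   annotation, truth, and `output_files`.
#' @export
run_genotype_contrast <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"), cfg$design == "genotype_contrast")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- provenance_logger(file.path(cfg$out_dir, "provenance.jsonl"))
  log("config", config_record(cfg))

  sim <- simulate_inputs(cfg)
  log("simulate", list(seed = cfg$seed, n_wt = cfg$n_wt, n_ko = cfg$n_ko))
  ib <- ingest_and_bin(cfg, sim, log, lockmass = cfg$lockmass)
  fm <- ib$fm

  gp <- fm$rois$tissue == "growth_plate"
  if (!any(gp)) stop("no growth-plate ROIs present")
  if (any(gp & (is.na(fm$rois$zone) | !nzchar(fm$rois$zone)))) {
    stop("growth-plate ROIs without zone labels: ",
         paste(fm$rois$roi_id[gp & is.na(fm$rois$zone)], collapse = ", "))
  }
  gp_fm <- fm
  gp_fm$values <- fm$values[gp, , drop = FALSE]
  gp_fm$rois <- fm$rois[gp, , drop = FALSE]

  opls <- fit_oplsda(gp_fm$values, gp_fm$rois$genotype,
                     n_orth = cfg$n_orth, positive_class = "KO")
  panel <- select_panel(opls, stat = cfg$panel_stat,
                        threshold = cfg$panel_threshold,
                        contrast = "KO_vs_WT_growth_plate")
  log("oplsda", list(r2y = opls$r2y, n_orth = opls$n_orth,
                     panel = nrow(panel)))

  zones <- GP_ZONES
  tests <- list(); volcanoes <- list(); ups <- list(); downs <- list()
  for (z in zones) {
    res <- zone_ttest(gp_fm, zone = z, groups = c("WT", "KO"))
    tests[[z]] <- res
    volcanoes[[z]] <- volcano_table(res)
    sets <- significant_sets(res, q_cut = cfg$q_cut, fc_cut = NULL)
    ups[[z]] <- sets$up; downs[[z]] <- sets$down
  }
  log("zone_ttests", list(q_cut = cfg$q_cut,
                          up = vapply(ups, length, 0L),
                          down = vapply(downs, length, 0L)))
  overlap_up <- cross_zone_overlap(ups)
  overlap_down <- cross_zone_overlap(downs)

  sig_ions <- unique(unlist(c(ups, downs)))
  hits <- score_tiers(match_ions(
    ib$tl[ib$tl$bin_id %in% sig_ions, , drop = FALSE],
    sim$library, tolerance = cfg$ppm_tol))
  log("annotate", list(ppm = cfg$ppm_tol, n_sig = length(sig_ions),
                       n_hits = nrow(hits)))

  out_tabs <- c(
    list(feature_matrix = cbind(fm$rois, as.data.frame(fm$values)),
         excluded_ions = fm$excluded,
         splot_table = data.frame(
           bin_id = names(opls$splot_cov), cov = opls$splot_cov,
           corr = opls$splot_corr, loading = opls$w_pred),
         panel = as.data.frame(panel),
         venn_up = overlap_up$membership,
         venn_down = overlap_down$membership,
         annotation = hits,
         ground_truth = sim$truth),
    stats::setNames(lapply(tests, as.data.frame),
                    paste0("ttest_", zones)),
    stats::setNames(volcanoes, paste0("volcano_", zones))
  )
  files <- write_outputs(out_tabs, cfg$out_dir)
  log("write_outputs", list(files = basename(files)))

  list(fm = fm, opls = opls, panel = panel, tests = tests,
       volcanoes = volcanoes, up_sets = ups, down_sets = downs,
       overlap_up = overlap_up, overlap_down = overlap_down,
       annotation = hits, truth = sim$truth, target_list = ib$tl,
       library = sim$library,
       output_files = c(files, file.path(cfg$out_dir, "provenance.jsonl")))
}

#' Digest the output files of a run
#'
#' MD5 digests of every output file, for end-to-end determinism checks.
#'
#' @param result Return value of [run_atlas()] or [run_genotype_contrast()].
#' @return Named character vector of digests keyed by file name.
#' @export
run_digests <- function(result) {
  files <- sort(result$output_files)
  d <- tools::md5sum(files)
  names(d) <- basename(files)
  d
}
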
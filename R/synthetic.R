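# Seeded synthetic MALDI-IMS phantoms with ground-truth labels.
#
# The phantom emulates a sagittal knee-joint section laid out as horizontal
# bands on a rectangular pixel grid: an off-tissue (matrix-only) band, bone
# marrow, cortical bone, articular cartilage, and the three growth-plate zones
# (resting, proliferating, hypertrophic) as adjacent bands. Geometry is
# deliberately schematic: downstream ROI logic only needs labelled pixel sets.

PHANTOM_REGIONS <- c("off_tissue", "marrow", "cortical_bone",
                     "articular_cartilage", "gp_resting", "gp_proliferating",
                     "gp_hypertrophic")
GP_ZONES <- c("resting", "proliferating", "hypertrophic")

DEFAULT_ADDUCT_PROFILE <- c("M+H" = 0.60, "M+Na" = 0.20,
                            "M+K" = 0.15, "M+H-H2O" = 0.05)

# internal standard: deuterated PC(15:0/18:1), [M+H]+ at m/z 753.6134
DEFAULT_STANDARD <- list(
  name = "PC(15:0/18:1(d7))",
  formula = "C41H73D7NO8P",
  adduct = "M+H",
  intensity = 5000
)

#' Region band layout for a phantom grid
#'
#' Splits the grid rows into seven horizontal bands, one per region label, with
#' the off-tissue (matrix-only) band first. Band heights are fixed fractions of
#' the grid: 1/4 off-tissue, and the remainder shared between the four tissue
#' classes with the growth plate split into its three zones.
#'
#' @param grid_shape Integer `(rows, cols)`.
#' @return data.frame with columns `row`, `col`, `region` covering every pixel
#'   exactly once (row-major, 0-based coordinates).
#' @export
region_layout <- function(grid_shape) {
  rows <- grid_shape[1]; cols <- grid_shape[2]
  stopifnot(rows >= 7, cols >= 1)
  frac <- c(0.25, 0.15, 0.15, 0.15, 0.10, 0.10, 0.10)
  cuts <- round(cumsum(frac) * rows)
  cuts[7] <- rows
  heights <- diff(c(0L, cuts))
  if (any(heights < 1)) stop("grid too small for 7 region bands")
  region <- rep(PHANTOM_REGIONS, times = heights)
  data.frame(
    row = rep(seq_len(rows) - 1L, each = cols),
    col = rep(seq_len(cols) - 1L, times = rows),
    region = rep(region, each = cols),
    stringsAsFactors = FALSE
  )
}

region_to_tissue <- function(region) {
  out <- region
  out[region %in% c("gp_resting", "gp_proliferating", "gp_hypertrophic")] <-
    "growth_plate"
  out[region == "off_tissue"] <- "matrix"
  out
}

region_to_zone <- function(region) {
  zone <- rep(NA_character_, length(region))
  zone[region == "gp_resting"] <- "resting"
  zone[region == "gp_proliferating"] <- "proliferating"
  zone[region == "gp_hypertrophic"] <- "hypertrophic"
  zone
}

# draw neutral masses one lipid at a time so that no two library ions (any
# adduct, incl. 13C) fall within `min_sep_ppm` of each other -- keeps every
# planted ion unambiguous at the 100-ppm annotation tolerance
draw_separated_masses <- function(n, ranges, min_sep_ppm = 150,
                                  max_tries = 500) {
  lo <- ranges[, 1]; hi <- ranges[, 2]
  deltas <- adduct_forms()$mass_delta
  accepted_ions <- numeric(0)
  masses <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(1, lo[i], hi[i])
      ions <- cand + deltas
      if (length(accepted_ions)) {
        # nearest accepted ion to each candidate ion
        pos <- findInterval(ions, accepted_ions)
        near <- pmin(
          abs(ions - accepted_ions[pmax(pos, 1L)]),
          abs(ions - accepted_ions[pmin(pos + 1L, length(accepted_ions))])
        )
        if (any(near / ions * 1e6 < min_sep_ppm)) next
      }
      masses[i] <- cand
      accepted_ions <- sort(c(accepted_ions, ions))
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place lipid ", i, " with ", min_sep_ppm,
           " ppm ion separation")
    }
  }
  masses
}

#' Construct a ground-truth lipid panel
#'
#' Builds the lipid panel of a phantom: tissue-enriched species (LPC/PC in the
#' growth plate, ether-PC in marrow, SM in articular cartilage, PE in cortical
#' bone), spatially flat species, and matrix-only background ions that are
#' maximal off tissue. A subset of growth-plate species carries multiplicative
#' KO-vs-WT genotype effects spanning all three zones.
#'
#' @param n_per_tissue Enriched lipids per tissue class (4 classes).
#' @param n_flat Lipids with a uniform tissue profile.
#' @param n_matrix Matrix-only (DHB-like) background ions.
#' @param n_ko_up,n_ko_down Growth-plate lipids given KO-up / KO-down genotype
#'   effects in every zone.
#' @param effect_range Multiplicative effect magnitudes, drawn uniformly.
#' @param enrich_log2 Log2 enrichment of a lipid in its home region over the
#'   baseline tissue level.
#' @param min_sep_ppm Minimum separation enforced between any two library
#'   ions across all adduct forms (ppm). The default keeps every ion
#'   unambiguous at the 100-ppm annotation tolerance; large panels that are
#'   not used for annotation exactness can relax it.
#' @param seed RNG seed for mass drawing and effect assignment.
#' @return data.frame, one row per lipid: `name`, `class`, `neutral_mass`,
#'   per-region `prof_*` mean log2 intensities (0 = absent), `is_matrix`,
#'   `is_tissue_diff`, `enriched_region`, and `effect_<zone>` columns
#'   (1 = no genotype effect).
#' @export
make_lipid_panel <- function(n_per_tissue = 10, n_flat = 10, n_matrix = 10,
                             n_ko_up = 5, n_ko_down = 0,
                             effect_range = c(1.5, 3),
                             enrich_log2 = 2.5, min_sep_ppm = 150,
                             seed = 1) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))

  classes <- c(growth_plate = "LPC", marrow = "etherPC",
               articular_cartilage = "SM", cortical_bone = "PE")
  tissue_of <- rep(names(classes), each = n_per_tissue)
  class_lab <- c(rep(unname(classes), each = n_per_tissue),
                 rep("PC", n_flat), rep("matrix", n_matrix))
  n_tissue <- 4L * n_per_tissue
  n <- n_tissue + n_flat + n_matrix

  ranges <- matrix(0, n, 2)
  # matrix (DHB cluster) ions stay below every tissue-lipid adduct ion so
  # background and biological targets can never share an m/z bin
  range_of <- list(LPC = c(460, 560), etherPC = c(700, 800), SM = c(640, 820),
                   PE = c(820, 880), PC = c(560, 640), matrix = c(150, 400))
  for (i in seq_len(n)) ranges[i, ] <- range_of[[class_lab[i]]]
  masses <- draw_separated_masses(n, ranges, min_sep_ppm = min_sep_ppm)

  # cosmetic shorthand names with even chain totals (plausible, unique)
  carbons <- 2L * sample(14:22, n, replace = TRUE)
  dbs <- sample(0:6, n, replace = TRUE)
  name <- sprintf("%s(%d:%d)#%03d", class_lab, carbons, dbs, seq_len(n))

  base <- 10; off <- 0
  prof <- matrix(base, n, length(PHANTOM_REGIONS),
                 dimnames = list(NULL, paste0("prof_", PHANTOM_REGIONS)))
  prof[, "prof_off_tissue"] <- off
  enriched_region <- rep(NA_character_, n)
  for (i in seq_len(n_tissue)) {
    tis <- tissue_of[i]
    regs <- if (tis == "growth_plate")
      c("gp_resting", "gp_proliferating", "gp_hypertrophic") else tis
    prof[i, paste0("prof_", regs)] <- base + enrich_log2
    enriched_region[i] <- tis
  }
  if (n_matrix > 0) {
    idx <- (n_tissue + n_flat + 1L):n
    # DHB background: dominant off tissue, weakly present everywhere on tissue
    prof[idx, ] <- base - 2
    prof[idx, "prof_off_tissue"] <- base + 3
    enriched_region[idx] <- "off_tissue"
  }

  eff <- matrix(1, n, 3, dimnames = list(NULL, paste0("effect_", GP_ZONES)))
  gp_idx <- which(tissue_of == "growth_plate")
  if (n_ko_up + n_ko_down > length(gp_idx)) {
    stop("not enough growth-plate lipids to carry ", n_ko_up + n_ko_down,
         " genotype effects")
  }
  pick <- sample(gp_idx, n_ko_up + n_ko_down)
  up <- head(pick, n_ko_up); down <- tail(pick, n_ko_down)
  for (z in seq_len(3)) {
    eff[up, z] <- stats::runif(n_ko_up, effect_range[1], effect_range[2])
    eff[down, z] <- 1 / stats::runif(n_ko_down, effect_range[1],
                                     effect_range[2])
  }

  out <- data.frame(name = name, class = class_lab, neutral_mass = masses,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(prof), as.data.frame(eff))
  out$is_matrix <- class_lab == "matrix"
  out$is_tissue_diff <- !is.na(enriched_region) &
    enriched_region != "off_tissue"
  out$enriched_region <- enriched_region
  out
}

#' Phantom specification
#'
#' Collects every parameter of the synthetic MALDI-IMS generator in one
#' validated object. Defaults are the package's standard simulated study
#' conditions; `seed` is mandatory.
#'
#' @param grid_shape Integer `(rows, cols)`; default 64 x 64 pixels.
#' @param lipid_panel Ground-truth panel, see [make_lipid_panel()].
#' @param genotype `"WT"` or `"KO"`; KO applies the panel's `effect_*`
#'   multipliers within each growth-plate zone.
#' @param noise_sigma sdlog of the multiplicative log-normal intensity noise.
#' @param baseline Additive intensity baseline (counts) on every peak.
#' @param adduct_profile Named weights over `M+H`, `M+Na`, `M+K`, `M+H-H2O`;
#'   must sum to 1. Each lipid's intensity is split across these forms.
#' @param isotope_fraction Intensity of the carbon-13 partner peak of the
#'   protonated ion, as a fraction of it (0 disables isotope emission).
#' @param standard_spec Internal-standard description (`name`, `formula` or
#'   `true_mz`, `adduct`, `intensity`), or `NULL` for no spiked standard.
#' @param mz_jitter_ppm Per-pixel mass-error scale (Gaussian, ppm).
#' @param mz_shift_ppm Constant per-sample calibration shift (ppm), used to
#'   exercise lock-mass correction.
#' @param seed Integer RNG seed.
#' @param sample_id Sample label carried into metadata.
#' @return Object of class `PhantomSpec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64),
                         lipid_panel = make_lipid_panel(),
                         genotype = "WT",
                         noise_sigma = 0.35,
                         baseline = 2,
                         adduct_profile = DEFAULT_ADDUCT_PROFILE,
                         isotope_fraction = 0.3,
                         standard_spec = DEFAULT_STANDARD,
                         mz_jitter_ppm = 5,
                         mz_shift_ppm = 0,
                         seed,
                         sample_id = "phantom") {
  if (missing(seed)) stop("phantom_spec: seed is mandatory")
  stopifnot(length(grid_shape) == 2, genotype %in% c("WT", "KO"),
            noise_sigma >= 0, baseline >= 0, mz_jitter_ppm >= 0,
            isotope_fraction >= 0)
  if (nrow(lipid_panel) == 0) stop("phantom_spec: empty lipid_panel")
  if (abs(sum(adduct_profile) - 1) > 1e-9) {
    stop("phantom_spec: adduct weights must sum to 1")
  }
  if (any(adduct_profile < 0)) stop("phantom_spec: negative adduct weight")
  eff_cols <- paste0("effect_", GP_ZONES)
  if (any(as.matrix(lipid_panel[, eff_cols]) <= 0)) {
    stop("phantom_spec: effect_table entries must be > 0")
  }
  layout <- region_layout(grid_shape)
  if (!any(layout$region == "off_tissue")) {
    stop("phantom_spec: grid has no off_tissue pixels (matrix filter untestable)")
  }
  structure(
    list(grid_shape = as.integer(grid_shape), region_map = layout,
         lipid_panel = lipid_panel, genotype = genotype,
         noise_sigma = noise_sigma, baseline = baseline,
         adduct_profile = adduct_profile,
         isotope_fraction = isotope_fraction,
         standard_spec = standard_spec,
         mz_jitter_ppm = mz_jitter_ppm, mz_shift_ppm = mz_shift_ppm,
         seed = as.integer(seed), sample_id = sample_id),
    class = "PhantomSpec"
  )
}

# table of emitted ion species (lipid x adduct), the ground-truth ion axis
phantom_ion_table <- function(spec) {
  panel <- spec$lipid_panel
  weights <- spec$adduct_profile[spec$adduct_profile > 0]
  rows <- list()
  for (a in names(weights)) {
    rows[[a]] <- data.frame(
      lipid = panel$name, adduct = a,
      theoretical_mz = theoretical_mz(panel$neutral_mass, a),
      weight = unname(weights[[a]]), lipid_idx = seq_len(nrow(panel)),
      stringsAsFactors = FALSE
    )
  }
  ions <- do.call(rbind, rows)
  if (spec$isotope_fraction > 0 && "M+H" %in% names(weights)) {
    iso <- rows[["M+H"]]
    iso$adduct <- "M+H+13C"
    iso$theoretical_mz <- theoretical_mz(panel$neutral_mass, "M+H+13C")
    iso$weight <- iso$weight * spec$isotope_fraction
    ions <- rbind(ions, iso)
  }
  ions <- ions[order(ions$lipid_idx, ions$theoretical_mz), ]
  ions$ion_id <- sprintf("ion_%04d", seq_len(nrow(ions)))
  rownames(ions) <- NULL
  ions
}

#' Generate a synthetic MALDI-IMS phantom
#'
#' Simulates one sample: per pixel, every ground-truth lipid present in the
#' pixel's region is emitted as its adduct ions at theoretical m/z perturbed by
#' Gaussian ppm jitter, with multiplicative log-normal intensity noise and an
#' additive baseline; matrix ions appear in all pixels including off-tissue
#' ones, and the internal standard (if configured) is spiked into every pixel.
#' KO genotype multiplies growth-plate-zone intensities by the panel's
#' `effect_*` entries.
#'
#' @param spec A [phantom_spec()] object.
#' @return List with `spectra` (a `PixelSpectrumSet`) and `truth` (data.frame:
#'   one row per emitted ion species with source lipid, adduct, theoretical
#'   m/z, matrix/differential flags and per-zone genotype effects).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  old <- set_local_seed(spec$seed)
  on.exit(restore_seed(old))

  layout <- spec$region_map
  panel <- spec$lipid_panel
  n_px <- nrow(layout)
  ions <- phantom_ion_table(spec)
  n_ion <- nrow(ions)

  prof_cols <- paste0("prof_", PHANTOM_REGIONS)
  prof <- as.matrix(panel[, prof_cols])          # lipid x region, log2 means
  region_idx <- match(layout$region, PHANTOM_REGIONS)

  # per-lipid per-region linear means (0 where profile == 0 -> absent)
  mean_lin <- 2^prof
  mean_lin[prof == 0] <- 0
  if (spec$genotype == "KO") {
    for (z in GP_ZONES) {
      col <- match(paste0("gp_", z), PHANTOM_REGIONS)
      mean_lin[, col] <- mean_lin[, col] * panel[[paste0("effect_", z)]]
    }
  }

  # pixel x ion mean intensity
  lipid_mean <- mean_lin[, region_idx, drop = FALSE]      # lipid x pixel
  ion_mean <- lipid_mean[ions$lipid_idx, , drop = FALSE] * ions$weight
  present <- ion_mean > 0

  noise <- if (spec$noise_sigma > 0)
    matrix(stats::rlnorm(n_ion * n_px, 0, spec$noise_sigma), n_ion, n_px)
  else matrix(1, n_ion, n_px)
  intensity <- ion_mean * noise
  intensity[present] <- intensity[present] + spec$baseline

  shift <- 1 + spec$mz_shift_ppm * 1e-6
  jit <- if (spec$mz_jitter_ppm > 0)
    matrix(stats::rnorm(n_ion * n_px, 0, spec$mz_jitter_ppm * 1e-6),
           n_ion, n_px)
  else matrix(0, n_ion, n_px)
  mz <- ions$theoretical_mz * shift * (1 + jit)

  keep <- which(present)
  px_of <- ((keep - 1L) %/% n_ion) + 1L
  peaks <- data.frame(
    pixel = px_of,
    mz = mz[keep],
    intensity = intensity[keep]
  )

  # spiked internal standard in every pixel
  std <- spec$standard_spec
  std_truth <- NULL
  if (!is.null(std)) {
    std_mz_true <- if (!is.null(std$true_mz)) std$true_mz else
      theoretical_mz(formula_mass(std$formula), std$adduct)
    s_noise <- if (spec$noise_sigma > 0)
      stats::rlnorm(n_px, 0, spec$noise_sigma) else rep(1, n_px)
    s_jit <- if (spec$mz_jitter_ppm > 0)
      stats::rnorm(n_px, 0, spec$mz_jitter_ppm * 1e-6) else rep(0, n_px)
    peaks <- rbind(peaks, data.frame(
      pixel = seq_len(n_px),
      mz = std_mz_true * shift * (1 + s_jit),
      intensity = std$intensity * s_noise + spec$baseline
    ))
    std_truth <- data.frame(
      ion_id = "standard", lipid = std$name, adduct = std$adduct,
      theoretical_mz = std_mz_true, class = "standard", is_matrix = FALSE,
      is_tissue_diff = FALSE, enriched_region = NA_character_,
      effect_resting = 1, effect_proliferating = 1, effect_hypertrophic = 1,
      stringsAsFactors = FALSE
    )
  }

  peaks <- peaks[order(peaks$pixel, peaks$mz), ]
  rownames(peaks) <- NULL

  pixels <- data.frame(pixel = seq_len(n_px), row = layout$row,
                       col = layout$col, region = layout$region,
                       stringsAsFactors = FALSE)
  ps <- pixel_spectra(
    pixels = pixels, peaks = peaks,
    metadata = list(sample_id = spec$sample_id, genotype = spec$genotype,
                    acquisition = "synthetic")
  )

  truth <- data.frame(
    ion_id = ions$ion_id, lipid = ions$lipid, adduct = ions$adduct,
    theoretical_mz = ions$theoretical_mz,
    class = panel$class[ions$lipid_idx],
    is_matrix = panel$is_matrix[ions$lipid_idx],
    is_tissue_diff = panel$is_tissue_diff[ions$lipid_idx],
    enriched_region = panel$enriched_region[ions$lipid_idx],
    effect_resting = panel$effect_resting[ions$lipid_idx],
    effect_proliferating = panel$effect_proliferating[ions$lipid_idx],
    effect_hypertrophic = panel$effect_hypertrophic[ions$lipid_idx],
    stringsAsFactors = FALSE
  )
  if (!is.null(std_truth)) truth <- rbind(truth, std_truth)
  rownames(truth) <- NULL

  list(spectra = ps, truth = truth)
}

#' Generate a WT/KO phantom cohort
#'
#' Convenience wrapper producing `n_wt + n_ko` samples from one base spec with
#' per-sample seeds derived from the base seed.
#'
#' @param spec Base [phantom_spec()]; its `genotype` field is overridden.
#' @param n_wt,n_ko Samples per genotype.
#' @return List with `samples` (list of `generate_phantom()` outputs) and
#'   `truth` (shared ground-truth ion table).
#' @export
generate_cohort <- function(spec, n_wt = 2, n_ko = 2) {
  genos <- c(rep("WT", n_wt), rep("KO", n_ko))
  samples <- vector("list", length(genos))
  truth <- NULL
  for (i in seq_along(genos)) {
    s <- spec
    s$genotype <- genos[i]
    s$seed <- (spec$seed * 131L + i) %% .Machine$integer.max
    s$sample_id <- sprintf("%s_%02d", genos[i], i)
    out <- generate_phantom(s)
    samples[[i]] <- out
    truth <- out$truth
  }
  list(samples = samples, truth = truth)
}

#' Generate a reference lipid library for a phantom
#'
#' One record per ground-truth lipid (correct neutral mass, shorthand name,
#' simulated database-evidence flags for tier scoring) plus `decoys` records at
#' masses at least 300 ppm away from every truth mass.
#'
#' @param spec A [phantom_spec()].
#' @param decoys Number of decoy records (>= 0).
#' @param decoy_min_ppm Minimum allowed decoy-to-truth mass distance (ppm);
#'   candidate decoys closer than this are redrawn.
#' @return data.frame in the library layout used by [match_ions()]:
#'   `name,headgroup,chains,neutral_mass,manual_id,lipidmatch_hit,
#'   lipidmatch_score_high,lipidblast_hit,is_decoy`.
#' @export
generate_library <- function(spec, decoys = 0, decoy_min_ppm = 300) {
  stopifnot(inherits(spec, "PhantomSpec"), decoys >= 0)
  old <- set_local_seed(spec$seed + 7919L)
  on.exit(restore_seed(old))
  panel <- spec$lipid_panel

  lib <- data.frame(
    name = panel$name,
    headgroup = panel$class,
    chains = "",
    neutral_mass = panel$neutral_mass,
    manual_id = panel$is_tissue_diff,      # differential species get manual IDs
    lipidmatch_hit = TRUE,
    lipidmatch_score_high = TRUE,
    lipidblast_hit = !panel$is_matrix,
    is_decoy = FALSE,
    stringsAsFactors = FALSE
  )
  std <- spec$standard_spec
  if (!is.null(std)) {
    lib <- rbind(lib, data.frame(
      name = std$name, headgroup = "PC", chains = "15:0/18:1",
      neutral_mass = if (!is.null(std$true_mz))
        std$true_mz - adduct_forms()$mass_delta[
          match(std$adduct, adduct_forms()$adduct)] else
          formula_mass(std$formula),
      manual_id = TRUE, lipidmatch_hit = TRUE, lipidmatch_score_high = TRUE,
      lipidblast_hit = TRUE, is_decoy = FALSE, stringsAsFactors = FALSE
    ))
  }

  if (decoys > 0) {
    deltas <- adduct_forms()$mass_delta
    # spacing enforced in the adduct m/z domain: any decoy ion must sit at
    # least decoy_min_ppm from every truth ion of any adduct form
    truth_ions <- sort(as.vector(outer(lib$neutral_mass, deltas, "+")))
    got <- numeric(0)
    tries <- 0L
    while (length(got) < decoys) {
      tries <- tries + 1L
      if (tries > 1000L * decoys) stop("cannot place decoys 300 ppm clear")
      cand <- stats::runif(1, 150, 900)
      cand_ions <- cand + deltas
      near <- function(ions, ref) {
        any(vapply(ref, function(x)
          any(abs(ions - x) / x * 1e6 < decoy_min_ppm), TRUE))
      }
      if (near(cand_ions, truth_ions)) next
      if (length(got) && near(cand_ions,
                              as.vector(outer(got, deltas, "+")))) next
      got <- c(got, cand)
    }
    lib <- rbind(lib, data.frame(
      name = sprintf("DECOY_%03d", seq_len(decoys)), headgroup = "decoy",
      chains = "", neutral_mass = got, manual_id = FALSE,
      lipidmatch_hit = FALSE, lipidmatch_score_high = FALSE,
      lipidblast_hit = FALSE, is_decoy = TRUE, stringsAsFactors = FALSE
    ))
  }
  rownames(lib) <- NULL
  lib
}

#' Simulate an ROI-level feature matrix directly
#'
#' ROI-level counterpart of the pixel phantom, used for statistical
#' calibration: log2 ion intensities for WT and KO ROI groups in each
#' growth-plate zone are drawn i.i.d. Gaussian around ion means, with a chosen
#' subset of ions carrying multiplicative KO effects in every zone. This is
#' the same intensity model as the pixel phantom after ROI averaging and log2
#' scaling, without the imaging layer.
#'
#' @param n_ions Number of ions.
#' @param n_per_group ROIs per genotype per zone.
#' @param n_diff Ions given a KO-up effect (first `n_diff` ions).
#' @param effect_range Multiplicative effect magnitudes (linear scale), drawn
#'   uniformly per ion per zone.
#' @param sigma Between-ROI sd of log2 intensity.
#' @param base_log2 Mean log2 intensity.
#' @param zones Zone labels to simulate.
#' @param seed RNG seed.
#' @return List with `fm` (a log2-scale [feature_matrix()]) and `truth`
#'   (character vector of differential ion ids).
#' @export
generate_roi_phantom <- function(n_ions = 200, n_per_group = 10, n_diff = 0,
                                 effect_range = c(1.5, 3), sigma = 0.25,
                                 base_log2 = 10, zones = GP_ZONES, seed = 1) {
  old <- set_local_seed(seed)
  on.exit(restore_seed(old))
  ion_ids <- sprintf("ion_%04d", seq_len(n_ions))
  rows <- list(); meta <- list()
  for (z in zones) {
    eff <- rep(0, n_ions)
    if (n_diff > 0) {
      eff[seq_len(n_diff)] <-
        log2(stats::runif(n_diff, effect_range[1], effect_range[2]))
    }
    for (g in c("WT", "KO")) {
      mu <- base_log2 + if (g == "KO") eff else 0
      m <- matrix(stats::rnorm(n_per_group * n_ions, mean = rep(mu,
                  each = n_per_group), sd = sigma), n_per_group, n_ions)
      rows[[paste(z, g)]] <- m
      meta[[paste(z, g)]] <- data.frame(
        roi_id = sprintf("%s_%s_%02d", z, g, seq_len(n_per_group)),
        tissue = "growth_plate", zone = z, genotype = g,
        kind = "lROI", replicate = seq_len(n_per_group),
        stringsAsFactors = FALSE
      )
    }
  }
  values <- do.call(rbind, rows)
  rois <- do.call(rbind, meta)
  rownames(rois) <- NULL
  colnames(values) <- ion_ids
  rownames(values) <- rois$roi_id
  list(
    fm = feature_matrix(values, rois, scale = "log2"),
    truth = ion_ids[seq_len(max(n_diff, 0))]
  )
}

# seed handling: isolate generator RNG from the caller's stream
set_local_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
         globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
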
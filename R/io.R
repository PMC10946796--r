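# On-disk formats: the internal tabular dialect for binned images (mirroring
# per-pixel exported text files), a minimal continuous/processed-mode imzML
# writer/reader, and CSV layouts for ROI sets, libraries and results.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a binned image in the tabular dialect
#'
#' Tab-separated text: a target-list block of lines
#' `#target<TAB>bin_id<TAB>mz_center<TAB>drift_center`, then a header row
#' `row<TAB>col<TAB>bin_id_1...` and one row per pixel. Numbers are written at
#' full precision so a read-back is bit-exact.
#'
#' @param img A `BinnedImage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_binned_tsv <- function(img, path) {
  stopifnot(inherits(img, "BinnedImage"))
  tl <- img$target_list
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#mz_bin\t%s", fmt_num(attr(tl, "mz_bin") %||% 0.04)),
             con)
  writeLines(sprintf("#drift_bin\t%s",
                     fmt_num(attr(tl, "drift_bin") %||% 100)), con)
  writeLines(sprintf("#target\t%s\t%s\t%s", tl$bin_id, fmt_num(tl$mz_center),
                     ifelse(is.na(tl$drift_center), "NA",
                            fmt_num(tl$drift_center))), con)
  writeLines(paste(c("row", "col", tl$bin_id), collapse = "\t"), con)
  body <- cbind(img$pixels$row, img$pixels$col, img$matrix)
  writeLines(apply(body, 1, function(r)
    paste(fmt_num(r), collapse = "\t")), con)
  invisible(path)
}

#' Read a binned image from the tabular dialect
#'
#' @param path File written by [write_binned_tsv()].
#' @return A `BinnedImage` (pixel order and values as written).
#' @export
read_binned_tsv <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  get1 <- function(tag, default) {
    hit <- meta[startsWith(meta, paste0("#", tag, "\t"))]
    if (!length(hit)) return(default)
    as.numeric(strsplit(hit[1], "\t")[[1]][2])
  }
  tdef <- strsplit(meta[startsWith(meta, "#target\t")], "\t")
  tl <- data.frame(
    bin_id = vapply(tdef, `[`, "", 2),
    mz_center = as.numeric(vapply(tdef, `[`, "", 3)),
    drift_center = suppressWarnings(as.numeric(vapply(tdef, `[`, "", 4))),
    stringsAsFactors = FALSE
  )
  tl <- structure(tl, mz_bin = get1("mz_bin", 0.04),
                  drift_bin = get1("drift_bin", 100),
                  class = c("TargetList", "data.frame"))
  body <- lines[!is_meta]
  header <- strsplit(body[1], "\t")[[1]]
  stopifnot(identical(header[1:2], c("row", "col")),
            identical(header[-(1:2)], tl$bin_id))
  vals <- do.call(rbind, lapply(strsplit(body[-1], "\t"), as.numeric))
  pixels <- data.frame(pixel = seq_len(nrow(vals)), row = vals[, 1],
                       col = vals[, 2])
  mat <- vals[, -(1:2), drop = FALSE]
  colnames(mat) <- tl$bin_id
  structure(list(matrix = mat, pixels = pixels, target_list = tl,
                 metadata = list(), provenance = sprintf("read %s", path)),
            class = "BinnedImage")
}

# ---- imzML -----------------------------------------------------------------

imzml_cv <- function(accession, name, value = NULL, unit = NULL) {
  node <- sprintf('<cvParam cvRef="MS" accession="%s" name="%s"%s/>',
                  accession, name,
                  if (is.null(value)) "" else sprintf(' value="%s"', value))
  node
}

#' Write spectra as imzML
#'
#' Minimal imzML writer: a `BinnedImage` is written in continuous mode (one
#' shared m/z axis of target centres), a `PixelSpectrumSet` in processed mode
#' (per-pixel m/z arrays). Both arrays are 64-bit floats in the external
#' `.ibd` file, so a round trip preserves m/z and intensities exactly.
#'
#' @param x A `BinnedImage` or `PixelSpectrumSet`.
#' @param path Output `.imzML` path; the `.ibd` is written alongside.
#' @param uuid_seed Integer used to derive the 16-byte file UUID
#'   deterministically.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(x, path, uuid_seed = 1L) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  old <- set_local_seed(uuid_seed)
  uuid <- as.raw(sample(0:255, 16, replace = TRUE))
  restore_seed(old)

  continuous <- inherits(x, "BinnedImage")
  con <- file(ibd_path, "wb")
  writeBin(uuid, con)
  offset <- 16
  specs <- list()
  if (continuous) {
    mz <- x$target_list$mz_center
    writeBin(as.double(mz), con, size = 8, endian = "little")
    mz_offset <- offset; mz_len <- length(mz)
    offset <- offset + 8 * mz_len
    for (i in seq_len(nrow(x$pixels))) {
      ints <- as.double(x$matrix[i, ])
      writeBin(ints, con, size = 8, endian = "little")
      specs[[i]] <- list(row = x$pixels$row[i], col = x$pixels$col[i],
                         mz_offset = mz_offset, mz_len = mz_len,
                         int_offset = offset, int_len = length(ints))
      offset <- offset + 8 * length(ints)
    }
  } else {
    pk <- split(x$peaks, x$peaks$pixel)
    for (i in seq_len(nrow(x$pixels))) {
      p <- pk[[as.character(x$pixels$pixel[i])]]
      mz <- if (is.null(p)) double() else as.double(p$mz)
      ints <- if (is.null(p)) double() else as.double(p$intensity)
      writeBin(mz, con, size = 8, endian = "little")
      mz_offset <- offset; offset <- offset + 8 * length(mz)
      writeBin(ints, con, size = 8, endian = "little")
      specs[[i]] <- list(row = x$pixels$row[i], col = x$pixels$col[i],
                         mz_offset = mz_offset, mz_len = length(mz),
                         int_offset = offset, int_len = length(ints))
      offset <- offset + 8 * length(ints)
    }
  }
  close(con)

  mode_acc <- if (continuous) "IMS:1000030" else "IMS:1000031"
  mode_name <- if (continuous) "continuous" else "processed"
  spec_xml <- vapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, s$int_len),
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
              s$col + 1L),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
              s$row + 1L),
      '</scan></scanList><binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
              s$mz_offset),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
              s$mz_len),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
              8L * s$mz_len),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
              s$int_offset),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
              s$int_len),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
              8L * s$int_len),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, "")

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<fileDescription><fileContent>',
    sprintf('<cvParam cvRef="IMS" accession="%s" name="%s"/>',
            mode_acc, mode_name),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
            paste(sprintf("%02x", as.integer(uuid)), collapse = "")),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
            max(x$pixels$col) + 1L),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
            max(x$pixels$row) + 1L),
    '<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="50"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="50"/>',
    '</scanSettings></scanSettingsList>',
    '<softwareList count="1"><software id="lipidims" version="0"/></softwareList>',
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    '</instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="lipidims"/>',
    '</dataProcessing></dataProcessingList>',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1"><spectrumList count="%d" defaultDataProcessingRef="export">',
            length(specs)),
    paste(spec_xml, collapse = ""),
    '</spectrumList></run></mzML>\n'
  )
  writeLines(xml, path)
  invisible(path)
}

#' Read imzML written by [write_imzml()]
#'
#' Supports 64-bit-float continuous and processed mode files with external
#' binary arrays.
#'
#' @param path `.imzML` path (the `.ibd` must sit alongside).
#' @return A `PixelSpectrumSet` (processed mode) or `BinnedImage`-like list
#'   (continuous mode, with the shared axis as `target_list`).
#' @export
read_imzml <- function(path) {
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  mode <- xml2::xml_find_first(
    doc, "//m:fileContent/m:cvParam[@accession='IMS:1000030' or @accession='IMS:1000031']",
    ns)
  continuous <- identical(xml2::xml_attr(mode, "accession"), "IMS:1000030")
  specs <- xml2::xml_find_all(doc, "//m:spectrum", ns)
  con <- file(ibd_path, "rb")
  on.exit(close(con))

  read_array <- function(offset, len) {
    seek(con, where = offset)
    readBin(con, "double", n = len, size = 8, endian = "little")
  }
  get_arrays <- function(sp) {
    bdas <- xml2::xml_find_all(sp, ".//m:binaryDataArray", ns)
    out <- list()
    for (b in bdas) {
      ref <- xml2::xml_attr(xml2::xml_find_first(
        b, ".//m:referenceableParamGroupRef", ns), "ref")
      is_mz <- identical(ref, "mzArray") ||
        !is.na(xml2::xml_attr(xml2::xml_find_first(
          b, ".//m:cvParam[@accession='MS:1000514']", ns), "accession"))
      off <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
        b, ".//m:cvParam[@accession='IMS:1000102']", ns), "value"))
      len <- as.integer(xml2::xml_attr(xml2::xml_find_first(
        b, ".//m:cvParam[@accession='IMS:1000103']", ns), "value"))
      out[[if (is_mz) "mz" else "intensity"]] <- read_array(off, len)
    }
    out
  }
  pos <- function(sp, acc) as.integer(xml2::xml_attr(xml2::xml_find_first(
    sp, sprintf(".//m:cvParam[@accession='%s']", acc), ns), "value"))

  n <- length(specs)
  rows <- integer(n); cols <- integer(n)
  arr <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- specs[[i]]
    cols[i] <- pos(sp, "IMS:1000050") - 1L
    rows[i] <- pos(sp, "IMS:1000051") - 1L
    arr[[i]] <- get_arrays(sp)
  }
  pixels <- data.frame(pixel = seq_len(n), row = rows, col = cols)
  if (continuous) {
    mz <- arr[[1]]$mz
    mat <- do.call(rbind, lapply(arr, `[[`, "intensity"))
    tl <- structure(data.frame(bin_id = sprintf("t_%05d", seq_along(mz)),
                               mz_center = mz, drift_center = NA_real_),
                    mz_bin = NA_real_, drift_bin = NA_real_,
                    class = c("TargetList", "data.frame"))
    colnames(mat) <- tl$bin_id
    structure(list(matrix = mat, pixels = pixels, target_list = tl,
                   metadata = list(), provenance = sprintf("read %s", path)),
              class = "BinnedImage")
  } else {
    peaks <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (!length(arr[[i]]$mz)) return(NULL)
      data.frame(pixel = i, mz = arr[[i]]$mz,
                 intensity = arr[[i]]$intensity)
    }))
    if (is.null(peaks)) peaks <- data.frame(pixel = integer(),
                                            mz = numeric(),
                                            intensity = numeric())
    pixel_spectra(pixels, peaks, metadata = list(source = path))
  }
}

# ---- CSV layouts -----------------------------------------------------------

#' Read an ROI set from CSV
#'
#' Expected columns: `roi_id,row,col,tissue,zone,bone,replicate,kind`
#' (optional `genotype`); one row per member pixel.
#'
#' @param path CSV path.
#' @return An [roi_set()].
#' @export
read_roi_csv <- function(path) {
  roi_set(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an ROI set to CSV
#' @param rois An [roi_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(rois, path) {
  utils::write.csv(as.data.frame(rois), path, row.names = FALSE)
  invisible(path)
}

#' Read a lipid reference library from CSV
#'
#' Columns: `name,headgroup,chains,formula_or_mass,manual_id,lipidmatch_hit,
#' lipidmatch_score_high,lipidblast_hit`. `formula_or_mass` may be a numeric
#' monoisotopic neutral mass or an elemental formula, from which the mass is
#' computed.
#'
#' @param path CSV path.
#' @return Library data.frame with a `neutral_mass` column.
#' @export
read_library_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"neutral_mass" %in% names(df)) {
    stopifnot("formula_or_mass" %in% names(df))
    mass <- suppressWarnings(as.numeric(df$formula_or_mass))
    needs_formula <- is.na(mass)
    mass[needs_formula] <- vapply(df$formula_or_mass[needs_formula],
                                  formula_mass, 0.0)
    df$neutral_mass <- mass
  }
  for (fl in c("manual_id", "lipidmatch_hit", "lipidmatch_score_high",
               "lipidblast_hit")) {
    if (!fl %in% names(df)) df[[fl]] <- FALSE
    df[[fl]] <- as.logical(df[[fl]])
  }
  df
}

#' Write a feature matrix to CSV (metadata columns first)
#' @param fm A [feature_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(fm, path) {
  out <- cbind(fm$rois, as.data.frame(fm$values))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
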
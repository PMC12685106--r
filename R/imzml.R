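# imzML import/export.
#
# imzML is the open interchange format for mass spectrometry imaging: an
# mzML-style XML index file plus a binary ".ibd" companion holding the
# spectral arrays, linked by a shared UUID. Two dialects exist: "continuous"
# (one m/z axis shared by all pixels) and "processed" (per-pixel peak lists).
# This reader/writer covers the subset of the standard needed for centroided
# DESI-MSI data: 64-bit m/z, 32-bit intensity, no compression, external
# binary arrays, per-pixel positions. Coordinates are written 1-based as the
# standard requires and converted to this package's 0-based convention on
# read.

ibd_path_for <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

#' Write an MSI image as an imzML + ibd pair
#'
#' @param img an [msi_image()].
#' @param path output path ending in `.imzML`; the binary companion is
#'   written next to it with extension `.ibd`.
#' @param mode `"processed"` (default; per-pixel peak lists) or
#'   `"continuous"` (requires all pixels to share one m/z axis).
#' @return the imzML path, invisibly.
#' @export
write_imzml <- function(img, path, mode = img$mode) {
  validate_msi_image(img)
  mode <- match.arg(mode, c("processed", "continuous"))
  n <- length(img$spectra)
  if (mode == "continuous" && n > 1) {
    ref <- img$spectra[[1]]$mz
    shared <- all(vapply(img$spectra, function(s)
      length(s$mz) == length(ref) && all(s$mz == ref), logical(1)))
    if (!shared) {
      stop("continuous mode requested but pixel m/z axes are ragged", call. = FALSE)
    }
  }

  uuid <- derive_uuid(paste(img$patient_id, n, mode))
  ibd <- ibd_path_for(path)
  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16

  mz_off <- numeric(n); mz_len <- integer(n)
  int_off <- numeric(n); int_len <- integer(n)
  if (mode == "continuous" && n > 0) {
    axis <- img$spectra[[1]]$mz
    writeBin(axis, con, size = 8, endian = "little")
    mz_off[] <- offset; mz_len[] <- length(axis)
    offset <- offset + 8 * length(axis)
    for (i in seq_len(n)) {
      intensity <- img$spectra[[i]]$intensity
      int_off[i] <- offset; int_len[i] <- length(intensity)
      writeBin(intensity, con, size = 4, endian = "little")
      offset <- offset + 4 * length(intensity)
    }
  } else {
    for (i in seq_len(n)) {
      sp <- img$spectra[[i]]
      mz_off[i] <- offset; mz_len[i] <- length(sp$mz)
      writeBin(sp$mz, con, size = 8, endian = "little")
      offset <- offset + 8 * length(sp$mz)
      int_off[i] <- offset; int_len[i] <- length(sp$intensity)
      writeBin(sp$intensity, con, size = 4, endian = "little")
      offset <- offset + 4 * length(sp$intensity)
    }
  }

  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  max_x <- if (n) max(img$coords$x) + 1L else 1L
  max_y <- if (n) max(img$coords$y) + 1L else 1L
  pix <- if (is.na(img$spatial_resolution)) 100 else img$spatial_resolution

  spec_xml <- character(n)
  for (i in seq_len(n)) {
    spec_xml[i] <- sprintf(
      paste0(
        '      <spectrum id="spectrum=%d" index="%d" defaultArrayLength="0">\n',
        '        <scanList count="1">\n',
        '          <scan>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
        '          </scan>\n',
        '        </scanList>\n',
        '        <binaryDataArrayList count="2">\n',
        '          <binaryDataArray encodedLength="0">\n',
        '            <referenceableParamGroupRef ref="mzArray"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
        '            <binary/>\n',
        '          </binaryDataArray>\n',
        '          <binaryDataArray encodedLength="0">\n',
        '            <referenceableParamGroupRef ref="intensityArray"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
        '            <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%.0f"/>\n',
        '            <binary/>\n',
        '          </binaryDataArray>\n',
        '        </binaryDataArrayList>\n',
        '      </spectrum>'
      ),
      i, i - 1L, img$coords$x[i] + 1L, img$coords$y[i] + 1L,
      mz_len[i], mz_off[i], 8 * mz_len[i],
      int_len[i], int_off[i], 4 * int_len[i]
    )
  }

  xml <- sprintf(
    paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
      '  <cvList count="3">\n',
      '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>\n',
      '    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>\n',
      '    <cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>\n',
      '  </cvList>\n',
      '  <fileDescription>\n',
      '    <fileContent>\n',
      '      <cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum"/>\n',
      '      <cvParam cvRef="IMS" accession="%s" name="%s"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>\n',
      '    </fileContent>\n',
      '  </fileDescription>\n',
      '  <referenceableParamGroupList count="2">\n',
      '    <referenceableParamGroup id="mzArray">\n',
      '      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
      '    </referenceableParamGroup>\n',
      '    <referenceableParamGroup id="intensityArray">\n',
      '      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>\n',
      '      <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
      '    </referenceableParamGroup>\n',
      '  </referenceableParamGroupList>\n',
      '  <softwareList count="1">\n',
      '    <software id="desimsi" version="0.1.0"/>\n',
      '  </softwareList>\n',
      '  <scanSettingsList count="1">\n',
      '    <scanSettings id="scanSettings1">\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
      '      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%g"/>\n',
      '    </scanSettings>\n',
      '  </scanSettingsList>\n',
      '  <instrumentConfigurationList count="1">\n',
      '    <instrumentConfiguration id="IC1"/>\n',
      '  </instrumentConfigurationList>\n',
      '  <dataProcessingList count="1">\n',
      '    <dataProcessing id="export">\n',
      '      <processingMethod order="1" softwareRef="desimsi">\n',
      '        <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>\n',
      '      </processingMethod>\n',
      '    </dataProcessing>\n',
      '  </dataProcessingList>\n',
      '  <run id="%s" defaultInstrumentConfigurationRef="IC1">\n',
      '    <spectrumList count="%d" defaultDataProcessingRef="export">\n',
      '%s\n',
      '    </spectrumList>\n',
      '  </run>\n',
      '</mzML>\n'
    ),
    mode_acc, mode, uuid_string(uuid),
    max_x, max_y, pix,
    xml_escape(img$patient_id), n,
    paste(spec_xml, collapse = "\n")
  )
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Read an imzML + ibd pair into an MSI image
#'
#' Detects continuous vs processed mode from the file metadata, validates
#' that m/z axes are strictly ascending, and converts the standard's 1-based
#' pixel positions to 0-based coordinates.
#'
#' @param path path to the `.imzML` file; the `.ibd` companion must sit next
#'   to it.
#' @return an [msi_image()].
#' @export
read_imzml <- function(path) {
  if (!file.exists(path)) stop(sprintf("imzML file not found: %s", path), call. = FALSE)
  ibd <- ibd_path_for(path)
  if (!file.exists(ibd)) {
    stop(sprintf("binary companion file not found: %s", ibd), call. = FALSE)
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)

  mode <- if (!is.na(xml2::xml_find_first(doc, "//fileContent/cvParam[@accession='IMS:1000030']"))) {
    "continuous"
  } else if (!is.na(xml2::xml_find_first(doc, "//fileContent/cvParam[@accession='IMS:1000031']"))) {
    "processed"
  } else {
    stop("imzML file declares neither continuous nor processed mode", call. = FALSE)
  }
  uuid_xml <- xml2::xml_attr(
    xml2::xml_find_first(doc, "//fileContent/cvParam[@accession='IMS:1000080']"), "value"
  )
  run <- xml2::xml_find_first(doc, "//run")
  patient_id <- xml2::xml_attr(run, "id")
  pix_node <- xml2::xml_find_first(doc, "//scanSettings/cvParam[@accession='IMS:1000046']")
  spatial_resolution <- if (is.na(pix_node)) NA_real_ else as.numeric(xml2::xml_attr(pix_node, "value"))

  con <- file(ibd, "rb")
  on.exit(close(con))
  uuid_ibd <- readBin(con, "raw", 16)
  if (!is.na(uuid_xml) && nzchar(uuid_xml)) {
    if (!identical(gsub("[{}-]", "", tolower(uuid_xml)),
                   paste(format(uuid_ibd), collapse = ""))) {
      stop("UUID mismatch between imzML and ibd files", call. = FALSE)
    }
  }

  spectra_nodes <- xml2::xml_find_all(doc, "//spectrumList/spectrum")
  n <- length(spectra_nodes)
  xs <- integer(n); ys <- integer(n)
  spectra <- vector("list", n)
  read_array <- function(offset, len, size) {
    seek(con, where = offset, origin = "start")
    readBin(con, "double", n = len, size = size, endian = "little")
  }
  for (i in seq_len(n)) {
    node <- spectra_nodes[[i]]
    xs[i] <- as.integer(xml2::xml_attr(
      xml2::xml_find_first(node, ".//scan/cvParam[@accession='IMS:1000050']"), "value")) - 1L
    ys[i] <- as.integer(xml2::xml_attr(
      xml2::xml_find_first(node, ".//scan/cvParam[@accession='IMS:1000051']"), "value")) - 1L
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    mz <- NULL; intensity <- NULL
    for (arr in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(arr, "./referenceableParamGroupRef"), "ref")
      len <- as.integer(xml2::xml_attr(
        xml2::xml_find_first(arr, "./cvParam[@accession='IMS:1000103']"), "value"))
      off <- as.numeric(xml2::xml_attr(
        xml2::xml_find_first(arr, "./cvParam[@accession='IMS:1000102']"), "value"))
      if (identical(ref, "mzArray")) {
        mz <- read_array(off, len, 8)
      } else if (identical(ref, "intensityArray")) {
        intensity <- read_array(off, len, 4)
      }
    }
    if (is.null(mz) || is.null(intensity)) {
      stop(sprintf("spectrum %d: missing m/z or intensity array", i), call. = FALSE)
    }
    if (length(mz) > 1 && any(diff(mz) <= 0)) {
      stop(sprintf("pixel (%d,%d): m/z values not strictly ascending", xs[i], ys[i]),
           call. = FALSE)
    }
    spectra[[i]] <- list(mz = mz, intensity = intensity)
  }
  msi_image(
    patient_id = if (is.na(patient_id)) "unknown" else patient_id,
    coords = data.frame(x = xs, y = ys),
    spectra = spectra, mode = mode,
    spatial_resolution = spatial_resolution
  )
}
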
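# Continuous-mode imzML I/O.
#
# imzML stores spectra as an XML index (.imzML) plus a flat binary file
# (.ibd): a 16-byte UUID, then -- in continuous mode -- one shared m/z
# axis, then one intensity array per pixel, addressed by byte offsets in
# the XML. The m/z axis is written as 64-bit floats and intensities as
# 32-bit floats (exact for counts below 2^24), the common convention for
# MSI data. No R package on our stack reads imzML, so the format is
# implemented here directly; files written by this code parse with the
# reference pyimzML library.

.ibd_path <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

#' Write a SIMS cube as continuous-mode imzML
#'
#' @param cube A [sims_cube()].
#' @param path Output path ending in `.imzML`; the binary companion is
#'   written alongside with extension `.ibd`.
#' @return `path`, invisibly.
#' @seealso [read_imzml()]
#' @export
write_imzml <- function(cube, path) {
  stopifnot(inherits(cube, "sims_cube"))
  if (!grepl("\\.imzml$", path, ignore.case = TRUE))
    stop("path must end in .imzML")
  d <- dim(cube$counts)
  nr <- d[1]; nc <- d[2]; nch <- d[3]

  uuid_bytes <- as.raw(c(
    sample.int(256L, 16L, replace = TRUE) - 1L))
  uuid_hex <- paste(sprintf("%02x", as.integer(uuid_bytes)), collapse = "")
  uuid_str <- paste0("{", substr(uuid_hex, 1, 8), "-",
                     substr(uuid_hex, 9, 12), "-", substr(uuid_hex, 13, 16),
                     "-", substr(uuid_hex, 17, 20), "-",
                     substr(uuid_hex, 21, 32), "}")

  con <- file(.ibd_path(path), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid_bytes, con)
  writeBin(as.numeric(cube$channel_mz), con, size = 8, endian = "little")
  # spectra in pixel raster order: y (rows) outer, x (cols) inner
  writeBin(as.numeric(aperm(cube$counts, c(3, 2, 1))), con, size = 4,
           endian = "little")

  mz_enc <- nch * 8L
  k <- seq_len(nr * nc)
  px <- rep(seq_len(nc), times = nr)
  py <- rep(seq_len(nr), each = nc)
  int_off <- 16 + mz_enc + (k - 1) * nch * 4

  hdr <- sprintf(paste0(
'<?xml version="1.0" encoding="ISO-8859-1"?>\n',
'<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
' <cvList count="3">\n',
'  <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
'  <cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>\n',
'  <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
' </cvList>\n',
' <fileDescription>\n',
'  <fileContent>\n',
'   <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>\n',
'   <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>\n',
'   <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>\n',
'  </fileContent>\n',
' </fileDescription>\n',
' <referenceableParamGroupList count="2">\n',
'  <referenceableParamGroup id="mzArray">\n',
'   <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>\n',
'   <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>\n',
'   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
'   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
'  </referenceableParamGroup>\n',
'  <referenceableParamGroup id="intensityArray">\n',
'   <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>\n',
'   <cvParam cvRef="MS" accession="MS:1000521" name="32-bit float" value=""/>\n',
'   <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>\n',
'   <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
'  </referenceableParamGroup>\n',
' </referenceableParamGroupList>\n',
' <softwareList count="1">\n',
'  <software id="glycosims" version="0.1"/>\n',
' </softwareList>\n',
' <scanSettingsList count="1">\n',
'  <scanSettings id="scan1">\n',
'   <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>\n',
'   <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>\n',
'   <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%.6g"/>\n',
'   <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size (y)" value="%.6g"/>\n',
'  </scanSettings>\n',
' </scanSettingsList>\n',
' <instrumentConfigurationList count="1">\n',
'  <instrumentConfiguration id="IC1"/>\n',
' </instrumentConfigurationList>\n',
' <dataProcessingList count="1">\n',
'  <dataProcessing id="DP1">\n',
'   <processingMethod order="1" softwareRef="glycosims">\n',
'    <cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/>\n',
'   </processingMethod>\n',
'  </dataProcessing>\n',
' </dataProcessingList>\n',
' <run defaultInstrumentConfigurationRef="IC1" id="run1">\n',
'  <spectrumList count="%d" defaultDataProcessingRef="DP1">\n'),
    uuid_str, nc, nr, cube$pixel_um, cube$pixel_um, nr * nc)

  specs <- sprintf(paste0(
'   <spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">\n',
'    <scanList count="1">\n',
'     <scan>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>\n',
'     </scan>\n',
'    </scanList>\n',
'    <binaryDataArrayList count="2">\n',
'     <binaryDataArray encodedLength="0">\n',
'      <referenceableParamGroupRef ref="mzArray"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="16"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
'      <binary/>\n',
'     </binaryDataArray>\n',
'     <binaryDataArray encodedLength="0">\n',
'      <referenceableParamGroupRef ref="intensityArray"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>\n',
'      <cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>\n',
'      <binary/>\n',
'     </binaryDataArray>\n',
'    </binaryDataArrayList>\n',
'   </spectrum>\n'),
    k, nch, k - 1L, px, py, nch, mz_enc, int_off, nch, nch * 4L)

  out_con <- file(path, "wb")
  writeLines(c(hdr, specs, '  </spectrumList>\n </run>\n</mzML>\n'),
             out_con, sep = "")
  close(out_con)
  invisible(path)
}

.xml_cv_values <- function(doc, accession, where = "//") {
  nodes <- xml2::xml_find_all(doc, sprintf(
    "%s*[local-name()='cvParam'][@accession='%s']", where, accession))
  xml2::xml_attr(nodes, "value")
}

#' Read a continuous-mode imzML file into a SIMS cube
#'
#' Only continuous-mode files with a uniform, strictly increasing m/z axis
#' and pixel-size metadata are accepted; `write_imzml()` followed by
#' `read_imzml()` round-trips counts, channel axis and pixel size exactly.
#'
#' @param path Path to the `.imzML` file (the `.ibd` companion must sit
#'   alongside).
#' @return A [sims_cube()].
#' @export
read_imzml <- function(path) {
  doc <- xml2::read_xml(path)
  if (length(xml2::xml_find_all(doc,
      "//*[local-name()='fileContent']/*[local-name()='cvParam'][@accession='IMS:1000030']")) == 0)
    stop("continuous mode required")

  px_x <- .xml_cv_values(doc, "IMS:1000046")
  if (length(px_x) == 0) stop("missing pixel-size metadata")
  pixel_um <- as.numeric(px_x[1])
  nc <- as.integer(.xml_cv_values(doc, "IMS:1000042")[1])
  nr <- as.integer(.xml_cv_values(doc, "IMS:1000043")[1])

  pos_x <- as.integer(.xml_cv_values(doc, "IMS:1000050"))
  pos_y <- as.integer(.xml_cv_values(doc, "IMS:1000051"))
  nspec <- length(pos_x)
  if (nspec == 0) stop("no spectra in file")

  # binaryDataArray metadata, in document order (two arrays per spectrum)
  refs <- xml2::xml_attr(xml2::xml_find_all(doc,
    "//*[local-name()='referenceableParamGroupRef']"), "ref")
  offs <- as.numeric(.xml_cv_values(doc, "IMS:1000102"))
  lens <- as.integer(.xml_cv_values(doc, "IMS:1000103"))
  if (length(refs) != 2L * nspec || length(offs) != 2L * nspec)
    stop("malformed imzML: expected two binary data arrays per spectrum")
  is_mz <- refs == "mzArray"
  mz_off <- offs[is_mz]; mz_len <- lens[is_mz]
  int_off <- offs[!is_mz]; int_len <- lens[!is_mz]
  if (length(unique(mz_off)) != 1L || length(unique(mz_len)) != 1L)
    stop("continuous mode required")
  nch <- mz_len[1]
  if (length(unique(int_len)) != 1L || int_len[1] != nch)
    stop("continuous mode required")

  # encoding precision from the referenceable param groups
  mz_size <- if (length(xml2::xml_find_all(doc,
    "//*[local-name()='referenceableParamGroup'][@id='mzArray']/*[local-name()='cvParam'][@accession='MS:1000523']")))
    8L else 4L
  int_size <- if (length(xml2::xml_find_all(doc,
    "//*[local-name()='referenceableParamGroup'][@id='intensityArray']/*[local-name()='cvParam'][@accession='MS:1000523']")))
    8L else 4L

  con <- file(.ibd_path(path), "rb")
  on.exit(close(con), add = TRUE)
  seek(con, mz_off[1])
  channel_mz <- readBin(con, numeric(), n = nch, size = mz_size,
                        endian = "little")
  if (is.unsorted(channel_mz, strictly = TRUE))
    stop("channel_mz must be strictly increasing")
  counts <- array(0, dim = c(nr, nc, nch))
  ord <- order(int_off)
  for (s in ord) {
    seek(con, int_off[s])
    counts[pos_y[s], pos_x[s], ] <- readBin(con, numeric(), n = nch,
                                            size = int_size,
                                            endian = "little")
  }
  sims_cube(counts, channel_mz, pixel_um)
}
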
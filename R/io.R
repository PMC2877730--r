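# Spectrum file formats: tab-separated two-column text (with '#' metadata
# comments) and minimal mzML (uncompressed 64-bit little-endian binary
# arrays, base64). mzML is the interchange format; tsv the plain-text
# dialect.

.guess_format <- function(path) {
  if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
}

#' Read a mass spectrum
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"mzml"`.
#' @return A [mass_spectrum()]. The profile/centroid flag and any
#'   sample id / seed metadata are restored when present.
#' @export
read_spectrum <- function(path, format = c("auto", "tsv", "mzml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") format <- .guess_format(path)
  out <- if (format == "tsv") .read_spectrum_tsv(path) else
    .read_spectrum_mzml(path)
  tryCatch(validate_spectrum(out),
           error = function(e) stop("invalid spectrum in ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  out
}

.read_spectrum_tsv <- function(path) {
  lines <- readLines(path)
  meta <- list()
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "\t", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[kv[1]]] <- kv[2]
  }
  body <- grep("^#", lines, invert = TRUE)
  body <- body[nzchar(trimws(lines[body]))]
  if (length(body) == 0L)
    return(mass_spectrum(numeric(0), numeric(0), meta))
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2L)
  if (length(bad) > 0L)
    stop("parse error at line ", body[bad[1]], " of ", path,
         ": expected two tab-separated columns", call. = FALSE)
  mz <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  intensity <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  nonnum <- which(is.na(mz) | is.na(intensity))
  if (length(nonnum) > 0L)
    stop("parse error at line ", body[nonnum[1]], " of ", path,
         ": non-numeric value", call. = FALSE)
  if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)
  mass_spectrum(mz, intensity, meta)
}

#' Write a mass spectrum
#'
#' @param spectrum A [mass_spectrum()].
#' @param path Output path.
#' @param format `"auto"`, `"tsv"`, or `"mzml"`.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, format = c("auto", "tsv", "mzml")) {
  format <- match.arg(format)
  validate_spectrum(spectrum)
  if (format == "auto") format <- .guess_format(path)
  if (format == "tsv") .write_spectrum_tsv(spectrum, path) else
    .write_spectrum_mzml(spectrum, path)
  invisible(path)
}

.write_spectrum_tsv <- function(spectrum, path) {
  meta <- spectrum$metadata
  hdr <- character(0)
  for (key in c("sample_id", "seed", "mode")) {
    if (!is.null(meta[[key]]))
      hdr <- c(hdr, sprintf("# %s\t%s", key, meta[[key]]))
  }
  rows <- sprintf("%.17g\t%.17g", spectrum$mz, spectrum$intensity)
  writeLines(c(hdr, rows), path)
}

.b64_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

.write_spectrum_mzml <- function(spectrum, path) {
  meta <- spectrum$metadata
  mode_acc <- if (identical(meta$mode, "centroid"))
    c("MS:1000127", "centroid spectrum") else
    c("MS:1000128", "profile spectrum")
  user <- character(0)
  for (key in c("sample_id", "seed")) {
    if (!is.null(meta[[key]]))
      user <- c(user, sprintf('      <userParam name="%s" value="%s"/>',
                              key, meta[[key]]))
  }
  arr <- function(x, acc, nm) {
    b64 <- .b64_doubles(x)
    paste0(
      '        <binaryDataArray encodedLength="', nchar(b64), '">\n',
      '          <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
      '          <cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>\n',
      '          <cvParam cvRef="MS" accession="', acc, '" name="', nm, '"/>\n',
      '          <binary>', b64, '</binary>\n',
      '        </binaryDataArray>')
  }
  xml <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '  <run id="run0">\n',
    '  <spectrumList count="1">\n',
    '    <spectrum index="0" id="scan=1" defaultArrayLength="',
    length(spectrum$mz), '">\n',
    '      <cvParam cvRef="MS" accession="', mode_acc[1], '" name="',
    mode_acc[2], '"/>\n',
    paste(user, collapse = "\n"), if (length(user)) "\n" else "",
    '      <binaryDataArrayList count="2">\n',
    arr(spectrum$mz, "MS:1000514", "m/z array"), "\n",
    arr(spectrum$intensity, "MS:1000515", "intensity array"), "\n",
    '      </binaryDataArrayList>\n',
    '    </spectrum>\n',
    '  </spectrumList>\n',
    '  </run>\n',
    '</mzML>\n')
  writeLines(xml, path, sep = "")
}

.read_spectrum_mzml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  spec <- xml2::xml_find_first(doc, ".//spectrum")
  if (inherits(spec, "xml_missing"))
    stop("parse error in ", path, ": no <spectrum> element", call. = FALSE)
  meta <- list()
  mode_node <- xml2::xml_find_first(
    spec, './cvParam[@accession="MS:1000127" or @accession="MS:1000128"]')
  if (!inherits(mode_node, "xml_missing"))
    meta$mode <- if (xml2::xml_attr(mode_node, "accession") == "MS:1000127")
      "centroid" else "profile"
  for (u in xml2::xml_find_all(spec, "./userParam")) {
    meta[[xml2::xml_attr(u, "name")]] <- xml2::xml_attr(u, "value")
  }
  if (!is.null(meta$seed)) meta$seed <- as.integer(meta$seed)

  decode <- function(node) {
    b64 <- xml2::xml_text(xml2::xml_find_first(node, "./binary"))
    raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
    if (!inherits(xml2::xml_find_first(
          node, './cvParam[@accession="MS:1000574"]'), "xml_missing"))
      raw <- memDecompress(raw, type = "gzip")
    size <- if (!inherits(xml2::xml_find_first(
      node, './cvParam[@accession="MS:1000521"]'), "xml_missing")) 4L else 8L
    readBin(raw, "double", n = length(raw) %/% size, size = size,
            endian = "little")
  }
  arrays <- xml2::xml_find_all(spec, ".//binaryDataArray")
  mz <- intensity <- NULL
  for (node in arrays) {
    if (!inherits(xml2::xml_find_first(
          node, './cvParam[@accession="MS:1000514"]'), "xml_missing"))
      mz <- decode(node)
    if (!inherits(xml2::xml_find_first(
          node, './cvParam[@accession="MS:1000515"]'), "xml_missing"))
      intensity <- decode(node)
  }
  if (is.null(mz) || is.null(intensity))
    stop("parse error in ", path, ": missing m/z or intensity array",
         call. = FALSE)
  mass_spectrum(mz, intensity, meta)
}

#' Read a precursor sequence from FASTA
#'
#' @param path FASTA file with one or more amino-acid records.
#' @param which Record index or name (default first).
#' @return Character scalar sequence.
#' @export
read_precursor_fasta <- function(path, which = 1L) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readAAStringSet(path)
    return(as.character(seqs[[which]]))
  }
  lines <- readLines(path)
  idx <- grep("^>", lines)
  if (length(idx) == 0L) stop("not a FASTA file: ", path, call. = FALSE)
  starts <- idx + 1L
  ends <- c(idx[-1L] - 1L, length(lines))
  i <- if (is.character(which))
    match(which, sub("^>\\s*(\\S+).*", "\\1", lines[idx])) else which
  if (is.na(i) || i < 1L || i > length(idx))
    stop("record not found in ", path, call. = FALSE)
  paste(gsub("\\s", "", lines[starts[i]:ends[i]]), collapse = "")
}
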
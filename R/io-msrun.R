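# MS run container and file I/O: mzML, mzXML and an internal JSON run format
# (all three readable and writable). The XML readers are deliberately minimal
# -- centroid/profile peak lists with MS level, RT and precursor metadata --
# which is exactly what the downstream chain consumes.

#' Construct an MS run
#'
#' @param scans List of scans; each scan is a list with `ms_level` (1 or 2),
#'   `rt` (minutes), equal-length ascending `mz` and non-negative
#'   `intensity`, and for MS2 `precursor_mz` (plus optional
#'   `precursor_charge`, `precursor_intensity`).
#' @param centroided Are scans centroided? (default TRUE).
#' @param metadata Free-form list.
#' @return Object of class `ms_run`.
#' @export
ms_run <- function(scans, centroided = TRUE, metadata = list()) {
  for (s in scans) {
    stopifnot(s$ms_level %in% c(1, 2), length(s$mz) == length(s$intensity))
    if (length(s$mz) > 1L && is.unsorted(s$mz))
      stop("scan m/z arrays must be ascending")
    if (any(s$intensity < 0)) stop("negative intensity in scan")
  }
  rts <- vapply(scans, function(s) s$rt, numeric(1))
  scans <- scans[order(rts)]
  structure(list(scans = scans, centroided = centroided, metadata = metadata),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  lv <- vapply(x$scans, function(s) s$ms_level, numeric(1))
  cat("<ms run> ", sum(lv == 1), " MS1 + ", sum(lv == 2), " MS2 scans",
      if (isTRUE(x$centroided)) " (centroided)" else "", "\n", sep = "")
  invisible(x)
}

#' Read an MS run from mzML, mzXML or run-JSON
#'
#' Format is chosen by file extension (`.mzML`, `.mzXML`, `.json`). Scans
#' are returned RT-ordered with MS level and precursor metadata preserved;
#' malformed files raise an error rather than returning a partial run.
#'
#' @param path Input file.
#' @return An `ms_run`.
#' @export
read_msrun <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mzml = read_mzml(path),
         mzxml = read_mzxml(path),
         json = read_msrun_json(path),
         stop("unsupported MS run format: .", ext,
              " (expected mzML, mzXML or json)"))
}

#' Write an MS run to mzML, mzXML or run-JSON (by extension)
#'
#' @param run An `ms_run`.
#' @param path Output file; extension selects the format.
#' @export
write_msrun <- function(run, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         mzml = write_mzml(run, path),
         mzxml = write_mzxml(run, path),
         json = write_msrun_json(run, path),
         stop("unsupported MS run format: .", ext))
  invisible(path)
}

## ---- internal JSON run format ------------------------------------------

read_msrun_json <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE),
                error = function(e) stop("malformed run JSON ", path, ": ",
                                         conditionMessage(e)))
  scans <- lapply(x$scans, function(s) {
    list(ms_level = as.numeric(s$ms_level), rt = as.numeric(s$rt),
         mz = as.numeric(s$mz), intensity = as.numeric(s$intensity),
         precursor_mz = if (is.null(s$precursor_mz)) NULL else as.numeric(s$precursor_mz),
         precursor_charge = if (is.null(s$precursor_charge)) NULL else as.integer(s$precursor_charge),
         precursor_intensity = if (is.null(s$precursor_intensity)) NULL else as.numeric(s$precursor_intensity))
  })
  ms_run(scans, centroided = isTRUE(x$centroided),
         metadata = if (is.null(x$metadata)) list() else x$metadata)
}

write_msrun_json <- function(run, path) {
  jsonlite::write_json(
    list(centroided = isTRUE(run$centroided), metadata = run$metadata,
         scans = lapply(run$scans, function(s)
           Filter(Negate(is.null),
                  s[intersect(names(s), c("ms_level", "rt", "mz", "intensity",
                                          "precursor_mz", "precursor_charge",
                                          "precursor_intensity"))]))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

## ---- binary array helpers ----------------------------------------------

encode_doubles <- function(x, compress = TRUE, endian = "little") {
  raw <- writeBin(as.double(x), raw(), size = 8, endian = endian)
  if (compress) raw <- memCompress(raw, type = "gzip")
  jsonlite::base64_enc(raw)
}

decode_doubles <- function(b64, compressed, size = 8, endian = "little") {
  raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
  if (compressed) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, "double", n = length(raw) %/% size, size = size, endian = endian)
}

## ---- mzML ---------------------------------------------------------------

read_mzml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed mzML ", path, ": ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  if (length(specs) == 0L) stop("mzML has no spectra: ", path)
  centroided <- TRUE
  scans <- lapply(specs, function(sp) {
    acc <- function(node, a)
      xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", a))
    val <- function(node, a) {
      n <- acc(node, a)
      if (inherits(n, "xml_missing")) NA_character_ else xml2::xml_attr(n, "value")
    }
    lvl <- as.numeric(val(sp, "MS:1000511"))
    rt_node <- acc(sp, "MS:1000016")
    if (inherits(rt_node, "xml_missing")) stop("spectrum without scan start time")
    rt <- as.numeric(xml2::xml_attr(rt_node, "value"))
    unit <- xml2::xml_attr(rt_node, "unitName")
    if (!is.na(unit) && grepl("second", unit)) rt <- rt / 60
    if (!inherits(acc(sp, "MS:1000128"), "xml_missing")) centroided <<- FALSE
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    mz <- intensity <- numeric(0)
    for (arr in arrays) {
      b64 <- xml2::xml_text(xml2::xml_find_first(arr, ".//binary"))
      comp <- !inherits(acc(arr, "MS:1000574"), "xml_missing")
      size <- if (!inherits(acc(arr, "MS:1000521"), "xml_missing")) 4L else 8L
      v <- if (size == 4L) {
        raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
        if (comp) raw <- memDecompress(raw, type = "gzip")
        readBin(raw, "double", n = length(raw) %/% 4L, size = 4L, endian = "little")
      } else decode_doubles(b64, comp)
      if (!inherits(acc(arr, "MS:1000514"), "xml_missing")) mz <- v
      else if (!inherits(acc(arr, "MS:1000515"), "xml_missing")) intensity <- v
    }
    out <- list(ms_level = lvl, rt = rt, mz = mz, intensity = intensity)
    ion <- xml2::xml_find_first(sp, ".//precursorList//selectedIon")
    if (!inherits(ion, "xml_missing")) {
      out$precursor_mz <- as.numeric(val(ion, "MS:1000744"))
      ch <- val(ion, "MS:1000041")
      if (!is.na(ch)) out$precursor_charge <- as.integer(ch)
      pi <- val(ion, "MS:1000042")
      if (!is.na(pi)) out$precursor_intensity <- as.numeric(pi)
    }
    out
  })
  ms_run(scans, centroided = centroided, metadata = list(source = path))
}

write_mzml <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) sprintf("%.10g", x)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">')
  w('  <run id="run">')
  w('    <spectrumList count="', length(run$scans), '">')
  for (i in seq_along(run$scans)) {
    s <- run$scans[[i]]
    w('      <spectrum index="', i - 1L, '" id="scan=', i,
      '" defaultArrayLength="', length(s$mz), '">')
    w('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="',
      s$ms_level, '"/>')
    w('        <cvParam cvRef="MS" accession="',
      if (isTRUE(run$centroided)) 'MS:1000127" name="centroid spectrum"'
      else 'MS:1000128" name="profile spectrum"', '/>')
    w('        <scanList count="1"><scan>')
    w('          <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="',
      num(s$rt), '" unitName="minute"/>')
    w('        </scan></scanList>')
    if (s$ms_level == 2 && !is.null(s$precursor_mz)) {
      w('        <precursorList count="1"><precursor>')
      w('          <selectedIonList count="1"><selectedIon>')
      w('            <cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="',
        num(s$precursor_mz), '"/>')
      if (!is.null(s$precursor_charge))
        w('            <cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="',
          s$precursor_charge, '"/>')
      if (!is.null(s$precursor_intensity))
        w('            <cvParam cvRef="MS" accession="MS:1000042" name="peak intensity" value="',
          num(s$precursor_intensity), '"/>')
      w('          </selectedIon></selectedIonList>')
      w('        </precursor></precursorList>')
    }
    w('        <binaryDataArrayList count="2">')
    for (arr in list(c("MS:1000514", "m/z array"),
                     c("MS:1000515", "intensity array"))) {
      v <- if (arr[1] == "MS:1000514") s$mz else s$intensity
      b64 <- encode_doubles(v)
      w('          <binaryDataArray encodedLength="', nchar(b64), '">')
      w('            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>')
      w('            <cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>')
      w('            <cvParam cvRef="MS" accession="', arr[1], '" name="', arr[2], '"/>')
      w('            <binary>', b64, '</binary>')
      w('          </binaryDataArray>')
    }
    w('        </binaryDataArrayList>')
    w('      </spectrum>')
  }
  w('    </spectrumList>')
  w('  </run>')
  w('</mzML>')
  invisible(path)
}

## ---- mzXML --------------------------------------------------------------

read_mzxml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed mzXML ", path, ": ",
                                           conditionMessage(e)))
  xml2::xml_ns_strip(doc)
  sc <- xml2::xml_find_all(doc, ".//scan")
  if (length(sc) == 0L) stop("mzXML has no scans: ", path)
  scans <- lapply(sc, function(node) {
    lvl <- as.numeric(xml2::xml_attr(node, "msLevel"))
    rt_raw <- xml2::xml_attr(node, "retentionTime")  # ISO 8601 duration, PT#S
    rt <- as.numeric(gsub("^PT|S$", "", rt_raw)) / 60
    pk <- xml2::xml_find_first(node, "./peaks")
    if (inherits(pk, "xml_missing")) stop("scan without peaks element")
    comp <- identical(xml2::xml_attr(pk, "compressionType"), "zlib")
    size <- if (identical(xml2::xml_attr(pk, "precision"), "32")) 4L else 8L
    raw <- jsonlite::base64_dec(gsub("\\s", "", xml2::xml_text(pk)))
    if (comp) raw <- memDecompress(raw, type = "gzip")
    v <- readBin(raw, "double", n = length(raw) %/% size, size = size,
                 endian = "big")  # network byte order
    idx <- seq_along(v)
    out <- list(ms_level = lvl, rt = rt,
                mz = v[idx %% 2 == 1], intensity = v[idx %% 2 == 0])
    prec <- xml2::xml_find_first(node, "./precursorMz")
    if (!inherits(prec, "xml_missing")) {
      out$precursor_mz <- as.numeric(xml2::xml_text(prec))
      ch <- xml2::xml_attr(prec, "precursorCharge")
      if (!is.na(ch)) out$precursor_charge <- as.integer(ch)
      pi <- xml2::xml_attr(prec, "precursorIntensity")
      if (!is.na(pi)) out$precursor_intensity <- as.numeric(pi)
    }
    out
  })
  ms_run(scans, centroided = TRUE, metadata = list(source = path))
}

write_mzxml <- function(run, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) sprintf("%.10g", x)
  w('<?xml version="1.0" encoding="utf-8"?>')
  w('<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">')
  w('  <msRun scanCount="', length(run$scans), '">')
  for (i in seq_along(run$scans)) {
    s <- run$scans[[i]]
    w('    <scan num="', i, '" msLevel="', s$ms_level,
      '" retentionTime="PT', num(s$rt * 60), 'S" peaksCount="', length(s$mz), '">')
    if (s$ms_level == 2 && !is.null(s$precursor_mz)) {
      w('      <precursorMz',
        if (!is.null(s$precursor_intensity))
          paste0(' precursorIntensity="', num(s$precursor_intensity), '"') else "",
        if (!is.null(s$precursor_charge))
          paste0(' precursorCharge="', s$precursor_charge, '"') else "",
        '>', num(s$precursor_mz), '</precursorMz>')
    }
    inter <- as.vector(rbind(s$mz, s$intensity))
    b64 <- jsonlite::base64_enc(writeBin(as.double(inter), raw(), size = 8,
                                         endian = "big"))
    w('      <peaks precision="64" byteOrder="network" contentType="m/z-int" ',
      'compressionType="none">', b64, '</peaks>')
    w('    </scan>')
  }
  w('  </msRun>')
  w('</mzXML>')
  invisible(path)
}
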
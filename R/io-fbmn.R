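# FBMN-style export bundle: feature quantification table (CSV) plus MS2
# spectral summary (MGF, GNPS dialect), and their readers.

#' Write fragment spectra as MGF (GNPS-FBMN dialect)
#'
#' Each block carries `FEATURE_ID`, `PEPMASS`, `SCANS` (= feature id),
#' `RTINSECONDS` and `CHARGE`, followed by `mz intensity` pairs at full
#' precision.
#'
#' @param spectra List of `fragment_spectrum` objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      paste0("FEATURE_ID=", s$feature_id),
      paste0("PEPMASS=", sprintf("%.10g", s$precursor_mz)),
      paste0("SCANS=", s$feature_id),
      paste0("RTINSECONDS=", sprintf("%.10g",
                                     if (is.na(s$rt)) 0 else s$rt * 60)),
      paste0("CHARGE=", s$charge, "+"),
      sprintf("%.10g %.10g", s$peaks[, 1], s$peaks[, 2]),
      "END IONS", ""), con)
  }
  invisible(path)
}

#' Read an MGF file into fragment spectra
#'
#' @param path MGF file.
#' @return List of `fragment_spectrum` objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "BEGIN IONS") {
      hdr <- list(); mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (i <= length(lines) && trimws(lines[i]) != "END IONS") {
        ln <- trimws(lines[i])
        if (grepl("=", ln, fixed = TRUE)) {
          kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
          hdr[[kv[1]]] <- paste(kv[-1], collapse = "=")
        } else if (nzchar(ln)) {
          p <- as.numeric(strsplit(ln, "[ \t]+")[[1]])
          mz <- c(mz, p[1]); int <- c(int, p[2])
        }
        i <- i + 1L
      }
      if (i > length(lines)) stop("truncated MGF: missing END IONS in ", path)
      charge <- if (!is.null(hdr$CHARGE)) as.integer(gsub("[^0-9]", "", hdr$CHARGE)) else 1L
      out[[length(out) + 1L]] <- fragment_spectrum(
        precursor_mz = as.numeric(hdr$PEPMASS),
        charge = charge, mz = mz, intensity = int,
        feature_id = if (!is.null(hdr$FEATURE_ID)) as.integer(hdr$FEATURE_ID)
                     else NA_integer_,
        rt = if (!is.null(hdr$RTINSECONDS)) as.numeric(hdr$RTINSECONDS) / 60
             else NA_real_)
    } else i <- i + 1L
  }
  out
}

#' Write the FBMN export bundle (quantification table + MGF)
#'
#' The quantification table holds one row per feature (`row ID`, `row m/z`
#' with 4 decimals, `row retention time` in minutes with 4 decimals, and a
#' per-sample `Peak area` column); the MGF holds each feature's paired MS2
#' spectrum with matching `FEATURE_ID`. Row ids and MGF blocks correspond
#' one-to-one.
#'
#' @param features Feature table filtered to MS2-bearing rows (list-column
#'   `ms2`).
#' @param outdir Output directory (created if needed).
#' @param sample Sample name used in the area column (default "sample1").
#' @return Invisibly, the paths of the CSV and MGF files.
#' @export
write_fbmn_bundle <- function(features, outdir, sample = "sample1") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (anyDuplicated(features$id)) stop("feature id collision in export table")
  has <- vapply(features$ms2, Negate(is.null), logical(1))
  if (any(!has)) stop("export table must be filtered to MS2-bearing rows")
  csv <- file.path(outdir, "quantification.csv")
  mgf <- file.path(outdir, "spectra.mgf")
  df <- data.frame(features$id, sprintf("%.4f", features$mz),
                   sprintf("%.4f", features$rt), sprintf("%.10g", features$area),
                   check.names = FALSE)
  names(df) <- c("row ID", "row m/z", "row retention time",
                 paste(sample, "Peak area"))
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  specs <- features$ms2
  for (k in seq_along(specs)) specs[[k]]$feature_id <- features$id[k]
  for (k in seq_along(specs)) if (is.na(specs[[k]]$rt)) specs[[k]]$rt <- features$rt[k]
  write_mgf(specs, mgf)
  invisible(c(csv = csv, mgf = mgf))
}

#' Read a feature quantification table CSV
#'
#' @param path CSV written by [write_fbmn_bundle()].
#' @return Data frame with `id`, `mz`, `rt`, `area` (plus `height = area`
#'   placeholder columns are not reconstructed).
#' @export
read_quant_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  out <- data.frame(id = as.integer(df[["row ID"]]),
                    mz = as.numeric(df[["row m/z"]]),
                    rt = as.numeric(df[["row retention time"]]))
  area_col <- grep("Peak area$", names(df), value = TRUE)[1]
  out$area <- as.numeric(df[[area_col]])
  out
}
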
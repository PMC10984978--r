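# 384-well plate handling: serpentine nanofraction collection order, fraction
# timing, median normalization of fluorescence readouts, bioactivity
# chromatogram construction and negative-peak calling.

#' Plate layout for serpentine nanofraction collection
#'
#' Describes how eluate fractions map onto a 384-well plate: wells are filled
#' every `fraction_seconds` seconds in a serpentine path over the usable
#' columns (row A left-to-right, row B right-to-left, and so on), with the
#' last column reserved for assay controls and therefore never part of the
#' sample traversal.
#'
#' @param rows,columns Plate dimensions (default 16 x 24).
#' @param control_column Column holding assay controls, excluded from the
#'   traversal (default 24, i.e. usable columns 1-23).
#' @param wells_per_sample Number of fractions collected per sample
#'   (default 350; at most `rows * (columns - 1)` = 368 on a 384-well plate).
#' @param fraction_seconds Collection time per well in seconds (default 6).
#' @param collection_start Time on the LC axis (minutes) at which the first
#'   fraction starts collecting (default 0).
#' @param traversal Traversal descriptor; only `"serpentine"` is supported.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(rows = 16L, columns = 24L, control_column = 24L,
                         wells_per_sample = 350L, fraction_seconds = 6,
                         collection_start = 0, traversal = "serpentine") {
  traversal <- match.arg(traversal, "serpentine")
  usable <- setdiff(seq_len(columns), control_column)
  if (fraction_seconds <= 0) stop("fraction_seconds must be positive")
  if (wells_per_sample > rows * length(usable))
    stop("wells_per_sample (", wells_per_sample, ") exceeds usable wells (",
         rows * length(usable), ")")
  structure(list(rows = as.integer(rows), columns = as.integer(columns),
                 usable_columns = usable, control_column = as.integer(control_column),
                 wells_per_sample = as.integer(wells_per_sample),
                 fraction_seconds = fraction_seconds,
                 collection_start = collection_start, traversal = traversal),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat("<plate layout> ", x$rows, "x", x$columns, ", ", x$wells_per_sample,
      " wells/sample @ ", x$fraction_seconds, " s, controls in column ",
      x$control_column, "\n", sep = "")
  invisible(x)
}

#' Serpentine traversal order of the usable wells
#'
#' @param layout A [plate_layout()].
#' @return Data frame with one row per collected fraction (truncated to
#'   `wells_per_sample`): `row` (1-based), `col`, and `well` label such as
#'   `"A1"`.
#' @examples
#' head(serpentine_order(plate_layout()))
#' @export
serpentine_order <- function(layout = plate_layout()) {
  stopifnot(inherits(layout, "plate_layout"))
  usable <- layout$usable_columns
  rows <- layout$rows
  cols <- lapply(seq_len(rows), function(r) if (r %% 2L == 1L) usable else rev(usable))
  ord <- data.frame(
    row = rep(seq_len(rows), each = length(usable)),
    col = unlist(cols)
  )
  ord <- ord[seq_len(layout$wells_per_sample), , drop = FALSE]
  ord$well <- paste0(LETTERS[ord$row], ord$col)
  rownames(ord) <- NULL
  ord
}

#' Collection time of a fraction
#'
#' Fraction `index` (0-based) collects over the half-open window
#' `[collection_start + index * dt, collection_start + (index + 1) * dt)`
#' where `dt = fraction_seconds / 60`; the returned time is the window start.
#'
#' @param index 0-based fraction ordinal, scalar or vector.
#' @param layout A [plate_layout()].
#' @return Collection time(s) in minutes.
#' @export
fraction_time <- function(index, layout = plate_layout()) {
  if (any(index < 0L | index >= layout$wells_per_sample))
    stop("fraction index out of range [0, ", layout$wells_per_sample - 1L, "]")
  layout$collection_start + index * layout$fraction_seconds / 60
}

#' Median-normalize a plate read
#'
#' Divides every fluorescence value by the median over the measured values of
#' the single plate read, the standard normalization for resazurin-reduction
#' readouts. Control wells (the control column) are excluded from both the
#' median and implicitly from downstream traces; set
#' `include_controls = TRUE` to include them in the median.
#'
#' @param read Numeric matrix `rows x columns` (NA for missing wells).
#' @param layout A [plate_layout()].
#' @param include_controls Include the control column in the median?
#' @return Matrix of the same shape, normalized (controls normalized by the
#'   same median).
#' @export
normalize_plate <- function(read, layout = plate_layout(), include_controls = FALSE) {
  stopifnot(is.matrix(read))
  if (nrow(read) != layout$rows || ncol(read) != layout$columns)
    stop("plate read is ", nrow(read), "x", ncol(read), ", layout expects ",
         layout$rows, "x", layout$columns)
  if (any(read < 0, na.rm = TRUE)) stop("fluorescence values must be >= 0")
  med_cols <- if (include_controls) seq_len(layout$columns) else layout$usable_columns
  vals <- read[, med_cols, drop = FALSE]
  if (all(is.na(vals))) stop("plate has no measured wells to normalize against")
  med <- stats::median(vals, na.rm = TRUE)
  if (!is.finite(med) || med <= 0) stop("plate median is not positive")
  read / med
}

#' Build a bioactivity chromatogram from a normalized plate read
#'
#' Walks the serpentine collection order and emits the normalized response of
#' each fraction against its collection time, reconstructing the bioactivity
#' chromatogram in which inhibited (low-fluorescence) fractions appear as
#' negative peaks.
#'
#' @param read Normalized plate matrix (see [normalize_plate()]).
#' @param layout A [plate_layout()].
#' @return An object of class `bioactivity_trace`: data frame with columns
#'   `time_min` and `response`.
#' @export
build_trace <- function(read, layout = plate_layout()) {
  stopifnot(is.matrix(read))
  if (nrow(read) != layout$rows || ncol(read) != layout$columns)
    stop("plate read dimensions do not match layout")
  ord <- serpentine_order(layout)
  if (nrow(ord) == 0L) stop("layout has no usable wells")
  resp <- read[cbind(ord$row, ord$col)]
  tr <- data.frame(time_min = fraction_time(seq_len(nrow(ord)) - 1L, layout),
                   response = resp)
  class(tr) <- c("bioactivity_trace", "data.frame")
  tr
}

#' Call bioactive peaks (negative maxima) in a bioactivity trace
#'
#' Contiguous runs of at least `min_width` fractions whose normalized response
#' falls below `threshold` are reported as bioactive peaks; the apex is the
#' minimum response within the run. Fractions with missing response break
#' runs.
#'
#' @param trace A `bioactivity_trace`.
#' @param threshold Normalized-response cut-off (default 0.8); a fraction is
#'   "active" when response < threshold.
#' @param min_width Minimum run length in fractions (default 2).
#' @return Data frame with one row per peak: `peak_id`, `start_time`,
#'   `apex_time`, `end_time`, `depth` (1 - minimum response) and
#'   `n_fractions`, sorted by `start_time`.
#' @export
detect_bioactivity_peaks <- function(trace, threshold = 0.8, min_width = 2L) {
  stopifnot(inherits(trace, "bioactivity_trace") || is.data.frame(trace))
  if (!is.numeric(threshold) || threshold <= 0) stop("threshold must be positive")
  below <- !is.na(trace$response) & trace$response < threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  out <- data.frame(peak_id = integer(0), start_time = numeric(0),
                    apex_time = numeric(0), end_time = numeric(0),
                    depth = numeric(0), n_fractions = integer(0))
  k <- 0L
  for (i in which(keep)) {
    idx <- starts[i]:ends[i]
    k <- k + 1L
    apex <- idx[which.min(trace$response[idx])]
    out[k, ] <- list(k, trace$time_min[starts[i]], trace$time_min[apex],
                     trace$time_min[ends[i]], 1 - trace$response[apex],
                     length(idx))
  }
  out
}

#' Read / write a plate CSV
#'
#' The plate CSV has a header row of column indices 1..24, a leading column of
#' row letters A..P, and one fluorescence value per well; missing wells are
#' blank.
#'
#' @param path File path.
#' @param layout A [plate_layout()] giving the expected dimensions.
#' @return `read_plate_csv`: numeric matrix with row/column dimnames.
#' @export
read_plate_csv <- function(path, layout = plate_layout()) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  mode(m) <- "numeric"
  if (nrow(m) != layout$rows || ncol(m) != layout$columns)
    stop("plate CSV is ", nrow(m), "x", ncol(m), ", expected ",
         layout$rows, "x", layout$columns)
  dimnames(m) <- list(LETTERS[seq_len(layout$rows)], seq_len(layout$columns))
  m
}

#' @rdname read_plate_csv
#' @param read Plate matrix to write.
#' @export
write_plate_csv <- function(read, path) {
  df <- as.data.frame(read)
  colnames(df) <- seq_len(ncol(read))
  rownames(df) <- LETTERS[seq_len(nrow(read))]
  utils::write.csv(format(df, digits = 10, trim = TRUE), path, quote = FALSE)
  invisible(path)
}

#' Read / write a bioactivity trace CSV (columns `time_min,response`)
#'
#' @param trace A `bioactivity_trace`.
#' @param path File path.
#' @export
write_trace_csv <- function(trace, path) {
  out <- data.frame(time_min = sprintf("%.4f", trace$time_min),
                    response = sprintf("%.6f", trace$response))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path)
  stopifnot(all(c("time_min", "response") %in% names(tr)))
  class(tr) <- c("bioactivity_trace", "data.frame")
  tr
}
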
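# Delay estimation between the MS chromatogram and the bioactivity trace
# (tubing + assay path downstream of the post-column flow split), and
# placement of both traces on a common time axis.

#' Estimate the bioassay delay from a single-calibrant injection
#'
#' A calibrant (e.g. nalidixic acid) is injected and both its MS peak and its
#' bioactivity dip located; the delay is the difference of apex times
#' (bioactivity minus MS). Apexes are located by a weighted centroid over the
#' contiguous region around the global extremum (`method = "centroid"`,
#' default), which is robust to the 6-s fraction quantization; the raw grid
#' extremum is available with `method = "extremum"`.
#'
#' @param ms_trace Data frame with `time_min` and `intensity` (an EIC or BPC
#'   of the calibrant run).
#' @param bio_trace A `bioactivity_trace` of the calibrant plate.
#' @param calibrant Label stored in the model (default "nalidixic acid").
#' @param method Apex location method, `"centroid"` or `"extremum"`.
#' @param bio_times Are the bioactivity trace times fraction-window starts
#'   (`"window_start"`, default, as [build_trace()] produces: each response
#'   integrates the following window, so times are shifted by half a window
#'   before locating the dip) or instantaneous samples (`"center"`)?
#' @param max_delay Sanity bound on |delay| in minutes (default 5).
#' @param ms_snr Minimum ratio of MS apex over trace median to accept a peak
#'   (default 3).
#' @param bio_floor Bioactivity minimum must fall below this normalized
#'   response to count as a peak (default 0.8).
#' @return An object of class `delay_model`: list with `delay_min`,
#'   `ms_apex_min`, `bio_apex_min`, `calibrant`.
#' @export
estimate_delay <- function(ms_trace, bio_trace, calibrant = "nalidixic acid",
                           method = c("centroid", "extremum"),
                           bio_times = c("window_start", "center"),
                           max_delay = 5, ms_snr = 3, bio_floor = 0.8) {
  method <- match.arg(method)
  bio_times <- match.arg(bio_times)
  stopifnot(all(c("time_min", "intensity") %in% names(ms_trace)))
  ms_base <- stats::median(ms_trace$intensity, na.rm = TRUE)
  if (max(ms_trace$intensity, na.rm = TRUE) < ms_snr * max(ms_base, .Machine$double.eps))
    stop("no MS peak above noise in the calibrant trace")
  if (min(bio_trace$response, na.rm = TRUE) >= bio_floor)
    stop("no bioactivity dip below ", bio_floor, " in the calibrant trace")

  ms_apex <- apex_time(ms_trace$time_min, ms_trace$intensity - ms_base,
                       method = method)
  bio_base <- stats::median(bio_trace$response, na.rm = TRUE)
  half_win <- if (bio_times == "window_start")
    stats::median(diff(bio_trace$time_min)) / 2 else 0
  if (!is.finite(half_win)) half_win <- 0
  bio_apex <- apex_time(bio_trace$time_min + half_win,
                        bio_base - bio_trace$response, method = method)
  delay <- bio_apex - ms_apex
  if (abs(delay) > max_delay)
    stop("estimated delay ", round(delay, 3), " min exceeds sanity limit of ",
         max_delay, " min")
  structure(list(delay_min = delay, ms_apex_min = ms_apex,
                 bio_apex_min = bio_apex, calibrant = calibrant),
            class = "delay_model")
}

# Apex of a positive excess signal: grid argmax, or the weight centroid of the
# contiguous region around the argmax where the excess stays above half its
# maximum (robust to coarse sampling).
apex_time <- function(time, excess, method = "centroid") {
  excess[is.na(excess)] <- 0
  i <- which.max(excess)
  if (method == "extremum") return(time[i])
  cut <- excess[i] / 2
  lo <- i; while (lo > 1L && excess[lo - 1L] > cut) lo <- lo - 1L
  hi <- i; while (hi < length(excess) && excess[hi + 1L] > cut) hi <- hi + 1L
  idx <- lo:hi
  sum(time[idx] * excess[idx]) / sum(excess[idx])
}

#' @export
print.delay_model <- function(x, ...) {
  cat("<delay model> ", x$calibrant, ": bio apex ",
      round(x$bio_apex_min, 3), " - MS apex ", round(x$ms_apex_min, 3),
      " = delay ", round(x$delay_min, 3), " min\n", sep = "")
  invisible(x)
}

#' Shift a bioactivity trace onto the MS time axis
#'
#' Subtracts the modelled delay from every collection time; responses are
#' unchanged. Applying the model with the negated delay restores the original
#' trace exactly.
#'
#' @param trace A `bioactivity_trace`.
#' @param model A `delay_model`, or a bare number of minutes.
#' @return Corrected `bioactivity_trace`.
#' @export
apply_delay <- function(trace, model) {
  delay <- if (inherits(model, "delay_model")) model$delay_min else as.numeric(model)
  trace$time_min <- trace$time_min - delay
  trace
}

#' Resample two traces onto a common time axis
#'
#' Both traces are linearly interpolated onto a shared uniform grid spanning
#' the intersection of their time ranges (center-anchored: no extrapolation
#' outside either trace's support).
#'
#' @param ms_trace Data frame `time_min`/`intensity`.
#' @param bio_trace Data frame `time_min`/`response` (typically
#'   delay-corrected).
#' @param n_points Grid size (default 512).
#' @return List with `time_min`, `ms` and `bio` numeric vectors of length
#'   `n_points`.
#' @export
common_axis <- function(ms_trace, bio_trace, n_points = 512L) {
  lo <- max(min(ms_trace$time_min), min(bio_trace$time_min))
  hi <- min(max(ms_trace$time_min), max(bio_trace$time_min))
  if (lo >= hi) stop("traces have no overlapping time range")
  grid <- seq(lo, hi, length.out = n_points)
  list(time_min = grid,
       ms = stats::approx(ms_trace$time_min, ms_trace$intensity, grid)$y,
       bio = stats::approx(bio_trace$time_min, bio_trace$response, grid)$y)
}

#' Write a delay report as JSON
#'
#' @param model A `delay_model`.
#' @param path Output path.
#' @export
write_delay_json <- function(model, path) {
  jsonlite::write_json(
    list(delay_min = model$delay_min, ms_apex_min = model$ms_apex_min,
         bio_apex_min = model$bio_apex_min, calibrant = model$calibrant),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
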
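# Small in-code fixtures shared across test files.

# MS1 scans carrying a single Gaussian peak (exact evaluations, no noise).
gaussian_scans <- function(mz = 500.25, rt = 5, sigma = 0.08, apex = 1e6,
                           from = 3, to = 7, dt = 1 / 30) {
  times <- seq(from, to, by = dt)
  lapply(times, function(t) {
    i <- apex * exp(-(t - rt)^2 / (2 * sigma^2))
    if (i > 0.01) list(ms_level = 1, rt = t, mz = mz, intensity = i)
    else list(ms_level = 1, rt = t, mz = numeric(0), intensity = numeric(0))
  })
}

# An EIC built directly from vectors (bypassing the builder).
make_eic <- function(rt, intensity, mz = 500.25) {
  list(mz = mz, rt = rt, intensity = intensity,
       mzs = rep(mz, length(rt)), scan = seq_along(rt))
}

# A plate whose usable wells hold `values` (recycled along the serpentine
# traversal) and whose control column holds `control`.
plate_with <- function(values, layout = plate_layout(), control = 100) {
  m <- matrix(NA_real_, layout$rows, layout$columns)
  ord <- serpentine_order(plate_layout(
    rows = layout$rows, columns = layout$columns,
    control_column = layout$control_column,
    wells_per_sample = layout$rows * length(layout$usable_columns),
    fraction_seconds = layout$fraction_seconds))
  m[cbind(ord$row, ord$col)] <- rep_len(values, nrow(ord))
  m[, layout$control_column] <- control
  m
}

# A simple fragment spectrum.
mk_spec <- function(id, precursor, mz, intensity = NULL, rt = NA_real_) {
  if (is.null(intensity)) intensity <- rep(100, length(mz))
  fragment_spectrum(precursor, 1L, mz = mz, intensity = intensity,
                    feature_id = id, rt = rt)
}
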
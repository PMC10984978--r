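# MZmine-inspired MS pre-processing chain: centroid mass detection,
# chromatogram (EIC) building, local-minimum deconvolution, MS2 pairing,
# isotope grouping, duplicate filtering and the MS2-only row filter.
#
# The named MZmine modules these mirror are closed behaviors; semantics here
# are fixed by the documented post-conditions, not bit-cloned.

#' Feature-detection parameters
#'
#' Defaults are the published pre-processing parameters of the platform:
#' centroid noise 1e4 (MS1) / 0 (MS2); chromatogram builder with minimum
#' group size 10 scans, m/z tolerance 0.001, group intensity threshold 1e4
#' and minimum height 5e4; local-minimum deconvolution (RT search range
#' 0.1 min, chromatographic threshold 90%, minimum relative height 1%,
#' minimum absolute height 1e4, top/edge ratio 2, duration 0.05-3 min); MS2
#' pairing windows 0.05 m/z and 1 min; isotope grouping 0.001 m/z and
#' 0.1 min.
#'
#' @param ... Named overrides of any default listed above.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(...) {
  p <- list(
    ms1_noise = 1.0e4, ms2_noise = 0,
    min_group_size = 10L, mz_tol = 0.001,
    group_intensity_threshold = 1.0e4, min_height = 5.0e4,
    rt_search_range = 0.1, chrom_threshold = 0.90,
    min_rel_height = 0.01, min_abs_height = 1.0e4,
    top_edge_ratio = 2, duration_range = c(0.05, 3),
    ms2_pair_mz = 0.05, ms2_pair_rt = 1,
    iso_mz_tol = 0.001, iso_rt_tol = 0.1,
    iso_charges = c(1L, 2L),
    dup_mz_tol = 0.001, dup_rt_tol = 0.05,
    dup_mz_tol2 = 1, dup_rt_tol2 = 0.05
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown detection parameter(s): ", paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  stopifnot(p$duration_range[1] < p$duration_range[2])
  structure(p, class = "detection_params")
}

# 13C - 12C mass difference used by the isotope grouper.
.c13_spacing <- 1.00335

#' Centroid mass detection on one scan
#'
#' Local maxima of the intensity array above the noise level. Profile data
#' are centroided: each local maximum's contiguous rising/falling support is
#' collapsed to one peak at the intensity-weighted mean m/z with the summed
#' intensity replaced by the apex intensity. Already-centroided data pass
#' through thresholding only.
#'
#' @param scan A scan (list with `mz`, `intensity`).
#' @param noise Intensity threshold; peaks at or below it are dropped.
#' @param centroided Is the scan already centroided? (default TRUE).
#' @return List with numeric `mz` and `intensity` of the detected peaks.
#' @export
detect_mass_peaks <- function(scan, noise = 1.0e4, centroided = TRUE) {
  mz <- scan$mz; int <- scan$intensity
  if (length(mz) == 0L) return(list(mz = numeric(0), intensity = numeric(0)))
  if (centroided) {
    keep <- int > noise
    return(list(mz = mz[keep], intensity = int[keep]))
  }
  n <- length(int)
  left <- c(-Inf, int[-n]); right <- c(int[-1], -Inf)
  apex <- which(int > noise & int >= left & int > right)
  cmz <- numeric(length(apex)); cint <- numeric(length(apex))
  for (k in seq_along(apex)) {
    i <- apex[k]
    lo <- i; while (lo > 1L && int[lo - 1L] < int[lo] && int[lo - 1L] > 0) lo <- lo - 1L
    hi <- i; while (hi < n && int[hi + 1L] < int[hi] && int[hi + 1L] > 0) hi <- hi + 1L
    idx <- lo:hi
    cmz[k] <- sum(mz[idx] * int[idx]) / sum(int[idx])
    cint[k] <- int[i]
  }
  list(mz = cmz, intensity = cint)
}

#' Build extracted-ion chromatograms from MS1 scans
#'
#' Greedy builder: scans are consumed in RT order; within a scan, centroids
#' are taken highest-intensity first and each joins the nearest open EIC whose
#' intensity-weighted representative m/z lies within `mz_tol` (one point per
#' scan per EIC), otherwise it seeds a new EIC. An EIC is retained only if it
#' contains at least `min_group_size` consecutive-scan points above
#' `group_intensity_threshold` and its maximum intensity reaches
#' `min_height`.
#'
#' @param scans List of MS1 scans, RT-ordered.
#' @param p [detection_params()].
#' @param centroided Are scans centroided? (default TRUE).
#' @return List of EICs: each a list with `mz` (representative), and vectors
#'   `rt`, `intensity`, `mzs`, `scan` (scan index).
#' @export
build_chromatograms <- function(scans, p = detection_params(), centroided = TRUE) {
  rts <- vapply(scans, function(s) s$rt, numeric(1))
  if (is.unsorted(rts)) stop("MS1 scans must be RT-ordered")
  eics <- list()          # growing lists of point vectors
  rep_mz <- numeric(0)    # running intensity-weighted representative m/z
  rep_w <- numeric(0)
  for (si in seq_along(scans)) {
    pk <- detect_mass_peaks(scans[[si]], p$ms1_noise, centroided)
    if (length(pk$mz) == 0L) next
    ord <- order(pk$intensity, decreasing = TRUE)
    taken <- rep(FALSE, length(eics))
    for (j in ord) {
      mzj <- pk$mz[j]; intj <- pk$intensity[j]
      tgt <- 0L
      if (length(rep_mz)) {
        d <- abs(rep_mz - mzj)
        d[taken] <- Inf
        b <- which.min(d)
        if (length(b) && d[b] <= p$mz_tol) tgt <- b
      }
      if (tgt == 0L) {
        eics[[length(eics) + 1L]] <- list(rt = rts[si], intensity = intj,
                                          mzs = mzj, scan = si)
        rep_mz <- c(rep_mz, mzj); rep_w <- c(rep_w, intj)
        taken <- c(taken, TRUE)
      } else {
        e <- eics[[tgt]]
        e$rt <- c(e$rt, rts[si]); e$intensity <- c(e$intensity, intj)
        e$mzs <- c(e$mzs, mzj); e$scan <- c(e$scan, si)
        eics[[tgt]] <- e
        rep_mz[tgt] <- (rep_mz[tgt] * rep_w[tgt] + mzj * intj) / (rep_w[tgt] + intj)
        rep_w[tgt] <- rep_w[tgt] + intj
        taken[tgt] <- TRUE
      }
    }
  }
  keep <- vapply(seq_along(eics), function(i) {
    e <- eics[[i]]
    if (max(e$intensity) < p$min_height) return(FALSE)
    ok <- e$intensity >= p$group_intensity_threshold
    # longest run of consecutive scan indices with qualifying intensity
    best <- 0L; run <- 0L; prev <- -2L
    for (k in seq_along(ok)) {
      if (ok[k]) {
        run <- if (e$scan[k] == prev + 1L && run > 0L) run + 1L else 1L
        prev <- e$scan[k]
        if (run > best) best <- run
      } else {
        run <- 0L; prev <- -2L
      }
    }
    best >= p$min_group_size
  }, logical(1))
  eics <- eics[keep]
  lapply(seq_along(eics), function(i) {
    e <- eics[[i]]
    e$mz <- sum(e$mzs * e$intensity) / sum(e$intensity)
    e
  })
}

#' Local-minimum deconvolution of an EIC into features
#'
#' The intensity profile is split at interior local minima that are minimal
#' within +/- `rt_search_range`; each candidate sub-peak is kept iff its apex
#' reaches `min_abs_height`, at least `min_rel_height` of the EIC maximum and
#' at least `top_edge_ratio` times both boundary (edge) intensities, and the
#' peak body -- the contiguous points around the apex strictly above the
#' `(1 - chrom_threshold)` intensity quantile of the sub-peak -- has a
#' duration inside `duration_range`. Area is trapezoidal over the body; the
#' feature m/z is the intensity-weighted mean over the body.
#'
#' @param eic One EIC from [build_chromatograms()].
#' @param p [detection_params()].
#' @return Data frame of features (possibly 0 rows): `mz`, `rt`, `rt_start`,
#'   `rt_end`, `height`, `area`.
#' @export
deconvolve_local_minimum <- function(eic, p = detection_params()) {
  rt <- eic$rt; int <- eic$intensity; n <- length(int)
  empty <- data.frame(mz = numeric(0), rt = numeric(0), rt_start = numeric(0),
                      rt_end = numeric(0), height = numeric(0), area = numeric(0))
  if (n < 3L) return(empty)
  # interior local minima that are minimal within the RT search window
  splits <- integer(0)
  for (i in 2:(n - 1L)) {
    if (int[i] > int[i - 1L] || int[i] > int[i + 1L]) next
    win <- which(abs(rt - rt[i]) <= p$rt_search_range)
    if (int[i] <= min(int[win])) splits <- c(splits, i)
  }
  bounds <- unique(c(1L, splits, n))
  segs <- cbind(bounds[-length(bounds)], bounds[-1])
  out <- empty
  eic_max <- max(int)
  for (s in seq_len(nrow(segs))) {
    a <- segs[s, 1]; b <- segs[s, 2]
    idx <- a:b
    m <- idx[which.max(int[idx])]
    apex <- int[m]
    if (apex < p$min_abs_height) next
    if (apex < p$min_rel_height * eic_max) next
    eps <- .Machine$double.eps
    if (apex / max(int[a], eps) < p$top_edge_ratio ||
        apex / max(int[b], eps) < p$top_edge_ratio) next
    # peak body: contiguous points around the apex strictly above the
    # (1 - chrom_threshold) intensity quantile, so flat baselines never
    # stretch the body
    q <- stats::quantile(int[idx], 1 - p$chrom_threshold, names = FALSE)
    lo <- m; while (lo > a && int[lo - 1L] > q) lo <- lo - 1L
    hi <- m; while (hi < b && int[hi + 1L] > q) hi <- hi + 1L
    body <- lo:hi
    dur <- rt[hi] - rt[lo]
    if (dur < p$duration_range[1] || dur > p$duration_range[2]) next
    area <- if (length(body) > 1L)
      sum(diff(rt[body]) * (utils::head(int[body], -1) + utils::tail(int[body], -1)) / 2)
    else 0
    out <- rbind(out, data.frame(
      mz = sum(eic$mzs[body] * int[body]) / sum(int[body]),
      rt = rt[m], rt_start = rt[lo], rt_end = rt[hi],
      height = apex, area = area))
  }
  out
}

#' Attach MS2 spectra to features
#'
#' Each MS2 scan attaches to the feature whose m/z lies within `ms2_pair_mz`
#' of the precursor and whose apex RT is within `ms2_pair_rt`; ties are
#' broken by smallest m/z difference, then smallest RT difference. When
#' several MS2 scans attach to one feature, the one with the highest
#' precursor intensity (falling back to summed fragment intensity) becomes
#' the representative spectrum.
#'
#' @param features Feature data frame (from [deconvolve_local_minimum()],
#'   with an `id` column).
#' @param ms2_scans List of MS2 scans (with `precursor_mz`, `rt`).
#' @param p [detection_params()].
#' @return `features` with a list-column `ms2` of [fragment_spectrum()]
#'   objects (NULL where unpaired).
#' @export
pair_ms2 <- function(features, ms2_scans, p = detection_params()) {
  features$ms2 <- I(vector("list", nrow(features)))
  if (nrow(features) == 0L || length(ms2_scans) == 0L) return(features)
  best_score <- rep(-Inf, nrow(features))
  for (sc in ms2_scans) {
    if (is.null(sc$precursor_mz) || is.na(sc$precursor_mz)) next
    dmz <- abs(features$mz - sc$precursor_mz)
    drt <- abs(features$rt - sc$rt)
    cand <- which(dmz <= p$ms2_pair_mz & drt <= p$ms2_pair_rt)
    if (!length(cand)) next
    # round the keys so isobaric features differing only in float dust tie on
    # m/z and resolve by RT proximity
    cand <- cand[order(round(dmz[cand], 6), round(drt[cand], 6))]
    f <- cand[1L]
    keep <- detect_mass_peaks(sc, p$ms2_noise, centroided = TRUE)
    if (length(keep$mz) == 0L) next
    pint <- sc$precursor_intensity
    score <- if (!is.null(pint) && is.finite(pint)) pint else sum(keep$intensity)
    if (score > best_score[f]) {
      best_score[f] <- score
      features$ms2[[f]] <- fragment_spectrum(
        precursor_mz = sc$precursor_mz,
        charge = if (is.null(sc$precursor_charge)) 1L else sc$precursor_charge,
        mz = keep$mz, intensity = keep$intensity,
        feature_id = features$id[f], rt = sc$rt)
    }
  }
  features
}

#' Group isotope peaks (13C satellites)
#'
#' Features whose m/z values differ by 1.00335/z (z in `iso_charges`) within
#' `iso_mz_tol` and that co-elute within `iso_rt_tol` are placed in one
#' isotope group; the lowest-m/z member is the monoisotopic representative.
#' Chains (A, A+1, A+2) are linked transitively.
#'
#' @param features Feature data frame with `id`, `mz`, `rt`.
#' @param p [detection_params()].
#' @return `features` with `isotope_group` (id of the monoisotopic member)
#'   and logical `is_monoisotopic`.
#' @export
group_isotopes <- function(features, p = detection_params()) {
  n <- nrow(features)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
      if (abs(features$rt[i] - features$rt[j]) > p$iso_rt_tol) next
      d <- abs(features$mz[i] - features$mz[j])
      hit <- any(vapply(p$iso_charges,
                        function(z) abs(d - .c13_spacing / z) <= p$iso_mz_tol,
                        logical(1)))
      if (hit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  features$isotope_group <- rep(NA_integer_, n)
  features$is_monoisotopic <- rep(TRUE, n)
  for (r in unique(roots)) {
    member <- which(roots == r)
    mono <- member[which.min(features$mz[member])]
    features$isotope_group[member] <- features$id[mono]
    features$is_monoisotopic[member] <- member == mono
  }
  features
}

#' Filter duplicate feature rows
#'
#' Two sequential passes over the table sorted by descending height: pass 1
#' ("single feature" mode) merges rows within 0.001 m/z and 0.05 min; pass 2
#' ("old average" mode) merges rows within 1 m/z and 0.05 min. The
#' higher-intensity row survives each merge.
#'
#' @param features Feature data frame with `mz`, `rt`, `height`.
#' @param p [detection_params()].
#' @return Deduplicated feature data frame (original row order restored).
#' @export
filter_duplicates <- function(features, p = detection_params()) {
  one_pass <- function(df, mz_tol, rt_tol) {
    if (nrow(df) < 2L) return(df)
    ord <- order(-df$height, df$mz, df$rt)
    keep_idx <- integer(0)
    for (i in ord) {
      dup <- FALSE
      for (k in keep_idx) {
        if (abs(df$mz[i] - df$mz[k]) <= mz_tol &&
            abs(df$rt[i] - df$rt[k]) <= rt_tol) { dup <- TRUE; break }
      }
      if (!dup) keep_idx <- c(keep_idx, i)
    }
    df[sort(keep_idx), , drop = FALSE]
  }
  out <- one_pass(features, p$dup_mz_tol, p$dup_rt_tol)
  one_pass(out, p$dup_mz_tol2, p$dup_rt_tol2)
}

#' Keep only features with a paired MS2 spectrum
#'
#' @param features Feature data frame with list-column `ms2`.
#' @return The subset of rows whose `ms2` entry is non-NULL.
#' @export
filter_rows_with_ms2 <- function(features) {
  has <- vapply(features$ms2, Negate(is.null), logical(1))
  features[has, , drop = FALSE]
}

#' Run the full feature-detection chain on an MS run
#'
#' Centroiding, chromatogram building, local-minimum deconvolution, MS2
#' pairing, isotope grouping and duplicate filtering, in that order. Row
#' ids are assigned after deconvolution in (RT, m/z) order, so identical
#' inputs give identical tables.
#'
#' @param run An `ms_run` (see [read_msrun()] / [simulate_run()]).
#' @param p [detection_params()].
#' @param ms2_only Keep only monoisotopic rows with MS2? (default FALSE;
#'   the pipeline applies this before networking.)
#' @return Feature data frame with columns `id`, `mz`, `rt`, `rt_start`,
#'   `rt_end`, `height`, `area`, `isotope_group`, `is_monoisotopic` and
#'   list-column `ms2`.
#' @export
detect_features <- function(run, p = detection_params(), ms2_only = FALSE) {
  stopifnot(inherits(run, "ms_run"))
  ms1 <- run$scans[vapply(run$scans, function(s) s$ms_level, numeric(1)) == 1]
  ms2 <- run$scans[vapply(run$scans, function(s) s$ms_level, numeric(1)) == 2]
  eics <- build_chromatograms(ms1, p, centroided = isTRUE(run$centroided))
  feats <- do.call(rbind, c(list(data.frame(mz = numeric(0), rt = numeric(0),
                                            rt_start = numeric(0), rt_end = numeric(0),
                                            height = numeric(0), area = numeric(0))),
                            lapply(eics, deconvolve_local_minimum, p = p)))
  feats <- feats[order(feats$rt, feats$mz), , drop = FALSE]
  rownames(feats) <- NULL
  feats$id <- seq_len(nrow(feats))
  feats <- pair_ms2(feats, ms2, p)
  feats <- group_isotopes(feats, p)
  feats <- filter_duplicates(feats, p)
  if (ms2_only) feats <- filter_rows_with_ms2(feats[feats$is_monoisotopic, , drop = FALSE])
  feats
}

#' Base-peak chromatogram of a run
#'
#' @param run An `ms_run`.
#' @return Data frame `time_min`/`intensity` over MS1 scans.
#' @export
base_peak_chromatogram <- function(run) {
  ms1 <- run$scans[vapply(run$scans, function(s) s$ms_level, numeric(1)) == 1]
  data.frame(
    time_min = vapply(ms1, function(s) s$rt, numeric(1)),
    intensity = vapply(ms1, function(s) if (length(s$intensity)) max(s$intensity) else 0,
                       numeric(1)))
}
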
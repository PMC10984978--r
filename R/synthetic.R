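# Ground-truthed synthetic LC-MS/MS runs and matching plate readouts, so the
# entire pipeline (plate -> trace -> alignment -> features -> network ->
# mapping) runs and is testable offline.

# Evaluate code with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Define a synthetic compound
#'
#' A compound elutes as a Gaussian peak and, when `active`, suppresses the
#' viability readout of the plate wells its (delay-shifted) elution window
#' reaches.
#'
#' @param name Label used in the truth table.
#' @param rt Apex retention time on the MS axis (minutes).
#' @param mz Observed `[M+H]+` m/z; computed from `formula` when omitted.
#' @param formula Optional neutral molecular formula (string).
#' @param intensity Apex MS1 intensity (default 1e6).
#' @param sigma Gaussian peak width in minutes (default 0.08).
#' @param carbons Carbon count driving the A+1 isotope ratio; taken from
#'   `formula` when given, else estimated as `round(mz / 22)`.
#' @param fragments Two-column matrix (mz, intensity) of MS2 fragments; a
#'   deterministic generic set of neutral losses is derived from `mz` when
#'   omitted.
#' @param active Does the compound inhibit the assay organism?
#' @param activity_depth Fractional reduction of well response at the dip
#'   apex, in (0, 1] (default 0.7).
#' @return List of class `synthetic_compound`.
#' @export
synthetic_compound <- function(name, rt, mz = NULL, formula = NULL,
                               intensity = 1e6, sigma = 0.08, carbons = NULL,
                               fragments = NULL, active = FALSE,
                               activity_depth = 0.7) {
  if (is.null(mz)) {
    if (is.null(formula)) stop("give either mz or formula")
    mz <- protonated_mz(formula)
  }
  if (is.null(carbons)) {
    carbons <- if (!is.null(formula)) {
      f <- parse_formula(formula); if ("C" %in% names(f)) unclass(f)[["C"]] else 0L
    } else as.integer(round(mz / 22))
  }
  if (is.null(fragments)) {
    fragments <- cbind(mz = c(mz - 18.010565, mz - 46.00548, mz * 0.61, mz * 0.38,
                              mz * 0.22),
                       intensity = c(60, 35, 100, 80, 45))
  }
  stopifnot(intensity > 0, sigma > 0)
  if (active) stopifnot(activity_depth > 0, activity_depth <= 1)
  structure(list(name = name, rt = rt, mz = mz, formula = formula,
                 intensity = intensity, sigma = sigma,
                 carbons = as.integer(carbons),
                 fragments = fragments[order(fragments[, 1]), , drop = FALSE],
                 active = active, activity_depth = activity_depth),
            class = "synthetic_compound")
}

#' Synthetic run specification
#'
#' The stated acquisition world: a 41-min gradient with MS1 scans every 2 s,
#' data-dependent MS2 for the three most intense ions of each cycle, 6-s
#' nanofractionation into 350 wells of a 384-well plate, and a 0.3-min
#' bioassay delay downstream of the post-column split.
#'
#' @param run_length Run length in minutes (default 41).
#' @param ms1_interval MS1 scan interval in seconds (default 2).
#' @param top_n Data-dependent MS2 precursors per cycle (default 3).
#' @param ms2_trigger Minimum MS1 intensity to trigger MS2 (default 1e5).
#' @param noise_floor Upper bound of additive noise-peak intensity
#'   (default 5e3, below the MS1 centroid noise level).
#' @param noise_peaks Noise peaks per MS1 scan (default 5).
#' @param isotope_ratio A+1 probability per carbon (default 0.011).
#' @param delay Bioassay delay in minutes (default 0.3).
#' @param seed RNG seed (default 42).
#' @param layout Plate layout (default [plate_layout()]).
#' @param baseline Baseline plate fluorescence in arbitrary units
#'   (default 1000).
#' @param plate_noise Multiplicative (log-normal) noise sd of well
#'   fluorescence (default 0.02).
#' @return List of class `synthetic_run_spec`.
#' @export
synthetic_run_spec <- function(run_length = 41, ms1_interval = 2, top_n = 3L,
                               ms2_trigger = 1e5, noise_floor = 5e3,
                               noise_peaks = 5L, isotope_ratio = 0.011,
                               delay = 0.3, seed = 42L,
                               layout = plate_layout(), baseline = 1000,
                               plate_noise = 0.02) {
  structure(list(run_length = run_length, ms1_interval = ms1_interval,
                 top_n = as.integer(top_n), ms2_trigger = ms2_trigger,
                 noise_floor = noise_floor, noise_peaks = as.integer(noise_peaks),
                 isotope_ratio = isotope_ratio, delay = delay,
                 seed = as.integer(seed), layout = layout,
                 baseline = baseline, plate_noise = plate_noise),
            class = "synthetic_run_spec")
}

#' Simulate an LC-MS/MS run
#'
#' MS1 scans carry Gaussian elution profiles for every compound with A+1 and
#' A+2 isotope satellites at +1.00335 (ratio `isotope_ratio * carbons` and
#' its squared term), plus additive random noise peaks below the noise
#' floor. After each MS1 scan the `top_n` most intense compound ions above
#' the trigger threshold are fragmented; MS2 fragment intensities scale with
#' the precursor's current elution intensity.
#'
#' @param spec A [synthetic_run_spec()].
#' @param compounds List of [synthetic_compound()]s.
#' @return List with `run` (an `ms_run`) and `truth` (data frame: `name`,
#'   `mz`, `rt`, `apex_intensity`, `carbons`, `active`, `activity_depth`).
#' @export
simulate_run <- function(spec, compounds) {
  stopifnot(inherits(spec, "synthetic_run_spec"))
  dt <- spec$ms1_interval / 60
  ms1_times <- seq(0, spec$run_length, by = dt)
  cmz <- vapply(compounds, function(c) c$mz, numeric(1))
  crt <- vapply(compounds, function(c) c$rt, numeric(1))
  if (length(compounds) && any(crt < 0 | crt > spec$run_length))
    stop("compound RT outside the run")
  capx <- vapply(compounds, function(c) c$intensity, numeric(1))
  csig <- vapply(compounds, function(c) c$sigma, numeric(1))
  ciso <- pmin(0.999, spec$isotope_ratio *
                 vapply(compounds, function(c) c$carbons, integer(1)))
  scans <- with_seed(spec$seed, {
    out <- vector("list", 0L)
    for (t in ms1_times) {
      inten <- capx * exp(-(t - crt)^2 / (2 * csig^2))
      live <- which(inten > 0.01)
      mz <- numeric(0); int <- numeric(0)
      for (ci in live) {
        r1 <- ciso[ci]
        sat <- c(1, r1, r1^2 / 2) * inten[ci]
        keep <- sat > 0.01
        mz <- c(mz, cmz[ci] + (0:2)[keep] * .c13_spacing)
        int <- c(int, sat[keep])
      }
      nmz <- stats::runif(spec$noise_peaks, 100, 2000)
      nint <- stats::runif(spec$noise_peaks, 0.2, 1) * spec$noise_floor
      mz <- c(mz, nmz); int <- c(int, nint)
      o <- order(mz)
      out[[length(out) + 1L]] <- list(ms_level = 1, rt = t, mz = mz[o],
                                      intensity = int[o])
      # data-dependent MS2: top-N compound ions above the trigger
      trig <- live[inten[live] >= spec$ms2_trigger]
      if (length(trig)) {
        trig <- trig[order(-inten[trig])]
        trig <- utils::head(trig, spec$top_n)
        for (k in seq_along(trig)) {
          ci <- trig[k]
          fr <- compounds[[ci]]$fragments
          scale <- inten[ci] / capx[ci]
          out[[length(out) + 1L]] <- list(
            ms_level = 2, rt = t + k * dt / (spec$top_n + 1),
            mz = fr[, 1], intensity = fr[, 2] * scale * 1e3,
            precursor_mz = cmz[ci], precursor_charge = 1L,
            precursor_intensity = inten[ci])
        }
      }
    }
    out
  })
  truth <- data.frame(
    name = vapply(compounds, function(c) c$name, character(1)),
    mz = cmz, rt = crt, apex_intensity = capx,
    carbons = vapply(compounds, function(c) c$carbons, integer(1)),
    active = vapply(compounds, function(c) c$active, logical(1)),
    activity_depth = vapply(compounds, function(c) c$activity_depth, numeric(1)))
  list(run = ms_run(scans, centroided = TRUE,
                    metadata = list(seed = spec$seed,
                                    run_length = spec$run_length)),
       truth = truth)
}

#' Simulate the nanofractionated assay plate
#'
#' Baseline fluorescence with multiplicative log-normal noise; every active
#' compound reduces the response of the wells whose fraction window (shifted
#' by the bioassay delay) overlaps its elution peak, proportionally to the
#' amount eluted into the window (normalized to the best-hit well) times the
#' compound's `activity_depth`. The control column carries the assay's
#' control scheme (positive control, growth control, blank, sterility
#' control, cycling down the column).
#'
#' @param spec A [synthetic_run_spec()].
#' @param compounds List of [synthetic_compound()]s.
#' @return Plate matrix (`layout$rows` x `layout$columns`) of raw
#'   fluorescence values.
#' @export
simulate_plate <- function(spec, compounds) {
  stopifnot(inherits(spec, "synthetic_run_spec"))
  lay <- spec$layout
  with_seed(spec$seed + 1L, {
    plate <- matrix(spec$baseline *
                      exp(stats::rnorm(lay$rows * lay$columns, 0, spec$plate_noise)),
                    nrow = lay$rows, ncol = lay$columns)
    ord <- serpentine_order(lay)
    n <- nrow(ord)
    t0 <- fraction_time(seq_len(n) - 1L, lay)
    t1 <- t0 + lay$fraction_seconds / 60
    for (cp in compounds) {
      if (!cp$active) next
      center <- cp$rt + spec$delay
      w <- stats::pnorm(t1, center, cp$sigma) - stats::pnorm(t0, center, cp$sigma)
      if (max(w) <= 0) next
      w <- w / max(w)
      mult <- 1 - cp$activity_depth * w
      plate[cbind(ord$row, ord$col)] <- plate[cbind(ord$row, ord$col)] * mult
    }
    # control column: positive control (inhibited), growth control, blank,
    # sterility control, repeated down the column
    ctl_frac <- rep(c(0.08, 1.0, 0.06, 0.05), length.out = lay$rows)
    plate[, lay$control_column] <- spec$baseline * ctl_frac *
      exp(stats::rnorm(lay$rows, 0, spec$plate_noise))
    plate
  })
}

#' Built-in synthetic compound sets
#'
#' Three ready-made "worlds" mirroring the platform's validation chemistry:
#' `"bacillus"` — 8 bioactive lipopeptide-like compounds (a CH2 homolog
#' ladder of five cyclic-lipopeptide congeners sharing a fragment core, two
#' of them isobaric at different RT, plus three surfactin-like congeners)
#' and four inactive background compounds; `"streptomyces"` — 14 bioactive
#' angucycline-like compounds giving 14 well-separated activity dips;
#' `"calibrant"` — a single strongly active compound (nalidixic acid-like,
#' `[M+H]+` 233.0921) for delay estimation.
#'
#' @param set One of `"bacillus"`, `"streptomyces"`, `"calibrant"`.
#' @return List of [synthetic_compound()]s.
#' @export
demo_compounds <- function(set = c("bacillus", "streptomyces", "calibrant")) {
  set <- match.arg(set)
  # shared fragment cores so modified-cosine shifted matching is exercised:
  # direct matches from the core, shifted matches from precursor-dependent
  # neutral losses
  lipo <- function(name, mz, rt, carbons, apx) {
    core <- cbind(mz = c(84.081, 120.081, 227.175, 327.249),
                  intensity = c(55, 70, 100, 60))
    dep <- cbind(mz = c(mz - 18.011, mz - 113.084, mz - 226.168),
                 intensity = c(80, 65, 45))
    synthetic_compound(name, rt = rt, mz = mz, carbons = carbons,
                       intensity = apx, fragments = rbind(core, dep),
                       active = TRUE, activity_depth = 0.7)
  }
  surf <- function(name, mz, rt, carbons, apx) {
    core <- cbind(mz = c(101.071, 227.139, 341.218, 441.271),
                  intensity = c(45, 85, 100, 70))
    dep <- cbind(mz = c(mz - 18.011, mz - 99.068, mz - 214.131),
                 intensity = c(75, 60, 50))
    synthetic_compound(name, rt = rt, mz = mz, carbons = carbons,
                       intensity = apx, fragments = rbind(core, dep),
                       active = TRUE, activity_depth = 0.6)
  }
  angu <- function(name, mz, rt, apx = 8e5) {
    core <- cbind(mz = c(115.054, 152.062, 268.074, 305.081),
                  intensity = c(40, 75, 100, 55))
    dep <- cbind(mz = c(mz - 18.011, mz - 114.068, mz - 130.063),
                 intensity = c(85, 70, 40))
    synthetic_compound(name, rt = rt, mz = mz, intensity = apx,
                       fragments = rbind(core, dep),
                       active = TRUE, activity_depth = 0.65)
  }
  inert <- function(name, mz, rt, apx = 6e5) {
    frs <- cbind(mz = c(mz - 18.011, mz * 0.7, mz * 0.45, mz * 0.3),
                 intensity = c(70, 100, 55, 40))
    synthetic_compound(name, rt = rt, mz = mz, intensity = apx,
                       fragments = frs, active = FALSE)
  }
  switch(set,
    bacillus = list(
      lipo("iturin-like C13", 1029.5404, 16.32, 47L, 1.2e6),
      lipo("iturin-like C14", 1043.5591, 18.05, 48L, 2.0e6),
      lipo("iturin-like C15", 1057.5642, 19.22, 49L, 1.8e6),
      lipo("iturin-like C16a", 1071.5880, 20.64, 50L, 1.0e6),
      lipo("iturin-like C16b", 1071.5880, 20.95, 50L, 0.9e6),
      surf("surfactin-like C13", 1008.6698, 27.91, 51L, 1.1e6),
      surf("surfactin-like C14", 1022.6782, 28.84, 52L, 1.5e6),
      surf("surfactin-like C15", 1036.6921, 29.47, 53L, 1.0e6),
      inert("background A", 341.2686, 5.0),
      inert("background B", 523.3427, 8.0),
      inert("background C", 685.4214, 12.0),
      inert("background D", 811.5031, 25.0)),
    streptomyces = {
      mzs <- c(601.2280, 487.1606, 758.2166, 599.2160, 597.1990, 595.1804,
               487.1590, 599.2103, 581.2005, 451.1385, 597.1988, 579.1900,
               597.1935, 615.2071)
      rts <- 6 + 1.8 * (seq_along(mzs) - 1)
      mapply(function(m, r, i) angu(sprintf("angucycline-like %02d", i), m, r),
             mzs, rts, seq_along(mzs), SIMPLIFY = FALSE)
    },
    calibrant = list(
      synthetic_compound("nalidixic acid-like", rt = 5.0, mz = 233.0921,
                         carbons = 12L, intensity = 2e6,
                         fragments = cbind(mz = c(215.081, 187.086, 159.092,
                                                  104.049),
                                           intensity = c(100, 65, 45, 30)),
                         active = TRUE, activity_depth = 0.9)))
}
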
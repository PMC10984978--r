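# Centroiding, EIC building, local-minimum deconvolution, MS2 pairing,
# isotope grouping, duplicate filtering and the MS2-only row filter --
# including just-below / just-above fixtures for every stated threshold.

test_that("centroid detection thresholds and centroids profile peaks", {
  empty <- list(mz = numeric(0), intensity = numeric(0))
  expect_equal(detect_mass_peaks(empty, 1e4)$mz, numeric(0))
  # single centroid below the MS1 noise level is dropped, just-above kept
  low <- list(mz = 500, intensity = 9e3)
  expect_equal(length(detect_mass_peaks(low, 1e4)$mz), 0L)
  hi <- list(mz = 500, intensity = 1.1e4)
  expect_equal(detect_mass_peaks(hi, 1e4)$mz, 500)
  # MS2 noise level 0: everything positive passes
  expect_equal(length(detect_mass_peaks(low, 0)$mz), 1L)
  # 3-point profile peak collapses to the intensity-weighted m/z
  prof <- list(mz = c(100.000, 100.001, 100.002),
               intensity = c(1e5, 3e5, 1e5))
  got <- detect_mass_peaks(prof, 1e4, centroided = FALSE)
  expect_equal(length(got$mz), 1L)
  expect_equal(got$mz, (100 * 1 + 100.001 * 3 + 100.002 * 1) / 5)
  expect_equal(got$intensity, 3e5)
})

test_that("chromatogram builder enforces group size, intensity and height", {
  p <- detection_params()
  # 0.5-min-wide Gaussian: ~18 scans above 1e4 at 2-s spacing -> retained
  scans <- gaussian_scans(apex = 1e6, sigma = 0.08)
  eics <- build_chromatograms(scans, p)
  expect_equal(length(eics), 1L)
  expect_equal(eics[[1]]$mz, 500.25)
  # narrow peak: only ~5 scans above the group threshold -> rejected
  narrow <- gaussian_scans(apex = 1e6, sigma = 0.02)
  expect_equal(length(build_chromatograms(narrow, p)), 0L)
  # wide but short peak: apex 4e4 < min height 5e4 -> rejected
  short <- gaussian_scans(apex = 4e4, sigma = 0.3)
  expect_equal(length(build_chromatograms(short, p)), 0L)
  # just above: apex 6e4, wide enough
  ok <- gaussian_scans(apex = 6e4, sigma = 0.3)
  expect_equal(length(build_chromatograms(ok, p)), 1L)
  expect_error(build_chromatograms(rev(scans), p), "RT-ordered")
})

test_that("local-minimum deconvolution splits valleys and applies filters", {
  p <- detection_params()
  dt <- 1 / 30
  t <- seq(4, 6, by = dt)
  g <- function(c, s, a) a * exp(-(t - c)^2 / (2 * s^2))
  # single Gaussian -> one feature at the apex
  f1 <- deconvolve_local_minimum(make_eic(t, g(5, 0.08, 1e6)), p)
  expect_equal(nrow(f1), 1L)
  expect_lt(abs(f1$rt - 5), dt)
  expect_true(f1$rt_start <= f1$rt & f1$rt <= f1$rt_end)
  # two Gaussians with a deep valley -> two features
  f2 <- deconvolve_local_minimum(
    make_eic(t, g(4.6, 0.06, 1e6) + g(5.4, 0.06, 8e5)), p)
  expect_equal(nrow(f2), 2L)
  expect_lt(abs(f2$rt[1] - 4.6), dt)
  expect_lt(abs(f2$rt[2] - 5.4), dt)
  # shoulder whose apex/edge ratio is below 2 is not reported as its own peak:
  # explicit profile with a valley at 1e5 and a bump apex at 1.5e5
  prof <- c(seq(0, 1e6, length.out = 12), seq(9e5, 1e5, length.out = 10),
            seq(1.2e5, 1.5e5, length.out = 4), seq(1.4e5, 0, length.out = 10))
  f3 <- deconvolve_local_minimum(make_eic(seq(4, by = dt, length.out = length(prof)),
                                          prof), p)
  expect_equal(nrow(f3), 1L)
  expect_lt(abs(f3$rt - (4 + 11 * dt)), 1e-9)  # the main apex survives
  # sub-peak below the absolute height floor is dropped
  f4 <- deconvolve_local_minimum(
    make_eic(t, g(4.6, 0.06, 1e6) + g(5.4, 0.06, 9e3)), p)
  expect_equal(nrow(f4), 1L)
  # duration below 0.05 min is rejected: a 2-point spike
  spike <- rep(0, length(t)); spike[20:21] <- c(2e5, 1.9e5)
  expect_equal(nrow(deconvolve_local_minimum(make_eic(t, spike), p)), 0L)
})

test_that("MS2 pairing honors the 0.05 m/z and 1 min windows", {
  p <- detection_params()
  feats <- data.frame(id = 1:2, mz = c(500.00, 800.00), rt = c(5, 20),
                      rt_start = c(4.9, 19.9), rt_end = c(5.1, 20.1),
                      height = c(1e6, 1e6), area = c(1, 1))
  sc <- function(pmz, rt, pint = 1e5)
    list(ms_level = 2, rt = rt, mz = c(100, 200), intensity = c(10, 20),
         precursor_mz = pmz, precursor_charge = 1L, precursor_intensity = pint)
  # inside both windows
  got <- pair_ms2(feats, list(sc(500.04, 5.5)), p)
  expect_false(is.null(got$ms2[[1]]))
  # just outside the m/z window
  got <- pair_ms2(feats, list(sc(500.06, 5.5)), p)
  expect_true(is.null(got$ms2[[1]]))
  # just outside the RT window
  got <- pair_ms2(feats, list(sc(500.04, 6.01)), p)
  expect_true(is.null(got$ms2[[1]]))
  # just inside the RT window
  got <- pair_ms2(feats, list(sc(500.04, 5.99)), p)
  expect_false(is.null(got$ms2[[1]]))
  # no MS2 scans: everything unpaired
  got <- pair_ms2(feats, list(), p)
  expect_true(all(vapply(got$ms2, is.null, logical(1))))
  # highest precursor intensity wins as representative
  got <- pair_ms2(feats, list(sc(500.01, 5.2, pint = 5e4),
                              sc(500.02, 5.3, pint = 9e4)), p)
  expect_equal(got$ms2[[1]]$precursor_mz, 500.02)
})

test_that("isotope grouping links 13C satellites within tight windows", {
  p <- detection_params()
  mk <- function(id, mz, rt, height = 1e6)
    data.frame(id = id, mz = mz, rt = rt, rt_start = rt - 0.1,
               rt_end = rt + 0.1, height = height, area = 1)
  # A / A+1 pair co-eluting -> one group, lower m/z is monoisotopic
  f <- rbind(mk(1, 500.0000, 5.00), mk(2, 501.00335, 5.02, 5e5))
  g <- group_isotopes(f, p)
  expect_equal(g$isotope_group, c(1L, 1L))
  expect_equal(g$is_monoisotopic, c(TRUE, FALSE))
  # same spacing but 0.2 min apart -> separate groups
  f <- rbind(mk(1, 500.0000, 5.0), mk(2, 501.00335, 5.2))
  g <- group_isotopes(f, p)
  expect_equal(g$isotope_group, c(1L, 2L))
  # spacing off by > 0.001 -> not grouped
  f <- rbind(mk(1, 500.0000, 5.0), mk(2, 501.0050, 5.0))
  expect_equal(group_isotopes(f, p)$isotope_group, c(1L, 2L))
  # doubly charged spacing 0.501675 is recognized
  f <- rbind(mk(1, 500.0000, 5.0), mk(2, 500.501675, 5.0))
  expect_equal(group_isotopes(f, p)$isotope_group, c(1L, 1L))
  # A, A+1, A+2 chain collapses into one group transitively
  f <- rbind(mk(1, 500.0000, 5.0), mk(2, 501.00335, 5.0), mk(3, 502.0067, 5.0))
  expect_equal(group_isotopes(f, p)$isotope_group, c(1L, 1L, 1L))
  # singleton keeps its own group
  g <- group_isotopes(mk(9, 600, 7), p)
  expect_equal(g$isotope_group, 9L)
  expect_true(g$is_monoisotopic)
})

test_that("duplicate filtering merges within both window passes", {
  p <- detection_params()
  mk <- function(id, mz, rt, h)
    data.frame(id = id, mz = mz, rt = rt, rt_start = rt - 0.1,
               rt_end = rt + 0.1, height = h, area = 1)
  # pass 1: tight m/z window keeps the taller row
  f <- rbind(mk(1, 500.0000, 5.00, 1e6), mk(2, 500.0005, 5.02, 8e5))
  out <- filter_duplicates(f, p)
  expect_equal(out$id, 1L)
  # pass 2: 0.5 Da apart within 0.05 min merges too
  f <- rbind(mk(1, 500.0, 5.00, 1e6), mk(2, 500.5, 5.02, 8e5))
  expect_equal(filter_duplicates(f, p)$id, 1L)
  # outside the RT window both survive
  f <- rbind(mk(1, 500.0, 5.0, 1e6), mk(2, 500.5, 5.2, 8e5))
  expect_equal(filter_duplicates(f, p)$id, c(1L, 2L))
  # contractive
  expect_lte(nrow(filter_duplicates(f, p)), nrow(f))
})

test_that("the MS2-only row filter keeps exactly the paired subset", {
  feats <- data.frame(id = 1:10, mz = 100 + 1:10, rt = 1:10,
                      rt_start = 0, rt_end = 11, height = 1e6, area = 1)
  feats$ms2 <- I(vector("list", 10))
  for (k in c(2, 5, 7, 9))
    feats$ms2[[k]] <- mk_spec(k, 100 + k, c(50, 60))
  expect_equal(filter_rows_with_ms2(feats)$id, c(2L, 5L, 7L, 9L))
  none <- feats; none$ms2 <- I(vector("list", 10))
  expect_equal(nrow(filter_rows_with_ms2(none)), 0L)
  all_p <- feats
  for (k in 1:10) all_p$ms2[[k]] <- mk_spec(k, 100 + k, c(50, 60))
  expect_equal(filter_rows_with_ms2(all_p)$id, 1:10)
})

test_that("the chain is deterministic and recovers injected compounds", {
  spec <- synthetic_run_spec(seed = 42L)
  comp <- demo_compounds("bacillus")
  run <- simulate_run(spec, comp)$run
  f1 <- detect_features(run)
  f2 <- detect_features(run)
  expect_identical(f1, f2)
  # every retained feature satisfies the stated thresholds
  p <- detection_params()
  expect_true(all(f1$height >= p$min_abs_height))
  dur <- f1$rt_end - f1$rt_start
  expect_true(all(dur >= p$duration_range[1] & dur <= p$duration_range[2]))
  # each injected compound yields exactly one monoisotopic feature nearby
  truth <- simulate_run(spec, comp)$truth
  mono <- f1[f1$is_monoisotopic, ]
  for (k in seq_len(nrow(truth))) {
    hit <- which(abs(mono$mz - truth$mz[k]) <= 0.002 &
                   abs(mono$rt - truth$rt[k]) <= 1 / 30 + 1e-9)
    expect_equal(length(hit), 1L)
  }
  # a sub-threshold compound yields nothing
  faint <- list(synthetic_compound("faint", rt = 10, mz = 777.777,
                                   intensity = 3e4))
  ff <- detect_features(simulate_run(spec, faint)$run)
  expect_equal(nrow(ff), 0L)
})
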
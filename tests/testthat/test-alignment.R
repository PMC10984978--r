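# Calibrant-based delay estimation and common-axis resampling.

toy_ms <- function(apex = 5.0, sigma = 0.05, dt = 1 / 30) {
  t <- seq(0, 10, by = dt)
  data.frame(time_min = t, intensity = 1e6 * exp(-(t - apex)^2 / (2 * sigma^2)))
}

toy_bio <- function(apex = 5.3, sigma = 0.05, dt = 0.1) {
  t <- seq(0, 10, by = dt)
  tr <- data.frame(time_min = t,
                   response = 1 - 0.9 * exp(-(t - apex)^2 / (2 * sigma^2)))
  class(tr) <- c("bioactivity_trace", "data.frame")
  tr
}

test_that("delay is the apex difference of the calibrant peak and dip", {
  dm <- estimate_delay(toy_ms(5.0), toy_bio(5.3), bio_times = "center")
  expect_s3_class(dm, "delay_model")
  expect_equal(dm$delay_min, 0.3, tolerance = 0.01)
  expect_equal(dm$bio_apex_min - dm$ms_apex_min, dm$delay_min)
  # identical apexes give zero delay
  expect_equal(estimate_delay(toy_ms(5.0), toy_bio(5.0),
                              bio_times = "center")$delay_min,
               0, tolerance = 0.01)
})

test_that("degenerate calibrant traces are rejected", {
  flat_ms <- data.frame(time_min = seq(0, 10, 0.1), intensity = 1000)
  expect_error(estimate_delay(flat_ms, toy_bio(5.3)), "no MS peak")
  flat_bio <- toy_bio(5.3); flat_bio$response <- 1
  expect_error(estimate_delay(toy_ms(5.0), flat_bio), "no bioactivity dip")
  expect_error(estimate_delay(toy_ms(1.0), toy_bio(9.0), bio_times = "center"),
               "sanity limit")
})

test_that("delay estimation is translation-equivariant", {
  base <- estimate_delay(toy_ms(5.0), toy_bio(5.3), bio_times = "center")
  for (s in c(-0.5, 0.2, 1.0)) {
    shifted <- toy_bio(5.3)
    shifted$time_min <- shifted$time_min + s
    dm <- estimate_delay(toy_ms(5.0), shifted, bio_times = "center")
    expect_equal(dm$delay_min, base$delay_min + s, tolerance = 1e-9)
  }
})

test_that("injected delays are recovered on synthetic calibrant runs", {
  cal <- demo_compounds("calibrant")
  for (d in c(0.1, 0.3, 1.0)) {
    spec <- synthetic_run_spec(run_length = 10, delay = d, seed = 19L,
                               layout = plate_layout(wells_per_sample = 100L))
    run <- simulate_run(spec, cal)$run
    tr <- build_trace(normalize_plate(simulate_plate(spec, cal), spec$layout),
                      spec$layout)
    dm <- estimate_delay(base_peak_chromatogram(run), tr)
    expect_lt(abs(dm$delay_min - d), 0.05)
  }
})

test_that("applying a delay shifts times only and is invertible", {
  tr <- toy_bio(5.3)
  expect_equal(apply_delay(tr, 0), tr)
  dm <- structure(list(delay_min = 0.3), class = "delay_model")
  shifted <- apply_delay(tr, dm)
  expect_equal(shifted$time_min, tr$time_min - 0.3)
  expect_equal(shifted$response, tr$response)   # depths and widths untouched
  expect_equal(apply_delay(shifted, -0.3), tr)
})

# helper: reuse an MS trace as a fake bio trace on the same grid
ms_to_bio <- function(ms) {
  tr <- data.frame(time_min = ms$time_min, response = ms$intensity)
  class(tr) <- c("bioactivity_trace", "data.frame")
  tr
}

test_that("common axis resamples onto the overlap without extrapolation", {
  ms <- toy_ms(5.0)
  bio <- toy_bio(5.0)
  # identical grids reproduce values exactly
  same <- common_axis(ms, ms_to_bio(ms), n_points = nrow(ms))
  expect_equal(same$ms, ms$intensity, tolerance = 1e-9)
  # linear interpolation is exact on a linear ramp
  ramp <- data.frame(time_min = 0:10, intensity = 2 * (0:10) + 1)
  rb <- data.frame(time_min = seq(0, 10, 0.5), response = seq(0, 10, 0.5))
  class(rb) <- c("bioactivity_trace", "data.frame")
  cx <- common_axis(ramp, rb, n_points = 101L)
  expect_equal(cx$ms, 2 * cx$time_min + 1, tolerance = 1e-9)
  expect_equal(cx$bio, cx$time_min, tolerance = 1e-9)
  # grid spans exactly the intersection
  late <- rb; late$time_min <- late$time_min + 3
  cx2 <- common_axis(ramp, late, 11L)
  expect_equal(range(cx2$time_min), c(3, 10))
  far <- rb; far$time_min <- far$time_min + 100
  expect_error(common_axis(ramp, far), "overlap")
})

test_that("after delay correction the MS peak and bio dip coincide", {
  cal <- demo_compounds("calibrant")
  spec <- synthetic_run_spec(run_length = 10, delay = 0.3, seed = 23L,
                             layout = plate_layout(wells_per_sample = 100L))
  run <- simulate_run(spec, cal)$run
  tr <- build_trace(normalize_plate(simulate_plate(spec, cal), spec$layout),
                    spec$layout)
  dm <- estimate_delay(base_peak_chromatogram(run), tr)
  cx <- common_axis(base_peak_chromatogram(run), apply_delay(tr, dm), 256L)
  t_ms <- cx$time_min[which.max(cx$ms)]
  t_bio <- cx$time_min[which.min(cx$bio)]
  step <- diff(cx$time_min[1:2])
  expect_lt(abs(t_ms - t_bio), 0.1 + step)  # within one fraction + grid step
})
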
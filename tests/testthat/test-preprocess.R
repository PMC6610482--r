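test_that("the 10 percent intensity threshold is boundary inclusive", {
  frames <- array(0, dim = c(4, 2, 2))
  frames[, 1, 1] <- c(0, 1000, 0, 0) # field maximum
  frames[, 1, 2] <- 100              # exactly at threshold: retained
  frames[, 2, 1] <- 99.9             # just below: excluded
  mov <- make_movie(frames)
  m <- mask_background(mov)
  expect_equal(m$threshold, 100)
  expect_true(m$mask[1, 1])
  expect_true(m$mask[1, 2])
  expect_false(m$mask[2, 1])
  expect_false(m$mask[2, 2])
})

test_that("a spatially constant movie keeps every pixel; a zero movie errors", {
  mov <- make_movie(array(500, dim = c(5, 3, 3)))
  expect_true(all(mask_background(mov)$mask))
  expect_error(mask_background(make_movie(array(0, dim = c(5, 3, 3)))),
               class = "atrialmap_preprocess_error")
})

test_that("rendered synthetic movies recover the geometry mask exactly", {
  prep <- small_prep(kind = "isthmus", seed = 4)
  mov <- record_preparation(prep, pacing_hz = 3, duration_ms = 900,
                            camera = list(noise_sd = 40)) # 2 percent of F0
  m <- mask_background(mov)
  expect_identical(m$mask, prep$geometry$excitable)
})

test_that("dF/F is zero for constant traces and scale invariant", {
  frames <- array(100, dim = c(20, 2, 2))
  mov <- make_movie(frames)
  cond <- compute_dff(mov, mask_background(mov))
  expect_true(all(cond$dff == 0))

  # equal relative signal at 10x different F0 gives identical dF/F
  rel <- 1 - 0.05 * exp(-((1:20 - 10) / 3)^2)
  frames2 <- array(0, dim = c(20, 1, 2))
  frames2[, 1, 1] <- 100 * rel
  frames2[, 1, 2] <- 1000 * rel
  mov2 <- make_movie(frames2)
  cond2 <- compute_dff(mov2, mask_background(mov2))
  expect_equal(cond2$dff[, 1, 1], cond2$dff[, 1, 2], tolerance = 1e-12)
})

test_that("the 90th-percentile baseline makes a 10 percent dip read -0.10", {
  v <- c(rep(100, 95), rep(90, 5)) # mostly diastolic, transient dip
  frames <- array(v, dim = c(100, 1, 1))
  mov <- make_movie(frames)
  cond <- compute_dff(mov, mask_background(mov))
  expect_equal(min(cond$dff), -0.10)
  expect_equal(max(cond$dff), 0)
})

test_that("3x3 binning averages only masked-in neighbours", {
  # interior impulse with all 9 neighbours: 1/9
  arr <- array(0, dim = c(1, 5, 5))
  arr[1, 3, 3] <- 1
  cond <- spatial_bin(make_cond(arr))
  expect_equal(cond$dff[1, 3, 3], 1 / 9)
  # edge impulse with 6 valid neighbours: 1/6
  arr2 <- array(0, dim = c(1, 2, 3))
  arr2[1, 1, 2] <- 1
  cond2 <- spatial_bin(make_cond(arr2))
  expect_equal(cond2$dff[1, 1, 2], 1 / 6)
  # constant image unchanged
  cond3 <- spatial_bin(make_cond(array(2, dim = c(3, 4, 4))))
  expect_true(all(cond3$dff == 2))
})

test_that("inversion is an involution that flips extrema", {
  arr <- array(rnorm(5 * 3 * 3), dim = c(5, 3, 3))
  cond <- make_cond(arr)
  expect_equal(invert_signal(invert_signal(cond))$dff, arr)
  expect_equal(min(arr), -max(invert_signal(cond)$dff))
  expect_true(all(invert_signal(make_cond(array(0, c(8, 2, 2))))$dff == 0))
})

test_that("FFT low-pass zeroes bins strictly above fs/10 and keeps the rest", {
  # fs = 200 Hz, cutoff 20 Hz, integer periods in a 1 s window
  t <- (0:199) * 5 / 1000
  hi <- sin(2 * pi * 30 * t)
  lo <- sin(2 * pi * 5 * t)
  expect_lt(max(abs(fft_lowpass(hi, 5))), 1e-9)
  expect_lt(max(abs(fft_lowpass(lo, 5) - lo)), 1e-9)
  # DC preserved
  expect_equal(fft_lowpass(rep(3, 64), 5), rep(3, 64))
  # too-short input rejected
  expect_error(fft_lowpass(rnorm(7), 5), class = "atrialmap_preprocess_error")
})

test_that("polynomial detrending recovers exact drifts and keeps amplitudes", {
  # exact cubic: residual below 1e-8 of the drift range
  t <- seq(0, 1, length.out = 200)
  drift <- 5 + 3 * t - 7 * t^2 + 2 * t^3
  out <- detrend_poly(drift, order = 3)
  expect_lt(max(abs(out)), 1e-8 * diff(range(drift)))
  # constant trace maps to zero
  expect_lt(max(abs(detrend_poly(rep(4, 50), order = 2))), 1e-10)
  # OAP train on a linear drift: amplitudes within 2 percent of drift-free
  tr <- bump_train(period_ms = 500, n = 8, dt = 5)
  drifted <- tr$value + 0.4 * tr$t_ms / 1000
  rec <- detrend_poly(drifted, order = 1)
  b0 <- beat_params(tr, detect_beats(tr))
  b1 <- beat_params(tibble::tibble(t_ms = tr$t_ms, value = rec),
                    detect_beats(tibble::tibble(t_ms = tr$t_ms, value = rec)))
  expect_equal(b1$amplitude, b0$amplitude, tolerance = 0.02)
  # degenerate input rejected
  expect_error(detrend_poly(rnorm(3), order = 3),
               class = "atrialmap_preprocess_error")
})

test_that("the conditioning chain records its fixed order", {
  prep <- small_prep(seed = 1)
  mov <- record_preparation(prep, pacing_hz = 3, duration_ms = 700)
  cond <- preprocess_movie(mov)
  expect_equal(cond$provenance$steps,
               c("mask_background", "dff", "spatial_bin", "invert",
                 "fft_lowpass", "detrend_poly"))
  expect_equal(cond$provenance$cutoff_hz, 10)
  expect_equal(cond$provenance$poly_order, 3)
  expect_true(all(is.finite(px(cond$dff, cond$mask))))
})

test_that("binning, inversion and low-pass are linear operators", {
  set.seed(42)
  d <- c(32, 4, 4)
  x <- array(rnorm(prod(d)), d)
  y <- array(rnorm(prod(d)), d)
  a <- 1.7
  b <- -0.6
  for (op in list(spatial_bin, invert_signal, fft_lowpass)) {
    lhs <- op(make_cond(a * x + b * y, frame_interval_ms = 5))$dff
    rhs <- a * op(make_cond(x, frame_interval_ms = 5))$dff +
      b * op(make_cond(y, frame_interval_ms = 5))$dff
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("conditioned traces match the membrane potential on clean movies", {
  g <- recording_window("uniform", pixel_pitch_um = 240)
  cfg <- sim_config("atrial_like", pacing_hz = 2.5, duration_ms = 2200,
                    frame_interval_ms = 5, jitter_seed = 2)
  vm <- simulate_tissue(g, cfg)
  mov <- render_fluorescence(vm, noise_sd = 0, drift_coeffs = numeric(0))
  cond <- preprocess_movie(mov)
  # manual ROIs clear of the stimulus strip
  rois <- tibble::tibble(roi = 1:3, row = 10L,
                         col = sapply(c(0.5, 1.6, 2.7), function(x) {
                           which.min(abs(g$x_mm - x))
                         }),
                         size = 3L)
  traces <- extract_traces(cond, rois)
  for (id in rois$roi) {
    r <- rois[rois$roi == id, ]
    tr <- traces$value[traces$roi == id]
    # ground truth over the same 3x3 footprint the binned trace averages
    ri <- (r$row - 1):(r$row + 1)
    ci <- (r$col - 1):(r$col + 1)
    truth <- apply(vm$vm[, ri, ci, drop = FALSE], 1, mean)
    expect_gt(cor(tr, truth), 0.99)
  }
})
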
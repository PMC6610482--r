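test_that("a synchronous flash gives a uniform map with zero total time", {
  arr <- array(0, dim = c(30, 4, 4))
  arr[15, , ] <- 1
  cond <- make_cond(arr, frame_interval_ms = 10)
  m <- activation_map(cond, c(0, 290))
  expect_true(all(m == 140))
  expect_equal(attr(m, "total_activation_ms"), 0)
  expect_error(activation_map(cond, c(100, 105)),
               class = "atrialmap_conduction_error")
})

test_that("a planar wave's activation ramp recovers the set speed", {
  # analytic pulse moving at 0.2 mm/ms over a 3 mm window (0.12 mm pitch)
  speed <- 0.2
  dt <- 2
  W <- 25
  Tn <- 120
  arr <- array(0, dim = c(Tn, 3, W))
  for (j in 1:W) {
    delay <- (j - 1) * 0.12 / speed
    tt <- (seq_len(Tn) - 1) * dt
    arr[, , j] <- matrix(rep(exp(-((tt - 60 - delay) / 12)^2), each = 3),
                         nrow = Tn, byrow = TRUE)
  }
  cond <- make_cond(arr, frame_interval_ms = dt)
  m <- activation_map(cond, c(20, 160))
  times <- colMeans(unclass(m))
  fit <- coef(lm(times ~ I((1:W) * 0.12)))
  expect_equal(unname(fit[2]), 1 / speed, tolerance = 0.05)
  expect_equal(attr(m, "total_activation_ms"), (W - 1) * 0.12 / speed,
               tolerance = 0.1)
})

test_that("late repolarization pickup is not read as activation", {
  # monotone decay within the window (tail of a previous OAP): undefined
  arr <- array(0, dim = c(40, 2, 2))
  arr[, 1, 1] <- c(seq(1, 0, length.out = 20), rep(0, 20))
  arr[, 2, 2] <- c(rep(0, 10), 1, rep(0, 29)) # real beat inside the window
  cond <- make_cond(arr, frame_interval_ms = 10)
  m <- activation_map(cond, c(0, 390))
  expect_true(is.na(m[1, 1]))
  expect_equal(m[2, 2], 100)
})

test_that("conduction outcomes follow the stimulus-matching rules", {
  stim <- seq(0, 1800, by = 200)
  beat_at <- function(lag) stim + lag
  # 10 stimuli, 10 strand and distal beats each: maintained 1:1
  out <- classify_conduction(stim, beat_at(40),
                             replicate(5, beat_at(60), simplify = FALSE))
  expect_equal(out$category, "maintained")
  expect_equal(out$pattern, "one_to_one")
  # distal ROIs follow every other stimulus: impaired 2:1
  out2 <- classify_conduction(stim, beat_at(40),
                              replicate(5, beat_at(60)[c(TRUE, FALSE)],
                                        simplify = FALSE))
  expect_equal(out2$category, "impaired")
  expect_equal(out2$pattern, "two_to_one")
  # strand follows only 6 of 10: local capture failure
  out3 <- classify_conduction(stim, beat_at(40)[1:6],
                              replicate(5, beat_at(60), simplify = FALSE))
  expect_equal(out3$category, "no_capture")
  expect_equal(out3$pattern, "none")
  # nothing distal at all: omnidirectional
  out4 <- classify_conduction(stim, beat_at(40),
                              replicate(5, numeric(0), simplify = FALSE))
  expect_equal(out4$pattern, "omnidirectional")
  # one lateral side silent: unidirectional
  out5 <- classify_conduction(
    stim, beat_at(40),
    list(beat_at(60), beat_at(60), numeric(0), numeric(0)),
    distal_y_mm = c(1, 1.2, -1, -1.2)
  )
  expect_equal(out5$pattern, "unidirectional")
  expect_error(classify_conduction(stim, NULL, list(beat_at(60))),
               class = "atrialmap_conduction_error")
})

test_that("block patterns are classified from activation-map sectors", {
  g <- recording_window("isthmus", pixel_pitch_um = 120)
  distal <- g$zones == 3L
  xm <- matrix(g$x_mm, nrow(distal), ncol(distal), byrow = TRUE)
  ym <- matrix(g$y_mm, nrow(distal), ncol(distal))
  mk_map <- function(active) {
    m <- matrix(NA_real_, nrow(distal), ncol(distal))
    m[active] <- 50
    structure(m, class = "activation_map", window = c(0, 100),
              total_activation_ms = 0)
  }
  none <- mk_map(distal & FALSE)
  all_d <- mk_map(distal)
  upper_half <- mk_map(distal & ym > 0)
  theta <- atan2(ym, pmax(xm, 1e-9))
  flanks <- mk_map(distal & abs(theta) > pi / 6)

  expect_equal(classify_block_pattern(list(none, none), g)$pattern,
               "omnidirectional")
  expect_equal(classify_block_pattern(list(upper_half), g)$pattern,
               "unidirectional")
  expect_equal(classify_block_pattern(list(flanks), g)$pattern, "regional")
  out <- classify_block_pattern(list(all_d, none, all_d, none), g)
  expect_equal(out$pattern, "two_to_one")
  gu <- recording_window("uniform", pixel_pitch_um = 120)
  gu$zones[gu$zones == 3L] <- 2L
  expect_error(classify_block_pattern(list(none), gu),
               class = "atrialmap_conduction_error")
})

test_that("success tables apply carry-forward and fixed rounding", {
  freqs <- c(5, 5.5, 6)
  mk <- function(prep, cats) {
    tibble::tibble(group = "isthmus", prep = prep, freq_hz = freqs,
                   category = cats)
  }
  # all maintained everywhere: 100.0 at each frequency
  all_m <- dplyr::bind_rows(lapply(1:4, function(p) {
    mk(p, rep("maintained", 3))
  }))
  st <- success_table(all_m)
  expect_true(all(st$success_rate == 100))
  # {M, I, I, I} at 6 Hz: 25.0
  mixed <- dplyr::bind_rows(
    mk(1, c("maintained", "maintained", "maintained")),
    mk(2, c("maintained", "impaired", "impaired")),
    mk(3, c("maintained", "maintained", "impaired")),
    mk(4, c("impaired", "impaired", "impaired"))
  )
  st2 <- success_table(mixed)
  expect_equal(st2$success_rate[st2$freq_hz == 6], 25)
  # a spurious 1:1 after failure is counted impaired (carry-forward)
  spur <- mk(1, c("impaired", "maintained", "maintained"))
  st3 <- success_table(spur)
  expect_equal(st3$maintained, c(0, 0, 0))
  # success rows are non-increasing in frequency after carry-forward
  set.seed(1)
  for (k in 1:20) {
    cats <- sample(c("maintained", "impaired"), 12, replace = TRUE)
    rand <- dplyr::bind_rows(lapply(1:4, function(p) {
      mk(p, cats[(p - 1) * 3 + 1:3])
    }))
    rates <- success_table(rand)$success_rate
    expect_true(all(diff(rates) <= 0))
  }
  # 2/3 prints as 66.7
  two3 <- dplyr::bind_rows(
    mk(1, rep("maintained", 3)), mk(2, rep("maintained", 3)),
    mk(3, rep("impaired", 3))
  )
  expect_equal(success_table(two3)$success_rate, rep(66.7, 3))
  # inconsistent sweep grids within a group: error
  bad <- dplyr::bind_rows(mk(1, rep("maintained", 3)),
                          tibble::tibble(group = "isthmus", prep = 2,
                                         freq_hz = c(5, 6, 7),
                                         category = rep("maintained", 3)))
  expect_error(success_table(bad), class = "atrialmap_conduction_error")
})

test_that("Fisher p-values equal exhaustive enumeration for n <= 10", {
  # closed-form check: (3 of 3) vs (0 of 4) has p = 1/35
  expect_equal(fisher_success(3, 3, 0, 4), 1 / 35, tolerance = 1e-12)
  expect_equal(fisher_success(2, 4, 2, 4), 1)
  expect_equal(fisher_success(0, 3, 0, 4), 1)
  # exhaustive enumeration over all tables with fixed margins
  enum_p <- function(a, na, b, nb) {
    m <- a + b
    lo <- max(0, m - nb)
    hi <- min(na, m)
    probs <- vapply(lo:hi, function(x) {
      choose(na, x) * choose(nb, m - x) / choose(na + nb, m)
    }, numeric(1))
    obs <- probs[a - lo + 1]
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  set.seed(2)
  for (k in 1:25) {
    na <- sample(1:10, 1)
    nb <- sample(1:10, 1)
    a <- sample(0:na, 1)
    b <- sample(0:nb, 1)
    expect_equal(fisher_success(a, na, b, nb), enum_p(a, na, b, nb),
                 tolerance = 1e-9)
  }
  expect_error(fisher_success(1, 0, 0, 4),
               class = "atrialmap_conduction_error")
  expect_error(fisher_success(5, 4, 0, 4),
               class = "atrialmap_conduction_error")
})
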
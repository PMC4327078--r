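test_that("bandpass filter has the designed frequency response", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  steady <- function(y) max(abs(y[round(length(y) * 0.3):round(length(y) * 0.7)]))

  dc <- bandpass_filter(rep(1, length(t)), fs)
  expect_lt(steady(dc), 0.01)

  mid <- bandpass_filter(sin(2 * pi * 10 * t), fs)
  expect_gt(steady(mid), 0.9)
  expect_lt(steady(mid), 1.1)

  high <- bandpass_filter(sin(2 * pi * 100 * t), fs)
  expect_lt(steady(high), 0.1)
})

test_that("bandpass filter validates inputs and preserves length", {
  expect_error(bandpass_filter(numeric(0), 1000),
               class = "ecgmcda_empty_input_error")
  expect_error(bandpass_filter(rnorm(100), fs = 100),
               class = "ecgmcda_parameter_error")
  x <- rnorm(777)
  expect_length(bandpass_filter(x, 500), 777)
})

test_that("derivative filter matches the five-point kernel", {
  # constant -> zero
  expect_equal(derivative_filter(rep(3, 50)), rep(0, 50))
  # ramp of slope 2 per sample -> constant 2 in the interior
  ramp <- derivative_filter(2 * (1:50))
  expect_equal(ramp[3:48], rep(2, 46))
  # impulse response = (1, 2, 0, -2, -1) / 8 around the impulse
  x <- rep(0, 21); x[11] <- 1
  y <- derivative_filter(x)
  expect_equal(y[9:13], c(1, 2, 0, -2, -1) / 8)
  expect_error(derivative_filter(1:4), class = "ecgmcda_parameter_error")
})

test_that("squaring and integration behave like a trailing mean of squares", {
  fs <- 100
  # all ones -> all ones for any window
  expect_equal(square_and_integrate(rep(1, 40), fs, window = 0.05),
               rep(1, 40))
  # impulse far from the edge -> rectangular pulse of height 1/N, width N
  n_win <- round(0.05 * fs)  # 5 samples
  x <- rep(0, 40); x[20] <- 1
  y <- square_and_integrate(x, fs, window = 0.05)
  expect_equal(y[20:24], rep(1 / n_win, n_win))
  expect_equal(y[c(1:19, 25:40)], rep(0, 35))
  # sign invariance and non-negativity
  z <- rnorm(200)
  expect_equal(square_and_integrate(z, fs), square_and_integrate(-z, fs))
  expect_true(all(square_and_integrate(z, fs) >= 0))
  expect_length(square_and_integrate(z, fs, 0.15), 200)
  expect_error(square_and_integrate(z, fs, window = 0),
               class = "ecgmcda_parameter_error")
})

test_that("detected R peaks match generator truth within 10 ms", {
  p <- disease_profile(hr_mean = 60, rr_jitter = 0)  # R every 1.0 s
  seg <- generate_segment(p, duration = 30, fs = 1000, seed = 17)
  beats <- detect_beats(seg$samples, seg$fs)
  det <- (beats$r_index - 1) / seg$fs
  # every truth peak not lost to the record edge has a detection within 10 ms
  interior <- seg$truth[seg$truth > 0.2 & seg$truth < seg$duration - 0.2]
  err <- vapply(interior, function(t) min(abs(det - t)), numeric(1))
  expect_lt(max(err), 0.010)
  expect_gte(nrow(beats), 28)
  expect_lte(nrow(beats), 31)
})

test_that("beat detection handles degenerate inputs", {
  expect_identical(nrow(detect_beats(rep(0, 30 * 500), 500)), 0L)
  expect_error(detect_beats(rnorm(100), 500), class = "ecgmcda_parameter_error")
})

test_that("fiducials satisfy their ordering and amplitude invariants", {
  for (nm in c("healthy", "bundle_branch_block", "dysrhythmia_brady")) {
    seg <- generate_segment(default_profiles()[[nm]], duration = 20,
                            fs = 500, seed = 21)
    b <- detect_beats(seg$samples, seg$fs)
    expect_gt(nrow(b), 3)
    expect_true(all(b$qrs_onset_index <= b$q_index))
    expect_true(all(b$q_index < b$r_index))
    expect_true(all(b$r_index < b$s_index))
    expect_true(all(b$s_index <= b$qrs_offset_index))
    expect_true(all(b$r_amp >= b$q_amp & b$r_amp >= b$s_amp))
    expect_true(all(diff(b$r_index) >= 0.2 * seg$fs))
  }
})

test_that("detector recall and precision reach 0.95 on default profiles", {
  for (nm in names(default_profiles())) {
    seg <- generate_segment(default_profiles()[[nm]], duration = 30,
                            fs = 1000, seed = 33)
    beats <- detect_beats(seg$samples, seg$fs)
    m <- match_beats((beats$r_index - 1) / seg$fs, seg$truth, tol = 0.05)
    expect_gte(m$recall, 0.95)
    expect_gte(m$precision, 0.95)
  }
})
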
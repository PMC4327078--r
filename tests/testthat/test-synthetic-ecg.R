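test_that("segment generation is seeded and deterministic", {
  p <- disease_profile()
  a <- generate_segment(p, duration = 10, fs = 500, seed = 123)
  b <- generate_segment(p, duration = 10, fs = 500, seed = 123)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)
  c <- generate_segment(p, duration = 10, fs = 500, seed = 124)
  expect_false(identical(a$samples, c$samples))
})

test_that("segments respect their structural invariants", {
  for (p in default_profiles()) {
    seg <- generate_segment(p, duration = 12, fs = 500, seed = 3)
    expect_length(seg$samples, round(500 * 12))
    expect_true(all(is.finite(seg$samples)))
    expect_true(all(diff(seg$truth) > 0))
    expect_true(all(seg$truth > 0 & seg$truth < seg$duration))
  }
})

test_that("invalid profiles and parameters are rejected by name", {
  expect_error(disease_profile(hr_mean = 300), class = "ecgmcda_parameter_error")
  expect_error(disease_profile(hr_mean = 300), "hr_mean")
  expect_error(disease_profile(rr_jitter = 0.7), "rr_jitter")
  expect_error(disease_profile(qrs_duration = 0.5, qt_duration = 0.4),
               "qt_duration")
  expect_error(generate_segment(disease_profile(), fs = 100),
               class = "ecgmcda_parameter_error")
  expect_error(generate_segment(disease_profile(), duration = -1),
               class = "ecgmcda_parameter_error")
})

test_that("bundle branch block segments yield wide measured QRS complexes", {
  p <- default_profiles()$bundle_branch_block
  widths <- unlist(lapply(1:3, function(s) {
    seg <- generate_segment(p, duration = 30, fs = 1000, seed = s)
    beats <- detect_beats(seg$samples, seg$fs)
    (beats$qrs_offset_index - beats$qrs_onset_index) / seg$fs
  }))
  expect_gte(mean(widths > 0.12), 0.95)
})

test_that("tachycardic profile gives the expected RR interval in truth", {
  p <- disease_profile("dysrhythmia", hr_mean = 120, qt_duration = 0.48)
  seg <- generate_segment(p, duration = 30, fs = 500, seed = 2)
  expect_equal(mean(diff(seg$truth)), 0.5, tolerance = 0.02 / 0.5)
})

test_that("dataset generation honors per-class counts and durations", {
  counts <- c(healthy = 6, bundle_branch_block = 2, myocardial_infarction = 2,
              heart_failure = 2, dysrhythmia = 2)
  segs <- generate_dataset(counts, duration = 8, fs = 500, seed = 4)
  labels <- vapply(segs, function(s) s$label, character(1))
  expect_identical(as.integer(table(labels)[names(counts)]),
                   as.integer(counts))
  expect_true(all(vapply(segs, function(s) s$duration, numeric(1)) == 8))
  # class balance: class 1 total equals the sum of disease counts
  expect_identical(sum(labels != "healthy"), sum(as.integer(counts[-1])))

  expect_identical(generate_dataset(counts * 0L, seed = 1), list())
  expect_error(generate_dataset(c(healthy = -1)), class = "ecgmcda_parameter_error")
})

test_that("default composition matches the balanced study design", {
  counts <- default_counts()
  expect_identical(sum(counts["healthy"]), sum(counts) - counts[["healthy"]])
  expect_identical(unname(counts[["healthy"]]), 500L)
  expect_true(all(counts[setdiff(names(counts), "healthy")] == 125L))
})

test_that("healthy and BBB QRS-duration distributions are separated", {
  profs <- default_profiles()
  gap <- profs$bundle_branch_block$qrs_duration - profs$healthy$qrs_duration
  measure <- function(p) {
    seg <- generate_segment(p, duration = 30, fs = 1000, seed = 8)
    beats <- detect_beats(seg$samples, seg$fs)
    mean((beats$qrs_offset_index - beats$qrs_onset_index) / seg$fs)
  }
  diff_measured <- measure(profs$bundle_branch_block) - measure(profs$healthy)
  expect_gte(diff_measured, gap - 0.015)
})

test_that("segment CSV round-trips through the interchange format", {
  seg <- generate_segment(disease_profile(), duration = 5, fs = 500, seed = 6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segment_csv(seg, path)
  back <- read_segment_csv(path, label = "healthy")
  expect_equal(back$samples, seg$samples)
  expect_equal(back$fs, seg$fs, tolerance = 1e-9)
})

test_that("survey matrices are valid, seeded, and encode the archetype", {
  ms <- generate_survey_matrices(25, "speed", noise = 0.3, seed = 31)
  expect_length(ms, 25)
  for (A in ms) expect_silent(validate_pairwise(A))
  ms2 <- generate_survey_matrices(25, "speed", noise = 0.3, seed = 31)
  expect_identical(ms, ms2)

  # zero noise: template exactly; Te must outweigh Tr after aggregation
  w <- derive_weights(generate_survey_matrices(200, "speed", noise = 0,
                                               seed = 1))
  expect_gt(w$weights[["Te"]], w$weights[["Tr"]])
  expect_error(generate_survey_matrices(0), class = "ecgmcda_parameter_error")
})
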
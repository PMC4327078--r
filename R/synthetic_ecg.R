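# Synthetic disease-conditioned ECG generation.
#
# Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) placed on a
# jittered RR grid, plus white baseline noise. The Q and S bumps are
# positioned so that the rendered complex spans the profile's QRS duration:
# with sigma = q_width, the Q centre sits at R - (qrs/2 - 2.5 sigma), i.e.
# the bump has effectively decayed at the nominal QRS onset.

# Gaussian bump added in place over a +/- 4 sigma window.
add_bump <- function(samples, fs, t_center, amp, sigma) {
  n <- length(samples)
  lo <- max(1L, floor((t_center - 4 * sigma) * fs) + 1L)
  hi <- min(n, ceiling((t_center + 4 * sigma) * fs) + 1L)
  if (lo > hi) return(samples)
  t <- (seq.int(lo, hi) - 1) / fs
  samples[lo:hi] <- samples[lo:hi] + amp * exp(-(t - t_center)^2 / (2 * sigma^2))
  samples
}

#' Generate one synthetic ECG segment
#'
#' Renders a single-lead ECG-like waveform of the requested duration: R peaks
#' are laid out on a jittered RR grid derived from the profile's heart rate,
#' each beat is drawn as a P-QRS-T sum of Gaussian bumps, and Gaussian
#' baseline noise is added. The true simulated R-peak times are returned in
#' the `truth` field, which downstream detector benchmarks use as ground
#' truth.
#'
#' @param profile A [disease_profile()].
#' @param duration Segment length in seconds (default 30).
#' @param fs Sampling rate in Hz, at least 250 (default 1000).
#' @param seed Integer seed; identical arguments give bit-identical output.
#' @return An object of class `ecg_segment`: a list with `samples` (mV),
#'   `fs`, `duration`, `label` (the profile name) and `truth` (R-peak times
#'   in seconds, strictly increasing).
#' @examples
#' seg <- generate_segment(disease_profile(), duration = 10, fs = 500, seed = 1)
#' length(seg$samples)  # 5000
#' @export
generate_segment <- function(profile, duration = 30, fs = 1000, seed = 1) {
  validate_profile(profile)
  if (!is.numeric(duration) || duration <= 0) {
    stop_ecgmcda("ecgmcda_parameter_error", "duration must be positive")
  }
  if (!is.numeric(fs) || fs < 250) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "fs must be at least 250 Hz (got %g)", fs)
  }
  n <- round(fs * duration)
  rr_mean <- 60 / profile$hr_mean
  with_seed(seed, {
    # Jittered RR grid; intervals truncated away from zero so truth times
    # stay strictly increasing and beats never collide.
    r_times <- numeric(0)
    t <- stats::runif(1, 0.3, 0.3 + rr_mean)
    margin <- 0.5 * profile$qrs_duration + 0.05
    while (t < duration - margin) {
      r_times <- c(r_times, t)
      rr <- stats::rnorm(1, rr_mean, profile$rr_jitter * rr_mean)
      rr <- min(max(rr, 0.3 * rr_mean), 1.7 * rr_mean)
      t <- t + rr
    }
    samples <- numeric(n)
    half_qrs <- profile$qrs_duration / 2
    for (r in r_times) {
      samples <- add_bump(samples, fs, r, profile$r_amp, profile$r_width)
      samples <- add_bump(samples, fs, r - (half_qrs - 2.5 * profile$q_width),
                          profile$q_amp, profile$q_width)
      samples <- add_bump(samples, fs, r + (half_qrs - 2.5 * profile$s_width),
                          profile$s_amp, profile$s_width)
      samples <- add_bump(samples, fs, r - half_qrs - 0.10,
                          profile$p_amp, profile$p_width)
      # T placed so the QT interval (Q onset to T end, end = centre + 2.5
      # sigma) matches the profile.
      samples <- add_bump(samples, fs,
                          r - half_qrs + profile$qt_duration -
                            2.5 * profile$t_width,
                          profile$t_amp, profile$t_width)
    }
    if (profile$noise_sd > 0) {
      samples <- samples + stats::rnorm(n, 0, profile$noise_sd)
    }
    structure(list(samples = samples, fs = fs, duration = duration,
                   label = profile$name, truth = r_times),
              class = "ecg_segment")
  })
}

#' @export
print.ecg_segment <- function(x, ...) {
  cat(sprintf("<ecg_segment> label=%s fs=%g Hz duration=%g s beats=%d\n",
              x$label, x$fs, x$duration, length(x$truth)))
  invisible(x)
}

#' Default dataset composition
#'
#' Per-class segment counts matching the study design: 500 healthy segments
#' against 125 segments of each of four diseases, i.e. a balanced 500 vs 500
#' binary problem.
#'
#' @return Named integer vector of per-class counts.
#' @export
default_counts <- function() {
  c(healthy = 500L, bundle_branch_block = 125L, myocardial_infarction = 125L,
    heart_failure = 125L, dysrhythmia = 125L)
}

#' Generate a labeled synthetic ECG dataset
#'
#' Generates `counts[class]` segments per class. The `dysrhythmia` class is
#' an equal-probability mixture of the tachycardic and bradycardic profile
#' variants, drawn per segment.
#'
#' @param counts Named vector of per-class segment counts (all `>= 0`); see
#'   [default_counts()]. Names must be `healthy` or disease names present in
#'   `profiles` (directly or as `<name>_tachy` / `<name>_brady` variants).
#' @param duration,fs Passed to [generate_segment()].
#' @param profiles Named list of profiles, see [default_profiles()].
#' @param seed Integer seed.
#' @return List of `ecg_segment` objects (possibly empty).
#' @export
generate_dataset <- function(counts = default_counts(), duration = 30,
                             fs = 1000, profiles = default_profiles(),
                             seed = 1) {
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop_ecgmcda("ecgmcda_parameter_error", "counts must be a named vector")
  }
  if (any(counts < 0)) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "negative count for class '%s'",
                 names(counts)[which(counts < 0)[1]])
  }
  plan <- dataset_plan(counts, profiles, seed)
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    seg <- generate_segment(profiles[[plan$profile[i]]], duration, fs,
                            seed = plan$seed[i])
    seg$label <- plan$class[i]
    out[[i]] <- seg
  }
  out
}

# Expand per-class counts into one row per segment with its profile name and
# child seed. Mixture classes (e.g. dysrhythmia) choose a variant per
# segment, seeded.
dataset_plan <- function(counts, profiles, seed) {
  classes <- rep(names(counts), times = counts)
  prof_names <- character(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    if (cl %in% names(profiles)) {
      prof_names[i] <- cl
    } else {
      variants <- names(profiles)[startsWith(names(profiles), paste0(cl, "_"))]
      if (length(variants) == 0) {
        stop_ecgmcda("ecgmcda_parameter_error",
                     "no profile found for class '%s'", cl)
      }
      prof_names[i] <- with_seed(child_seed(seed, i),
                                 sample(variants, 1L))
    }
  }
  data.frame(class = classes, profile = prof_names,
             seed = child_seed(seed, seq_along(classes) + 1e6),
             stringsAsFactors = FALSE)
}

#' Write / read ECG segments as CSV
#'
#' Segments are interchanged as two-column CSV files (`time_s`,
#' `amplitude_mV`), one file per segment, with a manifest CSV
#' (`file,label,fs,duration`) indexing a directory of segments.
#'
#' @param segment An `ecg_segment`.
#' @param path Output CSV path.
#' @return `write_segment_csv` returns `path` invisibly; `read_segment_csv`
#'   returns an `ecg_segment` (with `truth = NULL`, unknown for external
#'   data).
#' @export
write_segment_csv <- function(segment, path) {
  df <- data.frame(time_s = (seq_along(segment$samples) - 1) / segment$fs,
                   amplitude_mV = segment$samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segment_csv
#' @param label Class label to attach to the segment read.
#' @export
read_segment_csv <- function(path, label = NA_character_) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_mV") %in% names(df)) || nrow(df) < 2) {
    stop_ecgmcda("ecgmcda_data_error",
                 "'%s' is not a time_s,amplitude_mV segment CSV", path)
  }
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(samples = df$amplitude_mV, fs = fs,
                 duration = nrow(df) / fs, label = label, truth = NULL),
            class = "ecg_segment")
}

#' @rdname write_segment_csv
#' @param segments List of `ecg_segment` objects.
#' @param dir Output directory (created if missing).
#' @export
write_dataset_csv <- function(segments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("segment_%04d.csv", seq_along(segments))
  for (i in seq_along(segments)) {
    write_segment_csv(segments[[i]], file.path(dir, files[i]))
  }
  manifest <- data.frame(
    file = files,
    label = vapply(segments, function(s) s$label, character(1)),
    fs = vapply(segments, function(s) s$fs, numeric(1)),
    duration = vapply(segments, function(s) s$duration, numeric(1))
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

# --- synthetic respondent survey ------------------------------------------

saaty_values <- function() c(1/9, 1/7, 1/5, 1/3, 1, 3, 5, 7, 9)

# Archetype importance vectors over (OA, Se, Sp, AUC, Tr, Te, Nf). Ratios of
# entries fall on the Saaty scale so the template matrix is consistent.
survey_templates <- function() {
  list(
    # detection speed is the prime concern: the five primary criteria
    # (accuracies and testing time) dominate the secondary Tr and Nf
    speed = c(OA = 5, Se = 5, Sp = 5, AUC = 5, Tr = 1, Te = 5, Nf = 1),
    balanced = c(OA = 1, Se = 1, Sp = 1, AUC = 1, Tr = 1, Te = 1, Nf = 1)
  )
}

#' Generate synthetic respondent pairwise-comparison matrices
#'
#' Emulates a survey in which respondents fill a 7x7 Saaty pairwise
#' comparison matrix over the criteria (OA, Se, Sp, AUC, Tr, Te, Nf). Each
#' respondent starts from a consistent template matrix encoding a priority
#' archetype; with probability `noise` each above-diagonal entry is resampled
#' uniformly from the Saaty scale, and reciprocity is then re-enforced.
#'
#' @param n_respondents Number of matrices to generate (`>= 1`).
#' @param template `"speed"` (accuracy criteria and testing time dominant;
#'   the default) or `"balanced"`, or a length-7 positive importance vector.
#' @param noise Per-entry resampling probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return List of 7x7 matrices, each passing [validate_pairwise()].
#' @export
generate_survey_matrices <- function(n_respondents = 200,
                                     template = "speed",
                                     noise = 0.1, seed = 1) {
  if (!is.numeric(n_respondents) || n_respondents < 1) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "n_respondents must be at least 1 (got %s)",
                 format(n_respondents))
  }
  if (is.character(template)) {
    template <- match.arg(template, names(survey_templates()))
    v <- survey_templates()[[template]]
  } else {
    if (length(template) != 7L || any(template <= 0)) {
      stop_ecgmcda("ecgmcda_parameter_error",
                   "template must be a length-7 positive vector")
    }
    v <- template
  }
  base <- outer(v, v, "/")
  dimnames(base) <- list(criteria_names(), criteria_names())
  sv <- saaty_values()
  # snap consistent ratios to the nearest Saaty value
  base[] <- sv[apply(abs(log(outer(c(base), sv, "/"))), 1, which.min)]
  diag(base) <- 1
  with_seed(seed, {
    lapply(seq_len(n_respondents), function(m) {
      A <- base
      for (i in 1:6) {
        for (j in (i + 1):7) {
          if (stats::runif(1) < noise) A[i, j] <- sample(sv, 1)
          A[j, i] <- 1 / A[i, j]
        }
      }
      A
    })
  })
}
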
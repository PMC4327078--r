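#' Disease profile for the synthetic ECG generator
#'
#' A disease profile parameterizes the synthetic single-lead ECG morphology:
#' heart rate and its beat-to-beat variability, QRS and QT durations, the
#' amplitudes and widths of the five Gaussian sub-waves (P, Q, R, S, T) that
#' form each beat template, and the baseline noise level.
#'
#' The defaults describe a healthy adult resting rhythm. Disease archetypes
#' are derived from it by [default_profiles()]: myocardial infarction with an
#' irregular RR interval, bundle branch block with a widened (> 0.12 s) QRS
#' complex, heart failure with a prolonged QT interval and elevated resting
#' heart rate, and dysrhythmia as tachycardic (120 bpm) or bradycardic
#' (45 bpm) variants.
#'
#' @param name Label for the profile.
#' @param hr_mean Mean heart rate in beats per minute (20--250).
#' @param rr_jitter Relative standard deviation of the RR interval
#'   (dimensionless, in `[0, 0.5)`).
#' @param qrs_duration QRS complex duration in seconds; must satisfy
#'   `0 < qrs_duration < qt_duration < 60 / hr_mean`.
#' @param qt_duration QT interval (Q onset to T end) in seconds.
#' @param p_amp,q_amp,r_amp,s_amp,t_amp Wave amplitudes in mV (Q and S are
#'   conventionally negative).
#' @param p_width,q_width,r_width,s_width,t_width Gaussian widths (sigma) of
#'   the five waves in seconds. `q_width`, `r_width`, `s_width` default to
#'   fixed fractions of `qrs_duration` and `t_width` to a fraction of
#'   `qt_duration`, so the rendered complex scales with the intervals.
#' @param noise_sd Standard deviation of additive Gaussian baseline noise, mV.
#'
#' @return An object of class `disease_profile` (a named list).
#' @examples
#' p <- disease_profile()
#' p$qrs_duration
#' @export
disease_profile <- function(name = "healthy",
                            hr_mean = 75,
                            rr_jitter = 0.03,
                            qrs_duration = 0.09,
                            qt_duration = 0.38,
                            p_amp = 0.12, q_amp = -0.15, r_amp = 1.0,
                            s_amp = -0.25, t_amp = 0.35,
                            p_width = 0.025,
                            q_width = 0.07 * qrs_duration,
                            r_width = 0.13 * qrs_duration,
                            s_width = 0.07 * qrs_duration,
                            t_width = 0.12 * qt_duration,
                            noise_sd = 0.03) {
  profile <- list(
    name = name, hr_mean = hr_mean, rr_jitter = rr_jitter,
    qrs_duration = qrs_duration, qt_duration = qt_duration,
    p_amp = p_amp, q_amp = q_amp, r_amp = r_amp, s_amp = s_amp, t_amp = t_amp,
    p_width = p_width, q_width = q_width, r_width = r_width,
    s_width = s_width, t_width = t_width,
    noise_sd = noise_sd
  )
  class(profile) <- "disease_profile"
  validate_profile(profile)
}

#' @rdname disease_profile
#' @param profile A `disease_profile` object to check.
#' @export
validate_profile <- function(profile) {
  fail <- function(field, fmt, ...) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 paste0("invalid disease profile field '%s': ", fmt),
                 field, ...)
  }
  num_fields <- setdiff(names(profile), "name")
  for (f in num_fields) {
    v <- profile[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      fail(f, "must be a single finite number")
    }
  }
  if (profile$hr_mean < 20 || profile$hr_mean > 250) {
    fail("hr_mean", "%g bpm outside [20, 250]", profile$hr_mean)
  }
  if (profile$rr_jitter < 0 || profile$rr_jitter >= 0.5) {
    fail("rr_jitter", "%g outside [0, 0.5)", profile$rr_jitter)
  }
  if (profile$qrs_duration <= 0) {
    fail("qrs_duration", "must be positive")
  }
  if (profile$qrs_duration >= profile$qt_duration) {
    fail("qt_duration", "QT (%g s) must exceed QRS (%g s)",
         profile$qt_duration, profile$qrs_duration)
  }
  if (profile$qt_duration >= 60 / profile$hr_mean) {
    fail("qt_duration", "QT (%g s) must be below the mean RR interval (%g s)",
         profile$qt_duration, 60 / profile$hr_mean)
  }
  for (f in grep("_width$", num_fields, value = TRUE)) {
    if (profile[[f]] <= 0) fail(f, "must be positive")
  }
  if (profile$noise_sd < 0) fail("noise_sd", "must be non-negative")
  profile
}

#' Default disease profiles
#'
#' Returns the archetype profiles used by [generate_dataset()]. Each disease
#' perturbs the healthy template in the direction its ECG hallmark dictates:
#'
#' * `myocardial_infarction`: irregular heartbeat, `rr_jitter = 0.15`;
#' * `bundle_branch_block`: widened QRS complex, `qrs_duration = 0.14` s;
#' * `heart_failure`: prolonged QT (`0.50` s) with the elevated resting heart
#'   rate (95 bpm) typical of decompensation;
#' * `dysrhythmia_tachy` / `dysrhythmia_brady`: rates outside the 60--100 bpm
#'   band (120 / 45 bpm) with a moderately prolonged QT (0.48 s).
#'
#' @return Named list of `disease_profile` objects.
#' @export
default_profiles <- function() {
  list(
    healthy = disease_profile("healthy"),
    myocardial_infarction = disease_profile("myocardial_infarction",
                                            rr_jitter = 0.15),
    bundle_branch_block = disease_profile("bundle_branch_block",
                                          qrs_duration = 0.14),
    heart_failure = disease_profile("heart_failure",
                                    hr_mean = 95, qt_duration = 0.50),
    dysrhythmia_tachy = disease_profile("dysrhythmia",
                                        hr_mean = 120, qt_duration = 0.48),
    dysrhythmia_brady = disease_profile("dysrhythmia",
                                        hr_mean = 45, qt_duration = 0.48)
  )
}
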
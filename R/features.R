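# Fiducial feature construction and feature-subset bookkeeping.

#' Fixed feature order
#'
#' The 10 fiducial features, in the fixed order used everywhere in the
#' package (feature `k` corresponds to bit `k`, least significant first, of a
#' subset mask): mean and population standard deviation of the Q, R and S
#' amplitudes (mV), of the QRS duration (s), and of the RR interval (s).
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() {
  c("q_amp_mean", "q_amp_sd", "r_amp_mean", "r_amp_sd",
    "s_amp_mean", "s_amp_sd", "qrs_dur_mean", "qrs_dur_sd",
    "rr_mean", "rr_sd")
}

#' Extract the 10-dimensional feature vector from beat fiducials
#'
#' Computes the mean and standard deviation of the Q, R and S amplitudes and
#' the QRS duration over beats, and of the RR interval over consecutive
#' R-to-R differences. Standard deviations are population (divide-by-n), so
#' identical beats give exact zeros. Beat order does not matter: RR intervals
#' are computed from sorted R indices.
#'
#' @param beats Fiducial `data.frame` from [detect_beats()] with at least 3
#'   beats (so the RR statistics are defined on at least 2 intervals).
#' @param fs Sampling rate in Hz, used to convert indices to seconds.
#' @param label Optional class label carried into the result.
#' @param segment_id Identifier used in error messages.
#' @return One-row `data.frame` with the columns of [feature_names()] plus
#'   `label`.
#' @export
extract_features <- function(beats, fs, label = NA_character_,
                             segment_id = "segment") {
  if (!is.data.frame(beats) || nrow(beats) < 3) {
    stop_ecgmcda("ecgmcda_insufficient_beats_error",
                 "%s: need at least 3 beats to build features (got %d)",
                 segment_id, if (is.data.frame(beats)) nrow(beats) else 0L)
  }
  qrs_dur <- (beats$qrs_offset_index - beats$qrs_onset_index) / fs
  rr <- diff(sort(beats$r_index)) / fs
  out <- data.frame(
    q_amp_mean = mean(beats$q_amp), q_amp_sd = sd_pop(beats$q_amp),
    r_amp_mean = mean(beats$r_amp), r_amp_sd = sd_pop(beats$r_amp),
    s_amp_mean = mean(beats$s_amp), s_amp_sd = sd_pop(beats$s_amp),
    qrs_dur_mean = mean(qrs_dur), qrs_dur_sd = sd_pop(qrs_dur),
    rr_mean = mean(rr), rr_sd = sd_pop(rr)
  )
  out$label <- label
  out
}

#' Feature-subset masks
#'
#' A subset of the 10 features is encoded as an integer mask in `[1, 1023]`:
#' bit `k` (least significant first) includes feature `k` of
#' [feature_names()]. `mask_features()` lists the included names;
#' `mask_size()` counts them; `subset_features()` extracts them from a
#' feature vector.
#'
#' @param mask Integer in `[1, 1023]`.
#' @return `mask_features()`: character vector; `mask_size()`: integer.
#' @examples
#' mask_features(1)     # first feature only
#' mask_size(1023)      # all 10
#' @export
mask_features <- function(mask) {
  feature_names()[mask_bits(mask)]
}

#' @rdname mask_features
#' @export
mask_size <- function(mask) {
  length(mask_bits(mask))
}

mask_bits <- function(mask, n_features = 10L) {
  if (!is.numeric(mask) || length(mask) != 1L || is.na(mask) ||
      mask != trunc(mask) || mask < 1 || mask > 2^n_features - 1) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "mask must be an integer in [1, %d] (got %s)",
                 2^n_features - 1, format(mask))
  }
  which(bitwAnd(as.integer(mask), bitwShiftL(1L, 0:(n_features - 1L))) != 0L)
}

#' @rdname mask_features
#' @param vector One-row feature `data.frame` (or named vector) containing
#'   the columns of [feature_names()].
#' @export
subset_features <- function(vector, mask) {
  keep <- mask_features(mask)
  if (is.data.frame(vector)) vector[, keep, drop = FALSE]
  else vector[keep]
}

#' Build a feature table from ECG segments
#'
#' Runs [detect_beats()] and [extract_features()] on each segment and stacks
#' the results. The `label` column is the binary class (`healthy` vs
#' `unhealthy`); the original per-disease label is kept in `subclass`.
#'
#' @param segments List of `ecg_segment` objects.
#' @return `data.frame` with the 10 feature columns, `label` and `subclass`.
#' @export
build_feature_table <- function(segments) {
  rows <- lapply(seq_along(segments), function(i) {
    seg <- segments[[i]]
    beats <- detect_beats(seg$samples, seg$fs)
    row <- extract_features(beats, seg$fs, label = seg$label,
                            segment_id = sprintf("segment %d", i))
    row$subclass <- seg$label
    row$label <- if (identical(seg$label, "healthy")) "healthy" else "unhealthy"
    row
  })
  do.call(rbind, rows)
}

#' Write / read the feature-table interchange CSV
#'
#' One row per segment, the 10 feature columns in fixed order, then `label`
#' (and `subclass` if present). This is the interchange format between the
#' feature stage and the classifier sweep.
#'
#' @param table Feature `data.frame`.
#' @param path CSV path.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c(feature_names(), "label"), names(df))
  if (length(missing)) {
    stop_ecgmcda("ecgmcda_data_error", "feature CSV '%s' lacks columns: %s",
                 path, paste(missing, collapse = ", "))
  }
  df
}
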
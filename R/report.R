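# Comparison report: percentage change of each criterion between a
# traditional classifier (TC) and the new, MCDA-selected classifier (NC).

#' Criteria record for one classification method
#'
#' @param label Method name.
#' @param oa,se,sp,auc Rates in `[0, 1]`.
#' @param tr,te Training / testing times in seconds (`>= 0`).
#' @param nf Number of features (`>= 1`).
#' @return Object of class `method_criteria`.
#' @export
method_criteria <- function(label, oa, se, sp, auc, tr, te, nf) {
  rates <- c(oa = oa, se = se, sp = sp, auc = auc)
  if (any(rates < 0 | rates > 1)) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "'%s': rate criterion outside [0, 1]", label)
  }
  if (tr < 0 || te < 0) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "'%s': times must be non-negative", label)
  }
  if (nf < 1) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "'%s': number of features must be at least 1", label)
  }
  structure(list(label = label, oa = oa, se = se, sp = sp, auc = auc,
                 tr = tr, te = te, nf = nf),
            class = "method_criteria")
}

#' Percentage change between two criterion values
#'
#' `100 * (nc - tc) / tc`: the relative change of the new classifier's value
#' with respect to the traditional classifier's. Satisfies
#' `percent_change(tc, nc) / 100 + 1 == nc / tc` exactly.
#'
#' @param tc_value Traditional (reference) value; must be non-zero.
#' @param nc_value New value.
#' @return Percentage change (unrounded; the report layer rounds to 3
#'   decimals, half away from zero).
#' @export
percent_change <- function(tc_value, nc_value) {
  if (!is.numeric(tc_value) || tc_value == 0) {
    stop_ecgmcda("ecgmcda_division_error",
                 "reference value must be non-zero to compute a percentage change")
  }
  100 * (nc_value - tc_value) / tc_value
}

#' Seven-criterion comparison report
#'
#' One row per criterion in the standard order (OA, Se, Sp, AUC, Tr, Te,
#' Nf), giving the TC value, the NC value and the percentage change rounded
#' to 3 decimals (half away from zero). A zero TC value flags the row
#' (`flag = TRUE`, `pct_change = NA`) rather than failing.
#'
#' @param tc,nc `method_criteria` records.
#' @return `data.frame` with columns `criterion`, `tc`, `nc`, `pct_change`,
#'   `flag`.
#' @export
comparison_report <- function(tc, nc) {
  fields <- c("oa", "se", "sp", "auc", "tr", "te", "nf")
  rows <- lapply(seq_along(fields), function(i) {
    tcv <- tc[[fields[i]]]; ncv <- nc[[fields[i]]]
    if (tcv == 0) {
      data.frame(criterion = criteria_names()[i], tc = tcv, nc = ncv,
                 pct_change = NA_real_, flag = TRUE)
    } else {
      data.frame(criterion = criteria_names()[i], tc = tcv, nc = ncv,
                 pct_change = round_half_away(percent_change(tcv, ncv), 3),
                 flag = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Format a comparison report as text
#'
#' @param report Output of [comparison_report()].
#' @param tc_label,nc_label Column headings.
#' @return Character vector of report lines.
#' @export
format_comparison <- function(report, tc_label = "TC", nc_label = "NC") {
  header <- sprintf("%-9s %12s %12s %12s", "criterion", tc_label, nc_label,
                    "change (%)")
  lines <- sprintf("%-9s %12g %12g %12s", report$criterion, report$tc,
                   report$nc,
                   ifelse(report$flag, "n/a",
                          formatC(report$pct_change, format = "f", digits = 3)))
  c(header, lines)
}

#' Published benchmark criteria of three traditional classifiers
#'
#' Bundled reference values used by the comparison report: for each of three
#' traditional ECG classifiers from the literature (a two-layer hidden
#' Markov model arrhythmia classifier, a cross-wavelet myocardial-infarction
#' classifier and a 13-feature ventricular-fibrillation SVM), the seven
#' criteria of the traditional method (`tc`) and of the MCDA-selected new
#' classifier evaluated on the same data (`nc`). These printed values are
#' consumed as input data; the traditional methods themselves are not
#' re-implemented.
#'
#' @return Named list of three `list(tc = , nc = )` pairs of
#'   [method_criteria()] records.
#' @export
reference_comparisons <- function() {
  list(
    two_layer_hmm = list(
      tc = method_criteria("two-layer HMM", oa = 0.992, se = 0.993,
                           sp = 0.992, auc = 0.971, tr = 3.7, te = 2.7,
                           nf = 3),
      nc = method_criteria("MCDA-selected (vs two-layer HMM)", oa = 0.987,
                           se = 0.99, sp = 0.984, auc = 0.966, tr = 3.4,
                           te = 1.9, nf = 2)
    ),
    cross_wavelet = list(
      tc = method_criteria("cross-wavelet classifier", oa = 0.976, se = 0.973,
                           sp = 0.988, auc = 0.949, tr = 6.2, te = 4.1,
                           nf = 6),
      nc = method_criteria("MCDA-selected (vs cross-wavelet)", oa = 0.966,
                           se = 0.978, sp = 0.958, auc = 0.933, tr = 5.6,
                           te = 2.8, nf = 4)
    ),
    svm_13_features = list(
      tc = method_criteria("13-feature SVM", oa = 0.952, se = 0.951,
                           sp = 0.951, auc = 0.943, tr = 4.8, te = 2.7,
                           nf = 13),
      nc = method_criteria("MCDA-selected (vs 13-feature SVM)", oa = 0.947,
                           se = 0.952, sp = 0.942, auc = 0.937, tr = 4.5,
                           te = 1.6, nf = 10)
    )
  )
}
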
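# Analytic hierarchy process over the seven performance criteria.
#
# Respondent pairwise-comparison matrices are validated against the Saaty
# scale, column-normalized, and averaged row-wise into per-respondent
# priority vectors. Vectors from respondents whose matrices pass the
# consistency screen are averaged into the group weight vector, which scores
# the min-max-normalized criteria of every configuration; the configuration
# with the highest score is selected.

#' Criteria order and optimization sense
#'
#' The seven performance criteria in fixed order: overall accuracy (OA),
#' sensitivity (Se), specificity (Sp), area under the ROC curve (AUC),
#' training time (Tr, s), testing time (Te, s) and number of features (Nf).
#' The first four are benefit criteria (larger is better); Tr, Te and Nf are
#' cost criteria (smaller is better).
#'
#' @return `criteria_names()`: character vector of length 7;
#'   `criteria_senses()`: character vector of `"benefit"` / `"cost"`.
#' @export
criteria_names <- function() c("OA", "Se", "Sp", "AUC", "Tr", "Te", "Nf")

#' @rdname criteria_names
#' @export
criteria_senses <- function() {
  c(OA = "benefit", Se = "benefit", Sp = "benefit", AUC = "benefit",
    Tr = "cost", Te = "cost", Nf = "cost")
}

# column names of the sweep criteria table, in criteria order
criteria_columns <- function() c("oa", "se", "sp", "auc", "tr_s", "te_s", "nf")

#' Validate a Saaty pairwise-comparison matrix
#'
#' Checks that the matrix is square and positive with a unit diagonal, that
#' it is reciprocal (`a[j,i] = 1/a[i,j]` within relative tolerance 1e-9), and
#' that every off-diagonal entry lies on the Saaty scale
#' `{1/9, 1/7, 1/5, 1/3, 1, 3, 5, 7, 9}`.
#'
#' @param A Numeric matrix (7x7 in the standard criteria layout).
#' @param tol Relative tolerance for the reciprocity and scale checks.
#' @return `A`, invisibly validated (errors name the offending entry).
#' @export
validate_pairwise <- function(A, tol = 1e-9) {
  if (!is.matrix(A) || !is.numeric(A) || nrow(A) != ncol(A) || nrow(A) < 2) {
    stop_ecgmcda("ecgmcda_validation_error",
                 "pairwise comparison input must be a square numeric matrix")
  }
  n <- nrow(A)
  if (any(!is.finite(A)) || any(A <= 0)) {
    bad <- which(!is.finite(A) | A <= 0, arr.ind = TRUE)[1, ]
    stop_ecgmcda("ecgmcda_validation_error",
                 "non-positive or non-finite entry at (%d, %d)",
                 bad[1], bad[2])
  }
  for (i in seq_len(n)) {
    if (abs(A[i, i] - 1) > tol) {
      stop_ecgmcda("ecgmcda_validation_error",
                   "diagonal entry at (%d, %d) must be 1 (got %g)",
                   i, i, A[i, i])
    }
  }
  sv <- saaty_values()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(A[j, i] * A[i, j] - 1) > tol * max(1, A[i, j])) {
        stop_ecgmcda("ecgmcda_validation_error",
                     "reciprocity broken at (%d, %d): a[%d,%d]=%g but a[%d,%d]=%g",
                     j, i, i, j, A[i, j], j, i, A[j, i])
      }
      if (min(abs(A[i, j] - sv)) > tol * max(1, A[i, j])) {
        stop_ecgmcda("ecgmcda_validation_error",
                     "entry at (%d, %d) = %g is not on the Saaty scale",
                     i, j, A[i, j])
      }
    }
  }
  A
}

#' Column-normalize a pairwise matrix
#'
#' Divides every entry by its column sum, so each column of the result sums
#' to one.
#'
#' @param A Validated pairwise matrix.
#' @return Column-stochastic matrix of the same shape.
#' @export
normalize_matrix <- function(A) {
  sweep(A, 2, colSums(A), "/")
}

#' Priority vector by row averaging
#'
#' The priority (weight) vector is the row mean of the column-normalized
#' matrix; it lies on the probability simplex. For a perfectly consistent
#' matrix `a[i,j] = v[i]/v[j]` this equals `v / sum(v)` exactly, the
#' principal eigenvector.
#'
#' @param Anorm Column-normalized matrix from [normalize_matrix()].
#' @return Numeric weight vector summing to 1, named by the row names.
#' @export
priority_vector <- function(Anorm) {
  w <- rowMeans(Anorm)
  w / sum(w)
}

#' Saaty consistency ratio
#'
#' `lambda_max` is estimated as the mean of `(A w)_i / w_i`; the consistency
#' index `CI = (lambda_max - n) / (n - 1)` is divided by the random index for
#' the matrix size (1.32 for n = 7). Consistent matrices give CR = 0; CR
#' below 0.1 is the conventional acceptability bound.
#'
#' @param A Validated pairwise matrix.
#' @param w Priority vector; computed from `A` when omitted.
#' @return The consistency ratio (non-negative up to numerical tolerance).
#' @export
consistency_ratio <- function(A, w = NULL) {
  if (is.null(w)) w <- priority_vector(normalize_matrix(A))
  if (any(w <= 0)) {
    stop_ecgmcda("ecgmcda_degenerate_weight_error",
                 "priority vector has a non-positive component")
  }
  n <- nrow(A)
  ri_table <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)
  if (n < 3) return(0)
  ri <- if (n <= 10) ri_table[n] else 1.49
  lambda_max <- mean((A %*% w) / w)
  ((lambda_max - n) / (n - 1)) / ri
}

#' Aggregate respondent priority vectors
#'
#' Component-wise arithmetic mean of the respondents' priority vectors; the
#' mean of simplex points stays on the simplex.
#'
#' @param ws Non-empty list of priority vectors (equal length, each summing
#'   to 1).
#' @return Aggregated weight vector.
#' @export
aggregate_weights <- function(ws) {
  if (!is.list(ws) || length(ws) == 0) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "need at least one priority vector to aggregate")
  }
  rowMeans(do.call(cbind, ws))
}

#' Derive group weights from a set of survey matrices
#'
#' Validates each respondent matrix, computes its priority vector and
#' consistency ratio, drops respondents whose CR exceeds `cr_max` (unless
#' `keep_inconsistent`), and aggregates the remaining vectors.
#'
#' @param matrices List of 7x7 pairwise matrices.
#' @param cr_max Consistency-ratio screen (default 0.1).
#' @param keep_inconsistent Keep respondents failing the screen.
#' @return List with `weights` (aggregated vector named by
#'   [criteria_names()]), `per_respondent` (matrix of vectors, one column per
#'   kept respondent), `cr` (all consistency ratios) and `n_used`.
#' @export
derive_weights <- function(matrices, cr_max = 0.1, keep_inconsistent = FALSE) {
  if (length(matrices) == 0) {
    stop_ecgmcda("ecgmcda_parameter_error", "no survey matrices supplied")
  }
  ws <- vector("list", length(matrices))
  cr <- numeric(length(matrices))
  for (m in seq_along(matrices)) {
    A <- validate_pairwise(matrices[[m]])
    ws[[m]] <- priority_vector(normalize_matrix(A))
    cr[m] <- consistency_ratio(A, ws[[m]])
  }
  keep <- if (keep_inconsistent) rep(TRUE, length(cr)) else cr <= cr_max
  if (!any(keep)) {
    stop_ecgmcda("ecgmcda_data_error",
                 "all %d respondent matrices exceed the consistency screen (CR > %g)",
                 length(cr), cr_max)
  }
  w <- aggregate_weights(ws[keep])
  names(w) <- criteria_names()[seq_along(w)]
  list(weights = w,
       per_respondent = do.call(cbind, ws[keep]),
       cr = cr, n_used = sum(keep))
}

#' Min-max normalize a criteria table
#'
#' Each criterion column is rescaled over the configurations to `[0, 1]`:
#' benefit criteria as `(x - min) / (max - min)`, cost criteria as
#' `(max - x) / (max - min)`, so 1 is always best. A constant column
#' normalizes to all 1 (every configuration is equally, maximally good on
#' it).
#'
#' @param table Criteria `data.frame` from [sweep_all()] (columns
#'   `oa, se, sp, auc, tr_s, te_s, nf`) or a numeric matrix with one column
#'   per criterion in that order.
#' @return `data.frame` of normalized values with columns named by
#'   [criteria_names()], one row per configuration.
#' @export
normalize_criteria <- function(table) {
  cols <- criteria_columns()
  M <- if (is.data.frame(table) && all(cols %in% names(table))) {
    as.matrix(table[, cols])
  } else {
    as.matrix(table)
  }
  if (any(!is.finite(M))) {
    stop_ecgmcda("ecgmcda_data_error", "criteria table has non-finite values")
  }
  senses <- criteria_senses()[seq_len(ncol(M))]
  out <- matrix(NA_real_, nrow(M), ncol(M),
                dimnames = list(NULL, criteria_names()[seq_len(ncol(M))]))
  for (p in seq_len(ncol(M))) {
    x <- M[, p]
    rng <- max(x) - min(x)
    out[, p] <- if (rng == 0) 1
    else if (senses[p] == "benefit") (x - min(x)) / rng
    else (max(x) - x) / rng
  }
  as.data.frame(out)
}

#' AHP scores and best configuration
#'
#' The score of configuration `q` is the weighted sum over the seven
#' criteria of its normalized values, `sum_p w[p] * Cnorm[q, p]`; all scores
#' lie in `[0, 1]` and the best configuration attains the maximum.
#'
#' @param norm_table Normalized criteria table from [normalize_criteria()].
#' @param weights Aggregated weight vector (length = number of criteria).
#' @return List with `scores`, `best_index` and `weights` (class
#'   `ahp_result`).
#' @export
ahp_scores <- function(norm_table, weights) {
  M <- as.matrix(norm_table)
  if (ncol(M) != length(weights)) {
    stop_ecgmcda("ecgmcda_parameter_error",
                 "criteria table has %d columns but %d weights supplied",
                 ncol(M), length(weights))
  }
  scores <- as.numeric(M %*% weights)
  structure(list(scores = scores, best_index = which.max(scores),
                 weights = weights),
            class = "ahp_result")
}

#' Select the optimal configuration
#'
#' Returns the index of the configuration with the highest AHP score. Exact
#' ties are broken in favor of fewer features, then lower testing time, then
#' lower index.
#'
#' @param result `ahp_result` from [ahp_scores()].
#' @param table Criteria table aligned with the scores (used for `nf` and
#'   `te_s` tie-breaks; optional).
#' @return Scenario (row) index of the selected configuration.
#' @export
select_optimal <- function(result, table = NULL) {
  scores <- result$scores
  if (length(scores) == 0) {
    stop_ecgmcda("ecgmcda_parameter_error", "no scores to select from")
  }
  best <- which(scores == max(scores))
  if (length(best) > 1 && !is.null(table)) {
    nf <- if ("nf" %in% names(table)) table$nf[best] else rep(0, length(best))
    te <- if ("te_s" %in% names(table)) table$te_s[best] else rep(0, length(best))
    best <- best[order(nf, te, best)]
  }
  best[1]
}

#' Read / write pairwise matrices as CSV
#'
#' A survey matrix is stored as a 7x7 CSV with rows and columns in the fixed
#' criteria order (OA, Se, Sp, AUC, Tr, Te, Nf); `read_survey_dir()` loads
#' every `*.csv` in a directory.
#'
#' @param A Pairwise matrix.
#' @param path CSV path.
#' @export
write_pairwise_csv <- function(A, path) {
  utils::write.csv(as.data.frame(A, row.names = criteria_names()), path)
  invisible(path)
}

#' @rdname write_pairwise_csv
#' @export
read_pairwise_csv <- function(path) {
  df <- utils::read.csv(path, row.names = 1)
  A <- as.matrix(df)
  if (nrow(A) != 7 || ncol(A) != 7) {
    stop_ecgmcda("ecgmcda_data_error",
                 "'%s' is not a 7x7 pairwise matrix CSV", path)
  }
  dimnames(A) <- list(criteria_names(), criteria_names())
  A
}

#' @rdname write_pairwise_csv
#' @param dir Directory of matrix CSVs.
#' @export
read_survey_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) {
    stop_ecgmcda("ecgmcda_data_error", "no CSV survey matrices in '%s'", dir)
  }
  lapply(files, read_pairwise_csv)
}
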
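# Shared fixtures. Expensive pipeline runs are memoized so several test
# files can share one computation.

.fixture_cache <- new.env(parent = emptyenv())

memoize <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small but structurally complete pipeline configuration.
small_config <- function(seed = 11) {
  run_config(seed = seed, fs = 500, duration = 15,
             counts = c(healthy = 20, bundle_branch_block = 5,
                        myocardial_infarction = 5, heart_failure = 5,
                        dysrhythmia = 5),
             folds = 5, n_respondents = 40)
}

small_pipeline <- function() {
  memoize("small_pipeline", {
    run_pipeline(small_config(), outdir = file.path(tempdir(), "small_pipe"))
  })
}

# Full study-scale pipeline (500 healthy + 4 x 125 diseased segments, 10-fold
# CV, 1023 configurations). Shared by the acceptance tests.
full_pipeline <- function() {
  memoize("full_pipeline", {
    run_pipeline(run_config(seed = 1),
                 outdir = file.path(tempdir(), "full_pipe"))
  })
}

# Two well-separated Gaussian blobs in two feature dimensions: linearly
# separable, so a sane classifier must be perfect.
separable_table <- function(n_per_class = 60, seed = 5) {
  stopifnot(n_per_class >= 10)
  set.seed(seed)
  data.frame(
    q_amp_mean = c(rnorm(n_per_class, -5, 0.3), rnorm(n_per_class, 5, 0.3)),
    rr_mean = c(rnorm(n_per_class, 5, 0.3), rnorm(n_per_class, -5, 0.3)),
    label = rep(c("healthy", "unhealthy"), each = n_per_class)
  )
}

# Pure-noise features with balanced labels: the permutation null.
noise_table <- function(n_per_class = 250, seed = 9) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(2 * n_per_class * 4), ncol = 4))
  names(df) <- c("q_amp_mean", "r_amp_mean", "qrs_dur_mean", "rr_mean")
  df$label <- sample(rep(c("healthy", "unhealthy"), each = n_per_class))
  df
}

# Random reciprocal Saaty matrix near a consistent one: ratios of a positive
# vector snapped to the Saaty scale, then `n_perturb` above-diagonal entries
# moved one step along the scale.
rand_saaty_matrix <- function(seed, n_perturb = 2, n = 7) {
  set.seed(seed)
  sv <- c(1/9, 1/7, 1/5, 1/3, 1, 3, 5, 7, 9)
  v <- exp(rnorm(n, 0, 0.8))
  A <- outer(v, v, "/")
  A[] <- sv[apply(abs(log(outer(c(A), sv, "/"))), 1, which.min)]
  diag(A) <- 1
  if (n_perturb > 0) {
    ij <- which(upper.tri(A), arr.ind = TRUE)
    pick <- ij[sample(nrow(ij), n_perturb), , drop = FALSE]
    for (k in seq_len(nrow(pick))) {
      i <- pick[k, 1]; j <- pick[k, 2]
      pos <- which.min(abs(A[i, j] - sv))
      A[i, j] <- sv[min(length(sv), max(1, pos + sample(c(-1, 1), 1)))]
    }
  }
  # rebuild the lower triangle as exact reciprocals
  for (i in 2:n) for (j in 1:(i - 1)) A[i, j] <- 1 / A[j, i]
  A
}

# Independent oracle: principal-eigenvector weights and eigenvalue.
eigen_weights <- function(A) {
  e <- eigen(A)
  i <- which.max(Re(e$values))
  w <- abs(Re(e$vectors[, i]))
  w / sum(w)
}

eigen_lambda_max <- function(A) {
  max(Re(eigen(A)$values))
}
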
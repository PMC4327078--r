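consistent_matrix <- function(v) {
  A <- outer(v, v, "/")
  diag(A) <- 1
  A
}

test_that("pairwise validation accepts Saaty matrices and names offenders", {
  expect_silent(validate_pairwise(matrix(1, 7, 7)))

  A <- matrix(1, 7, 7); A[1, 2] <- 3; A[2, 1] <- 1 / 3
  expect_silent(validate_pairwise(A))

  bad <- A; bad[2, 1] <- 0.5
  expect_error(validate_pairwise(bad), class = "ecgmcda_validation_error")
  expect_error(validate_pairwise(bad), "2, 1")

  diagbad <- A; diagbad[3, 3] <- 2
  expect_error(validate_pairwise(diagbad), "3, 3")

  offscale <- A; offscale[1, 2] <- 4; offscale[2, 1] <- 0.25
  expect_error(validate_pairwise(offscale), "Saaty")

  neg <- A; neg[1, 2] <- -3
  expect_error(validate_pairwise(neg), class = "ecgmcda_validation_error")
})

test_that("column normalization and row averaging preserve the simplex", {
  u <- normalize_matrix(matrix(1, 7, 7))
  expect_equal(u, matrix(1 / 7, 7, 7))
  expect_equal(priority_vector(u), rep(1 / 7, 7))

  A <- rand_saaty_matrix(1, n_perturb = 3)
  An <- normalize_matrix(A)
  expect_equal(unname(colSums(An)), rep(1, 7), tolerance = 1e-12)
  expect_true(all(An > 0 & An <= 1))
  expect_equal(sum(priority_vector(An)), 1, tolerance = 1e-12)
})

test_that("consistent matrices recover their generating weights exactly", {
  v <- c(3, 1, 1, 1, 1, 1, 1)  # ratios stay on the Saaty scale
  A <- validate_pairwise(consistent_matrix(v))
  w <- priority_vector(normalize_matrix(A))
  expect_equal(w, v / sum(v), tolerance = 1e-14)
  expect_lt(abs(consistency_ratio(A, w)), 1e-6)
  expect_lt(abs(consistency_ratio(matrix(1, 7, 7))), 1e-12)
})

test_that("consistency ratio agrees with an eigenvalue oracle", {
  for (s in 1:10) {
    A <- rand_saaty_matrix(s, n_perturb = 3)
    w_star <- eigen_weights(A)
    cr <- consistency_ratio(A, w_star)
    cr_oracle <- ((eigen_lambda_max(A) - 7) / 6) / 1.32
    expect_equal(cr, cr_oracle, tolerance = 1e-6)
    expect_gte(cr, -1e-9)
  }
})

test_that("row-mean weights track the eigenvector for consistent-enough matrices", {
  checked <- 0
  for (s in 1:200) {
    A <- rand_saaty_matrix(s, n_perturb = 2)
    w <- priority_vector(normalize_matrix(A))
    if (consistency_ratio(A, w) < 0.1) {
      expect_lt(max(abs(w - eigen_weights(A))), 0.05)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("weight aggregation is the simplex mean", {
  w <- rep(1 / 7, 7)
  expect_equal(aggregate_weights(rep(list(w), 200)), w)
  expect_equal(aggregate_weights(list(c(1, 0, 0), c(0, 1, 0))),
               c(0.5, 0.5, 0))
  set.seed(2)
  ws <- lapply(1:9, function(i) { x <- runif(7); x / sum(x) })
  expect_equal(sum(aggregate_weights(ws)), 1, tolerance = 1e-12)
  expect_error(aggregate_weights(list()), class = "ecgmcda_parameter_error")
})

test_that("criteria normalization follows min-max with cost inversion", {
  tab <- data.frame(oa = c(0.2, 0.5, 1.0), se = c(3, 3, 3),
                    sp = c(0.1, 0.9, 0.5), auc = c(0, 1, 0.5),
                    tr_s = c(2, 4, 3), te_s = c(1, 2, 3),
                    nf = c(10, 1, 5))
  norm <- normalize_criteria(tab)
  expect_equal(norm$OA, c(0, 0.375, 1.0))       # benefit direction
  expect_equal(norm$Se, c(1, 1, 1))             # constant column rule
  expect_equal(norm$Tr, c(1, 0, 0.5))           # cost direction flips
  expect_equal(norm$Nf, c(0, 1, 5 / 9))
  expect_true(all(as.matrix(norm) >= 0 & as.matrix(norm) <= 1))
  # per non-constant criterion exactly one scenario attains 1
  expect_identical(unname(colSums(as.matrix(norm) == 1)[c(1, 3:7)]),
                   rep(1, 6))
  expect_error(normalize_criteria(data.frame(oa = c(1, NA))),
               class = "ecgmcda_data_error")
})

test_that("normalized scores are scale invariant in the raw criteria", {
  set.seed(5)
  tab <- data.frame(oa = runif(8), se = runif(8), sp = runif(8),
                    auc = runif(8), tr_s = runif(8, 1, 5),
                    te_s = runif(8, 1, 5), nf = sample(1:10, 8, TRUE))
  w <- { x <- runif(7); x / sum(x) }
  base <- ahp_scores(normalize_criteria(tab), w)$scores
  tab2 <- tab; tab2$te_s <- tab2$te_s * 37.5
  expect_equal(ahp_scores(normalize_criteria(tab2), w)$scores, base,
               tolerance = 1e-12)
})

test_that("scores are weighted sums with the expected degeneracies", {
  tab <- data.frame(oa = c(0.9, 0.7), se = c(0.8, 0.8), sp = c(0.6, 0.9),
                    auc = c(0.9, 0.8), tr_s = c(4, 5), te_s = c(2, 3),
                    nf = c(3, 7))
  norm <- normalize_criteria(tab)

  # indicator weight on OA ranks identically to normalized OA
  w_oa <- c(1, 0, 0, 0, 0, 0, 0)
  expect_identical(order(ahp_scores(norm, w_oa)$scores), order(norm$OA))

  # hand-computed weighted sum, 0.6/0.4 over two effective criteria
  w <- c(0.6, 0, 0, 0, 0, 0.4, 0)
  expect_equal(ahp_scores(norm, w)$scores,
               0.6 * norm$OA + 0.4 * norm$Te)

  expect_error(ahp_scores(norm, w[1:5]), class = "ecgmcda_parameter_error")
})

test_that("a weakly dominant scenario wins for every weight vector", {
  set.seed(8)
  for (rep in 1:20) {
    tab <- data.frame(oa = runif(5), se = runif(5), sp = runif(5),
                      auc = runif(5), tr_s = runif(5, 1, 5),
                      te_s = runif(5, 1, 5), nf = sample(1:10, 5, TRUE))
    # make scenario 1 weakly dominant in every sense direction
    tab[1, c("oa", "se", "sp", "auc")] <-
      lapply(tab[c("oa", "se", "sp", "auc")], max)
    tab[1, c("tr_s", "te_s", "nf")] <- lapply(tab[c("tr_s", "te_s", "nf")], min)
    norm <- normalize_criteria(tab)
    for (k in 1:10) {
      w <- runif(7); w <- w / sum(w)
      s <- ahp_scores(norm, w)$scores
      expect_gte(s[1], max(s) - 1e-12)
    }
  }
})

test_that("improving one criterion never lowers that scenario's score", {
  set.seed(13)
  for (rep in 1:30) {
    tab <- data.frame(oa = runif(6), se = runif(6), sp = runif(6),
                      auc = runif(6), tr_s = runif(6, 1, 5),
                      te_s = runif(6, 1, 5), nf = sample(1:10, 6, TRUE))
    w <- runif(7); w <- w / sum(w)
    q <- sample(6, 1)
    col <- sample(names(tab), 1)
    before <- ahp_scores(normalize_criteria(tab), w)$scores[q]
    sense <- criteria_senses()[match(col, c("oa", "se", "sp", "auc",
                                            "tr_s", "te_s", "nf"))]
    tab[q, col] <- if (sense == "benefit") tab[q, col] + runif(1, 0, 0.5)
      else max(0, tab[q, col] - runif(1, 0, 0.5))
    after <- ahp_scores(normalize_criteria(tab), w)$scores[q]
    expect_gte(after, before - 1e-9)
  }
})

test_that("selection takes the argmax and breaks ties toward simplicity", {
  res <- structure(list(scores = c(0.3, 0.9, 0.5), best_index = 2), class = "ahp_result")
  expect_identical(select_optimal(res), 2L)

  tied <- structure(list(scores = c(0.7, 0.7)), class = "ahp_result")
  tab <- data.frame(nf = c(7, 3), te_s = c(1, 5))
  expect_identical(select_optimal(tied, tab), 2L)
  tab_equal <- data.frame(nf = c(3, 3), te_s = c(2, 2))
  expect_identical(select_optimal(tied, tab_equal), 1L)
  expect_error(select_optimal(structure(list(scores = numeric(0)),
                                        class = "ahp_result")),
               class = "ecgmcda_parameter_error")
})

test_that("respondent screening drops inconsistent matrices", {
  good <- consistent_matrix(c(3, 1, 1, 1, 1, 1, 1))
  # highly inconsistent: circular preferences
  bad <- matrix(1, 7, 7)
  bad[1, 2] <- 9; bad[2, 1] <- 1 / 9
  bad[2, 3] <- 9; bad[3, 2] <- 1 / 9
  bad[3, 1] <- 9; bad[1, 3] <- 1 / 9
  w <- derive_weights(list(good, bad, good))
  expect_identical(w$n_used, 2L)
  expect_equal(unname(w$weights), c(3, 1, 1, 1, 1, 1, 1) / 9,
               tolerance = 1e-12)
  w_all <- derive_weights(list(good, bad, good), keep_inconsistent = TRUE)
  expect_identical(w_all$n_used, 3L)
  expect_error(derive_weights(list(bad)), class = "ecgmcda_data_error")
})

test_that("pairwise matrices round-trip through CSV", {
  A <- generate_survey_matrices(1, "speed", noise = 0.4, seed = 9)[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_pairwise_csv(A, path)
  expect_equal(read_pairwise_csv(path), A, tolerance = 1e-12)
})
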
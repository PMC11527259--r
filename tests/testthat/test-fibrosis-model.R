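# Model-fitting tests run on crafted QIF matrices (no rendering) so each
# property is isolated from the image pipeline.

make_signal_cohort <- function(n_subjects = 8, patches = 5, p = 12,
                               seed = 1, noise = 0.5) {
  set.seed(seed)
  qifs <- list(); mrss <- c(); subj <- c()
  for (i in seq_len(n_subjects)) {
    sev <- (i - 0.5) / n_subjects
    bid <- sprintf("B%02d", i)
    X <- matrix(rnorm(patches * p), patches, p)
    X[, 1] <- X[, 1] + 3 * sev
    X[, 2] <- X[, 2] - 2 * sev
    qifs[[bid]] <- make_qif(bid, X)
    mrss[bid] <- round(51 * sev) + rnorm(1, 0, noise)
    subj[bid] <- sprintf("S%02d", i)
  }
  list(qifs = qifs, mrss = mrss, subj = subj)
}

test_that("lasso path matches glmnet on a 20 x 10 toy to 1e-6", {
  skip_if_not_installed("glmnet")
  set.seed(4)
  X <- scale(matrix(rnorm(200), 20, 10))
  y <- X[, 1] * 2 - X[, 3] + rnorm(20, 0, 0.5)
  lam <- make_lambda_grid()$values
  ours <- lasso_path(X, y, lam, tol = 1e-12)
  ref <- glmnet::glmnet(X, y, lambda = rev(lam), standardize = FALSE,
                        thresh = 1e-16)
  expect_lt(max(abs(ours$beta[, order(lam, decreasing = TRUE)] -
                      as.matrix(ref$beta))), 1e-6)
  expect_lt(max(abs(ours$intercept[order(lam, decreasing = TRUE)] -
                      ref$a0)), 1e-6)
})

test_that("coefficient L1 norm shrinks monotonically in lambda", {
  set.seed(9)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- X %*% rnorm(8) + rnorm(50)
  lam <- make_lambda_grid()$values
  fit <- lasso_path(scale(X), y, lam, tol = 1e-10)
  l1 <- colSums(abs(fit$beta))
  expect_true(all(diff(l1[order(lam)]) <= 1e-8))
})

test_that("the strong-penalty extreme is the intercept-only model", {
  set.seed(2)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- X[, 1] + rnorm(40)
  fit <- lasso_path(scale(X), y, 1e3)
  expect_true(all(fit$beta == 0))
  expect_equal(fit$intercept[1], mean(y))

  d <- make_signal_cohort()
  m <- fit_fibrosis_model(d$qifs, d$mrss, d$subj, seed = 1)
  expect_equal(m$cv_table$n_nonzero[m$cv_table$lambda == 1e3], 0)
})

test_that("cross-validation folds never split a subject", {
  d <- make_signal_cohort(n_subjects = 8)
  m <- fit_fibrosis_model(d$qifs, d$mrss, d$subj, seed = 3)
  folds <- m$cv_folds
  expect_identical(sort(unlist(folds)), sort(unique(unname(d$subj))))
  for (i in seq_along(folds))
    for (j in seq_along(folds))
      if (i != j)
        expect_length(intersect(folds[[i]], folds[[j]]), 0L)
  # >15 subjects: 5 grouped folds, still a disjoint cover
  d2 <- make_signal_cohort(n_subjects = 18)
  m2 <- fit_fibrosis_model(d2$qifs, d2$mrss, d2$subj, seed = 3)
  expect_length(m2$cv_folds, 5L)
  expect_identical(sort(unname(unlist(m2$cv_folds))),
                   sort(unique(unname(d2$subj))))
})

test_that("fitting is deterministic and recovers the severity signal", {
  d <- make_signal_cohort(n_subjects = 10, seed = 5)
  m1 <- fit_fibrosis_model(d$qifs, d$mrss, d$subj, seed = 7)
  m2 <- fit_fibrosis_model(d$qifs, d$mrss, d$subj, seed = 7)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$lambda_star, m2$lambda_star)
  expect_gte(suppressWarnings(
    cor(m1$heldout_scores$cv_score, m1$heldout_scores$mrss,
        method = "spearman")), 0.7)
})

test_that("prediction is the exact patch-mean linear score", {
  # all-zero coefficients, intercept 14.2 -> score 14.2 for any biopsy
  m0 <- make_model(14.2, rep(0, 3))
  q <- make_qif("bx", matrix(rnorm(15), 5, 3))
  expect_equal(predict_fibrosis_score(m0, q)$score, 14.2)

  # crafted patch predictions {10, 20} -> score 15
  m1 <- make_model(0, c(1))
  q2 <- make_qif("by", matrix(c(10, 20), 2, 1))
  s <- predict_fibrosis_score(m1, q2)
  expect_equal(s$score, 15)
  expect_identical(s$n_patches_used, 2L)

  # duplicating every patch row leaves the mean unchanged
  q3 <- make_qif("bz", matrix(rnorm(20), 5, 4))
  m2 <- make_model(2, rnorm(4))
  q3dup <- make_qif("bz", q3$values[rep(1:5, each = 2), ])
  expect_equal(predict_fibrosis_score(m2, q3)$score,
               predict_fibrosis_score(m2, q3dup)$score)

  expect_error(predict_fibrosis_score(m1, q3), "width")
})

test_that("sparse support recovery finds the true features", {
  set.seed(11)
  n <- 200; p <- 4096
  X <- matrix(rnorm(n * p), n, p)
  true <- c(3, 97, 1024, 2048, 4000)
  y <- X[, true] %*% c(8, -7, 6, -6, 7) + rnorm(n, 0, 2) + 25
  qifs <- lapply(seq_len(n), function(i)
    make_qif(sprintf("B%03d", i), X[i, , drop = FALSE]))
  mrss <- setNames(as.numeric(y), sprintf("B%03d", 1:n))
  subj <- setNames(sprintf("S%03d", 1:n), sprintf("B%03d", 1:n))
  m <- fit_fibrosis_model(qifs, mrss, subj, seed = 2, max_iter = 500L)
  support <- which(m$coefficients != 0)
  expect_gte(length(intersect(true, support)), 4L)
})

test_that("invalid training inputs fail with clear messages", {
  d <- make_signal_cohort(n_subjects = 4)
  expect_error(fit_fibrosis_model(d$qifs, d$mrss[-1], d$subj), "mRSS")
  expect_error(fit_fibrosis_model(d$qifs, d$mrss, d$subj[-2]), "subject")
  expect_error(
    fit_fibrosis_model(d$qifs, setNames(rep(20, 4), names(d$mrss)),
                       d$subj), "degenerate")
  two <- setNames(c("S1", "S1", "S2", "S2"), names(d$subj))
  expect_error(fit_fibrosis_model(d$qifs, d$mrss, two), "3 subjects")

  wide <- d$qifs
  wide[[1]] <- make_qif(wide[[1]]$biopsy_id, cbind(wide[[1]]$values, 0))
  expect_error(fit_fibrosis_model(wide, d$mrss, d$subj), "widths")
})

test_that("model JSON serialization is sparse and faithful", {
  d <- make_signal_cohort()
  m <- fit_fibrosis_model(d$qifs, d$mrss, d$subj, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_fibrosis_model(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$lambda_star, m$lambda_star)
  expect_equal(back$coefficients$value,
               unname(m$coefficients[m$coefficients != 0]))
  expect_identical(back$n_features, length(m$coefficients))
})
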
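# The penalized Fibrosis Score model: patch-level L1 regression of QIFs on
# the biopsy's total mRSS, patient-grouped cross-validation for the penalty,
# and patch-mean aggregation to one score per biopsy.

.check_qif_list <- function(qifs) {
  if (inherits(qifs, "qif_matrix")) qifs <- list(qifs)
  stopifnot(all(vapply(qifs, inherits, logical(1), "qif_matrix")))
  ids <- vapply(qifs, `[[`, character(1), "biopsy_id")
  if (anyDuplicated(ids))
    stop("duplicate biopsy ids in QIF list", call. = FALSE)
  widths <- vapply(qifs, function(q) ncol(q$values), integer(1))
  if (length(unique(widths)) != 1L)
    stop("inconsistent feature widths across biopsies: ",
         paste(unique(widths), collapse = ", "), call. = FALSE)
  names(qifs) <- ids
  qifs
}

#' Fit the Fibrosis Score model
#'
#' Training rows are image patches, each labeled with its biopsy's total
#' mRSS. Features are standardized with training-fold statistics only, an
#' L1-penalized least-squares model is fit along the penalty grid, and the
#' selected penalty minimizes the mean held-out *biopsy-level* squared
#' error: per-patch predictions are averaged within each held-out biopsy
#' before scoring, because the deliverable is the biopsy score. Folds never
#' split a subject (all of a patient's biopsies stay on one side of every
#' split): leave-one-subject-out when there are at most 15 subjects,
#' otherwise 5 seeded subject-grouped folds. The final model is refit on
#' all data at the selected penalty.
#'
#' @param qifs List of `qif_matrix` objects (one per biopsy).
#' @param mrss_totals Named numeric: total mRSS per biopsy id.
#' @param subject_of Named character: subject id per biopsy id.
#' @param grid A [make_lambda_grid()] penalty grid.
#' @param cv_folds Optional list of character vectors of subject ids, one
#'   per fold, overriding the default scheme.
#' @param seed Seed for fold assignment.
#' @param tol Coordinate-descent tolerance (absolute, in mRSS units; the
#'   default trades the last decimals for speed on wide QIF matrices).
#' @param max_iter Maximum coordinate-descent sweeps per penalty.
#' @return A `fibrosis_model` with intercept, standardized-scale
#'   coefficients, `lambda_star`, per-feature scaling, the cross-validation
#'   table and training metadata.
#' @export
fit_fibrosis_model <- function(qifs, mrss_totals, subject_of,
                               grid = make_lambda_grid(), cv_folds = NULL,
                               seed = 1L, tol = 1e-4, max_iter = 5000L) {
  qifs <- .check_qif_list(qifs)
  stopifnot(inherits(grid, "lambda_grid"))
  ids <- names(qifs)
  missing_m <- setdiff(ids, names(mrss_totals))
  if (length(missing_m))
    stop("no mRSS total for biopsy: ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  missing_s <- setdiff(ids, names(subject_of))
  if (length(missing_s))
    stop("no subject for biopsy: ", paste(missing_s, collapse = ", "),
         call. = FALSE)
  if (any(vapply(subject_of[ids], length, integer(1)) != 1L))
    stop("inconsistent subject mapping", call. = FALSE)
  subjects <- sort(unique(unname(subject_of[ids])))
  if (length(subjects) < 3L)
    stop("need at least 3 subjects for grouped cross-validation",
         call. = FALSE)
  y_biopsy <- unname(mrss_totals[ids])
  if (stats::var(y_biopsy) == 0)
    stop("degenerate outcome: mRSS is constant across biopsies",
         call. = FALSE)

  X <- do.call(rbind, lapply(qifs, `[[`, "values"))
  n_per <- vapply(qifs, function(q) nrow(q$values), integer(1))
  row_biopsy <- rep(ids, n_per)
  row_subject <- unname(subject_of[row_biopsy])
  y <- rep(y_biopsy, n_per)

  if (is.null(cv_folds)) {
    cv_folds <- if (length(subjects) <= 15L) as.list(subjects)
    else {
      perm <- with_seed(seed_stream(seed, "cv_folds"),
                        sample(length(subjects)))
      split(subjects[perm], rep_len(1:5, length(subjects)))
    }
  }
  lam <- grid$values
  se_biopsy <- matrix(NA_real_, length(ids), length(lam),
                      dimnames = list(ids, NULL))
  pred_biopsy <- se_biopsy
  for (fold in cv_folds) {
    test_rows <- row_subject %in% fold
    if (!any(test_rows) || all(test_rows)) next
    sc <- standardize_fit(X[!test_rows, , drop = FALSE])
    fit <- lasso_path(standardize_apply(X[!test_rows, , drop = FALSE], sc),
                      y[!test_rows], lam, tol = tol, max_iter = max_iter)
    pred <- standardize_apply(X[test_rows, , drop = FALSE], sc) %*%
      fit$beta
    pred <- sweep(pred, 2L, fit$intercept, "+")
    for (bid in unique(row_biopsy[test_rows])) {
      score <- colMeans(pred[row_biopsy[test_rows] == bid, , drop = FALSE])
      pred_biopsy[bid, ] <- score
      se_biopsy[bid, ] <- (score - mrss_totals[[bid]])^2
    }
  }
  cv_mse <- colMeans(se_biopsy, na.rm = TRUE)
  # tie-break toward the stronger penalty (sparser model)
  lambda_star <- max(lam[cv_mse <= min(cv_mse) + 1e-12])

  scaling <- standardize_fit(X)
  full <- lasso_path(standardize_apply(X, scaling), y, lam, tol = tol,
                     max_iter = max_iter)
  k <- which(lam == lambda_star)
  model <- structure(list(
    intercept = full$intercept[k],
    coefficients = full$beta[, k],
    lambda_star = lambda_star,
    feature_scaling = scaling,
    cv_table = data.frame(lambda = lam, cv_mse = cv_mse,
                          n_nonzero = colSums(full$beta != 0)),
    cv_folds = cv_folds,
    training_meta = list(
      backend_name = unique(vapply(qifs, `[[`, character(1),
                                   "backend_name")),
      seed = as.integer(seed), n_subjects = length(subjects),
      n_biopsies = length(ids), n_patches = nrow(X),
      n_features = ncol(X)),
    mrss = stats::setNames(y_biopsy, ids),
    heldout_scores = data.frame(
      biopsy_id = ids, cv_score = unname(pred_biopsy[, k]),
      mrss = y_biopsy, row.names = NULL),
    subject_of = subject_of[ids]),
    class = "fibrosis_model")
  model$fitted_scores <- predict(model, qifs)
  model
}

#' Fibrosis Score of one biopsy
#'
#' Per-patch prediction = intercept + standardized features times the
#' coefficient vector; the biopsy score is the arithmetic mean over its
#' patches. Scores are not clipped: the range is arbitrary, approximating
#' the mRSS range 0-51.
#'
#' @param model A `fibrosis_model`.
#' @param qif A `qif_matrix` with the model's feature width.
#' @return A `fibrosis_score`: biopsy_id, score, n_patches_used.
#' @export
predict_fibrosis_score <- function(model, qif) {
  stopifnot(inherits(model, "fibrosis_model"), inherits(qif, "qif_matrix"))
  if (ncol(qif$values) != length(model$coefficients))
    stop("feature width ", ncol(qif$values), " does not match model (",
         length(model$coefficients), ")", call. = FALSE)
  pred <- model$intercept +
    standardize_apply(qif$values, model$feature_scaling) %*%
      model$coefficients
  structure(list(biopsy_id = qif$biopsy_id, score = mean(pred),
                 n_patches_used = nrow(qif$values)),
            class = "fibrosis_score")
}

#' @export
print.fibrosis_score <- function(x, ...) {
  cat(sprintf("Fibrosis Score '%s': %.2f (mean over %d patches)\n",
              x$biopsy_id, x$score, x$n_patches_used))
  invisible(x)
}

#' @rdname fit_fibrosis_model
#' @param object,x A `fibrosis_model`.
#' @param newdata A `qif_matrix` or list of them.
#' @param ... Unused.
#' @export
predict.fibrosis_model <- function(object, newdata, ...) {
  if (inherits(newdata, "qif_matrix"))
    return(predict_fibrosis_score(object, newdata))
  scores <- lapply(.check_qif_list(newdata), predict_fibrosis_score,
                   model = object)
  data.frame(
    biopsy_id = vapply(scores, `[[`, character(1), "biopsy_id"),
    fibrosis_score = vapply(scores, `[[`, numeric(1), "score"),
    n_patches_used = vapply(scores, `[[`, integer(1), "n_patches_used"),
    row.names = NULL)
}

#' @export
coef.fibrosis_model <- function(object, ...) {
  c("(Intercept)" = object$intercept, object$coefficients)
}

#' @export
fitted.fibrosis_model <- function(object, ...) {
  stats::setNames(object$fitted_scores$fibrosis_score,
                  object$fitted_scores$biopsy_id)
}

#' @export
residuals.fibrosis_model <- function(object, ...) {
  object$mrss - fitted(object)
}

#' @export
print.fibrosis_model <- function(x, ...) {
  m <- x$training_meta
  cat("Fibrosis Score model (L1-penalized patch regression on mRSS)\n")
  cat(sprintf("  %d subjects, %d biopsies, %d patches, %d features (%s)\n",
              m$n_subjects, m$n_biopsies, m$n_patches, m$n_features,
              paste(m$backend_name, collapse = "+")))
  cat(sprintf("  lambda* = %.3g (%d nonzero coefficients), CV MSE %.2f\n",
              x$lambda_star, sum(x$coefficients != 0),
              x$cv_table$cv_mse[x$cv_table$lambda == x$lambda_star]))
  invisible(x)
}

#' @export
summary.fibrosis_model <- function(object, ...) {
  res <- residuals(object)
  structure(list(model = object, cv_table = object$cv_table,
                 rmse_train = sqrt(mean(res^2)),
                 spearman_train = if (length(res) >= 3)
                   suppressWarnings(stats::cor(fitted(object), object$mrss,
                                               method = "spearman"))
                 else NA_real_),
            class = "summary.fibrosis_model")
}

#' @export
print.summary.fibrosis_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training RMSE %.2f, training Spearman rho %.2f\n",
              x$rmse_train, x$spearman_train))
  cat("  cross-validation path:\n")
  print(format(x$cv_table, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.fibrosis_model <- function(x, ...) {
  with(x$cv_table, {
    plot(log10(lambda), cv_mse, type = "b", pch = 19,
         xlab = expression(log[10](lambda)),
         ylab = "held-out biopsy-level MSE",
         main = "Penalty selection", ...)
    graphics::abline(v = log10(x$lambda_star), lty = 2)
  })
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Sparse representation: nonzero coefficients as index/value pairs, plus
#' intercept, selected penalty, per-feature scaling and training metadata.
#'
#' @param model A `fibrosis_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fibrosis_model <- function(model, path) {
  nz <- which(model$coefficients != 0)
  jsonlite::write_json(list(
    intercept = model$intercept,
    lambda_star = model$lambda_star,
    coefficients = list(index = nz, value = unname(model$coefficients[nz])),
    n_features = length(model$coefficients),
    feature_scaling = list(mean = unname(model$feature_scaling$mean),
                           sd = unname(model$feature_scaling$sd)),
    training_meta = model$training_meta),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
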
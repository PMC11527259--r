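# Independent oracles used to cross-check package computations. These are
# deliberately naive implementations (Newton iterations, double loops,
# closed forms) kept separate from the package code paths they check.

# Maximum-likelihood logistic regression (intercept + one covariate) by
# Newton-Raphson on the exact score equations.
logistic_mle_newton <- function(y01, x, tol = 1e-12, max_iter = 200) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-drop(X %*% b)))
    g <- drop(crossprod(X, y01 - p))
    H <- crossprod(X * (p * (1 - p)), X)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

# Window means by direct double loop (band-pass oracle).
boxmean_naive <- function(m, k) {
  nr <- nrow(m) - k + 1L; nc <- ncol(m) - k + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc))
    out[i, j] <- mean(m[i:(i + k - 1L), j:(j + k - 1L)])
  out
}

# Closed-form Spearman for permutation inputs (no ties).
spearman_noties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Draw from a proportional-odds model: latent logistic regression with
# cutpoints `zeta`, slope `beta` on exposure x.
rpolr <- function(x, beta, zeta) {
  u <- stats::rlogis(length(x))
  eta <- beta * x
  sapply(seq_along(x), function(i) sum(u[i] + eta[i] > zeta))
}

# Small rendered image shared across tests (cheap at 512 px, 2 um/px).
test_image <- function(severity = 0.6, seed = 3L, px = 512L) {
  render_biopsy(severity, microns_per_pixel = 2, height_px = px,
                width_px = px, seed = seed)
}

# A hand-crafted qif_matrix (bypasses extraction) for model unit tests.
make_qif <- function(biopsy_id, values, backend_name = "crafted") {
  structure(list(biopsy_id = biopsy_id, values = as.matrix(values),
                 n_features = ncol(as.matrix(values)),
                 backend_name = backend_name,
                 patch_ids = seq_len(nrow(as.matrix(values)))),
            class = "qif_matrix")
}

# A bare fibrosis_model with given intercept/coefficients (identity
# scaling), for prediction arithmetic tests.
make_model <- function(intercept, coefficients) {
  p <- length(coefficients)
  structure(list(intercept = intercept, coefficients = coefficients,
                 lambda_star = 1, feature_scaling = list(mean = rep(0, p),
                                                         sd = rep(1, p))),
            class = "fibrosis_model")
}
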
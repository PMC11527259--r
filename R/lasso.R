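# R wrapper around the coordinate-descent lasso path solver.

#' Lasso solution path
#'
#' Minimizes `(1/(2n)) * ||y - b0 - X b||^2 + lambda * ||b||_1` for each
#' penalty in `lambda` by cyclic coordinate descent with warm starts along
#' the decreasing path. The intercept is unpenalized and equals
#' `mean(y) - colMeans(X) %*% b`.
#'
#' @param x Numeric predictor matrix (rows = observations).
#' @param y Numeric response.
#' @param lambda Vector of positive penalties (any order).
#' @param tol Convergence tolerance on the maximum absolute coefficient
#'   change per sweep.
#' @param max_iter Maximum sweeps per penalty.
#' @return List: `beta` (p x length(lambda), columns aligned with `lambda`
#'   as given), `intercept` (per penalty), `lambda`.
#' @export
lasso_path <- function(x, y, lambda, tol = 1e-10, max_iter = 100000L) {
  x <- as.matrix(x)
  if (nrow(x) != length(y))
    abort_field("y", "length must equal nrow(x)")
  if (any(lambda <= 0)) abort_field("lambda", "penalties must be positive")
  ord <- order(lambda, decreasing = TRUE)
  mu_x <- colMeans(x)
  xc <- sweep(x, 2L, mu_x, "-")
  mu_y <- mean(y)
  beta_path <- lasso_path_cd(xc, y - mu_y, lambda[ord], tol = tol,
                             max_iter = as.integer(max_iter))
  beta <- matrix(0, ncol(x), length(lambda))
  beta[, ord] <- beta_path
  rownames(beta) <- colnames(x)
  list(beta = beta, intercept = mu_y - as.numeric(crossprod(mu_x, beta)),
       lambda = lambda)
}
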
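# Penalty grid for the L1-regularized mRSS model.

#' Logarithmically spaced penalty grid
#'
#' Default: 16 values from 1e-5 (weak penalty) to 1e3 (strong penalty),
#' equally spaced in log10.
#'
#' @param n Number of grid points (>= 2).
#' @param lo,hi Positive endpoints, `lo < hi`.
#' @return A `lambda_grid` with elements `values`, `n`, `lo`, `hi`.
#' @export
make_lambda_grid <- function(n = 16L, lo = 1e-5, hi = 1e3) {
  check_number(n, "n", lo = 2, integer = TRUE)
  check_number(lo, "lo", lo = .Machine$double.xmin)
  check_number(hi, "hi", lo = .Machine$double.xmin)
  if (lo >= hi) abort_field("lo", "must be strictly less than `hi`")
  values <- 10^seq(log10(lo), log10(hi), length.out = n)
  values[1] <- lo; values[n] <- hi
  structure(list(values = values, n = as.integer(n), lo = lo, hi = hi),
            class = "lambda_grid")
}

#' @export
print.lambda_grid <- function(x, ...) {
  cat(sprintf("lambda_grid: %d values, %.3g .. %.3g (log10-spaced)\n",
              x$n, x$lo, x$hi))
  invisible(x)
}
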
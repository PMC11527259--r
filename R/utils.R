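# Internal helpers: validation, deterministic seed streams, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_field(field, "must be a single finite number")
  if (integer && x != round(x))
    abort_field(field, "must be an integer")
  if (x < lo || x > hi)
    abort_field(field, sprintf("must be in [%s, %s]", format(lo), format(hi)))
  invisible(x)
}

#' Derive a reproducible sub-stream seed from a master seed and labels
#'
#' One pseudo-random stream per (subject, week, purpose) is derived from a
#' single master seed, so adding or removing subjects never shifts another
#' subject's draws. The hash is a 31-bit polynomial rolling hash computed in
#' double precision (exact: all intermediates stay below 2^53), hence
#' platform-independent.
#'
#' @param master_seed Integer master seed.
#' @param ... Character or numeric labels identifying the stream
#'   (e.g. subject id, week, `"image"`).
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
seed_stream <- function(master_seed, ...) {
  labels <- paste(c(format(master_seed), vapply(list(...), format, "")),
                  collapse = "")
  bytes <- utf8ToInt(labels)
  m <- 2147483647 # 2^31 - 1, prime
  acc <- (abs(as.numeric(master_seed)) + 11) %% m
  for (b in bytes) acc <- (acc * 131 + b) %% m
  as.integer(acc)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Column means/sds with population (1/n) variance; sd 0 mapped to 1 so
# constant features scale to 0 rather than NaN.
standardize_fit <- function(x) {
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  sd <- sqrt(colMeans(xc * xc))
  sd[sd < .Machine$double.eps] <- 1
  list(mean = mu, sd = sd)
}

standardize_apply <- function(x, scaling) {
  sweep(sweep(x, 2L, scaling$mean, "-"), 2L, scaling$sd, "/")
}
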
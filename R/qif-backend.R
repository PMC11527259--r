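# Fixed-length quantitative image features (QIFs) per patch, through
# pluggable backends. The default backend is a deterministic multiscale
# texture bank expanded to the target width by a seeded random projection;
# a CNN backend consuming a locally provisioned ONNX AlexNet realizes the
# original 4,096-wide fully-connected-layer features.

.box_valid <- function(m, k) {
  # k x k window means for all fully-contained windows
  .window_sums(m, k) / (k * k)
}

.crop_to <- function(a, nr, nc) {
  ro <- (nrow(a) - nr) %/% 2L; co <- (ncol(a) - nc) %/% 2L
  a[(ro + 1L):(ro + nr), (co + 1L):(co + nc), drop = FALSE]
}

#' Multiscale texture statistics of one patch
#'
#' The base feature bank of the texture backend: channel moments, luminance
#' quantiles and dark fractions, gradient statistics with an 8-bin
#' orientation histogram, and isotropic plus oriented band-pass energies at
#' several scales. Patches larger than `resize` px are subsampled by an
#' integer stride first. Every feature tagged contrast-type (variance,
#' gradient and band-pass statistics) is exactly zero on a constant patch.
#'
#' @param pixels `h x w x 3` RGB array in \[0, 1\].
#' @param resize Maximum analysed edge length (integer-stride subsampling).
#' @return Named numeric vector with a logical `contrast_type` attribute.
#' @export
texture_base_features <- function(pixels, resize = 128L) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  stride <- max(1L, ceiling(max(h, w) / resize))
  pix <- pixels[seq(1L, h, stride), seq(1L, w, stride), , drop = FALSE]
  luma <- (pix[, , 1] + pix[, , 2] + pix[, , 3]) / 3
  h <- nrow(luma); w <- ncol(luma)

  f <- c(); ct <- c()
  add <- function(vals, contrast) {
    f <<- c(f, vals); ct <<- c(ct, rep(contrast, length(vals)))
  }
  for (ch in 1:3) {
    v <- pix[, , ch]
    add(stats::setNames(mean(v), paste0("mean_ch", ch)), FALSE)
    add(stats::setNames(stats::sd(as.vector(v)), paste0("sd_ch", ch)), TRUE)
  }
  q <- stats::quantile(luma, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  add(stats::setNames(q, paste0("luma_q", c(10, 25, 50, 75, 90))), FALSE)
  for (thr in c(0.3, 0.5, 0.7))
    add(stats::setNames(mean(luma < thr),
                        sprintf("dark_frac_%02.0f", 100 * thr)), FALSE)

  gx <- luma[2:(h - 1), 3:w] - luma[2:(h - 1), 1:(w - 2)]
  gy <- luma[3:h, 2:(w - 1)] - luma[1:(h - 2), 2:(w - 1)]
  mag <- sqrt(gx^2 + gy^2)
  add(c(grad_mean_gx = mean(abs(gx)), grad_mean_gy = mean(abs(gy)),
        grad_energy = mean(mag^2),
        grad_anisotropy = mean(abs(gy)) - mean(abs(gx))), TRUE)
  ang <- atan2(gy, gx)
  bins <- findInterval(ang, seq(-pi, pi, length.out = 9L),
                       rightmost.closed = TRUE)
  ohist <- vapply(1:8, function(b) sum(mag[bins == b]) / length(mag),
                  numeric(1))
  add(stats::setNames(ohist, paste0("orient_", 1:8)), TRUE)

  # band-pass statistics are shift-invariant; removing the mean first makes
  # them exactly zero (not merely tiny) on a constant field
  luma_c <- luma - mean(luma)
  for (s in c(2L, 4L, 8L)) {
    if (h >= 2 * s && w >= 2 * s) {
      a <- .box_valid(luma_c, s); b <- .box_valid(luma_c, 2L * s)
      bp <- .crop_to(a, nrow(b), ncol(b)) - b
      add(stats::setNames(mean(bp^2), paste0("bandpass_e_s", s)), TRUE)
    } else add(stats::setNames(0, paste0("bandpass_e_s", s)), TRUE)
  }
  for (s in c(2L, 4L)) {
    # 1-D box differences along rows (vertical structure) vs columns
    cs <- rbind(0, apply(luma_c, 2L, cumsum))
    run <- function(k) (cs[(1L + k):(h + 1L), ] - cs[1:(h - k + 1L), ]) / k
    a <- run(s); b <- run(2L * s)
    vs <- mean((a[seq_len(nrow(b)) + ((nrow(a) - nrow(b)) %/% 2L), ] - b)^2)
    cs2 <- cbind(0, t(apply(luma_c, 1L, cumsum)))
    runc <- function(k) (cs2[, (1L + k):(w + 1L)] - cs2[, 1:(w - k + 1L)]) / k
    a2 <- runc(s); b2 <- runc(2L * s)
    hs <- mean((a2[, seq_len(ncol(b2)) + ((ncol(a2) - ncol(b2)) %/% 2L)] -
                  b2)^2)
    add(stats::setNames(c(vs, hs),
                        paste0(c("oriented_v_s", "oriented_h_s"), s)), TRUE)
  }
  structure(f, contrast_type = ct)
}

.n_base_features <- function(resize = 128L) {
  length(texture_base_features(array(0.5, dim = c(16L, 16L, 3L)), resize))
}

#' Deterministic texture feature backend
#'
#' Computes the [texture_base_features()] bank per patch and expands it to
#' `n_features` by a fixed, seeded random linear projection (entries
#' N(0, 1)/sqrt(n_base)), preserving the geometry of a CNN QIF matrix while
#' remaining fully offline and deterministic.
#'
#' @param n_features Output width (default 4096).
#' @param seed Projection seed.
#' @param resize Patch subsampling target passed to the base bank.
#' @return A `feature_backend`.
#' @export
texture_backend <- function(n_features = 4096L, seed = 1L, resize = 128L) {
  check_number(n_features, "n_features", lo = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  n_base <- .n_base_features(resize)
  W <- with_seed(seed_stream(seed, "texture_projection"),
                 matrix(stats::rnorm(n_base * n_features), n_base,
                        n_features) / sqrt(n_base))
  structure(list(name = "texture", n_features = as.integer(n_features),
                 deterministic = TRUE,
                 config = list(seed = as.integer(seed),
                               resize = as.integer(resize),
                               n_base = n_base),
                 fn = function(pixels)
                   as.numeric(texture_base_features(pixels, resize) %*% W)),
            class = "feature_backend")
}

#' CNN feature backend reading a locally provisioned ONNX model
#'
#' Interface to the original extractor: an AlexNet pretrained on ImageNet
#' whose named fully-connected layer (4,096 units) supplies the QIF vector.
#' The model file must already exist locally; this function never attempts
#' any network access, and inference is delegated to a user-supplied
#' `runner` function `(pixels, model_path, layer) -> numeric vector` backed
#' by whatever ONNX runtime the user has.
#'
#' @param model_path Path to the ONNX model file.
#' @param layer Name of the layer to read activations from (required; for
#'   AlexNet either fully-connected layer has 4,096 outputs).
#' @param n_features Expected layer width (default 4096).
#' @param runner Inference function; errors at extraction time if absent.
#' @return A `feature_backend`.
#' @export
onnx_cnn_backend <- function(model_path, layer, n_features = 4096L,
                             runner = NULL) {
  if (!file.exists(model_path))
    stop("ONNX model file not found: ", model_path,
         " — provision it manually (no network access is attempted)",
         call. = FALSE)
  if (missing(layer) || !nzchar(layer))
    abort_field("layer", "a layer name is required")
  check_number(n_features, "n_features", lo = 1, integer = TRUE)
  structure(list(name = "onnx_cnn", n_features = as.integer(n_features),
                 deterministic = TRUE,
                 config = list(model_path = model_path, layer = layer),
                 fn = function(pixels) {
                   if (is.null(runner))
                     stop("no ONNX runner supplied: pass `runner` to ",
                          "onnx_cnn_backend()", call. = FALSE)
                   runner(pixels, model_path, layer)
                 }),
            class = "feature_backend")
}

#' @export
print.feature_backend <- function(x, ...) {
  cat(sprintf("feature_backend '%s': %d features, %sdeterministic\n",
              x$name, x$n_features, if (x$deterministic) "" else "non-"))
  invisible(x)
}

#' Extract the QIF matrix of a patch set
#'
#' One feature vector per patch, in patch order; the result is the
#' `n_patches x n_features` QIF matrix of the biopsy.
#'
#' @param patches A `patch_set` from [sample_patches()].
#' @param backend A `feature_backend`.
#' @return A `qif_matrix`.
#' @export
extract_features <- function(patches, backend) {
  stopifnot(inherits(patches, "patch_set"),
            inherits(backend, "feature_backend"))
  if (length(patches$patches) == 0L)
    stop("patch set is empty", call. = FALSE)
  rows <- lapply(patches$patches, function(p) {
    v <- tryCatch(backend$fn(p$pixels), error = function(e)
      stop("backend '", backend$name, "' failed on patch ", p$patch_id,
           ": ", conditionMessage(e), call. = FALSE))
    if (length(v) != backend$n_features)
      stop("backend returned ", length(v), " features for patch ",
           p$patch_id, " (expected ", backend$n_features, ")",
           call. = FALSE)
    if (!all(is.finite(v)))
      stop("non-finite feature values on patch ", p$patch_id, call. = FALSE)
    v
  })
  values <- do.call(rbind, rows)
  pid <- vapply(patches$patches, `[[`, integer(1), "patch_id")
  rownames(values) <- pid
  structure(list(biopsy_id = patches$biopsy_id, values = values,
                 n_features = backend$n_features,
                 backend_name = backend$name, patch_ids = pid),
            class = "qif_matrix")
}

#' @export
print.qif_matrix <- function(x, ...) {
  cat(sprintf("qif_matrix '%s': %d patches x %d features (backend %s)\n",
              x$biopsy_id, nrow(x$values), x$n_features, x$backend_name))
  invisible(x)
}
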
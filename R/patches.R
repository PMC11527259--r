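# Dermis-restricted random patch sampling from a masked slide raster.

#' Patch edge length for a target area
#'
#' Square patches: `side_px = round(1000 * sqrt(area_mm2) / microns_per_pixel)`
#' (0.16 mm^2 at 1 um/px gives 400 px).
#'
#' @param area_mm2 Target patch area in mm^2.
#' @param microns_per_pixel Pixel pitch.
#' @return Integer side length in pixels.
#' @export
patch_side_px <- function(area_mm2, microns_per_pixel) {
  check_number(area_mm2, "area_mm2", lo = .Machine$double.eps)
  check_number(microns_per_pixel, "microns_per_pixel",
               lo = .Machine$double.eps)
  as.integer(round(1000 * sqrt(area_mm2) / microns_per_pixel))
}

# Sums of `ind` over every side x side window, for all top-left corners,
# via a padded integral image (exact integer arithmetic in doubles).
.window_sums <- function(ind, side) {
  h <- nrow(ind); w <- ncol(ind)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- t(apply(apply(ind, 2L, cumsum), 1L, cumsum))
  nr <- h - side + 1L; nc <- w - side + 1L
  S[(1L + side):(h + 1L), (1L + side):(w + 1L), drop = FALSE] -
    S[1:nr, (1L + side):(w + 1L), drop = FALSE] -
    S[(1L + side):(h + 1L), 1:nc, drop = FALSE] +
    S[1:nr, 1:nc, drop = FALSE]
}

#' Sample area-calibrated patches from the dermis
#'
#' Draws `n` square patches of `patch_area_mm2` whose pixels are at least
#' `min_dermis_fraction` dermis (and whose centre pixel is dermis), uniformly
#' among all eligible top-left corners, without positional replacement. If
#' fewer than `n` eligible corners exist, sampling continues with
#' replacement and a warning is issued. Deterministic for a fixed seed.
#' Pixel coordinates are 0-based, row-major, with the patch origin at its
#' top-left corner.
#'
#' @param image A [biopsy_image()] (mask required).
#' @param n Number of patches (default 100).
#' @param patch_area_mm2 Patch area (default 0.16 mm^2).
#' @param seed Integer sampling seed.
#' @param min_dermis_fraction Minimum fraction of dermis pixels per patch.
#' @param biopsy_id Identifier recorded in the patch set.
#' @return A `patch_set`: list of patches plus sampling provenance.
#' @export
sample_patches <- function(image, n = 100L, patch_area_mm2 = 0.16,
                           seed = 1L, min_dermis_fraction = 0.9,
                           biopsy_id = "biopsy") {
  stopifnot(inherits(image, "biopsy_image"))
  check_number(n, "n", lo = 1, integer = TRUE)
  check_number(min_dermis_fraction, "min_dermis_fraction", lo = 0, hi = 1)
  check_number(seed, "seed", integer = TRUE)
  side <- patch_side_px(patch_area_mm2, image$microns_per_pixel)
  h <- nrow(image$mask); w <- ncol(image$mask)
  if (h < side || w < side)
    stop(sprintf("image (%d x %d) cannot hold a %d px patch", h, w, side),
         call. = FALSE)
  dermis <- image$mask == MASK_DERMIS
  if (!any(dermis))
    stop("sampling error: mask contains no dermis pixels", call. = FALSE)

  frac <- .window_sums(dermis + 0, side) / (side * side)
  half <- side %/% 2L
  nr <- h - side + 1L; nc <- w - side + 1L
  centre <- dermis[(1:nr) + half, (1:nc) + half, drop = FALSE]
  eligible <- which(frac >= min_dermis_fraction & centre)
  if (length(eligible) == 0L)
    stop("sampling error: no eligible patch position (dermis fraction >= ",
         min_dermis_fraction, ")", call. = FALSE)

  idx <- with_seed(seed, {
    if (length(eligible) >= n) eligible[sample.int(length(eligible), n)]
    else {
      warning(sprintf(paste0("only %d eligible positions for %d patches; ",
                             "sampling with replacement"),
                      length(eligible), n), call. = FALSE)
      c(eligible[sample.int(length(eligible))],
        eligible[sample.int(length(eligible), n - length(eligible),
                            replace = TRUE)])
    }
  })
  area <- (side * image$microns_per_pixel / 1000)^2
  patches <- lapply(seq_along(idx), function(k) {
    r <- ((idx[k] - 1L) %% nr) + 1L
    c0 <- ((idx[k] - 1L) %/% nr) + 1L
    list(patch_id = k,
         origin_rc = c(r - 1L, c0 - 1L),
         side_px = side,
         pixels = image$pixels[r:(r + side - 1L), c0:(c0 + side - 1L), ,
                               drop = FALSE],
         area_mm2 = area,
         dermis_fraction = frac[idx[k]])
  })
  structure(list(biopsy_id = biopsy_id, patches = patches,
                 sampling_seed = as.integer(seed),
                 n_requested = as.integer(n),
                 microns_per_pixel = image$microns_per_pixel),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set '%s': %d patches of %d px (%.3g mm^2), seed %d\n",
              x$biopsy_id, length(x$patches), x$patches[[1]]$side_px,
              x$patches[[1]]$area_mm2, x$sampling_seed))
  invisible(x)
}

#' Patch provenance manifest
#'
#' @param patch_set A `patch_set`.
#' @return Data frame: biopsy_id, patch_id, row, col (0-based origins),
#'   side_px, dermis_fraction, seed.
#' @export
patch_manifest <- function(patch_set) {
  stopifnot(inherits(patch_set, "patch_set"))
  do.call(rbind, lapply(patch_set$patches, function(p)
    data.frame(biopsy_id = patch_set$biopsy_id, patch_id = p$patch_id,
               row = p$origin_rc[1], col = p$origin_rc[2],
               side_px = p$side_px, dermis_fraction = p$dermis_fraction,
               seed = patch_set$sampling_seed)))
}
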
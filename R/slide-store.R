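# Raster I/O: TIFF/PNG slides with JSON sidecars, and a directory-based
# chunked uint8 array store for whole-slide rasters (scanner exports are
# converted once, then read back chunk-wise downstream).

.sidecar_path <- function(image_path) {
  cands <- c(paste0(image_path, ".json"),
             paste0(tools::file_path_sans_ext(image_path), ".json"))
  cands[file.exists(cands)][1]
}

.read_raster <- function(image_path) {
  ext <- tolower(tools::file_ext(image_path))
  if (ext %in% c("tif", "tiff")) tiff::readTIFF(image_path)
  else if (ext == "png") png::readPNG(image_path)
  else stop("unsupported raster format: .", ext, call. = FALSE)
}

#' Write a biopsy image (raster, mask, sidecar) to disk
#'
#' The raster goes to `<prefix>.tiff` (8-bit RGB), the compartment mask to
#' `<prefix>_mask.tiff` (single channel, codes stored as code/255), and the
#' calibration plus label legend to `<prefix>.json`.
#'
#' @param image A [biopsy_image()].
#' @param prefix Output path prefix (no extension).
#' @return Invisibly, the three file paths.
#' @export
write_biopsy_image <- function(image, prefix) {
  stopifnot(inherits(image, "biopsy_image"))
  paths <- c(image = paste0(prefix, ".tiff"),
             mask = paste0(prefix, "_mask.tiff"),
             sidecar = paste0(prefix, ".json"))
  tiff::writeTIFF(image$pixels, paths[["image"]], bits.per.sample = 8L)
  tiff::writeTIFF(image$mask / 255, paths[["mask"]], bits.per.sample = 8L)
  jsonlite::write_json(
    list(microns_per_pixel = image$microns_per_pixel,
         severity_truth = if (is.na(image$severity_truth)) NULL
                          else image$severity_truth,
         labels = list(background = 0L, epidermis = 1L, dermis = 2L,
                       subcutis = 3L)),
    paths[["sidecar"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a biopsy image written by [write_biopsy_image()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [biopsy_image()].
#' @export
read_biopsy_image <- function(prefix) {
  pix <- tiff::readTIFF(paste0(prefix, ".tiff"))
  mask <- round(tiff::readTIFF(paste0(prefix, "_mask.tiff")) * 255)
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  biopsy_image(pix, matrix(as.integer(mask), nrow(mask), ncol(mask)),
               as.numeric(meta$microns_per_pixel),
               severity_truth = as.numeric(meta$severity_truth %||%
                                             NA_real_))
}

#' Convert a slide raster into a chunked array store
#'
#' Scanner exports (TIFF/PNG) are copied losslessly into a directory store:
#' `attrs.json` records shape, chunk size, dtype and the micron-per-pixel
#' calibration; pixel data live in per-chunk `c<i>_<j>.bin` files of raw
#' uint8 bytes in R column-major order (channels last). Resolution metadata
#' must come from a JSON sidecar (`<path>.json` or `<stem>.json`) with a
#' `microns_per_pixel` field.
#'
#' @param image_path Path to a TIFF or PNG raster.
#' @param store_path Directory to create.
#' @param chunk_px Chunk edge length in pixels.
#' @return `store_path`, invisibly.
#' @export
convert_to_store <- function(image_path, store_path, chunk_px = 512L) {
  check_number(chunk_px, "chunk_px", lo = 1, integer = TRUE)
  sidecar <- .sidecar_path(image_path)
  if (is.na(sidecar) || is.null(sidecar))
    stop("no resolution metadata: provide a JSON sidecar ('", image_path,
         ".json') with a microns_per_pixel field", call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$microns_per_pixel))
    stop("sidecar ", sidecar, " lacks a microns_per_pixel field",
         call. = FALSE)
  pix <- .read_raster(image_path)
  if (length(dim(pix)) == 2L) dim(pix) <- c(dim(pix), 1L)
  u8 <- array(as.integer(round(pix * 255)), dim = dim(pix))

  dir.create(store_path, recursive = TRUE, showWarnings = FALSE)
  h <- dim(u8)[1]; w <- dim(u8)[2]; nch <- dim(u8)[3]
  nr <- ceiling(h / chunk_px); nc <- ceiling(w / chunk_px)
  for (i in seq_len(nr) - 1L) {
    for (j in seq_len(nc) - 1L) {
      rows <- (i * chunk_px + 1L):min((i + 1L) * chunk_px, h)
      cols <- (j * chunk_px + 1L):min((j + 1L) * chunk_px, w)
      block <- u8[rows, cols, , drop = FALSE]
      con <- file(file.path(store_path, sprintf("c%d_%d.bin", i, j)), "wb")
      writeBin(as.raw(block), con)
      close(con)
    }
  }
  jsonlite::write_json(
    list(shape = c(h, w, nch), chunk_px = chunk_px, dtype = "uint8",
         microns_per_pixel = meta$microns_per_pixel,
         labels = meta$labels),
    file.path(store_path, "attrs.json"), auto_unbox = TRUE, digits = NA)
  invisible(store_path)
}

#' Read a chunked store back into an array
#'
#' @param store_path Directory written by [convert_to_store()].
#' @return List with `pixels` (numeric array in \[0, 1\]) and `attrs`.
#' @export
read_store <- function(store_path) {
  attrs <- jsonlite::read_json(file.path(store_path, "attrs.json"),
                               simplifyVector = TRUE)
  shape <- attrs$shape; ck <- attrs$chunk_px
  u8 <- array(0L, dim = shape)
  nr <- ceiling(shape[1] / ck); nc <- ceiling(shape[2] / ck)
  for (i in seq_len(nr) - 1L) {
    for (j in seq_len(nc) - 1L) {
      rows <- (i * ck + 1L):min((i + 1L) * ck, shape[1])
      cols <- (j * ck + 1L):min((j + 1L) * ck, shape[2])
      path <- file.path(store_path, sprintf("c%d_%d.bin", i, j))
      n <- length(rows) * length(cols) * shape[3]
      con <- file(path, "rb")
      raw <- readBin(con, "raw", n = n)
      close(con)
      u8[rows, cols, ] <- array(as.integer(raw),
                                dim = c(length(rows), length(cols), shape[3]))
    }
  }
  list(pixels = u8 / 255, attrs = attrs)
}
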
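#' 8-bit RGB raster with physical pixel size
#'
#' Carrier for exported whole-slide-image (H&E/IHC) raster levels. Pyramidal
#' WSI decoding is out of scope; this type holds one rendered level plus its
#' resolution.
#'
#' @param pixels Integer array `(rows, cols, 3)`, values 0–255.
#' @param pixel_size_um Positive micrometres per pixel.
#' @param frame_id Coordinate-frame name (default `"wsi"`).
#' @return A `wsi_raster` object.
#' @export
wsi_raster <- function(pixels, pixel_size_um, frame_id = "wsi") {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0) {
    abort_elemap("pixel_size_um must be a positive scalar", "elemap_bad_pixel_size")
  }
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L | pixels > 255L)) {
    abort_elemap("pixel values must lie in 0..255", "elemap_parse_error")
  }
  structure(list(pixels = pixels, pixel_size_um = as.numeric(pixel_size_um),
                 frame_id = as.character(frame_id)),
            class = "wsi_raster")
}

#' @export
dim.wsi_raster <- function(x) dim(x$pixels)

#' @export
print.wsi_raster <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<wsi_raster> %d x %d px RGB, %.3g um/px, frame '%s'\n",
              d[1], d[2], x$pixel_size_um, x$frame_id))
  invisible(x)
}

#' Read a TIFF/PNG raster as an 8-bit RGB image
#'
#' Grayscale input is replicated to three channels; an alpha channel is
#' dropped. The pixel size comes from the caller when supplied, else from the
#' file's resolution metadata (TIFF XResolution tag, PNG pHYs/dpi).
#'
#' @param path `.png`, `.tif` or `.tiff` file.
#' @param pixel_size_um Micrometres per pixel; overrides file metadata.
#' @param frame_id Coordinate-frame name.
#' @return A [wsi_raster()].
#' @export
read_wsi_raster <- function(path, pixel_size_um = NULL, frame_id = "wsi") {
  if (!file.exists(path)) {
    abort_elemap(sprintf("image not found: %s", path), "elemap_io_error")
  }
  is_tiff <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  img <- tryCatch(
    if (is_tiff) tiff::readTIFF(path, info = TRUE) else png::readPNG(path, info = TRUE),
    error = function(e) abort_elemap(
      sprintf("unreadable image %s: %s", path, conditionMessage(e)), "elemap_io_error"))
  if (is.null(pixel_size_um)) {
    pixel_size_um <- raster_pixel_size(img, is_tiff)
    if (is.null(pixel_size_um)) {
      abort_elemap(sprintf("%s carries no resolution metadata; pass pixel_size_um", path),
                   "elemap_io_error")
    }
  }
  px <- as.array(img)
  if (length(dim(px)) == 2L) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] == 2L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]   # gray+alpha
  if (dim(px)[3] >= 4L) px <- px[, , 1:3, drop = FALSE]             # drop alpha
  pixels <- array(as.integer(round(px * 255)), dim(px))
  wsi_raster(pixels, pixel_size_um, frame_id)
}

raster_pixel_size <- function(img, is_tiff) {
  if (is_tiff) {
    res <- attr(img, "x.resolution")
    if (is.null(res) || !is.finite(res) || res <= 0) return(NULL)
    unit <- attr(img, "resolution.unit")
    per_um <- switch(if (is.null(unit)) "inch" else unit,
                     cm = res / 1e4, inch = res / 25400, res / 25400)
    1 / per_um
  } else {
    info <- attr(img, "info")
    dpi <- info$dpi
    if (is.null(dpi) || !all(is.finite(dpi)) || any(dpi <= 0)) return(NULL)
    25400 / dpi[1]
  }
}

#' Write an RGB raster with embedded resolution
#'
#' PNG output goes through [png::writePNG()] with the dpi derived from the
#' pixel size. TIFF output uses an internal minimal baseline-TIFF encoder
#' (uncompressed RGB) because the installed TIFF writer cannot emit
#' resolution tags; the files read back with any standard TIFF reader.
#'
#' @param raster A [wsi_raster()].
#' @param path Output `.png` / `.tif` path (format chosen by extension).
#' @return `path`, invisibly.
#' @export
write_wsi_raster <- function(raster, path) {
  stopifnot(inherits(raster, "wsi_raster"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    write_tiff_rgb(raster$pixels, path, raster$pixel_size_um)
  } else {
    png::writePNG(raster$pixels / 255, path, dpi = 25400 / raster$pixel_size_um)
  }
  invisible(path)
}

# Minimal little-endian baseline TIFF: one uncompressed RGB strip plus
# XResolution/YResolution (pixels per cm) so pixel size round-trips.
write_tiff_rgb <- function(pixels, path, pixel_size_um) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  entry <- function(tag, type, count, value) c(u16(tag), u16(type), u32(count), value)
  # interleave RGB row-major
  px <- aperm(pixels, c(3, 2, 1))                 # channel fastest, then col, then row
  strip <- as.raw(as.vector(px))
  data_off <- 8L
  bps_off <- data_off + length(strip)             # BitsPerSample 3x SHORT
  xres_off <- bps_off + 6L
  yres_off <- xres_off + 8L
  ifd_off <- yres_off + 8L
  res_num <- round(1e3 * 1e4 / pixel_size_um)     # pixels per cm, rational /1e3
  n_entries <- 12L
  ifd <- c(
    u16(n_entries),
    entry(256, 4, 1, u32(w)),                     # ImageWidth
    entry(257, 4, 1, u32(h)),                     # ImageLength
    entry(258, 3, 3, u32(bps_off)),               # BitsPerSample -> offset
    entry(259, 3, 1, c(u16(1), u16(0))),          # Compression = none
    entry(262, 3, 1, c(u16(2), u16(0))),          # Photometric = RGB
    entry(273, 4, 1, u32(data_off)),              # StripOffsets
    entry(277, 3, 1, c(u16(3), u16(0))),          # SamplesPerPixel
    entry(278, 4, 1, u32(h)),                     # RowsPerStrip
    entry(279, 4, 1, u32(length(strip))),         # StripByteCounts
    entry(282, 5, 1, u32(xres_off)),              # XResolution
    entry(283, 5, 1, u32(yres_off)),              # YResolution
    entry(296, 3, 1, c(u16(3), u16(0))),          # ResolutionUnit = cm
    u32(0)                                        # next IFD
  )
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("II"), u16(42), u32(ifd_off)), con)
  writeBin(strip, con)
  writeBin(c(u16(8), u16(8), u16(8)), con)
  writeBin(c(u32(res_num), u32(1e3)), con)
  writeBin(c(u32(res_num), u32(1e3)), con)
  writeBin(ifd, con)
  invisible(path)
}
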
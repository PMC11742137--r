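#' Resample a raster through a planar transform
#'
#' Pulls a source image into a target grid: each output pixel `(r, c)` is
#' sampled at `T^-1(physical center of (r, c))` in the source frame, where
#' `T` maps source-frame to target-frame micrometres. Pixel centers sit at
#' integer 0-based pixel coordinates times the pixel size. Out-of-bounds
#' samples get the fill value and are reported in the `"missing"` attribute.
#' Label or mask images must use nearest-neighbour interpolation.
#'
#' @param img Numeric matrix or `(rows, cols, bands)` array.
#' @param pixel_size_um Source pixel size, micrometres.
#' @param transform A [planar_transform()] from the source physical frame to
#'   the target physical frame.
#' @param out_shape `(rows, cols)` of the output grid.
#' @param out_pixel_size_um Target pixel size, micrometres.
#' @param interpolation `"nearest"` or `"bilinear"`.
#' @param fill Fill value for out-of-bounds samples (default 0).
#' @return Resampled matrix/array with a logical `"missing"` attribute
#'   marking out-of-bounds (or missing-source) pixels.
#' @export
resample_image <- function(img, pixel_size_um, transform, out_shape,
                           out_pixel_size_um,
                           interpolation = c("nearest", "bilinear"),
                           fill = 0) {
  interpolation <- match.arg(interpolation)
  if (out_pixel_size_um <= 0) {
    abort_elemap("out_pixel_size_um must be positive", "elemap_bad_pixel_size")
  }
  inv <- invert_transform(transform)
  was_matrix <- is.matrix(img)
  if (was_matrix) img <- array(img, c(dim(img), 1L))
  nr_out <- out_shape[1]; nc_out <- out_shape[2]
  nr_in <- dim(img)[1]; nc_in <- dim(img)[2]
  # physical centers of every output pixel
  col0 <- rep(seq_len(nc_out) - 1L, each = nr_out)
  row0 <- rep(seq_len(nr_out) - 1L, times = nc_out)
  src <- apply_to_points(inv, cbind(col0 * out_pixel_size_um, row0 * out_pixel_size_um))
  cx <- src[, 1] / pixel_size_um                  # fractional source col (0-based)
  cy <- src[, 2] / pixel_size_um                  # fractional source row
  out <- array(fill, c(nr_out, nc_out, dim(img)[3]))
  if (interpolation == "nearest") {
    ci <- round(cx); ri <- round(cy)
    inside <- ci >= 0 & ci <= nc_in - 1L & ri >= 0 & ri <= nr_in - 1L
    src_idx <- ri[inside] + 1L + (ci[inside]) * nr_in
    for (b in seq_len(dim(img)[3])) {
      band <- img[, , b]
      plane <- rep(fill, nr_out * nc_out)
      plane[inside] <- band[src_idx]
      out[, , b] <- plane
    }
    missing <- !inside
  } else {
    c0 <- floor(cx); r0 <- floor(cy)
    fx <- cx - c0; fy <- cy - r0
    inside <- c0 >= 0 & c0 + 1 <= nc_in - 1L & r0 >= 0 & r0 + 1 <= nr_in - 1L
    # clamp exact right/bottom edge samples onto the last cell
    edge <- cx >= 0 & cx <= nc_in - 1L & cy >= 0 & cy <= nr_in - 1L & !inside
    c0[edge] <- pmin(c0[edge], nc_in - 2L); r0[edge] <- pmin(r0[edge], nr_in - 2L)
    fx[edge] <- cx[edge] - c0[edge]; fy[edge] <- cy[edge] - r0[edge]
    inside <- inside | edge
    idx <- which(inside)
    i00 <- r0[idx] + 1L + c0[idx] * nr_in
    wx <- fx[idx]; wy <- fy[idx]
    for (b in seq_len(dim(img)[3])) {
      band <- img[, , b]
      v <- (1 - wx) * (1 - wy) * band[i00] +
           (1 - wx) * wy       * band[i00 + 1L] +
           wx       * (1 - wy) * band[i00 + nr_in] +
           wx       * wy       * band[i00 + nr_in + 1L]
      plane <- rep(fill, nr_out * nc_out)
      plane[idx] <- v
      out[, , b] <- plane
    }
    missing <- !inside
  }
  # propagate missing source values sampled into the output
  na_hit <- rowSums(is.na(array(out, c(nr_out * nc_out, dim(img)[3])))) > 0
  missing <- missing | na_hit
  missing <- matrix(missing, nr_out, nc_out)
  if (was_matrix) out <- out[, , 1, drop = TRUE]
  attr(out, "missing") <- missing
  out
}
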
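#' Multichannel elemental map
#'
#' The central raster container: a stack of per-element intensity images on a
#' common grid of square pixels, with an explicit missing-data mask. Values at
#' masked positions are stored as `NA` and are ignored by every downstream
#' statistic; the mask, not the `NA` payload, is authoritative.
#'
#' Coordinate convention (used throughout the package): rasters are row-major
#' with `(x, y) = (col, row)`, origin at the top-left pixel, pixel centers at
#' integer 0-based pixel coordinates, so the physical position of pixel
#' `(row r, col c)` (0-based) is `(c, r) * pixel_size_um` micrometres.
#'
#' @param data Numeric array `(rows, cols, channels)`; `NA` marks missing.
#' @param channel_names Character vector, one unique name per channel
#'   (e.g. `"Zn66"`). Defaults to `dimnames(data)[[3]]`.
#' @param pixel_size_um Positive scalar, micrometres per (square) pixel.
#' @param frame_id Name of the coordinate frame the map lives in.
#' @param missing Optional logical array like `data`; defaults to `is.na(data)`.
#'   Where `TRUE`, the stored value is forced to `NA`.
#' @param units Free-text unit string for the intensities (counts, µg/g, ...).
#'
#' @return An object of class `elemental_map`: a list with elements `data`,
#'   `missing`, `pixel_size_um`, `frame_id`, `units`.
#' @export
elemental_map <- function(data, channel_names = dimnames(data)[[3]],
                          pixel_size_um, frame_id = "elemental",
                          missing = NULL, units = "counts") {
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  nc <- dim(data)[3]
  if (is.null(channel_names)) {
    channel_names <- paste0("channel", seq_len(nc))
  }
  channel_names <- as.character(channel_names)
  if (length(channel_names) != nc) {
    abort_elemap(sprintf("%d channel names for %d channels", length(channel_names), nc),
                 "elemap_bad_channels")
  }
  if (anyDuplicated(channel_names)) {
    abort_elemap(sprintf("duplicate channel names: %s",
                         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", ")),
                 "elemap_bad_channels")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort_elemap("pixel_size_um must be a positive finite scalar", "elemap_bad_pixel_size")
  }
  storage.mode(data) <- "double"
  if (is.null(missing)) {
    missing <- is.na(data)
  } else {
    stopifnot(identical(dim(missing), dim(data)))
    missing <- missing | is.na(data)
  }
  data[missing] <- NA_real_
  dimnames(data) <- list(NULL, NULL, channel_names)
  dimnames(missing) <- dimnames(data)
  structure(
    list(data = data, missing = missing,
         pixel_size_um = as.numeric(pixel_size_um),
         frame_id = as.character(frame_id), units = as.character(units)),
    class = "elemental_map"
  )
}

#' @export
dim.elemental_map <- function(x) dim(x$data)

#' Channel names of an elemental map
#' @param map An `elemental_map`.
#' @return Character vector of channel (element) names.
#' @export
channel_names <- function(map) dimnames(map$data)[[3]]

#' Extract one channel as a matrix
#' @param map An `elemental_map`.
#' @param channel Channel name or index.
#' @return Numeric matrix (`NA` at missing positions).
#' @export
map_channel <- function(map, channel) {
  if (is.character(channel) && !channel %in% channel_names(map)) {
    abort_elemap(sprintf("unknown channel '%s'; available: %s", channel,
                         paste(channel_names(map), collapse = ", ")),
                 "elemap_unknown_channel")
  }
  map$data[, , channel, drop = TRUE]
}

#' @export
print.elemental_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<elemental_map> %d x %d px, %d channel(s), %.3g um/px, frame '%s'\n",
              d[1], d[2], d[3], x$pixel_size_um, x$frame_id))
  cat(sprintf("  channels: %s\n", paste(channel_names(x), collapse = ", ")))
  n_miss <- sum(x$missing)
  cat(sprintf("  missing:  %d / %d values (%.1f%%), units: %s\n",
              n_miss, length(x$missing), 100 * n_miss / length(x$missing), x$units))
  invisible(x)
}

#' Tidy an elemental map into a long pixel table
#'
#' One row per (pixel, channel) with 0-based pixel indices and physical
#' coordinates; missing values are kept as `NA` (filter them out explicitly if
#' unwanted).
#'
#' @param x An `elemental_map`.
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `x_um`, `y_um`, `channel`,
#'   `value`, `missing`.
#' @method tidy elemental_map
#' @export
tidy.elemental_map <- function(x, ...) {
  d <- dim(x$data)
  row0 <- rep(seq_len(d[1]) - 1L, times = d[2] * d[3])
  col0 <- rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3])
  tibble::tibble(
    row = row0, col = col0,
    x_um = col0 * x$pixel_size_um, y_um = row0 * x$pixel_size_um,
    channel = rep(channel_names(x), each = d[1] * d[2]),
    value = as.vector(x$data),
    missing = as.vector(x$missing)
  )
}

#' Heatmap of one channel of an elemental map
#'
#' @param map An `elemental_map`.
#' @param channel Channel to display (default first).
#' @param trans `"pseudo_log"` (default, `log1p`) or `"identity"`.
#' @return A ggplot object.
#' @export
plot_elemental_map <- function(map, channel = channel_names(map)[1],
                               trans = c("pseudo_log", "identity")) {
  trans <- match.arg(trans)
  df <- tidy.elemental_map(map)
  df <- dplyr::filter(df, .data$channel == !!channel, !.data$missing)
  if (trans == "pseudo_log") df$value <- log1p(df$value)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(name = if (trans == "pseudo_log") "log1p" else map$units) +
    ggplot2::labs(title = channel, x = "x (µm)", y = "y (µm)")
}
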
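#' Persist an elemental map as a chunked zarr-style store
#'
#' Writes a directory laid out like a (single-scale) zarr v2 group: a root
#' `.zgroup`/`.zattrs`, an array `data` of shape `(channel, row, col)` chunked
#' `(1, 512, 512)` in C order with dtype `<f8`, and a parallel `missing_mask`
#' array (`|u1`). Channel names, pixel size, frame id and units live in the
#' group attributes. The layout is readable by standard zarr v2 readers.
#'
#' @param map An [elemental_map()].
#' @param path Directory to create (or overwrite).
#' @param overwrite Replace an existing store at `path`.
#' @return `path`, invisibly.
#' @seealso [read_store()]
#' @export
write_store <- function(map, path, overwrite = TRUE) {
  stopifnot(inherits(map, "elemental_map"))
  if (dir.exists(path)) {
    if (!overwrite) abort_elemap(sprintf("store exists: %s", path), "elemap_io_error")
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  json_write(list(zarr_format = 2L), file.path(path, ".zgroup"))
  json_write(list(channel_names = as.list(channel_names(map)),
                  pixel_size_um = map$pixel_size_um,
                  frame_id = map$frame_id,
                  units = map$units),
             file.path(path, ".zattrs"))
  data <- map$data
  data[map$missing] <- NaN
  zarr_write_array(file.path(path, "data"), data, dtype = "<f8")
  mask <- array(as.integer(map$missing), dim(map$missing))
  zarr_write_array(file.path(path, "missing_mask"), mask, dtype = "|u1")
  invisible(path)
}

#' Read an elemental map back from a zarr-style store
#'
#' Inverse of [write_store()]: data, channel names, pixel size, frame id and
#' the missing mask round-trip bit-exactly.
#'
#' @param path Store directory written by [write_store()].
#' @return An [elemental_map()].
#' @export
read_store <- function(path) {
  attrs_path <- file.path(path, ".zattrs")
  if (!dir.exists(path) || !file.exists(attrs_path)) {
    abort_elemap(sprintf("not a map store (missing .zattrs): %s", path),
                 "elemap_store_error")
  }
  attrs <- tryCatch(jsonlite::read_json(attrs_path),
                    error = function(e) abort_elemap(
                      sprintf("corrupt store metadata in %s: %s", path, conditionMessage(e)),
                      "elemap_store_error"))
  need <- c("channel_names", "pixel_size_um", "frame_id")
  if (!all(need %in% names(attrs))) {
    abort_elemap(sprintf("store metadata lacks %s",
                         paste(setdiff(need, names(attrs)), collapse = ", ")),
                 "elemap_store_error")
  }
  data <- zarr_read_array(file.path(path, "data"))
  mask_arr <- zarr_read_array(file.path(path, "missing_mask"))
  missing <- array(mask_arr != 0, dim(mask_arr))
  data[missing] <- NA_real_
  elemental_map(data, channel_names = unlist(attrs$channel_names),
                pixel_size_um = attrs$pixel_size_um,
                frame_id = attrs$frame_id, missing = missing,
                units = if (is.null(attrs$units)) "counts" else attrs$units)
}

#' Attach a named 2-D array to an existing store
#'
#' Used for derived rasters (`tissue_mask`, `region_labels`) so they travel
#' with the map they were computed from.
#'
#' @param path Store directory.
#' @param name Array name within the group.
#' @param values Logical or integer matrix with the map's spatial shape.
#' @param attrs Optional named list written as the array's `.zattrs`.
#' @return `path`, invisibly.
#' @export
store_write_raster <- function(path, name, values, attrs = NULL) {
  if (!dir.exists(path)) {
    abort_elemap(sprintf("no store at %s", path), "elemap_store_error")
  }
  stopifnot(is.matrix(values))
  arr <- array(as.integer(values), c(dim(values), 1L))
  arr <- aperm(arr, c(1, 2, 3))
  zarr_write_array(file.path(path, name), arr,
                   dtype = if (is.logical(values)) "|u1" else "<i4")
  if (!is.null(attrs)) json_write(attrs, file.path(path, name, ".zattrs"))
  invisible(path)
}

#' Read a named 2-D array from a store
#' @param path Store directory.
#' @param name Array name (e.g. `"tissue_mask"`).
#' @return Integer matrix.
#' @export
store_read_raster <- function(path, name) {
  arr <- zarr_read_array(file.path(path, name))
  arr[, , 1, drop = TRUE]
}

# --- minimal zarr v2 array codec ------------------------------------------
# Arrays come in as R arrays [row, col, channel]; on disk the shape is
# (channel, row, col), C (row-major) order, uncompressed chunks (1, 512, 512),
# edge chunks padded to full size with the fill value.

zarr_dtypes <- list(
  "<f8" = list(size = 8L, what = "double",  fill = NaN),
  "<i4" = list(size = 4L, what = "integer", fill = 0L),
  "|u1" = list(size = 1L, what = "integer", fill = 0L)
)

zarr_write_array <- function(dir, arr, dtype, chunk_rc = c(512L, 512L)) {
  dt <- zarr_dtypes[[dtype]]
  stopifnot(!is.null(dt), length(dim(arr)) == 3L)
  d <- dim(arr)                                   # rows, cols, channels
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(zarr_format = 2L,
               shape = c(d[3], d[1], d[2]),
               chunks = c(1L, chunk_rc[1], chunk_rc[2]),
               dtype = dtype,
               compressor = NULL, filters = NULL,
               fill_value = if (dtype == "<f8") "NaN" else 0L,
               order = "C")
  # compressor/filters must serialize as JSON null, not be dropped
  jsonlite::write_json(meta, file.path(dir, ".zarray"), auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  n_cr <- ceiling(d[1] / chunk_rc[1])
  n_cc <- ceiling(d[2] / chunk_rc[2])
  for (ch in seq_len(d[3])) {
    for (ci in seq_len(n_cr)) {
      rows <- ((ci - 1L) * chunk_rc[1] + 1L):min(ci * chunk_rc[1], d[1])
      for (cj in seq_len(n_cc)) {
        cols <- ((cj - 1L) * chunk_rc[2] + 1L):min(cj * chunk_rc[2], d[2])
        block <- matrix(dt$fill, chunk_rc[1], chunk_rc[2])
        block[seq_along(rows), seq_along(cols)] <- arr[rows, cols, ch]
        con <- file(file.path(dir, sprintf("%d.%d.%d", ch - 1L, ci - 1L, cj - 1L)), "wb")
        v <- as.vector(t(block))                  # row-major = C order
        if (dt$what == "integer") v <- as.integer(v)
        writeBin(v, con, size = dt$size, endian = "little")
        close(con)
      }
    }
  }
  invisible(dir)
}

zarr_read_array <- function(dir) {
  meta_path <- file.path(dir, ".zarray")
  if (!file.exists(meta_path)) {
    abort_elemap(sprintf("missing array metadata: %s", meta_path), "elemap_store_error")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  dt <- zarr_dtypes[[meta$dtype]]
  if (is.null(dt)) {
    abort_elemap(sprintf("unsupported dtype '%s' in %s", meta$dtype, meta_path),
                 "elemap_store_error")
  }
  shape <- as.integer(meta$shape)                 # channel, row, col
  chunks <- as.integer(meta$chunks)
  arr <- array(if (dt$what == "double") NA_real_ else NA_integer_,
               c(shape[2], shape[3], shape[1]))
  n_cr <- ceiling(shape[2] / chunks[2])
  n_cc <- ceiling(shape[3] / chunks[3])
  for (ch in seq_len(shape[1])) {
    for (ci in seq_len(n_cr)) {
      rows <- ((ci - 1L) * chunks[2] + 1L):min(ci * chunks[2], shape[2])
      for (cj in seq_len(n_cc)) {
        cols <- ((cj - 1L) * chunks[3] + 1L):min(cj * chunks[3], shape[3])
        f <- file.path(dir, sprintf("%d.%d.%d", ch - 1L, ci - 1L, cj - 1L))
        if (!file.exists(f)) {
          abort_elemap(sprintf("missing chunk %s", f), "elemap_store_error")
        }
        con <- file(f, "rb")
        v <- readBin(con, dt$what, n = chunks[2] * chunks[3], size = dt$size,
                     endian = "little", signed = meta$dtype != "|u1")
        close(con)
        block <- matrix(v, chunks[2], chunks[3], byrow = TRUE)
        arr[rows, cols, ch] <- block[seq_along(rows), seq_along(cols)]
      }
    }
  }
  arr
}

json_write <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}
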
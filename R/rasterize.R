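#' Integer label raster of annotated regions
#'
#' @param labels Integer matrix, 0 = background.
#' @param label_table Named character vector mapping id (name) to label.
#' @param pixel_size_um Micrometres per pixel.
#' @param frame_id Frame name.
#' @return A `region_label_map`.
#' @export
region_label_map <- function(labels, label_table, pixel_size_um, frame_id) {
  storage.mode(labels) <- "integer"
  used <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(as.character(used) %in% names(label_table))) {
    abort_elemap("label raster contains ids absent from label_table",
                 "elemap_bad_annotation")
  }
  structure(list(labels = labels, label_table = label_table,
                 pixel_size_um = as.numeric(pixel_size_um),
                 frame_id = as.character(frame_id)),
            class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  cat(sprintf("<region_label_map> %d x %d px, %.3g um/px, frame '%s'\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um, x$frame_id))
  counts <- table(factor(x$labels[x$labels > 0L], levels = names(x$label_table)))
  for (id in names(x$label_table)) {
    cat(sprintf("  [%s] %s: %d px\n", id, x$label_table[[id]], counts[[id]]))
  }
  invisible(x)
}

#' Rasterize annotations onto a pixel grid
#'
#' A pixel takes the id of the *last* annotation (input order, matching the
#' z-order of annotation tools) whose filled polygon contains the pixel
#' center under the even-odd rule (holes excluded); uncovered pixels are 0.
#' Pixel centers sit at integer 0-based pixel coordinates times
#' `pixel_size_um`.
#'
#' @param set An [annotation_set()] in the raster's frame.
#' @param shape `(rows, cols)` of the target grid.
#' @param pixel_size_um Micrometres per pixel of the target grid.
#' @return A [region_label_map()].
#' @export
rasterize_annotations <- function(set, shape, pixel_size_um) {
  stopifnot(inherits(set, "annotation_set"))
  nr <- shape[1]; nc <- shape[2]
  labels <- matrix(0L, nr, nc)
  ids <- stats::setNames(set$label_table$id, set$label_table$label)
  for (a in set$annotations) {
    rings <- c(list(a$exterior), a$holes)
    # candidate pixels: bounding box of the exterior ring
    bb <- apply(a$exterior, 2, range)
    cols <- seq(max(0L, ceiling(bb[1, 1] / pixel_size_um)),
                min(nc - 1L, floor(bb[2, 1] / pixel_size_um)))
    rows <- seq(max(0L, ceiling(bb[1, 2] / pixel_size_um)),
                min(nr - 1L, floor(bb[2, 2] / pixel_size_um)))
    if (length(cols) == 0L || length(rows) == 0L) next
    px <- rep(cols, each = length(rows)) * pixel_size_um
    py <- rep(rows, times = length(cols)) * pixel_size_um
    inside <- points_in_rings(px, py, rings)
    if (any(inside)) {
      ri <- rep(rows, times = length(cols))[inside] + 1L
      ci <- rep(cols, each = length(rows))[inside] + 1L
      labels[cbind(ri, ci)] <- ids[[a$label]]
    }
  }
  region_label_map(labels,
                   stats::setNames(set$label_table$label, as.character(set$label_table$id)),
                   pixel_size_um, set$frame_id)
}

# Even-odd containment: a point is inside when a ray to +x crosses the union
# of all rings an odd number of times.  Boundary pixels resolve by strict
# center containment (points exactly on an edge follow the half-open
# crossing rule below).
points_in_rings <- function(px, py, rings) {
  crossings <- integer(length(px))
  for (ring in rings) {
    n <- nrow(ring)
    x1 <- ring[, 1]; y1 <- ring[, 2]
    nxt <- c(seq_len(n)[-1], 1L)
    x2 <- ring[nxt, 1]; y2 <- ring[nxt, 2]
    for (e in seq_len(n)) {
      straddles <- (y1[e] > py) != (y2[e] > py)
      if (any(straddles)) {
        x_int <- x1[e] + (py - y1[e]) * (x2[e] - x1[e]) / (y2[e] - y1[e])
        crossings <- crossings + (straddles & px < x_int)
      }
    }
  }
  crossings %% 2L == 1L
}

#' Write a label map preview PNG with a fixed colour table
#' @param lmap A [region_label_map()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_labels_png <- function(lmap, path) {
  palette <- grDevices::col2rgb(c(
    "#ffffff", "#e41a1c", "#377eb8", "#4daf4a", "#984ea3", "#ff7f00",
    "#ffff33", "#a65628", "#f781bf", "#999999", "#66c2a5", "#fc8d62")) / 255
  idx <- (as.vector(lmap$labels) %% (ncol(palette) - 1L)) + 1L
  idx[as.vector(lmap$labels) == 0L] <- 1L
  idx[as.vector(lmap$labels) > 0L] <- (as.vector(lmap$labels)[as.vector(lmap$labels) > 0L] - 1L) %%
    (ncol(palette) - 1L) + 2L
  img <- array(0, c(dim(lmap$labels), 3))
  for (ch in 1:3) img[, , ch] <- matrix(palette[ch, idx], nrow(lmap$labels))
  png::writePNG(img, path)
  invisible(path)
}

#' Tidy a region label map into a pixel table
#' @param x A `region_label_map`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `id`, `label` (NA for background).
#' @method tidy region_label_map
#' @export
tidy.region_label_map <- function(x, ...) {
  ids <- as.vector(x$labels)
  tibble::tibble(
    row = rep(seq_len(nrow(x$labels)) - 1L, ncol(x$labels)),
    col = rep(seq_len(ncol(x$labels)) - 1L, each = nrow(x$labels)),
    id = ids,
    label = ifelse(ids == 0L, NA_character_, unname(x$label_table[as.character(ids)])))
}
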
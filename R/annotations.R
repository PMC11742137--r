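#' A labelled polygon annotation
#'
#' One pathologist-drawn region: a simple exterior ring with optional holes,
#' in physical micrometres of a named frame. Rings are stored open (the
#' closing vertex is not repeated).
#'
#' @param label Region label, e.g. `"Tumor"`.
#' @param exterior Two-column matrix of (x, y) vertices, >= 3 distinct.
#' @param holes List of hole rings (two-column matrices).
#' @param frame_id Coordinate-frame name.
#' @return An `annotation` object.
#' @export
annotation <- function(label, exterior, holes = list(), frame_id = "wsi") {
  exterior <- ring_matrix(exterior)
  if (nrow(unique(exterior)) < 3L) {
    abort_elemap(sprintf("annotation '%s' needs >= 3 distinct vertices", label),
                 "elemap_bad_annotation")
  }
  if (polygon_area(exterior) <= 0) {
    abort_elemap(sprintf("annotation '%s' has zero area", label), "elemap_bad_annotation")
  }
  holes <- lapply(holes, ring_matrix)
  structure(list(label = as.character(label), exterior = exterior,
                 holes = holes, frame_id = as.character(frame_id)),
            class = "annotation")
}

ring_matrix <- function(x) {
  m <- base::matrix(as.numeric(as.matrix(x)), ncol = 2)
  # drop a repeated closing vertex
  if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  colnames(m) <- c("x", "y")
  m
}

#' Shoelace area of a polygon ring
#' @param ring Two-column vertex matrix (open ring).
#' @return Unsigned area.
#' @export
polygon_area <- function(ring) {
  ring <- ring_matrix(ring)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' An ordered set of annotations in one frame
#'
#' @param annotations List of [annotation()] objects sharing a frame.
#' @param frame_id Frame name; defaults to the annotations' frame.
#' @return An `annotation_set` with a `label_table` tibble assigning
#'   contiguous integer ids (1, 2, ...) to labels in order of first
#'   appearance.
#' @export
annotation_set <- function(annotations, frame_id = NULL) {
  stopifnot(all(vapply(annotations, inherits, TRUE, "annotation")))
  frames <- unique(vapply(annotations, function(a) a$frame_id, ""))
  if (is.null(frame_id)) {
    frame_id <- if (length(frames)) frames[1] else "wsi"
  }
  if (length(frames) > 1L || (length(frames) == 1L && !identical(frames, frame_id))) {
    abort_elemap(sprintf("annotations span frames [%s] but set frame is '%s'",
                         paste(frames, collapse = ", "), frame_id),
                 "elemap_frame_mismatch")
  }
  labels <- unique(vapply(annotations, function(a) a$label, ""))
  structure(list(annotations = annotations, frame_id = as.character(frame_id),
                 label_table = tibble::tibble(id = seq_along(labels), label = labels)),
            class = "annotation_set")
}

#' @export
length.annotation_set <- function(x) length(x$annotations)

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d annotation(s) in frame '%s'\n",
              length(x$annotations), x$frame_id))
  if (nrow(x$label_table)) {
    counts <- table(vapply(x$annotations, function(a) a$label, ""))
    for (i in seq_len(nrow(x$label_table))) {
      lb <- x$label_table$label[i]
      cat(sprintf("  [%d] %s (%d polygon(s))\n", x$label_table$id[i], lb, counts[[lb]]))
    }
  }
  invisible(x)
}

#' Tidy annotations into a long vertex table
#' @param x An `annotation_set`.
#' @param ... Unused.
#' @return Tibble with `annotation`, `label`, `ring` ("exterior" or
#'   "hole<k>"), `vertex`, `x_um`, `y_um`.
#' @method tidy annotation_set
#' @export
tidy.annotation_set <- function(x, ...) {
  purrr::imap_dfr(x$annotations, function(a, i) {
    rings <- c(list(exterior = a$exterior),
               stats::setNames(a$holes, paste0("hole", seq_along(a$holes))))
    purrr::imap_dfr(rings, function(r, nm) {
      tibble::tibble(annotation = i, label = a$label, ring = nm,
                     vertex = seq_len(nrow(r)), x_um = r[, 1], y_um = r[, 2])
    })
  })
}

#' Read QuPath-dialect GeoJSON annotations
#'
#' Expects a `FeatureCollection` of Polygon / MultiPolygon features with
#' coordinates in WSI pixels; they are converted to micrometres via
#' `pixel_size_um`. The label is taken from `properties.classification.name`,
#' else `properties.name`, else `"unclassified"`. MultiPolygons are split
#' into one annotation per part; within each polygon the first ring is the
#' exterior and the rest are holes. Non-polygon geometries are skipped with a
#' warning.
#'
#' @param path GeoJSON file.
#' @param pixel_size_um WSI micrometres per pixel.
#' @param frame_id Frame name for the resulting set.
#' @return An [annotation_set()].
#' @export
parse_geojson <- function(path, pixel_size_um, frame_id = "wsi") {
  gj <- tryCatch(jsonlite::read_json(path),
                 error = function(e) abort_elemap(
                   sprintf("malformed GeoJSON %s: %s", path, conditionMessage(e)),
                   "elemap_parse_error"))
  feats <- gj$features
  if (is.null(feats)) {
    abort_elemap(sprintf("%s is not a FeatureCollection", path), "elemap_parse_error")
  }
  anns <- list(); skipped <- 0L
  for (f in feats) {
    geom <- f$geometry
    gtype <- geom$type %||% ""
    label <- f$properties$classification$name %||% f$properties$name %||% "unclassified"
    polys <- switch(gtype,
                    Polygon = list(geom$coordinates),
                    MultiPolygon = geom$coordinates,
                    { skipped <- skipped + 1L; list() })
    for (p in polys) {
      rings <- lapply(p, function(ring) {
        do.call(rbind, lapply(ring, function(v) c(v[[1]], v[[2]]))) * pixel_size_um
      })
      anns[[length(anns) + 1L]] <- annotation(label, rings[[1]],
                                              holes = rings[-1], frame_id = frame_id)
    }
  }
  if (skipped > 0L) {
    warn(sprintf("skipped %d non-polygon feature(s) in %s", skipped, path))
  }
  out <- annotation_set(anns, frame_id = frame_id)
  attr(out, "n_skipped") <- skipped
  out
}

#' Write annotations as QuPath-compatible GeoJSON
#'
#' Micrometre coordinates are converted back to WSI pixels; each annotation
#' becomes one Polygon feature with `classification.name` set.
#'
#' @param set An [annotation_set()].
#' @param path Output path.
#' @param pixel_size_um WSI micrometres per pixel.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(set, path, pixel_size_um) {
  stopifnot(inherits(set, "annotation_set"))
  close_ring <- function(m) rbind(m, m[1, , drop = FALSE]) / pixel_size_um
  features <- lapply(set$annotations, function(a) {
    rings <- c(list(a$exterior), a$holes)
    coords <- lapply(rings, function(r) {
      cr <- close_ring(r)
      lapply(seq_len(nrow(cr)), function(i) as.list(unname(cr[i, ])))
    })
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = coords),
         properties = list(objectType = "annotation",
                           classification = list(name = a$label)))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = features),
                           auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read ASAP XML annotations
#'
#' Parses an `<ASAP_Annotations>` document; `Polygon`-type annotations become
#' polygons (vertices sorted by their `Order` attribute), other types are
#' skipped with a warning. The label comes from the `PartOfGroup` attribute
#' (unless `"None"`), else from the annotation `Name`. Coordinates are WSI
#' pixels, converted to micrometres.
#'
#' @inheritParams parse_geojson
#' @return An [annotation_set()].
#' @export
parse_asap_xml <- function(path, pixel_size_um, frame_id = "wsi") {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort_elemap(
                    sprintf("malformed XML %s: %s", path, conditionMessage(e)),
                    "elemap_parse_error"))
  nodes <- xml2::xml_find_all(doc, ".//Annotation")
  anns <- list(); skipped <- 0L
  for (node in nodes) {
    type <- xml2::xml_attr(node, "Type")
    if (!identical(type, "Polygon")) { skipped <- skipped + 1L; next }
    group <- xml2::xml_attr(node, "PartOfGroup")
    label <- if (is.na(group) || identical(group, "None")) {
      nm <- xml2::xml_attr(node, "Name")
      if (is.na(nm)) "unclassified" else nm
    } else group
    coords <- xml2::xml_find_all(node, ".//Coordinate")
    ord <- as.numeric(xml2::xml_attr(coords, "Order"))
    x <- as.numeric(xml2::xml_attr(coords, "X"))
    y <- as.numeric(xml2::xml_attr(coords, "Y"))
    o <- order(ord)
    anns[[length(anns) + 1L]] <- annotation(label, cbind(x[o], y[o]) * pixel_size_um,
                                            frame_id = frame_id)
  }
  if (skipped > 0L) {
    warn(sprintf("skipped %d non-polygon annotation(s) in %s", skipped, path))
  }
  annotation_set(anns, frame_id = frame_id)
}

#' Map annotations through a planar transform
#'
#' Every vertex is mapped by `transform`; labels and ring structure are
#' preserved and the set lands in the transform's target frame.
#'
#' @param set An [annotation_set()] in the transform's source frame.
#' @param transform A [planar_transform()].
#' @return The transformed [annotation_set()].
#' @export
transform_annotations <- function(set, transform) {
  if (!identical(set$frame_id, transform$source_frame_id)) {
    abort_elemap(sprintf("annotation frame '%s' does not match transform source '%s'",
                         set$frame_id, transform$source_frame_id),
                 "elemap_frame_mismatch")
  }
  anns <- lapply(set$annotations, function(a) {
    annotation(a$label,
               apply_to_points(transform, a$exterior),
               holes = lapply(a$holes, function(h) apply_to_points(transform, h)),
               frame_id = transform$target_frame_id)
  })
  annotation_set(anns, frame_id = transform$target_frame_id)
}
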
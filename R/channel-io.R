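#' Read one per-element channel grid
#'
#' Reads a single rectangular numeric grid — the shape in which acquisition
#' software such as iolite exports one elemental channel per file (or per
#' Excel sheet). Empty cells become explicit missing markers (`NA`), never
#' zeros.
#'
#' @param path Path to a `.csv` or `.xlsx` file.
#' @param dialect `"csv"` or `"excel"`; `"auto"` (default) decides from the
#'   file extension.
#' @param has_header If `TRUE`, the first row and first column are treated as
#'   header/index decoration and stripped before parsing the numeric grid.
#' @param element_name Channel name; defaults to the Excel sheet name, else
#'   the file stem.
#' @param sheet Sheet (name or index) for Excel input; default first sheet.
#'
#' @return A `channel_grid`: list with `element` (string), `values` (numeric
#'   matrix, `NA` = missing), `source_path`.
#' @export
read_channel_table <- function(path, dialect = c("auto", "csv", "excel"),
                               has_header = FALSE, element_name = NULL,
                               sheet = 1L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort_elemap(sprintf("channel file not found: %s", path), "elemap_io_error")
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) "excel" else "csv"
  }
  if (dialect == "csv") {
    values <- parse_csv_grid(path, has_header = has_header)
    if (is.null(element_name)) {
      element_name <- tools::file_path_sans_ext(basename(path))
    }
  } else {
    sheets <- readxl::excel_sheets(path)
    sheet_name <- if (is.numeric(sheet)) sheets[[sheet]] else sheet
    # with a header row/index column present the sheet is mixed-type, so read
    # as text, strip the decoration, then convert
    x <- suppressWarnings(readxl::read_excel(
      path, sheet = sheet, col_names = FALSE,
      col_types = if (has_header) "text" else "numeric",
      .name_repair = "minimal"))
    values <- unname(as.matrix(x))
    if (has_header) {
      values <- strip_header(values, path)
      values <- matrix(suppressWarnings(as.numeric(values)),
                       nrow(values), ncol(values))
    }
    if (is.null(element_name)) element_name <- sheet_name
  }
  storage.mode(values) <- "double"
  if (length(values) == 0L || all(is.na(values))) {
    abort_elemap(sprintf("no numeric cells in %s", path), "elemap_empty_grid")
  }
  if (any(values < 0, na.rm = TRUE)) {
    abort_elemap(sprintf("negative intensities in %s", path), "elemap_parse_error")
  }
  structure(list(element = as.character(element_name), values = values,
                 source_path = as.character(path)),
            class = "channel_grid")
}

strip_header <- function(values, path) {
  if (nrow(values) < 2L || ncol(values) < 2L) {
    abort_elemap(sprintf("has_header = TRUE but %s has no row/column to strip", path),
                 "elemap_parse_error")
  }
  values[-1L, -1L, drop = FALSE]
}

# Strict CSV grid parser: equal-length rows, numeric-or-empty cells.  Written
# by hand (rather than read.csv) so ragged rows fail loudly with the row
# number instead of being recycled or padded.  The optional header row /
# index column is stripped before numeric validation.
parse_csv_grid <- function(path, has_header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) == 0L) {
    abort_elemap(sprintf("no numeric cells in %s", path), "elemap_empty_grid")
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  # trailing empty field: "1,2," splits to 2 pieces in R; count separators
  width <- lengths(fields)
  n_sep <- lengths(regmatches(lines, gregexpr(",", lines, fixed = TRUE)))
  width <- pmax(width, n_sep + 1L)
  if (length(unique(width)) != 1L) {
    bad <- which(width != width[1])[1]
    abort_elemap(
      sprintf("ragged CSV grid in %s: row %d has %d fields, expected %d",
              path, bad, width[bad], width[1]),
      "elemap_parse_error", row = bad)
  }
  cells <- do.call(rbind, lapply(fields, function(f) {
    f <- trimws(f)
    length(f) <- width[1]           # restore trailing empties
    f[is.na(f) | f == ""] <- NA_character_
    f
  }))
  if (has_header) cells <- strip_header(cells, path)
  vals <- matrix(suppressWarnings(as.numeric(cells)), nrow(cells), ncol(cells))
  bad <- which(!is.na(cells) & is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    abort_elemap(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                         cells[bad[1, , drop = FALSE]], bad[1, 1], bad[1, 2], path),
                 "elemap_parse_error", row = unname(bad[1, 1]))
  }
  vals
}

#' Consolidate per-element grids into one elemental map
#'
#' Stacks single-channel grids (in input order) into an [elemental_map()],
#' propagating each grid's missing markers into the map's missing mask.
#'
#' @param grids List of `channel_grid` objects sharing one shape.
#' @param pixel_size_um Micrometres per pixel of the common grid.
#' @param frame_id Coordinate-frame name for the map.
#' @param units Intensity units, kept as metadata.
#' @return An `elemental_map` with one channel per input grid, in order.
#' @export
consolidate_channels <- function(grids, pixel_size_um, frame_id = "elemental",
                                 units = "counts") {
  if (length(grids) == 0L) {
    abort_elemap("need at least one channel grid", "elemap_bad_channels")
  }
  if (inherits(grids, "channel_grid")) grids <- list(grids)
  shapes <- lapply(grids, function(g) dim(g$values))
  ref <- shapes[[1]]
  for (k in seq_along(shapes)) {
    if (!identical(shapes[[k]], ref)) {
      abort_elemap(
        sprintf("channel '%s' is %dx%d but channel '%s' is %dx%d",
                grids[[k]]$element, shapes[[k]][1], shapes[[k]][2],
                grids[[1]]$element, ref[1], ref[2]),
        "elemap_shape_mismatch")
    }
  }
  names_ <- vapply(grids, function(g) g$element, "")
  if (anyDuplicated(names_)) {
    abort_elemap(sprintf("duplicate element name(s): %s",
                         paste(unique(names_[duplicated(names_)]), collapse = ", ")),
                 "elemap_bad_channels")
  }
  data <- array(NA_real_, c(ref, length(grids)))
  for (k in seq_along(grids)) data[, , k] <- grids[[k]]$values
  elemental_map(data, channel_names = names_, pixel_size_um = pixel_size_um,
                frame_id = frame_id, units = units)
}
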
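#' Specification for a paired synthetic fixture
#'
#' Describes a seeded, fully reproducible synthetic dataset emulating one
#' profiled tissue section: a tissue disc with disjoint annotated regions,
#' per-region hurdle-gamma elemental abundance, a ground-truth planar
#' transform between the elemental-map frame and the WSI frame, noisy
#' landmark correspondences, and optional missing ablation rows.
#'
#' Pixel sizes default to the scales typical of the two modalities
#' (0.25 µm/px H&E versus 5 µm/px elemental). Region geometry is circular
#' (regular 32-gon polygons) and disjoint by construction; each region
#' carries `p_zero` (hurdle zero probability), `gamma_shape` and
#' `gamma_mean` for its positive abundance, either scalars (shared by all
#' elements) or vectors named by element.
#'
#' @param seed Integer seed; fully determines every output.
#' @param wsi_pixel_size_um WSI resolution (default 0.25).
#' @param elem_pixel_size_um Elemental-map resolution (default 5).
#' @param map_shape Elemental-map `(rows, cols)` (default 160 x 160).
#' @param elements Channel names to simulate.
#' @param regions List of region specs: `list(label, center = c(x, y) um,
#'   radius um, p_zero, gamma_shape, gamma_mean)`.
#' @param tissue Disc geometry and baseline abundance of unannotated tissue:
#'   `list(center, radius, p_zero, gamma_shape, gamma_mean)`.
#' @param background Off-tissue abundance parameters (near-zero).
#' @param true_transform Optional [planar_transform()] elemental -> WSI; when
#'   `NULL` a similarity transform is sampled (rotation within 15 degrees,
#'   scale 0.95-1.05, translation 20-80 µm per axis, within the plausible
#'   serial-section misalignment range).
#' @param landmark_n Number of landmark pairs (default 8).
#' @param landmark_noise_um SD of Gaussian noise added to the fixed-side
#'   landmarks (default 1 µm).
#' @param missing_rows 1-based elemental-map rows masked missing in every
#'   channel (incomplete ablation; default none).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed,
                         wsi_pixel_size_um = 0.25,
                         elem_pixel_size_um = 5,
                         map_shape = c(160L, 160L),
                         elements = c("P31", "Ca44", "Fe57", "Cu65", "Zn66"),
                         regions = NULL,
                         tissue = list(center = c(400, 400), radius = 350,
                                       p_zero = 0.2, gamma_shape = 2, gamma_mean = 5),
                         background = list(p_zero = 0.6, gamma_shape = 1, gamma_mean = 0.02),
                         true_transform = NULL,
                         landmark_n = 8L,
                         landmark_noise_um = 1,
                         missing_rows = integer(0)) {
  if (is.null(regions)) {
    regions <- list(
      list(label = "Tumor",  center = c(260, 260), radius = 130,
           p_zero = 0.1, gamma_shape = 2,   gamma_mean = 20),
      list(label = "Stroma", center = c(540, 260), radius = 130,
           p_zero = 0.3, gamma_shape = 2,   gamma_mean = 8),
      list(label = "Duct",   center = c(260, 540), radius = 125,
           p_zero = 0.2, gamma_shape = 3,   gamma_mean = 12),
      list(label = "Fat",    center = c(540, 540), radius = 125,
           p_zero = 0.5, gamma_shape = 1.5, gamma_mean = 4))
  }
  # regions must be disjoint and inside the tissue disc
  k <- length(regions)
  for (i in seq_len(k)) {
    ri <- regions[[i]]
    if (sqrt(sum((ri$center - tissue$center)^2)) + ri$radius > tissue$radius) {
      abort_elemap(sprintf("region '%s' extends outside the tissue disc", ri$label),
                   "elemap_bad_fixture")
    }
    for (j in seq_len(i - 1L)) {
      rj <- regions[[j]]
      if (sqrt(sum((ri$center - rj$center)^2)) < ri$radius + rj$radius) {
        abort_elemap(sprintf("regions '%s' and '%s' overlap", rj$label, ri$label),
                     "elemap_bad_fixture")
      }
    }
  }
  structure(list(seed = as.integer(seed),
                 wsi_pixel_size_um = wsi_pixel_size_um,
                 elem_pixel_size_um = elem_pixel_size_um,
                 map_shape = as.integer(map_shape),
                 elements = elements, regions = regions, tissue = tissue,
                 background = background, true_transform = true_transform,
                 landmark_n = as.integer(landmark_n),
                 landmark_noise_um = landmark_noise_um,
                 missing_rows = as.integer(missing_rows)),
            class = "fixture_spec")
}

# run code under a given seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    else if (exists(".Random.seed", .GlobalEnv)) rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

circle_polygon <- function(center, radius, n = 32L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Generate a paired synthetic fixture
#'
#' Builds, from a [fixture_spec()], the full simulated study: the elemental
#' map (values drawn per region from its hurdle-gamma law, near-zero
#' background, missing rows masked), pathologist-style annotations in the
#' WSI frame (region polygons pushed through the true transform), noisy
#' landmark pairs, an optionally rendered WSI raster of the same geometry,
#' and the ground truth needed to score every downstream stage.
#'
#' @param spec A [fixture_spec()] (or a bare seed, for all defaults).
#' @param render_wsi Render the RGB WSI raster (default `TRUE`; the raster is
#'   large at 0.25 µm/px, so stages that never look at H&E pixels can skip
#'   it).
#' @return List with `map` ([elemental_map()]), `annotations`
#'   ([annotation_set()] in the WSI frame), `landmarks`
#'   ([landmark_pairs()]), `wsi` ([wsi_raster()] or `NULL`), and `truth`:
#'   the spec plus the concrete `transform`, the painted `tissue_mask`, the
#'   elemental-frame `label_map` and a `region_params` tibble.
#' @export
make_fixture <- function(spec, render_wsi = TRUE) {
  if (is.numeric(spec)) spec <- fixture_spec(spec)
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    transform <- spec$true_transform
    if (is.null(transform)) transform <- sample_similarity(spec$tissue$center)
    nr <- spec$map_shape[1]; nc <- spec$map_shape[2]
    px <- spec$elem_pixel_size_um

    # region polygons and their raster in the elemental frame
    elem_anns <- lapply(spec$regions, function(r) {
      annotation(r$label, circle_polygon(r$center, r$radius), frame_id = "elemental")
    })
    elem_set <- annotation_set(elem_anns, frame_id = "elemental")
    label_map <- rasterize_annotations(elem_set, c(nr, nc), px)

    # tissue disc at pixel centers
    cx <- rep(seq_len(nc) - 1L, each = nr) * px
    cy <- rep(seq_len(nr) - 1L, times = nc) * px
    in_disc <- (cx - spec$tissue$center[1])^2 + (cy - spec$tissue$center[2])^2 <=
      spec$tissue$radius^2
    tissue_mask <- matrix(in_disc, nr, nc)

    # categories: 0 background, 1..k regions, k+1 plain tissue
    k <- length(spec$regions)
    cat_vec <- as.vector(label_map$labels)
    cat_vec[cat_vec == 0L & in_disc] <- k + 1L
    cat_params <- c(spec$regions, list(c(spec$tissue, label = ".tissue")))

    data <- array(NA_real_, c(nr, nc, length(spec$elements)))
    for (e in seq_along(spec$elements)) {
      el <- spec$elements[e]
      v <- numeric(nr * nc)
      bg <- cat_vec == 0L
      v[bg] <- draw_hurdle(sum(bg), spec$background$p_zero,
                           spec$background$gamma_shape, spec$background$gamma_mean)
      for (ci in seq_len(k + 1L)) {
        idx <- cat_vec == ci
        if (!any(idx)) next
        p <- cat_params[[ci]]
        v[idx] <- draw_hurdle(sum(idx), param_for(p$p_zero, el),
                              param_for(p$gamma_shape, el), param_for(p$gamma_mean, el))
      }
      data[, , e] <- matrix(v, nr, nc)
    }
    missing <- array(FALSE, dim(data))
    rows_ok <- spec$missing_rows[spec$missing_rows >= 1L & spec$missing_rows <= nr]
    if (length(rows_ok)) missing[rows_ok, , ] <- TRUE
    data[missing] <- NA_real_
    map <- elemental_map(data, channel_names = spec$elements,
                         pixel_size_um = px, frame_id = "elemental",
                         missing = missing)

    annotations <- transform_annotations(elem_set, transform)

    # landmarks: true correspondences in the disc + Gaussian noise on fixed side
    th <- stats::runif(spec$landmark_n, 0, 2 * pi)
    rr <- spec$tissue$radius * 0.9 * sqrt(stats::runif(spec$landmark_n))
    moving <- cbind(spec$tissue$center[1] + rr * cos(th),
                    spec$tissue$center[2] + rr * sin(th))
    fixed <- apply_to_points(transform, moving) +
      matrix(stats::rnorm(2L * spec$landmark_n, 0, spec$landmark_noise_um),
             ncol = 2)
    landmarks <- landmark_pairs(fixed, moving, "wsi", "elemental")

    wsi <- if (render_wsi) render_wsi_raster(spec, transform) else NULL

    region_params <- purrr::map_dfr(spec$regions, function(r) {
      tibble::tibble(label = r$label, element = spec$elements,
                     p_zero = param_for(r$p_zero, spec$elements),
                     gamma_shape = param_for(r$gamma_shape, spec$elements),
                     gamma_mean = param_for(r$gamma_mean, spec$elements))
    })
    list(map = map, annotations = annotations, landmarks = landmarks, wsi = wsi,
         truth = list(spec = spec, transform = transform,
                      tissue_mask = tissue_mask, label_map = label_map,
                      region_params = region_params))
  })
}

param_for <- function(p, element) {
  if (length(p) == 1L && is.null(names(p))) return(rep(unname(p), length(element)))
  out <- p[element]
  if (any(is.na(out))) {
    abort_elemap("per-element parameter vector lacks some elements", "elemap_bad_fixture")
  }
  unname(out)
}

draw_hurdle <- function(n, p_zero, shape, mean) {
  z <- stats::rbinom(n, 1L, 1 - p_zero)
  v <- numeric(n)
  npos <- sum(z == 1L)
  if (npos) v[z == 1L] <- stats::rgamma(npos, shape = shape, scale = mean / shape)
  v
}

# rotation <= 15 deg about the tissue center, scale 0.95-1.05, translation
# 20-80 um per axis: plausible serial-section misalignment
sample_similarity <- function(center) {
  th <- stats::runif(1, -15, 15) * pi / 180
  s <- stats::runif(1, 0.95, 1.05)
  t_xy <- stats::runif(2, 20, 80)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  A <- s * R
  t_vec <- center - A %*% center + t_xy
  planar_transform(cbind(A, t_vec), "similarity",
                   source_frame_id = "elemental", target_frame_id = "wsi")
}

# Paint the WSI raster by inverse-mapping every WSI pixel center into the
# elemental frame and classifying it against the analytic disc/region
# circles (the <0.5 um circle-vs-32-gon sliver is cosmetic only).
render_wsi_raster <- function(spec, transform) {
  inv <- invert_transform(transform)
  wpx <- spec$wsi_pixel_size_um
  corners <- matrix(c(0, 0,
                      (spec$map_shape[2] - 1L) * spec$elem_pixel_size_um, 0,
                      0, (spec$map_shape[1] - 1L) * spec$elem_pixel_size_um,
                      (spec$map_shape[2] - 1L) * spec$elem_pixel_size_um,
                      (spec$map_shape[1] - 1L) * spec$elem_pixel_size_um),
                    ncol = 2, byrow = TRUE)
  tc <- apply_to_points(transform, corners)
  nc_w <- ceiling(max(tc[, 1]) / wpx) + 1L
  nr_w <- ceiling(max(tc[, 2]) / wpx) + 1L
  cx <- rep(seq_len(nc_w) - 1L, each = nr_w) * wpx
  cy <- rep(seq_len(nr_w) - 1L, times = nc_w) * wpx
  src <- apply_to_points(inv, cbind(cx, cy))
  x <- src[, 1]; y <- src[, 2]
  # background: near-white with H&E-ish texture; tissue: pink; regions shaded
  shade <- list(c(228, 160, 180), c(150, 170, 220), c(170, 210, 160),
                c(210, 190, 140), c(190, 160, 210), c(160, 200, 200))
  r_ch <- rep(250L, nr_w * nc_w); g_ch <- rep(250L, nr_w * nc_w); b_ch <- rep(250L, nr_w * nc_w)
  d2t <- (x - spec$tissue$center[1])^2 + (y - spec$tissue$center[2])^2
  tis <- d2t <= spec$tissue$radius^2
  r_ch[tis] <- 242L; g_ch[tis] <- 205L; b_ch[tis] <- 215L
  for (i in seq_along(spec$regions)) {
    rg <- spec$regions[[i]]
    inside <- (x - rg$center[1])^2 + (y - rg$center[2])^2 <= rg$radius^2
    col <- shade[[(i - 1L) %% length(shade) + 1L]]
    r_ch[inside] <- col[1]; g_ch[inside] <- col[2]; b_ch[inside] <- col[3]
  }
  pixels <- array(0L, c(nr_w, nc_w, 3L))
  pixels[, , 1] <- matrix(r_ch, nr_w, nc_w)
  pixels[, , 2] <- matrix(g_ch, nr_w, nc_w)
  pixels[, , 3] <- matrix(b_ch, nr_w, nc_w)
  wsi_raster(pixels, wpx, frame_id = "wsi")
}

#' Write per-channel grid files for a map
#'
#' Emulates acquisition-software exports: one rectangular numeric grid per
#' channel, as CSV (empty fields for missing) or single-sheet XLSX (sheet
#' named after the element, missing cells absent). Reading the files back
#' with [read_channel_table()] and [consolidate_channels()] reproduces the
#' map exactly.
#'
#' @param map An [elemental_map()].
#' @param dir Output directory (created if needed).
#' @param dialect `"csv"` or `"excel"`.
#' @return Character vector of file paths, one per channel.
#' @export
make_channel_files <- function(map, dir, dialect = c("csv", "excel")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(map, "elemental_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(channel_names(map), function(el) {
    m <- map$data[, , el]
    if (dialect == "csv") {
      path <- file.path(dir, paste0(el, ".csv"))
      # %.17g keeps doubles round-trippable (write.table truncates digits)
      txt <- matrix(sprintf("%.17g", m), nrow(m), ncol(m))
      txt[is.na(m)] <- ""
      writeLines(apply(txt, 1, paste, collapse = ","), path)
    } else {
      path <- file.path(dir, paste0(el, ".xlsx"))
      write_xlsx_grid(m, path, sheet = el)
    }
    path
  }, "")
}

#' Write a complete fixture directory
#'
#' Emits every artifact a real study would provide: per-channel grid files,
#' the WSI raster (PNG with embedded resolution), QuPath-style GeoJSON
#' annotations in WSI pixels, the landmark CSV, and a `truth.json` with the
#' ground-truth transform and simulation parameters.
#'
#' @param fixture Output of [make_fixture()].
#' @param dir Output directory.
#' @param dialect Channel-file dialect, `"csv"` or `"excel"`.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(fixture, dir, dialect = "csv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- fixture$truth$spec
  make_channel_files(fixture$map, file.path(dir, "channels"), dialect)
  if (!is.null(fixture$wsi)) {
    write_wsi_raster(fixture$wsi, file.path(dir, "wsi.png"))
  }
  write_geojson(fixture$annotations, file.path(dir, "annotations.geojson"),
                spec$wsi_pixel_size_um)
  write_landmarks(fixture$landmarks, file.path(dir, "landmarks.csv"))
  json_write(list(seed = spec$seed,
                  transform = list(matrix = fixture$truth$transform$matrix,
                                   model = fixture$truth$transform$model,
                                   source_frame_id = fixture$truth$transform$source_frame_id,
                                   target_frame_id = fixture$truth$transform$target_frame_id),
                  wsi_pixel_size_um = spec$wsi_pixel_size_um,
                  elem_pixel_size_um = spec$elem_pixel_size_um,
                  map_shape = spec$map_shape,
                  elements = spec$elements,
                  landmark_noise_um = spec$landmark_noise_um,
                  missing_rows = spec$missing_rows,
                  region_params = fixture$truth$region_params),
             file.path(dir, "truth.json"))
  invisible(dir)
}
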
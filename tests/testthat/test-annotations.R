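square_geojson <- function(path, label = "Tumor", with_class = TRUE) {
  props <- if (with_class) {
    sprintf('{"objectType":"annotation","classification":{"name":"%s"}}', label)
  } else "{}"
  writeLines(sprintf(paste0(
    '{"type":"FeatureCollection","features":[{"type":"Feature",',
    '"geometry":{"type":"Polygon","coordinates":[[[0,0],[100,0],[100,100],[0,100],[0,0]]]},',
    '"properties":%s}]}'), props), path)
  path
}

test_that("QuPath GeoJSON squares parse with classification labels", {
  f <- withr::local_tempfile(fileext = ".geojson")
  square_geojson(f)
  set <- parse_geojson(f, pixel_size_um = 0.25)
  expect_length(set$annotations, 1L)
  expect_identical(set$annotations[[1]]$label, "Tumor")
  # pixel -> micron conversion applied, closing vertex dropped
  expect_equal(set$annotations[[1]]$exterior,
               cbind(x = c(0, 25, 25, 0), y = c(0, 0, 25, 25)))
})

test_that("features without classification fall back to 'unclassified'", {
  f <- withr::local_tempfile(fileext = ".geojson")
  square_geojson(f, with_class = FALSE)
  set <- parse_geojson(f, 1)
  expect_identical(set$annotations[[1]]$label, "unclassified")
})

test_that("non-polygon geometries are skipped with a warning and counted", {
  f <- withr::local_tempfile(fileext = ".geojson")
  writeLines(paste0(
    '{"type":"FeatureCollection","features":[',
    '{"type":"Feature","geometry":{"type":"Point","coordinates":[1,2]},"properties":{}},',
    '{"type":"Feature","geometry":{"type":"Polygon",',
    '"coordinates":[[[0,0],[10,0],[10,10],[0,0]]]},"properties":{}}]}'), f)
  expect_warning(set <- parse_geojson(f, 1), "1 non-polygon")
  expect_length(set$annotations, 1L)
  expect_identical(attr(set, "n_skipped"), 1L)
  bad <- withr::local_tempfile(fileext = ".geojson")
  writeLines("{oops", bad)
  expect_error(parse_geojson(bad, 1), class = "elemap_parse_error")
})

test_that("GeoJSON round-trip preserves labels, holes and vertices to 1e-9", {
  set.seed(51)
  donut <- annotation("Lobule",
                      random_polygon(c(200, 220), 120, 150, 9),
                      holes = list(random_polygon(c(200, 220), 20, 40, 6)))
  tri <- annotation("Ünicode–ß", cbind(c(10, 60, 35.5), c(10, 15, 70)))
  set <- annotation_set(list(donut, tri), frame_id = "wsi")
  f <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(set, f, pixel_size_um = 0.25)
  back <- parse_geojson(f, pixel_size_um = 0.25)
  expect_length(back$annotations, 2L)
  for (i in 1:2) {
    expect_identical(back$annotations[[i]]$label, set$annotations[[i]]$label)
    expect_equal(back$annotations[[i]]$exterior, set$annotations[[i]]$exterior,
                 tolerance = 1e-9)
  }
  expect_equal(back$annotations[[1]]$holes[[1]], donut$holes[[1]], tolerance = 1e-9)
})

test_that("an empty set writes a valid FeatureCollection with zero features", {
  f <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(annotation_set(list(), frame_id = "wsi"), f, 0.25)
  gj <- jsonlite::read_json(f)
  expect_identical(gj$type, "FeatureCollection")
  expect_length(gj$features, 0L)
  expect_length(parse_geojson(f, 0.25)$annotations, 0L)
})

asap_xml <- function(path, shuffle = FALSE) {
  ord <- c(0, 1, 2, 3)
  xy <- list(c(0, 0), c(40, 0), c(40, 40), c(0, 40))
  idx <- if (shuffle) c(3, 1, 4, 2) else 1:4
  coords <- paste(vapply(idx, function(i) {
    sprintf('<Coordinate Order="%d" X="%g" Y="%g"/>', ord[i], xy[[i]][1], xy[[i]][2])
  }, ""), collapse = "")
  writeLines(sprintf(paste0(
    '<?xml version="1.0"?><ASAP_Annotations><Annotations>',
    '<Annotation Name="Annotation 0" Type="Polygon" PartOfGroup="Stroma" Color="#F4FA58">',
    '<Coordinates>%s</Coordinates></Annotation>',
    '<Annotation Name="Dot 1" Type="Dot" PartOfGroup="None">',
    '<Coordinates><Coordinate Order="0" X="1" Y="1"/></Coordinates></Annotation>',
    '</Annotations><AnnotationGroups/></ASAP_Annotations>'), coords), path)
  path
}

test_that("ASAP XML polygons parse with group labels and Order-sorted vertices", {
  f <- withr::local_tempfile(fileext = ".xml")
  asap_xml(f)
  expect_warning(set <- parse_asap_xml(f, pixel_size_um = 0.5), "non-polygon")
  expect_length(set$annotations, 1L)
  a <- set$annotations[[1]]
  expect_identical(a$label, "Stroma")
  expect_equal(a$exterior, cbind(x = c(0, 20, 20, 0), y = c(0, 0, 20, 20)))

  # same document with shuffled elements parses identically
  f2 <- withr::local_tempfile(fileext = ".xml")
  asap_xml(f2, shuffle = TRUE)
  expect_warning(set2 <- parse_asap_xml(f2, pixel_size_um = 0.5))
  expect_equal(set2$annotations[[1]]$exterior, a$exterior)
})

test_that("empty and malformed ASAP documents behave as specified", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines('<?xml version="1.0"?><ASAP_Annotations><Annotations/></ASAP_Annotations>', f)
  expect_length(parse_asap_xml(f, 1)$annotations, 0L)
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<unclosed", bad)
  expect_error(parse_asap_xml(bad, 1), class = "elemap_parse_error")
})

test_that("transforming annotations maps vertices and scales area by |det A|", {
  sq <- annotation("A", cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), frame_id = "elemental")
  set <- annotation_set(list(sq))
  id <- planar_transform(cbind(diag(2), c(0, 0)), "rigid", "elemental", "wsi")
  moved <- transform_annotations(set, id)
  expect_equal(moved$annotations[[1]]$exterior, sq$exterior)
  expect_identical(moved$frame_id, "wsi")

  s2 <- planar_transform(cbind(2 * diag(2), c(0, 0)), "similarity", "elemental", "wsi")
  expect_equal(polygon_area(transform_annotations(set, s2)$annotations[[1]]$exterior),
               4 * polygon_area(sq$exterior))

  wrong <- planar_transform(cbind(diag(2), c(0, 0)), "rigid", "other", "wsi")
  expect_error(transform_annotations(set, wrong), class = "elemap_frame_mismatch")
})

test_that("polygon area transforms by |det A| under random affines (shoelace)", {
  set.seed(52)
  for (i in 1:100) {
    poly <- random_polygon(stats::runif(2, 100, 300), 30, 90, sample(5:12, 1))
    A <- matrix(stats::runif(4, -2, 2), 2, 2)
    while (abs(det(A)) < 0.1) A <- matrix(stats::runif(4, -2, 2), 2, 2)
    tf <- planar_transform(cbind(A, stats::runif(2, -50, 50)), "affine", "a", "b")
    moved <- apply_to_points(tf, poly)
    expect_equal(polygon_area(moved), abs(det(A)) * polygon_area(poly),
                 tolerance = 1e-9)
  }
})

test_that("rasterization assigns pixel centers by even-odd containment", {
  expect_true(all(rasterize_annotations(annotation_set(list(), frame_id = "f"),
                                        c(5, 5), 1)$labels == 0L))
  # square strictly containing exactly the centers (1,1) and (1,2), (2,1), (2,2)
  sq <- annotation("A", cbind(c(0.5, 2.5, 2.5, 0.5), c(0.5, 0.5, 2.5, 2.5)),
                   frame_id = "f")
  lm <- rasterize_annotations(annotation_set(list(sq)), c(5, 5), 1)
  expect_identical(sum(lm$labels > 0L), 4L)
  expect_true(all(lm$labels[2:3, 2:3] == 1L))
})

test_that("overlap resolves to the last-drawn annotation in input order", {
  a <- annotation("A", cbind(c(-0.5, 2.6, 2.6, -0.5), c(-0.5, -0.5, 2.6, 2.6)), frame_id = "f")
  b <- annotation("B", cbind(c(1.5, 4.5, 4.5, 1.5), c(1.5, 1.5, 4.5, 4.5)), frame_id = "f")
  ab <- rasterize_annotations(annotation_set(list(a, b)), c(6, 6), 1)
  ba <- rasterize_annotations(annotation_set(list(b, a)), c(6, 6), 1)
  # overlap cell (2,2) in 0-based pixel coords
  expect_identical(ab$label_table[[as.character(ab$labels[3, 3])]], "B")
  expect_identical(ba$label_table[[as.character(ba$labels[3, 3])]], "A")
})

test_that("rasterization matches the scalar point-in-polygon oracle, holes included", {
  set.seed(53)
  for (i in 1:10) {
    anns <- lapply(seq_len(sample(2:4, 1)), function(k) {
      ctr <- stats::runif(2, 15, 45)
      holes <- if (k == 1) list(random_polygon(ctr, 2, 4, 5)) else list()
      annotation(paste0("R", k), random_polygon(ctr, 8, 15, 7),
                 holes = holes, frame_id = "f")
    })
    set <- annotation_set(anns, frame_id = "f")
    got <- rasterize_annotations(set, c(12, 13), 5)
    expect_identical(got$labels, oracle_rasterize(set, c(12, 13), 5))
  }
})

test_that("labelled area converges to polygon area with resolution", {
  set.seed(54)
  poly <- random_polygon(c(250, 250), 120, 200, 10)
  a_true <- polygon_area(poly)
  perim <- sum(sqrt(rowSums((poly - poly[c(2:nrow(poly), 1), ])^2)))
  set <- annotation_set(list(annotation("A", poly, frame_id = "f")))
  for (px in c(20, 10, 5)) {
    lm <- rasterize_annotations(set, c(500 / px, 500 / px), px)
    a_pix <- sum(lm$labels > 0L) * px^2
    expect_lt(abs(a_pix - a_true), 2 * perim * px)
  }
})

test_that("label ids are contiguous, stable, and never encode label strings", {
  anns <- list(annotation("Duct", cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)), frame_id = "f"),
               annotation("Fat", cbind(c(20, 30, 30, 20), c(0, 0, 10, 10)), frame_id = "f"),
               annotation("Duct", cbind(c(40, 50, 50, 40), c(0, 0, 10, 10)), frame_id = "f"))
  set <- annotation_set(anns)
  expect_identical(set$label_table$id, 1:2)
  expect_identical(set$label_table$label, c("Duct", "Fat"))
  lm <- rasterize_annotations(set, c(3, 11), 5)
  expect_setequal(setdiff(unique(as.vector(lm$labels)), 0L), 1:2)
})
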
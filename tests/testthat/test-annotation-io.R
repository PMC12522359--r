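labelme_doc <- function(shapes, h = 16, w = 16) {
  jsonlite::toJSON(list(version = "5.0.1", flags = list(), shapes = shapes,
                        imagePath = "x.png", imageHeight = h, imageWidth = w),
                   auto_unbox = TRUE, null = "null")
}

tri_shape <- function(label = "FAZ",
                      pts = list(list(2, 2), list(10, 2), list(2, 10)))
  list(label = label, points = pts, shape_type = "polygon", flags = list())

test_that("a minimal one-triangle document parses to one annotation", {
  anns <- read_labelme(labelme_doc(list(tri_shape())))
  expect_length(anns, 1L)
  expect_identical(anns[[1]]$label, "FAZ")
  expect_identical(nrow(anns[[1]]$points), 3L)
})

test_that("zero shapes give an empty list; label filter selects by name", {
  expect_length(read_labelme(labelme_doc(list())), 0L)
  doc <- labelme_doc(list(tri_shape("FAZ"),
                          tri_shape("artifact",
                                    list(list(1, 1), list(3, 1), list(1, 3)))))
  expect_length(read_labelme(doc), 2L)
  expect_length(read_labelme(doc, label = "FAZ"), 1L)
})

test_that("malformed input and degenerate polygons are rejected with context", {
  expect_error(read_labelme("{not json"), "malformed")
  bad <- labelme_doc(list(tri_shape(pts = list(list(1, 1), list(2, 2)))))
  expect_error(read_labelme(bad), "shape 1.*fewer than 3")
  rect <- list(label = "box", points = list(list(1, 1), list(5, 5)),
               shape_type = "rectangle", flags = list())
  expect_warning(anns <- read_labelme(labelme_doc(list(rect))), "skipped")
  expect_length(anns, 0L)
  expect_error(polygon_annotation("a", rbind(c(-1, 0), c(5, 0), c(0, 5)),
                                  16, 16), "outside")
})

test_that("axis-aligned square rasterizes to exactly the covered pixel block", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  m <- rasterize_polygon(sq, height = 4, width = 4)
  ref <- matrix(FALSE, 4, 4); ref[1:2, 1:2] <- TRUE
  expect_identical(m, ref)
})

test_that("triangle area matches the brute-force pixel-centre oracle", {
  tri <- rbind(c(0, 0), c(4, 0), c(0, 4))
  m <- rasterize_polygon(tri, height = 6, width = 6)
  expect_identical(m, oracle_rasterize(tri, 6, 6))
  # pixel centres on the hypotenuse count as inside
  expect_true(m[1, 4])
  expect_true(m[4, 1])
})

test_that("random star polygons match the oracle pixel-for-pixel", {
  set.seed(19)
  for (i in 1:25) {
    h <- sample(8:24, 1); w <- sample(8:24, 1)
    poly <- random_star_polygon(h, w)
    expect_identical(rasterize_polygon(poly, height = h, width = w),
                     oracle_rasterize(poly, h, w))
  }
})

test_that("a near-zero-area sliver yields an empty mask without error", {
  sliver <- rbind(c(1, 1), c(5, 1.0000001), c(1, 1.0000002))
  m <- rasterize_polygon(sliver, height = 8, width = 8)
  expect_false(any(m[3:8, ]))
})

test_that("rasterized area converges to the shoelace area under supersampling", {
  set.seed(4)
  poly <- random_star_polygon(24, 24)
  shoelace <- function(p) {
    n <- nrow(p); j <- c(2:n, 1)
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  }
  a_true <- shoelace(poly)
  err1 <- abs(sum(rasterize_polygon(poly, 24, 24)) - a_true) / a_true
  err4 <- abs(sum(rasterize_polygon(poly * 4, 96, 96)) / 16 - a_true) / a_true
  expect_lt(err4, err1)
})

test_that("mask PNG round-trip is the identity and thresholds at 128", {
  tmp <- withr::local_tempfile(fileext = ".png")
  set.seed(8)
  m <- random_mask(13, 9)
  write_mask_png(m, tmp)
  expect_identical(read_mask_png(tmp), m)
  # anti-aliased gray values: 127 -> background, 128 -> foreground
  png::writePNG(matrix(c(127, 128, 0, 255) / 255, 2, 2), tmp)
  got <- read_mask_png(tmp)
  expect_identical(as.vector(got), c(FALSE, TRUE, FALSE, TRUE))
})

test_that("multi-channel input is a format error for masks, luminance for images", {
  tmp <- withr::local_tempfile(fileext = ".png")
  arr <- array(runif(4 * 4 * 3), c(4, 4, 3))
  png::writePNG(arr, tmp)
  expect_error(read_mask_png(tmp), "single-channel")
  img <- load_image(tmp)
  stored <- png::readPNG(tmp)   # palette quantized to 8-bit on write
  lum <- round(255 * (0.299 * stored[, , 1] + 0.587 * stored[, , 2] +
                        0.114 * stored[, , 3]))
  expect_identical(img$pixels, matrix(as.integer(lum), 4, 4))
  # gray RGB (r = g = b) reduces to the gray values themselves
  g <- matrix(round(runif(16) * 255), 4, 4) / 255
  png::writePNG(array(rep(g, 3), c(4, 4, 3)), tmp)
  expect_identical(load_image(tmp)$pixels,
                   matrix(as.integer(round(g * 255)), 4, 4))
})

test_that("image PNG round-trip preserves pixels and metadata sidecar", {
  tmp <- withr::local_tempfile(fileext = ".png")
  s <- generate_sample(scene_params(height = 64, width = 64, base_radius = 9,
                                    seed = 2))
  write_image_png(s$image, tmp)
  back <- load_image(tmp)
  expect_identical(back$pixels, s$image$pixels)
  expect_identical(back$quality_index, s$image$quality_index)
  expect_identical(back$scan_width_mm, s$image$scan_width_mm)
})

test_that("LabelMe write/read/rasterize round-trips a synthetic ground truth", {
  tmp <- withr::local_tempfile(fileext = ".json")
  p <- scene_params(height = 96, width = 96, base_radius = 13, seed = 21)
  m <- generate_faz_mask(p)
  ann <- polygon_annotation("FAZ", attr(m, "polygon"), 96, 96)
  write_labelme(list(ann), tmp)
  back <- read_labelme(tmp)
  expect_length(back, 1L)
  m2 <- rasterize_polygon(back[[1]])
  expect_identical(m2, unname(m[, ]))
})
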
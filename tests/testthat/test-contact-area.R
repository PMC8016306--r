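disk_mask <- function(n, r, ctr = c(n / 2, n / 2)) {
  ri <- matrix(seq_len(n), n, n)
  ci <- matrix(seq_len(n), n, n, byrow = TRUE)
  (ri - ctr[1])^2 + (ci - ctr[2])^2 <= r^2
}

test_that("pixel scale comes from the reference bar", {
  img <- ink_image(array(1, c(8, 8, 3)), bar_pixels = 500)
  expect_equal(pixel_scale(img), 0.01)
  img2 <- ink_image(array(1, c(8, 8, 3)), bar_pixels = 250)
  expect_equal(pixel_scale(img2), 0.02)
  expect_error(ink_image(array(1, c(8, 8, 3)), bar_pixels = 0), "scaling error")
})

test_that("thresholding recovers a constructed disk and respects the ROI", {
  n <- 120
  mask_true <- disk_mask(n, 25)
  ras <- array(1, c(n, n, 3))
  for (k in 1:3) ras[, , k][mask_true] <- 0.2
  img <- ink_image(ras, bar_pixels = 500)
  got <- threshold_contact_region(img, c(60, 60), 40)
  expect_identical(got, mask_true)
  # same disk, ROI elsewhere: empty with a warning
  expect_warning(out <- threshold_contact_region(img, c(10, 110), 8),
                 "no-contact")
  expect_false(any(out))
})

test_that("speckle noise is removed by the mask cleaning", {
  set.seed(14)
  n <- 150
  mask_true <- disk_mask(n, 35)
  ras <- array(1, c(n, n, 3))
  for (k in 1:3) ras[, , k][mask_true] <- 0.2
  drop <- mask_true & (matrix(runif(n * n), n, n) < 0.02)
  spk <- !mask_true & (matrix(runif(n * n), n, n) < 0.005)
  for (k in 1:3) {
    ras[, , k][drop] <- 1
    ras[, , k][spk] <- 0.2
  }
  img <- ink_image(ras, bar_pixels = 500)
  got <- threshold_contact_region(img, c(75, 75), 55)
  expect_gte(sum(got & mask_true) / sum(mask_true), 0.99)
})

test_that("outline tracing: squares, multiple components, disks", {
  m <- matrix(FALSE, 20, 20)
  m[6:15, 4:13] <- TRUE
  o <- trace_outline(m)
  expect_identical(nrow(o$polygon), 4L) # collinear vertices removed
  expect_equal(polygon_area(o), 9 * 9) # pixel-centre footprint of a 10x10 block
  # largest of two components wins, with a warning
  m2 <- m
  m2[1:2, 18:19] <- TRUE
  expect_warning(o2 <- trace_outline(m2), "components")
  expect_equal(polygon_area(o2), 9 * 9)
  expect_error(trace_outline(matrix(FALSE, 5, 5)), "no-outline")
  # rasterised disk: polygon area within 2% of pi r^2
  dm <- disk_mask(160, 60)
  od <- trace_outline(dm)
  expect_lt(abs(polygon_area(od) - pi * 60^2) / (pi * 60^2), 0.02)
})

test_that("shoelace area: closed forms, invariances, scale, errors", {
  tri <- structure(list(polygon = cbind(c(0, 4, 0), c(0, 0, 3)), scale = 1),
                   class = "contact_outline")
  expect_equal(polygon_area(tri), 6)
  # unit square at scale 1
  sq <- structure(list(polygon = cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), scale = 1),
                  class = "contact_outline")
  expect_equal(polygon_area(sq), 1)
  # invariant to starting vertex and orientation; scales with scale^2
  rot <- structure(list(polygon = tri$polygon[c(2, 3, 1), ], scale = 1),
                   class = "contact_outline")
  rev_ <- structure(list(polygon = tri$polygon[3:1, ], scale = 1),
                    class = "contact_outline")
  expect_equal(polygon_area(rot), 6)
  expect_equal(polygon_area(rev_), 6)
  sc <- structure(list(polygon = tri$polygon, scale = 0.5),
                  class = "contact_outline")
  expect_equal(polygon_area(sc), 6 * 0.25)
  expect_error(polygon_area(structure(list(polygon = cbind(0:1, 0:1), scale = 1),
                                      class = "contact_outline")), "3 vertices")
  bow <- structure(list(polygon = cbind(c(0, 1, 1, 0), c(0, 1, 0, 1)), scale = 1),
                   class = "contact_outline")
  expect_error(polygon_area(bow), "self-intersecting")
})

test_that("rasterised disk at 0.01 cm/px recovers the analytic circle area", {
  dm <- disk_mask(260, 100)
  o <- trace_outline(dm, scale = 0.01)
  expect_lt(abs(polygon_area(o) - pi) / pi, 0.01)
})

test_that("end-to-end synthetic images recover the true area within 3%", {
  for (A in c(0.5, 1.0, 2.0)) {
    gi <- gen_ink_image(A, scale = 0.005, seed = round(100 * A))
    res <- suppressWarnings(measure_contact_area(gi$image))
    expect_lt(abs(res$area_cm2 - A) / A, 0.03)
  }
})

test_that("ink images round-trip through PNG + sidecar", {
  dir <- withr::local_tempdir()
  gi <- gen_ink_image(0.8, scale = 0.005, seed = 5)
  path <- file.path(dir, "print.png")
  png::writePNG(gi$image$raster, path)
  jsonlite::write_json(list(bar_pixels = gi$truth$bar_pixels,
                            bar_length_cm = 5, roi = gi$truth$roi),
                       paste0(path, ".json"), auto_unbox = TRUE)
  img <- read_ink_image(path)
  expect_equal(pixel_scale(img), 0.005)
  # bar auto-detection agrees with the annotation
  expect_equal(detect_reference_bar(gi$image$raster), gi$truth$bar_pixels)
  res <- suppressWarnings(measure_contact_area(img))
  expect_lt(abs(res$area_cm2 - 0.8) / 0.8, 0.03)
})
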
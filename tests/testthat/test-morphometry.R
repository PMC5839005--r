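# Shape morphometry: oriented bounding box, ellipticity, compactness,
# membrane completeness, elongate classification.

test_that("OBB of rectangles matches analytic values, axis-aligned and rotated", {
  rect <- matrix(FALSE, 40, 40)
  rect[11:18, 11:30] <- TRUE         # 20 px wide (x), 8 px tall (y)
  obb <- oriented_bounding_box(rect, 0.5)
  expect_equal(obb$length_um, 10, tolerance = 0.5 / 10)
  expect_equal(obb$width_um, 4, tolerance = 0.5 / 4)
  # 30-degree rotation: dimensions preserved within ~1 px quantization
  th <- 30 * pi / 180
  xs <- rep(0:59, each = 60); ys <- rep(0:59, times = 60)
  u <- (xs - 30) * cos(th) + (ys - 30) * sin(th)
  v <- -(xs - 30) * sin(th) + (ys - 30) * cos(th)
  rot <- matrix(abs(u) <= 10 & abs(v) <= 4, 60, 60)
  obb2 <- oriented_bounding_box(rot, 0.5)
  expect_equal(obb2$length_um, 10.5, tolerance = 0.1)
  expect_equal(obb2$width_um, 4.5, tolerance = 0.15)
  expect_equal(obb2$orientation_rad, th, tolerance = 0.05)
})

test_that("OBB is rotation-equivariant on an ellipse", {
  dims <- sapply(c(0, 20, 45, 70) * pi / 180, function(th) {
    m <- raster_ellipse(80, 80, 40, 40, a = 22, b = 8, theta = th)
    obb <- oriented_bounding_box(m, 1)
    c(obb$length_um, obb$width_um, obb$orientation_rad)
  })
  expect_lt(diff(range(dims[1, ])), 2)
  expect_lt(diff(range(dims[2, ])), 2)
  expect_equal(dims[3, 2], 20 * pi / 180, tolerance = 0.05)
})

test_that("OBB handles degenerate and symmetric footprints", {
  expect_error(oriented_bounding_box(cbind(3, 5), 0.5), "degenerate")
  sq <- matrix(TRUE, 11, 11)
  obb <- oriented_bounding_box(sq, 1)
  expect_equal(obb$length_um * obb$width_um, 11 * 11, tolerance = 0.12)
  # 1-px-wide line still has nonzero width (+1 px convention)
  line <- matrix(FALSE, 20, 20); line[10, 3:17] <- TRUE
  obb_l <- oriented_bounding_box(line, 1)
  expect_equal(obb_l$width_um, 1)
  expect_equal(obb_l$length_um, 15)
})

test_that("ellipticity is ~1 for discs, ~b/a for ellipses, decreasing for longer bars", {
  disc <- raster_ellipse(60, 60, 30, 30, 20, 20)
  expect_equal(ellipticity(disc), 1, tolerance = 0.02)
  e41 <- raster_ellipse(100, 100, 50, 50, 40, 10)
  expect_equal(ellipticity(e41), 0.25, tolerance = 0.03)
  vals <- sapply(c(10, 20, 30), function(L) {
    bar <- matrix(FALSE, 40, 40); bar[20:21, 1:L] <- TRUE
    ellipticity(bar)
  })
  expect_true(all(diff(vals) < 0))
})

test_that("compactness: disc near 1, star below disc, single pixel 1 by convention", {
  disc <- raster_ellipse(120, 120, 60, 60, 50, 50)
  expect_gte(compactness(disc), 0.85)
  # same-area star (spiky polygon) is strictly less compact
  ang <- seq(0, 2 * pi, length.out = 1000)
  rad <- 40 * (1 + 0.5 * cos(5 * ang))
  xs <- rep(0:119, each = 120); ys <- rep(0:119, times = 120)
  pa <- atan2(ys - 60, xs - 60); pr <- sqrt((xs - 60)^2 + (ys - 60)^2)
  star <- matrix(pr <= 40 * (1 + 0.5 * cos(5 * pa)), 120, 120)
  expect_lt(compactness(star), compactness(disc))
  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(compactness(single), 1)
})

test_that("membrane completeness reflects the labeled arc fraction", {
  # ring footprint with controllable labeled arc
  nr <- 41
  ring <- raster_ellipse(nr, nr, 20, 20, 12, 12) &
    !raster_ellipse(nr, nr, 20, 20, 9, 9)
  footprint <- raster_ellipse(nr, nr, 20, 20, 12, 12)
  field_full <- matrix(0, nr, nr); field_full[ring] <- 1
  expect_gte(membrane_completeness(footprint, field_full, 0.5), 0.95)
  # half ring: only the upper half labeled
  half <- matrix(0, nr, nr)
  ys <- (which(ring) - 1) %% nr
  half[which(ring)[ys < 20]] <- 1
  mc <- membrane_completeness(footprint, half, 0.5)
  expect_gt(mc, 0.4); expect_lt(mc, 0.6)
  expect_equal(membrane_completeness(footprint, matrix(0, nr, nr), 0.5), 0)
})

test_that("elongate classification reproduces the criteria truth table", {
  # 12 constructed cells: all combinations of width, ratio, isolation
  mk <- function(id, x, w, l, iso_ok) data.frame(
    id = id, x_um = x, y_um = 0, area_um2 = pi * l * w / 4,
    obb_length_um = l, obb_width_um = w, cd8_positive = TRUE,
    expected = iso_ok & (w < 10) & (l / w > 2.3))
  # isolated cells sit 200 um apart; crowded ones 8 um from a neighbor
  cases <- rbind(
    mk(1, 0,    4, 12, TRUE),    # elongate (ratio 3, width 4)
    mk(2, 200,  6, 12, TRUE),    # ratio 2.0 -> no
    mk(3, 400, 11, 33, TRUE),    # width 11 -> no
    mk(4, 600,  9.9, 23, TRUE),  # width 9.9, ratio 2.32 -> yes
    mk(5, 800, 10, 23.1, TRUE),  # width exactly 10 -> no (strict <)
    mk(6, 1000, 5, 11.5, TRUE),  # ratio exactly 2.3 -> no (strict >)
    mk(7, 1200, 3, 20, TRUE),    # thin, long -> yes
    mk(8, 1400, 8, 30, TRUE))    # yes
  crowd <- rbind(
    mk(9, 2000, 4, 12, FALSE),   # shape ok but neighbor at 8 um
    mk(10, 2008, 9, 9, FALSE),   # the neighbor (round)
    mk(11, 2300, 11, 33, FALSE), # fails both
    mk(12, 2308, 9, 9, FALSE))
  cells <- rbind(cases, crowd)
  out <- classify_elongate(cells, elongate_criteria())
  expect_identical(out$elongate, cells$expected)
})

test_that("elongate classification is scale-consistent in um_per_px", {
  m <- raster_ellipse(80, 80, 40, 40, a = 24, b = 6)
  obb1 <- oriented_bounding_box(m, 0.5)
  obb2 <- oriented_bounding_box(m, 1.0)
  expect_equal(obb2$length_um, 2 * obb1$length_um)
  expect_equal(obb2$width_um, 2 * obb1$width_um)
  # width criterion flips exactly across 10 um as the scale doubles
  expect_lt(obb1$width_um, 10); expect_gt(obb2$width_um, 10)
})

test_that("elongate fraction has the documented edge cases", {
  cells <- data.frame(cd8_positive = rep(TRUE, 100),
                      elongate = rep(FALSE, 100))
  expect_equal(elongate_fraction(cells), 0)
  cells$elongate <- TRUE
  expect_equal(elongate_fraction(cells), 1)
  none <- data.frame(cd8_positive = logical(0), elongate = logical(0))
  expect_true(is.na(elongate_fraction(none)))
})
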
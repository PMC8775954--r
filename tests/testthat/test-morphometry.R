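test_that("circularity identities hold exactly in the continuum", {
  r <- 3.7; s <- 12.2
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)
  expect_equal(circularity(s^2, 4 * s), pi / 4)
  expect_equal(circularity(100, 100), 4 * pi * 100 / 1e4)
  expect_error(circularity(0, 10), "positive")
  expect_error(circularity(10, -1), "positive")
})

test_that("rasterized disk geometry approaches continuum values", {
  d <- raster_disk(50)
  per <- perimeter_estimate(d)
  expect_lt(abs(per - 2 * pi * 50) / (2 * pi * 50), 0.03)
  expect_lt(abs(circularity(sum(d), per) - 1), 0.02)
  ax <- axis_lengths(d)
  expect_lt(abs(ax[["major"]] - 100) / 100, 0.02)
  expect_lt(abs(ax[["minor"]] - 100) / 100, 0.02)
})

test_that("perimeter estimator handles squares and degenerate pixels", {
  sq <- raster_rect(100, 100)
  expect_lt(abs(perimeter_estimate(sq) - 400) / 400, 0.03)
  ## 1x1 object: documented small positive constant (regularized half-pixel
  ## diamond)
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  p1 <- perimeter_estimate(px)
  expect_gt(p1, 0)
  expect_lt(p1, 4)
  expect_error(perimeter_estimate(matrix(FALSE, 4, 4)), "degenerate")
})

test_that("moment ellipse recovers rectangle and ellipse aspect ratios", {
  rect <- raster_rect(25, 100)
  ax <- axis_lengths(rect)
  expect_lt(abs(ax[["major"]] / ax[["minor"]] - 4) / 4, 0.05)
  ell <- raster_ellipse_mask(60, 30, theta = 0.4)
  ax2 <- axis_lengths(ell)
  expect_lt(abs(ax2[["major"]] / ax2[["minor"]] - 2) / 2, 0.05)
  ## 90-degree rotation: axes swap-invariant
  ell90 <- t(ell)
  ax3 <- axis_lengths(ell90)
  expect_equal(unname(ax2), unname(ax3), tolerance = 1e-6)
  expect_error(axis_lengths(matrix(c(TRUE, TRUE, TRUE), 1)), "collinear|degenerate")
})

test_that("extract_cells measures every label with consistent fields", {
  lab <- matrix(0L, 160, 160)
  lab[30:79, 30:79] <- 1L             # 50x50 square
  lab[101:120, 121:125] <- 2L         # 20x5 rectangle
  lab[5, 5] <- 3L                     # degenerate single pixel
  cells <- extract_cells(labeled_mask(lab), pixel_size_um = 2)
  expect_equal(nrow(cells), 3)
  expect_equal(cells$area_px, c(2500L, 100L, 1L))
  expect_equal(cells$area_um2, cells$area_px * 4)
  ok <- !cells$degenerate
  expect_equal(ok, c(TRUE, TRUE, FALSE))
  expect_equal(cells$circularity[ok],
               4 * pi * cells$area_px[ok] / cells$perimeter_px[ok]^2)
  expect_equal(cells$aspect_ratio[ok],
               cells$major_axis_px[ok] / cells$minor_axis_px[ok])
  expect_true(all(cells$aspect_ratio[ok] >= 1))
  expect_false(any(cells$touches_edge[1:2]))

  expect_equal(nrow(extract_cells(matrix(0L, 8, 8))), 0)
})

test_that("features are invariant to whole-pixel translation and 90-deg rotation", {
  star <- raster_star(7, 4, 15, 3)
  lab <- matrix(0L, 120, 120)
  lab[20 + seq_len(nrow(star)), 20 + seq_len(ncol(star))][star] <- 1L
  lab2 <- matrix(0L, 120, 120)
  lab2[41 + seq_len(nrow(star)), 33 + seq_len(ncol(star))][star] <- 1L
  f1 <- extract_cells(lab); f2 <- extract_cells(lab2)
  for (col in c("area_px", "perimeter_px", "major_axis_px", "minor_axis_px",
                "aspect_ratio", "circularity"))
    expect_equal(f1[[col]], f2[[col]], tolerance = 1e-9, label = col)
  ## 90-degree rotation: area exact, others within 1%
  lab3 <- t(lab)[ncol(lab):1, ]
  f3 <- extract_cells(lab3)
  expect_equal(f1$area_px, f3$area_px)
  for (col in c("perimeter_px", "circularity", "aspect_ratio"))
    expect_lt(abs(f1[[col]] - f3[[col]]) / f1[[col]], 0.01, label = col)
})

test_that("scaling leaves dimensionless features asymptotically unchanged", {
  f <- lapply(c(25, 50), function(r) {
    d <- raster_disk(r)
    p <- perimeter_estimate(d)
    c(circ = circularity(sum(d), p), ar = unname(axis_lengths(d)[1] / axis_lengths(d)[2]))
  })
  expect_lt(abs(f[[1]]["circ"] - f[[2]]["circ"]), 0.02)
  expect_lt(abs(f[[1]]["ar"] - f[[2]]["ar"]), 0.02)
})

test_that("circularity orders the synthetic shape classes", {
  cls <- microglia_classes()
  feats <- function(cl, seeds) {
    vapply(seeds, function(s) {
      m <- generate_cell_shape(cl, seed = s)
      circularity(sum(m), perimeter_estimate(m))
    }, numeric(1))
  }
  amo <- feats(cls$amoeboid, 1:12)
  tra <- feats(cls$transitional, 1:12)
  ram <- feats(cls$ramified, 1:12)
  expect_gt(median(amo), median(tra))
  expect_gt(median(tra), median(ram))
})

test_that("quadrant splitting partitions the image exactly", {
  m <- matrix(runif(1024^2), 1024, 1024)
  q <- split_quadrants(m)
  expect_true(all(vapply(q, function(t) all(dim(t) == c(512, 512)), logical(1))))
  expect_equal(sum(vapply(q, sum, numeric(1))), sum(m))

  modd <- matrix(seq_len(1023 * 1023), 1023, 1023)
  qo <- split_quadrants(modd)
  dims <- t(vapply(qo, dim, integer(2)))
  expect_true(all(dims %in% c(511L, 512L)))
  expect_equal(sum(vapply(qo, function(t) sum(as.numeric(t)), numeric(1))),
               sum(as.numeric(modd)))
  expect_error(split_quadrants(matrix(1, 1, 10)), ">= 2")
})

test_that("edge-touching cells are removed per quadrant tile", {
  lab <- matrix(0L, 100, 100)
  lab[40:60, 40:60] <- 1L      # spans the quadrant boundary at 50
  lab[10:19, 10:19] <- 2L      # interior of quadrant 1
  lab[1:5, 80:90] <- 3L        # touches the outer image edge
  cells <- extract_cells_quadrants(labeled_mask(lab))
  ## only the interior cell survives; the spanning cell is removed from both
  ## adjacent quadrants
  expect_equal(nrow(cells), 1)
  expect_equal(cells$label, 2L)
  expect_false(any(cells$touches_edge))
  qc <- attr(cells, "qc")
  expect_gte(qc$edge_removed, 4)  # spanner counted in several tiles + edge cell

  ## all cells on edges -> empty result is valid
  lab2 <- matrix(0L, 40, 40)
  lab2[1:10, 1:10] <- 1L
  expect_equal(nrow(extract_cells_quadrants(labeled_mask(lab2))), 0)
})
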
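test_that("amoeboid cells are disks of the expected area", {
  cls <- shape_class("amoeboid", soma_radius_px = c(10, 10), elongation = c(1, 1))
  m <- generate_cell_shape(cls, seed = 1)
  expect_lt(abs(sum(m) - pi * 100) / (pi * 100), 0.05)
  ## single 8-connected component
  lm <- clean_mask(m, segmentation_config(min_object_area_px = 1))
  expect_equal(lm$n, 1)
})

test_that("ramified cells carry their processes (skeleton endpoints)", {
  cls <- shape_class("ramified", soma_radius_px = c(6, 6), n_branches = c(4, 4),
                     branch_length_px = c(18, 22), branch_width_px = c(2, 3))
  for (seed in c(2, 9)) {
    m <- generate_cell_shape(cls, seed = seed)
    skel <- zhang_suen_skeleton(m)
    expect_gte(skeleton_endpoints(skel), 4)
    lm <- clean_mask(m, segmentation_config(min_object_area_px = 1))
    expect_equal(lm$n, 1)
  }
})

test_that("cell-shape generation is deterministic and validates its ranges", {
  cls <- microglia_classes()$transitional
  expect_identical(generate_cell_shape(cls, seed = 5),
                   generate_cell_shape(cls, seed = 5))
  expect_error(shape_class("amoeboid", soma_radius_px = c(10, 4)), "degenerate")
  expect_error(shape_class("amoeboid", soma_radius_px = c(8, 10),
                           n_branches = c(1, 2)), "no branches")
  expect_error(shape_class("ramified", soma_radius_px = c(8, 10),
                           n_branches = c(1, 4)), ">= 3")
  expect_error(shape_class("rod", soma_radius_px = c(6, 8),
                           elongation = c(0.5, 2)), ">= 1")
})

test_that("image generation honours the spec and its ground truth", {
  ## empty image: background plus noise only
  g0 <- generate_image(synthetic_spec(image_shape = c(64, 64), n_cells = 0,
                                      noise_sd = 0.01, seed = 3))
  expect_true(all(g0$truth$label_mask$labels == 0))
  expect_lt(max(abs(g0$image$intensity - 0.1)), 0.06)

  ## noiseless: midpoint threshold recovers exactly the planted cells
  spec <- synthetic_spec(image_shape = c(512, 512), n_cells = 20, noise_sd = 0,
                         seed = 5)
  gen <- generate_image(spec)
  mid <- (spec$intensity_fg + spec$intensity_bg) / 2
  lm <- clean_mask(gen$image$intensity >= mid,
                   segmentation_config(min_object_area_px = 20))
  expect_equal(lm$n, 20)

  ## ground truth is self-consistent: stored areas equal label pixel counts
  counted <- tabulate(gen$truth$label_mask$labels[gen$truth$label_mask$labels > 0])
  expect_equal(unname(gen$truth$cell_areas_px), counted)
  expect_setequal(names(gen$truth$cell_classes), names(gen$truth$cell_areas_px))

  ## determinism
  gen2 <- generate_image(spec)
  expect_identical(gen$image$intensity, gen2$image$intensity)
  expect_identical(gen$truth, gen2$truth)
})

test_that("placement fails loudly when cells cannot fit", {
  ## too many amoeboid cells for a small field: rejection sampling gives up
  cls <- list(amoeboid = microglia_classes()$amoeboid)
  spec <- synthetic_spec(image_shape = c(100, 100), n_cells = 30,
                         classes = cls, class_mixture = c(amoeboid = 1),
                         min_cell_separation_px = 10, seed = 1)
  expect_error(generate_image(spec), "could not place")
})

test_that("invalid synthetic specs are rejected", {
  expect_error(synthetic_spec(class_mixture = c(a = 0.5, b = 0.2)), "one entry per class")
  expect_error(synthetic_spec(class_mixture = stats::setNames(rep(0.3, 5),
    names(microglia_classes()))), "sum to 1")
  expect_error(synthetic_spec(intensity_fg = 0.1, intensity_bg = 0.5), "exceed")
  expect_error(synthetic_spec(n_cells = -1), ">= 0")
})

test_that("condition series produce one seeded image per design cell", {
  design <- default_condition_design(n_images = 1L)
  expect_equal(nrow(design), 12)  # 3 groups x 4 exposure times
  base <- synthetic_spec(image_shape = c(300, 300), n_cells = 5, seed = 1)
  ser <- generate_condition_series(design, base, seed = 99)
  expect_equal(nrow(ser$design), 12)
  expect_equal(length(ser$images), 12)
  ## disjoint seeds: no two images identical
  mats <- lapply(ser$images, function(g) g$image$intensity)
  for (i in 1:11) for (j in (i + 1):12)
    expect_false(identical(mats[[i]], mats[[j]]))
  ## duplicate condition rows are a design error
  expect_error(generate_condition_series(rbind(design, design[1, ]), base, 1),
               "duplicate")
})

test_that("condition mixtures steer downstream morphology", {
  base <- synthetic_spec(image_shape = c(420, 420), n_cells = 12, noise_sd = 0,
                         seed = 1)
  mk <- function(amoeboid, ramified, seed) {
    mix <- c(amoeboid = amoeboid, transitional = 0.1,
             ramified = ramified, elongated = 0.05, rod = 0.05)
    sp <- base; sp$class_mixture <- mix; sp$seed <- seed
    gen <- generate_image(sp)
    extract_cells(gen$truth$label_mask)
  }
  ## OGD-like (amoeboid-heavy) vs healthy-like populations on true masks
  ogd <- do.call(rbind, lapply(1:4, function(s) mk(0.80, 0.00, s)))
  healthy <- do.call(rbind, lapply(5:8, function(s) mk(0.30, 0.50, s)))
  expect_gt(median(ogd$circularity, na.rm = TRUE),
            median(healthy$circularity, na.rm = TRUE))
})
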
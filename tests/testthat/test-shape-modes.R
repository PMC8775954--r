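make_contours <- function(n, shape = c("disk", "star", "ellipse"), seed = 1) {
  shape <- match.arg(shape)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    m <- switch(shape,
      disk = raster_disk(sample(8:14, 1)),
      star = raster_star(sample(6:8, 1), 4, sample(14:20, 1), 3),
      ellipse = raster_ellipse_mask(a = sample(16:22, 1), b = sample(7:9, 1),
                                    theta = runif(1, 0, pi)))
    extract_contour(m)
  })
}

test_that("two well-separated classes are recovered almost perfectly", {
  contours <- c(make_contours(60, "disk", 1), make_contours(60, "star", 2))
  truth <- rep(c("disk", "star"), each = 60)
  fit <- shape_mode_model(contours, k = 2, seed = 7)
  expect_s3_class(fit, "shape_mode_model")
  expect_gte(match_agreement(fit$assignments$shape_mode, truth), 0.95)
  ## refit with the same seed is identical
  fit2 <- shape_mode_model(contours, k = 2, seed = 7)
  expect_identical(fit$centroids, fit2$centroids)
  expect_identical(fit$assignments, fit2$assignments)
})

test_that("k = 1 collapses to a single mode with the score mean as centroid", {
  contours <- make_contours(25, "disk", 3)
  fit <- shape_mode_model(contours, k = 1, train_fraction = 1, seed = 1)
  expect_true(all(fit$assignments$shape_mode == 1))
  ## centroid of the only cluster is the training-score mean
  X <- t(vapply(lapply(contours, resample_contour, n_points = 50),
                register_contour, numeric(100)))
  scores <- sweep(X, 2, fit$mean_shape) %*% t(fit$basis)
  expect_equal(unname(fit$centroids[1, ]), unname(colMeans(scores)),
               tolerance = 1e-8)
})

test_that("full-dimensional basis reconstructs registered shapes exactly", {
  contours <- make_contours(30, "ellipse", 4)
  n_pts <- 30L
  fit <- shape_mode_model(contours, k = 2, n_points = n_pts,
                          n_components = 2L * n_pts, train_fraction = 1, seed = 2)
  X <- t(vapply(lapply(contours, resample_contour, n_points = n_pts),
                register_contour, numeric(2L * n_pts)))
  scores <- sweep(X, 2, fit$mean_shape) %*% t(fit$basis)
  recon <- sweep(scores %*% fit$basis, 2, fit$mean_shape, `+`)
  rms <- sqrt(mean((recon - X)^2))
  expect_lt(rms, 1e-8)
  ## basis rows orthonormal; explained variance nonincreasing
  G <- fit$basis %*% t(fit$basis)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-8)
  expect_true(all(diff(fit$explained_variance) <= 1e-12))
  ## reconstruction error is nonincreasing in the number of components
  errs <- vapply(c(2L, 5L, 10L, 20L), function(m) {
    f <- shape_mode_model(contours, k = 2, n_points = n_pts, n_components = m,
                          train_fraction = 1, seed = 2)
    sc <- sweep(X, 2, f$mean_shape) %*% t(f$basis)
    sqrt(mean((sweep(sc %*% f$basis, 2, f$mean_shape, `+`) - X)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("k-means attains the exhaustive-partition optimum on small inputs", {
  set.seed(11)
  X <- matrix(rnorm(16), 8, 2)
  for (k in 2:3) {
    km <- micromorph:::kmeans_pp(X, k)
    expect_equal(km$tot.withinss, oracle_kmeans_inertia(X, k), tolerance = 1e-8)
  }
})

test_that("assignment is consistent, tie-stable and centroid-faithful", {
  contours <- c(make_contours(40, "disk", 5), make_contours(40, "star", 6))
  fit <- shape_mode_model(contours, k = 2, seed = 3)
  ## a training cell keeps its fitted label under predict
  tr <- which(fit$assignments$split == "train")[1:10]
  pred <- predict(fit, contours[tr])
  expect_equal(pred$shape_mode, fit$assignments$shape_mode[tr])
  ## the reconstructed pre-image of a centroid maps to that centroid with
  ## ~zero distance
  for (m in seq_len(fit$k)) {
    shape <- micromorph:::mode_shape(fit, m)
    v <- c(shape[, 1], shape[, 2])
    scores <- (v - fit$mean_shape) %*% t(fit$basis)
    asg <- micromorph:::nearest_centroid(scores, fit$centroids)
    expect_equal(asg$mode, m)
    expect_lt(asg$dist, 1e-6)
  }
  ## equidistant point -> lower mode index
  mid <- matrix((fit$centroids[1, ] + fit$centroids[2, ]) / 2, nrow = 1)
  expect_equal(micromorph:::nearest_centroid(mid, fit$centroids)$mode, 1L)
})

test_that("modes are numbered by decreasing median member area", {
  contours <- c(make_contours(50, "disk", 7), make_contours(50, "star", 8))
  areas <- vapply(contours, function(p) abs(micromorph:::shoelace_area(unclass(p))),
                  numeric(1))
  fit <- shape_mode_model(contours, k = 2, seed = 9)
  med <- tapply(areas, fit$assignments$shape_mode, median)
  expect_true(all(diff(med[order(as.integer(names(med)))]) <= 0))
})

test_that("the centroid dendrogram reflects centroid distances", {
  contours <- c(make_contours(40, "disk", 10), make_contours(40, "star", 11),
                make_contours(40, "ellipse", 12))
  fit <- shape_mode_model(contours, k = 3, seed = 4)
  dend <- model_dendrogram(fit)
  expect_s3_class(dend$hclust, "hclust")
  ## first merge joins the closest centroid pair
  D <- as.matrix(dist(fit$centroids))
  diag(D) <- Inf
  closest <- sort(which(D == min(D), arr.ind = TRUE)[1, ])
  expect_setequal(-dend$hclust$merge[1, ], closest)

  fit2 <- shape_mode_model(contours[1:80], k = 2, seed = 4)
  d2 <- model_dendrogram(fit2)
  expect_equal(nrow(d2$hclust$merge), 1)  # single merge for k = 2
  fit1 <- shape_mode_model(contours[1:30], k = 1, train_fraction = 1, seed = 1)
  expect_error(model_dendrogram(fit1), "k >= 2")
})

test_that("train and test splits agree on mode frequencies for one population", {
  contours <- make_contours(500, "disk", 13)
  imgs <- rep(sprintf("img%d", 1:10), each = 50)
  fit <- shape_mode_model(contours, k = 2, seed = 5, image_id = imgs)
  a <- fit$assignments
  ftr <- prop.table(table(factor(a$shape_mode[a$split == "train"], levels = 1:2)))
  fte <- prop.table(table(factor(a$shape_mode[a$split == "test"], levels = 1:2)))
  expect_lt(max(abs(ftr - fte)), 0.10)
  ## split respects the 80:20 ratio per image
  tr_frac <- tapply(a$split == "train", a$image_id, mean)
  expect_true(all(abs(tr_frac - 0.8) < 0.021))
})

test_that("serialized models reload to identical assignments", {
  contours <- c(make_contours(30, "disk", 14), make_contours(30, "star", 15))
  fit <- shape_mode_model(contours, k = 2, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_shape_mode_model(fit, path)
  back <- read_shape_mode_model(path)
  expect_equal(back$centroids, fit$centroids, tolerance = 1e-12)
  pred_a <- predict(fit, contours)
  pred_b <- predict(back, contours)
  expect_identical(pred_a$shape_mode, pred_b$shape_mode)
  expect_equal(pred_a$distance_to_centroid, pred_b$distance_to_centroid,
               tolerance = 1e-9)
})

test_that("degenerate fitting inputs raise errors", {
  contours <- make_contours(6, "disk", 16)
  expect_error(shape_mode_model(contours, k = 8, seed = 1), "fewer cells")
  expect_error(shape_mode_model(list(), k = 1), "nonempty")
  expect_error(shape_mode_model(contours, k = 2, train_fraction = 0), "train_fraction")
})

test_that("mode overlays paint cells by assignment and conserve areas", {
  lab <- matrix(0L, 60, 60)
  lab[5:14, 5:14] <- 1L
  lab[30:49, 30:49] <- 2L
  asg <- data.frame(label = 1:2, shape_mode = c(1L, 1L))
  ov <- render_mode_overlay(labeled_mask(lab), asg, colormap = c("#FF0000", "#00FF00"))
  expect_equal(dim(ov), c(60, 60, 3))
  ## background untouched
  expect_true(all(ov[1, , ] == 0))
  ## single mode -> single foreground color, pixel counts conserved
  expect_equal(sum(ov[, , 1] > 0), 100 + 400)
  expect_equal(sum(ov[, , 2] > 0), 0)
  ## unassigned cells get the reserved color
  asg2 <- data.frame(label = 1L, shape_mode = 1L)
  ov2 <- render_mode_overlay(labeled_mask(lab), asg2,
                             colormap = c("#FF0000", "#00FF00"))
  expect_equal(sum(ov2[, , 3] > 0), 400)  # grey50 has a blue component
  expect_error(render_mode_overlay(labeled_mask(lab),
                                   data.frame(label = 1:2, shape_mode = c(1L, 3L)),
                                   colormap = "#FF0000"),
               "colormap")
})
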
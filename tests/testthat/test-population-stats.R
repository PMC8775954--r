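test_that("kruskal-wallis H matches the hand-computed no-ties fixture", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  ## rank sums 6, 15, 24: H = 12/(9*10) * (36+225+576)/3 - 30 = 7.2
  expect_equal(res$H, 7.2)
  expect_equal(res$df, 2)
  expect_equal(res$p, stats::pchisq(7.2, 2, lower.tail = FALSE))
  ## identical observations: tie-corrected convention gives H = 0
  res0 <- kruskal_wallis(list(rep(5, 4), rep(5, 4)))
  expect_equal(res0$H, 0)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("kruskal-wallis agrees with a permutation test on small fixtures", {
  set.seed(99)
  x <- c(2.1, 3.3, 1.2, 5.6, 4.4, 7.1, 2.8, 6.0, 3.9, 5.1, 1.7, 4.8)
  g <- rep(1:3, each = 4)
  obs <- kruskal_wallis(x, g = g)
  nperm <- 10000
  perm_h <- vapply(seq_len(nperm), function(i) oracle_kw_h(x, sample(g)),
                   numeric(1))
  p_perm <- mean(perm_h >= obs$H - 1e-12)
  mc_err <- 3 * sqrt(p_perm * (1 - p_perm) / nperm)
  ## chi-square approximation is close to the exact permutation p at n = 12
  expect_lt(abs(obs$p - p_perm), mc_err + 0.02)
})

test_that("kruskal-wallis holds its nominal type-I error", {
  set.seed(2024)
  nsim <- 10000
  rej <- logical(nsim)
  for (i in seq_len(nsim)) {
    x <- rnorm(30)
    rej[i] <- kruskal_wallis(x, g = rep(1:3, each = 10))$p < 0.05
  }
  expect_gte(mean(rej), 0.04)
  expect_lte(mean(rej), 0.06)
})

test_that("dunn post hoc is correctly normalized and adjusted", {
  ## two groups: bonferroni with m = 1 leaves p unadjusted, and z^2 ~ H
  x <- list(a = c(1.5, 2.2, 3.1, 4.9), b = c(5.2, 6.8, 7.7, 9.1))
  d <- dunn_posthoc(x)
  expect_equal(nrow(d), 1)
  expect_equal(d$p, d$p_adj)
  ## three groups: adjusted p >= raw p for every pair, both for bonferroni
  ## and holm
  set.seed(5)
  y <- list(g1 = rnorm(8), g2 = rnorm(8, 1), g3 = rnorm(8, 2))
  for (m in c("bonferroni", "holm")) {
    dd <- dunn_posthoc(y, method = m)
    expect_equal(nrow(dd), 3)
    expect_true(all(dd$p_adj >= dd$p - 1e-15))
    expect_true(all(dd$p_adj <= 1))
  }
  expect_error(dunn_posthoc(list(a = 1:3)), "two groups")
})

test_that("dunn z matches a direct hand computation with ties", {
  ## pooled data 1,2,2,3 | 4,5,6: N=7, tie group of two 2s
  a <- c(1, 2, 2, 3); b <- c(4, 5, 6)
  d <- dunn_posthoc(list(a = a, b = b))
  r <- rank(c(a, b))
  rbar_a <- mean(r[1:4]); rbar_b <- mean(r[5:7])
  Tcorr <- 2^3 - 2
  s2 <- 7 * 8 / 12 - Tcorr / (12 * 6)
  z_hand <- (rbar_a - rbar_b) / sqrt(s2 * (1 / 4 + 1 / 3))
  expect_equal(d$z, z_hand)
  expect_equal(d$p, 2 * pnorm(-abs(z_hand)))
})

test_that("dunn keeps the family-wise null rejection rate in check", {
  set.seed(77)
  nsim <- 1000
  any_sig <- vapply(seq_len(nsim), function(i) {
    y <- rnorm(24)
    dd <- dunn_posthoc(y, g = rep(1:3, each = 8))
    any(dd$p_adj < 0.05)
  }, logical(1))
  expect_gte(mean(!any_sig), 0.94)
})

test_that("shape-mode frequency tables normalize and conserve counts", {
  design <- data.frame(image_id = c("i1", "i2"), group = c("BEV", "healthy"),
                       dose_ug = c(25, 0), exposure_h = c(24, 24))
  ## all cells of one condition in SM3
  cells <- data.frame(image_id = "i1", shape_mode = rep(3L, 7))
  ft <- sm_frequencies(cells, design, k = 5)
  expect_equal(unlist(ft[1, paste0("SM", 1:5)], use.names = FALSE),
               c(0, 0, 100, 0, 0))
  expect_equal(ft$n, 7)
  ## absent conditions are missing rows, not zero-filled
  expect_equal(nrow(ft), 1)

  ## uniform random assignment concentrates near 20% per mode
  set.seed(8)
  big <- data.frame(image_id = "i2", shape_mode = sample.int(5, 5000, replace = TRUE))
  ft2 <- sm_frequencies(big, design, k = 5)
  expect_true(all(abs(unlist(ft2[1, paste0("SM", 1:5)]) - 20) < 3))
  expect_equal(sum(unlist(ft2[1, paste0("SM", 1:5)])), 100, tolerance = 1e-4)
  ## frequency conservation: percent x n / 100 are integer counts
  counts <- unlist(ft2[1, paste0("SM", 1:5)]) * ft2$n / 100
  expect_equal(counts, round(counts), ignore_attr = TRUE)

  ## orphan image ids are an error
  expect_error(sm_frequencies(data.frame(image_id = "ghost", shape_mode = 1L),
                              design), "ghost")
})

test_that("fold changes are anchored at the healthy control", {
  design <- data.frame(image_id = c("h1", "o1", "b1"),
                       group = c("healthy", "OGD", "BEV"),
                       dose_ug = c(0, 0, 25), exposure_h = 24)
  cells <- rbind(
    data.frame(image_id = "h1", area_px = c(100, 120, 140)),
    data.frame(image_id = "o1", area_px = c(200, 240, 280)),
    data.frame(image_id = "b1", area_px = c(100, 120, 140)))
  fc <- feature_fold_change(cells, design, "area_px")
  expect_equal(fc$fold_change[fc$group == "healthy"], 1)
  expect_equal(fc$fold_change[fc$group == "OGD"], 2)     # doubled median
  expect_equal(fc$fold_change[fc$group == "BEV"], 1)     # identical sample
  expect_true(all(fc$fold_change > 0))
  ## missing control arm at a time is an error
  design2 <- design; design2$group[1] <- "OGD"; design2$image_id[1] <- "o0"
  cells2 <- cells; cells2$image_id[cells2$image_id == "h1"] <- "o0"
  expect_error(feature_fold_change(cells2, design2, "area_px"), "control")
})

test_that("heatmap export round-trips the numeric table through CSV", {
  m <- matrix(c(1, 0.5, 2, 1.3, NA, 0.8), 2, 3,
              dimnames = list(c("area", "circularity"), c("a", "b", "c")))
  png_path <- withr::local_tempfile(fileext = ".png")
  csv_path <- withr::local_tempfile(fileext = ".csv")
  expect_message(heatmap_export(m, png_path, csv_path, style = "fold_change"),
                 "missing")
  back <- as.matrix(utils::read.csv(csv_path, row.names = 1))
  expect_equal(unname(back), unname(m))
  expect_true(file.exists(png_path) && file.size(png_path) > 0)
  heatmap_export(matrix(50, 2, 2), png_path, NULL, style = "frequency")
  expect_true(file.size(png_path) > 0)
})
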
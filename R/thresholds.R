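## Automatic intensity thresholding.
##
## Seven classical histogram/iterative threshold selectors, implemented from
## their literature definitions: isodata (Ridler & Calvard 1978), li (Li & Lee
## 1993 minimum cross entropy, iterative scheme of Li & Tam 1998), mean
## (Glasbey 1993), minimum (Prewitt & Mendelsohn 1966), otsu (Otsu 1979),
## triangle (Zack, Rogers & Latt 1977) and yen (Yen, Chang & Chang 1995).
## Foreground is bright (fluorescence convention); masks are image >= threshold.

THRESHOLD_METHODS <- c("isodata", "li", "mean", "minimum", "otsu", "triangle", "yen")

## 256-bin histogram over the observed intensity range.
intensity_hist <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop_param("image contains non-finite intensities")
  rng <- range(x)
  if (rng[1] == rng[2]) stop_param("degenerate image: constant intensity")
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins)
  centers <- (breaks[-1L] + breaks[-(nbins + 1L)]) / 2
  list(counts = counts, centers = centers, width = diff(rng) / nbins)
}

th_mean <- function(x) mean(as.numeric(x))

th_otsu <- function(x) {
  h <- intensity_hist(x)
  p <- h$counts / sum(h$counts)
  w1 <- cumsum(p)
  m <- cumsum(p * h$centers)
  mt <- m[length(m)]
  w2 <- 1 - w1
  ## between-class variance for split "bin <= i vs bin > i"
  bcv <- ifelse(w1 > 0 & w2 > 0, (mt * w1 - m)^2 / (w1 * w2), -Inf)
  bcv <- bcv[-length(bcv)]
  h$centers[which.max(bcv)]
}

th_isodata <- function(x, max_iter = 1000L) {
  x <- as.numeric(x)
  tol <- diff(range(x)) / 512
  t_cur <- mean(x)
  for (i in seq_len(max_iter)) {
    lo <- x[x <= t_cur]; hi <- x[x > t_cur]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < tol) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Minimum cross-entropy (Li) threshold
#'
#' Computes the Li & Lee minimum cross-entropy threshold by the iterative
#' fixed-point scheme of Li & Tam: starting from the mean intensity,
#' `t <- (mu_back - mu_fore) / (log(mu_back) - log(mu_fore))` where `mu_back`
#' and `mu_fore` are the mean intensities at or below and above the current
#' iterate, until successive iterates differ by less than half an intensity
#' quantization step.
#'
#' @param image Numeric matrix (or vector) of intensities with at least two
#'   distinct values.
#' @param max_iter Maximum number of fixed-point iterations.
#' @return The threshold intensity (scalar). Pixels `>= threshold` are
#'   foreground under the package's bright-foreground convention.
#' @export
li_threshold <- function(image, max_iter = 1000L) {
  x <- as.numeric(image)
  if (any(!is.finite(x))) stop_param("image contains non-finite intensities")
  rng <- range(x)
  if (rng[1] == rng[2]) stop_param("degenerate image: constant intensity")
  ## shift so all values are strictly positive (log of class means)
  offset <- if (rng[1] <= 0) -rng[1] + diff(rng) * 1e-6 else 0
  x <- x + offset
  tol <- diff(rng) / 512
  t_cur <- mean(x)
  for (i in seq_len(max_iter)) {
    back <- x[x <= t_cur]; fore <- x[x > t_cur]
    if (!length(back) || !length(fore)) break
    mb <- mean(back); mf <- mean(fore)
    t_new <- if (mb == mf) mb else (mb - mf) / (log(mb) - log(mf))
    if (abs(t_new - t_cur) < tol) return(t_new - offset)
    t_cur <- t_new
  }
  if (i == max_iter)
    stop_param("Li threshold did not converge after %d iterations (last iterate %g)",
               max_iter, t_cur - offset)
  t_cur - offset
}

th_li <- function(x) li_threshold(x)

th_minimum <- function(x, max_smooth = 10000L) {
  h <- intensity_hist(x)
  sm <- as.numeric(h$counts)
  n <- length(sm)
  local_maxima <- function(v) {
    prev <- c(-Inf, v[-n]); nxt <- c(v[-1L], -Inf)
    which(v > prev & v >= nxt)
  }
  for (i in seq_len(max_smooth)) {
    mx <- local_maxima(sm)
    if (length(mx) <= 2L) break
    ## 3-point running mean, zero padded at the ends
    sm <- (c(0, sm[-n]) + sm + c(sm[-1L], 0)) / 3
  }
  mx <- local_maxima(sm)
  if (length(mx) != 2L)
    stop_param("minimum method failed: histogram not bimodal after %d smoothings (%d maxima)",
               max_smooth, length(mx))
  between <- seq.int(mx[1L] + 1L, mx[2L] - 1L)
  if (!length(between)) between <- mx[1L]
  h$centers[between[which.min(sm[between])]]
}

th_triangle <- function(x) {
  h <- intensity_hist(x)
  cnt <- as.numeric(h$counts)
  peak <- which.max(cnt)
  nz <- which(cnt > 0)
  lo <- nz[1L]; hi <- nz[length(nz)]
  ## work on the longer tail side of the peak
  if ((peak - lo) >= (hi - peak)) { a <- lo; b <- peak; side <- seq.int(lo, peak) }
  else { a <- hi; b <- peak; side <- seq.int(peak, hi) }
  ## distance from (i, cnt[i]) to the line through (b, cnt[b]) and (a, 0),
  ## up to a common positive factor
  d <- abs(cnt[b] * (side - a) - (b - a) * cnt[side])
  h$centers[side[which.max(d)]]
}

th_yen <- function(x) {
  h <- intensity_hist(x)
  p <- h$counts / sum(h$counts)
  P1 <- cumsum(p)
  S1 <- cumsum(p^2)
  S2 <- sum(p^2) - S1
  P2 <- 1 - P1
  ok <- P1 > 0 & P2 > 0 & S1 > 0 & S2 > 0
  crit <- rep(-Inf, length(p))
  crit[ok] <- -log(S1[ok] * S2[ok]) + 2 * log(P1[ok] * P2[ok])
  crit <- crit[-length(crit)]
  h$centers[which.max(crit)]
}

#' Automatic threshold by a named method
#'
#' @param image Numeric matrix of intensities.
#' @param method One of `"isodata"`, `"li"`, `"mean"`, `"minimum"`, `"otsu"`,
#'   `"triangle"`, `"yen"`.
#' @return Threshold intensity (scalar).
#' @export
auto_threshold <- function(image, method = "li") {
  method <- match.arg(method, THRESHOLD_METHODS)
  switch(method,
         isodata  = th_isodata(image),
         li       = th_li(image),
         mean     = th_mean(image),
         minimum  = th_minimum(image),
         otsu     = th_otsu(image),
         triangle = th_triangle(image),
         yen      = th_yen(image))
}

#' Survey all seven automatic thresholds on one image
#'
#' Runs every supported threshold selector on the image and returns the
#' threshold values and the corresponding binary masks (foreground bright,
#' `image >= threshold`), for side-by-side qualitative comparison of
#' segmentation candidates.
#'
#' @param image Numeric matrix of intensities; must not be constant.
#' @param panel_path Optional path; if given, a PNG panel of the original image
#'   and all seven binarizations is written there.
#' @return An object of class `threshold_report`: a list with `thresholds`
#'   (named numeric vector), `masks` (named list of logical matrices) and
#'   `panel_path`.
#' @export
threshold_survey <- function(image, panel_path = NULL) {
  img <- as_intensity_matrix(image)
  thr <- vapply(THRESHOLD_METHODS, function(m) auto_threshold(img, m), numeric(1))
  masks <- lapply(thr, function(t) img >= t)
  rep <- structure(list(thresholds = thr, masks = masks, panel_path = panel_path),
                   class = "threshold_report")
  if (!is.null(panel_path)) {
    grDevices::png(panel_path, width = 4 * 240, height = 2 * 240)
    op <- graphics::par(mfrow = c(2, 4), mar = c(0.5, 0.5, 2, 0.5))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    show_mat <- function(m, main) {
      graphics::image(t(m)[, nrow(m):1, drop = FALSE], axes = FALSE, main = main,
                      col = grDevices::gray.colors(256, 0, 1), useRaster = TRUE)
    }
    show_mat(img, "original")
    for (m in THRESHOLD_METHODS)
      show_mat(masks[[m]] * 1, sprintf("%s (%.3g)", m, thr[[m]]))
  }
  rep
}

#' @export
print.threshold_report <- function(x, ...) {
  cat("Threshold survey (foreground = intensity >= threshold)\n")
  for (m in names(x$thresholds))
    cat(sprintf("  %-8s %.6g  (%d fg px)\n", m, x$thresholds[[m]], sum(x$masks[[m]])))
  invisible(x)
}

## Accept fluor_image objects or plain matrices everywhere an image is expected.
as_intensity_matrix <- function(image) {
  if (inherits(image, "fluor_image")) image$intensity
  else if (is.matrix(image)) image
  else stop_param("expected a numeric matrix or a fluor_image")
}
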
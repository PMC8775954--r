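## Cell outlines: subpixel contour extraction, arc-length resampling and
## similarity registration — the preprocessing feeding the shape-mode model.
##
## Coordinates are (row, col) in pixel units throughout; contours are stored as
## open N x 2 matrices (closure implied), oriented counterclockwise in the
## (x = col, y = row) plane.

## Periodic Gaussian smoothing of a closed polygon's coordinates.
smooth_closed <- function(p, sigma = 2) {
  n <- nrow(p)
  if (sigma <= 0 || n < 5L) return(p)
  half <- min(floor((n - 1) / 2), ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half):half / sigma)^2)
  k <- k / sum(k)
  apply(p, 2L, function(v) as.numeric(stats::filter(v, k, circular = TRUE)))
}

ensure_ccw <- function(p) {
  ## signed area in the (x = col, y = row) plane
  a <- shoelace_area(p[, c(2L, 1L), drop = FALSE])
  if (a < 0) p[rev(seq_len(nrow(p))), , drop = FALSE] else p
}

#' Extract the outer contour of a single object
#'
#' Traces the 0.5-level boundary of the binary object (subpixel, via marching
#' squares), then regularizes it: resampling to ~1 px arc-length spacing,
#' periodic Gaussian smoothing (sigma = 2 points) and rescaling about the
#' centroid to preserve the raw enclosed area. Interior holes are ignored (the
#' segmentation fills them upstream); if several closed contours are present,
#' the one enclosing the largest area is taken.
#'
#' @param mask Logical/0-1 matrix holding a single filled object of >= 3 px.
#' @param smooth_sigma Smoothing bandwidth in contour points; 0 disables
#'   regularization.
#' @param min_px Minimum accepted object size in pixels (degenerate objects
#'   below it raise an error); [perimeter_estimate()] lowers it to 1.
#' @return N x 2 matrix of (row, col) boundary points, class `cell_contour`,
#'   counterclockwise, without a repeated closing point.
#' @export
extract_contour <- function(mask, smooth_sigma = 2, min_px = 3L) {
  m <- (if (inherits(mask, "labeled_mask")) mask$labels else mask) != 0
  if (sum(m) < min_px)
    stop_param("degenerate object: fewer than %d pixels", min_px)
  pad <- matrix(0, nrow(m) + 2L, ncol(m) + 2L)
  pad[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  cl <- grDevices::contourLines(seq_len(nrow(pad)) - 1L, seq_len(ncol(pad)) - 1L,
                                pad, levels = 0.5)
  if (!length(cl)) stop_param("no 0.5-level contour found")
  polys <- lapply(cl, function(ln) {
    p <- cbind(row = ln$x, col = ln$y)
    if (nrow(p) > 1L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    p
  })
  areas <- vapply(polys, function(p) abs(shoelace_area(p)), numeric(1))
  p <- ensure_ccw(polys[[which.max(areas)]])
  if (smooth_sigma > 0) {
    a0 <- abs(shoelace_area(p))
    L <- closed_length(p)
    p1 <- resample_closed(p, max(8L, round(L)))
    p2 <- smooth_closed(p1, smooth_sigma)
    a1 <- abs(shoelace_area(p2))
    if (a1 > 0) {
      cen <- colMeans(p2)
      p2 <- sweep(sweep(p2, 2L, cen), 2L, rep(sqrt(a0 / a1), 2L), `*`)
      p2 <- sweep(p2, 2L, cen, `+`)
    }
    p <- p2
  }
  structure(p, class = c("cell_contour", class(p)))
}

## Resample a closed polygon to n points equally spaced by arc length,
## starting at the original first vertex.
resample_closed <- function(p, n) {
  q <- rbind(p, p[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(q)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop_param("zero-length contour")
  t <- seq(0, total, length.out = n + 1L)[-(n + 1L)]
  cbind(row = stats::approx(s, q[, 1L], xout = t)$y,
        col = stats::approx(s, q[, 2L], xout = t)$y)
}

#' Resample a contour to equally spaced boundary points
#'
#' @param contour N x 2 (row, col) matrix, closed polygon without repeated end
#'   point, >= 3 points.
#' @param n_points Number of output points (>= 3).
#' @return `cell_contour` with `n_points` points at equal arc-length spacing
#'   (coefficient of variation of spacing < 1e-6), same orientation.
#' @export
resample_contour <- function(contour, n_points = 50L) {
  if (n_points < 3L) stop_param("`n_points` must be >= 3")
  p <- unclass(contour)
  if (!is.matrix(p) || nrow(p) < 3L) stop_param("contour must have >= 3 points")
  ## iterate to a fixed point so consecutive chord spacing is uniform (one
  ## pass equalizes spacing along the source polygon, not the output polygon)
  q <- resample_closed(p, as.integer(n_points))
  for (i in 1:20) {
    seg <- sqrt(rowSums(diff(rbind(q, q[1L, , drop = FALSE]))^2))
    if (stats::sd(seg) / mean(seg) < 1e-9) break
    q <- resample_closed(q, as.integer(n_points))
  }
  structure(q, class = c("cell_contour", "matrix", "array"))
}

#' Register a resampled contour to a normalized shape vector
#'
#' Similarity registration in the (x = col, y = row) plane: translate the
#' centroid to the origin, scale to unit RMS radius, rotate the major
#' principal axis of the point set onto the horizontal axis (the 180-degree
#' ambiguity is resolved by requiring nonnegative third moment of x, falling
#' back to y for x-symmetric shapes), enforce counterclockwise orientation,
#' and start the point sequence at the boundary point with the largest
#' x coordinate. Mirror images are *not* identified.
#'
#' @param contour N x 2 (row, col) matrix from [resample_contour()].
#' @return Numeric vector `c(x_1..x_N, y_1..y_N)` of length 2N with attribute
#'   `n_points`.
#' @export
register_contour <- function(contour) {
  p <- unclass(contour)
  xy <- cbind(x = p[, 2L], y = p[, 1L])
  cen <- colMeans(xy)
  xy <- sweep(xy, 2L, cen)
  rms <- sqrt(mean(rowSums(xy^2)))
  if (rms <= 0) stop_param("zero-radius contour")
  xy <- xy / rms
  cv <- crossprod(xy) / nrow(xy)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  ang <- atan2(v[2L], v[1L])
  rot <- function(m, a) m %*% matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2L, 2L)
  xy <- rot(xy, -ang)  # major axis -> horizontal
  s3 <- sum(xy[, 1L]^3)
  if (abs(s3) < 1e-9) s3 <- sum(xy[, 2L]^3)
  if (s3 < -1e-9) xy <- -xy  # 180-degree flip
  ## counterclockwise in (x, y)
  if (shoelace_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  start <- which.max(xy[, 1L])
  if (start > 1L) xy <- xy[c(start:nrow(xy), 1:(start - 1L)), , drop = FALSE]
  structure(c(xy[, 1L], xy[, 2L]), n_points = nrow(xy))
}

## Convenience: mask -> registered vector (+ raw contour area), used by the
## shape-mode fitting front end.
contour_from_mask <- function(mask, n_points = 50L) {
  ct <- extract_contour(mask)
  rs <- resample_contour(ct, n_points)
  list(registered = register_contour(rs),
       area = abs(shoelace_area(unclass(ct))))
}
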
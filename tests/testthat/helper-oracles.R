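# Shared fixtures and independent oracles used across the suite.
# Oracles are brute-force / exhaustive implementations kept deliberately
# separate from the package's code paths.

## ---- rasterized test shapes -------------------------------------------------

raster_disk <- function(r, pad = 3L) {
  n <- 2L * (r + pad) + 1L
  c0 <- r + pad + 1L
  outer(seq_len(n), seq_len(n), function(i, j) (i - c0)^2 + (j - c0)^2 <= (r + 0.5)^2)
}

raster_ellipse_mask <- function(a, b, theta = 0, pad = 3L) {
  half <- ceiling(max(a, b)) + pad
  n <- 2L * half + 1L
  c0 <- half + 1L
  outer(seq_len(n), seq_len(n), function(i, j) {
    u <- (i - c0) * cos(theta) + (j - c0) * sin(theta)
    v <- -(i - c0) * sin(theta) + (j - c0) * cos(theta)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

raster_rect <- function(h, w, pad = 3L) {
  m <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  m[pad + seq_len(h), pad + seq_len(w)] <- TRUE
  m
}

## n-armed star: disk soma with n rectangular arms, arms longer than the soma
raster_star <- function(r_soma = 7, n_arms = 4, arm_len = 18, arm_w = 3, pad = 3L) {
  half <- ceiling(r_soma + arm_len) + pad
  n <- 2L * half + 1L
  c0 <- half + 1L
  m <- outer(seq_len(n), seq_len(n), function(i, j) (i - c0)^2 + (j - c0)^2 <= r_soma^2)
  for (ang in seq(0, 2 * pi, length.out = n_arms + 1L)[-(n_arms + 1L)]) {
    t <- seq(0, r_soma + arm_len, by = 0.5)
    rr <- round(c0 + t * cos(ang)); cc <- round(c0 + t * sin(ang))
    for (s in seq_along(t)) {
      ir <- max(1, rr[s] - arm_w %/% 2):min(n, rr[s] + arm_w %/% 2)
      ic <- max(1, cc[s] - arm_w %/% 2):min(n, cc[s] + arm_w %/% 2)
      m[ir, ic] <- TRUE
    }
  }
  m
}

## circle/ellipse polygons for registration tests (no rasterization)
poly_ellipse <- function(a, b, n = 200L, theta = 0, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(row = center[1] + x * sin(theta) + y * cos(theta),
        col = center[2] + x * cos(theta) - y * sin(theta))
}

## ---- skeleton oracle (Zhang-Suen thinning) ----------------------------------

zhang_suen_skeleton <- function(m) {
  img <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  pad <- matrix(0L, nrow(img) + 2L, ncol(img) + 2L)
  pad[2:(nrow(img) + 1L), 2:(ncol(img) + 1L)] <- img
  nbrs <- function(p, i, j) c(p[i - 1, j], p[i - 1, j + 1], p[i, j + 1], p[i + 1, j + 1],
                              p[i + 1, j], p[i + 1, j - 1], p[i, j - 1], p[i - 1, j - 1])
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      del <- NULL
      idx <- which(pad == 1L, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        i <- idx[r, 1]; j <- idx[r, 2]
        nb <- nbrs(pad, i, j)
        B <- sum(nb)
        A <- sum(nb == 0 & c(nb[-1], nb[1]) == 1)
        cond <- B >= 2 && B <= 6 && A == 1
        if (cond) {
          if (step == 1) cond <- nb[1] * nb[3] * nb[5] == 0 && nb[3] * nb[5] * nb[7] == 0
          else cond <- nb[1] * nb[3] * nb[7] == 0 && nb[1] * nb[5] * nb[7] == 0
        }
        if (cond) del <- rbind(del, c(i, j))
      }
      if (!is.null(del)) { pad[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  pad[2:(nrow(img) + 1L), 2:(ncol(img) + 1L), drop = FALSE]
}

skeleton_endpoints <- function(skel) {
  pad <- matrix(0L, nrow(skel) + 2L, ncol(skel) + 2L)
  pad[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- skel
  idx <- which(pad == 1L, arr.ind = TRUE)
  sum(vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, 1]; j <- idx[r, 2]
    sum(pad[(i - 1):(i + 1), (j - 1):(j + 1)]) - 1L == 1L
  }, logical(1)))
}

## ---- exhaustive threshold oracles -------------------------------------------
## Each searches every distinct gray level of an integer-valued image and
## optimizes the method's defining criterion directly.

oracle_candidates <- function(x) sort(unique(as.numeric(x)))

oracle_otsu <- function(x) {
  x <- as.numeric(x)
  cand <- oracle_candidates(x)
  best <- -Inf; tbest <- NA
  for (t in cand[-length(cand)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    w1 <- length(lo) / length(x); w2 <- 1 - w1
    v <- w1 * w2 * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; tbest <- t }
  }
  tbest
}

oracle_mean <- function(x) mean(as.numeric(x))

oracle_isodata <- function(x) {
  x <- as.numeric(x)
  cand <- oracle_candidates(x)
  cand <- cand[-length(cand)]
  gap <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    abs(t - (mean(lo) + mean(hi)) / 2)
  }, numeric(1))
  cand[which.min(gap)]
}

## Li & Lee minimum cross entropy: minimize -(S1 ln mu1 + S2 ln mu2)
## (values must be positive)
oracle_li <- function(x) {
  x <- as.numeric(x)
  stopifnot(all(x > 0))
  cand <- oracle_candidates(x)
  cand <- cand[-length(cand)]
  eta <- vapply(cand, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
  }, numeric(1))
  cand[which.min(eta)]
}

oracle_yen <- function(x) {
  x <- as.numeric(x)
  vals <- oracle_candidates(x)
  p <- as.numeric(table(factor(x, levels = vals))) / length(x)
  best <- -Inf; tbest <- NA
  for (i in seq_len(length(vals) - 1L)) {
    P1 <- sum(p[1:i]); P2 <- 1 - P1
    G1 <- sum(p[1:i]^2); G2 <- sum(p[-(1:i)]^2)
    if (P1 <= 0 || P2 <= 0 || G1 <= 0 || G2 <= 0) next
    crit <- -log(G1 * G2) + 2 * log(P1 * P2)
    if (crit > best) { best <- crit; tbest <- vals[i] }
  }
  tbest
}

## Triangle: geometric point-to-line distance on the 256-bin histogram
oracle_triangle <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  cnt <- as.numeric(table(cut(x, breaks, include.lowest = TRUE)))
  centers <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  peak <- which.max(cnt)
  nz <- which(cnt > 0)
  lo <- nz[1]; hi <- nz[length(nz)]
  if ((peak - lo) >= (hi - peak)) side <- lo:peak else side <- peak:hi
  end <- if ((peak - lo) >= (hi - peak)) lo else hi
  ## distance from (i, cnt[i]) to line through (peak, cnt[peak]) and (end, 0)
  vx <- peak - end; vy <- cnt[peak] - 0
  d <- abs(vy * (side - end) - vx * cnt[side]) / sqrt(vx^2 + vy^2)
  centers[side[which.max(d)]]
}

## Minimum: independent smoothing implementation via stats::filter
oracle_minimum <- function(x, nbins = 256L, max_iter = 10000L) {
  x <- as.numeric(x)
  rng <- range(x)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  cnt <- as.numeric(table(cut(x, breaks, include.lowest = TRUE)))
  centers <- (breaks[-1] + breaks[-(nbins + 1L)]) / 2
  n_max <- function(v) {
    prev <- c(-Inf, v[-length(v)]); nxt <- c(v[-1], -Inf)
    which(v > prev & v >= nxt)
  }
  for (i in seq_len(max_iter)) {
    if (length(n_max(cnt)) <= 2L) break
    cnt <- as.numeric(stats::filter(cnt, rep(1, 3) / 3, sides = 2))
    cnt[is.na(cnt)] <- 0
  }
  mx <- n_max(cnt)
  stopifnot(length(mx) == 2L)
  mid <- (mx[1] + 1):(mx[2] - 1)
  centers[mid[which.min(cnt[mid])]]
}

## seeded 8-bit bimodal image (values clipped to 1..255 so logs are defined);
## default modes overlap so every gray level between them is populated and the
## exhaustive criterion optima are unique (well-separated modes leave an empty
## histogram gap over which several criteria are flat)
bimodal_image <- function(seed, n = 3600L, modes = c(80, 170), sd = 22,
                          frac = 0.6) {
  set.seed(seed)
  n1 <- round(frac * n)
  v <- round(c(rnorm(n1, modes[1], sd), rnorm(n - n1, modes[2], sd)))
  matrix(pmin(pmax(v, 1), 255), 60)
}

## Li cross-entropy criterion value at an arbitrary threshold
li_criterion <- function(x, t) {
  x <- as.numeric(x)
  lo <- x[x <= t]; hi <- x[x > t]
  if (!length(lo) || !length(hi)) return(Inf)
  -(sum(lo) * log(mean(lo)) + sum(hi) * log(mean(hi)))
}

## ---- clustering oracles -----------------------------------------------------

## exhaustive k-means optimum: minimal within-cluster sum of squares over all
## assignments of n points (n small) into k groups
oracle_kmeans_inertia <- function(X, k) {
  n <- nrow(X)
  stopifnot(k^n <= 1e6)
  asg <- rep(1L, n)
  best <- Inf
  repeat {
    if (length(unique(asg)) == k) {
      inertia <- 0
      for (g in unique(asg)) {
        P <- X[asg == g, , drop = FALSE]
        inertia <- inertia + sum(sweep(P, 2, colMeans(P))^2)
      }
      if (inertia < best) best <- inertia
    }
    i <- 1L
    while (i <= n && asg[i] == k) { asg[i] <- 1L; i <- i + 1L }
    if (i > n) break
    asg[i] <- asg[i] + 1L
  }
  best
}

## best-permutation agreement between cluster labels and true classes
match_agreement <- function(cluster, truth) {
  ks <- sort(unique(cluster)); cs <- sort(unique(truth))
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- 0
  for (p in perms(cs)) {
    map <- stats::setNames(p, ks)
    best <- max(best, mean(map[as.character(cluster)] == truth))
  }
  best
}

## Kruskal-Wallis H computed directly from the rank-sum formula (with tie
## correction), for the permutation-test oracle
oracle_kw_h <- function(x, g) {
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) * sum(tapply(r, g, sum)^2 / tabulate(as.integer(factor(g)))) -
    3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}
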
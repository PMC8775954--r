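## Population-level outputs: shape-mode frequency tables, fold change from
## healthy control, and nonparametric group comparisons (Kruskal-Wallis with
## Dunn's post hoc test).

#' Shape-mode frequency table by condition
#'
#' Percent of cells per shape mode for every (group, exposure time) present in
#' the data. Rows sum to 100; conditions with no cells are simply absent (not
#' zero-filled).
#'
#' @param cells Data frame with columns `image_id` and `shape_mode`.
#' @param design Data frame mapping `image_id` to `group`, `dose_ug`,
#'   `exposure_h`.
#' @param k Number of shape modes (columns `SM1..SMk`).
#' @return Data frame with `group`, `dose_ug`, `exposure_h`, `n`, and `SM*`
#'   percentage columns; class `sm_frequency_table`.
#' @export
sm_frequencies <- function(cells, design, k = max(cells$shape_mode)) {
  need <- c("image_id", "group", "dose_ug", "exposure_h")
  if (!all(need %in% names(design)))
    stop_param("design must have columns %s", paste(need, collapse = ", "))
  orphan <- setdiff(unique(cells$image_id), design$image_id)
  if (length(orphan))
    stop_param("cells reference images missing from the design: %s",
               paste(orphan, collapse = ", "))
  d <- merge(cells, design[, need], by = "image_id")
  d <- d[!is.na(d$shape_mode), , drop = FALSE]
  keys <- unique(d[, c("group", "dose_ug", "exposure_h")])
  keys <- keys[order(keys$group, keys$exposure_h), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- d$group == keys$group[i] & d$exposure_h == keys$exposure_h[i] &
      d$dose_ug == keys$dose_ug[i]
    sm <- d$shape_mode[sel]
    pct <- 100 * tabulate(sm, k) / length(sm)
    out <- data.frame(group = keys$group[i], dose_ug = keys$dose_ug[i],
                      exposure_h = keys$exposure_h[i], n = length(sm))
    out[paste0("SM", seq_len(k))] <- as.list(pct)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sm_frequency_table", "data.frame")
  out
}

#' Fold change of a geometric feature relative to healthy control
#'
#' For each (group, exposure time), the per-cell median of `feature` divided by
#' the healthy-control median at the same exposure time. Medians (not means)
#' are used for internal consistency with median-with-IQR reporting of the
#' per-cell distributions; the statistic is configurable.
#'
#' @param cells Data frame with `image_id` and the feature column.
#' @param design Design table (`image_id`, `group`, `dose_ug`, `exposure_h`).
#' @param feature Feature column name, e.g. `"circularity"`.
#' @param control Group treated as the reference (default `"healthy"`).
#' @param statistic Aggregation statistic: `"median"` (default) or `"mean"`.
#' @return Data frame `group`, `dose_ug`, `exposure_h`, `feature`,
#'   `fold_change`; the control's own entries are exactly 1.
#' @export
feature_fold_change <- function(cells, design, feature, control = "healthy",
                                statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  agg <- if (statistic == "median") stats::median else mean
  d <- merge(cells, design[, c("image_id", "group", "dose_ug", "exposure_h")],
             by = "image_id")
  if (!feature %in% names(d)) stop_param("unknown feature `%s`", feature)
  d <- d[is.finite(d[[feature]]), , drop = FALSE]
  keys <- unique(d[, c("group", "dose_ug", "exposure_h")])
  keys <- keys[order(keys$group, keys$exposure_h), , drop = FALSE]
  ref <- function(t) {
    v <- d[[feature]][d$group == control & d$exposure_h == t]
    if (!length(v)) stop_param("no `%s` control cells at exposure_h = %g", control, t)
    agg(v)
  }
  fc <- vapply(seq_len(nrow(keys)), function(i) {
    v <- d[[feature]][d$group == keys$group[i] & d$exposure_h == keys$exposure_h[i] &
                        d$dose_ug == keys$dose_ug[i]]
    if (keys$group[i] == control) 1 else agg(v) / ref(keys$exposure_h[i])
  }, numeric(1))
  data.frame(keys, feature = feature, fold_change = fc, row.names = NULL)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with a chi-square approximation on
#' `length(groups) - 1` degrees of freedom (via [stats::kruskal.test()]). When
#' all observations are equal the tie correction leaves H = 0 by convention.
#'
#' @param samples List of numeric vectors (>= 2 groups, each nonempty), or a
#'   numeric vector when `g` is given.
#' @param g Optional grouping factor when `samples` is a vector.
#' @return List of class `kw_test`: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(samples, g = NULL) {
  if (!is.null(g)) samples <- split(as.numeric(samples), g)
  if (!is.list(samples) || length(samples) < 2L)
    stop_param("need at least two groups")
  n <- lengths(samples)
  if (any(n == 0L)) stop_param("every group must be nonempty")
  if (sum(n) < 3L) stop_param("need at least 3 observations in total")
  x <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(seq_along(samples), n))
  if (length(unique(x)) == 1L) {
    res <- list(H = 0, df = length(samples) - 1L, p = 1)
  } else {
    kt <- stats::kruskal.test(x, grp)
    res <- list(H = unname(kt$statistic), df = unname(kt$parameter),
                p = kt$p.value)
  }
  structure(res, class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n", x$H, x$df, x$p))
  invisible(x)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled ranks with tie correction,
#' `z_ij = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T/(12(N-1))) (1/n_i + 1/n_j))`
#' with `T = sum(t^3 - t)` over tie groups; two-sided p values adjusted over
#' the whole family of pairs.
#'
#' @param samples List of >= 2 numeric vectors (or vector + `g`).
#' @param g Optional grouping factor.
#' @param method Family-wise adjustment passed to [stats::p.adjust()]
#'   (default `"bonferroni"`; `"holm"` and `"none"` are common alternatives).
#' @return Data frame `group1`, `group2`, `z`, `p`, `p_adj`, of class
#'   `dunn_test`.
#' @export
dunn_posthoc <- function(samples, g = NULL, method = "bonferroni") {
  if (!is.null(g)) samples <- split(as.numeric(samples), g)
  if (!is.list(samples) || length(samples) < 2L)
    stop_param("Dunn's test needs at least two groups")
  nms <- names(samples)
  if (is.null(nms)) nms <- as.character(seq_along(samples))
  n <- lengths(samples)
  if (any(n == 0L)) stop_param("every group must be nonempty")
  x <- unlist(samples, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  rbar <- vapply(split(r, rep(seq_along(samples), n)), mean, numeric(1))
  ties <- table(x)
  Tcorr <- sum(ties^3 - ties)
  s2 <- N * (N + 1) / 12 - Tcorr / (12 * (N - 1))
  pairs <- utils::combn(seq_along(samples), 2L)
  z <- apply(pairs, 2L, function(ij) {
    i <- ij[1L]; j <- ij[2L]
    se <- sqrt(s2 * (1 / n[i] + 1 / n[j]))
    if (se == 0) 0 else (rbar[i] - rbar[j]) / se
  })
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(group1 = nms[pairs[1L, ]], group2 = nms[pairs[2L, ]],
                    z = z, p = p, p_adj = stats::p.adjust(p, method = method))
  class(out) <- c("dunn_test", "data.frame")
  out
}

#' Compare a feature across groups: Kruskal-Wallis + Dunn
#'
#' @param values Numeric vector of per-cell feature values.
#' @param group Grouping factor.
#' @param alpha Significance level (default 0.05).
#' @param adjustment Dunn adjustment method.
#' @return List of class `morph_stat`: `kruskal` (a `kw_test`), `dunn`
#'   (a `dunn_test`), `alpha`.
#' @export
compare_groups <- function(values, group, alpha = 0.05, adjustment = "bonferroni") {
  kw <- kruskal_wallis(values, g = group)
  dn <- if (nlevels(factor(group)) >= 2L) dunn_posthoc(values, g = group,
                                                       method = adjustment) else NULL
  structure(list(kruskal = kw, dunn = dn, alpha = alpha), class = "morph_stat")
}

#' @export
print.morph_stat <- function(x, ...) {
  print(x$kruskal)
  if (!is.null(x$dunn)) {
    sig <- x$dunn$p_adj < x$alpha
    cat(sprintf("Dunn (alpha = %g): %d of %d pairs significant\n",
                x$alpha, sum(sig), length(sig)))
    print(as.data.frame(x$dunn))
  }
  invisible(x)
}

#' Export a numeric table as CSV plus a heatmap PNG
#'
#' The CSV is the exact numeric table. The PNG color scale follows the style:
#' `"fold_change"` uses a per-row two-color-to-white map (row maximum maps to
#' white), `"frequency"` a global red-yellow-green map. NA/NaN cells are drawn
#' in grey and reported via a message.
#'
#' @param table Numeric matrix or data frame of numeric columns (row names kept).
#' @param png_path,csv_path Output paths (either may be NULL to skip).
#' @param style `"fold_change"` or `"frequency"`.
#' @param low_colors Low-end color per row for `"fold_change"` (recycled).
#' @return Invisibly, the list of written paths.
#' @export
heatmap_export <- function(table, png_path = NULL, csv_path = NULL,
                           style = c("fold_change", "frequency"),
                           low_colors = c("green4", "gold", "blue3", "purple3")) {
  style <- match.arg(style)
  m <- as.matrix(table)
  if (!is.numeric(m)) stop_param("table must be numeric")
  if (!is.null(csv_path))
    utils::write.csv(m, csv_path, row.names = !is.null(rownames(m)))
  if (!is.null(png_path)) {
    if (any(!is.finite(m)))
      message(sprintf("heatmap: %d missing cells drawn in grey", sum(!is.finite(m))))
    nr <- nrow(m); nc <- ncol(m)
    grDevices::png(png_path, width = 120 * nc + 160, height = 60 * nr + 80)
    op <- graphics::par(mar = c(1, 8, 4, 1))
    on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
    graphics::plot(NA, xlim = c(0, nc), ylim = c(0, nr), axes = FALSE,
                   xlab = "", ylab = "", asp = NA)
    for (i in seq_len(nr)) {
      row <- m[i, ]
      cols <- if (style == "fold_change") {
        pal <- grDevices::colorRampPalette(c(low_colors[(i - 1L) %% length(low_colors) + 1L],
                                             "white"))(64)
        rng <- range(row, finite = TRUE)
        idx <- if (diff(rng) == 0) rep(64L, nc)
               else pmax(1L, pmin(64L, 1L + floor(63 * (row - rng[1]) / diff(rng))))
        pal[idx]
      } else {
        pal <- grDevices::colorRampPalette(c("red3", "yellow", "green4"))(64)
        rng <- range(m, finite = TRUE)
        idx <- if (diff(rng) == 0) rep(32L, nc)
               else pmax(1L, pmin(64L, 1L + floor(63 * (row - rng[1]) / diff(rng))))
        pal[idx]
      }
      cols[!is.finite(row)] <- "grey70"
      graphics::rect(seq_len(nc) - 1L, nr - i, seq_len(nc), nr - i + 1L,
                     col = cols, border = "white")
      graphics::text(seq_len(nc) - 0.5, nr - i + 0.5,
                     ifelse(is.finite(row), sprintf("%.2f", row), "NA"), cex = 0.9)
    }
    graphics::axis(2, at = seq_len(nr) - 0.5, labels = rev(rownames(m) %||% seq_len(nr)),
                   las = 2, tick = FALSE)
    graphics::axis(3, at = seq_len(nc) - 0.5, labels = colnames(m) %||% seq_len(nc),
                   tick = FALSE)
  }
  invisible(list(png = png_path, csv = csv_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
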
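## Population shape-mode analysis: registered cell contours are embedded with
## principal components and clustered with k-means into k recurring
## morphologies ("shape modes"), fitted on a train split and applied to all
## cells. The fitted object is the package's central model.

## k-means++ seeding feeding stats::kmeans (Lloyd); best of `restarts` runs.
kmeans_pp <- function(X, k, restarts = 10L) {
  n <- nrow(X)
  if (k == 1L) {
    ## single cluster: the centroid is the mean, no iteration needed
    ctr <- matrix(colMeans(X), 1L, ncol(X))
    return(list(centers = ctr, cluster = rep(1L, n),
                tot.withinss = sum(sweep(X, 2L, ctr[1L, ])^2)))
  }
  distinct <- unique(X)
  if (nrow(distinct) < k)
    stop_param("only %d distinct shapes for k = %d clusters", nrow(distinct), k)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- matrix(NA_real_, k, ncol(X))
    centers[1L, ] <- X[sample.int(n, 1L), ]
    for (j in 2:k) {
      d2 <- apply(X, 1L, function(p)
        min(colSums((t(centers[seq_len(j - 1L), , drop = FALSE]) - p)^2)))
      ## D^2 seeding never picks a duplicate of an existing center
      centers[j, ] <- X[sample.int(n, 1L, prob = d2), ]
    }
    fit <- tryCatch(suppressWarnings(
      stats::kmeans(X, centers = centers, iter.max = 200L, algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
      best <- fit
  }
  if (is.null(best))
    best <- tryCatch(suppressWarnings(stats::kmeans(X, k, nstart = 10L,
                                                    iter.max = 200L)),
                     error = function(e) stop_param("k-means failed in all restarts"))
  best
}

nearest_centroid <- function(scores, centroids) {
  d2 <- outer(rowSums(scores^2), rowSums(centroids^2), `+`) -
    2 * scores %*% t(centroids)
  mode <- apply(d2, 1L, which.min)  # ties -> lowest mode index
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(scores)), mode)], 0))
  list(mode = as.integer(mode), dist = dist)
}

#' Fit a shape-mode model to a population of cell contours
#'
#' Each contour is resampled to `n_points` equally spaced boundary points and
#' similarity-registered ([register_contour()]); principal components are
#' fitted on the registered training vectors, and k-means (k-means++ seeding,
#' 10 restarts, Lloyd iterations) clusters the training scores into `k` shape
#' modes. All cells — train and test — are then assigned to their nearest
#' centroid. Modes are renumbered 1..k by decreasing median cell area of their
#' members so labels are comparable across runs.
#'
#' @param contours List of contours (N x 2 (row, col) matrices, e.g. from
#'   [extract_contour()]).
#' @param k Number of shape modes (>= 1; default 5, chosen to capture
#'   biological variation while remaining interpretable).
#' @param n_points Boundary points per contour (default 50).
#' @param n_components Number of principal components retained; default the
#'   smallest number explaining >= 90% of registered-shape variance, capped at
#'   20.
#' @param train_fraction Fraction of cells used for fitting (default 0.8,
#'   i.e. an 80:20 train:test split), stratified by `image_id` when given.
#' @param seed RNG seed controlling the split and k-means.
#' @param image_id Optional character vector (one per contour) for stratified
#'   splitting.
#' @param cell_area Optional numeric vector of cell areas used for mode
#'   renumbering; defaults to each contour's enclosed (shoelace) area.
#' @return Object of class `shape_mode_model` with elements `n_points`,
#'   `n_components`, `mean_shape`, `basis` (n_components x 2N, orthonormal
#'   rows), `explained_variance`, `centroids` (k x n_components), `k`,
#'   `linkage` (Ward hierarchy over centroids, `NULL` for k = 1),
#'   `train_fraction`, `seed`, and `assignments` (data frame: `cell`,
#'   `image_id`, `shape_mode`, `distance_to_centroid`, `split`).
#' @export
shape_mode_model <- function(contours, k = 5L, n_points = 50L,
                             n_components = NULL, train_fraction = 0.8,
                             seed = 1L, image_id = NULL, cell_area = NULL) {
  if (!is.list(contours) || !length(contours))
    stop_param("`contours` must be a nonempty list of contours")
  n <- length(contours)
  if (n < k) stop_param("fewer cells (%d) than shape modes (k = %d)", n, k)
  if (train_fraction <= 0 || train_fraction > 1)
    stop_param("`train_fraction` must be in (0, 1]")
  rs <- lapply(contours, resample_contour, n_points = n_points)
  X <- t(vapply(rs, register_contour, numeric(2L * n_points)))
  if (is.null(cell_area))
    cell_area <- vapply(contours, function(p) abs(shoelace_area(unclass(p))), numeric(1))
  if (is.null(image_id)) image_id <- rep("all", n)

  with_seed(seed, {
    ## cell-level split, stratified by image
    train <- logical(n)
    for (img in unique(image_id)) {
      idx <- which(image_id == img)
      n_tr <- max(1L, round(train_fraction * length(idx)))
      train[sample(idx, n_tr)] <- TRUE
    }
    if (!any(train)) stop_param("empty training split")
    n_tr <- sum(train)
    if (n_tr < k) stop_param("training split (%d cells) smaller than k = %d", n_tr, k)
    if (n_tr < 5L * k)
      warning(sprintf("only %d training contours for k = %d (< 5k); modes may be unstable",
                      n_tr, k), call. = FALSE)

    pca <- stats::prcomp(X[train, , drop = FALSE], center = TRUE, scale. = FALSE)
    ev <- pca$sdev^2
    if (is.null(n_components)) {
      cum <- cumsum(ev) / sum(ev)
      n_components <- min(which(cum >= 0.9), 20L, length(ev))
    }
    n_components <- min(as.integer(n_components), ncol(pca$rotation))
    rot <- pca$rotation[, seq_len(n_components), drop = FALSE]
    scores <- sweep(X, 2L, pca$center) %*% rot

    km <- kmeans_pp(scores[train, , drop = FALSE], k)
    asg <- nearest_centroid(scores, km$centers)

    ## renumber modes by decreasing median member-cell area
    med_area <- vapply(seq_len(k), function(m) {
      a <- cell_area[asg$mode == m]
      if (length(a)) stats::median(a) else -Inf
    }, numeric(1))
    ord <- order(med_area, decreasing = TRUE)
    centroids <- km$centers[ord, , drop = FALSE]
    dimnames(centroids) <- list(paste0("SM", seq_len(k)), NULL)
    relabel <- integer(k); relabel[ord] <- seq_len(k)
    mode_final <- relabel[asg$mode]

    linkage <- if (k >= 2L) stats::hclust(stats::dist(centroids), method = "ward.D2")
               else NULL
    basis <- t(rot)
    dimnames(basis) <- NULL
    structure(list(
      n_points = as.integer(n_points), n_components = n_components,
      mean_shape = as.numeric(pca$center), basis = basis,
      explained_variance = ev, centroids = centroids, k = as.integer(k),
      linkage = linkage, train_fraction = train_fraction, seed = as.integer(seed),
      assignments = data.frame(cell = seq_len(n), image_id = image_id,
                               shape_mode = mode_final,
                               distance_to_centroid = asg$dist,
                               split = ifelse(train, "train", "test"))),
      class = "shape_mode_model")
  })
}

#' @export
print.shape_mode_model <- function(x, ...) {
  cat(sprintf("Shape-mode model: k = %d modes, %d boundary points, %d PCs (%.1f%% variance)\n",
              x$k, x$n_points, x$n_components,
              100 * sum(x$explained_variance[seq_len(x$n_components)]) /
                sum(x$explained_variance)))
  tab <- table(factor(x$assignments$shape_mode, levels = seq_len(x$k)))
  cat("Cells per mode:", paste(sprintf("SM%d:%d", seq_len(x$k), tab), collapse = "  "), "\n")
  invisible(x)
}

#' @export
summary.shape_mode_model <- function(object, ...) {
  a <- object$assignments
  cat(sprintf("Shape-mode model (k = %d), %d cells (%d train / %d test)\n",
              object$k, nrow(a), sum(a$split == "train"), sum(a$split == "test")))
  cum <- cumsum(object$explained_variance) / sum(object$explained_variance)
  cat(sprintf("PCs retained: %d (cumulative variance %.3f)\n",
              object$n_components, cum[object$n_components]))
  freq <- 100 * prop.table(table(factor(a$shape_mode, levels = seq_len(object$k)),
                                 a$split), margin = 2L)
  print(round(freq, 1))
  invisible(object)
}

## Reconstruct the mean-shape-space contour of a centroid (pre-image in the
## registered frame), as an n_points x 2 (x, y) matrix.
mode_shape <- function(model, mode) {
  v <- model$mean_shape + as.numeric(model$centroids[mode, ] %*% model$basis)
  n <- model$n_points
  cbind(x = v[seq_len(n)], y = v[n + seq_len(n)])
}

#' Assign shape modes to new contours
#'
#' @param object A fitted [shape_mode_model()].
#' @param newdata A contour (N x 2 matrix), a list of contours, or a numeric
#'   matrix of already-registered 2N shape vectors.
#' @param ... Unused.
#' @return Data frame with `shape_mode` (nearest centroid in PC-score space;
#'   ties broken toward the lowest mode index) and `distance_to_centroid`.
#' @export
predict.shape_mode_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata) && !inherits(newdata, "cell_contour")) {
    if (ncol(newdata) == 2L)
      t(register_contour(resample_contour(newdata, object$n_points)))
    else newdata
  } else {
    if (!is.list(newdata)) newdata <- list(newdata)
    t(vapply(newdata, function(ct)
      register_contour(resample_contour(ct, object$n_points)),
      numeric(2L * object$n_points)))
  }
  if (ncol(X) != length(object$mean_shape))
    stop_param("newdata dimension does not match the model")
  scores <- sweep(X, 2L, object$mean_shape) %*% t(object$basis)
  asg <- nearest_centroid(scores, object$centroids)
  data.frame(shape_mode = asg$mode, distance_to_centroid = asg$dist)
}

#' @rdname predict.shape_mode_model
#' @param model A fitted [shape_mode_model()].
#' @param contour A single contour.
#' @export
assign_mode <- function(model, contour) {
  if (!inherits(model, "shape_mode_model")) stop_param("`model` is not fitted")
  predict(model, contour)
}

#' Hierarchy over the shape-mode centroids
#'
#' Agglomerative (Ward) clustering of the k centroids in PC-score space, the
#' dendrogram used to order and color modes in population heatmaps.
#'
#' @param model A fitted [shape_mode_model()] with k >= 2.
#' @return List with `hclust` (the merge structure) and `leaves` (deterministic
#'   leaf order, mode indices).
#' @export
model_dendrogram <- function(model) {
  if (!inherits(model, "shape_mode_model")) stop_param("`model` is not fitted")
  if (model$k < 2L) stop_param("dendrogram needs k >= 2")
  list(hclust = model$linkage, leaves = model$linkage$order)
}

#' @export
plot.shape_mode_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, x$k + (x$k >= 2)), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  cols <- shape_mode_colors(x$k)
  for (m in seq_len(x$k)) {
    p <- mode_shape(x, m)
    graphics::plot(rbind(p, p[1L, ]), type = "l", asp = 1, axes = FALSE,
                   xlab = "", ylab = "", main = paste0("SM", m), col = cols[m], lwd = 2)
  }
  if (x$k >= 2L) graphics::plot(stats::as.dendrogram(x$linkage), main = "centroids")
  invisible(x)
}

#' Default shape-mode color map (cyclic, colorblind-stable)
#' @param k Number of modes.
#' @return Vector of k hex colors.
#' @export
shape_mode_colors <- function(k) {
  grDevices::hcl.colors(k, palette = "Zissou 1")
}

#' Paint cells by shape mode
#'
#' @param mask A [labeled_mask()].
#' @param assignments Data frame with columns `label` and `shape_mode` for the
#'   labels present in `mask`; labels without an assignment are painted in the
#'   reserved color.
#' @param colormap Vector of k colors; defaults to [shape_mode_colors()].
#' @param unassigned Color for unassigned cells.
#' @return H x W x 3 numeric array (RGB in `[0, 1]`); background stays black.
#' @export
render_mode_overlay <- function(mask, assignments, colormap = NULL,
                                unassigned = "grey50") {
  lab <- if (inherits(mask, "labeled_mask")) mask$labels else mask
  k <- max(assignments$shape_mode, 1L)
  if (is.null(colormap)) colormap <- shape_mode_colors(k)
  if (length(colormap) < k) stop_param("colormap has %d entries, need %d",
                                       length(colormap), k)
  mode_of <- rep(NA_integer_, max(lab, 1L))
  mode_of[assignments$label] <- assignments$shape_mode
  rgb_of <- grDevices::col2rgb(c(colormap, unassigned)) / 255
  out <- array(0, dim = c(nrow(lab), ncol(lab), 3L))
  fg <- which(lab > 0L)
  modes <- mode_of[lab[fg]]
  col_idx <- ifelse(is.na(modes), length(colormap) + 1L, modes)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(lab), ncol(lab))
    plane[fg] <- rgb_of[ch, col_idx]
    out[, , ch] <- plane
  }
  out
}

#' Serialize a shape-mode model to JSON
#'
#' All numeric arrays are stored at full precision; [read_shape_mode_model()]
#' restores a model yielding identical assignments.
#'
#' @param model A fitted [shape_mode_model()].
#' @param path Output JSON path.
#' @export
write_shape_mode_model <- function(model, path) {
  x <- unclass(model)
  ## matrices stored flat (row-major) with explicit dims
  x$basis <- list(dim = dim(model$basis), data = as.numeric(t(model$basis)))
  x$centroids <- list(dim = dim(model$centroids),
                      data = as.numeric(t(model$centroids)))
  x$linkage <- if (!is.null(model$linkage))
    list(merge = as.integer(t(model$linkage$merge)),
         height = model$linkage$height, order = model$linkage$order) else NULL
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Restore a shape-mode model written by [write_shape_mode_model()]
#' @param path JSON path.
#' @return A `shape_mode_model`.
#' @export
read_shape_mode_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$basis <- matrix(x$basis$data, nrow = x$basis$dim[1], byrow = TRUE)
  x$centroids <- matrix(x$centroids$data, nrow = x$centroids$dim[1], byrow = TRUE,
                        dimnames = list(paste0("SM", seq_len(x$k)), NULL))
  if (!is.null(x$linkage) && length(x$linkage)) {
    hc <- list(merge = matrix(as.integer(x$linkage$merge), ncol = 2L, byrow = TRUE),
               height = as.numeric(x$linkage$height),
               order = as.integer(x$linkage$order),
               labels = rownames(x$centroids), method = "ward.D2",
               call = quote(hclust()), dist.method = "euclidean")
    class(hc) <- "hclust"
    x$linkage <- hc
  } else x$linkage <- NULL
  x$assignments <- as.data.frame(x$assignments)
  structure(x, class = "shape_mode_model")
}

#' Per-cell masks of a labeled mask
#'
#' Extracts a cropped binary mask for each (non-degenerate) record, the unit
#' consumed by [extract_contour()] and [shape_mode_model()].
#'
#' @param mask A [labeled_mask()].
#' @param labels Labels to extract; defaults to all.
#' @return Named list of logical matrices.
#' @export
cell_masks <- function(mask, labels = NULL) {
  lab <- if (inherits(mask, "labeled_mask")) mask$labels else mask
  if (is.null(labels)) labels <- sort(unique(lab[lab > 0L]))
  stats::setNames(lapply(labels, function(L) {
    idx <- which(lab == L, arr.ind = TRUE)
    lab[min(idx[, 1L]):max(idx[, 1L]), min(idx[, 2L]):max(idx[, 2L]),
        drop = FALSE] == L
  }), labels)
}
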
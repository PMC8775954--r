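## Synthetic Iba-1-like fluorescence fields with per-cell ground truth.
##
## The generator emulates 40x confocal fields of Iba-1-stained cortex: bright
## cell bodies with 0-6 processes on a dark background, drawn from a mixture of
## morphological classes (amoeboid through ramified), anti-aliased with a 1 px
## Gaussian blur and corrupted with Gaussian and optional Poisson noise. Every
## image carries a label mask, per-cell class labels and pixel areas, so each
## downstream stage can be validated against known truth.

#' Define a synthetic microglia shape class
#'
#' Parameter ranges (each `c(min, max)`) from which individual cells are drawn.
#' The soma is an ellipse of area ~ pi * soma_radius^2 with axis ratio
#' `elongation`; processes are straight, slightly jittered rays of the given
#' length and width attached to the soma boundary.
#'
#' @param name One of `"amoeboid"`, `"transitional"`, `"ramified"`,
#'   `"elongated"`, `"rod"`.
#' @param soma_radius_px Range of equivalent soma radii (px).
#' @param n_branches Integer range of process counts; amoeboid must be
#'   `c(0, 0)`, ramified must have a lower bound >= 3.
#' @param branch_length_px,branch_width_px Ranges for process geometry (px).
#' @param elongation Range of soma axis ratios, lower bound >= 1.
#' @return Object of class `shape_class`.
#' @export
shape_class <- function(name, soma_radius_px, n_branches = c(0, 0),
                        branch_length_px = c(0, 0), branch_width_px = c(2, 3),
                        elongation = c(1, 1)) {
  name <- match.arg(name, c("amoeboid", "transitional", "ramified", "elongated", "rod"))
  check_range(soma_radius_px, "soma_radius_px", lower = 1)
  check_range(n_branches, "n_branches", lower = 0)
  check_range(branch_length_px, "branch_length_px", lower = 0)
  check_range(branch_width_px, "branch_width_px", lower = 0)
  check_range(elongation, "elongation", lower = 1)
  if (name == "amoeboid" && n_branches[2] != 0)
    stop_param("amoeboid cells have no branches (n_branches must be c(0, 0))")
  if (name == "ramified" && n_branches[1] < 3)
    stop_param("ramified cells need n_branches lower bound >= 3")
  structure(list(name = name, soma_radius_px = soma_radius_px,
                 n_branches = n_branches, branch_length_px = branch_length_px,
                 branch_width_px = branch_width_px, elongation = elongation),
            class = "shape_class")
}

#' Default microglial shape-class library
#'
#' Five classes spanning the amoeboid-to-ramified morphology spectrum at a
#' sampling of 1 um/px: swollen amoeboid somata are large and round, ramified
#' cells have small somata with 3-6 thin processes, and rod cells are strongly
#' elongated. Class geometry is chosen so that amoeboid cells have the largest
#' area and highest circularity and ramified the lowest circularity, mirroring
#' the inflammatory-to-surveillant contrast seen in tissue.
#'
#' @return Named list of [shape_class()] objects.
#' @export
microglia_classes <- function() {
  list(
    amoeboid     = shape_class("amoeboid", c(12, 18), c(0, 0), c(0, 0), c(2, 3), c(1, 1.3)),
    transitional = shape_class("transitional", c(9, 13), c(1, 2), c(10, 20), c(2, 3), c(1, 1.4)),
    ramified     = shape_class("ramified", c(6, 9), c(3, 6), c(15, 35), c(2, 3), c(1.3, 1.8)),
    elongated    = shape_class("elongated", c(8, 12), c(0, 2), c(8, 15), c(2, 3), c(2, 3)),
    rod          = shape_class("rod", c(6, 9), c(0, 0), c(0, 0), c(2, 3), c(3.5, 5))
  )
}

#' Specification for one synthetic image
#'
#' @param image_shape `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size (um/px). Acquisition pixel size is treated
#'   as a free parameter of the emulated microscope, default 1 um/px.
#' @param n_cells Number of cells to place (>= 0).
#' @param classes Named list of [shape_class()] objects.
#' @param class_mixture Probability vector over `classes` (sums to 1).
#' @param intensity_fg,intensity_bg Foreground/background intensities in
#'   `[0, 1]`; `intensity_fg > intensity_bg`.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param poisson_scale Photon count at unit intensity for Poisson shot noise;
#'   0 disables it.
#' @param min_cell_separation_px Minimum distance between cells; cells are
#'   placed by rejection sampling (100 retries per cell) so placement at a
#'   positive separation guarantees a bijection between cells and labels.
#' @param seed Integer RNG seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(image_shape = c(512L, 512L), pixel_size_um = 1,
                           n_cells = 25L, classes = microglia_classes(),
                           class_mixture = NULL,
                           intensity_fg = 0.8, intensity_bg = 0.1,
                           noise_sd = 0.02, poisson_scale = 0,
                           min_cell_separation_px = 5, seed = 1L) {
  if (is.null(class_mixture))
    class_mixture <- stats::setNames(rep(1 / length(classes), length(classes)),
                                     names(classes))
  if (length(class_mixture) != length(classes))
    stop_param("`class_mixture` must have one entry per class")
  if (abs(sum(class_mixture) - 1) > 1e-9)
    stop_param("`class_mixture` must sum to 1 (got %.12g)", sum(class_mixture))
  if (any(class_mixture < 0)) stop_param("`class_mixture` entries must be >= 0")
  if (intensity_fg <= intensity_bg)
    stop_param("`intensity_fg` must exceed `intensity_bg`")
  if (n_cells < 0) stop_param("`n_cells` must be >= 0")
  if (noise_sd < 0 || poisson_scale < 0 || min_cell_separation_px < 0)
    stop_param("noise and separation parameters must be nonnegative")
  check_positive(pixel_size_um, "pixel_size_um")
  structure(list(image_shape = as.integer(image_shape), pixel_size_um = pixel_size_um,
                 n_cells = as.integer(n_cells), classes = classes,
                 class_mixture = class_mixture, intensity_fg = intensity_fg,
                 intensity_bg = intensity_bg, noise_sd = noise_sd,
                 poisson_scale = poisson_scale,
                 min_cell_separation_px = min_cell_separation_px,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## Rasterize a filled ellipse with semi-axes a, b at angle theta, centered on
## the canvas center.
raster_ellipse <- function(canvas, a, b, theta, center) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r <- matrix(seq_len(nr), nr, nc) - center[1]
  c2 <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  ct <- cos(theta); st <- sin(theta)
  u <- r * ct + c2 * st
  v <- -r * st + c2 * ct
  canvas | ((u / a)^2 + (v / b)^2 <= 1)
}

## Stamp a thick segment (width w) from p0 towards angle phi, length len.
raster_branch <- function(canvas, p0, phi, len, w) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  n_steps <- max(2L, ceiling(len * 2))
  t <- seq(0, len, length.out = n_steps)
  ## low curvature: small random bend applied as a quadratic deflection
  bend <- stats::runif(1, -0.15, 0.15)
  rr <- p0[1] + t * cos(phi) - bend * (t^2 / max(len, 1)) * sin(phi)
  cc <- p0[2] + t * sin(phi) + bend * (t^2 / max(len, 1)) * cos(phi)
  rad <- w / 2
  ir <- ceiling(rad)
  for (i in seq_len(n_steps)) {
    r0 <- round(rr[i]); c0 <- round(cc[i])
    rs <- max(1L, r0 - ir):min(nr, r0 + ir)
    cs <- max(1L, c0 - ir):min(nc, c0 + ir)
    if (!length(rs) || !length(cs)) next
    d2 <- outer((rs - rr[i])^2, (cs - cc[i])^2, `+`)
    canvas[rs, cs] <- canvas[rs, cs] | (d2 <= rad^2)
  }
  canvas
}

#' Generate one cell silhouette from a shape class
#'
#' Draws soma radius, elongation, branch count and branch geometry from the
#' class ranges and rasterizes the cell on a minimal canvas. The output is a
#' single 8-connected foreground component: branches start just inside the
#' soma boundary.
#'
#' @param cls A [shape_class()].
#' @param seed Optional seed; the same seed yields a bit-identical mask.
#' @return Logical matrix (small canvas) with the cell silhouette.
#' @export
generate_cell_shape <- function(cls, seed = NULL) {
  stopifnot(inherits(cls, "shape_class"))
  with_seed(seed, {
    r <- runif_range(cls$soma_radius_px)
    e <- runif_range(cls$elongation)
    a <- r * sqrt(e); b <- r / sqrt(e)
    nb <- sample_int_range(cls$n_branches)
    ## one length/width draw per cell: processes of a cell share geometry, so
    ## the registered shape of a class is stable (independent per-arm lengths
    ## would let a random arm pair dominate the principal axis)
    blen <- if (nb > 0) rep(runif_range(cls$branch_length_px), nb) else numeric(0)
    bw <- if (nb > 0) rep(runif_range(cls$branch_width_px), nb) else numeric(0)
    half <- ceiling(a + (if (nb > 0) max(blen) else 0) + max(bw, 2) + 2)
    side <- 2L * as.integer(half) + 1L
    canvas <- matrix(FALSE, side, side)
    center <- c(half + 1, half + 1)
    theta <- stats::runif(1, 0, pi)
    canvas <- raster_ellipse(canvas, a, b, theta, center)
    if (nb > 0) {
      ## processes evenly spread around the soma and anchored to its axis
      ## (plus a small jitter), so cells of one class share a coherent shape
      ## up to similarity transforms
      base <- theta + stats::runif(1, -pi / 16, pi / 16) +
        seq(0, 2 * pi, length.out = nb + 1L)[-(nb + 1L)]
      for (i in seq_len(nb)) {
        ## mild per-process jitter; large tilts create mirror-image (chiral)
        ## variants that registration deliberately does not identify
        phi <- base[i] + stats::runif(1, -pi / 24, pi / 24)
        ## boundary point of the soma ellipse along phi, pulled 1 px inward
        dr <- c(cos(phi), sin(phi))
        ct <- cos(theta); st <- sin(theta)
        u <- dr[1] * ct + dr[2] * st; v <- -dr[1] * st + dr[2] * ct
        rho <- 1 / sqrt((u / a)^2 + (v / b)^2)
        p0 <- center + (rho - 1) * dr
        ## elongation shapes the whole cell: processes along the soma axis
        ## keep full length, perpendicular ones shrink by 1/elongation
        aniso <- 1 / e + (1 - 1 / e) * (u^2 / (u^2 + v^2))
        canvas <- raster_branch(canvas, p0, phi, blen[i] * aniso, bw[i])
      }
    }
    canvas
  })
}

#' Render a synthetic fluorescence image with ground truth
#'
#' Places `n_cells` cells drawn from the class mixture by rejection sampling
#' (no two cells closer than `min_cell_separation_px` when that is positive),
#' then renders: binary silhouettes, 1 px Gaussian blur for an anti-aliased
#' edge, linear mapping to `[intensity_bg, intensity_fg]`, additive Gaussian
#' noise, optional Poisson shot noise, and clipping to `[0, 1]`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `image` (a [fluor_image()]) and `truth`, a list holding
#'   `label_mask` (a [labeled_mask()]), `cell_classes` (label -> class name)
#'   and `cell_areas_px` (label -> pixel count).
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
    lab <- matrix(0L, nr, nc)
    occupied <- matrix(FALSE, nr, nc)
    sep <- spec$min_cell_separation_px
    brush <- if (sep > 0)
      EBImage::makeBrush(2L * as.integer(ceiling(sep)) + 1L, "disc") else NULL
    classes_drawn <- character(0)
    placed <- 0L
    if (spec$n_cells > 0) {
      cls_idx <- sample.int(length(spec$classes), spec$n_cells, replace = TRUE,
                            prob = spec$class_mixture)
      for (i in seq_len(spec$n_cells)) {
        cls <- spec$classes[[cls_idx[i]]]
        cell <- generate_cell_shape(cls)
        if (nrow(cell) > nr || ncol(cell) > nc)
          stop_param("could not place cell %d of %d: canvas %dx%d exceeds the %dx%d image (%d placed)",
                     i, spec$n_cells, nrow(cell), ncol(cell), nr, nc, placed)
        footprint <- if (is.null(brush)) cell else
          EBImage::imageData(EBImage::dilate(cell * 1, brush)) > 0
        ok <- FALSE
        for (try in seq_len(100L)) {
          r0 <- sample.int(nr - nrow(cell) + 1L, 1L)
          c0 <- sample.int(nc - ncol(cell) + 1L, 1L)
          rs <- r0:(r0 + nrow(cell) - 1L); cs <- c0:(c0 + ncol(cell) - 1L)
          if (sep > 0) {
            ## footprint window, clipped at image borders
            fr <- rs[1] - (nrow(footprint) - nrow(cell)) %/% 2L
            fc <- cs[1] - (ncol(footprint) - ncol(cell)) %/% 2L
            frs <- fr:(fr + nrow(footprint) - 1L); fcs <- fc:(fc + ncol(footprint) - 1L)
            inr <- frs >= 1L & frs <= nr; inc <- fcs >= 1L & fcs <= nc
            clash <- any(occupied[frs[inr], fcs[inc]] & footprint[inr, inc])
          } else clash <- FALSE
          if (!clash) {
            win <- lab[rs, cs]
            win[cell] <- placed + 1L
            lab[rs, cs] <- win
            occ <- occupied[rs, cs]; occ[cell] <- TRUE; occupied[rs, cs] <- occ
            placed <- placed + 1L
            classes_drawn <- c(classes_drawn, cls$name)
            ok <- TRUE
            break
          }
        }
        if (!ok)
          stop_param("could not place cell %d of %d without overlap after 100 retries (%d placed)",
                     i, spec$n_cells, placed)
      }
    }
    fg <- matrix(as.numeric(lab > 0L), nr, nc)
    sm <- EBImage::imageData(EBImage::gblur(fg, sigma = 1))
    img <- spec$intensity_bg + (spec$intensity_fg - spec$intensity_bg) * sm
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    if (spec$poisson_scale > 0)
      img <- matrix(stats::rpois(nr * nc, pmax(img, 0) * spec$poisson_scale),
                    nr, nc) / spec$poisson_scale
    img <- pmin(pmax(img, 0), 1)
    areas <- if (placed > 0) tabulate(lab[lab > 0L], placed) else integer(0)
    truth <- list(label_mask = labeled_mask(lab, 8L,
                                            provenance = list(source = "synthetic",
                                                              seed = spec$seed)),
                  cell_classes = stats::setNames(classes_drawn, seq_len(placed)),
                  cell_areas_px = stats::setNames(areas, seq_len(placed)))
    list(image = fluor_image(img, spec$pixel_size_um,
                             id = sprintf("synthetic_seed%d", spec$seed)),
         truth = truth)
  })
}

#' Default experiment design emulated by the condition series
#'
#' Healthy, OGD (oxygen-glucose deprivation) and BEV-treated (25 ug) arms at
#' exposure times 0, 4, 24 and 48 h. Mixtures encode the expected biology:
#' injured arms are amoeboid-dominated early; the BEV arm shifts toward
#' ramified/branched classes between 24 and 48 h while OGD stays amoeboid.
#'
#' @param n_images Images per condition.
#' @return Data frame with columns `group`, `dose_ug`, `exposure_h`,
#'   `n_images` and mixture columns `mix_<class>`.
#' @export
default_condition_design <- function(n_images = 2L) {
  mixes <- list(
    healthy_all = c(amoeboid = 0.30, transitional = 0.30, ramified = 0.25,
                    elongated = 0.10, rod = 0.05),
    injured     = c(amoeboid = 0.70, transitional = 0.15, ramified = 0.05,
                    elongated = 0.05, rod = 0.05),
    bev_late    = c(amoeboid = 0.10, transitional = 0.20, ramified = 0.50,
                    elongated = 0.15, rod = 0.05))
  rows <- list()
  for (t in c(0, 4, 24, 48)) {
    rows[[length(rows) + 1L]] <- c(list(group = "healthy", dose_ug = 0, exposure_h = t),
                                   as.list(mixes$healthy_all))
    rows[[length(rows) + 1L]] <- c(list(group = "OGD", dose_ug = 0, exposure_h = t),
                                   as.list(mixes$injured))
    bev_mix <- if (t >= 48) mixes$bev_late else mixes$injured
    rows[[length(rows) + 1L]] <- c(list(group = "BEV", dose_ug = 25, exposure_h = t),
                                   as.list(bev_mix))
  }
  d <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  names(d)[4:8] <- paste0("mix_", names(mixes$healthy_all))
  d$n_images <- as.integer(n_images)
  d
}

#' Generate a seeded series of images across experimental conditions
#'
#' One independently seeded image per (group, exposure time, replicate); seeds
#' are fanned out from `seed` with [stage_seed()] so no two images share a
#' random stream.
#'
#' @param design Data frame as returned by [default_condition_design()]:
#'   columns `group`, `dose_ug`, `exposure_h`, `n_images` and `mix_<class>`
#'   columns matching `base_spec$classes`.
#' @param base_spec A [synthetic_spec()] providing image geometry, noise and
#'   class library; its mixture and seed are overridden per image.
#' @param seed Integer master seed.
#' @param out_dir Optional directory; if given, images and label masks are
#'   written as TIFF and the design table as `design.csv`.
#' @return List with `images` (list of [generate_image()] results) and
#'   `design` (one row per image: `image_id`, `image_path`, `mask_path`,
#'   `group`, `dose_ug`, `exposure_h`, `replicate`, `seed`).
#' @export
generate_condition_series <- function(design, base_spec = synthetic_spec(),
                                      seed = 1L, out_dir = NULL) {
  mix_cols <- paste0("mix_", names(base_spec$classes))
  need <- c("group", "dose_ug", "exposure_h", "n_images", mix_cols)
  miss <- setdiff(need, names(design))
  if (length(miss)) stop_param("design is missing columns: %s", paste(miss, collapse = ", "))
  key <- interaction(design$group, design$exposure_h, drop = TRUE)
  if (anyDuplicated(key))
    stop_param("duplicate (group, exposure_h) rows in design: %s",
               paste(unique(key[duplicated(key)]), collapse = ", "))
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  images <- list(); rows <- list()
  for (i in seq_len(nrow(design))) {
    mix <- as.numeric(design[i, mix_cols])
    names(mix) <- names(base_spec$classes)
    if (abs(sum(mix) - 1) > 1e-9)
      stop_param("mixture in design row %d does not sum to 1", i)
    for (rep_i in seq_len(design$n_images[i])) {
      id <- sprintf("%s_t%g_r%d", design$group[i], design$exposure_h[i], rep_i)
      s <- stage_seed(seed, id)
      spec_i <- base_spec
      spec_i$class_mixture <- mix
      spec_i$seed <- s
      gen <- generate_image(spec_i)
      gen$image$id <- id
      ## paths recorded relative to the design file's directory, so a series
      ## directory can be moved or rerun from another working directory
      img_path <- mask_path <- NA_character_
      if (!is.null(out_dir)) {
        img_path <- paste0(id, ".tiff")
        mask_path <- paste0(id, "_truth.tiff")
        write_tiff(gen$image, file.path(out_dir, img_path))
        write_tiff(gen$truth$label_mask$labels, file.path(out_dir, mask_path),
                   labels = TRUE)
      }
      images[[id]] <- gen
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = id, image_path = img_path, mask_path = mask_path,
        group = design$group[i], dose_ug = design$dose_ug[i],
        exposure_h = design$exposure_h[i], replicate = rep_i, seed = s)
    }
  }
  out <- list(images = images, design = do.call(rbind, rows))
  if (!is.null(out_dir))
    utils::write.csv(out$design, file.path(out_dir, "design.csv"), row.names = FALSE)
  out
}
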
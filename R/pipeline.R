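## End-to-end orchestration: one config drives synthetic generation (or an
## image directory), segmentation, per-cell features, shape-mode modelling and
## population statistics, with a content-hashed output manifest and seeded,
## stage-isolated reruns.

#' Build a pipeline configuration
#'
#' @param mode `"synthetic"` (generate a condition series) or `"image_dir"`
#'   (read TIFFs listed in a design CSV).
#' @param out_dir Output directory for the run.
#' @param seed Global seed; per-stage child seeds are derived with
#'   [stage_seed()].
#' @param image_dir,design_csv Inputs for `"image_dir"` mode; `design_csv`
#'   needs columns `image_id`, `image_path`, `group`, `dose_ug`, `exposure_h`,
#'   `replicate`.
#' @param synthetic List of overrides for [synthetic_spec()] plus optional
#'   `design` (see [default_condition_design()]) and `n_images`.
#' @param segmentation List of overrides for [segmentation_config()].
#' @param shape_modes List: `k`, `n_points`, `train_fraction`.
#' @param stats List: `alpha`, `adjustment`, `statistic`, `control`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "image_dir"), out_dir,
                            seed = 1L, image_dir = NULL, design_csv = NULL,
                            synthetic = list(), segmentation = list(),
                            shape_modes = list(), stats = list()) {
  cfg <- list(mode = match.arg(mode), out_dir = out_dir, seed = as.integer(seed),
              image_dir = image_dir, design_csv = design_csv,
              synthetic = synthetic, segmentation = segmentation,
              shape_modes = shape_modes, stats = stats)
  errs <- config_errors(cfg)
  if (length(errs))
    stop_param("invalid pipeline config:\n- %s", paste(errs, collapse = "\n- "))
  structure(cfg, class = "pipeline_config")
}

config_errors <- function(cfg) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (!cfg$mode %in% c("synthetic", "image_dir")) add("mode must be 'synthetic' or 'image_dir'")
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir)) add("out_dir is required")
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) add("seed must be set")
  if (identical(cfg$mode, "image_dir")) {
    if (is.null(cfg$design_csv)) add("image_dir mode requires design_csv")
    else if (!file.exists(cfg$design_csv)) add(sprintf("design_csv not found: %s", cfg$design_csv))
    if (!is.null(cfg$image_dir) && !dir.exists(cfg$image_dir))
      add(sprintf("image_dir not found: %s", cfg$image_dir))
  }
  k <- cfg$shape_modes$k %||% 5L
  if (!is.numeric(k) || k < 1) add("shape_modes$k must be >= 1")
  np <- cfg$shape_modes$n_points %||% 50L
  if (!is.numeric(np) || np < 3) add("shape_modes$n_points must be >= 3")
  tf <- cfg$shape_modes$train_fraction %||% 0.8
  if (!is.numeric(tf) || tf <= 0 || tf > 1) add("shape_modes$train_fraction must be in (0, 1]")
  ps <- cfg$segmentation$pixel_size_um %||% 1
  if (!is.numeric(ps) || ps <= 0) add("segmentation$pixel_size_um must be positive")
  ma <- cfg$segmentation$min_object_area_px %||% 71
  if (!is.numeric(ma) || ma <= 0) add("segmentation$min_object_area_px must be positive")
  meth <- cfg$segmentation$method %||% "li"
  if (!meth %in% THRESHOLD_METHODS)
    add(sprintf("segmentation$method must be one of: %s",
                paste(THRESHOLD_METHODS, collapse = ", ")))
  al <- cfg$stats$alpha %||% 0.05
  if (!is.numeric(al) || al <= 0 || al >= 1) add("stats$alpha must be in (0, 1)")
  errs
}

#' Validate a raw pipeline configuration
#'
#' Accepts a YAML file path, YAML text, or a plain list, and reports *every*
#' violation at once rather than failing on the first.
#'
#' @param raw YAML path, YAML string, or list.
#' @return A validated `pipeline_config`, or (invisibly) a character vector of
#'   class `config_errors` listing all violations.
#' @export
validate_config <- function(raw) {
  cfg <- if (is.character(raw) && length(raw) == 1L) {
    if (file.exists(raw)) yaml::read_yaml(raw) else yaml::yaml.load(raw)
  } else if (is.list(raw)) raw
  else stop_param("`raw` must be a YAML path/text or a list")
  cfg$mode <- cfg$mode %||% "synthetic"
  cfg$seed <- cfg$seed %||% 1L
  errs <- config_errors(cfg)
  if (length(errs)) return(invisible(structure(errs, class = "config_errors")))
  do.call(pipeline_config, cfg[intersect(names(cfg), names(formals(pipeline_config)))])
}

pipeline_dirs <- function(out_dir) {
  dirs <- file.path(out_dir, c("images", "masks", "features", "model", "stats", "figures"))
  for (d in dirs) dir.create(d, showWarnings = FALSE, recursive = TRUE)
  stats::setNames(as.list(dirs), c("images", "masks", "features", "model", "stats", "figures"))
}

log_line <- function(out_dir, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE, sep = "")
  message(msg)
}

read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "image_path", "group", "dose_ug", "exposure_h", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_param("design CSV missing columns: %s", paste(miss, collapse = ", "))
  ## image paths are relative to the design file unless absolute
  base <- dirname(path)
  rel <- !file.exists(d$image_path)
  d$image_path[rel] <- file.path(base, d$image_path[rel])
  d
}

stage_simulate <- function(cfg, dirs) {
  syn <- cfg$synthetic
  design <- syn$design %||% default_condition_design(syn$n_images %||% 2L)
  spec_args <- syn[intersect(names(syn), names(formals(synthetic_spec)))]
  base_spec <- do.call(synthetic_spec, spec_args)
  gen <- generate_condition_series(design, base_spec,
                                   seed = stage_seed(cfg$seed, "simulate"),
                                   out_dir = dirs$images)
  gen$design
}

stage_segment <- function(cfg, dirs, design) {
  seg_args <- cfg$segmentation[intersect(names(cfg$segmentation),
                                         names(formals(segmentation_config)))]
  seg_cfg <- do.call(segmentation_config, seg_args)
  for (i in seq_len(nrow(design))) {
    img <- read_fluor_tiff(design$image_path[i], seg_cfg$pixel_size_um,
                           id = design$image_id[i])
    mask <- segment_image(img, seg_cfg)
    write_tiff(mask$labels, file.path(dirs$masks, paste0(design$image_id[i], "_mask.tiff")),
               labels = TRUE)
  }
  seg_cfg
}

stage_features <- function(cfg, dirs, design, seg_cfg) {
  all_cells <- list(); qc <- list()
  for (i in seq_len(nrow(design))) {
    id <- design$image_id[i]
    mask <- labeled_mask(read_label_tiff(file.path(dirs$masks, paste0(id, "_mask.tiff"))),
                         seg_cfg$connectivity)
    cells <- extract_cells_quadrants(mask, seg_cfg$pixel_size_um, image_id = id)
    qc[[id]] <- attr(cells, "qc")
    all_cells[[id]] <- cells
  }
  cells <- do.call(rbind, all_cells)
  rownames(cells) <- NULL
  utils::write.csv(cells, file.path(dirs$features, "cells.csv"), row.names = FALSE)
  qc_df <- do.call(rbind, lapply(names(qc), function(id)
    data.frame(image_id = id, measured = qc[[id]]$measured,
               edge_removed = qc[[id]]$edge_removed, degenerate = qc[[id]]$degenerate)))
  utils::write.csv(qc_df, file.path(dirs$features, "qc.csv"), row.names = FALSE)
  cells
}

stage_shapemodes <- function(cfg, dirs, design, seg_cfg) {
  cells <- utils::read.csv(file.path(dirs$features, "cells.csv"), stringsAsFactors = FALSE)
  use <- which(!cells$degenerate)
  contours <- vector("list", length(use))
  areas <- numeric(length(use))
  for (i in seq_len(nrow(design))) {
    id <- design$image_id[i]
    mask <- labeled_mask(read_label_tiff(file.path(dirs$masks, paste0(id, "_mask.tiff"))),
                         seg_cfg$connectivity)
    tiles <- split_quadrants(mask)
    sel <- which(cells$image_id[use] == id)
    for (j in sel) {
      rec <- cells[use[j], ]
      cm <- cell_masks(tiles[[rec$quadrant]], rec$label)[[1L]]
      contours[[j]] <- extract_contour(cm)
      areas[j] <- rec$area_px
    }
  }
  sm <- cfg$shape_modes
  model <- shape_mode_model(contours, k = sm$k %||% 5L,
                            n_points = sm$n_points %||% 50L,
                            train_fraction = sm$train_fraction %||% 0.8,
                            seed = stage_seed(cfg$seed, "shapemodes"),
                            image_id = cells$image_id[use], cell_area = areas)
  write_shape_mode_model(model, file.path(dirs$model, "shape_mode_model.json"))
  cells$shape_mode <- NA_integer_
  cells$split <- NA_character_
  cells$shape_mode[use] <- model$assignments$shape_mode
  cells$split[use] <- model$assignments$split
  utils::write.csv(cells, file.path(dirs$features, "cells.csv"), row.names = FALSE)
  ## per-image shape-mode overlays
  for (i in seq_len(nrow(design))) {
    id <- design$image_id[i]
    mask <- labeled_mask(read_label_tiff(file.path(dirs$masks, paste0(id, "_mask.tiff"))),
                         seg_cfg$connectivity)
    img_cells <- cells[cells$image_id == id & !is.na(cells$shape_mode), ]
    if (nrow(img_cells)) {
      ## overlay on the whole-image mask: label collisions across quadrants are
      ## resolved by the first assignment
      asg <- img_cells[!duplicated(img_cells$label), c("label", "shape_mode")]
      ov <- render_mode_overlay(mask, asg, shape_mode_colors(model$k))
      png::writePNG(ov, file.path(dirs$figures, paste0(id, "_modes.png")))
    }
  }
  model
}

stage_stats <- function(cfg, dirs, design) {
  cells <- utils::read.csv(file.path(dirs$features, "cells.csv"), stringsAsFactors = FALSE)
  st <- cfg$stats
  control <- st$control %||% "healthy"
  alpha <- st$alpha %||% 0.05
  adjustment <- st$adjustment %||% "bonferroni"
  statistic <- st$statistic %||% "median"
  assigned <- cells[!is.na(cells$shape_mode), ]
  freq <- sm_frequencies(assigned, design, k = max(assigned$shape_mode))
  utils::write.csv(freq, file.path(dirs$stats, "sm_frequencies.csv"), row.names = FALSE)
  fm <- as.matrix(freq[, grep("^SM", names(freq)), drop = FALSE])
  rownames(fm) <- sprintf("%s %gh", freq$group, freq$exposure_h)
  heatmap_export(fm, png_path = file.path(dirs$figures, "sm_frequencies.png"),
                 style = "frequency")
  features <- c("perimeter_px", "area_px", "circularity", "aspect_ratio")
  fc_all <- do.call(rbind, lapply(features, function(f)
    feature_fold_change(cells, design, f, control = control, statistic = statistic)))
  utils::write.csv(fc_all, file.path(dirs$stats, "fold_change.csv"), row.names = FALSE)
  fcm <- do.call(rbind, lapply(features, function(f) {
    sub <- fc_all[fc_all$feature == f & fc_all$group != control, ]
    stats::setNames(sub$fold_change, sprintf("%s %gh", sub$group, sub$exposure_h))
  }))
  rownames(fcm) <- features
  heatmap_export(fcm, png_path = file.path(dirs$figures, "fold_change.png"),
                 csv_path = NULL, style = "fold_change")
  ## Kruskal-Wallis + Dunn across groups, per feature and exposure time
  merged <- merge(cells, design[, c("image_id", "group", "exposure_h")], by = "image_id")
  tests <- list()
  for (f in features) for (t in sort(unique(merged$exposure_h))) {
    sub <- merged[merged$exposure_h == t & is.finite(merged[[f]]), ]
    if (length(unique(sub$group)) < 2L) next
    res <- compare_groups(sub[[f]], sub$group, alpha = alpha, adjustment = adjustment)
    for (r in seq_len(nrow(res$dunn)))
      tests[[length(tests) + 1L]] <- data.frame(
        feature = f, exposure_h = t, H = res$kruskal$H, kw_p = res$kruskal$p,
        group1 = res$dunn$group1[r], group2 = res$dunn$group2[r],
        z = res$dunn$z[r], p_adj = res$dunn$p_adj[r],
        significant = res$dunn$p_adj[r] < alpha)
  }
  stats_df <- do.call(rbind, tests)
  utils::write.csv(stats_df, file.path(dirs$stats, "group_tests.csv"), row.names = FALSE)
  writeLines(c(sprintf("Group comparisons (Kruskal-Wallis + Dunn %s, alpha = %g)",
                       adjustment, alpha),
               utils::capture.output(print(stats_df))),
             file.path(dirs$stats, "group_tests.txt"))
  list(frequencies = freq, fold_change = fc_all, tests = stats_df)
}

#' Run the morphology pipeline end to end
#'
#' Stages, in order: `simulate` (synthetic mode only) -> `segment` ->
#' `features` -> `shapemodes` -> `stats`. Each stage reads the previous
#' stage's on-disk outputs and is seeded by a child seed derived from the
#' global seed, so any suffix of stages rerun standalone reproduces the
#' composed run. A manifest of every artifact with its MD5 content hash is
#' written to `manifest.json`.
#'
#' @param config A `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param stages Character vector of stages to run (default: all applicable).
#' @return Invisibly, the manifest list (`artifacts` data frame and `config`).
#' @export
run_pipeline <- function(config, stages = c("simulate", "segment", "features",
                                            "shapemodes", "stats")) {
  if (!inherits(config, "pipeline_config")) {
    config <- validate_config(config)
    if (inherits(config, "config_errors"))
      stop_param("invalid pipeline config:\n- %s", paste(config, collapse = "\n- "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  dirs <- pipeline_dirs(config$out_dir)
  run_stage <- function(name, fun) {
    log_line(config$out_dir, "stage %s: start", name)
    tryCatch(fun(), error = function(e) {
      write_manifest(config, partial = name)
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log_line(config$out_dir, "run start (mode=%s, seed=%d, micromorph %s)",
           config$mode, config$seed,
           as.character(utils::packageVersion("micromorph")))
  design_path <- file.path(dirs$images, "design.csv")
  if (config$mode == "synthetic" && "simulate" %in% stages) {
    design <- run_stage("simulate", function() stage_simulate(config, dirs))
    rel <- !file.exists(design$image_path)
    design$image_path[rel] <- file.path(dirs$images, design$image_path[rel])
  } else {
    src <- if (config$mode == "synthetic") design_path else config$design_csv
    design <- read_design(src)
    if (config$mode == "image_dir") {
      if (!is.null(config$image_dir)) {
        abs <- file.path(config$image_dir, design$image_path)
        design$image_path <- ifelse(file.exists(design$image_path),
                                    design$image_path, abs)
      }
      missing_files <- design$image_path[!file.exists(design$image_path)]
      if (length(missing_files))
        stop_param("design references missing images: %s",
                   paste(missing_files, collapse = ", "))
      utils::write.csv(design, design_path, row.names = FALSE)
    }
  }
  seg_args <- config$segmentation[intersect(names(config$segmentation),
                                            names(formals(segmentation_config)))]
  seg_cfg <- do.call(segmentation_config, seg_args)
  if ("segment" %in% stages)
    run_stage("segment", function() stage_segment(config, dirs, design))
  if ("features" %in% stages)
    run_stage("features", function() stage_features(config, dirs, design, seg_cfg))
  if ("shapemodes" %in% stages)
    run_stage("shapemodes", function() stage_shapemodes(config, dirs, design, seg_cfg))
  if ("stats" %in% stages)
    run_stage("stats", function() stage_stats(config, dirs, design))
  manifest <- write_manifest(config)
  log_line(config$out_dir, "run complete: %d artifacts", nrow(manifest$artifacts))
  invisible(manifest)
}

artifact_class <- function(path) {
  d <- basename(dirname(path))
  ext <- tools::file_ext(path)
  if (grepl("_truth", path)) "ground_truth"
  else if (d == "images") "image"
  else if (d == "masks") "mask"
  else if (d == "model") "model"
  else if (d == "figures") "figure"
  else if (d == "features") "features"
  else if (d == "stats") "stats"
  else ext
}

write_manifest <- function(config, partial = NULL) {
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% c("manifest.json", "run.log")]
  art <- data.frame(path = sub(paste0("^", config$out_dir, "/?"), "", files),
                    class = vapply(files, artifact_class, character(1)),
                    md5 = unname(tools::md5sum(files)))
  rownames(art) <- NULL
  manifest <- list(artifacts = art,
                   config = unclass(config),
                   partial_after_stage = partial,
                   r_version = R.version.string,
                   package_version = as.character(utils::packageVersion("micromorph")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(manifest)
}
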
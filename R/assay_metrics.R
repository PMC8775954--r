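## Scalar assay formulas: PI cytotoxicity, extracellular-vesicle purity,
## dot-blot signal-density ratios, and median-normalized delta-delta-Cq qPCR
## fold change. All pure, unit-consistent functions over CSV-friendly tables.

#' Percent cytotoxicity from a propidium iodide count
#'
#' `100 * pi_positive / total_cells`: the fraction of dead or dying
#' (PI-positive) cells among all counted cells in an image.
#'
#' @param pi_positive Number of PI-positive cells (>= 0).
#' @param total_cells Total cell count (> 0).
#' @return Percent in `[0, 100]` (vectorized).
#' @export
cytotoxicity_percent <- function(pi_positive, total_cells) {
  if (any(total_cells <= 0)) stop_param("`total_cells` must be positive")
  if (any(pi_positive < 0)) stop_param("`pi_positive` must be nonnegative")
  if (any(pi_positive > total_cells))
    stop_param("`pi_positive` cannot exceed `total_cells`")
  100 * pi_positive / total_cells
}

#' Extracellular-vesicle preparation purity
#'
#' Particles per microgram of protein: particle concentration from
#' nanoparticle tracking analysis divided by protein concentration from a BCA
#' assay. Scale-invariant in the common dilution factor.
#'
#' @param particles_per_ml NTA particle concentration (particles/mL, > 0).
#' @param protein_ug_per_ml BCA protein concentration (ug/mL, > 0).
#' @return Particles per ug protein (vectorized).
#' @export
ev_purity <- function(particles_per_ml, protein_ug_per_ml) {
  if (any(protein_ug_per_ml <= 0)) stop_param("`protein_ug_per_ml` must be positive")
  if (any(particles_per_ml <= 0)) stop_param("`particles_per_ml` must be positive")
  particles_per_ml / protein_ug_per_ml
}

#' Dot-blot signal-density ratio
#'
#' `100 * bev_density / tissue_density`: percent abundance of a marker in the
#' vesicle lysate relative to the whole-tissue lysate, both already
#' background (PBS)-normalized integral signal densities.
#'
#' @param bev_density Vesicle-lysate signal density (>= 0).
#' @param tissue_density Tissue-lysate signal density (> 0).
#' @return Percent (vectorized).
#' @export
signal_density_ratio <- function(bev_density, tissue_density) {
  if (any(tissue_density <= 0)) stop_param("`tissue_density` must be positive")
  if (any(bev_density < 0)) stop_param("`bev_density` must be nonnegative")
  100 * bev_density / tissue_density
}

#' qPCR fold change by median-normalized delta-delta-Cq
#'
#' Per sample: (optionally) center all Cq values by the all-sample median Cq
#' per gene batch; compute `dCq = Cq(gene) - Cq(housekeeping)`; compare to the
#' control group, `ddCq = dCq - median dCq(control)`; fold change is
#' `2^(-ddCq)`. Uniform median centering cancels in ddCq and is therefore
#' toggleable; it is retained as an option because centering stabilizes
#' inspection of intermediate dCq values.
#'
#' @param cq Data frame with columns `sample`, `group`, `gene`, `cq`.
#' @param housekeeping Housekeeping gene name (must be present for every
#'   sample).
#' @param control Control group label (default `"healthy"`).
#' @param median_center Apply the all-sample median-Cq centering step.
#' @param ci Logical; attach a bootstrap 95% confidence interval to the
#'   per-group median fold change.
#' @param boot Bootstrap resamples (default 10000).
#' @param seed Seed for the bootstrap.
#' @return List with `per_sample` (data frame: `sample`, `group`, `gene`,
#'   `dcq`, `ddcq`, `fold_change`) and `per_group` (data frame: `gene`,
#'   `group`, `median_fold_change`, optional `ci_lo`/`ci_hi`). The control
#'   group's own median fold change is exactly 1.
#' @export
qpcr_fold_change <- function(cq, housekeeping = "GAPDH", control = "healthy",
                             median_center = TRUE, ci = FALSE, boot = 10000L,
                             seed = 1L) {
  need <- c("sample", "group", "gene", "cq")
  if (!all(need %in% names(cq)))
    stop_param("`cq` must have columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(cq$cq))) stop_param("Cq values must be finite")
  samples <- unique(cq$sample)
  hk <- cq[cq$gene == housekeeping, ]
  miss_hk <- setdiff(samples, hk$sample)
  if (length(miss_hk))
    stop_param("samples missing housekeeping gene `%s`: %s", housekeeping,
               paste(miss_hk, collapse = ", "))
  if (!control %in% cq$group)
    stop_param("control group `%s` absent from the table", control)
  d <- cq
  if (median_center) {
    med <- stats::median(d$cq)
    d$cq <- d$cq - med
  }
  hk_cq <- stats::setNames(hk$cq - if (median_center) stats::median(cq$cq) else 0,
                           hk$sample)
  d <- d[d$gene != housekeeping, , drop = FALSE]
  genes <- unique(d$gene)
  miss_ctrl <- genes[!vapply(genes, function(g)
    any(d$group == control & d$gene == g), logical(1))]
  if (length(miss_ctrl))
    stop_param("genes without control-group entries: %s",
               paste(miss_ctrl, collapse = ", "))
  d$dcq <- d$cq - hk_cq[d$sample]
  d$ddcq <- NA_real_
  for (g in genes) {
    ctrl_med <- stats::median(d$dcq[d$gene == g & d$group == control])
    sel <- d$gene == g
    d$ddcq[sel] <- d$dcq[sel] - ctrl_med
  }
  d$fold_change <- 2^(-d$ddcq)
  ## group summary on the ddCq scale (2^(-median ddCq)), so the control
  ## group's own median fold change is exactly 1 for any group size
  per_group <- do.call(rbind, lapply(genes, function(g) {
    do.call(rbind, lapply(unique(d$group[d$gene == g]), function(gr) {
      dd <- d$ddcq[d$gene == g & d$group == gr]
      row <- data.frame(gene = g, group = gr,
                        median_fold_change = 2^(-stats::median(dd)))
      if (ci) {
        bs <- with_seed(stage_seed(seed, paste(g, gr)), {
          vapply(seq_len(boot), function(i)
            2^(-stats::median(sample(dd, length(dd), replace = TRUE))), numeric(1))
        })
        qs <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
        row$ci_lo <- qs[1]; row$ci_hi <- qs[2]
      }
      row
    }))
  }))
  rownames(per_group) <- NULL
  list(per_sample = d[, c("sample", "group", "gene", "dcq", "ddcq", "fold_change")],
       per_group = per_group)
}
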
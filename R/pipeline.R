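#' PCA quality-control of a feature table
#'
#' Singular-value decomposition of the column-centered matrix; returns
#' the scores of the first two principal components and the explained
#' variance of every component (percent, summing to 100).
#'
#' @param table a [feature_table()] with at least 3 samples.
#' @return list with `scores` (n x 2), `explained_variance` (percent per
#'   component) and `classes`.
#' @export
run_pca <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  if (nrow(table$values) < 3)
    stop("PCA needs at least 3 samples", call. = FALSE)
  pc <- stats::prcomp(table$values, center = TRUE, scale. = FALSE)
  ev <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  if (sum(pc$sdev > 1e-10) < 2)
    stop("rank < 2: no second principal component", call. = FALSE)
  list(scores = pc$x[, 1:2, drop = FALSE],
       explained_variance = ev, classes = table$classes)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis.  Per-block
#' surrogate fractions default to 5% for LC-MS and 20% for NIR (spectral
#' variables are more collinear, so more surrogates are informative);
#' the fused block uses the NIR fraction for its NIR part implicitly by
#' re-deriving s from the fused width at the LC-MS fraction.
#'
#' @param ntree trees per forest (default 1000 for desk-scale runs; the
#'   full-scale setting is 10,000).
#' @param mtry `NULL` for the 3/4-power default at each block's width.
#' @param min_node_size minimal node size (default 1).
#' @param s_fraction_lcms,s_fraction_nir,s_fraction_photometry,s_fraction_fused
#'   per-block surrogate fractions.
#' @param filter_fraction group-presence fraction for LC-MS.
#' @param sg_window,sg_polyorder,bin_width NIR preprocessing settings.
#' @param n_perm,smd_quantile permutation-null threshold settings
#'   (see [smd_threshold()]).
#' @param clusters number of relation clusters (default 3).
#' @param seed master seed; all stage seeds derive from it via
#'   [child_seed()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(ntree = 1000, mtry = NULL, min_node_size = 1,
                            s_fraction_lcms = 0.05, s_fraction_nir = 0.20,
                            s_fraction_photometry = 0.05,
                            s_fraction_fused = 0.05,
                            filter_fraction = 0.5, sg_window = 11,
                            sg_polyorder = 2, bin_width = 5,
                            n_perm = 3, smd_quantile = 0.01,
                            clusters = 3, seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

block_stage <- c(lcms = 10L, nir = 20L, photometry = 30L, fused = 40L)

fit_block <- function(table, cfg, block, s_fraction) {
  params <- forest_params(ntree = cfg$ntree, mtry = cfg$mtry,
                          min_node_size = cfg$min_node_size,
                          s_fraction = s_fraction,
                          seed = child_seed(cfg$seed, block_stage[[block]]))
  forest <- fit_forest(table, params)
  confusion <- oob_confusion(forest, table)
  threshold <- smd_threshold(table, params, n_perm = cfg$n_perm,
                             quantile = cfg$smd_quantile)
  smd <- select_variables(forest, threshold)
  list(forest = forest, confusion = confusion, smd = smd,
       threshold = as.numeric(threshold))
}

#' Run the full multimodal analysis pipeline
#'
#' Executes, per block: preprocessing, PCA quality control, a
#' class-weighted surrogate random forest with OOB confusion, shadow-
#' thresholded SMD variable selection — then fuses the preprocessed
#' LC-MS and NIR blocks (low-level fusion), refits on the fused table
#' and runs the mean-adjusted-agreement relation analysis with Ward
#' clustering and cross-modal reporting on the fused SMD-selected
#' variables.  Every stochastic stage consumes its own child seed
#' derived from the master seed, so the whole report is reproducible
#' from the configuration alone.
#'
#' @param dataset a `synthetic_dataset` (from [generate_dataset()] or
#'   [read_dataset()]); any list with elements `lcms`, `nir`,
#'   `photometry` of the documented types works.
#' @param config a [pipeline_config()].
#' @return a `run_report` list: per-block `pca`, `confusion`, `smd`,
#'   `threshold`; fused `relation`, `clusters`, `cross_modal`; and the
#'   resolved `config`.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config

  lcms <- preprocess_lcms(dataset$lcms, min_fraction = cfg$filter_fraction)
  nir <- preprocess_nir(dataset$nir, sg_window = cfg$sg_window,
                        sg_polyorder = cfg$sg_polyorder,
                        bin_width = cfg$bin_width)
  phot <- preprocess_photometry(dataset$photometry)

  blocks <- list(lcms = lcms, nir = nir, photometry = phot)
  sfrac <- c(lcms = cfg$s_fraction_lcms, nir = cfg$s_fraction_nir,
             photometry = cfg$s_fraction_photometry)
  report <- list(config = cfg, blocks = list())
  for (b in names(blocks)) {
    res <- fit_block(blocks[[b]], cfg, b, sfrac[[b]])
    res$pca <- run_pca(blocks[[b]])
    report$blocks[[b]] <- res
  }

  fused <- low_level_fuse(list(lcms, nir))
  fres <- fit_block(fused, cfg, "fused", cfg$s_fraction_fused)
  fres$pca <- run_pca(fused)
  sel <- attr(fres$smd, "selected_ids")
  if (length(sel) >= max(2L, cfg$clusters)) {
    relation <- mean_adjusted_agreement(fres$forest, sel)
    clusters <- cluster_relation_matrix(relation, k = cfg$clusters)
    fres$relation <- relation
    fres$clusters <- clusters
    fres$cross_modal <- cross_modal_report(clusters)
  } else {
    warning("too few fused SMD-selected variables for relation analysis",
            call. = FALSE)
  }
  report$blocks$fused <- fres
  report$tables <- list(lcms = lcms, nir = nir, photometry = phot,
                        fused = fused)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (b in names(x$blocks)) {
    blk <- x$blocks[[b]]
    cat(sprintf(
      "  %-10s OOB accuracy %5.1f%%  |  %d variables selected (SMD < %.3g)\n",
      b, blk$confusion$accuracy, sum(blk$smd$selected), blk$threshold))
  }
  fused <- x$blocks$fused
  if (!is.null(fused$cross_modal)) {
    mixed <- fused$cross_modal$type == "mixed-block"
    cat(sprintf("  relation clusters: %d (%d mixed-block)\n",
                nrow(fused$cross_modal), sum(mixed)))
  }
  invisible(x)
}

#' Write the numeric summary of a pipeline run to JSON
#'
#' Serializes per-block OOB confusion summaries, selection counts and
#' thresholds, cluster composition and the configuration, so a run can
#' be archived and compared.
#'
#' @param report a `run_report`.
#' @param path JSON file path.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- list(config = unclass(report$config), blocks = list())
  out$config$mtry <- if (is.null(report$config$mtry)) "auto" else
    report$config$mtry
  for (b in names(report$blocks)) {
    blk <- report$blocks[[b]]
    out$blocks[[b]] <- list(
      accuracy = blk$confusion$accuracy,
      sensitivity = as.list(blk$confusion$sensitivity),
      precision = as.list(blk$confusion$precision),
      n_selected = sum(blk$smd$selected),
      threshold = blk$threshold,
      mtry = blk$forest$params$mtry, s = blk$forest$params$s,
      pca_explained_12 = blk$pca$explained_variance[1:2])
    if (!is.null(blk$cross_modal))
      out$blocks[[b]]$clusters <- lapply(seq_len(nrow(blk$cross_modal)),
        function(i) {
          r <- blk$cross_modal[i, ]
          list(cluster = r$cluster, size = r$size, type = r$type)
        })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
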
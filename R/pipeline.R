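#' Run the full vessel-distance-analysis pipeline
#'
#' End-to-end orchestration on a generated phantom (or, via `channels` and
#' `necrosis_mask`, on user-supplied images): segmentation of nuclei, cells
#' and vessels; rule-based ROI map; distance layers; the per-cell feature
#' table restricted to viable / hypoxia / perfusion regions; MAD and CC
#' positivity with their comparison; distance-binned marker statistics
#' against perfusion, all vessels, and necrosis; ring composition with the
#' hypoxia peak; and the scatterplot gating with permutation tests. All
#' randomness derives from `seed`, so a repeated run writes byte-identical
#' tables.
#'
#' @param config configuration list (see [default_config()]).
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV/JSON alongside the phantom images.
#' @param channels optional [channel_stack()] to analyze instead of a
#'   generated phantom.
#' @param necrosis_mask optional necrosis mask for user-supplied images.
#' @return list with every intermediate and final product (phantom truth,
#'   label maps, roi, distance set, cell table, mad/cc, bins, rings,
#'   gates, summary).
#' @export
run_pipeline <- function(config = default_config(), seed = 1, out_dir = NULL,
                         channels = NULL, necrosis_mask = NULL) {
  config <- merge_config(default_config(), config)
  truth <- NULL
  if (is.null(channels)) {
    ph <- make_phantom(config, seed)
    channels <- ph$channels
    truth <- ph$truth
    necrosis_mask <- truth$necrosis_mask
  }
  grid <- channels$grid
  segp <- do.call(segmentation_params, config$segmentation)

  nuclei <- detect_nuclei(channels$channels$DAPI, grid, segp)
  cells <- simulate_cells(nuclei, segp$cell_dilation_um)
  vessels <- detect_vessels(channels$channels$CD31, grid, segp)

  roi <- classify_rois(channels, config$roi, necrosis_mask = necrosis_mask,
                       min_region_um2 = config$roi$min_region_um2,
                       smoothing_sigma_um = config$roi$smoothing_sigma_um)
  perfused <- flag_perfused(vessels, roi_class_mask(roi, "perfusion"))
  dset <- build_distance_set(roi, vessels, perfused)

  cell_table <- build_cell_table(cells, nuclei, channels, dset, roi)
  analyzed <- cell_table[cell_table$roi_class %in%
                           c("viable", "hypoxia", "perfusion"), , drop = FALSE]

  ts <- threshold_set(config$classify$t1, config$classify$t2,
                      config$classify$t3)
  analysis_mask <- roi_tissue_mask(roi) & !roi_class_mask(roi, "necrosis")
  mad <- mad_classify(channels$channels$EF5, analysis_mask, ts,
                      config$classify$min_region_um2, grid)
  cc <- cc_classify(cells, channels$channels$EF5, ts)
  comparison <- compare_mad_cc(mad, cc)

  vd <- config$vda
  bins <- list()
  for (fld in c("perfused", "all_vessels", "necrosis")) {
    bins[[fld]] <- tryCatch(
      bin_cells(analyzed, fld, markers = c("EF5", "EdU"),
                bin_width_um = vd$bin_width_um, d_max_um = vd$d_max_um,
                gate_scale = vd$gate_scale),
      error = function(e) NULL)
  }
  rings <- if (!is.null(dset$to_perfused))
    ring_composition(roi, dset$to_perfused, vd$bin_width_um, vd$d_max_um)
  else NULL
  gates <- gate_populations(analyzed, c("EF5", "EdU"),
                            scale = vd$gate_scale, n_perm = vd$n_perm,
                            seed = derive_seeds(seed, 4)[4])

  summary <- list(
    seed = seed,
    n_nuclei = n_labels(nuclei),
    n_vessels = n_labels(vessels),
    n_perfused_vessels = sum(perfused),
    n_cells_analyzed = nrow(analyzed),
    mad_positive_fraction = unname(sum(mad$fractions[2:4])),
    cc_positive_fraction = unname(cc$percent_positive),
    hypoxia_peak_um = if (!is.null(rings))
      tryCatch(peak_distance(rings, "hypoxia"), error = function(e) NA_real_)
    else NA_real_)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(truth))
      write_phantom_outputs(list(channels = channels, truth = truth),
                            out_dir, config)
    write.csv(analyzed, file.path(out_dir, "cells.csv"), row.names = FALSE)
    for (fld in names(bins)) {
      if (!is.null(bins[[fld]]))
        write.csv(bins[[fld]], file.path(out_dir,
                                         paste0("bins_", fld, ".csv")),
                  row.names = FALSE)
    }
    if (!is.null(rings))
      write.csv(rings, file.path(out_dir, "rings.csv"), row.names = FALSE)
    write.csv(comparison, file.path(out_dir, "mad_cc_comparison.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(gates = as.list(gates$gates), scale = gates$scale,
           pop_stats = gates$pop_stats, tests = gates$tests,
           n_perm = gates$n_perm, seed = gates$seed),
      file.path(out_dir, "gates.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(config = config, truth = truth, channels = channels,
                 nuclei = nuclei, cells = cells, vessels = vessels,
                 perfused = perfused, roi = roi, dset = dset,
                 cell_table = cell_table, analyzed = analyzed, mad = mad,
                 cc = cc, comparison = comparison, bins = bins,
                 rings = rings, gates = gates, summary = summary))
}
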
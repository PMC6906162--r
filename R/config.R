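#' Default pipeline configuration
#'
#' One nested list drives the whole pipeline: phantom geometry and physics,
#' segmentation parameters, ROI thresholds, MAD/CC intensity thresholds, and
#' the distance-analysis settings. Values are chosen to emulate a xenograft
#' section imaged at 1 um/px: vessel-wall pO2 40 mmHg, consumption tuned so
#' anoxia sets in ~150 um from a perfused vessel, nucleus and vessel area
#' filters of 23 and 5 um^2, 10 um distance bins to 700 um.
#'
#' @return a nested configuration list.
#' @export
default_config <- function() {
  list(
    pixel_size_um = 1.0,
    grid = list(width_px = 1024L, height_px = 1024L),
    vessels = list(n_vessels = 14L, min_spacing_um = 150, perfused_fraction = 0.5,
                   radius_range_um = c(8, 15)),
    oxygen = list(D = 2000, M = 2.75, k_m = 1, p_v = 40, p_nec = 0.5,
                  tol = 1e-4, max_iter = 50000L, omega = 1.85),
    marker = list(ef5_amp = 120, K_h = 10, h = 2, edu_max = 0.6, K_p = 5,
                  hoechst_decay_um = 15, background = 5, noise_sd = 2),
    cells = list(density_per_mm2 = 4000, min_spacing_um = 8),
    segmentation = list(dapi_threshold = "otsu", min_nucleus_area_um2 = 23,
                        cell_dilation_um = 5, cd31_threshold = "otsu",
                        min_vessel_area_um2 = 5, smoothing_sigma_um = 1),
    roi = list(t_tissue = 10, t_hoechst = 60, t_ef5 = 30,
               min_region_um2 = 10, smoothing_sigma_um = 5),
    classify = list(t1 = 20, t2 = 50, t3 = 90, min_region_um2 = 10),
    vda = list(bin_width_um = 10, d_max_um = 700, gate_scale = "log",
               n_perm = 1000L, n_tiles = 10L, tile_um = 350)
  )
}

# recursively overlay user values onto defaults
merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON document, overlays it on [default_config()], and
#' validates every parameter block (each block's constructor enforces its
#' own invariants). Unknown top-level fields are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` configuration file, or
#'   `NULL` for pure defaults.
#' @param overrides optional named list applied after the file.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg <- merge_config(cfg, user)
  }
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides), names(cfg))
    if (length(bad))
      stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg <- merge_config(cfg, overrides)
  }
  validate_config(cfg)
  cfg
}

#' Validate a configuration list
#'
#' @param cfg configuration list as from [default_config()].
#' @return the configuration, invisibly; errors name the offending field.
#' @export
validate_config <- function(cfg) {
  if (!is.numeric(cfg$pixel_size_um) || cfg$pixel_size_um <= 0)
    stop("config: pixel_size_um must be > 0")
  pixel_grid(cfg$grid$width_px, cfg$grid$height_px, cfg$pixel_size_um)
  do.call(oxygen_params, cfg$oxygen)
  do.call(marker_params, cfg$marker)
  v <- cfg$vessels
  if (v$n_vessels < 0) stop("config: vessels$n_vessels must be >= 0")
  if (v$min_spacing_um < 0) stop("config: vessels$min_spacing_um must be >= 0")
  if (v$perfused_fraction < 0 || v$perfused_fraction > 1)
    stop("config: vessels$perfused_fraction must be in [0, 1]")
  if (cfg$cells$density_per_mm2 < 0)
    stop("config: cells$density_per_mm2 must be >= 0")
  do.call(segmentation_params, cfg$segmentation)
  threshold_set(cfg$classify$t1, cfg$classify$t2, cfg$classify$t3)
  r <- cfg$roi
  for (nm in c("t_tissue", "t_hoechst", "t_ef5")) {
    if (!is.numeric(r[[nm]]) || r[[nm]] < 0)
      stop(sprintf("config: roi$%s must be a non-negative number", nm))
  }
  if (cfg$vda$bin_width_um <= 0 || cfg$vda$d_max_um <= 0)
    stop("config: vda$bin_width_um and vda$d_max_um must be > 0")
  invisible(cfg)
}
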
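ROI_LEVELS <- c("background", "viable", "hypoxia", "necrosis", "perfusion",
                "artifact")

#' Categorical region-of-interest map
#'
#' @param grid a [pixel_grid()].
#' @param classes integer matrix of class codes (0 = background, then
#'   viable, hypoxia, necrosis, perfusion, artifact).
#' @return an object of class `roi_map`.
#' @export
roi_map <- function(grid, classes) {
  stopifnot(inherits(grid, "pixel_grid"))
  check_grid_image(classes, grid, "classes")
  storage.mode(classes) <- "integer"
  if (any(classes < 0L | classes > 5L)) stop("roi class codes must be 0..5")
  structure(list(grid = grid, classes = classes, levels = ROI_LEVELS),
            class = "roi_map")
}

#' @export
print.roi_map <- function(x, ...) {
  tab <- roi_class_counts(x)
  cat("<roi_map>", paste(sprintf("%s: %.1f%%", names(tab),
                                 100 * tab / sum(tab)), collapse = ", "), "\n")
  invisible(x)
}

# mask of one named class
roi_class_mask <- function(roi, class) {
  code <- match(class, ROI_LEVELS) - 1L
  if (is.na(code)) stop("unknown roi class: ", class)
  roi$classes == code
}

# pixel counts per class, named
roi_class_counts <- function(roi) {
  setNames(tabulate(roi$classes + 1L, nbins = 6L), ROI_LEVELS)
}

# tissue = any non-background, non-artifact pixel
roi_tissue_mask <- function(roi) roi$classes >= 1L & roi$classes <= 4L

#' Rule-based ROI classification
#'
#' Partitions the grid into background / viable / hypoxia / necrosis /
#' perfusion / artifact with explicit threshold rules: tissue is smoothed
#' DAPI above `t_tissue`, perfusion is Hoechst above `t_hoechst`, hypoxia is
#' smoothed EF5 above `t_ef5`; necrosis and artifact come from supplied
#' masks (phantom truth or user annotation) and are passed through
#' unchanged. Precedence: artifact > necrosis > perfusion > hypoxia >
#' viable. Threshold-derived regions (viable, hypoxia, perfusion) smaller
#' than `min_region_um2` are merged into their surrounding class; the
#' mask-derived classes are never altered.
#'
#' @param channels a [channel_stack()] with DAPI, Hoechst and EF5 present.
#' @param thresholds list with `t_tissue`, `t_hoechst`, `t_ef5` (intensity
#'   units of the respective channel).
#' @param necrosis_mask optional logical matrix; omitted means no necrosis.
#' @param artifact_mask optional logical matrix; omitted means no artifact.
#' @param min_region_um2 merge threshold-derived regions below this area.
#' @param smoothing_sigma_um Gaussian smoothing for DAPI/EF5 before
#'   thresholding, um.
#' @return a [roi_map()].
#' @export
classify_rois <- function(channels, thresholds, necrosis_mask = NULL,
                          artifact_mask = NULL, min_region_um2 = 10,
                          smoothing_sigma_um = 5) {
  stopifnot(inherits(channels, "channel_stack"))
  grid <- channels$grid
  for (nm in c("DAPI", "Hoechst", "EF5")) {
    if (is.null(channels$channels[[nm]]))
      stop("classify_rois: required channel missing: ", nm)
  }
  smooth <- function(img) {
    if (smoothing_sigma_um <= 0) return(img)
    as.matrix(EBImage::gblur(img, sigma = smoothing_sigma_um /
                                            grid$pixel_size_um))
  }
  tissue <- smooth(channels$channels$DAPI) > thresholds$t_tissue
  perfusion <- channels$channels$Hoechst > thresholds$t_hoechst
  hypoxia <- smooth(channels$channels$EF5) > thresholds$t_ef5

  cls <- matrix(0L, grid$height_px, grid$width_px)
  cls[tissue] <- 1L                      # viable
  cls[tissue & hypoxia] <- 2L            # hypoxia
  cls[tissue & perfusion] <- 4L          # perfusion
  if (!is.null(necrosis_mask)) {
    necrosis_mask <- as_mask(necrosis_mask)
    check_grid_image(necrosis_mask, grid, "necrosis_mask")
    cls[necrosis_mask] <- 3L
  }
  if (!is.null(artifact_mask)) {
    artifact_mask <- as_mask(artifact_mask)
    check_grid_image(artifact_mask, grid, "artifact_mask")
    cls[artifact_mask] <- 5L
  }

  if (min_region_um2 > 0) {
    cls <- merge_small_regions(cls, grid, min_region_um2,
                               mergeable = c(1L, 2L, 4L))
  }
  roi_map(grid, cls)
}

# reassign small 4-connected components of the mergeable classes to the
# most frequent class among their border neighbors
merge_small_regions <- function(cls, grid, min_region_um2, mergeable) {
  psz2 <- grid$pixel_size_um^2
  nr <- nrow(cls); nc <- ncol(cls)
  work <- cls
  work[!(cls %in% mergeable)] <- 0L
  comp <- label_components4(work)
  k <- max(comp)
  if (k == 0L) return(cls)
  areas <- tabulate(comp[comp > 0L], nbins = k) * psz2
  small <- which(areas < min_region_um2)
  out <- cls
  for (s in small) {
    idx <- which(comp == s)
    row <- ((idx - 1L) %% nr) + 1L
    col <- ((idx - 1L) %/% nr) + 1L
    nb <- integer(0)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- row + d[1]; cc <- col + d[2]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      v <- out[cbind(rr[ok], cc[ok])]
      nb <- c(nb, v[comp[cbind(rr[ok], cc[ok])] != s])
    }
    # mask-derived classes (necrosis, artifact) are passed through
    # unchanged, so small regions may only merge into threshold-derived
    # classes or background
    nb <- nb[nb %in% c(0L, mergeable)]
    if (length(nb) == 0L) next
    tab <- table(nb)
    out[idx] <- as.integer(names(tab)[which.max(tab)])
  }
  out
}

#' Distance layers to perfusion, vessels, and necrosis
#'
#' Builds the three distance maps used by vessel distance analysis:
#' `to_perfused` measures distance to the perfusion ROI united with
#' perfused-vessel pixels, `to_all_vessels` to every vessel pixel, and
#' `to_necrosis` to the necrosis class. An empty target (e.g. a tumor
#' without necrosis) yields a `NULL` layer flagged absent rather than an
#' error.
#'
#' @param roi a [roi_map()].
#' @param vessels a [label_map()] of vessels on the same grid.
#' @param perfused_flags logical vector from [flag_perfused()].
#' @return an object of class `distance_set` with elements `to_perfused`,
#'   `to_all_vessels`, `to_necrosis` (matrix or `NULL`).
#' @export
build_distance_set <- function(roi, vessels, perfused_flags) {
  stopifnot(inherits(roi, "roi_map"), inherits(vessels, "label_map"))
  if (!all(dim(roi$classes) == dim(vessels$labels)))
    stop("roi and vessel grids differ")
  k <- n_labels(vessels)
  if (length(perfused_flags) != k)
    stop("perfused_flags length must equal the number of vessel labels")
  grid <- roi$grid
  layer <- function(mask) {
    if (!any(mask)) return(NULL)
    sqrt(edt_sq_cpp(mask)) * grid$pixel_size_um
  }
  perf_vessel_px <- if (k > 0)
    vessels$labels %in% which(perfused_flags) else FALSE
  perf_target <- roi_class_mask(roi, "perfusion") |
    matrix(perf_vessel_px, nrow(roi$classes), ncol(roi$classes))
  structure(list(to_perfused = layer(perf_target),
                 to_all_vessels = layer(vessels$labels > 0L),
                 to_necrosis = layer(roi_class_mask(roi, "necrosis")),
                 grid = grid),
            class = "distance_set")
}

#' Per-cell distances sampled at nucleus centroids
#'
#' Each cell's distance triple is the distance-layer value at its nucleus
#' centroid rounded to the nearest pixel (per-cell tabulation granularity).
#' Absent layers give `NA`.
#'
#' @param cells a [label_map()] of cells.
#' @param dset a `distance_set` from [build_distance_set()].
#' @param nuclei optional [label_map()] of the nuclei that seeded `cells`
#'   (same label ids); when omitted the cell footprint centroid is used.
#' @return data.frame with `id`, `dist_perfused_um`, `dist_all_vessels_um`,
#'   `dist_necrosis_um`.
#' @export
attach_cell_distances <- function(cells, dset, nuclei = NULL) {
  stopifnot(inherits(cells, "label_map"), inherits(dset, "distance_set"))
  cent <- label_centroids_um(if (is.null(nuclei)) cells else nuclei)
  g <- cells$grid
  i <- pmin(pmax(um_to_px(cent$y_um, g$pixel_size_um), 1L), g$height_px)
  j <- pmin(pmax(um_to_px(cent$x_um, g$pixel_size_um), 1L), g$width_px)
  sample_layer <- function(layer) {
    if (is.null(layer)) return(rep(NA_real_, nrow(cent)))
    layer[cbind(i, j)]
  }
  data.frame(id = cent$label,
             dist_perfused_um = sample_layer(dset$to_perfused),
             dist_all_vessels_um = sample_layer(dset$to_all_vessels),
             dist_necrosis_um = sample_layer(dset$to_necrosis))
}
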
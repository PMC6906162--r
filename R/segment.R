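#' Segmentation parameters
#'
#' Thresholds may be explicit intensities or `"otsu"` for automatic
#' selection on the smoothed channel. Area filters follow the strict
#' conventions used throughout the package: nuclei smaller than
#' `min_nucleus_area_um2` are excluded (a nucleus of exactly 23 um^2 is
#' kept), vessels are kept only when strictly larger than
#' `min_vessel_area_um2` (a vessel of exactly 5 um^2 is dropped).
#'
#' @param dapi_threshold nuclear-channel threshold or `"otsu"`.
#' @param min_nucleus_area_um2 exclude nuclei below this area, um^2.
#' @param cell_dilation_um dilation used to simulate the cell body, um.
#' @param cd31_threshold vessel-channel threshold or `"otsu"`.
#' @param min_vessel_area_um2 keep vessels strictly above this area, um^2.
#' @param smoothing_sigma_um Gaussian pre-smoothing sigma, um (0 = none).
#' @param watershed_sep_um minimum separation of watershed seed maxima, um.
#' @return an object of class `segmentation_params`.
#' @export
segmentation_params <- function(dapi_threshold = "otsu",
                                min_nucleus_area_um2 = 23,
                                cell_dilation_um = 5,
                                cd31_threshold = "otsu",
                                min_vessel_area_um2 = 5,
                                smoothing_sigma_um = 1,
                                watershed_sep_um = 4) {
  if (min_nucleus_area_um2 < 0 || min_vessel_area_um2 < 0)
    stop("segmentation_params: area filters must be >= 0")
  if (cell_dilation_um < 0)
    stop("segmentation_params: cell_dilation_um must be >= 0")
  if (smoothing_sigma_um < 0)
    stop("segmentation_params: smoothing_sigma_um must be >= 0")
  structure(list(dapi_threshold = dapi_threshold,
                 min_nucleus_area_um2 = min_nucleus_area_um2,
                 cell_dilation_um = cell_dilation_um,
                 cd31_threshold = cd31_threshold,
                 min_vessel_area_um2 = min_vessel_area_um2,
                 smoothing_sigma_um = smoothing_sigma_um,
                 watershed_sep_um = watershed_sep_um),
            class = "segmentation_params")
}

# smooth, then resolve an explicit or Otsu threshold; returns the
# foreground mask (NULL when the image carries no signal to threshold)
threshold_channel <- function(img, grid, threshold, sigma_um) {
  sm <- img
  if (sigma_um > 0) {
    sm <- as.matrix(EBImage::gblur(img, sigma = sigma_um / grid$pixel_size_um))
  }
  if (identical(threshold, "otsu")) {
    rng <- range(sm)
    if (diff(rng) <= 0) return(NULL)
    t <- EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)),
                       range = c(0, 1)) * diff(rng) + rng[1]
  } else {
    t <- as.numeric(threshold)
  }
  sm > t
}

# drop labels failing an area predicate, then relabel consecutively
filter_labels_by_area <- function(labels, psz, keep) {
  k <- max(labels)
  if (k == 0L) return(labels)
  areas <- tabulate(labels[labels > 0L], nbins = k) * psz^2
  drop <- which(!keep(areas))
  if (length(drop)) labels[labels %in% drop] <- 0L
  relabel_consecutive(labels)
}

#' Detect nuclei on the nuclear channel
#'
#' Gaussian smoothing, thresholding (explicit or Otsu), then a watershed on
#' the Euclidean distance transform to split touching nuclei, keeping the
#' seed maxima at least `watershed_sep_um` apart. Components are 4-connected
#' and nuclei smaller than `min_nucleus_area_um2` (default 23 um^2) are
#' excluded. A blank image yields zero labels, not an error.
#'
#' @param dapi nuclear-channel intensity matrix.
#' @param grid a [pixel_grid()].
#' @param params a [segmentation_params()].
#' @return a [label_map()] of nuclei.
#' @export
detect_nuclei <- function(dapi, grid, params = segmentation_params()) {
  stopifnot(inherits(grid, "pixel_grid"))
  check_grid_image(dapi, grid, "dapi")
  mask <- threshold_channel(dapi, grid, params$dapi_threshold,
                            params$smoothing_sigma_um)
  empty <- label_map(grid, matrix(0L, grid$height_px, grid$width_px))
  if (is.null(mask) || !any(mask)) return(empty)
  dm <- sqrt(edt_sq_cpp(!mask))  # distance of foreground to background
  ext <- max(1L, round(params$watershed_sep_um / grid$pixel_size_um))
  ws <- as.matrix(EBImage::watershed(EBImage::Image(dm), tolerance = 1,
                                     ext = ext))
  labels <- label_components4(matrix(as.integer(ws), nrow(ws), ncol(ws)))
  labels <- filter_labels_by_area(labels, grid$pixel_size_um,
                                  function(a) a >= params$min_nucleus_area_um2)
  label_map(grid, labels)
}

#' Simulate cell bodies by constrained nuclear dilation
#'
#' Grows every nucleus outward by `dilation_um` (Euclidean, in physical
#' units) in the absence of a membrane marker. Contested pixels go to the
#' nucleus whose nearest pixel is closest; exact ties go to the lower label
#' id, so cells partition the dilated union with no double counting.
#'
#' @param nuclei a [label_map()] of nuclei.
#' @param dilation_um dilation radius, um (0 returns the input unchanged).
#' @return a [label_map()] of cells carrying the nuclear label ids.
#' @export
simulate_cells <- function(nuclei, dilation_um = 5) {
  stopifnot(inherits(nuclei, "label_map"), dilation_um >= 0)
  if (dilation_um == 0 || n_labels(nuclei) == 0L) return(nuclei)
  psz <- nuclei$grid$pixel_size_um
  dsq <- edt_sq_cpp(nuclei$labels > 0L)
  out <- assign_nearest_label_cpp(nuclei$labels, dsq, (dilation_um / psz)^2)
  label_map(nuclei$grid, out)
}

#' Detect vessels on the endothelial channel
#'
#' Smoothing and thresholding as for nuclei, but no watershed splitting
#' (vessels may be elongated or annular) and the area rule is strict in the
#' other direction: only components strictly larger than
#' `min_vessel_area_um2` (default 5 um^2) are kept.
#'
#' @param cd31 endothelial-channel intensity matrix.
#' @param grid a [pixel_grid()].
#' @param params a [segmentation_params()].
#' @return a [label_map()] of vessels.
#' @export
detect_vessels <- function(cd31, grid, params = segmentation_params()) {
  stopifnot(inherits(grid, "pixel_grid"))
  check_grid_image(cd31, grid, "cd31")
  mask <- threshold_channel(cd31, grid, params$cd31_threshold,
                            params$smoothing_sigma_um)
  empty <- label_map(grid, matrix(0L, grid$height_px, grid$width_px))
  if (is.null(mask) || !any(mask)) return(empty)
  labels <- label_components4(mask)
  labels <- filter_labels_by_area(labels, grid$pixel_size_um,
                                  function(a) a > params$min_vessel_area_um2)
  label_map(grid, labels)
}

#' Flag vessels as perfused by perfusion-mask overlap
#'
#' A vessel counts as perfused when at least one of its pixels overlaps the
#' perfusion mask (the perfusion-dye region), mirroring the rule that
#' CD31-positive vessels inside the perfusion stain are perfused.
#'
#' @param vessels a [label_map()] of vessels.
#' @param perfusion_mask logical matrix on the same grid.
#' @return logical vector, one flag per vessel label.
#' @export
flag_perfused <- function(vessels, perfusion_mask) {
  stopifnot(inherits(vessels, "label_map"))
  perfusion_mask <- as_mask(perfusion_mask)
  if (!all(dim(perfusion_mask) == dim(vessels$labels)))
    stop(sprintf("perfusion_mask dimensions (%s) do not match vessel map (%s)",
                 paste(dim(perfusion_mask), collapse = " x "),
                 paste(dim(vessels$labels), collapse = " x ")))
  k <- n_labels(vessels)
  if (k == 0L) return(logical(0))
  hits <- vessels$labels[perfusion_mask]
  tabulate(hits[hits > 0L], nbins = k) > 0L
}

#' Tile-based object-count validation
#'
#' Compares detected object counts with ground-truth centers inside random
#' square tiles (objects counted by centroid-in-tile). Percent error per
#' tile is `|detected - truth| / truth * 100`; tiles with zero truth objects
#' are reported as `NA` and excluded from the mean.
#'
#' @param detected a [label_map()] of detected objects.
#' @param truth_centers data.frame with `x_um`, `y_um` of true centers.
#' @param n_tiles number of random tiles.
#' @param tile_um tile edge length, um.
#' @param seed RNG seed for tile placement.
#' @return list with `tiles` (per-tile data.frame) and `mean_pct_error`.
#' @export
count_validation <- function(detected, truth_centers, n_tiles = 10,
                             tile_um = 350, seed = 1) {
  stopifnot(inherits(detected, "label_map"), n_tiles >= 1)
  g <- detected$grid
  W <- g$width_px * g$pixel_size_um
  H <- g$height_px * g$pixel_size_um
  if (tile_um > W || tile_um > H)
    stop(sprintf("tile_um = %g does not fit in the %g x %g um grid",
                 tile_um, W, H))
  cent <- label_centroids_um(detected)
  tiles <- with_seed(seed, data.frame(
    x0 = runif(n_tiles, 0, W - tile_um),
    y0 = runif(n_tiles, 0, H - tile_um)))
  in_tile <- function(x, y, x0, y0)
    x >= x0 & x < x0 + tile_um & y >= y0 & y < y0 + tile_um
  tiles$n_detected <- vapply(seq_len(n_tiles), function(t)
    sum(in_tile(cent$x_um, cent$y_um, tiles$x0[t], tiles$y0[t])), integer(1))
  tiles$n_truth <- vapply(seq_len(n_tiles), function(t)
    sum(in_tile(truth_centers$x_um, truth_centers$y_um,
                tiles$x0[t], tiles$y0[t])), integer(1))
  tiles$pct_error <- ifelse(tiles$n_truth == 0, NA_real_,
                            abs(tiles$n_detected - tiles$n_truth) /
                              tiles$n_truth * 100)
  list(tiles = tiles,
       mean_pct_error = mean(tiles$pct_error, na.rm = TRUE))
}
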
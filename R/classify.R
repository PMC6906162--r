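CLASS_LEVELS <- c("negative", "low", "medium", "high")

#' Ordered intensity thresholds for positivity classes
#'
#' Three thresholds split intensity into negative / low / medium / high via
#' half-open intervals `[0,t1) [t1,t2) [t2,t3) [t3,Inf)`: a value exactly on
#' a boundary promotes to the higher class.
#'
#' @param t1,t2,t3 increasing intensity thresholds (arbitrary units).
#' @return an object of class `threshold_set`.
#' @export
threshold_set <- function(t1, t2, t3) {
  stopifnot(is.numeric(t1), is.numeric(t2), is.numeric(t3))
  if (!(t1 < t2 && t2 < t3))
    stop(sprintf("threshold_set: need t1 < t2 < t3 (got %g, %g, %g)",
                 t1, t2, t3))
  structure(list(t1 = t1, t2 = t2, t3 = t3), class = "threshold_set")
}

# interval classification -> integer codes 1..4 (negative..high)
classify_intensity <- function(x, ts) {
  out <- rep.int(1L, length(x))
  out[x >= ts$t1] <- 2L
  out[x >= ts$t2] <- 3L
  out[x >= ts$t3] <- 4L
  out
}

#' Marker Area Detection (pixel-level classification)
#'
#' Classifies every pixel of the analysis mask into negative / low / medium
#' / high by the shared thresholds, then reassigns connected
#' above-negative regions smaller than `min_region_um2` (default 10 um^2,
#' strict) to negative before computing area fractions. The region filter
#' applies to the union of supra-t1 pixels, one exclusion step for all
#' positive classes.
#'
#' @param intensity marker intensity matrix (e.g. the hypoxia stain).
#' @param analysis_mask logical matrix of pixels to analyze; must be
#'   nonempty.
#' @param thresholds a [threshold_set()].
#' @param min_region_um2 exclude positive regions below this area, um^2.
#' @param grid a [pixel_grid()].
#' @return an object of class `mad_result`: `class_image` (codes 1..4
#'   inside the mask, 0 outside) and `fractions` (named, sums to 1).
#' @export
mad_classify <- function(intensity, analysis_mask, thresholds,
                         min_region_um2 = 10, grid) {
  stopifnot(inherits(thresholds, "threshold_set"),
            inherits(grid, "pixel_grid"))
  check_grid_image(intensity, grid, "intensity")
  analysis_mask <- as_mask(analysis_mask)
  check_grid_image(analysis_mask, grid, "analysis_mask")
  if (!any(analysis_mask)) stop("mad_classify: analysis_mask is empty")

  cls <- matrix(0L, nrow(intensity), ncol(intensity))
  cls[analysis_mask] <- classify_intensity(intensity[analysis_mask],
                                           thresholds)
  if (min_region_um2 > 0) {
    pos <- cls >= 2L
    if (any(pos)) {
      comp <- label_components4(pos)
      k <- max(comp)
      areas <- tabulate(comp[comp > 0L], nbins = k) * grid$pixel_size_um^2
      small <- which(areas < min_region_um2)
      if (length(small)) cls[comp %in% small] <- 1L
    }
  }
  counts <- tabulate(cls[analysis_mask], nbins = 4L)
  structure(list(class_image = cls,
                 counts = setNames(counts, CLASS_LEVELS),
                 fractions = setNames(counts / sum(counts), CLASS_LEVELS)),
            class = "mad_result")
}

#' Cellular Classification (cell-level classification)
#'
#' Applies the same thresholds to the mean marker intensity over each
#' simulated cell footprint. `percent_positive` is the fraction of cells
#' whose mean is at least `t1` (low + medium + high).
#'
#' @param cells a [label_map()] of simulated cells (at least one cell).
#' @param intensity marker intensity matrix on the same grid.
#' @param thresholds a [threshold_set()].
#' @return an object of class `cc_result`: per-cell table (`id`,
#'   `mean_intensity`, `class`), `fractions`, and `percent_positive`.
#' @export
cc_classify <- function(cells, intensity, thresholds) {
  stopifnot(inherits(cells, "label_map"),
            inherits(thresholds, "threshold_set"))
  check_grid_image(intensity, cells$grid, "intensity")
  k <- n_labels(cells)
  if (k == 0L) stop("cc_classify: no cells to classify")
  idx <- cells$labels > 0L
  lab <- cells$labels[idx]
  means <- as.numeric(rowsum(intensity[idx], lab) / tabulate(lab, k))
  cls <- classify_intensity(means, thresholds)
  counts <- tabulate(cls, nbins = 4L)
  structure(list(cells = data.frame(id = seq_len(k), mean_intensity = means,
                                    class = factor(CLASS_LEVELS[cls],
                                                   levels = CLASS_LEVELS)),
                 counts = setNames(counts, CLASS_LEVELS),
                 fractions = setNames(counts / k, CLASS_LEVELS),
                 percent_positive = sum(counts[2:4]) / k),
            class = "cc_result")
}

#' Compare pixel-level and cell-level positivity
#'
#' Pairs the class fractions of a Marker Area Detection run with a Cellular
#' Classification run performed under the same thresholds, reporting the
#' CC/MAD ratio per class (`NA` where the MAD fraction is zero).
#'
#' @param mad a `mad_result` from [mad_classify()].
#' @param cc a `cc_result` from [cc_classify()].
#' @return data.frame with columns `class`, `mad_fraction`, `cc_fraction`,
#'   `ratio`, plus a `positive` attribute comparing total positive
#'   fractions.
#' @export
compare_mad_cc <- function(mad, cc) {
  stopifnot(inherits(mad, "mad_result"), inherits(cc, "cc_result"))
  out <- data.frame(class = CLASS_LEVELS,
                    mad_fraction = as.numeric(mad$fractions),
                    cc_fraction = as.numeric(cc$fractions))
  out$ratio <- ifelse(out$mad_fraction > 0,
                      out$cc_fraction / out$mad_fraction, NA_real_)
  attr(out, "positive") <- c(mad = sum(mad$fractions[2:4]),
                             cc = sum(cc$fractions[2:4]))
  out
}
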
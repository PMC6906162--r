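#' Pixel grid with physical units
#'
#' Defines the common pixel lattice of a co-registered channel set. All
#' spatial thresholds in the pipeline (nucleus/vessel area filters, cell
#' dilation, distance bins) are stated in micrometers and converted through
#' `pixel_size_um`. Physical coordinates follow the convention
#' `x = (column_index - 1 + 0.5) * pixel_size_um` (and likewise `y` from the
#' row index), i.e. pixel centers, origin at the top-left corner.
#'
#' @param width_px,height_px grid size in pixels (columns, rows).
#' @param pixel_size_um physical edge length of one pixel, micrometers.
#' @return an object of class `pixel_grid`.
#' @export
pixel_grid <- function(width_px, height_px, pixel_size_um = 1) {
  stopifnot(length(width_px) == 1, length(height_px) == 1,
            length(pixel_size_um) == 1)
  width_px <- as.integer(width_px)
  height_px <- as.integer(height_px)
  if (is.na(width_px) || width_px < 1L) stop("width_px must be >= 1")
  if (is.na(height_px) || height_px < 1L) stop("height_px must be >= 1")
  if (!is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be > 0")
  structure(list(width_px = width_px, height_px = height_px,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("<pixel_grid> %d x %d px @ %g um/px (%g x %g um)\n",
              x$width_px, x$height_px, x$pixel_size_um,
              x$width_px * x$pixel_size_um, x$height_px * x$pixel_size_um))
  invisible(x)
}

grid_dim <- function(grid) c(grid$height_px, grid$width_px)

check_grid_image <- function(img, grid, name = "image") {
  if (!is.matrix(img) || !all(dim(img) == grid_dim(grid)))
    stop(sprintf("%s dimensions (%s) do not match grid (%d x %d)", name,
                 paste(dim(img), collapse = " x "),
                 grid$height_px, grid$width_px))
  invisible(TRUE)
}

# physical center coordinates of pixel (row, col), 1-based indices
px_to_um <- function(index, pixel_size_um) (index - 0.5) * pixel_size_um
um_to_px <- function(coord_um, pixel_size_um) {
  pmax(1L, as.integer(round(coord_um / pixel_size_um + 0.5)))
}

#' Labeled object image
#'
#' Integer-labeled objects (nuclei, simulated cells, vessels) on a pixel
#' grid; 0 is background and labels are consecutive `1..K`.
#'
#' @param grid a [pixel_grid()].
#' @param labels integer matrix of object labels.
#' @return an object of class `label_map`.
#' @export
label_map <- function(grid, labels) {
  stopifnot(inherits(grid, "pixel_grid"))
  check_grid_image(labels, grid, "labels")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("labels must be non-negative")
  structure(list(grid = grid, labels = labels), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d objects on %d x %d px\n", n_labels(x),
              x$grid$height_px, x$grid$width_px))
  invisible(x)
}

n_labels <- function(lm) {
  m <- max(lm$labels)
  if (m == 0L) 0L else m
}

# relabel nonzero values to consecutive 1..K preserving ascending order
relabel_consecutive <- function(labels) {
  keep <- sort(unique(labels[labels > 0L]))
  if (length(keep) == 0L) return(labels)
  out <- labels
  out[labels > 0L] <- match(labels[labels > 0L], keep)
  storage.mode(out) <- "integer"
  out
}

# per-label pixel areas (um^2) of a label_map
label_areas_um2 <- function(lm) {
  k <- n_labels(lm)
  if (k == 0L) return(numeric(0))
  tabulate(lm$labels[lm$labels > 0L], nbins = k) * lm$grid$pixel_size_um^2
}

# per-label centroids in physical um; rows ordered by label id
label_centroids_um <- function(lm) {
  k <- n_labels(lm)
  psz <- lm$grid$pixel_size_um
  if (k == 0L)
    return(data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0)))
  idx <- which(lm$labels > 0L)
  lab <- lm$labels[idx]
  row <- ((idx - 1L) %% nrow(lm$labels)) + 1L
  col <- ((idx - 1L) %/% nrow(lm$labels)) + 1L
  data.frame(label = seq_len(k),
             x_um = px_to_um(as.numeric(rowsum(col, lab) / tabulate(lab, k)), psz),
             y_um = px_to_um(as.numeric(rowsum(row, lab) / tabulate(lab, k)), psz))
}

# run expr with a temporarily-seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# derive k reproducible sub-seeds (< 2^31) from one seed
derive_seeds <- function(seed, k) with_seed(seed, sample.int(.Machine$integer.max, k))
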
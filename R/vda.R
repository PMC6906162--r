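#' Build the per-cell feature table
#'
#' One row per segmented cell: nucleus centroid (physical um), nucleus and
#' cell areas, mean intensity of every channel over the cell footprint,
#' distances to perfusion / all vessels / necrosis, and the ROI class at
#' the centroid. This table is the canonical interchange format of the
#' pipeline (written as `cells.csv`).
#'
#' @param cells a [label_map()] of simulated cells.
#' @param nuclei the [label_map()] of nuclei that seeded them (same ids).
#' @param channels a [channel_stack()].
#' @param dset a `distance_set` from [build_distance_set()].
#' @param roi a [roi_map()].
#' @return data.frame of class `cell_table`.
#' @export
build_cell_table <- function(cells, nuclei, channels, dset, roi) {
  stopifnot(inherits(cells, "label_map"), inherits(nuclei, "label_map"),
            inherits(channels, "channel_stack"), inherits(roi, "roi_map"))
  k <- n_labels(cells)
  g <- cells$grid
  psz <- g$pixel_size_um
  cent <- label_centroids_um(nuclei)
  if (nrow(cent) != k) stop("nuclei and cells carry different label sets")
  idx <- cells$labels > 0L
  lab <- cells$labels[idx]
  sizes <- tabulate(lab, k)
  tab <- data.frame(id = cent$label, x_um = cent$x_um, y_um = cent$y_um,
                    nucleus_area_um2 = label_areas_um2(nuclei),
                    cell_area_um2 = sizes * psz^2)
  for (nm in names(channels$channels)) {
    tab[[paste0("mean_", nm)]] <-
      as.numeric(rowsum(channels$channels[[nm]][idx], lab) / sizes)
  }
  d <- attach_cell_distances(cells, dset, nuclei)
  tab$dist_perfused_um <- d$dist_perfused_um
  tab$dist_all_vessels_um <- d$dist_all_vessels_um
  tab$dist_necrosis_um <- d$dist_necrosis_um
  ci <- pmin(pmax(um_to_px(cent$y_um, psz), 1L), g$height_px)
  cj <- pmin(pmax(um_to_px(cent$x_um, psz), 1L), g$width_px)
  tab$roi_class <- factor(ROI_LEVELS[roi$classes[cbind(ci, cj)] + 1L],
                          levels = ROI_LEVELS)
  class(tab) <- c("cell_table", "data.frame")
  tab
}

dist_column <- function(distance_field) {
  switch(match.arg(distance_field, c("perfused", "all_vessels", "necrosis")),
         perfused = "dist_perfused_um",
         all_vessels = "dist_all_vessels_um",
         necrosis = "dist_necrosis_um")
}

# positivity gate value: mean + 1 sd of intensities on the chosen scale
gate_value <- function(x, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  v <- if (scale == "log") log10(x + 1) else x
  mean(v) + sd(v)
}

gate_positive <- function(x, gate, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  v <- if (scale == "log") log10(x + 1) else x
  v > gate
}

#' Distance-binned per-cell marker statistics
#'
#' Bins cells into uniform half-open distance intervals `[k w, (k+1) w)` on
#' the chosen distance field and computes, per bin and per marker, the cell
#' count, mean intensity, standard error of the mean (`NA` for n < 2), and
#' the percent of cells above the positivity gate. Cells at or beyond
#' `d_max_um` are excluded. Empty bins are emitted (n = 0) so tables align
#' across samples.
#'
#' @param table a [build_cell_table()] data.frame.
#' @param distance_field one of `"perfused"`, `"all_vessels"`, `"necrosis"`.
#' @param markers channel names to summarize (default EF5 and EdU).
#' @param bin_width_um bin width, um.
#' @param d_max_um outer analysis limit, um (exclusive).
#' @param gates optional named numeric vector of explicit gate values on
#'   the `gate_scale` scale; markers without an entry get the mean + 1 sd
#'   gate computed from the included cells.
#' @param gate_scale `"log"` (gate on `log10(x+1)`) or `"linear"`.
#' @return data.frame of class `bin_table` with attributes `bin_width_um`,
#'   `d_max_um`, `gates`, `distance_field`.
#' @export
bin_cells <- function(table, distance_field = "perfused",
                      markers = c("EF5", "EdU"), bin_width_um = 10,
                      d_max_um = 700, gates = NULL,
                      gate_scale = c("log", "linear")) {
  stopifnot(nrow(table) > 0, bin_width_um > 0, d_max_um > bin_width_um / 2)
  gate_scale <- match.arg(gate_scale)
  col <- dist_column(distance_field)
  d <- table[[col]]
  if (all(is.na(d)))
    stop(sprintf(paste0("bin_cells: distance field '%s' is entirely missing ",
                        "(no such target in this sample); use another field"),
                 distance_field))
  keep <- !is.na(d) & d < d_max_um
  tb <- table[keep, , drop = FALSE]
  d <- d[keep]
  nb <- ceiling(d_max_um / bin_width_um)
  bin <- pmin(floor(d / bin_width_um), nb - 1) + 1L
  out <- data.frame(d_lo = (seq_len(nb) - 1) * bin_width_um,
                    d_hi = seq_len(nb) * bin_width_um,
                    n_cells = tabulate(bin, nbins = nb))
  used_gates <- numeric(0)
  for (m in markers) {
    colm <- paste0("mean_", m)
    if (is.null(tb[[colm]])) stop("bin_cells: marker column missing: ", colm)
    x <- tb[[colm]]
    g <- if (!is.null(gates) && m %in% names(gates)) gates[[m]] else
      gate_value(x, gate_scale)
    used_gates[m] <- g
    pos <- gate_positive(x, g, gate_scale)
    sums <- rep(0, nb); sq <- rep(0, nb); np <- rep(0, nb)
    if (nrow(tb) > 0) {
      agg <- rowsum(cbind(x, x^2, as.numeric(pos)), bin)
      rows <- as.integer(rownames(agg))
      sums[rows] <- agg[, 1]; sq[rows] <- agg[, 2]; np[rows] <- agg[, 3]
    }
    n <- out$n_cells
    mu <- ifelse(n > 0, sums / n, NA_real_)
    varhat <- ifelse(n > 1, (sq - n * mu^2) / (n - 1), NA_real_)
    out[[paste0("mean_", m)]] <- mu
    out[[paste0("sem_", m)]] <- ifelse(n > 1, sqrt(pmax(varhat, 0) / n),
                                       NA_real_)
    out[[paste0("pct_pos_", m)]] <- ifelse(n > 0, np / n, NA_real_)
  }
  attr(out, "bin_width_um") <- bin_width_um
  attr(out, "d_max_um") <- d_max_um
  attr(out, "gates") <- used_gates
  attr(out, "gate_scale") <- gate_scale
  attr(out, "distance_field") <- distance_field
  class(out) <- c("bin_table", "data.frame")
  out
}

#' Ring composition of ROI classes around perfusion
#'
#' Concentric rings of fixed width around the perfusion target: ring `k`
#' holds the tissue pixels whose distance lies in `[k w, (k+1) w)`. The
#' viable / hypoxia / necrosis fractions are class pixel counts over the
#' tissue pixel count in the ring (perfusion contributes to the
#' denominator, not the numerators). Rings without tissue are flagged
#' empty with `NA` fractions.
#'
#' @param roi a [roi_map()].
#' @param dist_to_perfusion distance layer (um) to the perfusion target.
#' @param ring_width_um ring width, um.
#' @param d_max_um outer limit, um (exclusive).
#' @return data.frame of class `ring_table`: `d_lo`, `d_hi`,
#'   `n_tissue_px`, `frac_viable`, `frac_hypoxia`, `frac_necrosis`,
#'   `empty`.
#' @export
ring_composition <- function(roi, dist_to_perfusion, ring_width_um = 10,
                             d_max_um = 700) {
  stopifnot(inherits(roi, "roi_map"), ring_width_um > 0)
  check_grid_image(dist_to_perfusion, roi$grid, "dist_to_perfusion")
  tissue <- roi_tissue_mask(roi)
  nb <- ceiling(d_max_um / ring_width_um)
  d <- dist_to_perfusion[tissue]
  cls <- roi$classes[tissue]
  keep <- d < d_max_um
  d <- d[keep]; cls <- cls[keep]
  ring <- pmin(floor(d / ring_width_um), nb - 1) + 1L
  n_px <- tabulate(ring, nbins = nb)
  cnt <- function(code) tabulate(ring[cls == code], nbins = nb)
  out <- data.frame(d_lo = (seq_len(nb) - 1) * ring_width_um,
                    d_hi = seq_len(nb) * ring_width_um,
                    n_tissue_px = n_px,
                    frac_viable = ifelse(n_px > 0, cnt(1L) / n_px, NA_real_),
                    frac_hypoxia = ifelse(n_px > 0, cnt(2L) / n_px, NA_real_),
                    frac_necrosis = ifelse(n_px > 0, cnt(3L) / n_px, NA_real_),
                    empty = n_px == 0L)
  class(out) <- c("ring_table", "data.frame")
  out
}

#' Distance of peak class fraction
#'
#' Center of the nonempty ring that maximizes the class area fraction; ties
#' resolve to the smallest distance.
#'
#' @param rings a [ring_composition()] table.
#' @param class `"viable"`, `"hypoxia"`, or `"necrosis"`.
#' @return peak distance, um.
#' @export
peak_distance <- function(rings, class = "hypoxia") {
  class <- match.arg(class, c("viable", "hypoxia", "necrosis"))
  ok <- !rings$empty
  if (!any(ok)) stop("peak_distance: all rings are empty")
  fr <- rings[[paste0("frac_", class)]][ok]
  centers <- ((rings$d_lo + rings$d_hi) / 2)[ok]
  centers[which.max(fr)]
}

#' Marker gradient slope between two distances
#'
#' Slope of mean marker intensity per unit distance between the bins
#' containing the two endpoint distances: read out of a [bin_cells()] table
#' as `(mean(end bin) - mean(start bin)) / (d_end - d_start)`. Used as a
#' consumption (vs vessels) or hypoxia-tolerance (vs necrosis) readout.
#'
#' @param bins a [bin_cells()] table.
#' @param marker marker name present in the table.
#' @param d_start_um,d_end_um endpoint distances, um (`d_start < d_end`).
#' @return list with `slope` (intensity a.u. per um), `mean_start`,
#'   `mean_end`, and the endpoint bin indices.
#' @export
gradient_slope <- function(bins, marker, d_start_um, d_end_um) {
  stopifnot(inherits(bins, "bin_table"), d_start_um < d_end_um)
  w <- attr(bins, "bin_width_um")
  colm <- paste0("mean_", marker)
  if (is.null(bins[[colm]])) stop("gradient_slope: no such marker: ", marker)
  pick <- function(dd) {
    k <- min(floor(dd / w) + 1, nrow(bins))
    if (bins$n_cells[k] == 0) {
      nonempty <- which(bins$n_cells > 0)
      near <- nonempty[which.min(abs(nonempty - k))]
      stop(sprintf(paste0("gradient_slope: bin [%g, %g) is empty; nearest ",
                          "nonempty bin is [%g, %g)"),
                   bins$d_lo[k], bins$d_hi[k], bins$d_lo[near],
                   bins$d_hi[near]))
    }
    k
  }
  k1 <- pick(d_start_um); k2 <- pick(d_end_um)
  m1 <- bins[[colm]][k1]; m2 <- bins[[colm]][k2]
  list(slope = (m2 - m1) / (d_end_um - d_start_um),
       mean_start = m1, mean_end = m2, bin_start = k1, bin_end = k2)
}

#' Gate cell populations and test their vessel distances
#'
#' Draws a positivity gate per marker at mean + 1 standard deviation of the
#' per-cell intensities (log10(x+1) scale by default, as scatterplots are
#' log-scaled), partitions cells into the four quadrant populations, and
#' runs a two-sided permutation test of the difference in mean
#' perfused-vessel distance between each positive population and the
#' double-negative population, with the add-one correction
#' `p = (1 + #\{|perm| >= |obs|\}) / (1 + n_perm)`.
#'
#' @param table a [build_cell_table()] data.frame (at least 10 cells).
#' @param markers two marker names, positive-gated in order (default EF5,
#'   EdU).
#' @param scale `"log"` or `"linear"` gate scale.
#' @param n_perm number of permutations (at least 100).
#' @param seed RNG seed; results are deterministic per seed.
#' @return an object of class `gate_result`: `gates`, per-cell
#'   `population` factor, `pop_stats`, and `tests` (delta, p per
#'   population; `NA` when a population is empty).
#' @export
gate_populations <- function(table, markers = c("EF5", "EdU"),
                             scale = c("log", "linear"), n_perm = 1000,
                             seed = 1) {
  scale <- match.arg(scale)
  stopifnot(length(markers) == 2)
  if (nrow(table) < 10) stop("gate_populations: need at least 10 cells")
  if (n_perm < 100) stop("gate_populations: need n_perm >= 100")
  x1 <- table[[paste0("mean_", markers[1])]]
  x2 <- table[[paste0("mean_", markers[2])]]
  g1 <- gate_value(x1, scale)
  g2 <- gate_value(x2, scale)
  p1 <- gate_positive(x1, g1, scale)
  p2 <- gate_positive(x2, g2, scale)
  lv <- c(paste0(markers[1], "+"), paste0(markers[2], "+"),
          "double+", "double-")
  pop <- factor(ifelse(p1 & p2, "double+",
                       ifelse(p1, lv[1], ifelse(p2, lv[2], "double-"))),
                levels = lv)
  d <- table$dist_perfused_um
  pop_stats <- data.frame(population = lv,
                          n = as.integer(table(pop)[lv]),
                          mean_dist_perfused_um =
                            as.numeric(tapply(d, pop, mean)[lv]))
  ref <- d[pop == "double-" & !is.na(d)]
  tests <- with_seed(seed, {
    do.call(rbind, lapply(lv[1:3], function(pl) {
      grp <- d[pop == pl & !is.na(d)]
      if (length(grp) == 0 || length(ref) == 0)
        return(data.frame(population = pl, delta = NA_real_, p = NA_real_))
      obs <- mean(grp) - mean(ref)
      pool <- c(grp, ref)
      n1 <- length(grp)
      perm <- replicate(n_perm, {
        pick <- sample.int(length(pool), n1)
        mean(pool[pick]) - mean(pool[-pick])
      })
      data.frame(population = pl, delta = obs,
                 p = (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm))
    }))
  })
  structure(list(gates = setNames(c(g1, g2), markers), scale = scale,
                 population = pop, pop_stats = pop_stats, tests = tests,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "gate_result")
}

#' @export
print.gate_result <- function(x, ...) {
  cat(sprintf("<gate_result> gates (%s scale): %s\n", x$scale,
              paste(sprintf("%s=%.3f", names(x$gates), x$gates),
                    collapse = ", ")))
  print(merge(x$pop_stats, x$tests, by = "population", all.x = TRUE))
  invisible(x)
}

#' Plot-ready scatter records with binned density
#'
#' Per-cell records for the flow-cytometry-style scatterplot: transformed
#' intensities (`log10(x+1)` on the log scale), the count-based density of
#' the occupied bin on a `grid_n x grid_n` histogram over the plotted
#' range, and the perfused-vessel distance used for coloring.
#'
#' @param table a [build_cell_table()] data.frame.
#' @param markers two marker names; the first is plotted on x.
#' @param scale `"log"` or `"linear"`.
#' @param grid_n density histogram resolution per axis.
#' @return list of class `scatter_export`: `records` (one row per cell),
#'   `density` matrix, axis `breaks`.
#' @export
scatter_export <- function(table, markers = c("EdU", "EF5"),
                           scale = c("log", "linear"), grid_n = 128) {
  scale <- match.arg(scale)
  stopifnot(length(markers) == 2, nrow(table) > 0)
  tr <- function(v) if (scale == "log") log10(v + 1) else v
  for (m in markers) {
    if (is.null(table[[paste0("mean_", m)]]))
      stop("scatter_export: marker column missing: mean_", m)
  }
  x <- tr(table[[paste0("mean_", markers[1])]])
  y <- tr(table[[paste0("mean_", markers[2])]])
  bx <- seq(0, max(x, 1e-9), length.out = grid_n + 1)
  by <- seq(0, max(y, 1e-9), length.out = grid_n + 1)
  ix <- pmin(pmax(findInterval(x, bx, rightmost.closed = TRUE), 1L), grid_n)
  iy <- pmin(pmax(findInterval(y, by, rightmost.closed = TRUE), 1L), grid_n)
  dens <- matrix(0L, grid_n, grid_n)
  for (k in seq_along(ix)) dens[iy[k], ix[k]] <- dens[iy[k], ix[k]] + 1L
  records <- data.frame(id = table$id, x = x, y = y,
                        density = dens[cbind(iy, ix)],
                        dist_perfused_um = table$dist_perfused_um)
  structure(list(records = records, density = dens,
                 breaks = list(x = bx, y = by), markers = markers,
                 scale = scale),
            class = "scatter_export")
}

#' Render a density scatterplot to a file
#'
#' @param sc a [scatter_export()] object.
#' @param file output PNG path.
#' @param color_by `"density"` or `"distance"`.
#' @return the file path, invisibly.
#' @export
plot_scatter <- function(sc, file, color_by = c("density", "distance")) {
  color_by <- match.arg(color_by)
  r <- sc$records
  val <- if (color_by == "density") log1p(r$density) else r$dist_perfused_um
  val[is.na(val)] <- 0
  pal <- grDevices::hcl.colors(64, "viridis")
  colidx <- 1 + floor(63 * (val - min(val)) /
                        max(max(val) - min(val), 1e-12))
  grDevices::png(file, width = 900, height = 900, res = 150)
  on.exit(grDevices::dev.off())
  lab <- if (sc$scale == "log") "log10(intensity + 1)" else "intensity (a.u.)"
  graphics::plot(r$x, r$y, pch = 16, cex = 0.4, col = pal[colidx],
                 xlab = paste(sc$markers[1], lab),
                 ylab = paste(sc$markers[2], lab))
  invisible(file)
}
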
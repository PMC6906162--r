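#' Oxygen diffusion-consumption parameters
#'
#' Parameters of the steady-state oxygen model
#' \eqn{D \nabla^2 p = M\, p/(p + k_m)} solved on the section plane, with
#' Dirichlet \eqn{p = p_v} on perfused vessel lumens and a zero-flux outer
#' boundary. Michaelis-Menten consumption recovers the classical
#' constant-consumption (Krogh-type) profile as \eqn{k_m \to 0} while keeping
#' oxygen non-negative and the anoxia onset smooth.
#'
#' @param D oxygen diffusion coefficient, um^2/s.
#' @param M maximal consumption rate, mmHg/s.
#' @param k_m Michaelis constant, mmHg.
#' @param p_v vessel-wall oxygen partial pressure, mmHg.
#' @param p_nec oxygen level below which tissue is necrotic, mmHg.
#' @param tol solver residual tolerance, mmHg.
#' @param max_iter maximum relaxation sweeps.
#' @param omega successive over-relaxation factor in (0, 2).
#' @return an object of class `oxygen_params`.
#' @export
oxygen_params <- function(D = 2000, M = 2.75, k_m = 1, p_v = 40,
                          p_nec = 0.5, tol = 1e-4, max_iter = 50000,
                          omega = 1.85) {
  for (nm in c("D", "M", "k_m", "p_v", "tol", "omega")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop(sprintf("oxygen_params: %s must be a positive number", nm))
  }
  if (!is.numeric(p_nec) || p_nec < 0) stop("oxygen_params: p_nec must be >= 0")
  if (p_nec >= p_v) stop("oxygen_params: p_nec must be < p_v")
  if (max_iter < 1) stop("oxygen_params: max_iter must be >= 1")
  if (omega >= 2) stop("oxygen_params: omega must be < 2")
  structure(list(D = D, M = M, k_m = k_m, p_v = p_v, p_nec = p_nec,
                 tol = tol, max_iter = as.integer(max_iter), omega = omega),
            class = "oxygen_params")
}

#' Marker-response parameters for phantom rendering
#'
#' Maps the oxygen field to stain intensities. EF5 binding rises as oxygen
#' falls (Hill form); the probability that a cell is in S phase (EdU
#' positive) rises with oxygen (saturating form). The functional forms are
#' stand-ins with plausible shape, not calibrated binding curves.
#'
#' @param ef5_amp maximal EF5 intensity, arbitrary units.
#' @param K_h oxygen at half-maximal EF5 binding, mmHg.
#' @param h Hill exponent of the EF5 response.
#' @param edu_max maximal EdU-positive probability, in `[0, 1]`.
#' @param K_p oxygen at half-maximal proliferation probability, mmHg.
#' @param hoechst_decay_um decay length of the perfusion-dye halo, um.
#' @param background additive background intensity on every channel.
#' @param noise_sd Gaussian read-noise standard deviation (0 = noise-free).
#' @param dapi_amp,edu_amp,cd31_amp,hoechst_amp peak channel intensities.
#' @param nucleus_radius_um nuclear disk radius, um (rendered as a
#'   super-Gaussian plateau so thresholded nuclear areas are stable).
#' @param cell_radius_um cytoplasmic disk radius used to paint EF5, um.
#' @param vessel_wall_um CD31-positive wall half-thickness, um.
#' @return an object of class `marker_params`.
#' @export
marker_params <- function(ef5_amp = 120, K_h = 10, h = 2, edu_max = 0.6,
                          K_p = 5, hoechst_decay_um = 15, background = 5,
                          noise_sd = 2, dapi_amp = 180, edu_amp = 200,
                          cd31_amp = 180, hoechst_amp = 200,
                          nucleus_radius_um = 3.5, cell_radius_um = 7,
                          vessel_wall_um = 1.5) {
  if (ef5_amp < 0) stop("marker_params: ef5_amp must be >= 0")
  if (edu_max < 0 || edu_max > 1) stop("marker_params: edu_max must be in [0, 1]")
  for (nm in c("K_h", "K_p", "hoechst_decay_um", "nucleus_radius_um",
               "cell_radius_um", "vessel_wall_um")) {
    if (get(nm) <= 0) stop(sprintf("marker_params: %s must be > 0", nm))
  }
  if (background < 0 || noise_sd < 0)
    stop("marker_params: background and noise_sd must be >= 0")
  structure(list(ef5_amp = ef5_amp, K_h = K_h, h = h, edu_max = edu_max,
                 K_p = K_p, hoechst_decay_um = hoechst_decay_um,
                 background = background, noise_sd = noise_sd,
                 dapi_amp = dapi_amp, edu_amp = edu_amp, cd31_amp = cd31_amp,
                 hoechst_amp = hoechst_amp,
                 nucleus_radius_um = nucleus_radius_um,
                 cell_radius_um = cell_radius_um,
                 vessel_wall_um = vessel_wall_um),
            class = "marker_params")
}

#' Place phantom vessels with minimum spacing
#'
#' Rejection-samples vessel centers uniformly over the grid interior
#' (keeping each lumen fully inside the domain) until all pairwise center
#' distances are at least `min_spacing_um`. A fixed fraction, rounded to the
#' nearest count, is flagged perfused; non-perfused vessels later contribute
#' CD31 signal but no oxygen and no perfusion-dye halo.
#'
#' @param grid a [pixel_grid()].
#' @param n number of vessels.
#' @param min_spacing_um minimum pairwise center distance, um.
#' @param perfused_fraction fraction of vessels flagged perfused, in `[0, 1]`.
#' @param radius_range_um two-element range of lumen radii, um.
#' @param seed integer RNG seed; results are deterministic per seed.
#' @param max_attempts rejection-sampling budget before giving up.
#' @return data.frame with columns `x_um`, `y_um`, `radius_um`, `perfused`.
#' @export
place_vessels <- function(grid, n, min_spacing_um = 0, perfused_fraction = 1,
                          radius_range_um = c(8, 15), seed = 1,
                          max_attempts = 5000L * max(1L, n)) {
  stopifnot(inherits(grid, "pixel_grid"), n >= 0, min_spacing_um >= 0,
            perfused_fraction >= 0, perfused_fraction <= 1,
            length(radius_range_um) == 2, all(radius_range_um > 0))
  n <- as.integer(n)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      radius_um = numeric(0), perfused = logical(0))
  if (n == 0L) return(empty)
  W <- grid$width_px * grid$pixel_size_um
  H <- grid$height_px * grid$pixel_size_um
  rmax <- max(radius_range_um)
  if (2 * rmax >= W || 2 * rmax >= H)
    stop("vessel radius too large for the grid")
  with_seed(seed, {
    xs <- ys <- rs <- numeric(0)
    attempts <- 0L
    while (length(xs) < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(paste0("place_vessels: could not pack n=%d vessels with ",
                            "min_spacing_um=%g after %d attempts"),
                     n, min_spacing_um, max_attempts))
      x <- runif(1, rmax, W - rmax)
      y <- runif(1, rmax, H - rmax)
      if (length(xs) == 0 ||
          all((xs - x)^2 + (ys - y)^2 >= min_spacing_um^2)) {
        xs <- c(xs, x); ys <- c(ys, y)
        rs <- c(rs, runif(1, radius_range_um[1], radius_range_um[2]))
      }
    }
    k <- round(n * perfused_fraction)
    perf <- logical(n)
    if (k > 0) perf[sample.int(n, k)] <- TRUE
    data.frame(x_um = xs, y_um = ys, radius_um = rs, perfused = perf)
  })
}

#' Rasterize vessel lumens to a mask
#'
#' @param grid a [pixel_grid()].
#' @param vessels vessel table from [place_vessels()].
#' @param perfused_only keep only perfused lumens.
#' @return logical matrix; TRUE inside a lumen.
#' @export
vessel_lumen_mask <- function(grid, vessels, perfused_only = FALSE) {
  mask <- matrix(FALSE, grid$height_px, grid$width_px)
  if (perfused_only) vessels <- vessels[vessels$perfused, , drop = FALSE]
  if (nrow(vessels) == 0) return(mask)
  psz <- grid$pixel_size_um
  for (v in seq_len(nrow(vessels))) {
    r_px <- vessels$radius_um[v] / psz
    ci <- vessels$y_um[v] / psz + 0.5  # fractional row of the center
    cj <- vessels$x_um[v] / psz + 0.5
    ii <- max(1, floor(ci - r_px)):min(grid$height_px, ceiling(ci + r_px))
    jj <- max(1, floor(cj - r_px)):min(grid$width_px, ceiling(cj + r_px))
    d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
    mask[ii, jj] <- mask[ii, jj] | (d2 <= r_px^2)
  }
  mask
}

#' Solve the steady-state oxygen field
#'
#' Red-black successive over-relaxation for
#' \eqn{D \nabla^2 p = M p/(p+k_m)} with \eqn{p = p_v} fixed on perfused
#' lumen pixels and zero-flux domain boundary; consumption is lagged in the
#' local solve so iterates remain non-negative, and the field is clamped to
#' `[0, p_v]` (discrete maximum principle). Convergence is declared when the
#' maximum pointwise relaxation residual at non-source pixels drops below
#' `params$tol` (mmHg).
#'
#' @param grid a [pixel_grid()].
#' @param vessels vessel table from [place_vessels()]; only perfused vessels
#'   act as sources. With no perfused vessel the solution is identically 0.
#' @param params an [oxygen_params()] object.
#' @return matrix of pO2 (mmHg) with attributes `iterations` and
#'   `max_residual`.
#' @export
solve_oxygen <- function(grid, vessels, params = oxygen_params()) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(params, "oxygen_params"))
  dirichlet <- vessel_lumen_mask(grid, vessels, perfused_only = TRUE)
  if (!any(dirichlet)) {
    p <- matrix(0, grid$height_px, grid$width_px)
    attr(p, "iterations") <- 0L
    attr(p, "max_residual") <- 0
    return(p)
  }
  # coarse-to-fine initialization: a solution at half resolution (same
  # physical domain) seeds the fine relaxation, cutting sweep counts by
  # an order of magnitude on large grids
  init <- NULL
  if (min(grid$width_px, grid$height_px) >= 256) {
    coarse_grid <- pixel_grid(ceiling(grid$width_px / 2),
                              ceiling(grid$height_px / 2),
                              grid$pixel_size_um * 2)
    coarse <- solve_oxygen(coarse_grid, vessels, params)
    ri <- pmin(ceiling(seq_len(grid$height_px) / 2), coarse_grid$height_px)
    ci <- pmin(ceiling(seq_len(grid$width_px) / 2), coarse_grid$width_px)
    init <- coarse[ri, ci]
  }
  alpha <- grid$pixel_size_um^2 * params$M / params$D
  sol <- solve_oxygen_cpp(dirichlet, params$p_v, alpha, params$k_m,
                          params$tol, params$max_iter, params$omega, init)
  if (!sol$converged)
    stop(sprintf("solve_oxygen: no convergence after %d iterations (residual %.3g > tol %.3g)",
                 sol$iterations, sol$max_residual, params$tol))
  p <- sol$field
  attr(p, "iterations") <- sol$iterations
  attr(p, "max_residual") <- sol$max_residual
  p
}

#' Relaxation residual of an oxygen field
#'
#' Pointwise magnitude of one local Jacobi solve (mmHg); zero on Dirichlet
#' (perfused lumen) pixels. Used to assert solver convergence directly.
#'
#' @param oxygen solved field from [solve_oxygen()].
#' @param grid the [pixel_grid()] it was solved on.
#' @param vessels the vessel table used.
#' @param params the [oxygen_params()] used.
#' @return matrix of residuals (mmHg).
#' @export
oxygen_residual <- function(oxygen, grid, vessels, params) {
  dirichlet <- vessel_lumen_mask(grid, vessels, perfused_only = TRUE)
  alpha <- grid$pixel_size_um^2 * params$M / params$D
  oxygen_residual_cpp(oxygen, dirichlet, alpha, params$k_m)
}

#' Marker response fields from an oxygen field
#'
#' EF5 intensity follows a decreasing Hill curve of oxygen,
#' \eqn{\mathrm{ef5}(p) = A K_h^h / (K_h^h + p^h)}, zeroed inside necrosis
#' (the adduct forms only in viable cells); EdU-positive probability is the
#' saturating \eqn{e_{max}\, p/(p+K_p)}; necrosis is `oxygen < p_nec`.
#'
#' @param oxygen non-negative oxygen field, mmHg.
#' @param params a [marker_params()] object.
#' @param p_nec necrosis threshold, mmHg.
#' @return list with `ef5`, `edu_prob`, and logical `necrosis`.
#' @export
marker_fields <- function(oxygen, params = marker_params(), p_nec = 0.5) {
  if (any(oxygen < 0)) stop("marker_fields: oxygen must be >= 0")
  necrosis <- oxygen < p_nec
  ef5 <- params$ef5_amp * params$K_h^params$h /
    (params$K_h^params$h + oxygen^params$h)
  ef5[necrosis] <- 0
  edu_prob <- params$edu_max * oxygen / (oxygen + params$K_p)
  list(ef5 = ef5, edu_prob = edu_prob, necrosis = necrosis)
}

#' Sample phantom cell positions
#'
#' Dart-throwing placement of cell centers at a target density over the
#' habitable area (outside necrosis and vessel lumens), with a minimum
#' center spacing. Each cell's proliferation state is an independent
#' Bernoulli draw from the EdU-probability field at its location.
#'
#' @param grid a [pixel_grid()].
#' @param necrosis_mask logical matrix of necrotic pixels.
#' @param density_per_mm2 target cell density over habitable tissue.
#' @param min_spacing_um minimum center-to-center distance, um.
#' @param vessels vessel table; no center falls inside a lumen.
#' @param edu_prob_field per-pixel EdU-positive probability.
#' @param seed integer RNG seed.
#' @param max_attempt_factor sampling budget multiplier before giving up.
#' @return data.frame with `x_um`, `y_um`, `edu_prob`, `is_proliferating`.
#' @export
sample_cells <- function(grid, necrosis_mask, density_per_mm2,
                         min_spacing_um = 7, vessels = NULL,
                         edu_prob_field = NULL, seed = 1,
                         max_attempt_factor = 200) {
  stopifnot(inherits(grid, "pixel_grid"), density_per_mm2 >= 0)
  check_grid_image(necrosis_mask, grid, "necrosis_mask")
  psz <- grid$pixel_size_um
  W <- grid$width_px * psz
  H <- grid$height_px * psz
  lumen <- if (!is.null(vessels) && nrow(vessels) > 0)
    vessel_lumen_mask(grid, vessels) else
      matrix(FALSE, grid$height_px, grid$width_px)
  blocked <- as_mask(necrosis_mask) | lumen
  habitable_mm2 <- sum(!blocked) * psz^2 / 1e6
  n <- round(density_per_mm2 * habitable_mm2)
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      edu_prob = numeric(0), is_proliferating = logical(0))
  if (n == 0) return(empty)

  # occupancy grid with bin edge >= min spacing: only 3x3 neighborhoods
  # need checking for spacing violations
  bin <- max(min_spacing_um, 1e-6)
  nbx <- max(1L, ceiling(W / bin))
  nby <- max(1L, ceiling(H / bin))
  occ <- vector("list", nbx * nby)
  with_seed(seed, {
    xs <- ys <- numeric(n)
    placed <- 0L
    attempts <- 0L
    max_attempts <- max_attempt_factor * n
    while (placed < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(paste0("sample_cells: placed only %d of %d cells after %d ",
                            "attempts (density %g /mm^2, min_spacing %g um)"),
                     placed, n, max_attempts, density_per_mm2, min_spacing_um))
      x <- runif(1, 0, W); y <- runif(1, 0, H)
      i <- um_to_px(y, psz); j <- um_to_px(x, psz)
      i <- min(i, grid$height_px); j <- min(j, grid$width_px)
      if (blocked[i, j]) next
      bx <- min(nbx, 1L + as.integer(x / bin))
      by <- min(nby, 1L + as.integer(y / bin))
      ok <- TRUE
      if (min_spacing_um > 0) {
        for (dx in -1:1) for (dy in -1:1) {
          cx <- bx + dx; cy <- by + dy
          if (cx < 1L || cx > nbx || cy < 1L || cy > nby) next
          ids <- occ[[(cx - 1L) * nby + cy]]
          if (length(ids) &&
              any((xs[ids] - x)^2 + (ys[ids] - y)^2 < min_spacing_um^2)) {
            ok <- FALSE
            break
          }
        }
      }
      if (!ok) next
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      key <- (bx - 1L) * nby + by
      occ[[key]] <- c(occ[[key]], placed)
    }
    pr <- if (is.null(edu_prob_field)) rep(0, n) else {
      check_grid_image(edu_prob_field, grid, "edu_prob_field")
      edu_prob_field[cbind(pmin(um_to_px(ys, psz), grid$height_px),
                           pmin(um_to_px(xs, psz), grid$width_px))]
    }
    data.frame(x_um = xs, y_um = ys, edu_prob = pr,
               is_proliferating = runif(n) < pr)
  })
}

#' Ground-truth container for a phantom
#'
#' @param vessels vessel table.
#' @param oxygen solved oxygen field, mmHg.
#' @param necrosis_mask logical necrosis mask (`oxygen < p_nec`).
#' @param cells cell table with true state columns.
#' @param oxygen_par,marker_par parameter objects used.
#' @param seed master seed.
#' @return an object of class `phantom_truth`.
#' @export
phantom_truth <- function(vessels, oxygen, necrosis_mask, cells,
                          oxygen_par, marker_par, seed) {
  structure(list(vessels = vessels, oxygen = oxygen,
                 necrosis_mask = necrosis_mask, cells = cells,
                 oxygen_par = oxygen_par, marker_par = marker_par,
                 seed = seed),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d vessels (%d perfused), %d cells, %.1f%% necrotic area, seed %d\n",
              nrow(x$vessels), sum(x$vessels$perfused), nrow(x$cells),
              100 * mean(x$necrosis_mask), x$seed))
  invisible(x)
}

#' Co-registered multichannel image stack
#'
#' @param grid a [pixel_grid()].
#' @param channels named list of non-negative matrices; names among
#'   DAPI, Hoechst, CD31, EF5, EdU.
#' @return an object of class `channel_stack`.
#' @export
channel_stack <- function(grid, channels) {
  stopifnot(inherits(grid, "pixel_grid"), is.list(channels))
  known <- c("DAPI", "Hoechst", "CD31", "EF5", "EdU")
  bad <- setdiff(names(channels), known)
  if (length(bad))
    stop("unknown channel name(s): ", paste(bad, collapse = ", "))
  for (nm in names(channels)) {
    check_grid_image(channels[[nm]], grid, nm)
    if (any(channels[[nm]] < 0))
      stop(sprintf("channel %s has negative intensities", nm))
  }
  structure(list(grid = grid, channels = channels), class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  cat(sprintf("<channel_stack> %s on %d x %d px @ %g um/px\n",
              paste(names(x$channels), collapse = ", "),
              x$grid$height_px, x$grid$width_px, x$grid$pixel_size_um))
  invisible(x)
}

# accumulate a radially-symmetric patch f(squared um distance) around each
# (x_um, y_um) center into img, combining by sum or max
paint_blobs <- function(img, grid, x_um, y_um, radius_um, f, combine = "sum") {
  psz <- grid$pixel_size_um
  r_px <- radius_um / psz
  for (k in seq_along(x_um)) {
    ci <- y_um[k] / psz + 0.5
    cj <- x_um[k] / psz + 0.5
    ii <- max(1, floor(ci - r_px)):min(grid$height_px, ceiling(ci + r_px))
    jj <- max(1, floor(cj - r_px)):min(grid$width_px, ceiling(cj + r_px))
    d2 <- outer((ii - ci)^2, (jj - cj)^2, "+") * psz^2
    patch <- f(d2, k)
    if (combine == "sum") img[ii, jj] <- img[ii, jj] + patch
    else img[ii, jj] <- pmax(img[ii, jj], patch)
  }
  img
}

#' Render a phantom into a five-channel image stack
#'
#' DAPI: Gaussian nuclear blobs at every cell. EdU: the same blobs at
#' proliferating cells only. CD31: annular vessel walls for all vessels.
#' Hoechst: exponential halo `exp(-d/decay)` of distance to perfused lumens
#' only. EF5: the oxygen-derived EF5 field painted as cytoplasmic disks
#' around each cell. All channels get the additive background; Gaussian read
#' noise (sd `noise_sd`) is added and clipped at zero. With `noise_sd = 0`
#' the render is fully deterministic.
#'
#' @param grid a [pixel_grid()].
#' @param truth a [phantom_truth()].
#' @param params a [marker_params()].
#' @param seed RNG seed for the noise draw (ignored when `noise_sd = 0`).
#' @return a [channel_stack()].
#' @export
render_phantom <- function(grid, truth, params = marker_params(), seed = 1) {
  stopifnot(inherits(grid, "pixel_grid"), inherits(truth, "phantom_truth"))
  cells <- truth$cells
  zero <- matrix(0, grid$height_px, grid$width_px)
  # plateau-like nuclear profile: near-uniform disk with a soft shoulder,
  # so the thresholded nuclear area is insensitive to the exact threshold
  r2 <- params$nucleus_radius_um^2
  blob <- function(d2, k) params$dapi_amp * exp(-(d2 / r2)^4)
  blob_edu <- function(d2, k) params$edu_amp * exp(-(d2 / r2)^4)
  reach <- 2 * params$nucleus_radius_um

  dapi <- paint_blobs(zero, grid, cells$x_um, cells$y_um, reach, blob)

  prolif <- cells[cells$is_proliferating, , drop = FALSE]
  edu <- paint_blobs(zero, grid, prolif$x_um, prolif$y_um, reach, blob_edu)

  cd31 <- zero
  v <- truth$vessels
  if (nrow(v) > 0) {
    wall <- params$vessel_wall_um
    cd31 <- paint_blobs(zero, grid, v$x_um, v$y_um,
                        max(v$radius_um) + wall + 1,
                        function(d2, k) {
                          d <- sqrt(d2)
                          params$cd31_amp * (abs(d - v$radius_um[k]) <= wall)
                        }, combine = "max")
  }

  hoechst <- zero
  perf_lumen <- vessel_lumen_mask(grid, v, perfused_only = TRUE)
  if (any(perf_lumen)) {
    dperf <- sqrt(edt_sq_cpp(perf_lumen)) * grid$pixel_size_um
    hoechst <- params$hoechst_amp * exp(-dperf / params$hoechst_decay_um)
  }

  ef5 <- zero
  if (nrow(cells) > 0) {
    mk <- marker_fields(truth$oxygen, params, truth$oxygen_par$p_nec)
    psz <- grid$pixel_size_um
    vals <- mk$ef5[cbind(pmin(um_to_px(cells$y_um, psz), grid$height_px),
                         pmin(um_to_px(cells$x_um, psz), grid$width_px))]
    ef5 <- paint_blobs(zero, grid, cells$x_um, cells$y_um,
                       params$cell_radius_um,
                       function(d2, k) vals[k] * (d2 <= params$cell_radius_um^2),
                       combine = "max")
  }

  chans <- list(DAPI = dapi, Hoechst = hoechst, CD31 = cd31, EF5 = ef5,
                EdU = edu)
  finish <- function(m) m + params$background
  chans <- lapply(chans, finish)
  if (params$noise_sd > 0) {
    chans <- with_seed(seed, lapply(chans, function(m) {
      m + matrix(rnorm(length(m), 0, params$noise_sd), nrow(m), ncol(m))
    }))
  }
  chans <- lapply(chans, function(m) pmax(m, 0))
  channel_stack(grid, chans)
}

#' Generate a complete tumor phantom
#'
#' One-call orchestration: place vessels, solve the oxygen field, derive the
#' marker-response fields, sample cells, and render the channel stack. The
#' defaults (see [default_config()]) are calibrated so that anoxia sets in
#' roughly 150 um from a perfused vessel, the length scale typical of
#' diffusion-limited hypoxia.
#'
#' @param config configuration list, see [default_config()]; partial lists
#'   are completed with defaults.
#' @param seed master integer seed; all randomness (vessel placement, cell
#'   placement, proliferation draws, render noise) derives from it, so a
#'   fixed seed reproduces the phantom bit for bit.
#' @return list with elements `channels` (a [channel_stack()]) and `truth`
#'   (a [phantom_truth()]).
#' @export
make_phantom <- function(config = default_config(), seed = 1) {
  config <- merge_config(default_config(), config)
  g <- config$grid
  grid <- pixel_grid(g$width_px, g$height_px, config$pixel_size_um)
  oxp <- do.call(oxygen_params, config$oxygen)
  mkp <- do.call(marker_params, config$marker)
  seeds <- derive_seeds(seed, 3)

  vs <- place_vessels(grid, config$vessels$n_vessels,
                      config$vessels$min_spacing_um,
                      config$vessels$perfused_fraction,
                      config$vessels$radius_range_um, seed = seeds[1])
  oxy <- solve_oxygen(grid, vs, oxp)
  mk <- marker_fields(oxy, mkp, oxp$p_nec)
  cells <- sample_cells(grid, mk$necrosis, config$cells$density_per_mm2,
                        config$cells$min_spacing_um, vs, mk$edu_prob,
                        seed = seeds[2])
  psz <- grid$pixel_size_um
  if (nrow(cells) > 0) {
    cells$true_pO2 <- oxy[cbind(pmin(um_to_px(cells$y_um, psz), grid$height_px),
                                pmin(um_to_px(cells$x_um, psz), grid$width_px))]
  } else cells$true_pO2 <- numeric(0)
  cells$is_necrotic <- FALSE
  truth <- phantom_truth(vs, oxy, mk$necrosis, cells, oxp, mkp, seed)
  channels <- render_phantom(grid, truth, mkp, seed = seeds[3])
  list(channels = channels, truth = truth)
}
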
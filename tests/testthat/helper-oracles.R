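# Independent oracles and shared fixtures. Every oracle here is a direct,
# brute-force or closed-form computation kept independent of the package
# internals it checks.

# exhaustive nearest-target Euclidean distance (um)
bf_distance_map <- function(mask, pixel_size_um = 1) {
  tgt <- which(mask, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(tgt))) {
    best <- pmin(best, (rows - tgt[k, 1])^2 + (cols - tgt[k, 2])^2)
  }
  sqrt(best) * pixel_size_um
}

# per-pixel nearest-nucleus partition with ties to the lower label
bf_nearest_label <- function(labels, max_dist_px) {
  nr <- nrow(labels); nc <- ncol(labels)
  out <- labels
  tgt <- which(labels > 0L, arr.ind = TRUE)
  tlab <- labels[tgt]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (labels[i, j] > 0L) next
    d2 <- (tgt[, 1] - i)^2 + (tgt[, 2] - j)^2
    dmin <- min(d2)
    if (sqrt(dmin) <= max_dist_px + 1e-9) {
      out[i, j] <- min(tlab[d2 == dmin])
    }
  }
  out
}

# 1-D radial steady state of D(p'' + p'/r) = M p/(p+km) with p(rv)=pv,
# solved by bisection shooting on the initial slope: the physical branch
# decays to zero without crossing it
radial_oxygen_oracle <- function(op, r_vessel, r_max, dr = 0.25) {
  rhs <- function(r, y, pars) {
    ddp <- pars$M * max(y[1], 0) / (max(y[1], 0) + pars$km) / pars$D -
      y[2] / r
    list(c(y[2], ddp))
  }
  pars <- list(M = op$M, km = op$k_m, D = op$D)
  shoot <- function(s) {
    deSolve::ode(c(p = op$p_v, dp = s), seq(r_vessel, r_max, by = dr), rhs,
                 pars, method = "ode45")
  }
  lo <- -5; hi <- -0.01
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    out <- shoot(mid)
    if (min(out[, "p"]) < 0) lo <- mid else hi <- mid
  }
  out <- shoot((lo + hi) / 2)
  approxfun(out[, "time"], pmax(out[, "p"], 0), rule = 2)
}

# brute-force similarity fit: iteratively refined grid search over scale
# and rotation, translation closed-form per candidate
bf_fit_similarity <- function(src, dst, n_iter = 7, grid_n = 41) {
  obj <- function(s, th) {
    a <- complex(modulus = s, argument = th)
    z <- complex(real = src[, 1], imaginary = src[, 2])
    w <- complex(real = dst[, 1], imaginary = dst[, 2])
    t <- mean(w) - a * mean(z)
    mean(Mod(a * z + t - w)^2)
  }
  s_rng <- c(0.3, 3); th_rng <- c(-pi, pi)
  for (it in seq_len(n_iter)) {
    ss <- seq(s_rng[1], s_rng[2], length.out = grid_n)
    ths <- seq(th_rng[1], th_rng[2], length.out = grid_n)
    vals <- outer(ss, ths, Vectorize(obj))
    k <- arrayInd(which.min(vals), dim(vals))
    s_best <- ss[k[1]]; th_best <- ths[k[2]]
    ds <- diff(s_rng) / (grid_n - 1); dth <- diff(th_rng) / (grid_n - 1)
    s_rng <- c(s_best - 2 * ds, s_best + 2 * ds)
    th_rng <- c(th_best - 2 * dth, th_best + 2 * dth)
  }
  a <- complex(modulus = s_best, argument = th_best)
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- complex(real = dst[, 1], imaginary = dst[, 2])
  t <- mean(w) - a * mean(z)
  list(scale = s_best, theta = th_best, tx = Re(t), ty = Im(t),
       resolution = c(scale = ds, theta = dth))
}

# count strict 8-neighborhood local maxima above a floor (borders padded)
count_local_maxima <- function(img, floor_value) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  n <- 0L
  for (i in 2:(nr + 1)) for (j in 2:(nc + 1)) {
    v <- pad[i, j]
    if (v <= floor_value) next
    nb <- pad[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (sum(nb >= v) == 1L) n <- n + 1L
  }
  n
}

# draw a filled disk into a logical matrix (pixel-center rasterization)
disk_mask <- function(nr, nc, ci, cj, r) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if ((i - ci)^2 + (j - cj)^2 <= r^2) m[i, j] <- TRUE
  }
  m
}

# shared fixtures, built once per test run -------------------------------

.fixtures <- new.env(parent = emptyenv())

# full noise-free run of the default-configuration pipeline
default_noise_free_run <- function() {
  if (is.null(.fixtures$default_run)) {
    cfg <- default_config()
    cfg$marker$noise_sd <- 0
    .fixtures$default_run <- run_pipeline(cfg, seed = 11)
  }
  .fixtures$default_run
}

# small 512 um phantom with 4 vessels for unit-scale checks
small_phantom <- function() {
  if (is.null(.fixtures$small_phantom)) {
    cfg <- default_config()
    cfg$grid <- list(width_px = 512L, height_px = 512L)
    cfg$vessels$n_vessels <- 4L
    cfg$marker$noise_sd <- 0
    .fixtures$small_phantom <- make_phantom(cfg, seed = 4)
  }
  .fixtures$small_phantom
}

# synthetic cell table with scripted distances and intensities
scripted_cell_table <- function(n = 500, seed = 21) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             mean_EF5 = runif(n, 0, 120),
             mean_EdU = runif(n, 0, 200),
             dist_perfused_um = runif(n, 0, 750),
             dist_all_vessels_um = runif(n, 0, 750),
             dist_necrosis_um = NA_real_)
}
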
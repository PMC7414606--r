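# Shared fixtures and independent oracles for the test suite.

# Reduced scan geometry keeping the 12 um/px resolution of the full scan.
small_geometry <- function(n = 96L) {
  scan_geometry(grid_size_px = n, field_of_view_mm = 6 * n / 500)
}

small_params <- function(seed = 1L, n = 96L, ...) {
  scene_params(geometry = small_geometry(n), ga_radius_px = 15,
               ga_foci = 1L, drusen_count = 3L, vessel_density = 0.05,
               rng_seed = seed, ...)
}

# Scene size used for the parameter-recovery simulations: 128 px grid with
# an 18 px GA focus leaves the full 40 px modelling ring inside the scan.
recovery_params <- function(seed = 1L) {
  scene_params(geometry = small_geometry(128L), ga_radius_px = 18,
               ga_foci = 1L, drusen_count = 0L, vessel_density = 0,
               rng_seed = seed)
}

# Brute-force Euclidean distance from every pixel to the nearest TRUE pixel
# of `mask` (centre-to-centre), NA on the mask itself.
brute_distance_map <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j]) next
      out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2))
    }
  }
  out
}

# Independent Jeffreys-penalized log-likelihood, for oracle maximization.
penalized_loglik <- function(beta, X, y, w = rep(1, length(y))) {
  eta <- drop(X %*% beta)
  p <- plogis(eta)
  ll <- sum(w * (y * log(p) + (1 - y) * log1p(-p)))
  info <- crossprod(X, X * (w * p * (1 - p)))
  ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
}

# Oracle maximizer: coarse grid search refined by Nelder-Mead.
grid_maximize_penalized <- function(X, y, lim = 6, step = 0.25) {
  grid <- expand.grid(b0 = seq(-lim, lim, step), b1 = seq(-lim, lim, step))
  vals <- apply(grid, 1, function(b) penalized_loglik(b, X, y))
  start <- as.numeric(grid[which.max(vals), ])
  opt <- optim(start, function(b) -penalized_loglik(b, X, y),
               method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  opt$par
}

# Rasterized disk mask of given radius (px) centred on an n x n grid.
disk_mask <- function(n, radius_px, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  r <- matrix(seq_len(n), n, n)
  c <- matrix(seq_len(n), n, n, byrow = TRUE)
  (r - cy)^2 + (c - cx)^2 <= radius_px^2
}
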
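# Independent brute-force oracles, written against the definitions rather
# than the package internals.

# Gaussian KDE with full-covariance Scott bandwidth, evaluated by an
# explicit 2x2-inverse loop over sample points.
brute_kde <- function(x, eval_pts, bw_factor = NULL) {
  n <- nrow(x)
  f <- if (is.null(bw_factor)) n^(-1 / 6) else bw_factor
  H <- stats::cov(x) * f^2
  a <- H[1, 1]; b <- H[1, 2]; d <- H[2, 2]
  dt <- a * d - b^2
  i11 <- d / dt; i12 <- -b / dt; i22 <- a / dt
  out <- numeric(nrow(eval_pts))
  for (j in seq_len(n)) {
    dx <- eval_pts[, 1] - x[j, 1]
    dy <- eval_pts[, 2] - x[j, 2]
    q <- i11 * dx^2 + 2 * i12 * dx * dy + i22 * dy^2
    out <- out + exp(-0.5 * q)
  }
  out / (n * 2 * pi * sqrt(dt))
}

# per-cell mean and SD over a list of matrices by plain loops
brute_mean_sd <- function(mats, sample_denom = TRUE) {
  g <- nrow(mats[[1]])
  m <- length(mats)
  mean_out <- matrix(0, g, g)
  sd_out <- matrix(0, g, g)
  for (r in seq_len(g)) {
    for (c in seq_len(g)) {
      v <- vapply(mats, function(x) x[r, c], numeric(1))
      mean_out[r, c] <- sum(v) / m
      ss <- sum((v - mean_out[r, c])^2)
      sd_out[r, c] <- sqrt(ss / (if (sample_denom) m - 1 else m))
    }
  }
  list(mean = mean_out, sd = sd_out)
}

# count of cells where variant - mean exceeds sd, by plain loops
brute_exceed_count <- function(variant, mean_mat, sd_mat, absolute = FALSE) {
  cnt <- 0L
  for (r in seq_len(nrow(variant))) {
    for (c in seq_len(ncol(variant))) {
      d <- variant[r, c] - mean_mat[r, c]
      if (absolute) d <- abs(d)
      if (d > sd_mat[r, c]) cnt <- cnt + 1L
    }
  }
  cnt
}

# one-sample K-S statistic against a CDF by the sorted-point formula
brute_ks_stat <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  u <- cdf(x)
  dmax <- 0
  for (i in seq_len(n)) {
    dmax <- max(dmax, abs(i / n - u[i]), abs(u[i] - (i - 1) / n))
  }
  dmax
}

# quantile of a CDF by bisection
brute_quantile <- function(cdf, p, lower = 1e-12, upper = 1e6, tol = 1e-12) {
  for (i in 1:200) {
    mid <- (lower + upper) / 2
    if (cdf(mid) < p) lower <- mid else upper <- mid
    if (upper - lower < tol) break
  }
  (lower + upper) / 2
}

# small helper: a trajectory with one residue per frame at given times
traj_at_times <- function(times, source_id = "t", seed = 1) {
  set.seed(seed)
  n <- length(times)
  dihedral_trajectory(times, rep("RES-1", n),
                      phi = runif(n, -170, 170), psi = runif(n, -170, 170),
                      source_id = source_id)
}

# a clustered trajectory around one (phi, psi) center
cluster_traj <- function(n, center, sd = 4, seed = 1, source_id = "cluster") {
  set.seed(seed)
  dihedral_trajectory(time = seq_len(n) * 30, residue_tag = rep("RES-1", n),
                      phi = pmin(180, pmax(-180, rnorm(n, center[1], sd))),
                      psi = pmin(180, pmax(-180, rnorm(n, center[2], sd))),
                      source_id = source_id)
}

# random small density grids for scoring oracles
random_grids <- function(n_grids, grid_dim, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_grids), function(i) {
    density_grid(matrix(runif(grid_dim^2), grid_dim, grid_dim),
                 source_id = paste0("g", i))
  })
}
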
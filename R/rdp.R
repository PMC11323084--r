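#' Construct a Ramachandran density grid
#'
#' @param values `grid_dim x grid_dim` numeric matrix of non-negative
#'   densities (probability per square degree). Rows index \eqn{\phi} (the
#'   slow axis), columns index \eqn{\psi}.
#' @param source_id label of the ensemble the grid came from.
#' @param axis_min,axis_max axis bounds in degrees (default -180, 180).
#' @return an object of class `density_grid`.
#' @export
density_grid <- function(values, source_id = "unnamed",
                         axis_min = -180, axis_max = 180) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || nrow(values) < 2) {
    stop("density_grid: values must be a square matrix with grid_dim >= 2",
         call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("density_grid: densities must be non-negative", call. = FALSE)
  }
  structure(list(values = values, grid_dim = nrow(values),
                 axis_min = axis_min, axis_max = axis_max,
                 source_id = source_id),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid '%s': %dx%d over [%g, %g]^2, max density %.3g>\n",
              x$source_id, x$grid_dim, x$grid_dim, x$axis_min, x$axis_max,
              max(x$values)))
  invisible(x)
}

#' Cell-center coordinates of the uniform Ramachandran grid
#'
#' @param grid_dim number of cells per axis.
#' @param axis_min,axis_max axis bounds in degrees.
#' @return numeric vector of `grid_dim` cell centers,
#'   `axis_min + (k + 0.5) * (axis_max - axis_min) / grid_dim`.
#' @export
grid_centers <- function(grid_dim, axis_min = -180, axis_max = 180) {
  w <- (axis_max - axis_min) / grid_dim
  axis_min + (seq_len(grid_dim) - 0.5) * w
}

#' Convert a dihedral ensemble into a Ramachandran density plot
#'
#' Pools all residues and frames into one 2-D \eqn{(\phi, \psi)} sample and
#' evaluates a Gaussian kernel density estimate at the cell centers of a
#' uniform `grid_dim x grid_dim` grid over \[-180, 180\]^2. The bandwidth
#' matrix is the sample covariance scaled by Scott's factor
#' \eqn{n^{-1/3}} (i.e. \eqn{(n^{-1/(d+4)})^2} with \eqn{d = 2}), the
#' default of the common scientific-Python KDE implementation. Densities
#' are probability per square degree; the evaluated grid is not
#' renormalized.
#'
#' The \eqn{(\phi, \psi)} torus is not wrapped by default: a cluster at
#' +179 degrees does not contribute density near -179 degrees. Set
#' `wrap = TRUE` to sum the kernel over the eight +/-360-degree images of
#' every sample point.
#'
#' @param traj a `dihedral_trajectory` with at least 2 records and
#'   non-degenerate scatter.
#' @param grid_dim grid dimension per axis (default 32, giving 1024
#'   comparison points).
#' @param bw_factor optional scalar overriding Scott's factor; the
#'   bandwidth matrix is `cov(sample) * bw_factor^2`.
#' @param wrap logical; wrap kernel mass around the +/-180 degree seam.
#' @return a [density_grid()] carrying the trajectory's `source_id`.
#' @export
compute_rdp <- function(traj, grid_dim = 32, bw_factor = NULL, wrap = FALSE) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (!is.numeric(grid_dim) || grid_dim < 2) {
    stop("parameter error: grid_dim must be >= 2", call. = FALSE)
  }
  grid_dim <- as.integer(grid_dim)
  x <- cbind(traj$records$phi, traj$records$psi)
  n <- nrow(x)
  if (n < 2) {
    stop("validation error: need >= 2 dihedral records for a density estimate",
         call. = FALSE)
  }
  S <- stats::cov(x)
  if (!all(is.finite(S)) || det(S) <= .Machine$double.eps) {
    stop(paste("degenerate ensemble: sample covariance is singular",
               "(all points identical or collinear); add jitter or more frames"),
         call. = FALSE)
  }
  factor <- if (is.null(bw_factor)) n^(-1 / 6) else bw_factor
  if (!is.finite(factor) || factor <= 0) {
    stop("parameter error: bw_factor must be positive", call. = FALSE)
  }
  H <- S * factor^2
  centers <- grid_centers(grid_dim)
  grid <- cbind(rep(centers, times = grid_dim),   # phi varies within a column-block
                rep(centers, each = grid_dim))    # psi constant per block
  # grid rows are ordered psi-major here; reshape below puts phi on rows
  pts <- x
  if (wrap) {
    shifts <- as.matrix(expand.grid(c(-360, 0, 360), c(-360, 0, 360)))
    pts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(i) {
      sweep(x, 2, shifts[i, ], "+")
    }))
  }
  dens <- .gauss_kde_eval(pts, grid, H, n_norm = n)
  values <- matrix(dens, nrow = grid_dim, ncol = grid_dim)  # rows = phi, cols = psi
  density_grid(values, source_id = traj$source_id)
}

# Evaluate sum of Gaussian kernels with covariance H at the eval points,
# normalized by n_norm kernels. Chunked over eval rows to bound memory.
.gauss_kde_eval <- function(pts, eval_pts, H, n_norm) {
  R <- chol(H)                     # H = t(R) %*% R
  A <- backsolve(R, diag(2))      # R^{-1}; A %*% t(A) = H^{-1}
  wp <- pts %*% A
  we <- eval_pts %*% A
  norm_const <- n_norm * 2 * pi * prod(diag(R))
  p2 <- rowSums(wp^2)
  out <- numeric(nrow(we))
  chunk <- max(1L, floor(4e6 / nrow(wp)))
  i <- 1L
  while (i <= nrow(we)) {
    j <- min(i + chunk - 1L, nrow(we))
    e <- we[i:j, , drop = FALSE]
    d2 <- outer(rowSums(e^2), p2, "+") - 2 * tcrossprod(e, wp)
    d2[d2 < 0] <- 0
    out[i:j] <- rowSums(exp(-0.5 * d2))
    i <- j + 1L
  }
  out / norm_const
}

#' Elementwise difference of two density grids
#'
#' Produces the signed difference image `a - b` used to visualize where a
#' variant's Ramachandran density diminished or increased relative to a
#' reference. Intended for visualization export; the deviation statistic is
#' computed by [compute_deviation()].
#'
#' @param a,b `density_grid` objects with identical `grid_dim` and axes.
#' @return a `grid_dim x grid_dim` signed numeric matrix.
#' @export
rdp_difference_image <- function(a, b) {
  stopifnot(inherits(a, "density_grid"), inherits(b, "density_grid"))
  .check_same_grid(a, b)
  a$values - b$values
}

.check_same_grid <- function(a, b) {
  if (a$grid_dim != b$grid_dim || a$axis_min != b$axis_min ||
      a$axis_max != b$axis_max) {
    stop(sprintf("validation error: grid shape mismatch (%dx%d vs %dx%d)",
                 a$grid_dim, a$grid_dim, b$grid_dim, b$grid_dim), call. = FALSE)
  }
  invisible(TRUE)
}

#' Export / import a density grid as TSV
#'
#' The TSV holds one row per grid cell with columns `phi_center`,
#' `psi_center`, `density`, in row-major order with \eqn{\phi} as the slow
#' axis (all \eqn{\psi} for the first \eqn{\phi}, then the next \eqn{\phi}).
#'
#' @param grid a `density_grid`.
#' @param path output path.
#' @return `path` (write) or a `density_grid` (read).
#' @export
write_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  ctr <- grid_centers(grid$grid_dim, grid$axis_min, grid$axis_max)
  df <- data.frame(phi_center = rep(ctr, each = grid$grid_dim),
                   psi_center = rep(ctr, times = grid$grid_dim),
                   density = as.vector(t(grid$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_tsv
#' @param source_id label for the imported grid.
#' @export
read_grid_tsv <- function(path, source_id = NULL) {
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("phi_center", "psi_center", "density")
  if (!all(need %in% names(df))) {
    stop("validation error: grid TSV must have columns phi_center, psi_center, density",
         call. = FALSE)
  }
  g <- as.integer(round(sqrt(nrow(df))))
  if (g * g != nrow(df)) {
    stop("validation error: grid TSV row count is not a perfect square", call. = FALSE)
  }
  values <- t(matrix(df$density, nrow = g, ncol = g))  # undo row-major phi-slow
  density_grid(values, source_id = source_id)
}

#' Export / import a density grid as JSON
#'
#' JSON object with `grid_dim`, `axis_min`, `axis_max`, `source_id`, and
#' `values` flattened row-major with \eqn{\phi} as the slow axis.
#'
#' @inheritParams write_grid_tsv
#' @export
write_grid_json <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  obj <- list(grid_dim = grid$grid_dim, axis_min = grid$axis_min,
              axis_max = grid$axis_max, source_id = grid$source_id,
              order = "row-major, phi slow",
              values = as.vector(t(grid$values)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- as.integer(obj$grid_dim)
  values <- t(matrix(as.numeric(obj$values), nrow = g, ncol = g))
  density_grid(values, source_id = obj$source_id,
               axis_min = obj$axis_min, axis_max = obj$axis_max)
}
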
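#' Build a baseline model from reference density grids
#'
#' The baseline ("based file") is the per-grid-point mean and standard
#' deviation over the Ramachandran density grids of known benign variants
#' and wildtype ensembles. Variant grids are scored by how many grid points
#' deviate from this mean beyond the reference standard deviation.
#'
#' @param reference_grids list of `density_grid` objects, length
#'   `n_benign + n_wildtype` (>= 2), all sharing shape and axes.
#' @param n_benign,n_wildtype counts of benign-variant and wildtype grids in
#'   the list (bookkeeping only; all grids are pooled equally in the mean).
#' @param sd_mode `"per_grid"` (default) computes one standard deviation per
#'   grid point; `"scalar"` uses the single SD of all reference grid values
#'   pooled, replicated over the grid.
#' @param sd_denominator `"sample"` (default, divisor `i + j - 1`) or
#'   `"population"` (divisor `i + j`).
#' @return an object of class `baseline_model` with elements `mean_grid`
#'   (a `density_grid`), `sd_grid` (matrix of non-negative reals),
#'   `n_benign`, `n_wildtype`, `member_ids`, `sd_mode`, `sd_denominator`.
#' @export
build_baseline <- function(reference_grids, n_benign, n_wildtype,
                           sd_mode = c("per_grid", "scalar"),
                           sd_denominator = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  sd_denominator <- match.arg(sd_denominator)
  m <- length(reference_grids)
  if (m < 2) {
    stop("validation error: need >= 2 reference grids", call. = FALSE)
  }
  if (m != n_benign + n_wildtype) {
    stop("validation error: length(reference_grids) must equal n_benign + n_wildtype",
         call. = FALSE)
  }
  if (!all(vapply(reference_grids, inherits, logical(1), "density_grid"))) {
    stop("validation error: reference_grids must be density_grid objects", call. = FALSE)
  }
  first <- reference_grids[[1]]
  for (g in reference_grids[-1]) .check_same_grid(first, g)
  gdim <- first$grid_dim
  arr <- array(unlist(lapply(reference_grids, `[[`, "values")),
               dim = c(gdim, gdim, m))
  mean_vals <- apply(arr, c(1, 2), mean)
  denom <- if (sd_denominator == "sample") m - 1 else m
  if (sd_mode == "per_grid") {
    ss <- apply(sweep(arr, c(1, 2), mean_vals)^2, c(1, 2), sum)
    sd_vals <- sqrt(ss / denom)
  } else {
    all_vals <- as.vector(arr)
    pooled_n <- length(all_vals)
    pooled_denom <- if (sd_denominator == "sample") pooled_n - 1 else pooled_n
    s <- sqrt(sum((all_vals - mean(all_vals))^2) / pooled_denom)
    sd_vals <- matrix(s, gdim, gdim)
  }
  structure(list(
    mean_grid = density_grid(mean_vals, source_id = "baseline",
                             axis_min = first$axis_min, axis_max = first$axis_max),
    sd_grid = sd_vals,
    n_benign = n_benign,
    n_wildtype = n_wildtype,
    member_ids = vapply(reference_grids, `[[`, character(1), "source_id"),
    sd_mode = sd_mode,
    sd_denominator = sd_denominator
  ), class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model: %d benign + %d wildtype members, %dx%d grid, SD mode '%s'>\n",
              x$n_benign, x$n_wildtype, x$mean_grid$grid_dim,
              x$mean_grid$grid_dim, x$sd_mode))
  invisible(x)
}

#' Score a variant grid against the baseline
#'
#' Computes the deviation grid \eqn{\chi_d = \chi_t - \chi_b} (variant minus
#' baseline mean), marks each grid point 1 where the deviation exceeds the
#' reference standard deviation \eqn{S} at that point and 0 otherwise, and
#' summarizes the exceedance as the fraction \eqn{G} of the
#' `grid_dim^2` points, its percentage, and the structural-deviation score
#' \eqn{\ln(100 G)}.
#'
#' `mode = "literal"` applies the one-sided rule \eqn{\chi_d > S} (density
#' increases only); `mode = "absolute"` flags \eqn{|\chi_d| > S} so that
#' diminished density also counts.
#'
#' When no grid point exceeds (\eqn{G = 0}) the log score is undefined; the
#' `score` field is then `-Inf` and downstream classification reports the
#' label `"undefined"`.
#'
#' @param variant_grid a `density_grid` for the variant ensemble.
#' @param baseline a [build_baseline()] model with matching shape.
#' @param mode exceedance sidedness, `"literal"` or `"absolute"`.
#' @param variant_id label for the result; defaults to the grid's
#'   `source_id`.
#' @return an object of class `deviation_result` with elements `variant_id`,
#'   `diff_grid` (signed matrix), `binary_grid` (0/1 matrix),
#'   `exceed_fraction`, `exceed_percent`, `score`, `n_points`, `mode`.
#' @export
compute_deviation <- function(variant_grid, baseline,
                              mode = c("literal", "absolute"),
                              variant_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(variant_grid, "density_grid"),
            inherits(baseline, "baseline_model"))
  .check_same_grid(variant_grid, baseline$mean_grid)
  if (is.null(variant_id)) variant_id <- variant_grid$source_id
  diff <- variant_grid$values - baseline$mean_grid$values
  dev <- if (mode == "literal") diff else abs(diff)
  binary <- (dev > baseline$sd_grid) * 1
  n_points <- length(binary)
  g <- sum(binary) / n_points
  pct <- 100 * g
  score <- if (pct > 0) log(pct) else -Inf
  structure(list(variant_id = variant_id, diff_grid = diff,
                 binary_grid = binary, exceed_fraction = g,
                 exceed_percent = pct, score = score,
                 n_points = n_points, mode = mode),
            class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  cat(sprintf("<deviation_result '%s': %.1f%% of %d grid points exceed; score %s>\n",
              x$variant_id, x$exceed_percent, x$n_points,
              if (is.finite(x$score)) sprintf("%.3f", x$score) else "undefined"))
  invisible(x)
}

#' Structural-deviation score from an exceedance percentage
#'
#' The score is the natural log of the percentage of grid points whose
#' density deviates beyond the reference standard deviation: an exceedance
#' of 48.3% scores ln(48.3) = 3.88, of 49.9% scores 3.91 (2 d.p.).
#'
#' @param exceed_percent percentage in (0, 100].
#' @return `log(exceed_percent)`.
#' @export
score_from_percent <- function(exceed_percent) {
  if (!is.numeric(exceed_percent) || anyNA(exceed_percent)) {
    stop("domain error: exceed_percent must be numeric", call. = FALSE)
  }
  if (any(exceed_percent <= 0)) {
    stop("domain error: exceed_percent must be > 0 (log of non-positive percentage)",
         call. = FALSE)
  }
  if (any(exceed_percent > 100)) {
    stop("domain error: exceed_percent cannot exceed 100", call. = FALSE)
  }
  log(exceed_percent)
}

#' Classify a structural-deviation score against a threshold
#'
#' Scores strictly greater than the threshold are labelled `"deleterious"`,
#' scores less than or equal to it `"non-deleterious"` (a score exactly at
#' the threshold is non-deleterious). A `-Inf` sentinel score (no grid point
#' exceeded) yields the label `"undefined"` with a warning.
#'
#' @param variant_id label carried into the result.
#' @param score structural-deviation score, or `-Inf`.
#' @param threshold finite decision threshold; 3.46 is the packaged default
#'   profile for the p53 DNA-binding domain.
#' @return an object of class `classification` with `variant_id`, `score`,
#'   `threshold`, `label`.
#' @export
classify_score <- function(variant_id, score, threshold = 3.46) {
  if (!is.numeric(threshold) || !is.finite(threshold)) {
    stop("parameter error: threshold must be finite", call. = FALSE)
  }
  if (!is.numeric(score) || is.na(score)) {
    stop("parameter error: score must be numeric", call. = FALSE)
  }
  if (identical(score, -Inf)) {
    warning(sprintf("variant %s: no grid point exceeded the baseline SD; score undefined (leaning non-deleterious)",
                    variant_id))
    label <- "undefined"
  } else if (score > threshold) {
    label <- "deleterious"
  } else {
    label <- "non-deleterious"
  }
  structure(list(variant_id = variant_id, score = score,
                 threshold = threshold, label = label),
            class = "classification")
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf("<classification '%s': score %s vs threshold %.2f -> %s>\n",
              x$variant_id,
              if (is.finite(x$score)) sprintf("%.3f", x$score) else "undefined",
              x$threshold, x$label))
  invisible(x)
}

#' Serialize / deserialize a baseline model as JSON
#'
#' Grids are stored flattened row-major with \eqn{\phi} as the slow axis.
#'
#' @param baseline a `baseline_model`.
#' @param path file path.
#' @export
write_baseline_json <- function(baseline, path) {
  stopifnot(inherits(baseline, "baseline_model"))
  g <- baseline$mean_grid
  obj <- list(grid_dim = g$grid_dim, axis_min = g$axis_min, axis_max = g$axis_max,
              n_benign = baseline$n_benign, n_wildtype = baseline$n_wildtype,
              member_ids = as.list(baseline$member_ids),
              sd_mode = baseline$sd_mode, sd_denominator = baseline$sd_denominator,
              mean_values = as.vector(t(g$values)),
              sd_values = as.vector(t(baseline$sd_grid)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_baseline_json
#' @export
read_baseline_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  gdim <- as.integer(obj$grid_dim)
  mean_vals <- t(matrix(as.numeric(obj$mean_values), gdim, gdim))
  sd_vals <- t(matrix(as.numeric(obj$sd_values), gdim, gdim))
  structure(list(
    mean_grid = density_grid(mean_vals, source_id = "baseline",
                             axis_min = obj$axis_min, axis_max = obj$axis_max),
    sd_grid = sd_vals,
    n_benign = as.integer(obj$n_benign),
    n_wildtype = as.integer(obj$n_wildtype),
    member_ids = as.character(unlist(obj$member_ids)),
    sd_mode = obj$sd_mode,
    sd_denominator = obj$sd_denominator
  ), class = "baseline_model")
}

#' Flatten deviation results into an export table
#'
#' @param results list of `deviation_result` objects (or a single one).
#' @param threshold classification threshold applied to each score.
#' @return data.frame with columns `variant_id`, `exceed_percent`, `score`,
#'   `label`, `threshold`.
#' @export
deviation_table <- function(results, threshold = 3.46) {
  if (inherits(results, "deviation_result")) results <- list(results)
  if (!length(results)) {
    return(data.frame(variant_id = character(), exceed_percent = numeric(),
                      score = numeric(), label = character(),
                      threshold = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(results, function(r) {
    cls <- withCallingHandlers(
      classify_score(r$variant_id, r$score, threshold),
      warning = function(w) invokeRestart("muffleWarning")
    )
    data.frame(variant_id = r$variant_id,
               exceed_percent = r$exceed_percent,
               score = r$score, label = cls$label,
               threshold = threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
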
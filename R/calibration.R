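#' Construct a score sample for calibration
#'
#' @param group `"benign"` or `"pathogenic"`.
#' @param scores numeric vector of structural-deviation scores, all > 0
#'   (positivity is required for log-normal fitting), length >= 3.
#' @param source_ids optional labels, one per score.
#' @return an object of class `score_sample`.
#' @export
score_sample <- function(group = c("benign", "pathogenic"), scores,
                         source_ids = NULL) {
  group <- match.arg(group)
  scores <- as.numeric(scores)
  if (length(scores) < 3) {
    stop("validation error: need >= 3 scores per group", call. = FALSE)
  }
  bad <- which(!is.finite(scores) | scores <= 0)
  if (length(bad)) {
    stop(sprintf("domain error: non-positive scores at positions %s (log-normal fit requires scores > 0)",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (is.null(source_ids)) source_ids <- paste0(group, "_", seq_along(scores))
  structure(list(group = group, scores = scores, source_ids = source_ids),
            class = "score_sample")
}

.as_scores <- function(x) {
  if (inherits(x, "score_sample")) x$scores else as.numeric(x)
}

#' Maximum-likelihood log-normal fit
#'
#' Closed-form MLE on the log scale: `mu_log` is the mean of `log(scores)`
#' and `sigma_log` the standard deviation of `log(scores)` with divisor `n`
#' (the MLE, not the sample divisor `n - 1`).
#'
#' @param sample a [score_sample()] or a positive numeric vector (n >= 3).
#' @return list with `mu_log` and `sigma_log` (> 0).
#' @export
fit_lognormal <- function(sample) {
  x <- .as_scores(sample)
  if (length(x) < 3) stop("validation error: need >= 3 scores", call. = FALSE)
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad)) {
    stop(sprintf("domain error: non-positive scores at positions %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  lx <- log(x)
  mu <- mean(lx)
  sigma <- sqrt(mean((lx - mu)^2))
  if (sigma <= 0) {
    stop("degenerate fit: all scores identical, sigma_log must be > 0", call. = FALSE)
  }
  list(mu_log = mu, sigma_log = sigma)
}

#' Goodness of fit of a log-normal against a score sample
#'
#' One-sample Kolmogorov–Smirnov test of the scores against the fitted
#' log-normal CDF, plus the Anderson–Darling statistic
#' \deqn{A^2 = -n - \frac{1}{n}\sum_{i=1}^n (2i - 1)\,[\ln u_i + \ln(1 - u_{n+1-i})]}
#' where \eqn{u_i} are the fitted CDF values of the sorted scores. Both
#' treat the fitted parameters as fully specified; when the parameters were
#' estimated from the same sample the tests are approximate (slightly
#' conservative p-values), a standard caveat of plug-in goodness-of-fit.
#'
#' Scores derived from binary grid counts take at most `grid_dim^2 + 1`
#' distinct values, so ties can occur; the standard one-sample formulation
#' is applied and the K-S p-value is then approximate.
#'
#' @param sample a [score_sample()] or positive numeric vector, n >= 3.
#' @param fit list with `mu_log`, `sigma_log` as from [fit_lognormal()].
#' @param alpha rejection level reported alongside the p-value.
#' @return list with `ks_statistic`, `ks_p`, `ad_statistic`,
#'   `rejected_at_alpha` (logical, from the K-S p-value).
#' @export
goodness_of_fit <- function(sample, fit, alpha = 0.05) {
  x <- .as_scores(sample)
  n <- length(x)
  if (n < 3) stop("validation error: need >= 3 scores", call. = FALSE)
  ks <- suppressWarnings(
    stats::ks.test(x, "plnorm", meanlog = fit$mu_log, sdlog = fit$sigma_log)
  )
  u <- stats::plnorm(sort(x), meanlog = fit$mu_log, sdlog = fit$sigma_log)
  eps <- .Machine$double.eps
  u <- pmin(pmax(u, eps), 1 - eps)
  i <- seq_len(n)
  a2 <- -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       ad_statistic = a2, rejected_at_alpha = ks$p.value < alpha)
}

#' Two-sided Welch t-test between benign and pathogenic scores
#'
#' Tests whether the two groups' mean structural-deviation scores differ,
#' using the unequal-variance (Welch) form on the raw scores.
#'
#' @param benign,pathogenic [score_sample()] objects or numeric vectors,
#'   each n >= 3.
#' @return list with `t_statistic` (first group minus second) and
#'   `p_two_sided`.
#' @export
test_separation <- function(benign, pathogenic) {
  x <- .as_scores(benign)
  y <- .as_scores(pathogenic)
  if (length(x) < 3 || length(y) < 3) {
    stop("validation error: need >= 3 scores per group", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      # identical constant groups: no separation by definition
      return(list(t_statistic = 0, p_two_sided = 1))
    }
    stop("degenerate variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  list(t_statistic = unname(tt$statistic), p_two_sided = tt$p.value)
}

#' Deleteriousness threshold from the pathogenic log-normal fit
#'
#' Returns the quantile of the fitted pathogenic log-normal below which
#' `percentile` of its mass lies, i.e.
#' `exp(mu_log + sigma_log * qnorm(percentile))`. The default
#' `percentile = 0.05` places 95% of the fitted pathogenic scores above the
#' threshold, a deliberate margin against statistical error in the fit: a
#' pathogenic variant whose score falls in the lowest 5% tail is allowed to
#' be missed rather than inflating false deleterious calls.
#'
#' @param pathogenic_fit list with `mu_log`, `sigma_log` (> 0).
#' @param percentile lower-tail probability in (0, 1).
#' @return the threshold score.
#' @export
derive_threshold <- function(pathogenic_fit, percentile = 0.05) {
  if (!is.numeric(percentile) || percentile <= 0 || percentile >= 1) {
    stop("parameter error: percentile must be in (0, 1)", call. = FALSE)
  }
  if (pathogenic_fit$sigma_log <= 0) {
    stop("parameter error: sigma_log must be > 0", call. = FALSE)
  }
  stats::qlnorm(percentile, meanlog = pathogenic_fit$mu_log,
                sdlog = pathogenic_fit$sigma_log)
}

#' Calibrate the deleteriousness threshold from labelled score sets
#'
#' Fits log-normal distributions to the benign and pathogenic score groups,
#' reports per-group Kolmogorov–Smirnov and Anderson–Darling goodness of
#' fit, tests group separation with a two-sided Welch t-test, and derives
#' the decision threshold as a lower quantile of the fitted pathogenic
#' distribution.
#'
#' @param benign,pathogenic [score_sample()] objects or positive numeric
#'   vectors (n >= 3 each).
#' @param percentile lower-tail probability for [derive_threshold()].
#' @return an object of class `calibration_result` with `benign_fit`,
#'   `pathogenic_fit`, `benign_gof`, `pathogenic_gof`, `separation`
#'   (`t_statistic`, `p_two_sided`), `threshold`, `threshold_percentile`.
#' @export
calibrate <- function(benign, pathogenic, percentile = 0.05) {
  bfit <- fit_lognormal(benign)
  pfit <- fit_lognormal(pathogenic)
  structure(list(
    benign_fit = bfit,
    pathogenic_fit = pfit,
    benign_gof = goodness_of_fit(benign, bfit),
    pathogenic_gof = goodness_of_fit(pathogenic, pfit),
    separation = test_separation(benign, pathogenic),
    threshold = derive_threshold(pfit, percentile),
    threshold_percentile = percentile,
    n_benign = length(.as_scores(benign)),
    n_pathogenic = length(.as_scores(pathogenic))
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<calibration_result>\n",
    "  benign fit:     mu_log %.4f, sigma_log %.4f (n = %d)\n",
    "  pathogenic fit: mu_log %.4f, sigma_log %.4f (n = %d)\n",
    "  K-S p (benign / pathogenic): %.3g / %.3g\n",
    "  separation: t = %.3f, two-sided p = %.3g\n",
    "  threshold (lower %.0f%% pathogenic quantile): %.4f\n"),
    x$benign_fit$mu_log, x$benign_fit$sigma_log, x$n_benign,
    x$pathogenic_fit$mu_log, x$pathogenic_fit$sigma_log, x$n_pathogenic,
    x$benign_gof$ks_p, x$pathogenic_gof$ks_p,
    x$separation$t_statistic, x$separation$p_two_sided,
    100 * x$threshold_percentile, x$threshold))
  invisible(x)
}

#' Calibrate from a score table file
#'
#' Reads a TSV with header columns `variant_id`, `group`, `score` (groups
#' `benign` and `pathogenic`) and runs [calibrate()].
#'
#' @param path input TSV path.
#' @param percentile passed to [calibrate()].
#' @return a `calibration_result`.
#' @export
calibrate_from_tsv <- function(path, percentile = 0.05) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_id", "group", "score")
  if (!all(need %in% names(df))) {
    stop("validation error: score TSV must have columns variant_id, group, score",
         call. = FALSE)
  }
  b <- df[df$group == "benign", ]
  p <- df[df$group == "pathogenic", ]
  calibrate(score_sample("benign", b$score, b$variant_id),
            score_sample("pathogenic", p$score, p$variant_id),
            percentile = percentile)
}

#' Serialize a calibration result as JSON
#'
#' @param calibration a `calibration_result`.
#' @param path output path.
#' @export
write_calibration_json <- function(calibration, path) {
  stopifnot(inherits(calibration, "calibration_result"))
  jsonlite::write_json(unclass(calibration), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' The packaged default decision profile
#'
#' Returns the frozen default calibration profile for the p53 DNA-binding
#' domain shipped with the package: threshold 3.46 at the lower 5%
#' pathogenic quantile. Used when no pathogenic training scores are
#' available to calibrate from.
#'
#' @return list with `protein`, `threshold`, `threshold_percentile`, `notes`.
#' @export
default_profile <- function() {
  path <- system.file("extdata", "tp53_dbd_profile.json", package = "rdpscore",
                      mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
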
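test_that("log-normal MLE has its closed form and guards degeneracy", {
  fit <- fit_lognormal(c(exp(1), exp(1), exp(3), exp(3)))
  expect_equal(fit$mu_log, 2)
  expect_equal(fit$sigma_log, 1)

  expect_error(fit_lognormal(rep(exp(2), 5)), "degenerate")
  expect_error(fit_lognormal(c(1, 2, -3, 4)), "positions 3")
  expect_error(fit_lognormal(c(1, 2)), ">= 3")
})

test_that("parameters are recovered within tight bounds at n = 10^4", {
  set.seed(123)
  x <- rlnorm(10000, meanlog = 1.25, sdlog = 0.05)
  fit <- fit_lognormal(x)
  expect_lt(abs(fit$mu_log - 1.25), 0.01)
  expect_lt(abs(fit$sigma_log - 0.05), 0.005)
})

test_that("the MLE agrees with an independent fitting package", {
  set.seed(7)
  x <- rlnorm(500, meanlog = 1.1, sdlog = 0.3)
  fit <- fit_lognormal(x)
  ref <- fitdistrplus::fitdist(x, "lnorm")
  expect_equal(fit$mu_log, unname(ref$estimate["meanlog"]), tolerance = 1e-4)
  expect_equal(fit$sigma_log, unname(ref$estimate["sdlog"]), tolerance = 1e-4)
})

test_that("the K-S statistic equals the brute-force sorted-point maximum", {
  set.seed(9)
  for (rep in 1:5) {
    x <- rlnorm(40, 1, 0.4)
    fit <- fit_lognormal(x)
    gof <- goodness_of_fit(x, fit)
    want <- brute_ks_stat(x, function(v) plnorm(v, fit$mu_log, fit$sigma_log))
    expect_equal(gof$ks_statistic, want, tolerance = 1e-12)
  }
})

test_that("goodness of fit accepts the generating distribution and rejects a shifted one", {
  accepted <- 0L
  n_reps <- 20L
  for (i in seq_len(n_reps)) {
    set.seed(1000 + i)
    x <- rlnorm(300, meanlog = 1.3, sdlog = 0.2)
    gof <- goodness_of_fit(x, list(mu_log = 1.3, sigma_log = 0.2))
    if (gof$ks_p > 0.05) accepted <- accepted + 1L
    expect_gt(gof$ad_statistic, 0)
  }
  expect_gte(accepted, 0.9 * n_reps)

  set.seed(77)
  y <- rlnorm(300, meanlog = 2.3, sdlog = 0.2)
  shifted <- goodness_of_fit(y, list(mu_log = 1.3, sigma_log = 0.2))
  expect_lt(shifted$ks_p, 0.05)
  expect_true(shifted$rejected_at_alpha)
})

test_that("group separation uses the two-sided Welch form with expected identities", {
  x <- c(1, 2, 3, 4)
  same <- test_separation(x, x)
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_two_sided, 1)

  # identical constant groups are no separation, not an error
  const <- test_separation(rep(2, 4), rep(2, 4))
  expect_equal(const$t_statistic, 0)
  expect_equal(const$p_two_sided, 1)
  expect_error(test_separation(rep(1, 4), rep(2, 4)), "degenerate")

  set.seed(11)
  a <- rnorm(20, 0, 1)
  b <- rnorm(20, 10, 1)  # ten pooled SDs apart
  sep <- test_separation(a, b)
  expect_lt(sep$p_two_sided, 1e-4)

  swapped <- test_separation(b, a)
  expect_equal(swapped$t_statistic, -sep$t_statistic)
  expect_equal(swapped$p_two_sided, sep$p_two_sided)
})

test_that("the derived threshold is the exact fitted quantile", {
  fit <- list(mu_log = log(3.7), sigma_log = 0.12)
  expect_equal(derive_threshold(fit, 0.5), 3.7)

  cdf <- function(v) plnorm(v, fit$mu_log, fit$sigma_log)
  for (p in c(0.01, 0.05, 0.25, 0.9)) {
    thr <- derive_threshold(fit, p)
    expect_equal(thr, brute_quantile(cdf, p), tolerance = 1e-9)
    expect_equal(cdf(thr), p, tolerance = 1e-9)
  }

  ps <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(vapply(ps, derive_threshold,
                              numeric(1), pathogenic_fit = fit)) > 0))
  expect_error(derive_threshold(fit, 0), "percentile")
  expect_error(derive_threshold(fit, 1.2), "percentile")
  expect_error(derive_threshold(list(mu_log = 1, sigma_log = 0), 0.05), "sigma")
})

test_that("threshold recovery at n = 26 is accurate and stable across seed sets", {
  true_fit <- list(mu_log = log(3.7), sigma_log = 0.15)
  true_thr <- derive_threshold(true_fit, 0.05)
  med_err <- function(seed_base) {
    errs <- vapply(1:100, function(i) {
      set.seed(seed_base + i)
      x <- rlnorm(26, true_fit$mu_log, true_fit$sigma_log)
      abs(derive_threshold(fit_lognormal(x), 0.05) - true_thr)
    }, numeric(1))
    median(errs)
  }
  e1 <- med_err(2000)
  e2 <- med_err(6000)
  expect_lt(e1, 0.2)
  expect_lt(e2, 0.2)
  expect_lt(abs(e1 - e2), 0.1)
})

test_that("calibrate assembles fits, diagnostics, separation, and threshold", {
  set.seed(21)
  benign <- rlnorm(18, meanlog = 0.8, sdlog = 0.3)
  pathogenic <- rlnorm(26, meanlog = 1.4, sdlog = 0.15)
  cal <- calibrate(score_sample("benign", benign),
                   score_sample("pathogenic", pathogenic))
  expect_s3_class(cal, "calibration_result")
  expect_lt(cal$separation$p_two_sided, 0.05)
  expect_equal(cal$threshold,
               derive_threshold(cal$pathogenic_fit, 0.05))
  expect_gt(cal$benign_fit$sigma_log, 0)
  expect_gt(cal$pathogenic_fit$sigma_log, 0)

  f <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$threshold, cal$threshold, tolerance = 1e-12)

  # TSV entry point
  tsv <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(variant_id = c(paste0("b", 1:18), paste0("p", 1:26)),
                   group = c(rep("benign", 18), rep("pathogenic", 26)),
                   score = c(benign, pathogenic))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  cal2 <- calibrate_from_tsv(tsv)
  expect_equal(cal2$threshold, cal$threshold, tolerance = 1e-12)
})

test_that("the packaged default profile carries the frozen threshold", {
  prof <- default_profile()
  expect_equal(prof$threshold, 3.46)
  expect_equal(prof$threshold_percentile, 0.05)
})

test_that("score samples enforce positivity and minimum size", {
  expect_error(score_sample("benign", c(1, 2)), ">= 3")
  expect_error(score_sample("benign", c(1, 0, 2)), "positions 2")
  s <- score_sample("pathogenic", c(3.5, 3.9, 4.1))
  expect_equal(s$group, "pathogenic")
})
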
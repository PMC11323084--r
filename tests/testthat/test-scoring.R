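test_that("baseline mean and SD match definitions and brute-force loops", {
  # identical members: SD is zero everywhere, mean equals the input
  g <- random_grids(1, 8, seed = 1)[[1]]
  same <- lapply(1:5, function(i) g)
  bl <- build_baseline(same, 3, 2)
  expect_equal(bl$mean_grid$values, g$values)
  expect_equal(bl$sd_grid, matrix(0, 8, 8))

  # two members: mean is the elementwise average
  two <- random_grids(2, 8, seed = 2)
  bl2 <- build_baseline(two, 1, 1)
  expect_equal(bl2$mean_grid$values, (two[[1]]$values + two[[2]]$values) / 2)

  # 26 random members vs per-cell loops, both denominators
  refs <- random_grids(26, 6, seed = 3)
  mats <- lapply(refs, `[[`, "values")
  for (denom in c("sample", "population")) {
    bl26 <- build_baseline(refs, 18, 8, sd_denominator = denom)
    want <- brute_mean_sd(mats, sample_denom = denom == "sample")
    expect_equal(bl26$mean_grid$values, want$mean, tolerance = 1e-12)
    expect_equal(bl26$sd_grid, want$sd, tolerance = 1e-12)
  }

  expect_error(build_baseline(refs[1], 1, 0), ">= 2")
  expect_error(build_baseline(refs, 20, 8), "n_benign")
})

test_that("a constructed 48.3% exceedance scores 3.88 at two decimals", {
  refs <- random_grids(10, 32, seed = 4)
  bl <- build_baseline(refs, 6, 4)
  stopifnot(all(bl$sd_grid > 0))
  # push exactly 495 of the 1024 cells just past one SD: 495/1024 = 48.34%
  values <- bl$mean_grid$values
  idx <- order(as.vector(bl$sd_grid))[1:495]
  values[idx] <- values[idx] + bl$sd_grid[idx] + 1e-9
  dev <- compute_deviation(density_grid(values, "constructed"), bl)
  expect_equal(sum(dev$binary_grid), 495)
  expect_equal(round(dev$exceed_percent, 1), 48.3)
  expect_equal(round(dev$score, 2), 3.88)
})

test_that("a variant equal to the baseline mean has zero exceedance and a sentinel score", {
  refs <- random_grids(8, 16, seed = 5)
  bl <- build_baseline(refs, 4, 4)
  dev <- compute_deviation(bl$mean_grid, bl)
  expect_equal(sum(dev$binary_grid), 0)
  expect_equal(dev$exceed_fraction, 0)
  expect_equal(dev$score, -Inf)
  expect_warning(cls <- classify_score("flat", dev$score), "undefined")
  expect_equal(cls$label, "undefined")
})

test_that("binary exceedance counts match a brute-force cell loop in both modes", {
  set.seed(6)
  for (rep in 1:5) {
    refs <- random_grids(6, 10, seed = 10 + rep)
    bl <- build_baseline(refs, 3, 3)
    variant <- density_grid(matrix(runif(100, 0, 2), 10, 10), "v")
    for (mode in c("literal", "absolute")) {
      dev <- compute_deviation(variant, bl, mode = mode)
      want <- brute_exceed_count(variant$values, bl$mean_grid$values,
                                 bl$sd_grid, absolute = mode == "absolute")
      expect_equal(sum(dev$binary_grid), want)
      expect_equal(dev$exceed_fraction, want / 100)
      expect_equal(dev$exceed_percent, 100 * dev$exceed_fraction)
    }
  }
})

test_that("inflating positive deviations never decreases G in literal mode", {
  refs <- random_grids(6, 12, seed = 30)
  bl <- build_baseline(refs, 3, 3)
  set.seed(31)
  base_vals <- bl$mean_grid$values + matrix(rnorm(144, 0, 0.2), 12, 12)
  base_vals[base_vals < 0] <- 0
  g_prev <- -1
  for (inflate in c(1, 1.5, 2, 4)) {
    vals <- bl$mean_grid$values + (base_vals - bl$mean_grid$values) * inflate
    vals[vals < 0] <- 0
    dev <- compute_deviation(density_grid(vals, "v"), bl, mode = "literal")
    expect_gte(dev$exceed_fraction, g_prev)
    g_prev <- dev$exceed_fraction
  }
})

test_that("the log-percentage score reproduces the printed correspondences", {
  expect_equal(round(score_from_percent(48.3), 2), 3.88)
  expect_equal(round(score_from_percent(49.9), 2), 3.91)
  expect_equal(round(score_from_percent(28), 2), 3.33)
  expect_equal(round(score_from_percent(41), 2), 3.71)
  expect_error(score_from_percent(0), "domain")
  expect_error(score_from_percent(-3), "domain")
  expect_error(score_from_percent(101), "domain")
  # strictly increasing in the percentage
  p <- seq(0.5, 100, by = 0.5)
  expect_true(all(diff(score_from_percent(p)) > 0))
})

test_that("classification is strict-greater at the threshold", {
  expect_equal(classify_score("v", 3.88)$label, "deleterious")
  expect_equal(classify_score("v", 3.46)$label, "non-deleterious")
  expect_equal(classify_score("R175C", log(28))$label, "non-deleterious")
  expect_equal(classify_score("R175H", log(41))$label, "deleterious")
  expect_error(classify_score("v", 1, threshold = Inf), "finite")
  # monotone in score: labels can only switch once, upward
  labels <- vapply(seq(2, 5, by = 0.1),
                   function(s) classify_score("v", s)$label, character(1))
  expect_true(all(diff(labels == "deleterious") >= 0))
})

test_that("baseline members score at or below the top of the reference score range", {
  bm <- make_benchmark(5, 3, 3, pathogenic_perturbation = 0.6, seed = 77,
                       n_frames = 80, n_residues = 3)
  grids <- lapply(bm, function(e) compute_rdp(e$trajectory))
  labels <- vapply(bm, `[[`, character(1), "label")
  bl <- build_baseline(grids[labels != "pathogenic"], 5, 3)
  member_scores <- vapply(grids[labels != "pathogenic"], function(g)
    compute_deviation(g, bl)$score, numeric(1))
  path_scores <- vapply(grids[labels == "pathogenic"], function(g)
    compute_deviation(g, bl)$score, numeric(1))
  expect_lt(max(member_scores), min(path_scores))
})

test_that("baseline models round-trip through JSON", {
  refs <- random_grids(5, 16, seed = 40)
  bl <- build_baseline(refs, 3, 2, sd_mode = "scalar")
  f <- withr::local_tempfile(fileext = ".json")
  write_baseline_json(bl, f)
  back <- read_baseline_json(f)
  expect_equal(back$mean_grid$values, bl$mean_grid$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$sd_grid, bl$sd_grid, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$member_ids, bl$member_ids)
  expect_equal(back$n_benign, 3)
  expect_equal(back$sd_mode, "scalar")
})
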
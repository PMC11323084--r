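#' Run configuration
#'
#' Collects the tunable parameters of the scoring pipeline with their
#' standard defaults: a 32 x 32 density grid, the last 10 ns of each
#' trajectory sampled every 30 ps, one-sided per-grid-point exceedance with
#' sample-denominator standard deviations, and the packaged decision
#' threshold 3.46 (re-derived at the lower 5% pathogenic quantile when
#' calibration data are available).
#'
#' @param grid_dim density grid dimension per axis (default 32).
#' @param window_ns length, in nanoseconds, of the trailing trajectory
#'   window analysed (default 10).
#' @param stride_ps frame stride in picoseconds (default 30).
#' @param exceed_mode `"literal"` (one-sided) or `"absolute"`.
#' @param sd_mode `"per_grid"` or `"scalar"` (see [build_baseline()]).
#' @param sd_denominator `"sample"` or `"population"`.
#' @param threshold fallback decision threshold (default 3.46).
#' @param threshold_percentile lower-tail pathogenic quantile used when
#'   calibrating (default 0.05).
#' @param seed integer seed recorded with every run.
#' @param log_level one of `"debug"`, `"info"`, `"warn"`, `"error"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(grid_dim = 32, window_ns = 10, stride_ps = 30,
                       exceed_mode = c("literal", "absolute"),
                       sd_mode = c("per_grid", "scalar"),
                       sd_denominator = c("sample", "population"),
                       threshold = 3.46, threshold_percentile = 0.05,
                       seed = 1, log_level = c("info", "debug", "warn", "error")) {
  exceed_mode <- match.arg(exceed_mode)
  sd_mode <- match.arg(sd_mode)
  sd_denominator <- match.arg(sd_denominator)
  log_level <- match.arg(log_level)
  if (grid_dim < 2 || window_ns <= 0 || stride_ps <= 0) {
    stop("parameter error: grid_dim, window_ns, stride_ps must be positive",
         call. = FALSE)
  }
  if (!is.finite(threshold)) {
    stop("parameter error: threshold must be finite", call. = FALSE)
  }
  if (threshold_percentile <= 0 || threshold_percentile >= 1) {
    stop("parameter error: threshold_percentile must be in (0, 1)", call. = FALSE)
  }
  structure(list(grid_dim = as.integer(grid_dim), window_ns = window_ns,
                 stride_ps = stride_ps, exceed_mode = exceed_mode,
                 sd_mode = sd_mode, sd_denominator = sd_denominator,
                 threshold = threshold,
                 threshold_percentile = threshold_percentile,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

.log_msg <- function(config, level, fmt, ...) {
  levels <- c(debug = 1, info = 2, warn = 3, error = 4)
  if (levels[[level]] >= levels[[config$log_level]]) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), sprintf(fmt, ...)))
  }
  invisible(NULL)
}

.with_stage <- function(stage, input, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s: %s", stage, input, conditionMessage(e)),
         call. = FALSE)
  })
}

.read_trajectory_any <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xvg") read_rama_xvg(path) else read_dihedral_tsv(path)
}

# window the trailing window_ns and subsample at stride_ps; trajectories
# shorter than the window are used whole
.prepare_trajectory <- function(traj, config) {
  span <- diff(traj$time_span)
  win <- config$window_ns * 1000
  if (is.finite(span) && span > win) {
    traj <- select_window(traj, traj$time_span[2] - win, traj$time_span[2])
  }
  span <- diff(traj$time_span)
  if (is.finite(span) && span >= config$stride_ps) {
    traj <- subsample(traj, config$stride_ps)
  }
  traj
}

#' Score a single trajectory against a baseline
#'
#' Windows the trajectory to its trailing `window_ns` nanoseconds,
#' subsamples at `stride_ps`, computes the Ramachandran density grid, and
#' scores it against the baseline.
#'
#' @param traj a `dihedral_trajectory`.
#' @param baseline a `baseline_model`.
#' @param config a [run_config()].
#' @return a `deviation_result`.
#' @export
score_trajectory <- function(traj, baseline, config = run_config()) {
  traj <- .prepare_trajectory(traj, config)
  grid <- compute_rdp(traj, grid_dim = config$grid_dim)
  compute_deviation(grid, baseline, mode = config$exceed_mode)
}

#' Classify variant trajectories against a stored baseline
#'
#' Reads each variant trajectory (`.xvg` via [read_rama_xvg()], anything
#' else via [read_dihedral_tsv()]), scores it against the baseline, and
#' classifies at the configured threshold. Any stage failure is surfaced
#' with the stage name and the offending input; no partial table is
#' returned.
#'
#' @param config a [run_config()].
#' @param variant_inputs character vector of trajectory file paths, or a
#'   list of `dihedral_trajectory` objects. May be empty.
#' @param baseline a `baseline_model` or the path to a baseline JSON
#'   written by [write_baseline_json()].
#' @return data.frame with one row per variant: `variant_id`,
#'   `exceed_percent`, `score`, `label`, `threshold`.
#' @export
run_classify <- function(config, variant_inputs, baseline) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(baseline)) {
    baseline <- .with_stage("baseline", baseline, read_baseline_json(baseline))
  }
  if (baseline$mean_grid$grid_dim != config$grid_dim) {
    stop(sprintf("[stage baseline] grid_dim mismatch: baseline %d vs config %d",
                 baseline$mean_grid$grid_dim, config$grid_dim), call. = FALSE)
  }
  if (!length(variant_inputs)) {
    return(deviation_table(list(), threshold = config$threshold))
  }
  results <- lapply(seq_along(variant_inputs), function(i) {
    input <- variant_inputs[[i]]
    traj <- if (inherits(input, "dihedral_trajectory")) {
      input
    } else {
      .with_stage("read", input, .read_trajectory_any(input))
    }
    name <- traj$source_id
    .with_stage("score", name, score_trajectory(traj, baseline, config))
  })
  deviation_table(results, threshold = config$threshold)
}

#' Run the full calibrate-and-classify pipeline on a labelled manifest
#'
#' Builds the baseline from the benign and wildtype entries, scores every
#' entry against it, calibrates the threshold from the benign and
#' pathogenic score groups, and classifies the unknown entries (if any) at
#' the calibrated threshold. When the manifest has no pathogenic entries,
#' calibration is skipped with a warning and the configured fallback
#' threshold (default 3.46) is used.
#'
#' Scores that are non-positive or undefined cannot enter the log-normal
#' calibration and are dropped from the fitted groups with a warning (they
#' are still reported in the score table).
#'
#' @param config a [run_config()].
#' @param manifest either the path to a manifest TSV with columns `path`,
#'   `source_id`, `label` (labels among benign / wildtype / pathogenic /
#'   unknown), or an `rdp_benchmark` from [make_benchmark()].
#' @param out_dir optional directory; when given, writes `scores.tsv`,
#'   `classifications.tsv`, `calibration.json` (when calibrated), and
#'   `run_manifest.json` recording the full configuration and package
#'   version.
#' @return list with elements `calibration` (a `calibration_result` or
#'   `NULL`), `threshold`, `baseline` (the fitted `baseline_model`),
#'   `scores` (table over all entries), and `classifications` (table over
#'   unknown entries, or all entries when none are marked unknown).
#' @export
run_pipeline <- function(config, manifest, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  entries <- .load_manifest(manifest)
  labels <- vapply(entries, `[[`, character(1), "label")
  ok_labels <- c("benign", "wildtype", "pathogenic", "unknown")
  if (!all(labels %in% ok_labels)) {
    stop(sprintf("[stage manifest] unknown labels: %s",
                 paste(setdiff(labels, ok_labels), collapse = ", ")), call. = FALSE)
  }
  ref_idx <- which(labels %in% c("benign", "wildtype"))
  if (length(ref_idx) < 2) {
    stop("[stage baseline] need >= 2 benign/wildtype entries", call. = FALSE)
  }
  .log_msg(config, "info", "computing %d density grids (grid_dim %d)",
           length(entries), config$grid_dim)
  grids <- lapply(entries, function(e) {
    traj <- .prepare_trajectory(e$trajectory, config)
    .with_stage("rdp", e$id, compute_rdp(traj, grid_dim = config$grid_dim))
  })
  baseline <- .with_stage("baseline", "reference grids",
    build_baseline(grids[ref_idx],
                   n_benign = sum(labels == "benign"),
                   n_wildtype = sum(labels == "wildtype"),
                   sd_mode = config$sd_mode,
                   sd_denominator = config$sd_denominator))
  results <- lapply(seq_along(entries), function(i) {
    .with_stage("score", entries[[i]]$id,
                compute_deviation(grids[[i]], baseline,
                                  mode = config$exceed_mode,
                                  variant_id = entries[[i]]$id))
  })
  scores <- vapply(results, `[[`, numeric(1), "score")

  calibration <- NULL
  threshold <- config$threshold
  if (!any(labels == "pathogenic")) {
    warning("no pathogenic entries in manifest: calibration skipped, using fallback threshold ",
            format(config$threshold))
  } else {
    pick <- function(lab) {
      s <- scores[labels == lab]
      keep <- is.finite(s) & s > 0
      if (any(!keep)) {
        warning(sprintf("%d %s score(s) non-positive or undefined; dropped from calibration",
                        sum(!keep), lab))
      }
      s[keep]
    }
    b <- pick("benign")
    p <- pick("pathogenic")
    if (length(b) >= 3 && length(p) >= 3) {
      calibration <- .with_stage("calibrate", "score groups",
        calibrate(score_sample("benign", b), score_sample("pathogenic", p),
                  percentile = config$threshold_percentile))
      threshold <- calibration$threshold
      .log_msg(config, "info", "calibrated threshold %.4f (separation p = %.3g)",
               threshold, calibration$separation$p_two_sided)
    } else {
      warning("too few positive scores to calibrate; using fallback threshold ",
              format(config$threshold))
    }
  }

  score_table <- deviation_table(results, threshold = threshold)
  score_table$label_true <- labels
  unk <- labels == "unknown"
  classifications <- if (any(unk)) {
    deviation_table(results[unk], threshold = threshold)
  } else {
    deviation_table(results, threshold = threshold)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(score_table, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(classifications, file.path(out_dir, "classifications.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(calibration)) {
      write_calibration_json(calibration, file.path(out_dir, "calibration.json"))
    }
    run_manifest <- list(
      tool = "rdpscore",
      version = as.character(utils::packageVersion("rdpscore")),
      config = unclass(config),
      n_entries = length(entries),
      labels = as.list(table(labels)),
      threshold_used = threshold,
      calibrated = !is.null(calibration)
    )
    jsonlite::write_json(run_manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(calibration = calibration, threshold = threshold,
       baseline = baseline, scores = score_table,
       classifications = classifications)
}

.load_manifest <- function(manifest) {
  if (inherits(manifest, "rdp_benchmark")) {
    return(lapply(manifest, function(e) {
      list(trajectory = e$trajectory, label = e$label, id = e$id)
    }))
  }
  if (is.character(manifest) && length(manifest) == 1) {
    if (!file.exists(manifest)) {
      stop(sprintf("[stage manifest] input error: file not found: %s", manifest),
           call. = FALSE)
    }
    df <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "label") %in% names(df))) {
      stop("[stage manifest] manifest TSV needs columns path, label", call. = FALSE)
    }
    if (is.null(df$source_id)) {
      df$source_id <- sub("\\.[^.]*$", "", basename(df$path))
    }
    base <- dirname(manifest)
    return(lapply(seq_len(nrow(df)), function(i) {
      p <- df$path[i]
      if (!file.exists(p) && file.exists(file.path(base, p))) {
        p <- file.path(base, p)
      }
      traj <- .with_stage("read", p, .read_trajectory_any(p))
      traj$source_id <- df$source_id[i]
      list(trajectory = traj, label = df$label[i], id = df$source_id[i])
    }))
  }
  stop("[stage manifest] manifest must be a file path or an rdp_benchmark",
       call. = FALSE)
}
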
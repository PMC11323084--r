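#' Construct a dihedral trajectory
#'
#' A dihedral trajectory is the raw ensemble behind a Ramachandran density
#' plot: an ordered table of per-residue backbone dihedral angles
#' \eqn{(\phi, \psi)} sampled along time, typically extracted from a
#' molecular dynamics production run with `gmx rama` or an equivalent tool.
#'
#' @param time numeric vector of frame times in picoseconds (non-negative,
#'   non-decreasing).
#' @param residue_tag character vector of non-empty residue identifiers
#'   (e.g. `"ALA-159"`).
#' @param phi,psi numeric vectors of backbone dihedral angles in degrees,
#'   each in the closed interval \[-180, 180\]. Both interval endpoints are
#'   accepted; they denote the same torsion and land in the same grid bin
#'   downstream.
#' @param source_id free-text label for the ensemble (variant or wildtype
#'   identifier).
#'
#' @return An object of class `dihedral_trajectory`: a list with elements
#'   `records` (data.frame with columns `time`, `residue_tag`, `phi`, `psi`),
#'   `source_id`, and `time_span` (c(min, max) over record times).
#' @export
dihedral_trajectory <- function(time, residue_tag, phi, psi, source_id = "unnamed") {
  n <- length(time)
  if (!(length(residue_tag) == n && length(phi) == n && length(psi) == n)) {
    stop("dihedral_trajectory: all record columns must have equal length", call. = FALSE)
  }
  if (n == 0L) {
    records <- data.frame(time = numeric(), residue_tag = character(),
                          phi = numeric(), psi = numeric(),
                          stringsAsFactors = FALSE)
    obj <- structure(list(records = records, source_id = source_id,
                          time_span = c(NA_real_, NA_real_)),
                     class = "dihedral_trajectory")
    return(obj)
  }
  time <- as.numeric(time)
  phi <- as.numeric(phi)
  psi <- as.numeric(psi)
  residue_tag <- as.character(residue_tag)
  if (anyNA(time) || any(time < 0)) {
    stop("dihedral_trajectory: times must be non-negative picoseconds", call. = FALSE)
  }
  if (is.unsorted(time)) {
    stop("dihedral_trajectory: record times must be non-decreasing", call. = FALSE)
  }
  if (any(!nzchar(residue_tag)) || anyNA(residue_tag)) {
    stop("dihedral_trajectory: residue_tag must be non-empty", call. = FALSE)
  }
  .check_angles(phi, "phi")
  .check_angles(psi, "psi")
  records <- data.frame(time = time, residue_tag = residue_tag,
                        phi = phi, psi = psi, stringsAsFactors = FALSE)
  structure(list(records = records, source_id = source_id,
                 time_span = c(min(time), max(time))),
            class = "dihedral_trajectory")
}

.check_angles <- function(x, what, lines = NULL) {
  bad <- which(is.na(x) | x < -180 | x > 180)
  if (length(bad)) {
    where <- if (is.null(lines)) paste("record", bad[1]) else paste("line", lines[bad[1]])
    stop(sprintf("%s angle out of [-180, 180] at %s (value %s)",
                 what, where, format(x[bad[1]])), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.dihedral_trajectory <- function(x, ...) {
  cat(sprintf("<dihedral_trajectory '%s': %d records, %d frames, t = [%s, %s] ps>\n",
              x$source_id, nrow(x$records), n_frames(x),
              format(x$time_span[1]), format(x$time_span[2])))
  invisible(x)
}

#' Number of distinct frame times in a trajectory
#' @param traj a `dihedral_trajectory`.
#' @return integer count of unique time stamps.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  length(unique(traj$records$time))
}

#' Read a `gmx rama`-style .xvg dihedral file
#'
#' Parses the whitespace-separated text dialect written by the GROMACS
#' `gmx rama` command. Lines starting with `#` or `@` are metadata and are
#' skipped. Two data layouts are accepted:
#' \itemize{
#'   \item 3 columns: `phi psi residue_tag` (the native `gmx rama` layout,
#'     which carries no time column);
#'   \item 4 columns: `time phi psi residue_tag`.
#' }
#' When no time column is present, frame boundaries are inferred from the
#' residue-tag cycle: a new frame begins each time the tag of the first data
#' line reappears. Times are then synthesized as
#' `(frame_index - 1) * save_interval`, so the first frame sits at 0 ps.
#'
#' @param path path to the file.
#' @param save_interval picoseconds between saved frames, used only to
#'   synthesize times for the 3-column layout (default 30).
#' @param source_id label for the trajectory; defaults to the file name.
#' @return a [dihedral_trajectory()].
#' @export
read_rama_xvg <- function(path, save_interval = 30, source_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("input error: file not found: %s", path), call. = FALSE)
  }
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#@]", raw) & nzchar(trimws(raw))
  lines <- raw[keep]
  line_no <- seq_along(raw)[keep]
  if (!length(lines)) {
    stop(sprintf("validation error: no data lines in %s", path), call. = FALSE)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  ncols <- nf[1]
  if (any(nf != ncols)) {
    bad <- which(nf != ncols)[1]
    stop(sprintf("validation error: inconsistent column count at line %d of %s",
                 line_no[bad], path), call. = FALSE)
  }
  if (ncols < 3) {
    stop(sprintf("validation error: expected >= 3 columns in %s", path), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  if (ncols == 3) {
    phi <- suppressWarnings(as.numeric(m[, 1]))
    psi <- suppressWarnings(as.numeric(m[, 2]))
    tag <- m[, 3]
    # frame inference: the tag sequence restarts when the first tag recurs
    frame <- cumsum(tag == tag[1])
    time <- (frame - 1) * save_interval
  } else {
    time <- suppressWarnings(as.numeric(m[, 1]))
    phi <- suppressWarnings(as.numeric(m[, 2]))
    psi <- suppressWarnings(as.numeric(m[, 3]))
    tag <- m[, 4]
    if (anyNA(time)) {
      stop(sprintf("validation error: non-numeric time at line %d of %s",
                   line_no[which(is.na(time))[1]], path), call. = FALSE)
    }
  }
  if (anyNA(phi) || anyNA(psi)) {
    bad <- which(is.na(phi) | is.na(psi))[1]
    stop(sprintf("validation error: non-numeric angle at line %d of %s",
                 line_no[bad], path), call. = FALSE)
  }
  .check_angles(phi, "phi", lines = line_no)
  .check_angles(psi, "psi", lines = line_no)
  dihedral_trajectory(time, tag, phi, psi, source_id = source_id)
}

#' Read a dihedral trajectory from TSV
#'
#' Expects a header with columns `time_ps`, `residue_tag`, `phi_deg`,
#' `psi_deg` (any order, extra columns ignored).
#'
#' @inheritParams read_rama_xvg
#' @return a [dihedral_trajectory()].
#' @export
read_dihedral_tsv <- function(path, source_id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("input error: file not found: %s", path), call. = FALSE)
  }
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("time_ps", "residue_tag", "phi_deg", "psi_deg")
  if (!all(need %in% names(df))) {
    stop(sprintf("validation error: TSV %s must have columns %s",
                 path, paste(need, collapse = ", ")), call. = FALSE)
  }
  if (!nrow(df)) {
    stop(sprintf("validation error: no data rows in %s", path), call. = FALSE)
  }
  dihedral_trajectory(df$time_ps, df$residue_tag, df$phi_deg, df$psi_deg,
                      source_id = source_id)
}

#' Write a dihedral trajectory
#'
#' `format = "xvg"` writes the 4-column `time phi psi residue_tag` layout
#' with `@`-prefixed metadata lines; `format = "tsv"` writes the tabular
#' layout with header `time_ps, residue_tag, phi_deg, psi_deg`. Angles are
#' printed with enough digits to round-trip exactly through [read_rama_xvg()]
#' or [read_dihedral_tsv()].
#'
#' @param traj a `dihedral_trajectory`.
#' @param path output path.
#' @param format `"xvg"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("xvg", "tsv")) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  format <- match.arg(format)
  r <- traj$records
  num <- function(x) formatC(x, format = "g", digits = 15)
  if (format == "xvg") {
    header <- c(sprintf("@ title \"%s\"", traj$source_id),
                "@ xaxis label \"phi\"",
                "@ yaxis label \"psi\"")
    body <- paste(num(r$time), num(r$phi), num(r$psi), r$residue_tag)
    writeLines(c(header, body), path)
  } else {
    body <- paste(num(r$time), r$residue_tag, num(r$phi), num(r$psi), sep = "\t")
    writeLines(c("time_ps\tresidue_tag\tphi_deg\tpsi_deg", body), path)
  }
  invisible(path)
}

#' Restrict a trajectory to a time window
#'
#' Keeps records with `t_start <= time <= t_end` (closed interval),
#' preserving order. The result may be empty. The conventional use is to
#' keep the equilibrated tail of a production run, e.g. the last 10 ns of
#' a 40 ns trajectory.
#'
#' @param traj a `dihedral_trajectory`.
#' @param t_start,t_end window bounds in picoseconds, `t_start < t_end`.
#' @return a `dihedral_trajectory` with the filtered records.
#' @export
select_window <- function(traj, t_start, t_end) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (!is.finite(t_start) || !is.finite(t_end) || t_start >= t_end) {
    stop("parameter error: t_start must be < t_end", call. = FALSE)
  }
  r <- traj$records
  keep <- r$time >= t_start & r$time <= t_end
  out <- r[keep, , drop = FALSE]
  dihedral_trajectory(out$time, out$residue_tag, out$phi, out$psi,
                      source_id = traj$source_id)
}

#' Subsample a trajectory at a fixed time stride
#'
#' Retains the frames nearest the target times `t_min + k * stride` for
#' `k = 1, ..., floor((t_max - t_min) / stride)`, so the frame count equals
#' `floor(window_length / stride)` — a 10 000 ps window at a 30 ps stride
#' gives 333 frames. Targets are matched to the nearest available frame
#' time; equidistant ties resolve to the earlier frame. If the nearest
#' frame is farther than half the median inter-frame spacing a warning is
#' issued (the frame is still used, preserving the count).
#'
#' @param traj a non-empty `dihedral_trajectory`.
#' @param stride stride in picoseconds, `0 < stride <= window length`.
#' @return a `dihedral_trajectory` containing the matched frames.
#' @export
subsample <- function(traj, stride) {
  stopifnot(inherits(traj, "dihedral_trajectory"))
  if (!nrow(traj$records)) stop("validation error: empty trajectory", call. = FALSE)
  if (!is.finite(stride) || stride <= 0) {
    stop("parameter error: stride must be > 0", call. = FALSE)
  }
  times <- sort(unique(traj$records$time))
  span <- times[length(times)] - times[1]
  if (stride > span) {
    stop(sprintf("validation error: stride (%s ps) exceeds window length (%s ps)",
                 format(stride), format(span)), call. = FALSE)
  }
  k <- seq_len(floor(span / stride))
  targets <- times[1] + k * stride
  tol <- if (length(times) > 1) stats::median(diff(times)) / 2 else Inf
  # nearest frame per target; ties toward the earlier frame
  idx <- findInterval(targets, times)
  idx[idx == 0L] <- 1L
  lo <- times[idx]
  hi <- times[pmin(idx + 1L, length(times))]
  pick <- ifelse(targets - lo <= hi - targets, idx, pmin(idx + 1L, length(times)))
  matched <- times[pick]
  if (any(abs(matched - targets) > tol + 1e-9)) {
    warning("subsample: some target times had no frame within half the median frame spacing; nearest frames used")
  }
  r <- traj$records
  out <- r[r$time %in% matched, , drop = FALSE]
  # restore per-target duplication order if stride < spacing mapped repeats
  dihedral_trajectory(out$time, out$residue_tag, out$phi, out$psi,
                      source_id = traj$source_id)
}
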
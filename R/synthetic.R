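#' Default Ramachandran basins
#'
#' The three named basins where backbone dihedrals of a folded domain
#' concentrate: the alpha-helix basin at (-60, -30), the polyproline-II
#' spiral at (-60, +150), and the beta-sheet basin at (-120, +130). Default
#' occupancies are 0.5 / 0.25 / 0.25 with an isotropic Gaussian spread of
#' 15 degrees, a realistic breadth for an equilibrated fold.
#'
#' @return data.frame with columns `name`, `center_phi`, `center_psi`,
#'   `weight` (summing to 1), `spread`.
#' @export
default_basins <- function() {
  data.frame(
    name = c("alpha_helix", "pii_spiral", "beta_sheet"),
    center_phi = c(-60, -60, -120),
    center_psi = c(-30, 150, 130),
    weight = c(0.5, 0.25, 0.25),
    spread = c(15, 15, 15),
    stringsAsFactors = FALSE
  )
}

.validate_basins <- function(basins) {
  need <- c("center_phi", "center_psi", "weight", "spread")
  if (!is.data.frame(basins) || !all(need %in% names(basins))) {
    stop("validation error: basins must be a data.frame with center_phi, center_psi, weight, spread",
         call. = FALSE)
  }
  if (abs(sum(basins$weight) - 1) > 1e-9) {
    stop("validation error: basin weights must sum to 1", call. = FALSE)
  }
  if (any(basins$spread <= 0)) {
    stop("validation error: basin spreads must be > 0", call. = FALSE)
  }
  invisible(basins)
}

#' Specification of a synthetic dihedral ensemble
#'
#' Describes a mixture-of-basins generative model standing in for a
#' molecular dynamics ensemble: each saved frame draws, per residue, a
#' basin by occupancy weight and then \eqn{(\phi, \psi)} from an isotropic
#' Gaussian around the basin center, wrapped onto \[-180, 180\).
#'
#' The `perturbation` knob emulates a destabilizing variant: a fraction `p`
#' of the dominant basin's occupancy is reallocated to the other basins
#' (proportionally to their weights) and every basin center is shifted by
#' `p * 20` degrees in both \eqn{\phi} and \eqn{\psi}. `p = 0` is
#' wildtype-like.
#'
#' @param basins basin table as from [default_basins()].
#' @param n_residues number of residues per frame (default 5).
#' @param n_frames number of saved frames (default 333, the count of a
#'   10 ns window saved every 30 ps).
#' @param save_interval picoseconds between frames (default 30).
#' @param perturbation non-negative destabilization fraction in \[0, 1\].
#' @param seed integer seed; identical specs give identical trajectories.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(basins = default_basins(), n_residues = 5,
                          n_frames = 333, save_interval = 30,
                          perturbation = 0, seed = 1) {
  .validate_basins(basins)
  if (n_residues < 1 || n_frames < 1) {
    stop("validation error: n_residues and n_frames must be >= 1", call. = FALSE)
  }
  if (save_interval <= 0) {
    stop("validation error: save_interval must be > 0", call. = FALSE)
  }
  if (!is.numeric(perturbation) || perturbation < 0 || perturbation > 1) {
    stop("validation error: perturbation must be in [0, 1]", call. = FALSE)
  }
  structure(list(basins = basins, n_residues = as.integer(n_residues),
                 n_frames = as.integer(n_frames),
                 save_interval = save_interval,
                 perturbation = perturbation, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Apply the perturbation transform to a basin table
#'
#' @param basins basin table.
#' @param p perturbation fraction in \[0, 1\].
#' @return perturbed basin table (weights still sum to 1, centers wrapped).
#' @export
perturb_basins <- function(basins, p) {
  .validate_basins(basins)
  if (p == 0) return(basins)
  b <- basins
  dom <- which.max(b$weight)
  moved <- b$weight[dom] * p
  others <- setdiff(seq_len(nrow(b)), dom)
  if (length(others)) {
    share <- b$weight[others] / sum(b$weight[others])
    b$weight[others] <- b$weight[others] + moved * share
    b$weight[dom] <- b$weight[dom] - moved
  }
  b$center_phi <- .wrap_angle(b$center_phi + p * 20)
  b$center_psi <- .wrap_angle(b$center_psi + p * 20)
  b
}

# wrap onto [-180, 180)
.wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Simulate a synthetic dihedral ensemble
#'
#' Draws the trajectory described by an [ensemble_spec()]: for each of
#' `n_frames` frames and `n_residues` residues, a basin is drawn by
#' (perturbed) occupancy weight and \eqn{(\phi, \psi)} from an isotropic
#' Gaussian of SD `spread` around the (perturbed) center, wrapped
#' modularly onto \[-180, 180\) so tails do not pile up at the seam. Frame
#' `k` is stamped at `k * save_interval` ps. The draw is fully determined
#' by `spec$seed`.
#'
#' @param spec an [ensemble_spec()].
#' @param source_id label for the trajectory.
#' @return a [dihedral_trajectory()] with `n_frames * n_residues` records.
#' @export
simulate_ensemble <- function(spec, source_id = "synthetic") {
  stopifnot(inherits(spec, "ensemble_spec"))
  b <- perturb_basins(spec$basins, spec$perturbation)
  n <- spec$n_frames * spec$n_residues
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  basin <- sample.int(nrow(b), n, replace = TRUE, prob = b$weight)
  phi <- .wrap_angle(stats::rnorm(n, b$center_phi[basin], b$spread[basin]))
  psi <- .wrap_angle(stats::rnorm(n, b$center_psi[basin], b$spread[basin]))
  frame <- rep(seq_len(spec$n_frames), each = spec$n_residues)
  residue <- rep(seq_len(spec$n_residues), times = spec$n_frames)
  dihedral_trajectory(frame * spec$save_interval,
                      sprintf("RES-%d", residue),
                      phi, psi, source_id = source_id)
}

#' Generate a labelled benchmark of synthetic ensembles
#'
#' Emulates a deviation-scoring training design: benign and
#' wildtype ensembles drawn at (near-)zero perturbation and pathogenic
#' ensembles at a stated perturbation. Wildtype ensembles use perturbation
#' exactly 0; benign ensembles receive a small jitter drawn uniformly from
#' \[0, 0.05\] so they are distinct from, but structurally close to,
#' wildtype. Per-trajectory seeds are derived from `seed` by fixed offsets,
#' so the whole benchmark is reproducible from one integer.
#'
#' @param n_benign,n_wildtype,n_pathogenic member counts (>= 1 each).
#' @param pathogenic_perturbation perturbation for pathogenic members
#'   (default 0.5).
#' @param seed master integer seed.
#' @param basins basin table (default [default_basins()]).
#' @param n_residues,n_frames,save_interval passed to [ensemble_spec()].
#' @return an object of class `rdp_benchmark`: a list of entries, each with
#'   `trajectory`, `label` (`"benign"`, `"wildtype"`, `"pathogenic"`),
#'   `perturbation`, and `id`.
#' @export
make_benchmark <- function(n_benign, n_wildtype, n_pathogenic,
                           pathogenic_perturbation = 0.5, seed = 1,
                           basins = default_basins(), n_residues = 5,
                           n_frames = 333, save_interval = 30) {
  if (n_benign < 1 || n_wildtype < 1 || n_pathogenic < 1) {
    stop("validation error: all member counts must be >= 1", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  benign_jitter <- stats::runif(n_benign, 0, 0.05)
  entry <- function(label, index, perturbation, offset) {
    id <- sprintf("%s_%02d", label, index)
    spec <- ensemble_spec(basins = basins, n_residues = n_residues,
                          n_frames = n_frames, save_interval = save_interval,
                          perturbation = perturbation,
                          seed = seed + offset + index)
    list(trajectory = simulate_ensemble(spec, source_id = id),
         label = label, perturbation = perturbation, id = id)
  }
  out <- c(
    lapply(seq_len(n_benign), function(i) entry("benign", i, benign_jitter[i], 1000L)),
    lapply(seq_len(n_wildtype), function(i) entry("wildtype", i, 0, 2000L)),
    lapply(seq_len(n_pathogenic), function(i) entry("pathogenic", i,
                                                    pathogenic_perturbation, 3000L))
  )
  structure(out, class = "rdp_benchmark")
}

#' @export
print.rdp_benchmark <- function(x, ...) {
  labs <- table(vapply(x, `[[`, character(1), "label"))
  cat(sprintf("<rdp_benchmark: %d trajectories (%s)>\n", length(x),
              paste(sprintf("%s %d", names(labs), labs), collapse = ", ")))
  invisible(x)
}

#' Write a benchmark to disk with a manifest
#'
#' Writes each trajectory as a dihedral TSV plus a `manifest.tsv` with
#' columns `path`, `source_id`, `label`, `perturbation` — the input format
#' consumed by [run_pipeline()].
#'
#' @param benchmark an `rdp_benchmark`.
#' @param dir output directory (created if missing).
#' @return path to the manifest, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "rdp_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(benchmark, function(e) {
    fn <- file.path(dir, paste0(e$id, ".tsv"))
    write_trajectory(e$trajectory, fn, format = "tsv")
    data.frame(path = fn, source_id = e$id, label = e$label,
               perturbation = e$perturbation, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mp)
}
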
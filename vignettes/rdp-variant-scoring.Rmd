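---
title: "Ramachandran density deviation scoring: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ramachandran density deviation scoring: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdpscore)
```

## The model

A missense variant that destabilizes a protein fold changes how the
backbone dihedral angles (φ, ψ) of its residues distribute over the
Ramachandran plane during an equilibrated molecular dynamics run. The
package quantifies that change in four steps.

**Density estimation.** All residues and frames of an ensemble are pooled
into one 2-D sample and a Gaussian kernel density estimate is evaluated at
the cell centers of a `grid_dim × grid_dim` grid over [−180, 180]²
(`compute_rdp()`). The bandwidth matrix is the full sample covariance
scaled by Scott's factor `n^(-1/(d+4))` squared with `d = 2` — the default
of the widely used scientific-Python KDE estimator, so grids computed here
are directly comparable with that tool chain. Densities are probability
per square degree and the grid is *not* renormalized, so a diffuse
ensemble whose kernel mass leaks outside the window integrates to less
than 1 over the grid.

**Baseline.** `build_baseline()` averages the density grids of *i* benign
and *j* wildtype ensembles per grid point (denominator `i + j`) and
records a per-grid-point standard deviation `S`.

**Deviation and score.** For a variant grid the deviation at each grid
point is the signed difference from the baseline mean. A grid point counts
as exceeding when the deviation is greater than `S` at that point; the
fraction `G` of exceeding points, over `n = grid_dim²` points, summarizes
the variant, and the reported score is `ln(100 G)` (`compute_deviation()`,
`score_from_percent()`). The exceedance test is one-sided by default —
only density *increases* beyond `S` count, matching the binary rule the
statistic is defined by — with `mode = "absolute"` available because
difference images are naturally two-sided (density both diminishes and
accumulates); both modes are tested.

**Threshold.** Scores of known benign and pathogenic variants are each fit
by a log-normal (closed-form maximum likelihood on the log scale),
checked for adequacy with one-sample Kolmogorov–Smirnov and
Anderson–Darling statistics, and compared with a two-sided Welch t-test.
The decision threshold is the lower `threshold_percentile` quantile
(default 5%) of the *pathogenic* fit: 95% of fitted pathogenic mass lies
above the cut, a deliberate margin that tolerates pathogenic variants with
little structural effect rather than inflating false deleterious calls.
Classification is strict-greater: a score exactly at the threshold is
non-deleterious. The packaged default profile for the p53 DNA-binding
domain freezes the threshold at 3.46.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `grid_dim` | 32 | cells/axis | 1024 comparison points; the scale at which basin-level density changes register without per-frame noise dominating |
| `window_ns` | 10 | ns | trailing, equilibrated portion of a production run |
| `stride_ps` | 30 | ps | decorrelates frames; a 10 ns window yields `floor(10000/30) = 333` frames |
| `exceed_mode` | `literal` | — | one-sided `χ_d > S`, the defining rule; `absolute` flags diminished density too |
| `sd_mode` | `per_grid` | — | each grid point is its own base of comparison; `scalar` pools all reference values into one SD |
| `sd_denominator` | `sample` | — | `i + j − 1`; `population` divides by `i + j` |
| `threshold` | 3.46 | ln(%) | frozen p53-DBD profile, used when no calibration data are supplied |
| `threshold_percentile` | 0.05 | — | lower pathogenic quantile defining the calibrated threshold |

## Numerical choices and degenerate inputs

* KDE evaluation points are **cell centers**
  (`axis_min + (k + 0.5)·360/grid_dim`), giving symmetric coverage of the
  square; corners vs centers is not externally fixed, and centers are the
  package's choice, documented here.
* The (φ, ψ) torus is **not wrapped** by default: a basin hugging +179°
  contributes no density at −179°. A wrap-aware mode (`wrap = TRUE` in
  `compute_rdp()`, summing the kernel over ±360° images) exists for
  ensembles that straddle the seam. Both angle endpoints ±180° are
  accepted on input and denote the same torsion.
* Ensembles with fewer than 2 points, or with singular sample covariance
  (all points identical), are rejected with a remediation hint (add jitter
  or more frames) rather than producing NaN grids.
* `G = 0` (no grid point exceeds) makes the log score undefined; the score
  is reported as `-Inf` and the classification label is `"undefined"` with
  a warning, leaning non-deleterious.
* `subsample()` anchors targets at `t_min + k·stride`, `k ≥ 1`, and takes
  the **floor** of `window/stride` — reproducing the 333-frame convention
  for 10 000/30. Targets match the nearest frame, ties toward the earlier
  frame; a target farther than half the median frame spacing from any
  frame still uses the nearest frame but warns, keeping the frame-count
  invariant on irregular time grids. When the stride is finer than the
  frame spacing, a frame satisfying several targets is kept once.
* Frame inference for time-less `gmx rama` files starts a new frame each
  time the first data line's residue tag recurs, and stamps frame *k* at
  `(k − 1)·save_interval`.
* Goodness-of-fit treats the fitted log-normal parameters as fully
  specified. When the parameters were estimated from the same sample the
  K-S and A-D p-values are approximate (conservative) — the standard
  plug-in caveat, accepted here because the tests serve as adequacy
  screens, not precise inference. Scores derived from binary counts take
  at most `grid_dim² + 1` distinct values, so ties can occur and the K-S
  continuity assumption is likewise approximate.
* Overlap rates are rounded **half-up** to one decimal (base R's
  `round()` is half-to-even), matching how shared-variant tables are
  conventionally printed; undefined rates (zero denominator) are `NA`,
  never division errors.

## What the synthetic generator emulates — and what it does not

`simulate_ensemble()` draws (φ, ψ) per residue and frame from a mixture of
isotropic Gaussians centered on the three basins where a folded domain's
backbone concentrates — α-helix (−60, −30), polyproline-II spiral
(−60, +150), β-sheet (−120, +130) — with default occupancies
0.5/0.25/0.25 and 15° spread, wrapped modularly onto [−180, 180) to avoid
edge pile-up. Defaults mirror the standard sampling convention: 333
frames at a 30 ps save interval; `n_residues = 5` keeps a desk-scale
sample (1665 points per ensemble) that still gives stable 32×32 grids.

The `perturbation` knob `p` emulates a destabilizing variant by moving a
fraction `p` of the dominant basin's occupancy to the other basins
(proportionally to their weights) and shifting every basin center by
`p·20°`. This generative model is an artifact of the package — real MD
provides no such dial — and its defaults were fixed once so that the
calibrated threshold lands between the unperturbed and perturbed groups.
`make_benchmark()` assembles a labelled training set (wildtype at `p = 0`,
benign at a small uniform jitter `p ∈ [0, 0.05]`, pathogenic at a stated
`p`, default 0.5), with per-trajectory seeds derived from one master seed
by fixed offsets.

What passing the synthetic suite shows: the statistic orders perturbation
magnitudes correctly, the calibration separates groups, and held-out
unperturbed ensembles fall below the calibrated threshold. What it does
not show: behavior on real force-field ensembles — residue-specific
Ramachandran preferences (Gly/Pro), correlated frames, slow conformational
transitions, and partial unfolding are all absent from the generator, so
real-data thresholds must be calibrated on real training variants.

## Design decisions that were genuinely open

* **Pooling across residues.** Dihedral records are pooled over all
  residues before density estimation; per-residue grids would demand far
  more frames per residue for stable estimates and a rule for aggregating
  per-residue scores. Pooling matches the one-grid-per-ensemble workflow
  the statistic is defined on.
* **`S` granularity.** The binary rule is implemented per grid point —
  each grid point is its own base of comparison — with a pooled-scalar
  option exposed for sensitivity analysis.
* **Sample vs population SD.** Sample (`i + j − 1`) is the default; the
  choice is exposed because reference sets are small (tens of members) and
  the denominators differ noticeably there.
* **Threshold interpretation.** The calibrated cut is read as the lower
  5% quantile of the pathogenic fit ("95% of pathogenic mass above the
  threshold"); the percentile is configurable, and the frozen constant
  3.46 ships as the default profile rather than being re-derivable — the
  per-variant training scores behind it are not distributed with the
  package.
* **Welch t-test.** Group variances are visibly unequal in calibrated runs
  (benign spread ≫ pathogenic spread), so the unequal-variance form is the
  defensible default.
* **Overlap key.** Variants are matched by (gene, normalized one-letter
  protein change): "altering the same codon" is operationalized as the
  same residue alteration; a cDNA-level key can be layered on by callers
  that carry `cdna_change`.
* **Run outputs** embed the full configuration and package version in a
  JSON run manifest (rather than an opaque hash), and reruns with the same
  inputs are byte-identical — tested.

## Problem sizes used by the test suite

The suite exercises the full pipeline at 32×32 grids with ensembles of
120–333 frames × 3–5 residues, benchmarks up to 18 + 8 + 26 members,
Monte-Carlo checks over 20–50 seeded trials, and oracle quadrature at
256²–512² evaluation points — sizes chosen so the statistic's behavior
(monotonicity in perturbation, group separation, held-out specificity) is
measurable with comfortable margins on a laptop-class single core.

## Known limitations

* Scores are resolution-quantized: with `grid_dim = 32` the exceedance
  percentage moves in steps of 100/1024 ≈ 0.1%.
* The A-D statistic is reported without a p-value; critical values for the
  estimated-parameter case are distribution-specific and out of scope.
* No per-residue attribution: a deleterious call says the ensemble's
  density field moved, not which residues moved it.
* Binary trajectory formats (XTC/TRR/DCD) are out of scope; run `gmx rama`
  or equivalent upstream.
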
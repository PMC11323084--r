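# rdpscore

Structural-deviation scoring of missense variants from backbone dihedral
ensembles.

## What it does, and for whom

Molecular dynamics (MD) simulations of a variant-bearing protein produce,
after post-processing with a tool such as GROMACS `gmx rama`, a time series
of backbone dihedral angles (φ, ψ) per residue. `rdpscore` turns those
ensembles into a two-class call — *deleterious* or *non-deleterious* — for
each missense variant, by measuring how far the variant's Ramachandran
density departs from a baseline built from known-benign and wildtype
ensembles. It is aimed at structural bioinformaticians who already run MD
(or have dihedral time series from any source) and want a reproducible,
calibrated deleteriousness statistic without hand-tuned structure
inspection.

The package does **not** run MD or compute dihedrals from coordinates; it
starts from `gmx rama` `.xvg` output or an equivalent TSV. A synthetic
basin-mixture simulator is included so the entire pipeline can be exercised
and tested at desk scale.

## The statistic

1. Each ensemble (all residues and frames pooled) is converted to a
   **Ramachandran density plot (RDP)**: a Gaussian kernel density estimate
   (Scott's-rule, full-covariance bandwidth) evaluated at the cell centers
   of a 32 × 32 grid over [−180, 180]².
2. A **baseline** is the per-grid-point mean χ_b and standard deviation S
   over *i* benign + *j* wildtype RDPs.
3. For a variant grid χ_t, the deviation grid is χ_d = χ_t − χ_b. Each of
   the n = 32² grid points contributes a binary exceedance
   b = 1 if χ_d > S (else 0), and G = Σb / n.
4. The **structural-deviation score** is ln(100·G), the natural log of the
   exceedance percentage. An exceedance of 48.3% scores ln(48.3) = 3.88; of
   49.9%, 3.91.
5. The decision **threshold** is calibrated by fitting log-normal
   distributions to known benign and pathogenic score sets (with
   Kolmogorov–Smirnov / Anderson–Darling adequacy checks and a Welch
   t-test for separation) and taking the lower 5% quantile of the fitted
   pathogenic distribution. Scores strictly above the threshold are
   deleterious; at or below, non-deleterious. A frozen default profile for
   the p53 DNA-binding domain ships with threshold 3.46.

A companion module intersects germline- and somatic-origin variant tables
by (gene, normalized protein change) and reports shared counts and rates.

## Worked example

```r
library(rdpscore)

# a labelled synthetic benchmark: 18 benign + 8 wildtype references and
# 26 destabilized ("pathogenic") ensembles, 333 frames each
bench <- make_benchmark(n_benign = 18, n_wildtype = 8, n_pathogenic = 26,
                        pathogenic_perturbation = 0.5, seed = 42)

config <- run_config(seed = 42, log_level = "warn")
result <- run_pipeline(config, bench)
result$calibration
#> <calibration_result>
#>   benign fit:     mu_log 0.7423, sigma_log 0.3454 (n = 18)
#>   pathogenic fit: mu_log 1.4271, sigma_log 0.0164 (n = 26)
#>   K-S p (benign / pathogenic): 0.548 / 1
#>   separation: t = -11.345, two-sided p = 2.05e-09
#>   threshold (lower 5% pathogenic quantile): 4.0556

# classify two new ensembles against the calibrated threshold
quiet <- simulate_ensemble(ensemble_spec(perturbation = 0,   seed = 7), "variant_A")
hot   <- simulate_ensemble(ensemble_spec(perturbation = 0.6, seed = 8), "variant_B")
run_classify(run_config(threshold = result$threshold), list(quiet, hot),
             result$baseline)
#>   variant_id exceed_percent    score           label threshold
#> 1  variant_A       6.152344 1.816833 non-deleterious  4.055636
#> 2  variant_B      69.140625 4.236142     deleterious  4.055636
```

The benign and pathogenic groups separate cleanly (two-sided Welch
p = 2×10⁻⁹); the unperturbed held-out ensemble scores 1.82, far below the
calibrated threshold 4.06, while the strongly perturbed one scores 4.24 and
is called deleterious.

A thin command-line front end over the same functions is installed at
`system.file("scripts", "rdpscore", package = "rdpscore")` with subcommands
`simulate`, `baseline`, `score`, `classify`, `calibrate`, `pipeline`, and
`overlap`.

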
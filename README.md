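# wmIschemia

Voxel-based quantification of white-matter ischemia from combined
diffusion and perfusion MRI, for imaging scientists studying hyperacute
stroke and for anyone who needs a fully testable, dependency-light
reference implementation of the standard analysis chain:

* **DTI maps** — per-voxel log-linear least-squares tensor fit
  (`ln S_i = ln S0 − b gᵢᵀD gᵢ`), closed-form eigenvalues, fractional
  anisotropy `FA = √(3/2)·‖λ−λ̄‖/‖λ‖` and ADC = mean diffusivity.
* **DSC perfusion Tmax** — signal-to-concentration conversion
  `C(t) = −ln(S/S0)/TE`, block-circulant SVD deconvolution against an
  arterial input function (zero-padded to 2N, singular values below 10% of
  the largest discarded), and Tmax as the time-to-maximum of the recovered
  residue function.
* **Threshold segmentation** — white matter as FA > 0.15, infarct core as
  ADC < 600×10⁻⁶ mm²/s inside the perfusion ROI, hypoperfused WM as the
  ADC-preserved remainder of the ROI, plus a mirrored contralateral
  normal-WM region.
* **Cohort statistics** — person–region means, one-way within-subject
  (repeated-measures) ANOVA with Tukey-adjusted pairwise comparisons,
  Spearman correlations, and a single-split regression-tree search for the
  Tmax threshold that best separates FA into high and low values, with a
  selection-aware permutation p-value.
* **Digital phantom** — multi-subject DWI + DSC simulation with known
  per-region FA/ADC/Tmax ground truth, so the entire pipeline is
  verifiable end to end without any patient data.

## Worked example

Simulate an 8-subject phantom cohort, run the full pipeline (tensor fit →
deconvolution → segmentation → statistics), and inspect the report:

```r
library(wmIschemia)

spec <- defaultPhantomSpec(nSubjects = 8, seed = 42)
dir <- file.path(tempdir(), "cohort")
generateCohort(spec, dir)            # writes NIfTI + bval/bvec bundles

cfg <- defaultPipelineConfig()
cfg$statistics$nPermutations <- 2000L
res <- runPipeline(dir, cfg)

subset(res$report$regionSummary, measure == "FA")
#>  measure        region  mean      sd
#>       FA  hypoperfused 0.413 0.01577
#>       FA  infarct_core 0.334 0.04538
#>       FA normal_contra 0.381 0.00547

res$report$anova$FA
#> Repeated-measures ANOVA: F(2, 14) = 15.42, p = 0.000289 (n = 8 subjects)
#> Tukey-adjusted pairwise comparisons:
#>       region1       region2    meanDiff       pTukey
#>  hypoperfused  infarct_core  0.07889653 0.0002083545
#>  hypoperfused normal_contra  0.03217599 0.0967210636
#>  infarct_core normal_contra -0.04672054 0.0144719923
```

The cohort mean FA is highest in hypoperfused WM, lowest in the infarct
core and intermediate in normal contralateral WM — the planted ordering —
and the within-subject ANOVA flags the regional differences as highly
significant, with the core-versus-other contrasts surviving Tukey
adjustment even at n = 8.

The split search on a hand-computable toy (FA steps up for the two large
Tmax values):

```r
bestSplit(c(1, 2, 3, 10, 11), c(0.30, 0.31, 0.29, 0.40, 0.41),
          nPermutations = 999, seed = 1)
#> Single-split search: threshold 6.5 s
#>   low  (n=3): mean 0.3
#>   high (n=2): mean 0.405
#>   difference 0.105, permutation p = 0.205 (B = 999), Welch p = 0.001022
```

The threshold lands at the midpoint (6.5 s) between the two groups and the
subgroup means follow directly. Note the two p-values: the naive Welch
test on the *selected* groups looks highly significant, while the honest
permutation p (which re-runs the whole search per permutation and so
accounts for threshold selection) is unimpressive at n = 5 — exactly the
selection effect the permutation test exists to correct.

A command-line front end over the same functions ships in
`inst/cli/wmischemia.R`, with subcommands `phantom`, `fit-dti`, `fit-dsc`,
`segment`, `analyze` and `run`:

```sh
Rscript inst/cli/wmischemia.R phantom --out cohort --subjects 21 --seed 1
Rscript inst/cli/wmischemia.R run --cohort cohort --out report
```

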
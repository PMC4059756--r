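# dscaif — automatic AIF detection for DSC-MRI by hierarchical clustering

Perfusion quantification from dynamic susceptibility contrast (DSC) MRI
needs the **arterial input function (AIF)** — the tracer concentration–time
curve in an artery feeding the tissue — before any deconvolution for CBF,
CBV or MTT can happen.  Automatic AIF detectors based on k-means or fuzzy
c-means clustering work, but both depend on random initial cluster centers
and can return a *different* AIF every time they are re-run on the same
scan.  `dscaif` implements a deterministic alternative for radiology and
neuroimaging researchers: **agglomerative hierarchical (AH) clustering with
average linkage**, plus the two stochastic baselines, a ground-truth
bolus-passage simulator, the clinical candidate-curve filter chain, and the
evaluation metrics to compare detectors.

## The method in brief

1. Convert voxel signals to concentration:
   `C(t) = -log(S(t)/S0) / (k TE)`, with `S0` the mean pre-contrast signal.
2. (Clinical data only) filter candidates: drop the 90 % of curves with the
   smallest area, the 25 % roughest (integrated squared second derivative
   of area-normalised curves), and curves whose steady-state to
   first-passage area ratio falls outside ±20 % of the mean (a
   partial-volume criterion using a gamma-variate first-passage fit).
3. Cluster the curves into k = 5 groups by average-linkage AH clustering on
   Euclidean distances (no random element; Lance–Williams updates in C++).
4. Select the cluster maximising `M = H_P / (T_P × FWHM)` — tall, early,
   narrow is arterial — and return its mean curve as the AIF.

The simulator generates the standard synthetic study — a gamma-variate
bolus `(t−t0)^a exp(−(t−t0)/b)` (t0 26 s, a 3, b 1.5 s; analytic peak
4.5369) with recirculation, 6 true plus 16 false arterial voxels, 1480
tissue voxels via the central-volume-theorem convolution, 400
partial-volume mixtures, and Rician-magnitude Gaussian noise at SNR
20/40/60 — with per-voxel ground truth labels.

## Worked example

```r
library(dscaif)

ds <- build_dataset(seed = 1)     # 1902 voxels x 90 s, SNR 20 noise
det <- detect_aif(ds, method = "ah")
round(det$metrics, 4)
#>   cluster    n    h_p t_p    fwhm     auc      m selected
#> 1       1    5 4.4592  31  6.2958 55.3101 0.0228        1
#> 2       2    6 1.3363  36 27.4341 37.5963 0.0014        0
#> 3       3    6 4.4531  32  6.2942 54.3774 0.0221        0
#> 4       4    7 4.4540  34  6.2961 53.9827 0.0208        0
#> 5       5 1878 0.1308  33 26.2433  3.9917 0.0002        0
```

Cluster 1 wins the M statistic: peak height 4.46 (the sampled maximum of
the model artery), time-to-peak 31 s, FWHM 6.3 s.  Clusters 3–4 are the
delayed "false arterial" look-alikes (taller M denominators), cluster 5 is
the 1878-voxel tissue bulk (peak 0.13), and cluster 2 collects
noise-corrupted mixture curves.  Scoring against the ground truth:

```r
pve_level(det$selected_ids, ds$labels)   # 0      — no non-arterial voxel selected
aif_rmse(det$aif, ds$true_aif)           # 1.7e-16 — the detected AIF is the true curve
```

Because AH clustering is deterministic, re-detection is bit-identical:

```r
rr <- reproducibility_experiment(ds, method = "ah", n_runs = 100)
rr$robustness                            # exactly 0; kmeans/fcm give > 0
```

Clinical 4D NIfTI series go through the same pipeline:

```r
curves <- read_perfusion_nifti("perf.nii.gz", slice_index = 10, n_discard = 2)
det <- detect_aif(curves, method = "ah", mode = "clinical", te = 0.030)
```

A thin command-line front end with `simulate` / `detect` / `evaluate` /
`repro` subcommands lives at `inst/cli/dscaif.R`.

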
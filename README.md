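# pammspec

Finite-temperature infrared spectra of flexible peptides, reconstructed as
population-weighted averages over representative conformers.

A flexible molecule at equilibrium is a canonical ensemble of metastable
conformers, and its IR spectrum superposes their individual spectra in
proportion to their populations. `pammspec` implements the analysis chain
that turns a conformer trajectory with per-frame energies into such an
ensemble-averaged spectrum, and quantifies its agreement with a reference:

- **Descriptors** — average SOAP power spectra per frame: the
  Gaussian-smeared neighbor density expanded in an orthonormal radial basis
  times real spherical harmonics, contracted to rotation/permutation
  invariants, then reduced by PCA.
- **Clustering (PAMM-style)** — farthest-point-sampled landmark grid,
  localized-Silverman Gaussian kernel density, quick-shift mode seeking
  with cutoff `alpha * lambda_i`, canonical weights `w_c = n_c / n`, and
  lowest-energy representatives; adjacency-restricted Ward merging builds
  the cluster hierarchy.
- **Hydrogen-bond statistics** — continuous counts over N-H...O triplets
  (`s_A` accepted per O, `s_D` donated per N, `s_H` per H) from a 0-1
  mixture-posterior membership; triangular-kernel-smoothed probability
  surfaces and free energies `F = -k_B T ln P` (kcal/mol), with per-cluster
  summary tables.
- **Spectra** — Gaussian broadening (10 cm^-1 FWHM), weighted ensemble
  averaging, hierarchical-merge spectrum series, moving-average smoothing,
  and Pendry reliability factors
  `R_P = sum((Y_a - Y_b)^2) / sum(Y_a^2 + Y_b^2)` with
  `Y = L / (1 + v_oi^2 L^2)`, `L = I'/I`, reported per amide region
  (600-1800 and 2700-3600 cm^-1).
- **Synthetic ground truth** — a generator of conformer ensembles from a
  fixed peptide-like chain template with planted basin populations, H-bond
  geometries and stick spectra, so every stage can be validated against
  known answers.

## Worked example

```r
library(pammspec)

report <- run_pipeline(list(
  seed = 42,
  synth = list(n_frames = 2000),                       # three-basin ground truth
  clustering = list(f_points = 0.1, alpha = 3,         # macrocluster preset
                    bandwidth = "localization")))
print(report)
#> <run_report> 2003 frames -> 3 clusters
#> # A tibble: 3 x 8
#>   cluster mean_sA sd_sA mean_sD sd_sD mp_tuple mp_pct weight_pct
#>     <int>   <dbl> <dbl>   <dbl> <dbl> <chr>     <dbl>      <dbl>
#> 1       1   0.598 0.122   1.45  0.535 (0,1)      25.4      60.0
#> 2       2   0.199 0.245   0.231 0.268 (0,0)      78.5       9.74
#> 3       3   1.50  0.397   0.815 0.176 (2,1)      57.7      30.3
#> # A tibble: 2 x 5
#>   region              lo    hi        r_p  v_oi
#>   <chr>            <dbl> <dbl>      <dbl> <dbl>
#> 1 amide I/II/III/V   600  1800 0.0000831      5
#> 2 amide A/B         2700  3600 0.00000924     5
```

The generator planted three basins with populations (0.6, 0.3, 0.1); the
pipeline recovers three clusters with weights 60.0%, 30.3% and 9.7%, the
per-cluster hydrogen-bond means track the planted bond strengths (the
strong-bond basin donates `mean_sD = 1.45`, the broken-bond basin 0.23),
and the recovered ensemble-averaged spectrum matches the ground-truth
reference with Pendry factors below 1e-4 in both amide windows (0 is a
perfect match, 1 is no correlation).

Whether one representative per cluster suffices can be probed directly:

```r
cons <- within_cluster_consistency(report, which.max(report$clusters$weights),
                                   n_fps = 4)
sprintf("within %.3f vs cross %.3f", cons$within_mean, cons$cross_mean)
#> "within 0.156 vs cross 1.151"
```

FPS-selected members of the dominant cluster agree far better with their own
representative than with other clusters' representatives.

Other entry points: `generate_ensemble()` / `write_ensemble()` /
`read_ensemble()` (extended-XYZ with per-frame energies), `compute_soap()`,
`pca_project()`, `pamm()`, `merge_hierarchy()` (+ `write_newick()`),
`count_hbonds()`, `hbond_surface()`, `per_cluster_summary()`, `broaden()`,
`ensemble_average()`, `hierarchical_series()`, `pendry_r()`,
`region_report()`, `rerun_spectra()`, plot helpers (`plot_spectra()`,
`plot_cluster_map()`, `plot_merge_tree()`, `autoplot()` on free-energy
surfaces) and `tidy()`/`glance()` methods on the fitted objects.

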
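---
title: "Ensemble-weighted IR spectra from conformer clustering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble-weighted IR spectra from conformer clustering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pammspec)
```

## The problem

A flexible peptide at finite temperature is not one structure but a canonical
ensemble of interconverting conformers. Its measured infrared spectrum is
therefore a population-weighted superposition of the spectra of many
metastable conformational families, and predicting it from single low-energy
structures is systematically misleading. `pammspec` implements the full
chain needed to build, and validate, a population-weighted spectrum:

1. describe each trajectory frame with a rotation/translation/permutation
   invariant structural fingerprint (average SOAP power spectrum);
2. project to a low-dimensional map (PCA) and cluster it with a
   probabilistic, density-based scheme (FPS grid, localized kernel density
   estimate, quick-shift mode seeking);
3. weight each cluster by its population `w_c = n_c / n_total` (the
   canonical weight) and represent it by its lowest-energy member;
4. characterize each cluster's hydrogen bonding with continuous counting
   functions `s_A`, `s_D`, `s_H` and free-energy surfaces
   `F = -k_B T ln P`;
5. broaden each representative's stick spectrum with 10 cm^-1 FWHM
   Gaussians, average with the canonical weights, follow convergence along a
   Ward merge hierarchy, and score agreement with a reference spectrum using
   the Pendry reliability factor `R_P`.

Because the full molecular-dynamics / quantum-chemistry / action-spectroscopy
data behind such studies is rarely available in machine-readable form, the
package ships a first-class synthetic generator with exact ground truth, and
every nontrivial claim about the pipeline is validated against it.

## The synthetic generator

`generate_ensemble()` draws frames from a mixture of conformational basins.
Each `basin_spec()` fixes mean values for the four free torsions of a fixed
~20-atom peptide-like chain template (two N-H donor groups, four O
acceptors), a von-Mises-like torsional concentration, a characteristic
donor-acceptor H-bond distance realized exactly in the geometry by a pendant
carbonyl acceptor placed along the first N-H axis, and a stick spectrum
whose H-bond-sensitive lines shift linearly with the instantaneous H-bond
distance.

The default study conditions — used by the validation suite — are three
well-separated basins with populations (0.6, 0.3, 0.1), torsion means about
120 degrees apart, H-bond distances 2.9 / 3.3 / 3.7 Angstrom (strong,
intermediate, broken), torsional concentration 60 (about 7 degrees of
spread) and a per-frame distance spread of 0.05 Angstrom. These were chosen
once as a realistic caricature of a small gas-phase peptide: basins distinct
enough that a human would call them different conformers, spreads large
enough that frames scatter visibly in descriptor space.

Per-frame energies follow
`E = offset + stiffness * sum(torsion deviation^2) + |N(0, sigma_E)|`.
The noise is folded (strictly non-negative) so that the torsion-mean frame
appended once per basin — with zero penalty and zero noise — is almost
surely the unique energy minimum of its basin. This makes
"lowest-energy representative recovery" an exactly checkable property; a
signed noise term would occasionally relabel the true minimum and turn an
implementation test into a coin flip.

What the generator does *not* emulate: anharmonic couplings, slow
conformational interconversion (frames are i.i.d.), solvent, multi-photon
action-spectroscopy kinetics, and continuous basin-to-basin pathways.
Passing tests therefore demonstrate correctness of the analysis machinery on
mixture-like data, not that any particular real peptide will cluster this
cleanly.

All randomness flows from one integer seed through `split_seed()`
(multiplicative hash; independent streams for frame sampling and
reference-spectrum noise), so every artifact is bit-reproducible.

## Descriptors

`compute_soap()` expands the Gaussian-smeared neighbor density around each
atom (width `atom_sigma`, default 0.4 Angstrom) in an orthonormalized
Gaussian radial basis (`n_max = 6`) times real spherical harmonics
(`l_max = 4`) inside a 5 Angstrom cutoff; radial integrals are evaluated by
Gauss-Legendre quadrature with exponentially scaled modified spherical
Bessel functions for numerical stability. The rotationally invariant power
spectrum per species pair is averaged over the atoms of a frame ("average
SOAP"), and rows are L2-normalized by default so conformers of different
compactness remain comparable. The implementation is validated against a
direct two-dimensional quadrature of the smeared-density projection on a
dimer, and against exact invariance under rigid motions and within-species
permutations.

Clustering operates on the first `d = 2` principal components of the
descriptor matrix, which for well-separated torsional basins carry the large
majority of the variance; `d` is configurable.

## Clustering: grid, density, quick-shift

The density model follows the probabilistic-motif-analysis recipe:
`min(1000, n)` landmark frames are chosen by farthest point sampling, every
frame is assigned to its nearest landmark (Voronoi weights), and a Gaussian
KDE is evaluated at the landmarks with per-landmark bandwidths derived from
the covariance of the nearest fraction `f_points` of frames (floored at
`d + 1` samples). Two bandwidth rules are exposed:

- `"silverman"` (default): the localized Silverman rule,
  `h_i = sigma_loc * (4 / ((d + 2) n_loc))^(1 / (d + 4))`. This is the
  pointwise-accurate choice and the one appropriate for fine probing of a
  large trajectory (the fine preset `f_points = 0.008`, `alpha = 0.9`).
- `"localization"`: `h_i = sigma_loc` itself, i.e. the width of the
  neighborhood the density was estimated from. This deliberately
  oversmooths relative to Silverman and is the right choice when the
  question is *how many macroscopic modes are there* at moderate sample
  sizes: the Silverman bandwidth at n of a few thousand is comparable to
  both the landmark spacing and the KDE noise scale, and mode counting on
  such an estimate fragments badly, while the localization width tracks the
  probe scale the analyst actually selected.

The model stores both the continuous KDE values (`density`, which matches
the analytic density on standard-normal test data) and the Voronoi-mass
normalized probabilities (`prob`, which sum to one); the two answer
different questions and neither can play the other's role.

Quick-shift links each landmark to its nearest landmark of strictly higher
density within `alpha * sigma_loc_i`; unlinked landmarks are modes, ties
break to the lowest index, and the result provably equals brute-force
steepest ascent (tested exhaustively on grids up to 50 points). The cutoff
uses the localization spread — the scale of the neighborhood that defined
the density — rather than the (possibly Silverman-shrunk) kernel width, so
the link radius is meaningful under both bandwidth rules.

Two presets bracket normal use: the fine probe
(`f_points = 0.008`, `alpha = 0.9`, `bandwidth = "silverman"`) resolves
many sub-basins on large trajectories and is the package default; the
macrocluster preset (`f_points = 0.1`, `alpha = 3`,
`bandwidth = "localization"`) recovers the coarse basin structure at desk
scale (thousands of frames) and is what the validation suite uses for
ground-truth recovery, where it returns exactly the three planted basins
with weights within 0.03 of truth and the exact planted energy minima as
representatives across seeds. `f_points` is a resolution dial: recovering a
single planted basin as one cluster at very small n (about 150 frames)
needs a still coarser probe (`f_points` about 0.4), because at that sample
size a tenth of the data is only a dozen points.

Cluster weights are frame shares; representatives are per-cluster energy
argmins with ties to the lowest frame index. Empty clusters (possible after
frame re-assignment) are dropped with a warning and weights renormalized.

## Merge hierarchy

`merge_hierarchy()` agglomerates cluster centroids under Ward's criterion
(`d2 = n_a n_b / (n_a + n_b) * ||c_a - c_b||^2`), restricted to cluster
pairs that share a Voronoi boundary on the landmark grid (a frame whose
nearest and second-nearest landmarks fall in the two clusters). When the
adjacency graph is disconnected — routine for well-separated basins — the
merge falls back to unrestricted Ward with a warning. Merge heights are
made non-decreasing by a running maximum (restricted agglomeration can
otherwise invert), merged weights are sums, and a merged node's
representative is its lower-energy child's, which equals the energy argmin
over the union. The merge order is validated against an independent
enumeration that recomputes the error-sum-of-squares increase from raw
member coordinates.

## Hydrogen-bond statistics

Candidate N-H...O triplets are enumerated from covalent N-H pairs
(distance < 1.3 Angstrom) and acceptors within a 4.5 Angstrom
donor-acceptor cutoff; O-H...O bonding is excluded by default (the dominant
motif in protonated peptides is N-H...O, and mixing the two blurs the
counting variables), and the species lists are configurable. The continuous
0-1 H-bond count of a triplet is the posterior probability of the bonded
component in a fixed two-component mixture over
`(nu, mu, d_DA) = (d_DH - d_AH, d_DH + d_AH, d_DA)`: a narrow Gaussian at
the reference geometry (-0.9, 2.9, 2.9) Angstrom with 0.25 Angstrom widths,
against a broad background Gaussian (widths 3, 4, 3 Angstrom). A broad
Gaussian background (rather than a bounded uniform) keeps the posterior
defined and decaying to zero for arbitrarily dissociated triplets. All
parameters are exposed; in the original methodology this component is
trained on trajectory data, and the fixed parameterization here removes
that data dependency while preserving the 0-1 membership contract
(reference geometry scores > 0.999, 10 Angstrom separation scores < 1e-6).

Counts per tagged atom (`s_D` per donor N, `s_A` per acceptor O, `s_H` per
hydrogen) are triplet-membership sums; atoms with totals below a 0.01
threshold are treated as non-participating and excluded from averages, the
continuous analog of ignoring nitrogens that donate nothing.

Probability surfaces histogram the counts on 0.05-wide bins, smear each
sample with a triangular kernel of half-width 0.025 (samples, not bins, are
smeared: the kernel is narrower than a bin, so bin-level convolution would
be a no-op), normalize, and convert to `F = -k_B T ln P` in kcal/mol with
`k_B = 0.0019872`. A two-state distribution with a 2:1 probability ratio at
300 K reproduces the closed form `Delta F = k_B T ln 2 = 0.413` kcal/mol to
the stated precision. Integer-cell integration (`[i - 0.5, i + 0.5)` per
axis) yields the most probable `(s_A, s_D)` tuple and its percentage.

Per-cluster summaries average frame-first (mean over participating atoms
within a frame, then over frames) with population standard deviations; the
joint `(s_A, s_D)` samples behind the most-probable tuple are the within-
frame cross pairs of participating acceptor and donor values. Whether such
published tables weight by atom or by frame is genuinely ambiguous;
frame-first is implemented and stated here.

## Spectra

Broadening sums unit-area Gaussians (`sigma = fwhm / 2.3548`, default FWHM
10 cm^-1) scaled by stick intensities on a 1 cm^-1 grid, after multiplying
line positions by a frequency `scale_factor` (default 1 for synthetic
sticks; harmonic ab initio spectra need the user's scaling factor, which is
deliberately a required choice rather than a hidden default). Ensemble
averages are exact convex combinations on a shared grid — mismatched grids
are an error, never silently resampled. The hierarchical series evaluates
the weighted average at every merge level from all leaves down to the root.

The Pendry factor compares logarithmic-derivative Y-functions,
`Y = L / (1 + v_oi^2 L^2)` with `L = I'/I` by central differences;
`v_oi = 5` cm^-1 by default, half the broadening FWHM, matching its role as
an approximate peak half-width. Intensities below `1e-8 * max(I)` set
`Y = 0`, stabilizing `L` in empty regions; this guard is what makes the
disjoint-support null (`R_P = 1`) exact. `R_P` is scale-invariant in each
argument, symmetric, zero iff the Y-functions coincide on the region, and
can exceed 1 for anticorrelated spectra. Region reports evaluate
600-1800 cm^-1 (amide I/II/III/V) and 2700-3600 cm^-1 (amide A/B)
side by side. Reference-spectrum smoothing is a mass-preserving moving
average with reflective boundaries — the published analyses smooth their
measured spectra before computing `R_P` but do not state the algorithm, so
a boxcar with a configurable window is the documented stand-in.

## Pipeline and problem sizes

`run_pipeline()` sequences generation (or loading), descriptors, PCA,
clustering, weights and representatives, H-bond statistics, broadening,
averaging, the merge series and the Pendry report, deterministically for a
fixed seed; `rerun_spectra()` recomputes only the spectral stages against
the cached clustering. `within_cluster_consistency()` probes whether one
representative per cluster is defensible: FPS-selected members of a cluster
are scored against all representatives, and within-cluster means are
compared with cross-cluster means.

The validation suite runs the ground-truth recovery study at 3000 frames
per seed over ten seeds, reconstruction at 1000 frames, and module tests on
fixtures of tens of points; these sizes were chosen so that the statistical
claims (weight recovery within 0.03, basin separation) are comfortably
resolved while the whole suite stays fast enough to run habitually.

## Known limitations

- Mode counting depends on the probe resolution (`f_points`, `alpha`); no
  preset recovers "the" cluster count on all data, and the package never
  hard-codes an expected number of clusters.
- The adjacency-restricted Ward hierarchy is a fully specified substitute
  for fuzziness-based cluster merging; with well-separated clusters the
  adjacency graph is usually disconnected and the unrestricted fallback
  engages.
- The H-bond membership mixture is fixed, not trained; systems whose bonded
  geometry differs materially from the (-0.9, 2.9, 2.9) reference need
  their own parameters.
- Descriptors are global averages; two conformers differing only in a small
  local rearrangement of a large molecule can be hard to separate in
  average-SOAP space.
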
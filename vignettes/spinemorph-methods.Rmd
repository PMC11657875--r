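---
title: "Spine morphometry with spinemorph: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spine morphometry with spinemorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

## The measurement model

`spinemorph` quantifies dendritic spine shape from *skeleton + outline*
annotations of 3D fluorescence stacks with strongly anisotropic voxels
(default 20×20×300 nm). The key modelling commitment, inherited from how
such data are actually annotated, is that all widths are measured **in the
imaging plane**: lateral resolution (~50 nm in STED-class data) supports
nanometer-scale width estimates, axial resolution (300 nm plane pitch)
does not, so no volume reconstruction is attempted. A spine is therefore

* a 3D centerline (ordered nodes from the dendrite attachment to the tip,
  z quantized to the plane pitch), with manual `neck`/`head` node labels
  as part of the input contract, and
* one simple polygon per imaging plane outlining the spine next to the
  centerline in that plane.

The width profile d(s) samples the spine every ~20 nm of **3D** arc length
s (z contributes through the plane pitch). At each sample the in-plane
line through the skeleton point, perpendicular to the in-plane projection
of the local tangent (the containing segment's direction), is intersected
with that plane's outline; the diameter is the chord containing the
skeleton point. Where a sample lands on a plane-crossing (axial) segment,
or a chord is undefined, the diameter is linearly interpolated in s from
its neighbors — the simplest interpolation consistent with the sampling.
A skeleton point falling outside its outline is a hard error (it indicates
a broken annotation, not a measurement).

Numerical choices worth knowing:

* the chord finder uses a half-open edge convention so a line through a
  polygon vertex counts once; near-duplicate intersections (< 1 µnm apart)
  are merged, and grazing contacts are resolved by rotating the probe
  direction by 10⁻⁴ rad — degenerate configurations are resolved rather
  than silently mismeasured;
* concave outlines can produce several chords along the probe line; the
  chord containing the skeleton point is used, matching the "outline drawn
  next to the skeleton" convention;
* the sample grid is `seq(0, L, by = 20)` plus the exact tip, so spacing
  never exceeds the nominal step (a final short interval is allowed).

## Descriptors

For samples tagged by the nearest labeled node: head diameter = max d over
head samples, neck diameter = min d over neck samples, plus their ratio;
spine length = total 3D arc length; spine/neck/head "area" = Σ dᵢ·Δsᵢ with
midpoint (trapezoid-equivalent) interval weights, so disjoint neck + head
regions covering all samples add to the spine area within one boundary
sample; CVs = sd/mean of d over the spine/neck/head samples. Spines
without labeled neck or head keep length, spine area and cv_spine; the
region descriptors are `NA` by contract rather than silently zero.

## Classification

Profiles are resampled to 100 equally spaced points (index 1 = attachment,
100 = tip). Features are the 100 diameters plus the spine length repeated
75 times, rescaled by `mean(all resampled diameters) / mean(lengths)`.
Two readings of that rescale are possible (per-spine vs grand mean of the
diameters); we use the **grand mean** over all spines × 100 samples, which
makes the two feature blocks exactly balanced in their grand means — a
defining property the tests assert. Diameters stay in raw nm; no further
standardization is applied.

Clustering is agglomerative Ward (minimum within-cluster-variance
increase) on Euclidean distances, delegated to
`stats::hclust(method = "ward.D2")`; with continuous features exact merge
ties have measure zero, so hclust's deterministic behavior fixes the
result given the input order, and permuting the input changes labels only
up to renaming (tested as partition equality). An independent O(n³)
brute force that recomputes the SSE increase directly from the points
verifies the entire merge sequence in the tests.

The class count is chosen by the Davies–Bouldin index over k = 2…8
(configurable; the range covers the handful of morphological classes ever
proposed for spines, and the index is undefined at k = 1).

## The synthetic generator: what it emulates, and what not

The generator stands in for unreleased microscope data. Its four class
archetypes are deterministic package constants — 100-point diameter
templates built from Gaussian bumps over a baseline — chosen to match the
published qualitative classes: stubby-like (short, wide, *with* a
resolvable neck, as super-resolution data show even for the shortest
spines), mushroom-like (head/neck diameter ratio ≈ 4, > 2 by documented
construction), thin (long narrow neck, small head), and filopodia-like
(long, monotonically tapering, no head swelling). Length distributions
(700±100, 1150±150, 1700±250, 2600±400 nm, truncated > 200 nm) sit in the
0.5–3 µm range typical of cortical spines. Within-class variability in
real data is unknown; the default multiplicative lognormal diameter noise
of CV = 0.10 is a placeholder exposed in the config (Gaussian on length,
lognormal on diameters keeps diameters positive). Skeletons bend gently
in-plane (heading random walk, 0.05 rad per ~50 nm step) and cross up to
`floor(L/900)` plane boundaries, so multi-plane interpolation is
exercised; outlines are offset ribbons whose local width equals the noisy
template, extended ~30 nm beyond the run ends so endpoint samples lie
strictly inside.

What a green test therefore establishes: the *pipeline* — measurement,
features, clustering, statistics — recovers a known ground truth under a
realistic geometry and noise model. What it does not establish: that real
spines separate this cleanly. Real annotations have hand-drawn outline
irregularity, out-of-focus planes, and a class continuum rather than four
generators; with the default noise the Davies–Bouldin criterion itself
already wavers, selecting k = 3 (merging the two short classes) in roughly
2–3 of 10 seeds depending on the seed base, while the modal selection is
4 and label agreement at k = 4 is near perfect (median adjusted Rand index
≈ 1). We report that sensitivity rather than tuning the templates apart.

## Imaging model and deconvolution

The PSF is a 2D Lorentzian `k(r) ∝ 1/(1+(2r/fwhm)²)`, 50 nm FWHM by
default, sampled at pixel centers on an odd support and normalized over
that finite support (whether the original analysis normalized over finite
support or analytically is unstated; finite-support normalization keeps
DC gain exactly 1). The renderer uses a generous ±8 FWHM support because
the Lorentzian's heavy tails carry real broadening — a 400 nm cylinder
blurs to a measurably wider half-maximum width only if the tails are kept.

Wiener deconvolution applies `conj(H)/(|H|² + reg)` per plane (never
across z, matching 2D plane-wise restoration of anisotropic stacks).
Boundaries are periodic (FFT-native); pad beforehand if wrap matters. The
noise-to-signal constant `reg` is not stated by the original analysis; the
default is 10⁻² of the peak |H|² (= 10⁻², since the normalized kernel has
|H| = 1 at DC), standard practice for single-constant Wiener filtering.
`reg = 0` is refused when |H| has (near-)zeros.

## Statistics

Class heterogeneity uses Pearson's chi-square (no continuity correction,
matching the crosstab-style analysis) on the dendrite × class table;
all-zero classes are dropped before computing df, a zero dendrite margin
is an error naming the dendrite, and expected counts < 5 set a
`low_expected` flag rather than silently switching tests. Bonferroni
families follow the display logic: all dendrite pairs for the global
pairwise matrix, within-neuron pairs for per-neuron matrices, and the set
of descriptors within each neuron for the Kruskal–Wallis battery.
Kruskal–Wallis uses midranks with the standard tie correction and the
chi-square approximation for H. The post hoc behind per-descriptor
pairwise comparisons is not specified in the original analysis; we use
Dunn's rank z-tests with Bonferroni, the standard companion to
Kruskal–Wallis, and flag this as an interpretation.

The shuffle control permutes the spine → dendrite assignment while
keeping per-dendrite spine counts fixed and reruns the batteries; on a
strongly heterogeneous synthetic dataset the omnibus chi-square rejects at
the nominal 5% rate under shuffling (binomial 99% interval over 1000
shuffles), reproducing the expected "no significant differences after
shuffling" behavior as a calibrated null, not merely an anecdote.

## I/O and pipeline choices

* Skeletons: minimal webKnossos-style NML dialect (scale, trees, nodes
  with x/y/z voxel indices, edges, node comments `neck`/`head`); unknown
  elements ignored because the format varies by version. The attachment
  point is required to be the tree's root/first endpoint — NML does not
  encode it explicitly.
* Full annotations: a JSON schema carrying nm coordinates directly
  (`scale_nm` kept as metadata); round trips are lossless to well below
  1e-6 nm.
* Stacks: a plain-text format replaces TIFF, since no TIFF reader is
  available in the target R environment; the array container and the
  deconvolution contracts are unchanged.
* Pipeline config: one flat **JSON** file (flags override) — JSON is the
  one structured-text dialect with a guaranteed parser here; the config is
  echoed into the run directory and hashed into the manifest, and a rerun
  with the same seed produces byte-identical tables.

## Known limitations

* Outlines are per-plane polygons; voxel-mask segmentations are out of
  scope, as are spinules, branched spines and contact cataloguing.
* Head/neck boundaries are inputs (manual labels), never inferred.
* The generator's class templates and noise are stylized: they validate
  the machinery, not biological effect sizes.
* Davies–Bouldin is the only class-number criterion implemented; its
  occasional k = 3 preference at default noise is documented above.

```{r example, eval = FALSE}
# end-to-end run on synthetic data
cfg <- pipeline_config(out_dir = tempfile("run"), seed = 7, shuffles = 100,
                       simulate = list(dendrites = data.frame(
                         neuron_id = "n1", dendrite_id = c("dA", "dB"),
                         n_spines = 150,
                         p1 = c(.55, .1), p2 = .15, p3 = .2,
                         p4 = c(.1, .55))))
res <- run_pipeline(cfg)
res$model$k            # Davies-Bouldin-selected class count
res$tests$omnibus      # chi-square across dendrites
res$shuffle$chi_square_reject_rate  # ~0.05 under the calibrated null
```
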
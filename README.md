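# spinemorph

Dendritic spines — the micron-scale protrusions that carry most excitatory
synapses — are classically binned into "stubby", "mushroom", "thin" and
"filopodia" shapes, and growing evidence suggests that individual dendrites
of the same neuron carry *different mixtures* of these shapes. Testing that
requires (i) nanometer-scale width measurements along each spine in 3D,
(ii) an unbiased, clustering-based definition of spine classes, and
(iii) statistics that ask whether class composition is homogeneous across
dendrites. `spinemorph` implements that analysis chain for skeleton
annotations of super-resolution (STED-class) image stacks with anisotropic
voxels (20×20×300 nm), together with a synthetic ground-truth generator so
every stage can be validated without microscope data.

## What it computes

**Width profiles.** Each spine is annotated by a 3D centerline (attachment
→ tip) plus a segmentation outline polygon per imaging plane. The spine
width d(s) is measured every ~20 nm of 3D arc length s, in the imaging
plane, perpendicular to the in-plane projection of the local skeleton
tangent: the diameter is the chord of the outline containing the skeleton
point, linearly interpolated where a sample falls between planes.

**Ten descriptors per spine.** Head diameter `max d` over head samples,
neck diameter `min d` over neck samples, their ratio, spine length
(final s, in 3D), spine/neck/head area `Σ dᵢ·Δsᵢ`, and the coefficient of
variation of d over the spine, neck and head.

**Classification.** Profiles are resampled to 100 points; the feature
vector is `(d₁,…,d₁₀₀, c·L,…,c·L)` with the length L repeated 75 times and
`c = mean(all diameters)/mean(lengths)` so both blocks carry equal weight.
Ward hierarchical clustering (Euclidean distances) is cut at the class
count k minimizing the Davies–Bouldin index
`DB = (1/k) Σᵢ maxⱼ≠ᵢ (Sᵢ+Sⱼ)/Mᵢⱼ` over candidates k = 2…8.

**Heterogeneity statistics.** Pearson chi-square on the dendrite × class
count table (omnibus, per neuron, and all dendrite pairs with Bonferroni
correction over the pair family), per-descriptor Kruskal–Wallis tests
across dendrites with Dunn's post hoc, and a shuffle control that
permutes spines over dendrites (per-dendrite counts fixed) to confirm the
tests calibrate to their nominal level.

**Imaging model.** A 2D Lorentzian PSF `k(r) ∝ 1/(1+(2r/fwhm)²)`
(50 nm FWHM by default) with plane-wise Wiener deconvolution
`conj(H)/(|H|²+reg)`, plus a renderer producing blurred, Poisson-noisy
stacks from synthetic annotations.

## Worked example

```r
library(spinemorph)

# two dendrites of one neuron with opposite class mixtures, 150 spines each
dend <- data.frame(neuron_id = "n1", dendrite_id = c("dA", "dB"),
                   n_spines = 150,
                   p1 = c(0.55, 0.10), p2 = c(0.15, 0.15),
                   p3 = c(0.20, 0.20), p4 = c(0.10, 0.55))
ds    <- sample_dataset(synth_config(dend, seed = 7))
meas  <- measure_dataset(ds)
model <- cluster_spines(meas$profiles, k_range = 2:8)
idx   <- dataset_index(ds)
tests <- heterogeneity_tests(idx, model$labels, meas$descriptors)
```

Output (printed by the code above):

```
selected k: 4
    2     3     4     5     6     7     8
0.554 0.524 0.520 0.583 0.643 0.684 0.895      # Davies-Bouldin curve
                test    comparison statistic df            p
1 pearson_chi_square all dendrites  93.36189  3 4.152669e-20
        class
dendrite  1  2  3  4
      dA 33 78 28 11
      dB 58 11 20 61
ARI vs ground truth: 0.808
```

Davies–Bouldin selects k = 4 classes (its minimum over the candidate
range), the omnibus chi-square rejects homogeneity of the class
composition across the two dendrites at p ≈ 4×10⁻²⁰ — the two engineered
mixtures are clearly distinguishable — and the recovered labels agree with
the generator's ground truth (adjusted Rand index 0.81). Per-spine
descriptors are in `meas$descriptors`:

```
     spine_id head_diameter neck_diameter spine_length cv_spine
 n1_dA_sp0001        104.12         98.22      2069.66     0.33
 n1_dA_sp0002        364.71        206.19       591.61     0.19
 n1_dA_sp0003        365.27        222.64       634.27     0.16
```

The same pipeline runs from the command line
(`exec/spinemorph simulate|deconvolve|measure|cluster|compare|run`) or in
one call via `run_pipeline(pipeline_config(...))`, which writes the
descriptor/count/test CSVs plus a manifest under an output directory.

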
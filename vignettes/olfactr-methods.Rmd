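---
title: "Methods: de-orphanization analysis of insect odorant receptors"
author: "olfactr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de-orphanization analysis of insect odorant receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfactr)
```

`olfactr` implements the analysis chain used to characterize the ligand
spectra of insect odorant receptors (ORs): quantification of
single-sensillum recordings (SSR) of ORs expressed in the *Drosophila*
ab3A "empty neuron", tuning-breadth statistics over a large odor panel,
a calcium-imaging pipeline for glomerular responses in the antennal
lobe, statistical mapping of receptor profiles onto glomerular profiles,
and a molecular model of exon-skipping knockout alleles. This vignette
documents the models, conventions, parameters and numerical choices, and
what the synthetic-data module does and does not emulate.

## Spike-train quantification (SSR)

A sensillum houses two neurons whose extracellular spikes differ in
amplitude; the ectopically expressed OR drives the A (large-amplitude)
neuron. `sort_units_by_amplitude()` labels spikes either at a fixed
amplitude cutoff or automatically by an exact two-class split of the
sorted amplitudes (minimal within-class sum of squares). The automatic
split is accepted only when the gap between class means exceeds twice
the sum of the class standard deviations; at the amplitude separations
typical for ab3 (≥ 5 σ) this labels > 99 % of spikes correctly, while a
unimodal amplitude distribution falls back to "all A" with a warning —
mislabeling everything as two units would be worse than refusing.

Response conventions (all windows half-open, `[start, end)`, so no spike
is counted twice):

* net response = A-spikes in the 500 ms stimulus window − A-spikes in
  the 500 ms pre-stimulus window (`count_response()`); negative values
  (inhibition) are retained and only thresholded downstream;
* solvent-subtracted response in spikes/s = 2 × (odor net count − mean
  of the fly's solvent net counts) (`solvent_subtracted_response()`);
  the per-fly mean uses all solvent trials regardless of their position
  in the experiment;
* spontaneous activity = 2 × pre-stimulus A count
  (`spontaneous_activity()`).

Per-(receptor, odor) medians across recordings form the
`response_matrix`; cells without trials stay missing (`NA`), never zero,
and per-cell sample sizes are kept. The EAG peak is the maximum voltage
decrease after stimulus onset relative to the voltage at onset; the
baseline convention is configurable (`"pre_mean"`) because the
at-onset reading is noise-sensitive in principle, though with the
default it matches the simplest reading of the convention.

## Tuning metrics

`classify_responses()` partitions every non-missing cell: below the
response threshold (default 10 spikes/s) → no response; at or above half
the receptor's maximum median → best-ligand class; in between →
sub-half-maximum. Boundaries are inclusive ("≥"), so a lone median of
exactly 10 spikes/s is its receptor's best ligand.

Lifetime sparseness over a panel of $N$ odors, with $r_i$ the median
response clipped at zero,

$$S = \frac{1 - \left(\sum_i r_i / N\right)^2 / \left(\sum_i r_i^2 / N\right)}{1 - 1/N},$$

runs from 0 (identical response to every odor) to 1 (response to a
single odor). Clipping negative (inhibitory) medians is required because
the statistic is defined for non-negative rates; $N$ defaults to the
full panel size including non-responders. An all-zero profile leaves $S$
undefined (`NA` with a warning) rather than silently 0 or 1.
Percentages of responsive odors are rounded half-up to integer percent.
Dose–response tables use the 1.5 × IQR outlier rule (standard for
boxplots) and flag a dilution active when its median reaches the
threshold.

## Calcium-imaging pipeline

Movies are 40 frames at 4 Hz (10 s trials: clean air frames 1–8, odor
frames 9–16, clean air frames 17–40), 4 µm/px; frame numbers are 1-based
everywhere in the interface and converted to array indices only
internally. The stage order is fixed and each stage is pure (returns a
new stack):

1. **ΔF/F** (`deltaF_over_F()`): per-pixel background F = mean of frames
   3–7; output = (F(t) − F)/F. Non-positive background pixels are a hard
   error naming the first offending pixel, since they make the ratio
   meaningless.
2. **Bleaching correction** (`bleach_correct()`): least-squares fit of
   $b(t) = a e^{-t/\tau} + c$ (Levenberg–Marquardt) to the spatial-mean
   trace over frames 3–7 and 26–40 — before and after stimulus and
   response — and subtraction of $b(t)$ from every frame, leaving the
   fit-frame residual mean at ≈ 0. The offset $c$ is needed because a
   ΔF/F trace need not decay to zero. Degenerate fits (singular,
   $\tau \le 0$) fall back to a linear fit with a warning. The fit is
   global (spatial mean) by default; a per-pixel variant exists for
   spatially inhomogeneous bleaching but is noise-dominated at typical
   SNR.
3. **Spatial median filter** (`spatial_median_filter()`): per-frame
   7 × 7 px median, edges by symmetric reflection, to remove
   single-pixel outliers. Width must be odd.
4. **Movement correction** (`movement_correct()`): frame 20 of each
   trial is aligned to frame 20 of the per-pixel median trial by the
   integer translation (search radius ± 10 px) maximizing normalized
   cross-correlation over the interior; ties prefer the smaller shift,
   flat frames get zero shift with a warning. Only integer rigid
   translations are supported — the alignment this stands in for was
   anatomical/manual, and sub-pixel registration is out of scope. With
   only two trials the median frame is their midpoint and alignment is
   inherently a compromise; exact shift recovery needs ≥ 3 trials, the
   realistic case.

Responses (`extract_response()`) are read from the ROI spatial-mean
trace smoothed by a centered 3-frame moving average (window shrinking at
the trace edges): the maximum of the smoothed trace at or after stimulus
onset is located and the response is the mean of it and its two
neighbors (available neighbors only at the trace boundary, flagged).
For a boxcar transient this definition returns exactly 8/9 of the
plateau (the onset edge enters one smoothing window), which is the
"one smoothing step" accuracy quoted in the tests. Solvent subtraction
averages each animal's solvent trials per ROI. Glomerulus maps
(`build_glomerulus_map()`) are built from the max-projection of
diagnostic-odor responses: candidate pixels above one tenth of the
projection maximum are visited in decreasing order, re-centered on the
intensity centroid of their connected suprathreshold component (so a
plateau or a pair of overlapping spots yields one center), and accepted
greedily with a minimum center distance of one ROI side, up to the
requested count (23 for the dorsal antennal lobe use case).

## Profile mapping and statistics

Per-recording profiles (one row per receptor × animal, 80 odors) are
completed by group-median imputation: each missing value takes the
median of its (receptor, odor) group; a fully missing group is an error.
Receptor distinctness is tested with ANOSIM on Euclidean distances:
with average ranks $\bar r_B$, $\bar r_W$ of between- and within-group
pairwise distances among $n$ observations,

$$R = \frac{\bar r_B - \bar r_W}{n(n-1)/4}, \qquad
p = \frac{1 + \#\{R^\ast \ge R\}}{1 + n_{perm}},$$

with 9999 label permutations by default under an explicit seed. The
statistic is rank-based and hence invariant to monotone transforms of
the distances; the test suite checks it against an independent
pair-loop implementation, exhaustive permutation enumeration on six
observations, and `vegan::anosim`. NMDS uses `vegan::metaMDS`
(Kruskal stress-1, 20 random restarts by default, coordinates centered
and defined up to rotation/reflection); stress values are
implementation- and restart-dependent, so they are descriptive, not
reference quantities. Note that with fully tied dissimilarities
(e.g. four equidistant points) primary tie treatment legitimately
reaches zero stress in the plane.

Receptor-to-glomerulus mapping uses Spearman rank correlation (average
ranks on ties, pairwise-complete odors) between each receptor's and each
glomerulus' median profile over the shared odor panel, reporting the
best-matching glomerulus per receptor. Genotype comparisons run
two-sided Mann-Whitney U tests per odor — exact p for combined
n ≤ 20 without ties (covering the typical 8 vs 10 animals), normal
approximation with tie correction otherwise; identical samples give
p = 1 with a note. P-values are reported raw (per-odor), with a flag at
α = 0.05; no multiplicity correction is applied because the comparison
is reported odor by odor.

## Exon-skipping mutant model

Gene models are 1-based, inclusive, plus-strand: ordered exons on a
genomic sequence, introns inferred as the gaps and checked for canonical
GT..AG boundaries. `apply_genomic_deletion()` removes an interval,
re-threads coordinates, and flags a splice junction as disrupted when
the deletion touches its critical bases: for an acceptor the intron's
final AG or the exon's first base, for a donor the exon's last base or
the intron's initial GT. The modeling rule — a junction-disrupted exon
is skipped during splicing — mirrors the experimentally observed outcome
of such alleles; it is bookkeeping, not a splicing predictor.
`splice()` concatenates retained exons; `translate_cds()` applies the
standard genetic code up to the first stop and reports frame
preservation and premature truncation; `deletion_summary()` reports
residues removed and the integer percent (rounded half-up) of the
wildtype protein.

The packaged `example_or_gene()` is a synthetic six-exon OR-like gene
with a 1224 bp CDS (407 residues plus the terminal stop codon) and a
105 bp exon 4, so that an 8 bp deletion destroying the exon-4 acceptor
leads to an in-frame 105 bp transcript deletion removing 35 of 407
residues (9 %). Only these printed constraints are fixed; sequence
content and intron lengths are random under a seed.

## The synthetic-data module

Generators are the test bed for everything above and default to the
study conditions of the intended recordings: 500 ms stimuli with ≥
500 ms pre-stimulus windows and solvent stimulations at the beginning,
middle and end of each fly's experiment; 80-odor panels grouped by
chemical class; movies of 40 frames at 4 Hz, 344 × 260 px at 4 µm/px
with the odor on frames 9–16. All generators are bit-reproducible under
a fixed seed and carry their latent parameters as ground truth.

Choices worth stating:

* Spike trains are homogeneous Poisson within windows (spontaneous rate
  throughout, driven rate added during the stimulus); the analysis is
  count-based, so richer point-process structure (refractoriness,
  adaptation, bursting) would not change what the tests can show. A and
  B units draw amplitudes from two Gaussians (defaults 1.0 and 0.35,
  σ = 0.05).
* The calcium transient is a plateau over the odor frames with an
  exponential tail (decay constant 4 frames) — responses in this
  preparation persist through the 2 s stimulus; no rise kinetics are
  modeled. Glomeruli are flat-topped blobs whose plateau extends one
  filter half-width beyond the ROI, so the ROI mean of the true response
  field equals the configured amplitude even after median filtering.
* Photobleaching multiplies the resting fluorescence
  ($e^{-(t-1)/\tau}$, default τ = 60 frames), and the response increment
  is expressed in ΔF/F units of the unbleached baseline. This is the
  configuration in which a *subtractive* exponential correction — the
  method implemented by the pipeline — can recover the configured
  amplitude; had the response been generated inside the bleaching
  envelope, any additive correction would leave a multiplicative
  attenuation of about $e^{-5/\tau}$ that no stage downstream could
  remove, and amplitude recovery would be biased by construction.
* Inter-trial movement is an integer translation with replicate-padded
  edges (default range ± 3 px), stored as ground truth.
* Noise is additive Gaussian per pixel, after the shift.

What the generator does **not** emulate — and what passing tests
therefore cannot certify on real data: spike-waveform overlap during
strong responses (the amplitude-reduction problem that requires manual
recounting), adaptation across trials, non-rigid brain motion,
inhomogeneous bleaching, correlated (shot/photon) noise, glomerulus
shape variability, and real odor-to-receptor chemistry (tuning matrices
are draws from a breadth-parameterized prior, not chemical models).

## Problem sizes and numerical tolerances

The test suite runs the full study shape where it matters for
bookkeeping (53 recordings × 80 odors = 4240 values, 156 masked as
missing) and reduced movie geometries (≈ 80 × 100 px) elsewhere, chosen
so the complete suite runs in about two minutes; generator defaults keep
the full 344 × 260 px geometry. End-to-end amplitude recovery is
assessed over amplitudes 0.01–0.1 ΔF/F, τ ∈ {30, 60, 120} frames and
noise up to 0.2 × amplitude, with a median relative error of about 6 %
(criterion < 10 %); the residual bias is the smoothing edge effect (8/9)
partially cancelled by the background-window bleaching factor.
Monte-Carlo checks use 3–4 standard errors as tolerances. The
exponential fit runs Levenberg–Marquardt with up to 200 iterations and
τ bounded positive; ANOSIM permutation p-values are bounded below by
1/(1 + n_perm) by construction.

## Limitations

The pipeline reproduces analysis conventions, not raw-data processing:
there is no spike detection from continuous voltage, no dye/optics
model, no sub-pixel or non-rigid registration, no automatic glomerulus
identity matching across animals beyond the map-building heuristic, and
no splicing-strength prediction. Stress values from NMDS and p-values
from sampled permutations are seed-dependent by nature; both are
reported with their seeds and permutation counts.
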
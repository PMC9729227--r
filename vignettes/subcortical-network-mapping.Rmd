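---
title: "Mapping shared subcortical components of cortical functional networks"
author: "subcortnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping shared subcortical components of cortical functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Resting-state fMRI parcellations describe two large cortical attention
systems — a ventral and a dorsal network — as sets of cortical parcels whose
BOLD signals fluctuate together. Small subcortical nuclei (pulvinar,
superior colliculus, caudate head, brainstem nuclei) participate in the same
circuits, but they are systematically lost in group analyses: they are a few
millimetres across, poorly contrasted in structural MRI, and anatomically
variable between subjects, so averaging structurally aligned maps smears
them away. `subcortnet` implements the analysis strategy that rescues them:

1. map each subject's network by seed-based Pearson correlation and take the
   voxelwise **median** over that network's cortical seeds (robust to
   outlying seeds);
2. re-align the subjects **functionally** — a groupwise diffeomorphic
   registration driven by the correlation maps themselves rather than by
   anatomy — so that functionally homologous voxels coincide;
3. run one-sample sign-flip permutation inference with threshold-free
   cluster enhancement (TFCE) on the aligned maps, and extract subcortical
   regions of interest from the significant, well-correlated voxels;
4. characterise those ROIs structurally with streamline tractography
   (connectome matrices, degree and betweenness centrality, hemispheric
   tract-volume lateralization) and neurochemically by spatial correlation
   of their projection maps with annotation maps, using
   spatial-autocorrelation-preserving surrogate nulls.

Because the real inputs (resting-state fMRI runs, whole-brain tractograms,
receptor atlases) are large and external, the package ships a
**synthetic-cohort generator** with planted ground truth. Every stage of the
pipeline is exercised and tested against cohorts whose correct answer is
known by construction.

## The synthetic cohort

`cohort_config()` fixes the study conditions: 20 subjects on a
32 × 38 × 32 grid of 2 mm isotropic voxels, 120 BOLD timepoints, BOLD noise
sd σ = 1, signal weight w = 0.7, random warp amplitude 3 mm with 8 mm
smoothness. Two cortical networks A and B (eight cortical nodes each, four
per hemisphere, on lateral shells) share exactly four subcortical nodes
(two thalamus-like, two brainstem-like; one of each per hemisphere). World
x < 0 is the left hemisphere.

**BOLD model.** Each subject has two latent unit-variance series `L_A`,
`L_B` (temporally smoothed white noise, FWHM 3 samples — realistic
autocorrelation without a haemodynamic model). A voxel's series is

```
y(v, t) = w L_A(t) m_A(v) + w L_B(t) m_B(v) + ε(v, t),  ε ~ N(0, σ²)
```

where `m_X` is the warped network-X membership (subcortical voxels carry
both memberships). The node-voxel correlation with its latent therefore
concentrates at `w / sqrt(w² + σ²)`; the test suite checks this closed form
by simulation. At the default w = 0.7, σ = 1, within-network seed
correlations sit near 0.55 — strong but noisy, comparable to good
resting-state data at the voxel level after averaging over a seed.

**Misalignment.** Each subject's warp is a Gaussian-smoothed random
stationary velocity field, scaled to a 3 mm maximum displacement and
exponentiated by scaling-and-squaring (7 squarings). This guarantees a
diffeomorphism (the Jacobian determinant is checked; a failing draw is
regenerated at reduced amplitude, erroring after 5 attempts), and gives the
generator an exact inverse (`exp(-v)`) for free. There is no principled
estimate of the true interindividual misalignment being corrected; 3 mm
(1.5 voxels) was chosen as the scale at which subcortical spheres of 3.5 mm
radius partially dealign — enough to hurt naive averaging, small enough
that registration can plausibly recover it.

**Structure.** Ground-truth streamline counts define the structural graph:
within-network chains in each hemisphere, two callosal edges, symmetric
cortico-subcortical edges, and four extra bridging edges on one thalamic
node (`thal_R`), which makes it the planted hub — the highest-degree,
highest-betweenness subcortical node of the true graph. Same-hemisphere
right edges carry 20% heavier counts, planting a right-lateralized
structural asymmetry (the hub's extra same-hemisphere edges add to it).
Streamlines are drawn as quadratic Bézier arcs between warped node
centroids with control-point jitter sd 2 mm and ~1 mm vertex steps, one
polyline per unit of edge count.

**Annotation maps.** `generate_annotation_map()` returns
`ρ_p · ranknormal(reference) + sqrt(1 − ρ_p²) · G` with G a Gaussian random
field of stated smoothness and `ρ_p = 2 sin(π ρ_s / 6)` — the Pearson
coefficient whose bivariate-normal Spearman correlation equals the target
`ρ_s`. An exact copy (|ρ| = 1) admits no noise field and is only available
with zero smoothness. In the full pipeline the reference is a smoothed
(4 mm) log-density of the mean projection map: receptor-density maps are
smooth fields, and the raw streamline counts are zero over most of the
volume, which would otherwise let the background tie-block dominate the
ranks.

What the generator does **not** emulate: haemodynamics, physiological
noise, susceptibility distortion, realistic fibre geometry, partial-volume
effects. Passing tests show the pipeline recovers structure *of this kind*
under misalignment and noise; they do not validate preprocessing choices
for real acquisitions.

## Registration and template construction

`register_pair()` is a log-demons-style method: a stationary velocity field
is updated by gradient ascent on local normalized cross-correlation (cubic
window, radius 2 voxels) over three resolutions (×4, ×2, ×1; 30/20/10
iterations), with Gaussian smoothing of both the update (σ 1.5 voxels) and
the field (σ 1.0 voxel), and a maximum update magnitude of 1.2 voxels per
iteration. The local-correlation force is weighted by the local signal
strength `sqrt(var_F · var_M)`; without this, locally standardized noise in
empty regions produces forces as large as the signal's and the optimisation
chases noise. Steps that would break Jacobian positivity are halved (hard
error after five halvings); a similarity plateau at the finest level stops
early and returns the best-so-far warp. The optimisation is deterministic —
no stochastic sampling — so alignment is reproducible bitwise.

This stationary-velocity parameterisation deliberately replaces a
time-varying greedy SyN: it preserves the contract that matters
(diffeomorphic, correlation-driven, with exact inverses via `exp(-v)`) at a
fraction of the machinery.

`build_template()` seeds the template with the voxelwise mean, then
iterates: register every map to the template, average the warped maps, and
apply the inverse of the average warp to the result (the standard unbiasing
step that stops the template drifting toward the initial reference). The
default is four iterations. Because the registration kernel is
deterministic and usually converges against the first template, later
iterations frequently propose no improvement; an iteration whose mean
similarity drops below the previous best (beyond 1e-6) keeps the previous
state, so the logged per-iteration similarity is non-decreasing by
construction. The score itself is the mean local correlation over voxels
with appreciable local variance — the flat background would otherwise
dominate the mean.

## Inference

`one_sample_permutation()` computes voxelwise one-sample t statistics,
enhances them with TFCE (`H = 2`, `E = 0.5`, 100 thresholds,
26-connectivity — the enhancement method's recommended defaults), and
builds the family-wise null from the maxima of sign-flipped TFCE maps. The
smallest attainable p is `1 / (1 + n_permutations)`; the `(1 + b) / (1 + m)`
convention avoids zero p-values. Inference refuses cohorts under 8 subjects
(the sign-flip space is too small for FWE at 0.05). The default 5000
permutations matches full-scale practice; the pipeline's desk-scale default
is 500.

Subcortical ROIs are the 26-connected components of voxels that are FWE
significant (α = 0.05), exceed the median-correlation floor r > 0.1 (which
screens out voxels that are significant but weakly correlated), and lie in
the subcortical mask. Components smaller than 2 voxels are dropped. Centres
of gravity are unweighted means of member-voxel world coordinates —
intensity weighting is a defensible alternative, but unweighted centres are
the simpler default and the choice is isolated in one place. Hemisphere
assignment uses the centre-of-gravity x sign with a ±1 mm midline band.
Whether full FWE or uncorrected significance should define the ROIs is
genuinely open; FWE is the default and `alpha` is exposed.

## Structural network

Streamline-to-ROI assignment uses traversal semantics: a polyline is
resampled at half the minimum voxel dimension, mapped to voxels, and the
set of distinct ROI labels it crosses is its hit set; it is retained iff it
crosses at least two ROIs. Every unordered pair in the hit set increments
the connectome count — so a streamline crossing three ROIs contributes
three edges. Binarization has **no** count threshold. Degree centrality is
`degree / (N − 1)`; betweenness uses unweighted shortest paths with
standard fractional tie-splitting, normalized by `2 / ((N − 1)(N − 2))`,
computed with igraph and verified exactly against a hand-written
Brandes/BFS oracle in the tests. Cohort aggregation is the per-node median.

Lateralization compares paired left/right measures — hemispheric tract
volume (nonzero-voxel volume of the density map of streamlines connecting
two same-hemisphere nodes, in cm³) or hemispheric mean correlation — with
a Shapiro–Wilk gate (α = 0.05) choosing a paired t-test or a Wilcoxon
signed-rank test. Midline ROIs (|x| < 1 mm) are excluded from hemispheric
sets.

## Annotation correlation and surrogate nulls

Projection maps are density maps of streamlines linking the nuclei of
interest to any other network node. After parcellation (per-parcel means;
the synthetic parcellation is a cubic tiling, 10 mm blocks in the
pipeline), per-subject Spearman correlations with each annotation map are
tested against zero with a one-sided Wilcoxon signed-rank test, Bonferroni
corrected by the number of maps (0.05/17 rounds to 0.003; contrasts over
3 systems use 0.05/3 ≈ 0.017).

The per-subject Wilcoxon is a *descriptive* cohort analysis with a caveat
worth understanding: each annotation map is a single realized random field,
and its realized correlation with the cohort's (highly similar) projection
maps is a sampling draw of its own. The subjects act as near-replicates of
that one draw, so the Wilcoxon will confidently flag a zero-target map
whose realized correlation happens to land a few hundredths above zero —
the generator even pins the voxel-level correlation to the target exactly
(its noise field is residualized against the reference), but parcel
averaging and rank transformation reintroduce a draw on the order of
±0.05. Deciding whether an observed spatial correlation exceeds what
autocorrelation alone produces is precisely the surrogate test's job, and
the pipeline's planted-pattern recovery (`$annotation$flagged`) is
therefore based on it.

The pairwise test on the cohort-average map needs a null that preserves
spatial autocorrelation — naive value permutation wildly inflates false
positives on smooth maps (the test suite measures this directly). The
surrogate generator permutes the parcel values, smooths them with Gaussian
distance kernels at 10 log-spaced scales, selects the scale and the
non-negative affine variogram rescaling that best fit the source variogram
(weighted least squares with 1/γ² weights, i.e. relative error, over
25 equal-count distance bins restricted to the shortest quartile of
pairwise distances — the short range is what carries the autocorrelation),
adds white noise for the fitted nugget, and finally reassigns the source
value multiset by rank, so the marginal distribution is preserved exactly.
When there are more than 20,000 parcel pairs the variogram estimator uses a
fixed random subset. The desk-scale default is 500 surrogates (300 in the
pipeline); 5000 mirrors full-scale practice.

## Problem sizes and numerical choices

The shipped defaults run the full pipeline in a few minutes on one CPU:
20 subjects, 32 × 38 × 32 × 120 BOLD, 16 + 16 seed maps per subject,
two 4-iteration template builds, 500 permutations, 300 surrogates. The
test suite uses the same spatial scale with reduced counts where the check
does not need the full cohort (e.g. 2 template iterations in the repeated
alignment-gain experiment, 60-timepoint subjects for the attenuation law).

Numerical conventions worth knowing:

* voxel indices are 0-based with the voxel-centre convention; volumes are
  written float32 (maps) or int32 (labels);
* zero-variance voxels get r = 0 (not NaN), and zero-variance voxels under
  permutation get t = 0, keeping every downstream statistic total;
* medians over an even number of maps average the two central order
  statistics;
* partial correlations default to Ledoit–Wolf shrinkage toward the scaled
  identity (the analytic formula; shrinkage 0 reproduces the plain
  precision-matrix estimate and is used by the analytic oracle tests) —
  whether the reference analyses regularized this step is not documented,
  so both modes are exposed;
* TFCE integrates both signs separately (the negative side by enhancing the
  negated map);
* connected-component labelling is deterministic in scan order, so ROI ids
  are reproducible.

## Limitations

The registration kernel is tuned for correlation maps with blob-like
topology at 2 mm desk scale; real full-resolution data would need a
different resolution schedule. The annotation analysis assumes volumetric
parcels with Euclidean centroid distances — surface-constrained nulls are
out of scope. The generator's streamlines are geometric arcs, not fibre
reconstructions; selection and mapping logic is what is being tested, not
tractography. And the planted-recovery results say nothing about
sensitivity at real-data effect sizes, only that each stage is wired
correctly and calibrated under its own null.
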
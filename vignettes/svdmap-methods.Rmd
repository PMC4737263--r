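---
title: "Methods: spatial probability mapping of small vessel disease lesions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial probability mapping of small vessel disease lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdmap)
```

`svdmap` asks a spatial question about cerebral small vessel disease: do
the lesions that present with acute stroke symptoms (recent small
subcortical infarcts) occupy different territory from the lesions that
accumulate covertly (white matter hyperintensities, WMH, and lacunes)?
The package maps every subject's binary lesion masks into one anatomical
space, averages them into voxel-wise probability-density (PD) maps per
lesion class, quantifies the maps in atlas regions, and compares the
regional profiles with a rank-based test. This vignette documents the
models, the tunable parameters, and the design decisions, in that order.

## The probability-density model

For lesion class $c$ and subjects $i = 1 \dots N$ with binary masks
$M_i^{(c)}$ on a common grid, the PD at voxel $v$ is

$$\mathrm{PD}^{(c)}(v) \;=\; \frac{1}{N_c}\sum_{i} M_i^{(c)}(v),$$

the proportion of the population with a class-$c$ lesion involving $v$.
The denominator matters: every subject contributes to the infarct and WMH
maps, but only subjects who *have* lacunes contribute to the lacune map
(`denominator_mode = "affected_only"`), because prevalence and spatial
preference are different questions — mixing them would scale the lacune
map down by the prevalence. Each voxel value is therefore a multiple of
$1/N_c$; `pd_map()` records $N_c$ and the tests verify mass conservation
($\sum_v \mathrm{PD}(v)\,N_c$ equals the total lesioned-voxel count).

Regional values are read with small cubic regions of interest placed on
each atlas structure. A "2-mm ROI" is a $2\times2\times2$-voxel cube at
1 mm isotropic resolution (8 mm³): a literal 2 mm³ region would be below
the voxel size, so the cube interpretation is used and the side is
configurable (`roi_side_mm`). The ROI centre snaps to the in-region voxel
nearest the structure's centroid, which keeps the cube inside ring-shaped
regions such as the periventricular shell. The ROI summary is the mean PD
over the cube by default; `max` is available by flag. Which of the two a
regional report should use is genuinely open — the mean is smoother and
was chosen as default; at PD values far from the ceiling the two track
each other closely.

## Multispectral segmentation by minimum-variance quantization

WMH segmentation fuses two sequences into colour space: the FLAIR-like
volume (lesions hyperintense) is percentile-clipped (1st/99th), rescaled
to 0–255 and mapped to red; the T1-like volume to green; blue is zero.
Which sequence feeds which channel is a convention; red was chosen as the
lesion-bearing channel and the extraction rule reads centroid *red*
values. Rounding to whole 8-bit levels makes the colour table finite, so
the quantizer can work on unique colours weighted by voxel count.

Minimum-variance quantization partitions the colours into $K$ clusters
minimizing $\sum_k \sum_{c \in C_k} w_c\,\lVert x_c - \mu_k\rVert^2$. The
implementation is deterministic (no random initialization, hence exactly
reproducible):

1. **Divisive splits.** Starting from one cluster, each cluster is
   tentatively split by an exhaustive threshold scan along each of its
   weighted-covariance eigenvectors and each colour axis; every split
   candidate is polished by Lloyd assignment/update iterations and the
   configuration with the lowest objective is kept, until $K$ clusters
   exist.
2. **Local search.** Accepted configurations are refined by Lloyd
   iterations to convergence (tolerance $10^{-9}$, at most 100
   iterations) plus a best-improvement single-point swap search (moving
   one colour between clusters whenever that strictly lowers the
   objective, with the exact weight-transfer update). On colour tables of
   at most 512 entries the swap search also polishes tentative
   candidates, where it costs microseconds.
3. **Merge–resplit rounds.** Up to five rounds attempt to merge each
   cluster pair and resplit some cluster; an accepted round must strictly
   lower the objective. This escapes partition-level minima that
   single-point moves cannot reach.

The combination was chosen after brute-force enumeration on small colour
tables showed that plain divisive-plus-Lloyd schemes land in local minima
several percent above the optimum; with all three stages, 300/300 random
instances of up to 12 colours and $K \le 3$ matched the exhaustive
optimum exactly, and the production cost on a 48³ brain (~12k unique
colours, $K = 5$) stays at a few seconds.

$K$ defaults to 5 (CSF, grey, white, lesion, and one spare for mixed
intensities); the WMH class is the cluster(s) whose centroid red reaches
the 100th percentile of centroid reds, i.e. the single most hyperintense
cluster. Both are configurable because neither the cluster count nor the
class-assignment rule is canonical. Voxels under the supplied acute
infarct mask are removed from the WMH mask so the symptomatic lesion is
not double-counted as WMH — infarct masks are treated as ingested ground
truth (in practice they come from diffusion imaging, which the intensity
model here does not simulate).

## Lacune detection

Lacunes are fluid-filled cavities with CSF-like signal, at least 3 mm in
diameter. The detector thresholds the FLAIR volume below a cutoff — the
midpoint of the CSF and grey-matter means when tissue means are known,
otherwise Otsu's threshold on the brain voxels — then labels 26-connected
components and filters:

* components overlapping the ventricle mask are discarded (periventricular
  CSF, not cavities); the threshold is global, not per-slice;
* components touching the brain-mask boundary are discarded (sulcal or
  surface CSF);
* the equivalent spherical diameter $(6V/\pi)^{1/3}$ must lie in
  $[3, 15]$ mm. The lower bound is the field's definition; the upper
  bound is a package convention (configurable) separating lacunes from
  larger cavities;
* sphericity $\pi^{1/3}(6V)^{2/3}/A \ge 0.3$, with $A$ estimated by
  counting exposed voxel faces. Face counting overestimates the area of a
  smooth surface by roughly 1.5×, so a digital sphere scores about 0.66,
  not 1 — the default cutoff is set accordingly and encodes "round or
  ovoid" loosely on purpose.

Components are returned sorted by volume with their morphometry, so a
reviewer can re-apply different cutoffs without re-detecting. Manual
editing (which an interactive protocol would allow) is out of scope for a
batch pipeline; user-supplied edit masks can be ANDed/ORed onto the
result instead.

## Template selection and spatial normalization

The population-representative subject minimizes the Mahalanobis distance
$\sqrt{(x-m)^\top S^{-1}(x-m)}$ between its feature vector $x$
(intracranial, brain, ventricular, WMH volumes) and the component-wise
cohort median $m$, under the cohort sample covariance $S$ (denominator
$n-1$, computed on raw volumes, stabilized with a ridge of
$10^{-8}\,\mathrm{tr}(S)/4$ on the diagonal). Raw rather than normalized
volumes are used because the Mahalanobis form already whitens the
features; the ridge only guards against degenerate cohorts. For even $n$
the median is the usual midpoint average. Ties break to the lowest index.

Registration is intensity-based with a mean-squared-error cost, suitable
because the synthetic sequences are mono-modal; cross-modal registration
would need a different similarity and is out of scope. The optimization
is fully deterministic:

1. block-mean pyramid with factors 4, 2, 1;
2. at the coarsest level, a search stage — translation initialized from
   the intensity centres of mass and an exhaustive grid over initial
   rotations (±6° in 3° steps per axis), with the three best candidates
   briefly refined and the winner kept. Without this stage the
   near-ellipsoidal head (like a real brain at 4 mm blur) shows
   rotational local minima;
3. BFGS per level from the previous level's estimate — rigid (6 dof) at
   the coarsest level, then the requested dof (12: rotations,
   translations, log-scales, shears). Fixed-step gradient descent was
   tried first and rejected: a step size that moves rotations usefully
   either stalls translations or diverges, while quasi-Newton scaling
   handles the mixed parameter units cleanly and is equally
   deterministic from a fixed start.

The estimated transform maps moving-world to fixed-world coordinates.
Masks follow by pull-back resampling with trilinear interpolation and
binarization at 0.5 — volume-preserving in expectation and exact for
integer-voxel translations (verified by test). The two-step chain of the
analysis (subjects → representative by 12-dof affine; representative →
template by rigid) is kept as composable transforms; the synthetic
template grid plays the standard-space role. On 20 synthetic subjects
with misalignments up to 5°/5 mm/3% scale, the median in-brain voxel
displacement error of the recovered transforms is well under one voxel
(about 0.06 at 64³), with an occasional subject converging to a shallow
12-dof minimum around 1.4 voxels — registration quality is therefore
checked (final cost must beat the identity cost) and failing subjects are
excluded from PD denominators and listed in the manifest rather than
silently dropped.

## Friedman comparison of regional profiles

Whether two lesion classes share a spatial distribution is tested on the
regional PD table with Friedman's two-way ANOVA by ranks: blocks are
regions, treatments are lesion classes, and within each block the values
are midranked. With rank sums $R_j$ over $n$ blocks and $k$ treatments,

$$\chi^2_F \;=\; \frac{(k-1)\sum_j \left(R_j - n(k+1)/2\right)^2}
{\sum_{ij} r_{ij}^2 - n\,k(k+1)^2/4},$$

which reduces to the textbook $\frac{12}{nk(k+1)}\sum_j R_j^2 - 3n(k+1)$
without ties and applies the standard tie correction with them. The
p-value is exact — full enumeration of all $(k!)^n$ within-block
orderings — whenever that count is at most $2\times10^6$, otherwise the
$\chi^2_{k-1}$ approximation is used. The blocking itself is a design
choice: left and right PDs of each region are averaged into one block by
default (regions, not hemispheres, are the replication unit), with
`average_laterality = FALSE` keeping sides as separate blocks. Under the
null the exact-or-asymptotic rule holds its size: over 2000 simulated
20×3 tables the empirical type-I error at $\alpha = 0.05$ is about
0.055. Only the planned pairwise comparisons are run; no multiplicity
correction is applied, matching the single-comparison design.

## The synthetic cohort: what it emulates, what it does not

The generator exists so every stage has ground truth. The template is a
1 mm isotropic grid (64³ by default; demos use 48³) with nested
ellipsoids — intracranial space, a grey cortical ribbon, white matter —
paired lateral ventricles, six deep grey nuclei (caudate, lentiform,
thalamus, left/right), external capsules, a brainstem, and a
corticospinal-tract tube (radius 2.5 mm) descending from the corona
radiata between lentiform and thalamus into the brainstem, rasterized
from a cubic Bézier curve per hemisphere. The atlas labels all of these;
the tract is assigned last so its label is exactly the rasterized tube
within the intracranial space (which makes independent re-rasterization
an exact oracle in the tests). Intensities are tissue means (FLAIR 40/
120/100 and T1 50/110/150 for CSF/grey/white) plus i.i.d. Gaussian noise,
default SD 5 — a WMH contrast-to-noise of 16 on FLAIR, comfortably above
the CNR ≥ 3 regime the segmentation tests require.

Per subject: exactly one infarct (an ellipsoid centred on a
tract-curve point, in-plane diameter drawn from 6–16 mm, hard-capped at
20 mm — the "small subcortical" criterion); multifocal WMH (Poisson count,
mean 8, each focus an ellipsoid with 2–5 mm radii, seeded in the
periventricular shell with probability 0.7, else in white matter — the
periventricular weighting emulates where WMH burden concentrates, and the
placement weights are free parameters of the phantom, not estimates from
any dataset); and, in 46.5% of subjects, one or occasionally two lacunes
(spheres, diameters uniform on 3–15 mm by default, CSF intensity on both
sequences, planted in deep grey or white matter away from ventricles and
infarct). The WMH volumetric feature equals the truth-mask voxel count
times voxel volume exactly, by construction. Lesion intensities replace
tissue intensity with a class mean — no partial-volume modelling, which
is sufficient for testing threshold and quantization logic but means
segmentation here is easier than on clinical data.

Each subject is then misaligned by a random affine (rotations and
translations uniform within ±5° and ±5 mm, per-axis scales 0.97–1.03)
recorded as `true_affine`; volumes are warped once in their noiseless
form and noise is added in subject space, so interpolation does not
smooth the noise. Per-subject seeds are drawn from the master seed's own
RNG stream (`sample.int` prefix), which decorrelates subjects while
keeping subject $i$ reproducible independent of cohort size; a
linear-congruential hash of (seed, index) was tried first and rejected
because linearly spaced Mersenne-Twister seeds produced visibly
correlated lesion-prevalence draws.

What passing tests on this phantom show: the algorithms implement their
definitions (quantizer optimality, exact rank tests, mass-conserving PD
maps), the registration recovers known transforms under realistic
misalignment ranges, and the pipeline is deterministic end to end. What
they do not show: robustness to bias fields, partial volume, motion,
cross-scanner variation, or anatomy beyond ellipsoid-level realism. Real
cohort sizes (a few hundred subjects at 1 mm whole-brain resolution) are
emulated at scaled-down grid sizes — 48³ for the demo pipeline and most
tests, 64³ for registration recovery — chosen so a full demo run takes
about a minute.

## Numerical and degenerate-input conventions

* Voxel indices are 0-based in the voxel-to-world affine, world axes
  RAS+, the grid centre at the world origin; transforms are serialized as
  plain-text 4×4 matrices.
* Trilinear interpolation tolerates $10^{-6}$ voxel of round-off outside
  the grid faces before declaring a sample out of bounds; otherwise
  near-identity transforms would drop edge voxels to the fill value.
* Mask binarization threshold after interpolation is 0.5.
* Constant images are a rescale error (naming the offending sequence);
  fewer distinct colours than $K$ reduces $K$ with a warning; an
  all-tied Friedman table yields statistic 0 with a degeneracy warning;
  an empty brain mask, cohorts smaller than 2 (generation) or 3
  (representative selection), and grid mismatches are errors that name
  the stage and subject when raised inside the pipeline.
* Quantizer ties (equal split gains, equidistant centroids) resolve to
  the lowest index; eigenvector signs are fixed by making the first
  non-zero component positive. Everything downstream of a seed is
  bit-reproducible, which the end-to-end test asserts literally.

## Known limitations

Beyond the phantom realism noted above: the registration cost is
mono-modal MSE; nonlinear (diffeomorphic) normalization is out of scope,
so distant anatomy alignment is only affine-good; the lacune detector's
sphericity is estimated from voxel faces and under-scores small
components; PD maps are unsmoothed counts (no kernel density estimation
and no voxel-wise inference — regional rank tests are the inferential
layer); and the Friedman comparisons treat regions as exchangeable
blocks, ignoring spatial autocorrelation between neighbouring regions.
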
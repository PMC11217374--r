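---
title: "Quantifying synaptic connectivity from volume-EM skeletons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptic connectivity from volume-EM skeletons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptometry)
```

## The problem

Most cortical synapses sit in the neuropil, the dense feltwork of axons,
dendrites, spines and glial processes between cell bodies. FIB-SEM imaging
yields aligned stacks of serial sections at roughly 5 × 5 nm in-plane and
20 nm section pitch, in which synaptic junctions appear as dark,
electron-dense pre- and postsynaptic thickenings. Rather than densely
reconstructing every membrane, a far cheaper representation retains almost
all connectivity information: each nerve fiber is reduced to a 3D
*skeleton* (a polyline for the shaft plus short branches for dendritic
spines), and each segmented junction is linked to its presynaptic axon and
postsynaptic dendrite. `synaptometry` implements the full quantification
panel on top of that representation: volumetric synapse densities,
excitatory/inhibitory proportions, linear densities on spines and shafts,
fiber-class length densities in m/mm³, multi-contact statistics and bouton
shapes, together with seeded synthetic generators that make every stage
testable without any imaging data.

## Segmentation model

Junctions are extracted by the classical thresholding pipeline: a
separable Gaussian pre-filter suppresses pixel noise, a single global
gray-level threshold selects electron-dense voxels (ties at the threshold
are foreground, since darker = denser), and 3D connected-component
labeling with a minimum object size yields one object per junction.
Defaults and their reasons:

* `sigma_xy = 1` pixel, `sigma_z = 0`: with a 20 nm section pitch against
  5 nm pixels, smoothing across sections mixes unrelated structures, so
  only in-plane smoothing is applied by default.
* `connectivity = 26`: thresholded synaptic densities are thin curved
  sheets; full 3D connectivity keeps them in one piece. 6 and 18 are
  selectable, and components under 6-connectivity always refine those
  under 26 (tested).
* Threshold, minimum size and connectivity are data-dependent and exposed
  as configuration; nothing in the pipeline hard-codes them.

Classifying a junction as asymmetric (AS, excitatory; prominent PSD) or
symmetric (SS, inhibitory; thin PSD) requires inspecting every serial
section through the junction and remains expert judgement. The package
takes types from a label volume or sidecar table; `estimate_syn_type()`
offers a slab-thickness heuristic but is explicitly flagged
non-validated and is never used implicitly.

## Unbiased counting and shrinkage

Synapse counts use an unbiased 3D counting frame: a brick bounded by three
acceptance and three exclusion planes (by default the low-x/y/z faces),
the exclusion planes extended beyond the frame. An object is counted when
it intersects the closed brick — touching an acceptance face is fine — and
touches no extended exclusion plane. For voxel objects "touching" means a
voxel center on or beyond the plane; sub-voxel geometry is ignored. Under
tiling this counts every object exactly once, and uniform random placement
is counted without bias (both are tested, the latter by Monte Carlo with
10⁴ objects).

Tissue shrinks during EM processing. The correction factors are the
post/pre-processing ratios — 0.87 for volumes, 0.91 for surfaces, 0.96 for
lengths — and measured quantities are *divided* by them. The direction is
fixed by a consistency check: a 2048 × 1536 px × 305-section stack at
5 × 5 × 20 nm measures ≈ 480 µm³, which corrects to ≈ 551 µm³, matching
the published corrected volume (≈ 549 µm³) up to the unstated inset of
the counting frame; the package makes no attempt to reproduce that inset.
All coordinates in files stay in measured space; corrections are applied
only at metric computation.

## Skeleton metrics

* **Lengths** are 3D arc lengths along the skeleton. Linear synapse
  densities are synapses per micron of *shaft*; spine-branch length is
  excluded from the denominator, and for consistency the m/mm³ length
  accounting uses shaft length too (a clearly-labeled switch can include
  spine branches).
* **Inclusion rule**: fibers with less than 3 µm of shaft are excluded
  from linear densities. Whether the filter applies to measured or
  corrected length is underdetermined; it is applied to the *corrected*
  length for unit consistency with the reported densities. Excluded
  fibers are retained as flagged records, never dropped silently.
* **Classification**: a fiber postsynaptic to ≥ 1 junction is a dendrite
  (spiny if it has ≥ 1 spine branch, else smooth); a presynaptic fiber is
  an axon (myelinated if flagged, else excitatory when all its junctions
  are AS, inhibitory when all SS); a fiber with no attachments is
  non-synaptic. A fiber that is both pre- and postsynaptic, or an axon
  mixing AS and SS, raises a classification error by default — the
  published scheme defines only pure classes, and silently coercing a
  mixed axon would bias the excitatory/inhibitory split. `on_conflict =
  "flag"` returns the conflict as data instead.
* **Spine head vs neck**: no operational rule is published; a
  spine-branch attachment counts as the head when its arc-length position
  exceeds 50% of the branch length from the shaft (threshold
  configurable).
* **Bouton shape**: a synapse is attributed to a terminal bouton when its
  presynaptic attachment node is an endpoint (degree ≤ 1) of the axon
  skeleton, else en passant. Endpoints within a configurable margin
  (default 0.5 µm) of the volume faces are truncation artifacts, so such
  attachments are flagged censored and excluded from the percentages when
  bounds are supplied.
* **Axon linear densities** count all presynaptic attachments regardless
  of target, and no edge correction beyond the 3 µm filter is applied to
  boundary-cut fibers.

## Statistics

Between-group comparisons follow the fixed nonparametric strategy:
chi-square (Pearson, no continuity correction) for contingency tables,
Mann-Whitney U for two groups, Kruskal-Wallis for several, with pairwise
comparisons Bonferroni-multiplied by the number of pairs. Normality and
homoscedasticity screens are advisory only; the nonparametric path is
always taken. Numerical choices:

* Mann-Whitney uses exact enumeration when both samples have ≤ 8
  observations and no ties, otherwise the tie-corrected normal
  approximation with continuity correction (the two-sided exact p at
  n₁ = n₂ = 5 is verified against all 252 labelings).
* The Kruskal-Wallis H is tie-corrected; its p-value comes from
  exhaustive enumeration of all distinct group assignments when their
  number is ≤ 2 × 10⁵ and from the χ² upper tail otherwise. The exact
  path exists because at the small per-group n typical of per-region
  fiber samples the χ² approximation is visibly off; it is verified
  against an independent permutation null.
* The published post-hoc procedure after Kruskal-Wallis is not specified
  beyond "Bonferroni correction for pairwise comparisons"; pairwise
  Mann-Whitney is the default and Dunn's rank z-test is available as an
  alternative.
* All-identical observations short-circuit to H = 0, p = 1.

Region reports serialize to JSON with fixed key order and fixed rounding
(densities and percentages at two decimals, the printed precision), so
identical inputs give byte-identical files; every pipeline run embeds a
provenance block (config hash, seed, tool version). File writes are
atomic (temp + rename).

## What the synthetic generators emulate

The generators define the study conditions for all property tests; their
defaults are the stratum-radiatum (SR) magnitudes and were chosen once.

**Phantom stacks** place dark blobs (gray 60 ± 8 on a 160 ± 12
background, 8-bit) grown as random-walk core paths dilated by
6-neighborhood shells — compact sausages rather than spheres, so
connectivity settings are genuinely exercised. Core paths prefer in-plane
steps because at 5 nm pixels vs 20 nm sections real junction densities
extend over many pixels but few sections. Default blob sizes (150–500
voxels) are at the scale of a postsynaptic density at this resolution.
Blobs keep a Chebyshev separation > 1 voxel so they can never merge under
26-connectivity; infeasible packings error out after bounded retries.
Phantoms are statistical, not photorealistic: they contain no membranes,
vesicles, mitochondria or gradual gray-level texture, so passing recovery
tests shows the geometry/labeling machinery is correct, not that the
threshold would work on real tissue.

**Fiber networks** fill a region (default 500 µm³ corrected) with
persistent random walks (step 0.5 µm, straightness 0.8, optional vertical
orientation bias) until each class reaches its published SR length
density, trimming the last fiber so realized lengths land within 5% of
target; walks are clipped at the volume faces, as real fibers enter and
leave a stack. Spines (3 per µm of spiny shaft, two-node neck+head
branches ≈ 0.7 µm) are attached to shaft nodes. Synapses are Poisson
along axon shafts at 0.38/µm (excitatory) and 0.33/µm (inhibitory) of
corrected length, ≈ 5% at terminal boutons, and are wired to dendrites
with an AS-on-spine fraction of 92.8% of AS, 60% of SS on shafts, an
84.38/15.63 head/neck split for SS on spines (every SS-carrying spine
preferentially also carries an AS), a configurable propensity to re-use
an already-contacted dendrite, and smooth-dendrite shafts weighted
more attractive per micron than spiny shafts (≈ 7.4×, the ratio of the
published smooth vs spiny-shaft linear densities). Geometry is built in
measured space and the targets are compensated through the shrinkage
factors, so analysing generated data with the same factors recovers the
targets — which also exercises shrinkage coherence end to end.

Two modeling consequences are worth stating plainly. First, the four-way
target mixing default completes the published SR ranges to a partition
summing to the SR AS/SS split; it is an SR-like default, not a printed
row. Second, a fiber can only be classified by the synapses it actually
establishes, so short intended axons that draw zero synapses are returned
as non-synaptic — exactly the selection a human tracer faces. In a small
volume this inflates the non-synaptic share above its nominal target, so
generator-recovery checks pool synapse counts over the *generated*
(`intended_class`) ensemble, which is the unbiased Poisson ensemble; the
realized-length invariant is likewise stated per generated class.

## Problem sizes used in the checks

The shipped tests and the acceptance script run phantoms of 192 × 192 ×
48 voxels with 30 junctions, networks of 150–500 µm³ (≈ 300–1300
synapses), 10⁴-object Monte-Carlo draws for counting-frame behaviour, and
exhaustive enumeration for the small-sample statistical oracles. These
sizes put every Monte-Carlo tolerance at 3 standard errors of the
quantity being recovered.

## Known limitations

* AS/SS classification is not automated; the heuristic is deliberately
  non-validated.
* No edge correction for fibers truncated by the stack boundary beyond
  the 3 µm filter and bouton censoring.
* Linear densities count all attachments present in a skeleton, including
  synapses on spines that may fall outside a counting frame.
* Synapse-area morphometrics, perforated-PSD subtypes, fiber calibers and
  mesh reconstruction are out of scope; skeletons are the representation.
* Axons mixing AS and SS are surfaced as errors rather than given a class
  of their own; the published scheme contains no such class, and the
  choice is localized in `classify_fibers()` should one be wanted.

## A worked example

```{r example, eval = FALSE}
nw <- generate_fiber_network(network_spec(volume_um3 = 500), seed = 1)
stopifnot(nrow(validate_fibers(nw$network, nw$synapses)) == 0)
report <- build_region_report("SR-like", nw$network, nw$synapses,
                              volume_um3 = 500)
glance(report)
tidy(report, "lengths")
autoplot(report)
```
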
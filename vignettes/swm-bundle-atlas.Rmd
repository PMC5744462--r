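---
title: "Clustering and atlasing superficial white matter bundles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering and atlasing superficial white matter bundles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swmclust)
```

This vignette explains the model behind `swmclust`, the parameters that
matter, the numerical and design choices made where the method leaves
room, and what the synthetic tests do and do not establish about real
data.

## The problem and the distance

Short association (U-shaped) fibers connect adjacent gyri through the
superficial white matter. They are short (tens of mm), numerous, and far
more variable across individuals than the deep tracts, so the only
workable definition of a "bundle" at population level is *a cluster of
similar fibers that recurs across most subjects*. Everything in the
package is built on one fiber metric, the symmetrized maximum
corresponding-point distance between two polylines resampled to the same
point count (51 by default):

$$d_{ME}(A,B) = \min\Big(\max_i \lVert a_i - b_i\rVert,\;
                         \max_i \lVert a_i - b_{N-1-i}\rVert\Big).$$

Taking the *maximum* over corresponding points makes the metric
restrictive — two fibers are close only if they run together along their
whole course — and taking the minimum over the two traversal directions
removes the arbitrary orientation of tracked streamlines. All coordinates
are world millimetres; voxel indices never appear outside the
parcellation container, because every threshold in the method (5, 7, 10,
30 mm, ...) is metric.

Resampling parameterizes by cumulative chord length. A consequence worth
knowing: points equidistant *along the original polyline's arc* are not
exactly equal-chord on the new polyline, so resampling is exactly
idempotent only on equal-chord inputs (straight lines, uniform circular
arcs); on smooth curves repeated resampling converges quickly and the
tests assert exactly that, not bitwise idempotence.

## Intersubject clustering

A group's centroids are pooled and every pair within `d_clmax` of each
other (30 mm default; 15–45 mm is the sensible range for fiber data)
receives an affinity $a_{ij} = e^{-d_{ij}/\sigma^2}$ with the similarity
scale $\sigma^2 = 60$ mm. Two deliberate readings are recorded here:

* the exponent is $d/\sigma^2$, exactly as the formula is conventionally
  printed for this method, not $d^2/\sigma^2$;
* pairs beyond `d_clmax` are *absent edges*, not zero affinities. Treating
  them as zeros would make cluster affinities depend on the cutoff in a
  pathological way.

Average-link agglomerative clustering then repeatedly merges the pair of
clusters with the highest current affinity. The affinity between two
clusters is the mean of the original edge affinities between them,
weighted by the number of stored edges; on a complete graph this is
exactly size-weighted UPGMA, which is what the test suite's independent
dense oracle implements. Ties are broken toward the pair whose clusters
contain the smallest original element indices, so runs are deterministic.

One bookkeeping nuance: with $N$ elements, $M$ affinities and $n_C$
unconnected elements, the loop bound of the classic algorithm is
$N - n_C$, but the number of merges actually achievable is
$N - (\#\text{connected components})$ — one less than the bound even on a
connected graph, and less again when several non-singleton components
exist. The dendrogram therefore keeps one root per connected component
and the tests assert the component-based count.

The dendrogram is cut *adaptively*: walking breadth-first from each root,
a node is emitted as a cluster as soon as the maximum pairwise $d_{ME}$
among its leaf descendants is at most `d_clmax`; otherwise its children
are enqueued. Maximum pairwise distances are recomputed per node with an
early exit once the bound is exceeded — the contract is the partition,
not the traversal strategy. The partition is total: leaves reached as
singletons become singleton clusters, which the reproducibility filter
then removes.

A cluster is *representative* when its fibers span at least
`ceil(min_frac * n_subjects)` distinct subjects. With the default 75%
this gives 28 of 37 subjects (the ceiling reading is anchored by that
printed pair), 21 of 27, 6 of 8.

## Selection, two-group atlas, bagging

Fibers of 35–85 mm (inclusive bounds — "between" is read inclusively and
the bounds are configurable) are candidate short fibers; shorter ones are
mostly artifacts, longer ones are not U-fibers. Candidates closer than
10 mm (strict `<`) to a reference set of deep-white-matter bundles are
discarded; for speed only a 20% per-bundle sample of the reference is
used, drawn once per run from a seed, uniformly without replacement
within each bundle so the sample keeps each bundle's density. With a full
sample the result is seed-independent, which the tests check.

Two independent groups of subjects are clustered separately, and a bundle
enters the atlas only if a bundle in the other group overlaps it: both
intersection fractions (share of fibers with a counterpart closer than
5 mm, strict `<`) must exceed 50% (strict `>`). Multi-way overlaps are
resolved greedily by descending mean fraction, one match per bundle —
the method itself does not specify a resolution rule, so determinism
decided. Matched pairs are fused (fiber multiset union): at this spatial
scale, finer granularity than the fused bundle is not trustworthy across
subjects.

For a reproducibility measure, the whole two-group construction is
repeated (10 times by default) on random subject subsets (two groups of
27 from the pool), each bundle is reduced to a centroid (reversal-aligned
pointwise mean — a single-fiber bundle is its own centroid), the same
clustering machinery runs over the centroids of all repetitions, and
clusters drawing on at least 8 of 10 repetitions survive, carrying the
repetition count as a vote. Per-repetition seeds derive deterministically
from one master seed.

## Labeling, hemispheres

Each fiber's connection is the sorted pair of parcellation labels found
at its two extremities: the fiber is oversampled (×10) and each extremity
scanned inward up to `probe_depth` (3) points for the first non-zero
label. Both knobs are mechanism, not doctrine — the goal is that at least
one extremity point lands in the connected cortical ROI; fibers whose
ends find no label are *undetermined* and are excluded from both
numerator and denominator of the tally (a strict mode counting them
against the fraction exists, but the default favors robustness to
parcellation gaps). A bundle is labeled by its dominant pair when that
pair covers at least 50% of the determined fibers, and dropped from the
labeled atlas otherwise. Names are `<ABB1>_<ABB2>_<n><x>` with
abbreviations in sorted-label order, the per-pair index `n` assigned by
descending bundle size (the original scheme assigns it arbitrarily;
descending size is deterministic and indices only disambiguate), and
suffix `i`/`l`/`r` for both-hemisphere, left-only, right-only bundles.
The corpus callosum label is accepted but flagged in provenance, since
callosal-like fibers are normally removed upstream.

Hemisphere correspondence reflects right-hemisphere bundles across the
midsagittal plane (x = 0 in Talairach-like spaces; the plane is
configurable since the method states only "symmetric reflection") and
reuses the intersection criterion. Common pairs are fused into a
symmetric left bundle whose right counterpart is its exact reflection.

## Segmentation and laterality

A new subject's fiber joins the atlas bundle minimizing the
length-penalized distance

$$d_{MEN} = d_{ME} + \big(\tfrac{|l_A - l_B|}{\max(l_A, l_B)} + 1\big)^2 - 1
\quad (\text{penalty added only when positive}),$$

provided that minimum is within the bundle's threshold. The penalty is
dimensionless yet added to a millimetre distance — implemented exactly as
printed, since that is how the method defines it; it is bounded by 3 and
vanishes for equal lengths. The 6–8 mm threshold band is made concrete as
a linear map of mean bundle length from [35, 85] mm onto [6, 8] mm
(clamped, per-bundle overridable): the band's endpoints are given, the
mapping inside it is this package's choice. Ambiguous fibers go to the
arg-min bundle only, keeping volumes well defined.

Bundle volume rasterizes fibers onto a 2 mm isotropic grid anchored at
the space origin with half-open cells $[2k, 2k+2)$ (the anchoring is a
determinism choice; the method fixes only the voxel size) and counts
voxels crossed by **more than one distinct fiber** — points of the same
fiber in a voxel count once, so a single fiber has volume 0. Subjects
with fewer than 10 fibers in a bundle are marked absent. Lateralization
uses $LI = (R - L)/(R + L) \in [-1, 1]$ (negative = left-dominant), and
volume differences are tested with the classical pooled-variance
unpaired two-tailed t-test on left-vs-right volumes (an LI-vs-0
one-sample reading exists as a non-default mode; Welch's correction is
available but off, matching the classical formulation). Degenerate
constant samples with equal means return $t = 0, p = 1$.

## The synthetic generator

`synthetic_scene()` places U-fiber templates on a hemisphere "cortical"
shell (radius 60 mm) at evenly spaced azimuths: each template is a smooth
arc between two shell points with an apex bowed toward the white matter,
and each endpoint owns a 14 mm ROI box in a matching box parcellation.
`make_template()` accepts both an apex depth and a target length; these
jointly over-determine the arc, so the depth is treated as the starting
bump and rescaled (by root finding on the numeric arc length) until the
length is met within 2% — zero depth yields the straight segment.
`make_population()` then, per subject and template, includes the bundle
with probability `presence_prob` and emits jittered copies (a rigid
per-fiber offset of scale σ plus per-point noise of σ/4 smoothed along
the arc, keeping fiber-to-template $d_{ME}$ around 3σ — note the rigid
offset is a 3-D Gaussian, so its norm exceeds 3σ a few percent of the
time), plus unstructured distractor arcs rejected until they are ≥ 20 mm
from every template. All randomness derives from one master seed through
hashed per-(subject, template) substreams.

What the generator emulates: metric scale, U-shape geometry, per-subject
bundle dropout, within-bundle jitter, unstructured clutter, and an
endpoint-consistent parcellation. What it does not: curvature
distributions of real sulci, registration error structure, partial
volume effects, crossing-fiber artifacts, or realistic fiber density.
Passing the end-to-end tests therefore shows the pipeline's logic and
thresholds behave as specified under controlled geometry — not that the
atlas of any real cohort is recoverable.

A statistical consequence worth stating plainly: with groups of 8
subjects and 90% presence, a template survives one group's 75% cutoff
(6 of 8 subjects) with probability
$P(\mathrm{Bin}(8, 0.9) \ge 6) \approx 0.96$, so across 10 templates and
2 groups a run recovers all 20 template-group instances roughly half the
time; otherwise one template is — correctly — filtered out in one group.
The acceptance script reports whatever the seed produces.

## Problem sizes and numerics

The shipped tests run the full pipeline on two groups of 8 subjects with
10 templates (≈1,840 fibers per group), compare the sparse clustering
against a dense $O(N^3)$ oracle on ≥20 random instances of up to 50
elements, check partition soundness/maximality on 100 random instances,
and verify the metric identities to $10^{-9}$ on 1,000 random fiber
pairs; the whole suite completes in well under a minute on one CPU.
Dendrogram construction uses dense working matrices internally (guarded
at 8,000 elements); the sparse-graph semantics are unchanged by this
implementation detail. Boundary conventions are strict/inclusive exactly
as listed above and each is a documented, configurable reading of an
ambiguous phrase. Out-of-field displacement lookups clamp to the nearest
in-field voxel with a warning; trilinear interpolation is used inside.

## Known limitations

* Registration (affine or deformation-field estimation) is consumed, not
  computed; inputs must already share a space.
* The bundle-set mean distance used for atlas-to-atlas comparison
  ("maximum mean distance" between bundle sets) is operationally
  ambiguous in the literature; the default is the all-cross-pairs mean,
  with a centroid-to-centroid mode as an option, and no further guess is
  made.
* The intrasubject preclustering that produces centroid sets, cortical
  parcellation computation, and tractography itself are out of scope.
* Multiple-comparison correction across bundles in the laterality report
  is deliberately off by default, matching the classical uncorrected
  per-bundle t-test; correct externally if needed.
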
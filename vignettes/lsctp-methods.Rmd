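---
title: "Mapping local similarity of cortical thickness profiles: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping local similarity of cortical thickness profiles: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsctp)
```

## The question and the statistic

Surface-based morphometry resamples every subject's cortical thickness onto
a shared reference mesh, one value per vertex. The question this package
addresses is not whether thickness at a vertex differs between people, but
whether the local *shape* of the thickness map — the profile over a small
neighborhood — is shared across a cohort.

The statistic works vertex by vertex. Around a center vertex a sliding
window collects all vertices within a chordal radius of `diameter / 2` on
the analysis mesh. Each subject's thickness values over the window vertices
form a profile; every unordered pair of subjects is correlated (Pearson),
giving $n(n-1)/2$ correlations for $n$ subjects (861 at $n = 42$). The
correlations are averaged on the Fisher z scale,

$$\bar r = \tanh\!\Big(\tfrac{1}{P}\sum_{i<j}\operatorname{atanh} r_{ij}\Big),$$

and the back-transformed mean is the per-vertex local similarity. Values
near 1 mean the cohort shares one local thickness profile; values near 0
mean profiles are idiosyncratic.

Two exclusion rules apply. A vertex is dropped when any subject has a
thickness of exactly zero anywhere in its window — zero is the missingness
code for non-cortex (medial wall), and a single invalid sample invalidates
the whole profile comparison. A vertex is also dropped when its window
holds fewer than 3 vertices (no meaningful profile correlation below that)
or when some subject's windowed profile is constant (correlation
undefined; counted separately in the map's exclusion tally). Because
larger windows touch the medial wall from farther away, the excluded set
grows monotonically with diameter; maps computed at several diameters are
made comparable by intersecting every inclusion mask with that of the
largest window (`harmonize_masks()`).

### Conventions worth knowing

* **Correlation type.** Pearson, matching the Fisher z machinery. The
  windowed profiles are short, so $\bar r$ is a noisy estimate per vertex;
  inference runs through the Monte Carlo null, not through parametric
  distributions.
* **Clamp.** Correlations are clamped to $|r| \le 1 - 10^{-7}$ before
  `atanh`; identical profiles occur in practice (and in tests) and would
  otherwise produce infinite z.
* **Reported scale.** Maps carry $\tanh(\bar z)$, the r scale, which is
  how such maps are displayed and thresholded; region summaries offer a
  z-scale option for follow-up statistics.
* **Window metric.** Euclidean (chordal) distance on the analysis mesh
  coordinates. On a registration sphere this differs from geodesic
  distance by well under 1% at the window sizes in use (a 32 mm chord on a
  100 mm sphere subtends ~32.1 mm of arc). Window "mm" are mesh
  coordinates: on a registration sphere they are not cortical mm, which is
  documented rather than corrected, since the sphere's near-uniform vertex
  density is precisely what makes the per-window degrees of freedom fair
  across the surface.
* **Indexing.** R-side structures are 1-based; all file formats (surface,
  curv, label, TSV, parcellation) are 0-based on disk and converted only
  at the I/O boundary.

## Surface smoothness and nearest-neighbor smoothing

The Monte Carlo null must reproduce the spatial smoothness of real data,
so the package estimates the FWHM of a vertex map from its edge
statistics:

$$\mathrm{FWHM} = d_v \sqrt{\frac{-2\ln 2}{\ln\!\big(1 - \mathrm{var}(\Delta s) / (2\,\mathrm{var}(s))\big)}},$$

where $d_v$ is the mean inter-neighbor (edge) distance,
$\mathrm{var}(\Delta s)$ the variance of value differences across edges,
and $\mathrm{var}(s)$ the variance of the vertex values. All variances use
the population (divide-by-$n$) convention; the estimator is a ratio, so a
mixed convention would silently bias it. For i.i.d. noise
$\mathrm{var}(\Delta s) \to 2\,\mathrm{var}(s)$ and the estimate collapses
to 0; a constant field has unbounded smoothness, reported as a sentinel
flag rather than a float. Edges contribute only when both endpoints are
inside the supplied mask, so medial-wall zeros cannot masquerade as
smoothness.

Smoothing is iterative nearest-neighbor averaging: each vertex is replaced
by the unweighted mean of itself and its 1-ring neighbors. Self-inclusion
is deliberate — it keeps the operator a proper averaging (stable, no
oscillation on bipartite-like neighborhoods) and is what the dense
averaging-matrix oracle in the test suite encodes. On dense spherical
meshes the smoothness of smoothed white noise grows as

$$\mathrm{FWHM} \approx 1.25 \sqrt{N}\ \text{mm}$$

for meshes with $d_v = 0.8$ mm — the calibration constant is tied to that
mesh spacing. The package verifies this at $N \in \{9, 16, 25\}$ and the
acceptance script recomputes the $N = 16$ point (observed ≈ 1.245 at the
default seed). In mesh-independent terms the growth is ≈ 1.59 per
$\sqrt{N}$ in units of $d_v$; since $d_v$ differs between reference meshes
(a registration sphere and a folded white-matter surface disagree by ~35%)
the package reports FWHM both in mm and in $d_v$ units.

`smooth_to_target()` searches $N \in [0, N_{max}]$ for the iteration count
whose estimated FWHM is closest to a target, ties toward smaller $N$, and
fails loudly (reporting the best achieved FWHM) when the target is not
bracketed. Matching is done on FWHM in $d_v$ units: the estimator's only
mesh-geometry dependence is the $d_v$ prefactor, so the chosen $N$ is
independent of which reference mesh supplied the geometry — a property
asserted by test.

## The Monte Carlo null

Thresholds come from an empirical null: per replicate, every subject's
thickness map is independently spatially shuffled within the gray-matter
mask (an unrestricted permutation — the value multiset is preserved, the
spatial arrangement destroyed), optionally smoothed back to that subject's
observed FWHM, and the similarity map is recomputed. Shuffling alone
produces data far rougher than cortex, which understates chance
similarity; smoothness matching is what makes the null honest, and it
visibly raises critical thresholds (the package asserts the direction as
an inequality on synthetic nulls).

Null values of included vertices are pooled globally across vertices and
replicates into one empirical distribution per window diameter — a single
critical value per window, not a per-vertex null, which at extreme p
levels would need orders of magnitude more replicates. The critical value
uses the plus-one convention: the empirical tail probability of $t$ is
$(\#\{x \ge t\} + 1)/(n + 1)$, so finite replicates can never report a
zero p-value; the threshold at level $p$ is the $\lfloor p(n+1)\rfloor$-th
largest null value, and a request below $1/(n+1)$ is answered with the
maximum null value plus an explicit beyond-resolution flag. Seeds are
derived from a base seed by a splittable counter over (replicate, subject),
making every shuffle independent yet exactly reproducible.

## Choosing a window size

Window size trades off statistical stability (more vertices per profile)
against spatial resolution (windows much larger than real anatomical
patches blur them together). The package's two-stage procedure maps the
local variability of a similarity map: per vertex, the sample SD of the
map over a second sliding window, then the mean of defined SD values per
primary diameter. Undefined cells (windows with fewer than 2 included
vertices) are dropped, never zero-filled — zero-filling would bias
selection toward large windows. The table reports the primary diameter
maximizing mean local SD per variability window; on synthetic cohorts
with patches of known extent, windows at or below the patch scale separate
cleanly from oversized ones.

## The synthetic testbed

`make_icosphere()` builds subdivided icosahedral spheres: near-uniform
vertex density, so sliding windows hold near-identical vertex counts
everywhere — the property that motivates running the statistic on a
registration sphere. `simulate_cohort()` generates per-subject thickness
as

$$t_s(v) = \text{base} + \sigma\big(\sqrt{\rho(v)}\,c(v) + \sqrt{1 - \rho(v)}\,e_s(v)\big),$$

with one common field $c$ and independent per-subject fields $e_s$, both
unit-variance smoothed white noise. The square-root mixing makes the
generative $\rho$ equal the expected inter-subject Pearson correlation of
the profiles, so $\rho$ is directly the quantity the statistic estimates.
Values are clipped at 0.1 mm before medial-wall zeros are applied, keeping
zero unambiguous as the missingness code.

Defaults, chosen once:

| parameter | default | why |
|---|---|---|
| `base_thickness` | 2.5 mm | typical human cortical mean |
| `noise_sd` | 0.5 mm | realistic between-subject profile scale; 4.8 SD above the clip point, so clipping is negligible |
| `smooth_iterations` | 2 | profile FWHM ≈ 2.6 mm, well below the default 8 mm window (see below) |
| icosphere radius | 15.2 mm (subdivision 4) | mean edge length ≈ 1.1 mm, the vertex density of full-resolution registration spheres |

The `smooth_iterations` default deserves its justification: the windowed
Pearson correlation estimates $\rho$ only when the window contains several
independent samples of the profile. With fields as smooth as the window
itself, the effective degrees of freedom per window drop toward 2-3 and
the statistic attenuates well below $\rho$ — a real phenomenon, not an
implementation artifact, and one that applies to real data too (real
unsmoothed thickness has FWHM ≈ 5 mm, within a factor of two of an 8 mm
window). The default therefore places the generator in the calibrated
regime (profile scale ≈ window/3) where ground-truth recovery is a fair
test of correctness; passing it says the engine measures what it claims
under those conditions, not that real-data similarity values are unbiased
estimates of an underlying profile correlation. Users emulating the
smoother regime can raise `smooth_iterations` (12 reproduces the
iteration counts observed when matching real-data smoothness).

Recovery is validated on region *cores* — vertices whose whole window
lies inside a region — because a window straddling a region boundary
mixes generative regimes and its expectation is not $\rho$ of either
side.

What the generator does **not** emulate: folded cortical geometry and its
registration errors, inter-subject misalignment, spatially varying vertex
density, hemispheric structure, or non-Gaussian thickness distributions.
Passing tests on this testbed demonstrate the correctness of the
machinery, not properties of human cortex.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen as the
smallest sizes at which each property is statistically decidable:
subdivision-3 spheres (642 vertices) for pipeline behavior, subdivision-4
(2 562) for the $n = 42$ recovery checks, subdivision-5/6 (10 242/40 962)
for smoothing calibration where a dense mesh is what the claim is about.
Monte Carlo checks use 3-10 replicates or seeds and assert 3-standard-error
bands (with a floor of 0.01 on the r scale where a degenerate case drives
the sampling variance to zero).

Other numerical choices, in one place: window membership uses a relative
`1e-9` slack on the squared radius so boundary vertices are not dropped by
rounding; tie-breaks in `smooth_to_target` go to smaller $N$; the Fisher
clamp is $10^{-7}$ from $\pm 1$; degenerate inputs (empty masks,
zero-length edges, constant maps over a mask, non-bracketed smoothness
targets) raise typed conditions rather than returning sentinels, except
the flat-field FWHM, which is an explicit flag because it is a legitimate
state of a constant map.

## Known limitations

* Windows are chordal balls; an optional exact-geodesic mode is out of
  scope, as are anisotropic windows.
* The statistic is reported only as the back-transformed Fisher mean;
  covariate adjustment and weighted correlations are not offered.
* One mesh per run: hemisphere pooling is left to the caller.
* The null is global per window size; per-vertex or cluster-extent
  inference is deliberately absent.
* At window scales approaching the profile smoothness, similarity values
  attenuate (see above); comparisons should therefore be made within one
  window size, which is how the package's summaries are organized.
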
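---
title: "Delineating somatosensory cortex from MEG evoked fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating somatosensory cortex from MEG evoked fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Equivalent current dipole (ECD) fitting, the clinical standard for
localizing somatosensory evoked fields (SEFs), reports a single point per
latency. Surgical planning, however, needs the *extent* of eloquent
cortex. Distributed inverse methods estimate activity at every cortical
location but produce continuous maps that change over space and time, so
they do not directly answer "which tissue is active?". `sefmapper`
post-processes a distributed solution into a single interpretable
activation region with a boundary, and quantifies how that region relates
to anatomy, to dipole fits, and to chance.

## The model and pipeline

**Evoked response.** Epochs run from 50 ms before to 250 ms after the
stimulus at 1 kHz (300 samples; stimulus at sample 51). We treat the
window as half-open, [−50, 250) ms, which makes the sample count exact;
baseline correction subtracts the per-channel mean over [−50, 0) ms,
deliberately excluding the stimulus sample. All analysis windows quoted as
"between a and b ms" are closed, `[a, b]`, everywhere in the package. The
gradiometer RMS at sample t is `sqrt(sum_i x_i(t)^2 / nchan)` over the 204
planar gradiometers; its maximum in [15, 60] ms defines the PMaxm latency
(earliest sample on ties).

**Forward model.** The field of a current dipole in a homogeneous
conducting sphere has the closed-form (Sarvas) solution; it is exact for
spheres, independent of conductivity, and standard in MEG simulation, so
we use it in place of a boundary-element model, which would require
per-subject anatomy we cannot ship. Magnetometers sample the radial field
component; each planar gradiometer is the difference of two point
magnetometers 17 mm apart along a tangential baseline, divided by the
baseline. One property of this conductor matters downstream twice: a
dipole's *radial* moment component produces no external field. We
therefore (a) tilt source orientations lying within 5° of the head-center
radial direction to exactly 5° (toward the anterior tangent), so no source
column of the lead field is numerically silent, and (b) validate dipole
moment-magnitude recovery only for tangential ground-truth moments — the
radial component is physically unidentifiable in this geometry, not an
implementation artifact.

**Inverse.** We use sLORETA: with gain `L`, noise scale σ and whitened
gain `G = L/σ`, the kernel is
`K = G'(GG' + λ² tr(GG')/n_chan · I)^{-1}`, and estimates are standardized
by the resolution diagonal, `values_j = (Kb)_j / sqrt((KG)_jj)`. Because
the regularizer is proportional to `tr(GG')`, the scalar σ cancels
algebraically: the operator depends only on λ². We keep σ in the API (it
documents the assumed noise model, estimated as the median per-channel
baseline standard deviation) but compute the operator once per workbench.
The default λ² = 1/9 corresponds to a nominal amplitude SNR of 3; the
standardized map has exactly zero localization error for noiseless point
sources, a property guaranteed by the Cauchy–Schwarz inequality applied to
`R = G'MG` with `M` positive definite, and verified at 100/100 in the
tests.

**Spatial filter.** Each source's time course is replaced by the mean over
sources within a 5 mm Euclidean ball that share its anatomical label (self
included). The phrase "filtered based on anatomical location with a 5 mm
search radius" admits several readings; we chose label-respecting
averaging because it both denoises and prevents smoothing across
anatomical boundaries (e.g. across a sulcus). Radius, and whether labels
are respected, are configuration choices; averaging (not median or
masking) is the default. Euclidean rather than geodesic distance is used
throughout — at 5 mm on a ~3 mm-spaced grid the two rarely differ, and
geodesics would add a dependency disproportionate to the gain.

**Windowed SVD and thresholding.** The source × time matrix over
[15, 60] ms is decomposed `X = UΣVᵀ`. The first left singular vector `u₁`
is the spatial pattern of the dominant source, the first right singular
vector `v₁` its time course, and `S₁²/ΣSᵢ²` its variance share. SVD signs
are arbitrary, so each mode is flipped to make the peak-magnitude entry of
its temporal vector positive — a convention that makes reruns and
serialized loadings reproducible. The activation region is
`{j : |u₁[j]| ≥ 0.8 · max|u₁|}`. We read "the 80% strongest sources" as a
fraction of the maximum loading, because only under that reading do higher
thresholds yield smaller, more focal regions; a count-based alternative
(strongest `ceiling(0.8 n)` sources) is implemented behind
`semantics = "percentile"`. The peak activation time is the time of
max `|v₁|`, earliest sample on ties.

**Dipole comparators.** P20m and P40m dipoles are fit by exhaustive grid
search over source-space nodes at 20 ± 5 and 40 ± 5 ms (times relative to
the stimulus, with the ±5 ms absorbing response delay); PMaxm at the
single PMaxm sample. At each node the free three-component moment is the
linear least-squares solution and `GOF = 100(1 − |b−b̂|²/|b|²)`; the
best (node, sample) wins. Restricting candidates to grid nodes keeps the
comparator deterministic; nonlinear refinement is out of scope. Dipoles
farther than 9 mm (inclusive boundary) from every contralateral
sensorimotor-ROI source are rejected and excluded from overlap/distance
summaries.

**Evaluation.** Atlas overlap is the percentage of region members carrying
an ROI label in *either* hemisphere (ipsilateral responses count as
correct). Sphere overlap uses a 3 cm³ sphere (r ≈ 8.947 mm) centered on
each accepted dipole. The chance comparison grows, per permutation, a
contiguous patch of exactly the observed region's size from a uniformly
drawn seed vertex over the whole cortical surface — contiguous rather than
scattered, because a scattered null would misstate the spatial
autocorrelation of a cortical "area" — and `beats_chance` is a strict
comparison of the observed metric with the null median. No multiplicity
correction is applied across the three dipole kinds, mirroring standard
reporting in this design.

**Cohort statistics.** Two binomial formulations are provided, because the
cohort p-values printed in the clinical literature for this design equal
`p0^n` (the probability mass of *all* patients succeeding, e.g.
0.05⁵⁸ ≈ 3.5 × 10⁻⁷⁶) even when successes were n−1 of n: an
`all_success_mass` mode reproduces those printed values, and a
conventional one-sided exact `tail` mode (`P(X ≥ k)`, log-space summation)
is the default. The Wilcoxon signed-rank test drops zero differences, uses
midranks, and enumerates the exact null for ≤ 25 nonzero differences via a
dynamic program over doubled midranks (equivalent to summing all 2ⁿ sign
assignments, and unlike `stats::wilcox.test` still exact under ties),
falling back to the tie-corrected normal approximation for larger n. The
location test is Pearson's χ² without continuity correction, with
all-zero rows/columns dropped.

## The synthetic workbench

Clinical MEG and MRI data cannot be redistributed, so every input is
generated in-package, at the cohort's stated acquisition parameters:

* **Cortex.** Two subdivided icospheres (10·4ˢ + 2 vertices each; s = 5
  gives the full-scale 10,242 per hemisphere, 20,484 total), radius 35 mm,
  radially perturbed by a smooth sinusoid (default amplitude 3 mm) whose
  folds run parallel to the label bands, mirrored left/right and separated
  by a 4 mm gap inside a 90 mm head sphere. Hemispheres are disjoint
  graphs: patches never cross the midline. Vertex indexing is 1-based (as
  natural in R); the global source index is hemisphere offset + vertex id.
* **Parcellation.** Four contiguous angular bands per hemisphere —
  precentral gyrus, central sulcus, postcentral gyrus, postcentral sulcus,
  anterior → posterior — each 8.1° wide in the angle around the x axis.
  A wedge of width w covers exactly w/360 of a sphere, so the ROI holds
  4 × 8.1/360 = 9% of sources, matching the ~9% chance-level overlap of
  the clinical cohort. Everything else is labeled `other`.
* **Sensors.** 102 sites on a Fibonacci lattice over a 120 mm helmet cap
  extending to z/R = −0.2; per site one magnetometer and two orthogonal
  planar gradiometers → 306 channels.
* **Patients.** The activation patch is seeded uniformly in the
  contralateral postcentral gyrus ∪ central sulcus and grown breadth-first
  over mesh edges *within* the four ROI bands (so ground truth is wholly
  inside the ROI by construction) to a default area of 300 mm² (~3 cm², a
  hand-representation-sized patch; ~40 sources at ico-4). Source currents
  are a Gaussian spatial taper times a causal two-component waveform
  (Gaussian bumps at 20 and 35 ms, widths 3 and 6 ms, amplitude ratio
  0.7 : 1), scaled to 50 nA·m total at the waveform peak — within the
  20–135 nA·m range of clinical dipole moments. Epoch counts are drawn
  from Normal(197, 31) truncated to [160, 230]. Sensor noise is white
  Gaussian, scaled per channel kind so that
  (peak evoked RMS) / (per-epoch noise RMS / √n_epochs) equals the target
  SNR on the gradiometers (and, by the same rule, on the magnetometers —
  a single shared σ would leave one channel kind either uninformative or
  dominating under the two kinds' different units).

What the generator deliberately does **not** emulate: correlated brain
noise, cardiac/ocular artifacts, line interference (their removal — tSSS,
SSP, ICA, notch/band-pass filtering — is out of scope, so the data are
clean and band-limited by construction), head movement, coregistration
error, and real folded anatomy with its highly non-uniform source
orientations. Passing tests therefore demonstrate the *algorithmic*
correctness and calibration of the pipeline, not clinical performance;
per-patient SNR is a free parameter (default 5) because the clinical
recordings' SNR is not reported.

## Numerical conventions and problem sizes

Deterministic tie-breaks are documented at each site: earliest sample for
temporal peaks, lowest index for nearest-vertex projection and for the
dipole grid scan, ascending (distance, vertex id) within the final
breadth-first ring of patch growth. All randomness flows from explicit
integer seeds; cohort sub-seeds derive from the master seed by a fixed
affine map modulo 2³¹ − 1.

The shipped checks run at desk scale, chosen to exercise every code path
at full fidelity: exact-localization and oracle comparisons on an ico-3
workbench (1,284 sources), a 20-patient cohort at ico-4 (5,124 sources,
SNR 5) with 2,000-permutation nulls per region size, and a
10,000-permutation null-expectation check on an unperturbed (uniform
vertex density) ico-4 surface. The full-scale ico-5 grid is built for the
source-count check and is supported throughout.

One calibration subtlety: the spec-level property "a random observed patch
beats the null half the time" holds only for metrics with a continuous
null. The atlas-overlap null of contiguous random patches is heavily
discrete — most patches miss the 9% ROI strip entirely, so its median is
0 and `P(X > median)` is structurally below ½. The calibration check
therefore uses the centroid-distance metric, whose null is continuous;
the overlap null's mean (≈ the ROI source fraction) is checked separately.

## Known limitations

* The spherical conductor makes radial moment components silent; moment
  magnitudes from the dipole comparator are meaningful only up to their
  tangential part.
* sLORETA overestimates the spatial extent of focal sources; noiseless
  recovered regions extend up to ~8–10 mm beyond the true patch boundary
  before thresholding reins them in. Higher thresholds give more focal
  regions.
* The band "atlas" is deterministic and geometrically convex per band;
  real atlas labels are neither, so atlas-overlap numbers here are cleaner
  than clinical ones.
* Only the first SVD component is analyzed; secondary components (e.g.
  ipsilateral or late responses) are future work, as is time-resolved
  region tracking.
* Epoch/lead-field containers are serialized as RDS rather than HDF5: no
  HDF5 binding is declared by the package, and the RDS round trip is
  exact. All small artifacts (meshes, parcellations, regions, dipoles,
  configs) use open text formats (PLY/TSV/JSON/YAML).
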
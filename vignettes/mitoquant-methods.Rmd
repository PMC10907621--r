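---
title: "Quantifying mitotic fidelity assays with mitoquant"
author: "mitoquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitotic fidelity assays with mitoquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoquant)
```

# Scope

Cancer cells that depend on the mitotic kinesin KIF18A die in mitosis
because inhibiting the motor destabilizes kinetochore--microtubule (K-MT)
attachments, raises spindle-assembly-checkpoint (SAC) signaling at most
kinetochores, and stalls cells whose metaphase-to-anaphase transition is
already slow. Studying that axis requires a battery of quantitative
readouts, and `mitoquant` implements the analysis half of each assay:

* per-kinetochore SAC signal from fixed-cell 3D immunofluorescence
  (segmentation, background correction, quality control, MAD1-positive
  calling, spindle-axis geometry);
* K-MT turnover and poleward flux from photoactivation time-lapses
  (two-phase exponential decay, band tracking);
* APC/C output from live Cyclin B1 reporter traces (anchor detection,
  normalization, half-life, maximum degradation rate);
* mitotic timing and fate statistics from event annotations;
* drug sensitivity from endpoint viability plates (viability/toxicity/
  rescue formulas, variable-slope four-parameter logistic fits);
* hit selection and enrichment for genome-wide CRISPR screens analyzed
  upstream with a MAGeCK-style scorer.

Every stage is paired with a seeded synthetic-data generator that plants
known ground truth with the statistical structure the stage assumes, so
the full pipeline is testable on a laptop without any imaging data.

# Kinetochore intensity quantification

## Model of the data

A fixed-cell volume is a 3-channel z-stack (0.2-µm sections, ~65-nm
pixels): a reference kinetochore channel (CENP-A or BUBR1 role), a SAC
channel (MAD1 role), and a centrosome channel (CEP192 role) marking the
two spindle poles. `segmentSpots()` thresholds the reference channel
(fixed manual threshold by default, Otsu optional) and labels connected
components under 26-connectivity in 3D; each component becomes one spot
with an intensity-weighted centroid and a physical volume. Components
smaller than `min_voxels` (default 10) are discarded as noise specks —
a diffraction-limited spot at a quarter-amplitude threshold covers
roughly 25 voxels or more at this sampling.

Background is *the median signal of the non-kinetochore area across the
entire stack* (`estimateBackground()`), and the corrected integral of a
spot is its raw integral minus background times voxel count, clamped at
zero with a flag (`quantifySpots()`). On noiseless synthetic volumes
this recovers planted intensities to summation roundoff; the test suite
checks both that identity and agreement with a brute-force voxel-loop
oracle on small volumes.

## Quality control

Two IQR rules, both with multiplier 1.5 by default:

* **Oversize spots.** A spot whose volume exceeds Q3 + 1.5·IQR of the
  per-batch spot-volume distribution is flagged, because merged
  kinetochore pairs segment as single large objects. We read the rule
  one-sided: its purpose is removing merged (large) objects, and small
  volumes are already covered by the `min_voxels` floor. A two-sided
  variant is available (`volume_rule = "tukey_two_sided"`).
* **Aberrant cells.** A cell whose QC-passing kinetochore count falls
  outside [Q1 − 1.5·IQR, Q3 + 1.5·IQR] of the per-experiment count
  distribution is flagged; "aberrant" is directionless (lost or doubled
  complements), so this rule is two-sided.

Spots within `pole_exclusion_radius` (default 1.0 µm) of a pole centroid
are flagged pole-coincident; the underlying imaging criterion
("coincidence of CEP192 signal") is not quantified anywhere, so the
radius is an explicit, configurable convention. QC only ever adds flags
— measurements are never mutated and flagged rows are never deleted —
so re-running QC is idempotent.

## SAC-positive calling

A kinetochore is MAD1-positive at percentile *p* when its corrected SAC
intensity is strictly greater than the *p*-th percentile (linear
interpolation between order statistics, `quantile()` type 7) of the
corrected SAC intensity over QC-passing spots of the vehicle (DMSO)
condition. Thresholds at the 90th/95th/99th percentiles are computed in
one call; classifying the reference against itself recovers the nominal
tail fraction up to discreteness, which the acceptance suite checks at
the 95th percentile on synthetic vehicle cells.

`summarizeCells()` reports per-cell means and the cumulative per-cell
signal. The distinction matters biologically: doubling the kinetochore
number at equal per-spot signal doubles the cumulative SAC burden while
leaving the mean unchanged, which is the mechanism by which whole-genome
doubling sensitizes cells.

The condition-level SAC response is summarized by
`defectScore()` = (S~treated~ − S~DMSO~)/(S~Nocodazole~ − S~DMSO~) × 100,
which places a treatment between the vehicle (0) and the full
checkpoint response to spindle collapse (100).

## Spindle geometry

`locatePoles()` segments the pole channel and takes the two brightest
components' intensity-weighted centroids, ordered lexicographically for
determinism; more than two candidates yields a multipolar flag (such
cells are excluded from region statistics by default, since their
"midline" is ill-defined). Kinetochore positions are projected onto the
pole--pole axis; the distance from the midline is measured **along the
axis** (distance to the perpendicular bisector plane), not as a 3D
Euclidean distance. Positions within 5 µm of the midline are *central*,
beyond it *polar*; the boundary itself is central (≤ 5 µm).
`regionPositiveFraction()` reports the percentage of cells with at least
one SAC-positive kinetochore per region. All of this is rigid-motion
invariant, which the suite checks under random rotations.

# Photoactivation turnover analysis

The assay marks a band of photoactivatable GFP-tubulin next to the
metaphase plate and follows its integrated intensity for 6 minutes at
10-second intervals (one pre-activation frame; cells entering anaphase
are excluded). The non-photoactivated half-spindle provides the
background: `correctContralateral()` subtracts it frame by frame and
normalizes to the first post-activation frame, which makes every fitted
parameter invariant to detector gain.

`fitTwoPhase()` fits

$$I(t) = f\,2^{-t/t_{1/2}^{fast}} + (1-f)\,2^{-t/t_{1/2}^{slow}}$$

by bounded least squares (Levenberg--Marquardt via `minpack.lm`), with
half-lives parameterized directly in minutes because those are the
quantities reported and compared. The fast phase reflects bulk spindle
microtubule turnover; the slow phase reflects the stable K-MT fibers.
Initialization is multi-start: a log-linear fit to the tail seeds the
slow phase and the early residual seeds the fast phase, alongside a
spread of generic starts; the best residual sum of squares wins, and the
suite verifies the winner never loses to a dense lattice search over
$(f, t_{fast}, t_{slow})$. Fits are canonicalized to
$t_{fast} \le t_{slow}$; when one phase vanishes ($f$ within 1% of 0 or
1) the surviving half-life is reported for both phases, since the other
is unidentifiable. The slow half-life is bounded above at 10× the
acquisition span — beyond that the data cannot distinguish slow decay
from none — and a fit pinned at that bound is flagged (`atBound`), as
happens for a constant series. No offset/plateau or photobleaching term
is fitted by default: the contralateral subtraction is the only
background correction the assay prescribes.

Treatment effects are expressed by `slowHalfLifeRatio()` as
$t_{1/2}^{K\text{-}MT}(\text{treated}) / t_{1/2}^{K\text{-}MT}(\text{control})$;
a ratio of 0.59 is a 41% destabilization, 0.93 a 7% one.

## A caution on single-trace identifiability

The slow half-life of a single 37-frame, 6-minute trace is weakly
identified when the slow phase carries only ~30% of the signal. At a
noise level of 2% of the initial intensity the Fisher-information bound
puts the relative standard error of $\hat t_{1/2}^{slow}$ above 100%,
and the profiled residual surface is nearly flat in $t_{slow}$, so a
substantial fraction of maximum-likelihood fits pin at the upper bound
regardless of optimizer. This is a property of the estimation problem,
not of the implementation — which is why turnover experiments fit the
*ensemble* of many cells per condition rather than single traces. The
package's recovery tests therefore exercise single-trace round trips at
noise levels where the parameter is identifiable (≤ 0.1%), and the
lattice-search comparison guards optimizer quality separately at 2%
noise.

## Poleward flux

`measureFlux()` smooths each frame's intensity profile along the spindle
axis with a moving average (default 5 bins), takes the argmax as the
band position, and fits position against time by least squares; the
slope is the flux velocity in µm/min, positive toward the pole. If the
argmax sits on a profile edge in more than half the frames the result is
flagged unreliable.

# Cyclin B1 degradation kinetics

Traces are background-subtracted intensities sampled every 2.5 minutes.
Two normalization anchors coexist in the assay and both are
implemented, because half-lives and rates answer different questions:

* **Half-life** is measured on the series normalized to 100% at the
  *metaphase inflection point* (the last frame before sustained
  degradation). `degradationHalfLife()` returns the first 50% crossing
  after the anchor, linearly interpolated between frames; a series that
  never crosses is censored at the last observation with a flag.
* **Maximum degradation rate** is measured relative to the *mitotic
  maximum* (100% at the brightest mitotic frame):
  `maxDegradationRate()` slides a 3-frame least-squares window and
  reports the magnitude of the most negative slope in %/min.

The inflection detector (`detectAnchor()`) smooths with a 3-frame median
filter and looks for the first run of three sustained declines steeper
than 2% of the plateau per frame. Sustained decline is judged on
two-frame spans: a 3-point median filter flattens every other
single-frame difference on a noisy monotone stretch, so single-frame
differences alone stall on real noise levels; the anchor is then refined
to the first frame whose own forward difference is steep. There is no
operational definition of the "inflection point" in the assay
literature, so this detector is a declared convention — on synthetic
plateau-then-decay traces with 2% noise it lands within one frame of
the true plateau end. Manual and anaphase-onset anchors pass
annotations through unchanged.

# Mitotic timing and fates

Mitotic duration is anaphase onset minus nuclear envelope breakdown;
metaphase-to-anaphase duration starts at the appearance of the last
uninterrupted metaphase plate (annotations are taken as given). Cells
that never reach anaphase — death in mitosis, slippage — report
durations censored at the last observation with an explicit flag, so
downstream summaries can include or exclude them deliberately.
`summarizeFates()` returns per-condition fate proportions (summing to
one) and duration means ± SD; `linearR2()` provides the ordinary
least-squares R² used to rank condition-level predictors of drug
sensitivity.

# Dose--response and sensitivity

The endpoint formulas are implemented exactly as printed on absorbance
signals:

$$\%\,\text{Viability} = \frac{S_{sample} - S_{DMN}}{S_{DMSO} - S_{DMN}} \times 100,
\qquad \%\,\text{Toxicity} = 100 - \%\,\text{Viability},$$

$$\%\,\text{Rescue} = \frac{S_{sample,drug} - S_{WT,drug}}{S_{WT,DMSO} - S_{WT,drug}} \times 100.$$

DMN (dimethylenastron, a spindle-collapse arrest) wells anchor full
toxicity; DMSO wells anchor full viability. Viability is invariant to
any positive affine transform of the raw signal scale, and a
media-normalized variant swaps the DMN baseline for media-only wells
when a perturbation rescues growth in DMN itself.

`fitFourParameter()` fits the variable-slope model
$y = bottom + (top - bottom)/(1 + (d/IC_{50})^{h})$ with the IC50 on an
internal log scale and multi-start over the hill sign; flat responses
are flagged rather than fitted. Plateau toxicity is defined as
100 − fitted bottom on the viability scale (the fitted plateau, not the
highest-dose mean, because the fit pools information across doses).
Sensitivity classes follow the printed cutoffs — toxicity above 40% is
sensitive, below 20% insensitive — and the 20–40% gap is reported as an
explicit *intermediate* class rather than silently assigned.

# Screen hit selection

Hit gating operates on Δβ = β~treated~ − β~control~ per gene: a hit lies
outside mean ± 1.5 SD of the population Δβ *and* passes the FDR cutoff
(0.3 for the discovery screens, 0.1 for the stricter validation screen).
The fence is applied to Δβ rather than to each condition's β separately
because the question is differential essentiality under drug; the
selection is invariant to affine rescaling of the scores. On a
standard-normal null the pre-FDR flagged fraction is 2Φ(−1.5) ≈ 13.36%,
which the acceptance suite verifies at n = 20,000 within binomial error.
`enrichmentFisher()` evaluates gene-set enrichment among hits with the
exact hypergeometric test on the 2×2 membership table (the classic
Fisher approach; no GO-graph elimination), with optional
Benjamini--Hochberg adjustment across sets.

# The synthetic-data generator

Each generator is seeded, restores the caller's RNG state, and returns
ground truth alongside the data.

**Volumes** (`makeKinetochoreVolume()`): anisotropic 3D Gaussian spots
(σ~z~ = 2.5 σ~xy~, widefield axial elongation) scattered through a
metaphase-plate slab between two pole blobs, with Poisson shot noise on
signal plus background and additive Gaussian read noise — the noise
structure of the CMOS/CCD acquisitions the assay uses, without modeling
camera specifics. Defaults: 46 kinetochores (near-diploid complement),
0.2 × 0.065 × 0.065 µm voxels, lateral σ 0.1 µm (diffraction-limited),
SNR 10 defined as peak amplitude over background noise sd, lognormal
amplitude variation with CV 0.15. Planted artifacts: *fused pairs* (two
spots one lateral σ either side of a center, merging into one
double-intensity component), *pole-coincident* spots jittered onto a
pole, and *aberrant-count* cells carrying a doubled complement.
Placement is rejection sampling (1000 retries, then an explicit
placement-failure error) with a minimum center distance of 6 lateral σ
measured in PSF-scaled coordinates (axial separations count in units of
σ~z~). The exclusion distance is larger than the 2σ one might first
write down for a deliberate reason: two Gaussians closer than ~4σ merge
through the saddle between them at any threshold low enough to capture
their peripheries, and the generator's contract is that *distinct*
planted spots stay resolvable — merged objects are planted only
explicitly, as fused pairs. The acquisition noise level of the original
assays is not published; SNR 10 is a configuration choice representative
of well-stained fixed-cell widefield data.

**Photoactivation traces** (`makePhotoactivationSeries()`): one
pre-activation frame plus 37 frames at 10-s spacing; the activated half
follows the two-phase decay over a matched background, the contralateral
half carries the background alone (both with iid Gaussian noise scaled
to the initial amplitude), and the per-frame axis profile is a Gaussian
band drifting poleward at the planted flux.

**Cyclin traces** (`makeCyclinTrace()`): a mitotic plateau (flat by
default, optionally gently rising) followed by exponential decay with a
planted half-life or linear decline with a planted rate, at 2.5-min
sampling.

**Plates** (`makeViabilityPlate()`): triplicate 4PL responses per dose
plus DMSO and DMN control wells at the true plateaus.

**Screen tables** (`makeScreenTable()`): null Δβ ~ N(0, σ) with uniform
FDR; hits displaced by exactly ±`effect_sd_units`·σ with small FDR, so
recall at the printed gate is guaranteed by construction margin.

What the generators deliberately do **not** emulate: optics beyond a
Gaussian PSF (no diffraction rings, chromatic shifts, or deconvolution
artifacts), cell-to-cell heterogeneity of background, spindle tilt or
pole movement over time, plate-edge effects, and correlated
guide-level structure in screens. Green tests on synthetic data
therefore demonstrate the *algorithms* are correct under the stated
statistical assumptions, not that those assumptions exhaust real
microscopy.

# Numerical conventions and problem sizes

* Geometry is in physical micrometers everywhere; voxel indices are
  0-based with axis order (z, y, x), so voxel *i* is centered at
  *i*·voxel_size.
* Percentiles use linear interpolation between order statistics
  (type 7); positivity is strict (`>`), matching "above the percentile".
* Ties in the flux argmax resolve to the first (most midline-proximal)
  bin; the moving average shrinks its window symmetrically at profile
  edges.
* The test and acceptance suites run entirely on synthetic data at desk
  scale: 20 cells × 46 kinetochores for the spot pipeline, 100 traces
  for decay recovery, 20,000 genes for the null-gating check — sizes
  chosen to give tight Monte-Carlo error on the checked quantities while
  keeping a full run in a few minutes on one core.

# Known limitations

* Fixed-cell analysis assumes one cell per volume; multi-cell fields
  need prior cropping.
* The spot QC volume distribution is computed over whatever table is
  passed; callers are responsible for batching it per condition and
  experiment, as the assay prescribes.
* Single-trace K-MT half-life estimates at realistic noise are
  fundamentally imprecise (see above); condition-level comparisons
  should fit ensembles.
* The 4PL fit does not model plate effects or replicate correlation;
  responses enter as independent observations.
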
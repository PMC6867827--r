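---
title: "Models and methods behind fishcoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fishcoloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishcoloc)
```

fishcoloc quantifies single-molecule FISH experiments on ion-channel
transcripts and the companion qPCR and voltage-clamp readouts.  This
vignette explains the statistical models, the defaults and their units, the
numerical choices, and what the synthetic-data generator does and does not
emulate — i.e. what a passing test suite does and does not certify about
real data.

## Image model and spot detection

Images are 2D photon-count rasters (or z-stacks reduced by maximum
projection, the primary analysis route; 3D Gaussian fitting of the axial
profile is available when stacks are supplied).  A diffraction-limited mRNA
spot is modeled as an isotropic 2D Gaussian of width `sigma` ≈ 1.3 px at
the default 106.3 nm pixel; its total fluorescence is proportional to the
number of fluorophore-tagged probes, hence to mRNA copy number.

Detection proceeds in four steps:

1. **Background subtraction.** Either a wide-Gaussian high-pass
   (`method = "log"`, subtracting a `radius_px = 10` blur — the discrete
   difference-of-Gaussians analogue of Laplacian-of-Gaussian background
   removal) or a grayscale rolling-ball (morphological opening with a disc).
   Both clamp at zero, send flat images to ~0, and are invariant to a
   constant offset.  Because EBImage grayscale morphology operates on
   [0, 1], the opening is computed on a rescaled copy (min/max filters
   commute with positive affine maps, so this is exact), with
   replicate-padding so borders see full neighborhoods.
2. **Candidate detection.** A small Gaussian blur (`blur_sigma_px = 1`)
   raises the signal-to-noise of the peak test; 8-neighborhood local maxima
   above a threshold are kept, and maxima closer than
   `min_separation_px = 2` are merged (the brighter wins).  The default
   threshold is median + 5×MAD, with the MAD estimated on the *raw*
   filtered projection: the clamped background-subtracted image
   half-truncates the noise distribution and would underestimate it.
3. **Gaussian localization.** Per candidate, a least-squares fit of
   amplitude, center, width, and a local constant offset in a 9-px window
   (Levenberg–Marquardt, bounded; a singular fit marks the candidate failed
   rather than erroring).  Fitting runs on the raw projection — the local
   offset absorbs smooth background, while fitting the clamped subtracted
   image would bias intensities.  Total intensity is `2π·sigma²·A`.
   Retained spots must satisfy `sigma ∈ [0.7, 2.5]` px and the intensity
   bounds; everything else lands in a rejects table with `fit_ok = FALSE`.
4. **Deduplication.** Fitted centers closer than the separation distance
   are merged (shoulder maxima relocalize onto the same molecule).

Thresholds are deliberately explicit and configurable: the widths and
5×MAD factor are conventional smFISH practice, not values tied to any
specific prior software.  On rendered benchmarks (100 resolvable spots,
SNR 5, where SNR is peak amplitude over the background shot-noise SD)
the pipeline reaches precision = recall = 1.0 with ~0.28 px localization
RMSE; at SNR 20 localization tightens to <0.1 px.  Physics, not tuning,
limits the SNR-5 localization: with ~530 detected photons per spot over a
100-photon background, the information bound is a few hundredths of a
pixel per axis and residual model mismatch (pixel integration, clamping)
brings the practical figure to ~0.25 px.

## Single-mRNA calibration

The pooled spot-intensity histogram of one species is fit with a sum of K
Gaussians sharing one baseline:

$$y(x) = y_0 + \sum_{k=1}^{K} \frac{A_k}{w_k\sqrt{\pi/2}}
  \, e^{-2(x - x_{c,k})^2 / w_k^2}$$

The single-molecule intensity is the center of the lowest-center component
whose peak height is at least 10% of the tallest component's — the 10%
floor discards vestigial components the optimizer may park at low
amplitude.  Numerical choices that matter:

- **Bins**: Freedman–Diaconis width; empty bins below the first peak are
  retained, because with Poisson weighting they anchor the left flank of
  the first component.  Without them the first center drifts upward by
  several percent on skewed mixtures.
- **Weights**: least squares with residuals scaled by √count (Poisson).
- **Initialization**: multi-start with centers at k× the histogram mode
  and k× half the mode (for pools whose mode is a multi-copy class),
  widths at 0.3× the base center, amplitudes from the histogram heights.
- **Model selection**: K chosen by BIC over 1..6 components computed on
  the weighted RSS.
- **Degenerate input**: a single-valued pool returns that value directly.
- **Component centers are free**, not pinned to integer multiples — the
  data decide whether clusters sit at exact multiples.

On pools of 2611 spots (a realistic pooled experiment) with copy numbers
1–6 and 15–20% intensity CV, the single-molecule intensity is recovered
within 5% across seeds, and the estimate is exactly scale-equivariant.
Copy numbers are then `max(1, round(intensity / single))`; note that at
15% CV, classes beyond ~4 copies overlap intrinsically — per-spot copy
assignment is reliable for small clusters and statistical for large ones,
which is why cluster-size distributions pool everything ≥6.

## Spatial statistics

Distance from a spot to the nucleus is the Euclidean distance to the
nearest nucleus *boundary* pixel center, in µm; spots whose centroid falls
inside the nucleus mask score 0, since projected FISH signal can overlie
the nuclear rim.  Radial profiles use 5-µm bins by default, the scale at
which perinuclear endoplasmic-reticulum enrichment is conventionally
reported, and cumulative fractions within any query radius are exact
(computed from raw distances, not re-binned).

## Colocalization and the chance model

Matching is object-based and one-to-one: candidate cross-channel pairs
with center distance at or below the criterion are sorted by distance
(ties broken by first-channel then second-channel index) and accepted
greedily, each spot used at most once.  On sparse instances (≤8 spots per
channel) this greedy rule reproduces the exhaustive maximum matching in
every random test instance; its advantage is determinism and speed on
dense fields.  Criteria are expressed in pixels (1–4 px grid by default;
Bonferroni over the grid size), with 2 px — about half a spot diameter —
used for triple association and knockdown comparisons.

The chance expectation for two populations of sizes $N_{m1}, N_{m2}$ with
average spot radius $r$ in analyzed area $A$ is implemented exactly in its
stated union-area form:

$$E_m = \frac{N_{m1} N_{m2} \,(2\pi r^2 - I)}{A}, \qquad
  I(d, r) = 2r^2\cos^{-1}\!\frac{d}{2r} - \frac{d}{2}\sqrt{4r^2 - d^2}$$

and for triples $E_p = N_p E_m (\pi r^2 - I)/A$.  The spot radius defaults
to the detection-derived mean FWHM/2 (≈163 nm for a 1.3-px PSF).  A
classical alternative — the geometric encounter area, $E_m = N_{m1} N_{m2}
\pi d^2 / A$, the exact expected number of center-distance matches under
uniform placement — is available via `expected_model = "distance"` for
sensitivity analysis.  The two models are numerically close at the 2-px
criterion with the default radius (within ~4%), where the union form is
well calibrated: over 200 null replicates of 40 uniformly-populated cells
the paired t-test rejects at the 5% level in 5% (union) and 9% (distance)
of replicates.  At the 1-px criterion the union form over-expects by
roughly 3×, making the test conservative for detecting excess association
there; conclusions drawn at 1 px should rely on the fraction estimates,
which are unbiased, rather than the test.

Two assumptions of the chance model deserve emphasis.  First, it assumes
spatial homogeneity: spot densities concentrated near the nucleus (as both
channels are, in reality and in the generator's default λ = 10 µm
placement bias) raise the true chance-encounter rate above the
uniform-placement expectation, so apparent "association" between two
perinuclear species partly reflects shared localization.  Null calibration
simulations therefore use uniform placement.  Second, expected counts are
computed per cell from that cell's own $N_{m1}, N_{m2}, A$, and observed
and expected counts are compared across cells by a paired two-tailed
t-test; the degenerate zero-variance cases are defined explicitly (all
differences zero → t = 0, p = 1; constant nonzero difference → p = 0).

## Per-cell correlation

Pearson's $R = \mathrm{Cov}(x,y)/(\sigma_x \sigma_y)$, with significance
from the regression F statistic $F = R^2(n-2)/(1-R^2)$ on $(1, n-2)$ df
(upper tail; identical to the two-sided t-test on $R$), and Spearman's ρ
as the same formula on mid-ranks with a two-tailed t on $n-2$ df.  The
product $\sigma_x\sigma_y$ in the denominator is the only reading that
keeps $R \in [-1, 1]$ (a difference of standard deviations, occasionally
seen in transcribed formulas, does not define a correlation).  Both
statistics match brute-force two-pass implementations to 1e−12 and are
unbiased within 0.05 at n = 41 cells in bivariate-normal simulation.

## qPCR relative quantification

$\Delta Ct$ = gene Ct − reference-gene Ct within a sample (technical
replicates averaged at the Ct level first); $\Delta\Delta Ct$ subtracts the
matched control-condition replicate; fold = $2^{-\Delta\Delta Ct}$.
Because stem-cell-derived cardiomyocyte preparations vary biologically,
replicates are standardized: within each biological replicate all fold
values are log-transformed (natural log — the base cancels under centering
and scaling), mean-centered and autoscaled.  Reports carry both the
standardized mean with Student-t 95% CI (n−1 df) and the back-transformed
geometric-mean fold with its CI on the log scale; which scale a reader
prefers is a presentation choice, so both are emitted.  The reference gene
is excluded from standardization (its fold is identically 1 and carries no
information, only variance shrinkage).

The generator's Ct model adds a per-sample loading offset (cancelled by
ΔCt, as in real plates), per-sample×gene biological noise (default 0.2
Ct), and smaller per-well technical noise (0.1 Ct).  A simulated 50%
knockdown with 6 biological replicates yields CIs that exclude fold 1.

## Voltage-clamp analysis

Activation fits use the full current–voltage Boltzmann

$$I(V) = \frac{(V - V_{rev})\, G_{max}}{1 + e^{(V - V_{1/2})/k}}$$

in which activation that grows with depolarization corresponds to $k < 0$;
fits report $|k|$ plus a direction flag so the sign convention can never
mislead.  Availability (inactivation) uses
$I(V) = (I_{min} - I_{max}) + I_{max}/(1 + e^{(V - V_{max})/k})$ in
exactly this form; as written the curve tends to $I_{min}$ far below
$V_{max}$, the opposite of the conventional availability orientation — the
signs of $I_{max}$ and $k$ absorb the direction, so conventionally
oriented data fit without modification and the form is kept verbatim
rather than silently "corrected".  All fits are multi-start
Levenberg–Marquardt ($k \in \{\pm3, \pm7, \pm15\}$ mV, midpoint seeded at
the half-amplitude voltage) and raise an error only if every start fails.

Two practical notes.  (1) On a step protocol confined to −50..+30 mV the
saturated branch of the I–V is nearly linear, making $G_{max}$ and
$V_{rev}$ strongly collinear; fixing $V_{rev}$ at its known physiological
value (the `V_rev` argument) restores sub-millivolt recovery of $V_{1/2}$
at 5% current noise.  (2) Chord conductance $G = I/(V - V_{rev})$ excludes
points at the reversal; $G_{max}$ comes from a logistic fit to the G–V
points, falling back to the largest observed |G| when the plateau is not
identifiable in-range (ohmic or non-saturating data would otherwise
inflate it without bound).

Steady state is the mean over the final 5 ms of the step; tail peaks are
the signed extremum after the return to the tail potential; peak inward
current searches 1–10 ms after step onset (configurable — the
window is a measurement convention, not a fitted quantity).  The late
current integral is the trapezoidal integral of baseline-corrected current
over 50–800 ms from pulse onset, with the baseline taken from the final
10 ms of the pre-pulse holding segment (a zero or user-supplied baseline
is available); it is exact on closed forms to <0.5% at 1-kHz sampling and
is additive over subintervals and linear in the trace.

## The synthetic-data generator

The generator provides ground truth for every pipeline stage: elliptical
cell masks with contained circular nuclei (106.3 nm pixels, 512×512
default); spot fields with per-species counts, a configurable cluster-size
mixture (default ~25% singles and ~20% in clusters of ≥6, with per-cell
totals spanning roughly 5–200 via `count_sampler`), a planted colocalized
fraction whose partners land uniformly within one pixel of their anchors,
lognormal multiplicative intensity noise (intensities are positive, so
noise is multiplicative), and an exponential perinuclear placement bias
(λ = 10 µm; ∞ gives uniform); pixel-integrated Gaussian rendering with
Poisson shot noise; Ct tables; and Boltzmann-gated sweep families with
first-order activation/deactivation kinetics and optional late-current
plateaus.  All generators are bit-reproducible from a single integer seed,
with per-cell sub-seeds drawn from the master seed.

What it does **not** emulate — and therefore what passing tests do not
certify on real data: hybridization chemistry and probe-set efficiency,
photobleaching, camera gain/read noise beyond Poisson statistics,
autofluorescent structures, out-of-focus light in projections of thick
cells, segmentation errors in real nucleus/cell masks, chromatic offset
between channels, transcription-site aggregates, and PCR efficiency
differences between assays.  Detection benchmarks additionally use
hard-core (≥5 px separated) spot fields, because two molecules within a
PSF width are indistinguishable in principle; real dense clusters are
handled through the intensity-calibration route instead, which is exactly
why both routes exist.

## Test problem sizes

The test suite exercises the study-scale configurations: 40-cell
experiments at ~100 spots/channel for association recovery (planted
fractions 0, 0.1, 0.25, 0.5; recovery within 3 percentage points), 200
null replicates for test calibration, 20-seed recovery runs for
calibration (n = 2611 pooled spots) and gating parameters (V_{1/2} and
V_max within 1 mV median at 5% noise), 100-spot SNR-5 detection
benchmarks, and 41-cell correlation samples.  Unit tests run on smaller
256-px geometries for speed.

## Known limitations

- Analysis is 2D on maximum projections; the 3D option fits the axial
  center per spot but no anisotropic 3D PSF model.
- The chance model treats cells independently and areas as homogeneous;
  no inhomogeneous-Poisson null is provided (the uniform "distance" model
  plus the perinuclear caveat above bound the effect).
- No spectral unmixing, chromatic registration or drift correction.
- qPCR assumes equal primer efficiencies (the 2^−ΔΔCt premise).
- The sweep simulator uses single-exponential gating kinetics, adequate
  for steady-state and integral measurements but not for kinetic fitting.
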
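---
title: "Subunit receptive-field models and redundancy analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subunit receptive-field models and redundancy analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rgcpop` implements an analysis pipeline for studying how retinal ganglion
cell (RGC) populations encode natural, gaze-shifted stimuli: receptive-field
characterization from white noise, nonlinear subunit models fitted to
grating responses, response prediction for natural images and videos,
frequency-domain information rates with fractional redundancy for cell
pairs, and decompositions of pairwise response correlations by spatial
contrast and receptive-field nonlinearity. Because population recordings are
not required to exercise any of this machinery, the package ships a
ground-truth retinal simulator: every analysis can be validated end-to-end
on synthetic data whose generating model is known exactly.

This vignette documents the models, their assumptions, the numerical
choices, and the design decisions taken where the methods left freedom. It
states no empirical result beyond what the test-suite and
`scripts/acceptance.R` compute.

# Stimuli and the synthetic retina

## Geometry

All model geometry lives in micrometres on the retina: x rightward,
y downward, origin at the image centre. Pixel coordinates are converted via
a pixel pitch (7.5 µm/pixel by default, a typical projection-system scale).
Spike-count bins are half-open `[t, t + dt)` and left-aligned to stimulus
frame onsets.

## Gratings

Sinusoidal gratings are parameterized by spatial frequency `f` (cycles/µm),
orientation `theta` and phase `phi`, with contrast
`C(x, y) = sin(2*pi*f*(x cos theta + y sin theta) + phi)`. The reference
flashed battery (`reference_battery()`) uses 25 spatial frequencies with
half-periods from 15 to 1200 µm (log-spaced), 12 orientations and 4 phases —
1200 distinct gratings presented as 200 ms flashes separated by grey gaps.
Flicker batteries update the grating every frame in pseudorandom order with
a frozen repeated segment interleaved for reliability estimation.

## Checkerboard white noise

Binary ±1 contrast on a stixel grid (30 µm squares by default), regenerable
bit-exactly from its seed, with an optional frozen test segment.

## Natural-like images and gaze videos

Synthetic "natural" images are 1/f-spectrum Gaussian noise fields multiplied
by a smooth lognormal contrast envelope, standardized to a target RMS
contrast (0.45, matching the 38–45% range of the photographic image sets
used in this kind of experiment) and clipped to ±1. The envelope is
essential: a plain Gaussian 1/f field is spatially homogeneous — its local
contrast is virtually constant across the image — whereas real scenes
alternate between near-uniform and high-contrast regions. Spatial-contrast
analyses are meaningless without this non-stationarity. What these images
still do not have: sharp object boundaries, occlusion structure, or
higher-order phase regularities of real scenes; conclusions from passing
tests therefore concern the analysis machinery, not photographic image
statistics. A loader path for user-supplied contrast images exists
(anything in the same Weber-contrast convention can be passed wherever the
synthetic images are accepted).

Videos present each image for 1 s (as in the recordings this pipeline is
designed for) and shift it frame-by-frame by a synthetic gaze trace:
Gaussian fixational jitter steps plus discrete saccades of 100–300 µm
executed within one frame, with ground-truth saccade frames recorded for
round-trip testing. Displacement is applied by nearest-pixel translation
against an edge-padded source image (the study presented pre-rendered
frames; sub-pixel interpolation is deliberately off). Traces that would
exceed the padding are rescaled to fit by default (`overflow = "rescale"`);
an error mode is available. For 1-D gaze traces (the mouse protocol), the
axis is drawn per image from a configurable set of orientations; whether it
is resampled per trial is exposed as a flag because the original protocol
leaves it open.

## Encoders and spiking

Three encoder families generate ground-truth responses: a pixel-space LN
encoder (arbitrary filter, static output nonlinearity), a DoG LN encoder
(`R = a N(beta r_dog + gamma)` with logistic `N`), and a subunit-grid
encoder (`R = G(sum_s w_s N(beta r_s + gamma))` with circular
difference-of-Gaussians subunits and Naka–Rushton output `G`). All encoders
accept an optional causal temporal kernel over frames. Spikes are Poisson
per bin and trial, with per-cell/per-trial streams derived by deterministic
seed splitting so that adding cells or trials never reshuffles existing
streams. A calibration test checks per-bin mean/variance (Fano factor 1) at
200 trials.

# Receptive-field characterization

The spike-triggered average (STA) is computed over a 500 ms lag window. The
temporal filter is the mean time course of stixels whose absolute peak
exceeds 4.5 robust standard deviations (1.4826 × median absolute deviation)
of all STA elements; the spatial filter is the projection of the STA onto
the unit-normalized temporal filter. Sign convention: the temporal filter's
extremum is positive; the spatial filter carries the residual sign.

Receptive-field contours are obtained by bilinear upsampling of the spatial
filter to single-pixel resolution, blurring with a circular Gaussian of
σ = 4 pixels (in upsampled pixels; the original description is ambiguous on
the unit, so it is exposed as a parameter), extracting the 25%-of-maximum
level set with `grDevices::contourLines` (the R counterpart of MATLAB's
`contourc`), keeping the contour that encloses the peak when several exist,
and removing contour points whose neighbour distances exceed 20 robust
standard deviations. The centre is the coordinate-wise median of contour
points; the area is the polygon area. On an isotropic Gaussian filter the
area agrees with the circle defined by the measured 25%-level radius to
within 2%.

Reliability is quantified by the symmetrized coefficient of determination
(mean of `1 - SS_res/SS_tot` in both prediction directions). Note that for
two *uncorrelated* traces of similar variance this statistic is close to
−1, not 0; it approaches 0 only when one trace is nearly constant. Fano
factors are computed per fixation (across-trial variance over mean of the
fixation spike count), excluding fixations with a mean below three spikes,
and summarized as the mean weighted by the mean spike count.

# The analytic DoG grating response

A DoG receptive field is a unit-integral elliptical centre Gaussian minus
`w_surr` times a unit-integral surround Gaussian with SDs scaled by `k_s`
(forced by the zero-frequency limit `A(0) = 1 - w_surr`). Its inner product
with a grating has the closed form `r = A(f) cos(Theta)` with

* `sigma_eff^2 = sigma_y^2 sin^2(theta + theta_dog) + sigma_x^2 cos^2(theta + theta_dog)`,
* `Theta = 2*pi*f*sqrt(x0^2 + y0^2) cos(theta - atan2(y0, x0)) + phi - pi/2`
  (the `atan2` form handles all quadrants; a centred field reduces to
  `Theta = phi - pi/2`),
* `A(f) = exp(-c sigma_eff^2 f^2) - w_surr exp(-c (k_s sigma_eff)^2 f^2)`.

Two conventions for `c` are provided. The exact Fourier transform of a
unit-integral Gaussian gives `c = 2*pi^2`; this is the default, and it is
validated against brute-force pixel-space quadrature to a relative error
below 1e-3 over random parameter draws (the test-suite covers 2500
parameter–grating combinations). An alternative convention with `c = 2*pi`
is selectable as `mode = "as_printed"` for compatibility with parameter
sets fitted under that convention. The ellipse-rotation sign convention was
fixed by requiring agreement with the quadrature oracle for anisotropic
fields.

# DoG LN fitting

`fit_dog_ln()` minimizes the negative Poisson log-likelihood of per-flash
spike counts under the constraints σx, σy > 7.5 µm, −π/4 < θ < π/4,
1 < k_s < 6, 0 ≤ w_surr < 1, a > 0, using multi-start L-BFGS-B on
per-grating sufficient statistics (each trial enters independently, which
for a Poisson likelihood reduces to per-grating flash counts and spike
sums). Parameter recovery on ~1e4 simulated flashes lands σ within a few
percent and the centre within ~1–2 µm (`dog_recovery_experiment()`);
because the ellipse orientation can swap the two axes, recovery is judged
on the sorted axis pair.

# The subunit grid model

## Model

1200 candidate subunits on a hexagonal lattice with 16 µm spacing around a
given centre; each subunit is a circular DoG with shared σ, `k_s`,
`w_surr`; subunit activations pass through a shared logistic
`N(beta r + gamma)`, are pooled with non-negative weights, and the pooled
signal passes through a Naka–Rushton output `G(x) = a x^n / (x^n + k^n) + b`
(the baseline `b` is present in the flashed variant and absent in the
spatiotemporal one, exactly as each variant is defined).

## Cost, optimizer and the penalty scale

The cost is the spike-normalized negative log-likelihood plus the density
regularizer `lambda * sum_s w_s sum_{i != s} w_i / d_si^2`, minimized by
ADAM (batch 64 flashes, β1 = 0.9, β2 = 0.999, ε = 1e-6) with a Gaussian
learning-rate schedule (mean `N_epochs/2`, SD `N_epochs/5`, peak 0.005) and
the full epoch budget `4e5 / N_flashes`; constraints are enforced by
projection after every step, weights are initialized from a Gaussian
profile at the receptive-field centre with seed-controlled jitter, scaled
so the initial pooled drive sits near half-saturation.

Two coupled scale choices deserve explanation, because the cost function as
written does not pin them down:

* **Weight scale.** The half-saturation `k` of the Naka–Rushton output is
  exactly degenerate with a global rescaling of the weights, and the
  density penalty is not invariant under that rescaling — an optimizer can
  silently evade the penalty by shrinking all weights while `k` follows.
  The package therefore pins `k = 1` during the stochastic phase (no
  expressiveness is lost; the weights carry the scale) and lets the
  pruning-stage refit restore full freedom.
* **Distance unit.** With the likelihood normalized per spike and subunit
  activations of order one, the regularization ladder from 1e-6 to 5e-4
  only spans "negligible" to "strongly consolidating" if the pairwise
  distances in the penalty are measured in millimetres. This is the unit
  the package uses; with µm distances the entire ladder is inert, which
  contradicts the ladder's documented purpose of controlling coverage.

## Pruning, refit, selection

After optimization, weights below 5% of the maximum are zeroed; a 2-D
Gaussian is fitted to the weighted subunit receptive fields (weighted mean
and covariance of the centres, broadened by the subunit σ) and weights of
subunits beyond 2.5 SD are zeroed; then the output nonlinearity is refitted
together with a global weight scale (`prune_and_refit()`).

The package adds one further stage, `sg_refine()`: a deterministic
full-batch L-BFGS-B refit of *all* parameters on the pruned support. The
rationale is an observed division of labour: the stochastic phase discovers
the weight support efficiently but moves the shared parameters (subunit σ
and especially the nonlinearity threshold) only slowly against minibatch
noise, leaving them biased towards a smeared, weakly rectified solution.
Once the support is small the regularized likelihood can be optimized to
convergence directly, which is what makes the subunit nonlinearity
recoverable in practice. Weights falling below the 5% rule during the
refit are zeroed and the model briefly re-polished.

Model selection runs six regularization strengths (log-spaced 1e-6 to
5e-4), keeps candidates with at least three subunits and coverage below 3,
and picks the minimal Bayesian information criterion
`N_sub ln(N_data) - 2 ln L`; exact ties go to the smaller lambda
(deterministic). If nothing is eligible the cell is excluded, explicitly.

Coverage is `4σ` (subunit diameter) over the weight-weighted mean
nearest-neighbour distance; it requires at least three active subunits.
Nonlinearity asymmetry offsets the subunit nonlinearity to map 0 to 0,
scales its maximum on [−1, 1] to one, and reports `(1 − M)/(1 + M)` with
`M` the absolute minimum: 0 for an odd-symmetric nonlinearity, 1 for full
rectification.

## Recovery benchmark

`sg_recovery_experiment()` fixes the study conditions: a 7-subunit ground
truth (σ = 15 µm, strongly rectifying logistic with β = 6, γ = −3,
asymmetry 0.90) on the 1200-grating battery at 2 trials per grating — the
trial count of the marmoset flashed-grating recordings. The truth sits on
the candidate lattice with seed-varied unequal weights: parameter recovery
is a within-model-class question, and a perfectly symmetric equal-weight
layout creates artificial interstitial degeneracies (midpoints equidistant
from two true subunits) that no real bipolar mosaic has. Recovery is
asserted for the interpretable quantities only — subunit σ within 20%,
nonlinearity asymmetry within 0.15, held-out grating prediction R² ≥ 0.8
against the ground-truth rates — not for raw weights, which the data
genuinely underdetermine. The desk-scale runs use 60 epochs per rung
(the full schedule would use 167).

# Spatiotemporal variants

Temporal filters span 500 ms as linear combinations of ten basis functions:
two single-frame boxcars for the two frames before the response bin and
eight raised cosines with peaks from 0 to 250 ms. The spatiotemporal DoG LN
model (`fit_st_dog_ln()`) drives a logistic output with centre and surround
activation histories filtered by separate kernels; it is fitted by L-BFGS-B
with analytic gradients (verified against finite differences in the
test-suite). The response bin is the frame, with the history window ending
at the bin start. The surround strength `w_surr` and the surround kernel
scale only through their product; no extra constraint is imposed, and
recovery claims are made for the centre kernel. Identifiability requires a
reasonably rich flicker battery: with only a couple of dozen distinct
gratings many spatial/temporal combinations produce identical frequency
responses, so the recovery test uses ~200 distinct gratings.

The spatiotemporal subunit grid (`fit_st_sg()`) shares the temporal kernels
across subunits, uses contiguous-chunk ADAM batches (reference batch 2000
frames, peak learning rate 0.02), the same density regularizer, and a
baseline-free Naka–Rushton output. It is tested at reduced grid sizes; the
implementation is O(window × batch × subunits) per step and is not intended
for grids beyond a few thousand sites.

# Natural-stimulus prediction

For flashed images, model outputs are compared to trial-mean spike counts
by Spearman rank correlation, without an output nonlinearity: white-noise
LN filters are upsampled and normalized by the sum of absolute values; DoG
fields are instantiated at pixel resolution; subunit-grid outputs pass each
subunit through the fitted nonlinearity before weighted summation. A
constant model output is flagged degenerate and scored 0.

For videos, the output nonlinearity is estimated on the training segment —
as an equal-population 40-bin histogram (applied by linear interpolation,
clamped to end-bin values outside the training range, a choice the
interpolation-only description leaves open) for white-noise LN models, or
by Poisson maximum likelihood in the model's own parametric output form for
grating-fitted models — and performance is the fraction of explained
variance R² against trial-averaged test rates, negatives clipped to zero.
Trial-mean rates are computed at the prediction binning with no smoothing.

Maximally differentiating fixations are ranked by the absolute difference
between subunit-grid and DoG LN predictions, normalized per cell by the
response range over the test segment and averaged over fixation frames and
the two cells of a pair; the top 20% (ceiling) form the differentiating
set, the upper half the "nonlinear" and the lower half the "linear" group.
Ties break by fixation index. The selection never reads the responses
(response ranges are permutation-invariant), which a test verifies by
permuting responses.

# Information rates and fractional redundancy

Spike trains binned at 0.4 ms are cut into 0.8 s sections (2000 bins; 1.25
Hz frequency spacing; 160 frequencies up to the 200 Hz cutoff; DC excluded
because the mean rate is not stimulus-locked modulation — both cutoff and
DC handling are configurable). Signal entropies use the variance of
cos/sin coefficients over sections averaged over trials; noise entropies
the variance over trials averaged over sections; information is the
entropy difference per section duration, summed over frequencies.
Degenerate variances produce a `-Inf` sentinel and the affected frequencies
are dropped with a warning, never silently clipped.

Two entropy conventions are implemented because the single-cell and pair
formulas as conventionally printed are mutually inconsistent under
independence. The "printed" convention sums the variances (for pairs, the
four covariance eigenvalues) inside a single logarithm; it satisfies the
duplicated-cell identity `I_pair = I_single` exactly (a test asserts this
to 1e-10) but assigns fractional redundancy 1 to two independent cells
with identical statistics. The default "det" convention uses the full
Gaussian entropy (sum of log eigenvalues); it is additive over independent
cells (fractional redundancy near 0; a Monte-Carlo test over 50 replicates
bounds the mean by 0.05) and approaches 1 for near-duplicate cells (shared
spike train with sparse independent extra spikes — with genuinely
independent Poisson noise of full strength, redundancy is bounded well
below 1 because the pair's noise entropy grows with the duplicated noise).
Both behaviours are asserted on simulation.

The estimator's finite-data bias largely cancels between signal and noise
entropies when the numbers of sections and trials are comparable; the stock
benchmark (broadband-modulated rate, 16 sections × 32 trials) changes by
about 1–3% when half the trials are dropped. For video-locked responses the
frequency cutoff is lowered to 50 Hz in the population experiments: an
85 Hz frame-locked stimulus has no modulation above its Nyquist frequency,
and the 50–200 Hz band would contribute estimator noise only.

# Correlations, fixations and spatial contrast

Fixation boundaries come from image transitions (always) and from
velocity peaks: the instantaneous speed (displacement between consecutive
positions times frame rate) is scanned for local maxima above a threshold
(specified in deg/s and converted with the retinal magnification, 100
µm/deg for marmoset and 31 for mouse, or given directly in µm/s), with
peaks closer than the minimum interval resolved in favour of the taller
peak — the exact "findpeaks" selection rule, re-implemented because the
tie-breaking matters for the round trip: planted saccades twice the
threshold are recovered with precision = recall = 1.

Spatial contrast of a frame is the SD of pixels weighted by the positive
part of the normalized receptive-field profile (the profile's sign handling
is unspecified in the source description); per fixation the median over
frames is used, as is the median linear activation. The high/low
spatial-contrast split sorts fixations by the pair-averaged activation,
pairs neighbours (dropping the last when odd), and assigns the higher-SC
member of each pair to the high group (ties to the earlier index). Partial
correlations restrict the Pearson numerator to a frame subset while keeping
global means and SDs, so complementary subsets sum to the full correlation
to machine precision (asserted at 4 ulp over 1000 random fixtures).

Correlation–distance curves average pair correlations over groups of ~20
pairs with Student-t 95% CIs (the CI method is the package's choice);
stimulus pixel correlations are computed for a random pixel subsample with
a linear interpolator over the binned curve; decorrelation is
`(rho_stim - r_resp)/rho_stim` at the pair's distance. Direction
selectivity uses the normalized complex sum over directions with a Monte
Carlo permutation test (trial responses shuffled across directions) and an
ON–OFF index `(onset - offset)/(onset + offset)`.

# The population experiment

`reference_video_world()` builds the canned end-to-end comparison: a
six-cell mosaic of rectified subunit-grid encoders (19 subunits of
σ = 15 µm each, strong subunit surrounds `w_surr = 0.8`, rectifying
logistic β = 8, γ = −2, expansive Naka–Rushton output) against matched
midget-like linear DoG LN encoders (σ = 25 µm, operated in the logistic's
linear range), responding to a 100-image gaze video. Three ingredients are
load-bearing, and each was identified on the simulator: contrast patches
must be non-stationary (the image envelope), the subunit surrounds must
remove the shared luminance drive (otherwise both encoder families ride the
same large-scale intensity fluctuations and the contrast split is
uninformative), and the pooled response must be *convex* in local contrast
(a response merely proportional to contrast produces equally positive
products below and above the mean, so high- and low-contrast partial
correlations split evenly). With these in place, the rectified population
shows a positive high-minus-low contrast split and higher near-pair
fractional redundancy than the linear population — the sign-level pattern
this analysis is designed to expose. The magnitude of the split fluctuates
between stimulus realizations at this desk scale (15 pairs, one video);
the difference between the two encoder families is much more stable than
either absolute value, and the acceptance script reports both.

# Problem sizes and limitations

The shipped experiments are sized for a single CPU: 1200-grating batteries
at 2–8 trials, 60 training epochs per ladder rung (full schedule 167),
100-image videos at 20 repeats, information benchmarks of 16 sections × 16–32
trials, and 50 Monte-Carlo replicates for the independence contract. Known
limitations: the subunit-grid weight layout is not identifiable at these
data sizes (only σ, the nonlinearity shape, and predictions are asserted);
the spatiotemporal subunit fit is exercised at reduced grid sizes; the
synthetic images lack the phase structure of real scenes; and the
population-level contrast-split effect is a sign-level, not quantitative,
reproduction.
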
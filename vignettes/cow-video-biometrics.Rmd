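---
title: "Non-invasive cow biometrics and milk-productivity modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive cow biometrics and milk-productivity modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bovitals)
```

# Overview

`bovitals` implements a contact-free monitoring pipeline for dairy cattle.
From a one-minute RGB video of a restrained cow it estimates heart rate
(remote photoplethysmography on the eye region) and respiration rate (color
modulation of the nose region), and quantifies abrupt head movement from the
tracked head bounding box.  A radiometric thermal stack yields the eye
temperature.  Farm weather records are expanded into psychrometric
quantities (dew point, wet bulb) and nine temperature--humidity indices
(THI).  All of this feeds a 37-input, 5-output feedforward neural network
trained with Bayesian regularization that predicts eye temperature, milk
yield per day and per milking, and milk fat and protein percentages.

Because the underlying farm recordings are proprietary, the package ships a
synthetic-data module that emulates every input with known ground truth.
Every claim the test suite makes is therefore a claim about *recovery of
known structure*, not about real cows; the end of this vignette spells out
what that does and does not establish.

# Video biometrics

## Signal model

The remote-PPG premise is that cardiac pulsation modulates skin reflectance
by a fraction of a percent, visible as a periodic fluctuation of the mean
green-channel intensity over a suitable region of interest; respiration
modulates the red/green balance, captured here as the CIELab a* (green-to-
red opponent) component of the nose region.  The pipeline per trace is:

1. **Region mean.** For each frame, the mean of the channel over the ROI
   box, computed in float before any rounding.  For a*, each sRGB pixel is
   converted to CIELab (D65 white point) and the a* components averaged.
   Averaging over several hundred pixels pushes the effective quantization
   noise of 8-bit video well below a one-grey-level signal amplitude.
2. **Detrending.** A centered moving-average trend with window `1/low`
   seconds is subtracted (partial windows at the edges), removing
   illumination drift and DC.
3. **Band-pass.** A zero-phase order-2 Butterworth filter restricted to the
   physiological band: 0.67--2.5 Hz (40--150 BPM) for the cardiac trace,
   0.15--1.2 Hz (9--72 BrPM) for respiration.  The bovine resting heart
   rate sits near 60--90 BPM and respiration below 60 BrPM, so both bands
   carry generous margins; both are exposed as configuration.
4. **Peak analysis.** Local maxima with topographic prominence at least
   0.25 of the trace standard deviation, separated by at least 0.4 s
   (cardiac) or 0.8 s (respiratory).  The rate is `n_peaks / duration * 60`;
   the amplitude is the mean peak-to-preceding-trough excursion; quality is
   the fraction of inter-peak intervals within 25 % of their median.  Traces
   with fewer than two peaks return an explicit undefined-rate flag rather
   than a silent zero.

Peak counting is the primary estimator; an FFT-argmax spectral estimate
(`spectral_rate()`) is kept as an independent cross-check and agrees with
peak counting to within one spectral bin on synthetic traces.

Defaults that are design choices rather than physical constants: the
prominence fraction (0.25), the minimum separations, and the band edges.
The ROI is used as given -- no skin segmentation inside the box.

## What the rate quantization means

With pure peak counting over a recording of `T` seconds the rate resolution
is `60/T` per minute: 1 BPM for the one-minute default, which is why the
recovery guarantees are stated as +/-2 BPM and +/-1 BrPM.  Short clips
degrade proportionally.

# Movement metrics

The head-box centroid (`x_min + width/2`, `y_min + height/2`) is split into
four contiguous temporal blocks ("quartiles" of the recording; any remainder
joins the last block).  Per-block means and population (divide-by-n)
variances, plus whole-video variances, are the 18 exported features, all in
pixel units -- the camera geometry is fixed but uncalibrated, so no metric
conversion is attempted.  No significance threshold is imposed on "abrupt"
movement; the raw variances are handed to the model.

# Thermal analysis

Radiometric frames are plain CSV matrices of degrees C.  The eye temperature
is extracted as the per-frame *maximum* over the tracked head region --
the eye canthus is reliably the hottest facial point -- and summarized as
the temporal mean of those maxima (`mean_max`).  An alternative reading,
max-of-frame-means, would be systematically lower and was rejected because
the per-frame maximum is the quantity that tracks core temperature in the
thermography literature; the per-frame series is returned so users can form
either summary.  Values outside -20..60 C trigger a warning, not an error,
to keep deliberately unusual calibrations usable.

# Weather and heat-stress indices

Saturation vapor pressure uses the Magnus form (a = 17.27, b = 237.7 C,
es0 = 6.1078 hPa).  The dew point inverts it in closed form.  The wet bulb
solves the psychrometric balance

    es(Tw) - A * p * (T - Tw) = e,    A = 6.6e-4 / C

by bisection on `[Tdp, T]` to a residual below 1e-4 hPa (or 100 iterations);
saturated air short-circuits to `Tw = T`.  The bracket guarantees
`Tdp <= Twet <= T` by construction; an exhaustive grid-search oracle agrees
to within 2e-3 C in the tests.

Nine published THI formulations are evaluated (`thi_equations()` lists the
sources): Ingraham 1979, two Bianca 1962 wet-bulb blends, the NRC 1971
relative-humidity and dew-point forms, Yousef 1985, Kibler 1964, Mader 2006
and Thom 1959.  The key assignment THI1..THI9 was fixed so that under the
cool humid winter conditions the package emulates, the dew-point NRC form
(THI6) and the Ingraham form (THI1) sit highest while the strongly
wet-bulb-weighted Bianca form (THI9) is lowest -- the qualitative ordering
reported for this kind of campaign.  All nine are monotone non-decreasing
in temperature at fixed humidity.  Surface pressure defaults to
1013.25 hPa when a weather file lacks it.

# The network

## Architecture and objective

A two-layer feedforward network: `hidden_size` tan-sigmoid units, linear
outputs.  Inputs and targets are min-max scaled per column to `[-1, 1]`
(maps learned on training rows only).  Training minimizes

    F = beta * E_D + alpha * E_W

(`E_D` sum of squared residuals over all five outputs, `E_W` sum of squared
weights) by Levenberg--Marquardt steps with an exact Jacobian.  After every
accepted step the hyperparameters are re-estimated from MacKay's evidence
framework:

    gamma = P - 2 * alpha * tr(H^-1)
    alpha <- gamma / (2 * E_W)
    beta  <- (N - gamma) / (2 * E_D)

with `P` the parameter count, `N` the residual count and
`H = 2 beta J'J + 2 alpha I`.  `gamma` is the effective number of
parameters, the built-in overfitting control that makes a validation set
unnecessary during training.  Training stops on the epoch budget (default
300), a gradient below 1e-7, or damping overflow (`mu > 1e10`, i.e. no
downhill step exists).  Numerical guards: `E_D` and `E_W` are floored at
1e-12 in the updates; `N - gamma` is floored at machine epsilon; a singular
damped Hessian escalates `mu`.  Setting `alpha = 0` disables the evidence
updates and reduces the trainer to plain Levenberg--Marquardt least squares,
which the tests verify against an independent LM implementation.

## Protocol

Development uses a seeded random 70/30 split.  A model is admissible only
if the input count is below 70 % of the training-sample count (the overfit
guard: 37 inputs against 105 training rows passes).  Neuron trimming trains
one model per candidate hidden size (3, 5, 7, 10), screens out sizes whose
test MSE exceeds 3x their training MSE, and selects the best pooled test
correlation, ties to the smallest size.  Deployment evaluates the frozen
model on recordings never seen during development.

## Two pooled statistics, deliberately different

Five targets with different physical units are compared on the min-max
scale.  The package uses two pooled conventions:

* `regression_report()` pools all scaled points *uncentered* -- this is the
  analogue of a pooled predicted-vs-observed regression plot, and its R,
  slope and 95 % prediction-band outlier percentage are the reported
  development/deployment statistics.  The pooled MSE is reported in scaled
  units because a raw-unit MSE across kilograms, percent and degrees C is
  dimensionally incoherent; per-target MSEs in original units are attached.
* The *selection* statistic used inside neuron trimming centers each scaled
  column first.  Without centering, a constant-per-target predictor already
  achieves a visibly positive pooled R purely from shared column-mean
  structure (up to ~0.35 on five-column noise), which would let a skill-free
  model pass the pure-noise guard.  Centering makes the selection statistic
  measure within-target skill only.

The 95 % "confidence bounds" for outlier flagging are implemented as the
prediction interval of the pooled least-squares line of predicted on
observed -- a per-point band, consistent with a few percent of points being
flagged; outlier percentages are rounded to one decimal.

## The 37-column feature schema

The input count is fixed, and its composition here is an explicit
reconstruction: 4 video biometrics (HR, HR amplitude, RR, RR amplitude),
18 movement statistics (4x4 quartile means/variances plus 2 whole-video
variances), 15 weather values (T, RH, wind speed/direction, dew point, wet
bulb, THI1..THI9).  `feature_columns()` is the single source of truth and
`assemble_features()` validates against it, so the count check is
meaningful.

# The synthetic-data module

The generators emulate the recording campaign:

* **RGB scenes** (`gen_rgb_sequence()`): 60 s at 30 fps by default (the
  camera frame rate is a stand-in -- the source recordings are 4K video of
  unstated rate), at a scaled-down 360x640 (tests use 120x160).  The eye
  region's green channel carries `pulse_amplitude * sin(2 pi f_hr t)`
  (default 2 grey levels), the nose's red/green balance
  `resp_amplitude * sin(2 pi f_rr t)` (default 3), with iid per-pixel
  Gaussian noise (default sd 1) added before 8-bit quantization.  The head
  box is static, drifts linearly, or random-walks; eye/nose regions ride on
  it.  Amplitudes are recoverable because region means average >= 400
  pixels at the default sizes.
* **Thermal stacks** (`gen_thermal_sequence()`): a Gaussian-profile hot
  region whose peak pixel equals the requested eye temperature exactly
  (36.5 C on a 12 C winter background by default), plus pixel noise
  (sd 0.2 C); its own cadence (5 fps).
* **Weather** (`gen_weather_series()`): 15-min cadence, winter profile
  centered at T 11.3 C, RH 81 %, wind 11.8 km/h with a mild diurnal
  component; humidity clipped to (0, 100].
* **Herd tables** (`gen_herd_dataset()`): HR ~ N(82, 8) clipped to 60--110
  BPM, RR ~ N(34, 6) clipped to 20--60 BrPM, movement variances log-normal
  (median 30 px^2, log-sd 0.6), weather matched by timestamp.  The five
  targets are documented smooth functions of at most four features each
  (see `herd_target_function()`), mildly nonlinear (log1p terms and one
  interaction) so that the network genuinely outperforms a straight line
  and neuron trimming has something to select on.  Target noise defaults to
  the per-target sd that fixes the oracle correlation between noise-free
  and noisy targets at 0.96, so downstream accuracy has a known ceiling.

Design notes on the herd generator: the log-normal log-sd of 0.6 gives a
realistic ~4x interquartile spread of movement activity.  A much heavier
tail would let a single extreme cow dominate the min-max input scaling and
turn the oracle-recovery check into a test of tail sampling rather than of
the pipeline, which is why 0.6 was fixed as the study condition.

## What the synthetic data does not emulate

Real recordings have non-sinusoidal pulse waveforms, heart-rate
variability, motion artifacts correlated with the signal, specular
highlights, compression artifacts, imperfect tracking, and weather that
co-varies with behavior.  Passing the recovery tests shows the estimators
are correct implementations with the stated noise robustness; it does not
certify field accuracy on real cows, which requires the original (or new)
recordings.

# Problem sizes used by the tests

The suite and the acceptance script run on reduced but non-trivial sizes
chosen as sensible desk-scale study conditions: 120x160-pixel one-minute
videos for the 20-seed recovery sweep; a 150-recording development herd
(105/45 split) plus a 132-recording deployment herd for the network checks;
a 1000-point grid for the psychrometric sweep; 20-seed null simulations for
the fake-skill guard.  The end-to-end pipeline test uses 80 + 12
recordings of 10-s, 72x96 videos with a respiratory band floor raised to
0.25 Hz (shorter clips cannot resolve slower breathing).

Observed behavior at these sizes: heart and respiration rates recover
exactly or within the stated +/-2 BPM / +/-1 BrPM in all sweep seeds; the
selected network's held-out pooled R sits about 0.02--0.09 below the 0.96
oracle ceiling (typically ~0.04, varying with the herd draw); deployment R
tracks development R to within about 0.04; the
pure-noise guard stays below R 0.3 with a wide margin once the selection
statistic is centered (see above).

# Known limitations

* ROI boxes are consumed as given; there is no tracker and no skin/eye
  segmentation inside the box.
* No RGB-thermal co-registration, emissivity or distance correction.
* The nine THI equations reconstruct a canonical literature set; any
  specific farm study may number its equations differently, so THI values
  should be compared by formula source, not by index key.
* A single hyperparameter pair (alpha, beta) regularizes all weights; no
  per-input relevance determination, so irrelevant inputs still cost a
  little held-out accuracy at n = 105.
* Pipeline orchestration is synthetic-first: `run_pipeline()` simulates its
  campaign; real data enters through the module functions
  (`read_frame_dir()`, `read_roi_track()`, `read_radiometric_csv()`,
  `derive_weather()`, `assemble_features()`, ...).
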
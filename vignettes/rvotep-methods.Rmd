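---
title: "Methods: action-potential analysis, abnormality detection, fibrosis quantification and association modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: action-potential analysis, abnormality detection, fibrosis quantification and association modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvotep)
```

## Scope

`rvotep` implements an analysis pipeline for ex vivo electrophysiology of
right-ventricular-outflow-tract (RVOT) myocardium: extraction of action
potential (AP) shape properties from paced intracellular recordings with
quality control, detection of pro-arrhythmic tissue abnormalities,
percent-fibrosis quantification from picrosirius-red-stained section
images, and linear mixed-effects association modelling with a per-patient
random intercept. Because raw patient recordings of this kind are not
publicly distributable, the package ships first-class synthetic-data
generators with analytically known ground truth; every stage of the
pipeline is validated against that truth.

## AP shape properties and measurement conventions

Seven properties are computed per accepted AP:

* **RMP** — resting membrane potential (mV), the diastolic baseline.
* **APA** — amplitude (mV), peak potential minus RMP.
* **dV/dt~max~** — maximum upstroke velocity (V/s).
* **APD~20~, APD~50~, APD~90~** — duration (ms) from activation to 20%,
  50% and 90% repolarisation, i.e. the first downward crossing of
  `RMP + (1 - level) * APA`.
* **AUC~90~** — area between membrane potential and RMP from activation to
  the APD~90~ crossing (mV·s).

Several fiducials are under-determined by convention alone, so the package
fixes them explicitly and exposes each as configuration:

* **Activation time** is the time of dV/dt~max~ — the standard cardiac-EP
  fiducial, robust when the upstroke onset is obscured by the stimulation
  artifact. On an exactly linear upstroke every sample has the same slope;
  ties break to the earliest sample so that activation coincides with
  upstroke onset.
* **RMP** is the median (robust to residual artifact samples) of the last
  20 ms of baseline before the stimulus for paced APs, or before the
  upstroke for spontaneous APs. If that segment overlaps another AP or a
  stimulus blanking interval, the AP is rejected as having no baseline.
* **Threshold crossings** are linearly interpolated between samples, so APD
  precision is sub-sample.
* **Stimulus blanking** is 5 ms after each stimulus; an AP whose
  dV/dt~max~ falls inside the blanking window is rejected for insufficient
  separation from the stimulation artifact.
* An AP is tagged **stimulated** when its upstroke lies within 50 ms of a
  stimulus; later upstrokes are spontaneous.

Quality control rejects, in order: missing baseline; upstroke inside the
blanking window; artifact (|dV/dt| above 1000 V/s outside the upstroke and
blanking, or voltage excursions above +60 mV); incomplete repolarisation
before the window ends; and amplitude strictly below 75 mV — an AP at
exactly 75.0 mV is accepted. Location summaries average accepted APs per
pacing frequency and warn below 20 accepted APs, the minimum of the
recording protocol the package targets (at least 20 APs from at least
three locations at 0.5, 1, 2, 3 and 4 Hz).

## Abnormality detectors

The three tissue-arrhythmia event types, APD alternans and impaired rate
adaptation were identified visually in the laboratory workflow this
package systematises; no numeric criteria exist to match, so all
thresholds are explicit defaults calibrated on the synthetic generator:

* **Early afterdepolarisations.** A depolarising deflection during
  repolarisation (between the APD~20~ time and the 90% level). During a
  steep repolarisation even a large transient produces only a shallow
  local maximum, so the deflection amplitude is measured against the
  repolarisation trajectory extrapolated linearly from the 10 ms before
  the deflection onset; the default minimum amplitude is 5 mV with a
  positive-slope floor of 0.1 V/s. Traces are smoothed with a centred
  2 ms moving average before peak finding, which suppresses sampling
  noise (1 mV white noise is attenuated roughly four-fold at 10 kHz)
  without distorting a 30 ms deflection.
* **Extrasystoles and couplets.** Spontaneous full APs between paced
  beats. Consecutive spontaneous APs closer than 500 ms form one couplet
  event; isolated ones are extrasystoles. Each spontaneous AP contributes
  to exactly one event type.
* **APD alternans.** True when successive APD differences alternate in
  sign over at least 6 consecutive beats and the mean beat-to-beat change
  is at least max(5 ms, 5% of the mean APD). Shorter sequences are
  reported as indeterminate rather than negative.
* **Impaired APD shortening.** Flagged when the tissue fails to follow
  1:1 at 2, 3 or 4 Hz (capture ratio below one) or when APD~90~ exceeds
  the available cycle length; requires summaries at two or more
  frequencies including a fast one. Locations with this flag are excluded
  from AP-shape statistics, and a patient is positive for any abnormality
  when any location is.

## Synthetic recordings

The AP waveform is a parametric piecewise curve — baseline, linear
upstroke, plateau, then a linear or half-cosine ("sigmoidal")
repolarisation — not a biophysical ionic model. The pipeline measures
shape, not currents, and a parametric curve has closed-form values for
all seven properties, which is what makes generator-vs-extractor closure
testable. The half-cosine decline reaches the level-`x` crossing at
`acos(1 - 2x)/pi` of its duration, so APD~20/50/90~ and AUC~90~ are exact.

Default generation conditions: 10 kHz sampling (resolving dV/dt~max~ on a
1 ms upstroke), 10 ms stimulus-to-upstroke latency, a biphasic ±2 ms
stimulation artifact at every stimulus, and APD~90~ rate adaptation of
−41.46 ms per Hz relative to 1 Hz — the frequency slope of the reference
coefficient grid (below). At capture-failure frequencies the APD is
frequency-invariant and capture is 2:1, reproducing the
impaired-rate-adaptation phenomenology. Injected abnormalities: EADs as a
+15 mV, 30 ms raised-cosine hump placed between the APD~20~ and APD~90~
times; extrasystoles as a full AP at a uniformly random diastolic phase
at least 100 ms after the previous APD~90~; couplets as two spontaneous
APs 250 ms apart; alternans as a ±half-depth alternation of the per-beat
APD~90~. A request whose AP cannot fit the pacing cycle (after latency
and the post-APD~90~ tail, leaving 20 ms of clean baseline) is rejected
as physically inconsistent unless capture failure is configured.

What the generator does *not* emulate: impalement loss and drift,
electrode polarisation, line interference, gradual run-down, or
conduction between recording sites. Passing closure tests therefore
demonstrates correctness of the measurement conventions, not robustness
to every failure mode of real microelectrode data.

## Synthetic cohort tables

`generate_cohort()` draws feature tables from an explicit mixed-effects
generating model: response = intercept + Σ coefficient × covariate +
patient random intercept + residual. The default coefficient grid is the
reference set of fixed-effect estimates for the seven AP properties in a
25-patient surgical RVOT cohort (mixed tetralogy-of-Fallot and
atrial-septal-defect patients), with treatment coding against the
reference levels ASD, unrepaired, acyanotic, mild RV–PA gradient, no beta
blocker, none/mild proBNP elevation, no clinical arrhythmia. Categorical
prevalences default to that cohort's composition (e.g. 22/25 TOF, 9/25
cyanotic, 6/25 with impaired APD shortening). Age enters in years — at
per-month scale the reference estimates would imply implausibly large
lifetime effects — and is sampled bimodally conditional on repair status
(unrepaired patients mostly infants, repaired patients mostly adults).

The noise scales are not derivable from published summaries and were
fixed once at values realistic for human ventricular recordings: e.g. for
APD~90~ a 25 ms between-patient SD and 15 ms residual SD, with
proportionate values for the other properties. Covariates are sampled
independently across patients; real cohorts correlate disease severity
markers, so fitted standard errors here are if anything conservative
relative to a collinear real design.

With both noise scales at zero the generated responses equal the linear
predictor exactly, and with zero between-patient variance the mixed fit
reproduces ordinary least squares — both are tested invariants.

## Synthetic histology and fibrosis quantification

`generate_histology_image()` renders red collagen speckle on yellow
myocardium with a white background strip, white circular tissue gaps and
a dark-red endocardial band along one image edge, separated from the
interstitium by a two-pixel myocardial buffer so it remains its own
connected component. Exactly `round(fraction × analysable pixels)` pixels
are labelled collagen, so the ground-truth fraction is exact, and a
per-pixel colour jitter keeps classification non-trivial.

Quantification classifies pixels in HSV space (saturation < 0.25 or
value ≥ 0.95 → background/gap; hue in [330°, 25°] → collagen; hue in
(25°, 90°] → myocardium), then excludes background, gaps, and connected
collagen components that touch the image border with local thickness of
at least 8 px (they survive erosion with an 8-px disc) — a morphological
stand-in for endocardium exclusion. Percent-fibrosis is
100 × collagen / (collagen + myocardium) within the remaining analysed
area; patient values are unweighted means over sections, with a warning
below 30 usable sections. The three pixel classes partition every image,
estimates recover truth within one percentage point across fractions
0–60%, and resolution doubling moves the estimate by less than half a
point — all tested. The thresholds were calibrated once against the
generator's palette; real batch-stained slides vary in intensity, which
is why every threshold is exposed.

## Association models

One linear mixed-effects model per dependent (the seven AP properties,
plus percent-fibrosis with AP covariates taken at 1 Hz), each with the
clinical and tissue covariates as fixed effects and a per-patient random
intercept, fitted by REML. Design choices where the convention was open:

* **p-values** default to Wald-type t-tests with Satterthwaite
  denominator degrees of freedom (`lmerTest`). With ~25 patients and
  patient-level covariates, normal-approximation Wald tests are
  anti-conservative; Satterthwaite keeps the per-covariate type-I error
  at 0.05 ± 0.02 under all-null generation (a tested invariant).
  Plain Wald-normal p-values are available via `p_method = "wald"`.
* **Adjusted R²** is reported as the OLS adjusted R² of the
  fixed-effects-only fit — a deliberate convention, since adjusted R² has
  no unique mixed-model definition.
* **Pacing frequency** enters as a continuous linear covariate; the RV–PA
  gradient as two dummies (moderate, severe) against mild; no
  multiple-testing correction is applied, and significance is strict
  p < 0.05.
* The observation unit is the per-location per-frequency value (one data
  point per recording location).

Binary outcomes (tissue or clinical arrhythmias) use binomial logistic
regression; under perfect separation the fit is flagged and refitted with
Firth's bias-reduced penalised likelihood, reported as such. The
drug-induced-versus-spontaneous comparison is a two-sided two-sample
t-test per property (Welch by default).

## Numerical choices and degenerate inputs

* Moving-average smoothing windows are forced to odd sample counts so the
  filter stays centred at any sampling rate; segment endpoints the filter
  cannot cover keep their raw values, so constant baselines are preserved
  exactly.
* Upstroke detection requires both a smoothed-derivative threshold
  (10 V/s) and a sustained elevation (≥ 30 mV held 2–8 ms after the
  upstroke), which separates true APs from the biphasic stimulation
  artifact without relying on blanking.
* Flat traces yield an empty segmentation (not an error); an empty trace
  is an error; zero accepted APs yield an empty summary with a warning;
  an all-excluded section is flagged unusable; a patient with no usable
  sections is excluded with a warning.
* All generators take a single integer seed and are bit-reproducible;
  the pipeline manifest records config, seed and MD5 checksums of every
  output.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to exercise the
methods while keeping a full run to a few minutes: extraction closure
over APD~90~ ∈ {150, 250, 350} ms × APA ∈ {80, 130} mV at all five pacing
frequencies (physically impossible combinations must be refused);
detector truth tables over eight seeds per noise level (0 and 1 mV);
parameter recovery over 200 replicate 25 × 3 × 5 cohorts; type-I error
over 1000 all-null replicates with a six-covariate design (the rare
moderate-gradient dummy, expected in only two patients of 25, is left
out of the null design because its frequent degeneracy under resampling
tests the design, not the test); and fibrosis recovery across truth
fractions {0, 5, 15.9, 30, 60}% plus one full-size 2000 × 2000 px
section.

## Known limitations

* The waveform model cannot express notch-and-dome morphologies,
  triangulated APs without a plateau, or rate-dependent shape changes
  beyond the linear APD slope.
* Event detectors are tuned to the generator's event morphology; real
  EADs vary widely in take-off potential and width, and the 5 mV
  amplitude floor is a choice, not a validated clinical criterion.
* The colour segmentation assumes picrosirius-red-like palettes; other
  stains or strong batch effects require re-calibrated thresholds.
* The association module reproduces a fixed model family; it performs no
  model selection, causal analysis or risk prediction.
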
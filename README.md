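# rvotep

Analysis pipeline for ex vivo electrophysiology and histology of right
ventricular outflow tract (RVOT) myocardium — the tissue resected during
surgical repair of congenital heart defects such as tetralogy of Fallot.
Arrhythmias in these patients can originate from myocardium untouched by
surgery, and characterising that tissue requires three linked analyses
that this package implements end to end:

1. **Action-potential feature extraction.** Paced intracellular
   recordings (0.5–4 Hz) are segmented into individual action potentials,
   quality-controlled (artifact screen, amplitude strictly below 75 mV
   rejected, upstroke must be separated from the stimulation artifact),
   and reduced to seven shape properties: resting membrane potential
   (RMP), amplitude (APA), maximum upstroke velocity (dV/dt_max), APD20,
   APD50, APD90 (duration to the first interpolated crossing of
   `RMP + (1 - level) * APA` from the time of dV/dt_max), and AUC90 (area
   above baseline to the APD90 crossing).
2. **Pro-arrhythmic abnormality detection.** Early afterdepolarisations
   (depolarising deflections during repolarisation, measured against the
   extrapolated repolarisation trend), extrasystoles, spontaneous
   couplets, beat-to-beat APD alternans, and impaired APD shortening with
   2:1 capture failure at fast pacing.
3. **Percent-fibrosis quantification.** HSV-rule segmentation of
   picrosirius-red section images (red collagen, yellow myocardium),
   morphological exclusion of background, tissue gaps and the thickened
   endocardial collagen band, then
   `100 * collagen / (collagen + myocardium)` per section, averaged per
   patient.

The statistical core ties these together with linear mixed-effects
models, one per property *y*:

    y_ijk = beta0 + X_ik' beta + b_i + e_ijk,   b_i ~ N(0, sigma_b^2)

with patient *i*, location *j*, pacing frequency *k*, clinical/tissue
covariates *X* and a per-patient random intercept, fitted by REML with
Satterthwaite-df Wald t-tests; plus binomial logistic regressions (Firth
fallback under separation) and two-sample t-tests.

Because raw patient recordings of this kind are not publicly available,
the package includes first-class synthetic generators with analytically
known ground truth — parametric AP trains with injected abnormalities,
stained-section images with exact collagen fractions, and cohort feature
tables drawn from an explicit mixed-effects generating model — so every
stage is testable without any download.

## Worked example

```r
library(rvotep)

# simulate a paced recording, extract features, summarise the location
sim <- generate_recording(ap_params(apa_mV = 110, apd90_ms = 280),
                          pacing_freq = 1, n_beats = 20, seed = 1)
feats <- extract_features(sim$recording)
summarise_location(feats)
#>   pacing_freq rmp apa dvdt_max  apd20  apd50 apd90 auc90 n_accepted
#> 1           1 -80 110      110 191.97 228.03   280 24.89         20
```

All 20 paced APs pass QC; the extracted APD90 (280 ms), APA (110 mV) and
dV/dt_max (110 V/s) equal the generator's ground truth to within one
sample period / 0.5 mV.

```r
# quantify a synthetic stained section with 15.9% true collagen
sec <- generate_histology_image(histology_truth(0.159), 400, 400, seed = 42)
quantify_section(sec$image)
#>   section_id collagen_px myocardium_px excluded_px percent_fibrosis usable
#> 1        S01       22888        121061       16051         15.90008   TRUE
```

The estimate recovers the generating fraction to within a hundredth of a
percentage point; the endocardial band and gaps land in `excluded_px`.

```r
# fit the APD90 mixed model on a simulated 25-patient cohort
tab <- generate_cohort(seed = 1)
fit_ap_mixed_model(tab, model_spec("apd90"))
#> <assoc_result> apd90: 375 obs, 25 patients, adj R2 = 0.95
#>            term estimate     se  df statistic   p_value
#>     (Intercept)  156.200 34.600  12      4.51  7.08e-04
#>  stim_frequency  -41.140  0.596 349    -69.10 1.22e-205
#>        cyanosis   40.150 10.200  12      3.94  1.95e-03
#>  ...
```

The fitted frequency slope (−41.1 ms/Hz) and cyanosis effect (+40.2 ms)
recover the generating coefficients (−41.46, +41.21) within two standard
errors on a single cohort.

`run_pipeline(list(seed = 1, output_dir = "run"))` executes the whole
chain (simulate → extract → detect → quantify → fit) and writes CSV/JSON
outputs plus a manifest with MD5 checksums; a thin CLI wrapper with
subcommands lives at `inst/cli/rvotep-cli.R`.

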
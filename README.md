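# renalmri

Multiparametric renal MRI quantification and CKD-progression analysis in R.

Chronic kidney disease (CKD) is heterogeneous: some patients lose filtration
rapidly while others stay stable for years. Multiparametric renal MRI —
longitudinal relaxation time (T1), apparent diffusion coefficient (ADC),
BOLD-sensitive T2\*, arterial-spin-labelling (ASL) perfusion, and total kidney
volume (TKV) — offers a non-invasive window on the fibrosis, microstructure,
oxygenation and perfusion changes that drive that divergence. `renalmri`
implements the full quantification and analysis pipeline for such a study:
voxel-wise map fitting from the raw acquisition series, histogram-based
cortex/medulla segmentation, per-tissue summaries, eGFR-slope progression
classification, and the prediction/monitoring statistics — plus a digital
kidney phantom and synthetic cohort generator with known ground truth, so
every stage is testable end to end without patient data.

It is written tidyverse-style: tabular inputs and outputs are tibbles, fitted
objects have `tidy()`/`glance()` methods, and every result type has an
`autoplot()`.

## Models

**T1 mapping** — voxel-wise fit of the magnitude inversion-recovery signal at
inversion times TI (default 200–1300 ms in 100 ms steps plus 1500 ms):

    S(TI) = | M0 (1 − 2 ε e^(−TI/T1)) |

with polarity restoration (candidate sign flips before the null crossing,
best SSE wins) and ε = 1 fixed by default. The null point obeys
TI\* = T1 ln 2.

**ADC** — the three orthogonal diffusion directions are combined by voxelwise
geometric mean (the arithmetic mean in the log domain) and log(S) is
regressed on all 11 b-values (0–500 s/mm²): slope = −ADC.

**T2\*** — ordinary least squares of log(S) on the 12 echo times (TE 5 ms,
ΔTE 3 ms): slope = −1/T2\*.

**ASL perfusion** — FAIR selective/non-selective pairs are subtracted and
averaged per post-label delay (300/500/700/900 ms × 4 pairs, 1800 ms × 25
pairs) to form ΔM maps; the Buxton pulsed-ASL general kinetic model

    ΔM(t) = (2 α M0 / λ) (f / 6·10⁶) e^(−t/T1') · [e^(−k·Δt) − e^(−k·min(t, Δt+τ))] / k,  t > Δt

(k = 1/T1b − 1/T1', zero before arrival at Δt, bolus duration τ) is fitted
across delays for transit time Δt and perfusion f (mL/100 g/min), and
inverted exactly at the long delay for the perfusion map.

**Segmentation & summaries** — a two-component Gaussian mixture on the
in-kidney T1 histogram gives the cortex/medulla threshold (cortex is the
lower-T1 component at 3T); each map is summarised per tissue by the mode and
FWHM (= 2√(2 ln 2) σ) of a Gaussian fitted to its histogram; TKV is
mask volume in mL, optionally BSA-corrected (DuBois).

**Clinical & statistics** — eGFR from the CKD-EPI 2009 creatinine equation;
per-subject least-squares eGFR slope over all available visits; slope ≤ −5
mL/min/1.73 m²/yr labels a progressor. Baseline measures are compared
between groups with a Shapiro-Wilk-gated Welch t / Mann-Whitney test,
evaluated as predictors by rank-based ROC AUC with stratified bootstrap CIs,
and correlated (Pearson/Spearman, normality-gated) with eGFR and log(PCR).
Longitudinal monitoring computes percentage change from baseline per subject
and calls a cell "decline"/"improve" only when the change is significant
*and* exceeds the measure's published between-session CV, with the polarity
map {TKV↓, ADC↓, T2\*↓, T1↑} = decline.

## Worked example

```r
library(renalmri)

# digital phantom -> simulate -> fit -> segment -> summarise
ph  <- make_phantom(phantom_spec(grid = c(32, 32, 10), noise_sd = 0.01, seed = 42))
ser <- simulate_ir_series(ph, seed = 1)
fit <- fit_t1_ir(ser, ph$masks$kidney)
thr <- t1_threshold(fit$t1_ms, ph$masks$kidney)
seg <- apply_threshold(fit$t1_ms, ph$masks$kidney, thr, ph$spec$voxel_mm)
seg
#> <tissue_masks: kidney 1644, cortex 1284, medulla 360 voxels, T1 threshold 1706.1 ms>
summarize_tissues(list(t1 = fit$t1_ms), seg)
#> # A tibble: 2 × 8
#>   tissue  measure  mode  fwhm sigma n_voxels    r2 status
#> 1 cortex  t1      1499.  117.  49.6     1284 0.980      0
#> 2 medulla t1      1902.  126.  53.4      360 0.936      0
```

The phantom's cortex and medulla were generated at T1 = 1500 / 1900 ms with
50 ms intra-tissue SD: the fitted modes (1499, 1902 ms) and FWHMs
(≈ 2.355 × 50 ≈ 118 ms) recover that truth, and the threshold (1706 ms)
splits the tissues with Dice 1.0 here.

```r
# synthetic cohort -> eGFR slopes -> labels -> full statistics layer
cohort   <- simulate_cohort(cohort_spec(seed = 2024))
analysis <- analyze_cohort(cohort, n_boot = 2000, seed = 7)
analysis
#> <ckd_analysis>
#>   22 subjects, 10 progressors (realized)
#>   baseline differences: perfusion_cortex, t1_cortex, t1_medulla
#>   change-report cells: 9 decline, 0 improve, 23 no-change
```

At baseline only cortex perfusion (p = 6.3e-06), cortex T1 (p = 1.7e-04) and
medulla T1 (p = 1.8e-03) differ between realized progressors and stable
subjects — the generator's built-in pattern — while TKV, ADC and T2\* do not.
Baseline cortex perfusion predicts progression with AUC 0.97 (95% CI
0.88–1.00; lower perfusion predicts progression). `autoplot(analysis$change_report)`
draws the red/blue/grey monitoring heat map.

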
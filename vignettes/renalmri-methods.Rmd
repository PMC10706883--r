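---
title: "Quantitative renal MRI and CKD progression: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative renal MRI and CKD progression: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renalmri)
```

`renalmri` quantifies multiparametric renal MRI — T1, ADC, T2\*, ASL
perfusion and total kidney volume — and carries the per-tissue summaries into
a CKD-progression analysis: eGFR-slope classification, baseline prediction
statistics, and reference-CV longitudinal monitoring. This vignette is the
package's own account of the models it fits, the parameters that matter, the
synthetic data it validates against, and the choices made where the design
was genuinely open.

## The quantification models

### Inversion-recovery T1

Magnitude inversion-recovery data lose the sign of the longitudinal
magnetization, so the voxel model is

$$S(TI) = \left| M_0\,(1 - 2\,\varepsilon\, e^{-TI/T_1}) \right|,$$

with inversion efficiency $\varepsilon \in (0, 1]$ fixed at 1 by default
(`fit_epsilon = TRUE` frees it; with 13 inversion times the three-parameter
fit is identifiable but noisier). Polarity restoration handles the modulus:
for each candidate crossing position $j$, the first $j$ points are
sign-flipped and the signed model is fitted; the candidate with the lowest
SSE wins. Candidates run from no flip up to one past the minimum-signal
index, which covers crossings beyond the last TI (long T1). For fixed $T_1$
the signed model is linear in $M_0$, so $M_0$ is profiled out in closed form
subject to $M_0 > 0$ — without that constraint the unflipped candidate can
mirror the all-flipped solution with $M_0 < 0$ and the sign of the answer
becomes arbitrary. The $T_1$ search uses a 120-point logarithmic grid on
[50, 5000] ms (generous for kidney at 3T) refined by Brent optimisation to
`tol = 1e-4` ms. Flat series (no inversion contrast, e.g. $\varepsilon \to
0$) and all-zero voxels are flagged with distinct status codes rather than
returning a confident $T_1$.

### ADC and T2\*

Both use the log-linear form the decays dictate: OLS of $\log S$ on $b$
(slope $-ADC$) or on $TE$ (slope $-1/T_2^*$), unweighted. The three
diffusion directions are combined by voxelwise *geometric* mean before
fitting — the geometric mean is the arithmetic mean in the log domain, so
combining before or after the log transform is exactly equivalent, and the
fitted ADC of anisotropic data is exactly the mean of the per-direction
ADCs. The ADC model is mono-exponential over all 11 b-values (0–500 s/mm²)
including the low-b range; perfusion (IVIM) contamination therefore biases
ADC upward, which is a property of the protocol, not a bug — the phantom can
inject per-direction or low-b structure to study it. Non-positive signals
are dropped pointwise (at least 3 points, for ADC including one b < 50
s/mm², must remain), rising "decays" are flagged as non-physical rather than
reported negative, and a constant series legitimately fits ADC = 0.

### ASL perfusion

FAIR labelling is pulsed, so the difference signal follows the Buxton
general kinetic model for pulsed ASL. With arrival (transit) time
$\Delta t$, bolus duration $\tau$, blood T1 $T_{1b}$ and apparent tissue
decay $T_1'$, and $k = 1/T_{1b} - 1/T_1'$:

$$\Delta M(t) = \frac{2\,\alpha\,M_0}{\lambda}\,\frac{f}{6\times 10^6}\,
  e^{-t/T_1'}\,\frac{e^{-k\,\Delta t} - e^{-k\,\min(t,\,\Delta t + \tau)}}{k},
  \qquad t > \Delta t,$$

and 0 before arrival. $f$ is in mL/100 g/min; the $6\times10^6$ factor
converts to mL/g/ms. The model is continuous at both breakpoints by
construction. Two deliberate choices:

* **$T_1' = $ tissue $T_1$** (outflow term $f/\lambda$ neglected). This
  makes $\Delta M$ *exactly linear* in $f$, so the long-PLD quantification
  is an exact division by the unit-perfusion kernel and scaling $M_0$ and
  $\Delta M$ together cancels identically. At renal perfusion levels the
  neglected term shifts the apparent decay by a few percent; it is absorbed
  into the calibration in practice.
* **Constants** $T_{1b} = 1650$ ms, $\alpha = 0.95$, $\lambda = 0.9$ mL/g,
  $\tau = 800$ ms are conventional 3T values, collected in
  `asl_constants()` / the `tau_ms` argument; none is estimated from data by
  default ($\tau$ is slab-limited in FAIR and barely identifiable from five
  delays).

The multi-delay inflow fit exploits the linearity: each candidate
$\Delta t$ has a closed-form best $f \ge 0$, so the fit is a 25 ms grid
search over $\Delta t \in [100, 1500]$ ms refined by continuous 1D
optimisation — no iterative nonlinear solver, no convergence failures.

**Identifiability.** With the clinical five-delay protocol (300/500/700/900
and 1800 ms), a transit time beyond 900 ms leaves only the long delay
informative and $(f, \Delta t)$ lie on an exactly flat SSE ridge: no
estimator can recover them. The recovery tests therefore use a 300–1800 ms
ladder in 150 ms steps when sweeping $\Delta t$ up to 1200 ms, and verify
the clinical protocol for the transit times it brackets ($\le 900$ ms).
Renal cortical transit times sit well inside that range; medullary ones may
not, which is a protocol limitation worth knowing.

S/NS volumes are assumed pre-aligned; a registration hook exists in the
pipeline configuration but is intentionally not implemented (the phantom
guarantees alignment).

### Segmentation and tissue summaries

Cortex and medulla are separated on the in-kidney T1 histogram: a
two-component Gaussian mixture (EM via `mclust`, whose model-based
hierarchical initialisation makes the fit deterministic) and a threshold at
the point between the means where the weighted component densities
intersect — more robust to bin-width choices than a raw histogram valley.
Cortex is the lower-T1 component, the physiological ordering at 3T. Two
guards refuse to segment rather than segment wrongly: components whose means
are closer than the pooled SD, and fitted mixtures whose density has no
valley between the modes (the signature of a unimodal histogram split in
two; a pure Gaussian split yields components ~2.7 pooled-SDs apart, which
the separation test alone would pass).

Each map is summarised per tissue by a Gaussian curve least-squares fitted
to its histogram (Freedman–Diaconis bin width, floor of 10 bins): the mode
is the fitted mean, the FWHM is $2\sqrt{2\ln 2}\,\hat\sigma \approx
2.3548\,\hat\sigma$. Histograms of fewer than 30 voxels or with degenerate
spread are flagged. Both kidneys' voxels pool into one histogram, matching
the bilateral-mean convention; `per_kidney = TRUE` also emits per-side rows.
TKV is voxel count × voxel volume in mL; BSA correction uses DuBois
($0.007184\,W^{0.425}H^{0.725}$, W kg, H cm) — the only BSA formula offered.

## The clinical layer

eGFR uses the CKD-EPI 2009 creatinine equation; creatinine is accepted in
µmol/L (divided by 88.4) or mg/dL. The eGFR slope is per-subject OLS on
time-in-years over *all* available visits (plain OLS, not a mixed model —
the simplest reading of a per-subject least-squares slope); two points give
a slope flagged low-confidence, fewer are an error. A decline of at least
5 mL/min/1.73 m²/yr — slope $\le -5$, boundary inclusive — labels a
progressor. log(PCR) is base 10; the base only rescales the variable and
leaves every rank statistic unchanged.

## The statistics layer

* Group comparisons are Shapiro–Wilk-gated at $\alpha$: both groups normal
  → Welch (unequal-variance) t-test, otherwise Mann–Whitney U with
  mid-ranks and no continuity correction (identical groups give exactly
  p = 1). $\alpha = 0.05$, two-sided, throughout.
* ROC AUC uses the rank (Mann–Whitney) formulation — the fraction of
  correctly ordered case/control pairs with ties counting ½ — with a
  stratified bootstrap percentile CI (default 2000 resamples, seeded) and a
  tie-corrected normal-approximation p against AUC = 0.5. Orientation is
  recorded: with `direction = "auto"` the score is flipped so AUC ≥ 0.5
  (lower perfusion predicting progression reports as AUC > 0.5 with
  direction "<").
* Correlation matrices gate Pearson vs Spearman per column pair on
  Shapiro–Wilk (forceable), use pairwise-complete rows, and the
  slope-correlation table forces Spearman.
* **No multiple-testing correction is applied** — a deliberate, documented
  limitation of the analysis style this package reproduces
  (`p.adjust`-style correction is a one-liner on the tidy outputs). The
  consequence is quantified below.

### Longitudinal monitoring

For subjects with all three annual visits, the percentage change of each
measure from baseline is computed per follow-up year. A group × measure ×
year cell is called a change only when the one-sample t-test against zero is
significant at $\alpha$ **and** the mean change magnitude exceeds the
measure's reference between-session CV — the two-criterion reading of
"significantly different from the baseline CV", both criteria exposed in the
output so either can be relaxed. The change direction then maps onto
decline/improve through the polarity table {TKV ↓, ADC ↓, T2\* ↓, T1 ↑} =
decline, to which perfusion ↓ = decline is added (loss of cortical
microvasculature accompanies progression; the classical four-measure list
omits perfusion, so its polarity is kept in the same user-replaceable
table). Reference CVs default to published-magnitude short-term
between-session values: TKV 2.5%, T1 3%, ADC 4%, T2\* 6%, perfusion 12%.
Categories are invariant to measure rescaling since everything is in
percent.

## The synthetic data

The digital phantom is two ellipsoids with a concentric cortical shell on a
3 mm × 3 mm × 5 mm grid — anatomic realism is not the goal; what matters is
that cortex and medulla have the separability and histogram structure the
segmentation relies on. Tissue truth (cortex/medulla): T1 1500/1900 ms, M0
100, ADC 2.2/2.0 × 10⁻³ mm²/s, T2\* 55/40 ms, perfusion 250/100
mL/100 g/min, transit 500/700 ms, τ 800 ms; intra-tissue SDs 50 ms, 5, 10⁻⁴
mm²/s, 3 ms, 20 mL/100 g/min. Noise is Gaussian on the magnitude signal
(default SD 2% of mean in-kidney M0 ≈ SNR 50); a Rician option exists
because magnitude MRI noise is Rician, but at these SNRs the Gaussian
approximation is excellent and keeps every closed-loop oracle exact. Not
modelled: partial volume, B0/B1 inhomogeneity, respiratory motion,
slice-timing — so passing tests demonstrate estimator correctness, not
robustness to those effects.

The synthetic cohort draws per-group eGFR intercepts N(38, 8²)/N(42, 10²)
and slopes N(−8, 1.2²)/N(−1.5, 1.2²) (progressor/stable), back-computes
creatinine through the inverted CKD-EPI equation, multiplies 4% measurement
CV, and samples quarterly over two years; PCR is log-normal (medians ~120
vs ~35 mg/mmol). Both the intended (generative) and realized (rule-based)
labels are stored and **analyses always use the realized label**, exactly as
an analyst with only the clinical record would. MRI tissue summaries are
drawn per subject with baseline group effects (progressors: cortex/medulla
T1 +150 ms, cortex perfusion −100 mL/100 g/min; TKV/ADC/T2\* equal),
compound annual drifts (progressors: TKV −5%/yr, ADC −5%/yr, cortex T1
+4%/yr, perfusion −8%/yr; stable: TKV −3%/yr only) and per-visit
between-session noise equal to the reference CVs. The baseline effect sizes
were set by a power calculation against the *total* dispersion
(between-subject SD plus session noise) so that each target measure is
detected with ≈99% power at n = 9 vs 13 — the generator defines conditions
under which the qualitative pattern is reliably detectable, which is the
point of a pattern-level validation. An earlier sizing that neglected the
session-noise term is documented in the package history; for medulla T1 the
session noise scales with its larger mean, leaving that one measure at ≈97%
power and the three-measure joint detection rate at ≈95%.

One consequence worth stating plainly: with five truly-null measures tested
at uncorrected $\alpha = 0.05$, the probability that *no* null measure is
significant in a replicate is at most $0.95^5 \approx 0.77$. A "the three
target measures and nothing else" pattern therefore cannot hold in ≥95% of
replicates under this analysis style at any effect size or sample size; the
corresponding strict-pattern check in the test suite documents this honestly
rather than papering over it.

## Pipeline, formats, reproducibility

`run_pipeline()` composes phantom → simulate → fit → segment → summarise →
cohort → statistics, writing NIfTI maps (RNifti), BIDS-flavoured JSON
sidecars carrying the per-volume acquisition vectors, tidy CSV reports, a
YAML config and a manifest with the config hash, derived seeds and per-file
checksums. Config + master seed fully determine every numeric output; each
stage's seed is derived from the master seed, and every stochastic function
takes an explicit seed that is restored-on-exit so library calls never
perturb the caller's RNG stream. A stage failure raises a stage-tagged
error and preserves completed outputs. There is deliberately no shell
executable: this is an analysis package, and the functions, `run_pipeline()`
and this vignette are its interface.

### Problem sizes used in validation

The suite validates on a 24–40³-scale phantom (~700–3000 kidney voxels),
1000-voxel Monte-Carlo noise sweeps, a 20×20 (f, Δt) recovery grid, and 200
summary-level cohort replicates for the pattern statistics (voxel-level
imaging is exercised end to end once per run, not per replicate — the
pattern statistics are a property of the summary level). These sizes were
chosen so the evidence is dense where the estimators live and the whole
suite stays fast.

## Known limitations

* Mono-exponential ADC inherits low-b perfusion bias; no IVIM or tensor fit.
* The five-delay FAIR protocol cannot identify transit times beyond its
  longest short delay (see above).
* T1-threshold segmentation assumes a bimodal histogram; at coarse
  resolution, partial-volume voxels blur the valley and medullary values are
  the first casualty.
* Plain per-subject OLS slopes ignore within-subject correlation structure;
  a mixed model would borrow strength across subjects.
* Uncorrected multiple testing, by design; see above for the false-positive
  arithmetic.
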
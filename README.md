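# oxymetr

Quantification of cortical oxidative metabolism from multimodal
NIRS–MRI in mouse cohorts.

In neuroinflammatory disease models such as experimental autoimmune
encephalomyelitis (EAE), cortical gray matter can be hypoperfused and
hypoxic while mitochondria are damaged, long before overt
demyelination or neuronal loss. Detecting that state in vivo requires
measuring several coupled quantities at once: cerebral blood flow
(CBF), microvascular hemoglobin oxygenation (StO₂), the content and
redox state of cytochrome c oxidase (CCO, the terminal electron
acceptor of the respiratory chain), and the cerebral metabolic rate of
oxygen (CMRO₂). oxymetr implements the complete analysis chain for a
combined broadband near-infrared spectroscopy (NIRS) + arterial spin
labeling (ASL) MRI experiment, plus a synthetic raw-data generator so
the whole pipeline is testable end to end, for researchers analyzing
such multimodal data or prototyping against realistic simulations.

## The models at the core

**Spectroscopy.** Tissue attenuation follows the modified
Beer–Lambert law, A(λ) = L·(Σᵢ εᵢ(λ)cᵢ + f_w·M_w·ε_w(λ)) + a + bλ.
Assuming scattering and water content are constant, the second
derivative in λ removes the baseline exactly; deoxyhemoglobin is
fitted in second-derivative space (760 nm band), the mean optical
pathlength L comes from the water feature at 800–850 nm and the known
80% brain water fraction, and the oxidized/reduced CCO couple from a
baseline-augmented multilinear regression. A terminal 50-s anoxia
pulse deoxygenates all hemoglobin, so the dHb plateau calibrates total
hemoglobin ([tHb] = [dHb]) and StO₂ = (1 − dHb/tHb)·100.

**Oximetry.** Tissue blood is modeled as a 0.25/0.75 arterial/venous
mixture: SvO₂ = (StO₂ − 0.25·SaO₂)/0.75, OEF = (SaO₂ − SvO₂)/SaO₂,
and the modified Fick principle gives
CMRO₂ = CBF · OEF · (SaO₂/100) · k_O2.

**Perfusion.** A variable-TR saturation-recovery series yields a
voxelwise T1 map via M(TR) = M0·(1 − e^(−TR/T1)); two control and two
tagged CASL images are averaged and differenced (MT correction), and
CBF = 6000·λ·ΔM / (2α·T1·M_ctrl) in ml·100g⁻¹·min⁻¹.

**Statistics.** Shapiro–Wilk screening, Kruskal–Wallis with
Bonferroni-corrected pairwise comparisons, Pearson correlations,
coefficients of variation, normal-approximation sample-size
calculation, and day-by-day disease-trajectory divergence.

## Worked example

Simulate one EAE animal's raw data and run the full quantification:

```r
library(oxymetr)

preset <- builtin_presets()$eae
animal <- sample_animal(preset, seed = 42)
table  <- builtin_extinction_table()

# 25 min of 6 Hz spectra with a terminal anoxia pulse, then invert
frames <- simulate_nirs_timeseries(animal, nirs_protocol(), table,
                                   noise_sd_od = 1e-3, seed = 1)
nirs <- analyze_nirs(frames, table)

# ASL stack -> T1 map -> perfusion-weighted -> CBF -> cortical ROI
stack <- simulate_asl_stack(animal, seed = 1)
asl <- analyze_asl(stack, fit_mask = stack$mask)

cbind(nirs[, c("dHb_uM", "totCCO_uM", "tHb_uM", "StO2_pct")],
      CBF = asl$roi$mean) |> round(2)
#>   dHb_uM totCCO_uM tHb_uM StO2_pct    CBF
#> 1  34.53      4.22 103.66    66.69 253.57
```

The animal's ground truth (from the generator's manifest) is dHb
34.50 µM, totCCO 4.22 µM, tHb 103.63 µM, StO₂ 66.71 %, CBF
253.18 ml·100g⁻¹·min⁻¹ — the pipeline recovers each to a fraction of
a percent at the default noise level. `compute_oximetry()` then adds
SvO₂, OEF and CMRO₂, and for a whole cohort:

```r
dir <- tempfile()
cfg <- run_config(seed = 7, frame_stride = 10)
run_simulate(cfg, dir)           # 42 animals: spectra, NIfTI, scores
res <- run_analyze(cfg, dir)     # per-animal estimates + group stats
res$stats$CBF
#> Kruskal-Wallis comparison of `CBF` across `group`
#>   H = 23.132, df = 2, omnibus p = 9.485e-06
#> Pairwise (wilcoxon, Bonferroni x3):
#>              pair        raw_p bonferroni_p
#>    cfa_ptx vs eae 2.116699e-02 0.0635009747
#>  cfa_ptx vs naive 3.718347e-05 0.0001115504
#>      eae vs naive 2.284984e-04 0.0006854953
#> Group summaries:
#>    group  n     mean       sd    cv_pct
#>  cfa_ptx 14 207.9560 24.27731 11.674254
#>      eae 13 180.9338 46.13438 25.497937
#>    naive 15 257.8337 18.95631  7.352143
```

i.e. in this simulated cohort both injected groups are hypoperfused
relative to naive animals (EAE vs naive corrected p = 7e-4), with the
EAE group showing the largest spread (CV 25%) — the same qualitative
pattern the presets encode. Hypoxia flags and the remaining metrics
are in `res$cohort` and `res$group_summary`.

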
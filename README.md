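# casrcoop

Quantitative analysis of functional cooperativity of the calcium-sensing
receptor (CaSR), a family C GPCR that monitors extracellular calcium
([Ca²⁺]ₒ) and aromatic amino acids. The package is aimed at cell-signaling
labs studying CaSR disease mutations — in particular the "toggle" residues
Leu173 and Pro221 at the hinge of the extracellular Venus-flytrap domain,
where different substitutions either activate (L173F, P221L; ADHH) or
inactivate (L173P, P221Q; FHH) the receptor — and at anyone who needs a
tested, reproducible pipeline for the three analyses this literature relies
on:

1. **Single-cell Ca²⁺-oscillation patterns.** Fura-2 ratio traces recorded
   under stepwise [Ca²⁺]ₒ protocols are summarized by three parameters:
   the *starting point* (lowest [Ca²⁺]ₒ at which a cell shows ≥ 3
   successive peaks after the initial step transient), the *frequency*
   (peaks/min at a designated step) and the *ending point* ([Ca²⁺]ₒ at
   which oscillations cease and the trace reaches a sustained plateau).
2. **Hill-model dose-response fitting.** Monophasic and biphasic fits of
   `r(c) = r₀ + (rmax − r₀)·cⁿ/(EC₅₀ⁿ + cⁿ)` for [Ca²⁺]ᵢ, IP₁ (through the
   competition-assay percent-inhibition transform) and phospho-ERK₁/₂
   readouts, AICc-based monophasic/biphasic model selection, and
   heterotropic-shift reports for the allosteric modulator L-Phe (EC₅₀
   left-shift, Hill-coefficient change). A Hill coefficient n > 1 reports
   positive homotropic cooperativity among the receptor's Ca²⁺ sites.
3. **Ensemble dynamics.** Residue-residue dynamic cross-correlation maps
   `C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)`, inter-site coupling
   scores, and essential-dynamics PCA of superposed coordinate ensembles
   (multi-model PDB or plain XYZ), the machinery used to compare correlated
   motions of wild-type and mutant receptor models.

No raw data are deposited for this class of experiment, so the package
ships a first-class synthetic-data generator whose defaults encode the
published population parameters (EC₅₀s, Hill coefficients, oscillation
thresholds and frequencies for WT and the four toggle mutants, with and
without 5 mM L-Phe). Every analysis stage is validated by
simulate-then-recover tests against that ground truth.

## Worked example

```r
library(casrcoop)

## --- oscillation analysis of a simulated WT cell population -------------
prot  <- default_protocol()                     # 0.5 -> 30 mM, 180 s steps
pop   <- preset_population("WT", n_cells = 60)
cells <- simulate_population(pop, prot, seed = 42)
feats <- do.call(rbind, lapply(cells$traces, extract_features, freq_at = 3.0))
summarize_population(feats)
#> population_summary: 60 cells, 92% oscillatory
#>   modal start: 3 mM (45% of oscillatory cells)
#>   frequency: 1.28 +/- 0.02 peaks/min (n = 32)

## --- Hill fit of the [Ca2+]i population dose-response -------------------
dr  <- simulate_dose_response(casr_preset("WT")$ca_i$none,
                              c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10),
                              noise_cv = 0.05, replicates = 3, seed = 42)
fit <- fit_hill(dr)
fit
#> Hill fit [ca_i]: EC50 = 3 +/- 0.081 mM, n = 3.37 +/- 0.29
#>   r0 = -0.00936, rmax = 1, RSS = 0.0502 on 30 points

## --- heterotropic left shift produced by 5 mM L-Phe ---------------------
dr_phe <- simulate_dose_response(casr_preset("WT")$ca_i$phe,
                                 c(0.5, 1, 1.5, 2, 2.5, 3, 4, 5, 7.5, 10),
                                 noise_cv = 0.05, replicates = 3, seed = 43,
                                 phe_mM = 5)
heterotropic_shift(fit, fit_hill(dr_phe))
#> Heterotropic shift [ca_i]: EC50 3 -> 1.87 mM (delta 1.13, ratio 0.62); n 3.37 -> 5.59

## --- correlated motions of a synthetic ensemble -------------------------
ens <- superpose(simulate_ensemble(covariance_preset("wt_like"), 2000,
                                   seed = 42))
map <- compute_dccm(ens)
site_coupling(map, 1:6, 61:66)       # site 1 vs site 3
#> site_coupling over 36 pairs: mean C = -0.775, mean |C| = 0.775, |C| >= 0.5 in 100%
```

Reading the numbers: the simulated WT population starts oscillating at the
3.0 mM step (modal bin holding about half the oscillatory cells) at about
1.3 peaks/min; the fitted EC₅₀ of 3.0 mM with n ≈ 3.4 reproduces the
steep, cooperative population curve the data were generated from; adding
L-Phe shifts the EC₅₀ left by ≈ 1.1 mM while raising the apparent Hill
coefficient; and the site-1/site-3 coupling score recovers the strong
negative correlation (−0.8) built into the "wild-type-like" covariance
preset.

`run_pipeline(run_config("WT", seed = 1))` chains all of the above —
trace populations ± L-Phe, all three dose-response readouts with model
selection and shift reports, optional ensemble scores — into a single
JSON-serializable report; see the methods vignette
(`vignettes/casr-cooperativity.Rmd`) for the model assumptions and
parameter choices.

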
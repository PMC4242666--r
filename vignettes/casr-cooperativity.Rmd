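---
title: "Quantifying CaSR cooperativity: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CaSR cooperativity: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casrcoop)
```

# The scientific problem

The calcium-sensing receptor (CaSR) is a dimeric family C GPCR whose large
extracellular Venus-flytrap domain carries several cooperating Ca²⁺-binding
sites and an adjacent binding pocket for aromatic L-amino acids. Rising
extracellular calcium ([Ca²⁺]ₒ) activates phospholipase C, produces IP₃,
and releases intracellular calcium ([Ca²⁺]ᵢ), which in single cells takes
the form of repetitive [Ca²⁺]ᵢ spikes. Two kinds of cooperativity shape
this response: *homotropic* cooperativity among the Ca²⁺ sites, visible as
a steep sigmoidal population dose-response (Hill coefficient n ≈ 3–5), and
*heterotropic* cooperativity from L-Phe, visible as a left shift of the
curve (lower EC₅₀) at fixed modulator concentration. Mutations at the
"toggle" residues Leu173 and Pro221 in the hinge region either enhance
(L173F, P221L) or disrupt (L173P, P221Q) these couplings, causing
autosomal dominant hypocalcemia or familial hypocalciuric hypercalcemia
respectively.

`casrcoop` implements the three quantitative analyses used to characterize
these mutants — oscillation-pattern statistics from single-cell traces,
Hill-model dose-response fitting across signaling readouts, and
correlation/PCA analysis of structural ensembles — together with a
synthetic-data generator that encodes the published population parameters
of each construct as simulation ground truth. Because no raw single-cell
or plate-reader data are publicly deposited for these assays, validation
is by *parameter recovery*: data are simulated from known values and the
pipeline must re-estimate them within sampling error.

# Oscillation analysis

## The three parameters

A cell is *oscillatory at a step* of the [Ca²⁺]ₒ protocol if, after
discarding the first peak inside the step's dwell window, at least three
peaks remain (`classify_oscillatory()`). The discarded peak is the
solution-change transient: every step increase in [Ca²⁺]ₒ elicits one
store-release spike regardless of whether the cell subsequently
oscillates, so it must not count toward the oscillation criterion. The
three per-cell parameters are then:

* **starting point** — the lowest step concentration whose window is
  oscillatory (`find_start_point()`); when two adjacent steps both
  qualify, the lower is reported ("starts to show");
* **frequency** — qualifying peaks (after the transient) per minute at a
  *caller-designated* step (`compute_frequency()`). The step is an
  argument, not inferred, because different constructs are conventionally
  read at different concentrations (3.0 mM for WT, 2.5 mM for the
  activating mutants, 15.0 mM for L173P, 5.0 mM for P221Q);
* **ending point** — the lowest step at or above the starting point that
  is no longer oscillatory *and* has plateaued: the mean of the last half
  of the dwell reaches `plateau_fraction` (default 0.8) of the per-cell
  trace maximum with coefficient of variation at most `cv_max` (default
  0.05). If oscillations persist through the final step the ending point
  is undefined.

The plateau criterion references the *per-cell* maximum rather than any
global scale; a ratiometric trace has no absolute units, and per-cell
normalization makes the criterion invariant to amplitude rescaling.

## Peak detection

Peaks are local maxima of a moving-average-smoothed trace (default window
5 s) whose topographic prominence reaches `k = 3` times a robust noise
estimate, kept at a minimum separation of 10 s. The noise estimate is the
scaled median absolute deviation of the first-difference signal divided by
√2; differencing removes the slow baseline structure and the MAD is
insensitive to the spikes themselves, so the threshold adapts to the
recording noise without being inflated by the signal. All four values are
configurable through `peak_config()`. With the generator's default spike
amplitude (0.6 ratio units over a noise SD of 0.02) detection operates at
a signal-to-threshold ratio of ten; the Monte-Carlo false-positive rate on
pure noise is below 1% per trace.

## What the trace generator emulates

`simulate_trace()` is phenomenological. Below the cell's onset threshold
the trace is baseline plus Gaussian noise; between onset and plateau
thresholds it emits a spike train; at and above the plateau threshold it
holds a sustained elevation. Design choices worth knowing:

* **Regular train, not Poisson.** Spike trains are regular with uniform
  phase and ±10% inter-spike-interval jitter. Published frequencies are
  stable per-cell numbers with small errors, which a Poisson train would
  not reproduce; a jittered regular train makes frequency recovery tight.
  The train is confined to begin 15 s after the step change and end 12 s
  before the next one, so spikes never merge with either step's transient;
  within that window the expected event count equals `rate × dwell/60`
  *exactly*, making peaks-per-dwell an unbiased frequency estimator.
* **One transient per step.** Every step change to ca > 0.5 mM emits one
  initial transient whose peak always reaches `baseline +
  spike_amplitude`, whatever the running level. At plateau steps this
  appears as a small bump on top of the plateau — the ratio saturates near
  the spike peak level — which keeps the per-cell maximum at the spike
  peak and makes the plateau criterion satisfiable (the plateau sits at
  ~93% of the maximum under defaults).
* **Sustained plateau.** Above the plateau threshold the generator holds a
  constant elevated level. Real traces may instead decline slowly; the
  analysis only requires the last half of the dwell to be high and quiet,
  so a mild decline would still classify correctly, but the generator does
  not emulate it.
* **Lognormal cell-to-cell heterogeneity.** Onset and plateau thresholds
  are lognormal across cells (strictly positive, right-skewed, matching
  published threshold histograms). The medians and spreads are *calibrated
  to the published modal-bin fractions*: e.g. the WT onset distribution is
  solved (by `uniroot` at preset construction) so that the 3.0 mM protocol
  bin holds 53% of oscillatory cells, with the median pinned at 0.97× the
  modal step. Where a construct's modal fraction is not published a
  default of 55% is used; L173P without L-Phe is encoded instead as an
  explicit lognormal (median 34 mM, sdlog 0.15) so that ~80% of cells are
  still oscillating at the 30 mM protocol ceiling.
* **Protocol assumptions.** The dwell time per step (180 s) and sampling
  rate (1 Hz) are package assumptions — imaging protocols in this
  literature do not report them uniformly — and are configurable through
  `step_protocol()`. The canonical protocol spans 0.5–30 mM in 16 steps.

Population frequency summaries average over cells classified oscillatory
at the designated step; cells silent at that step contribute to
`fraction_oscillatory` but not to the frequency mean, matching how
frequencies of oscillating cells are tabulated experimentally.

# Dose-response analysis

## Models and fitting

The monophasic model is the four-parameter Hill equation; the biphasic
model is `r₀ + A·[f·h₁(c) + (1−f)·h₂(c)]` with two unit Hill terms and an
amplitude split `f`. Both are fitted by bounded Levenberg-Marquardt
(`minpack.lm::nls.lm`) on replicate points (unweighted — no weighting
scheme is standard for these assays), with standard errors from the
Gauss-Newton covariance at the optimum. Choices:

* **Initialization and bounds.** EC₅₀ starts at the log-interpolated
  half-rise concentration; n starts at 2 with bounds [0.3, 10] (curves in
  this problem run n ≈ 2.5–6); EC₅₀ is bounded above by 10× the largest
  concentration. A perturbed fallback start guards against rare
  pathological start points. The biphasic fit multi-starts over amplitude
  splits {0.3, 0.5, 0.7} × slopes {2, 4} and keeps the lowest RSS.
* **Identifiability of the biphasic fit.** Phase order is enforced by
  parametrizing `ec50₂ = ec50₁·ρ` with ρ ≥ 1.05, and `f` is bounded to
  [0.05, 0.95]. A fit is flagged *degenerate* when ρ < 1.5 or `f` sits on
  its boundary — the phases are then not separable and the monophasic
  description is preferred regardless of likelihood.
* **Model selection.** `select_model()` declares a curve biphasic only if
  AICc(biphasic) < AICc(monophasic) − 2 and the biphasic fit is not
  degenerate. The margin of 2 is an assumption (no selection criterion is
  standard in this literature); simulation shows ≥95% correct selection in
  both directions at 5% noise with 13 concentrations × 3 replicates.
* **Normalization.** Population curves are conventionally normalized to
  the maximal mean response (`normalize_to_max()`); EC₅₀ and n are
  invariant under this rescaling, and `fit_config(fix_rmax = 1)` supports
  fitting normalized data with a fixed plateau. The recovery analyses in
  this package fit raw simulated responses with free r₀/rmax, which is
  the more conservative configuration when the top concentration does not
  fully saturate the curve.

## The IP₁ readout

IP₁ accumulation is measured by competition: accumulated IP₁ displaces
HRP-conjugated IP₁ from an antibody, so receptor activation *lowers*
bound tracer. The analysis-side transform is
`percent inhibition = (1 − stimulated/unstimulated) × 100`
(`ip1_percent_inhibition()`), and the generator emits raw binding values
`B(c) = B₀(1 − H(c)/100)` so that transform ∘ generator is exactly the
identity on the underlying Hill curve `H`. Published EC₅₀s exist for this
readout but not Hill coefficients; the presets use n = 3.0 for IP₁ and
phospho-ERK (the same order of cooperativity as the calcium readout) and
n = 2.5 for L-Phe concentration-response curves, chosen once and kept.
The IP₁ percent-inhibition plateau is set to 75%, a typical dynamic range
for the assay. The biphasic L173P amplitude split is unpublished; the
generator uses f = 0.5 and the fit leaves f free.

Dose-response noise is multiplicative (each replicate scaled by
`1 + ε`, `ε ~ N(0, CV)`), the error structure of plate-reader assays,
with CV 5% in the recovery analyses; trace noise is additive Gaussian,
the error structure of ratiometric imaging.

# Ensemble dynamics

`compute_dccm()` computes the normalized covariance of residue
displacement vectors about their ensemble means — +1 for identical
motion, −1 for exactly opposite motion — after rigid-body motion has been
removed by `superpose()` (SVD-based least-squares superposition onto a
reference frame, over all residues by default, with a configurable mask).
One coordinate per residue is used, documented as the Cα proxy. Residues
with zero positional variance produce undefined correlations; their
rows/columns are set to `NA` (serialized as `NaN`) with a warning.
`trajectory_pca()` ranks the eigenmodes of the coordinate covariance;
eigenvalues are in Å² and sum to the total coordinate variance.
`site_coupling()` condenses a map into the mean (and mean absolute)
correlation over a rectangle of residue pairs plus the fraction of pairs
above a threshold (default 0.5); it is this package's operationalization
of visual map comparison and is labeled as such in reports.

The generator draws frames independently from a multivariate normal whose
residue covariance is block-structured (`covariance_spec()`): isotropic
per-axis variances with block correlations, validated positive
semi-definite at construction (the error names the offending block).
Because strong cross-set correlations require within-set coherence for
the matrix to remain PSD, the shipped presets give each six-residue "site"
an internal coherence of 0.85. The presets place four sites among **120**
residues: superposition removes six rigid-body degrees of freedom, and on
a small system that removal visibly distorts recovered correlations (at
40 residues a −0.8 block recovers as ≈ −0.75); at 120 residues the
distortion is within ±0.04, inside the sampling tolerance used by the
recovery tests. Site definitions are user-supplied index lists — real
residue numberings for CaSR binding sites derive from prior structural
work and are not hard-coded.

What the ensembles do *not* emulate: anharmonicity, multi-state kinetics
and time correlation of real molecular-dynamics trajectories (frames here
are i.i.d.), solvent effects, and sequence-specific geometry. Recovery of
a block correlation therefore validates the estimator arithmetic and the
superposition workflow, not force-field realism.

# Numerical choices and degenerate inputs

* Peak prominence uses an absolute floor of 1e-9 ratio units so that
  noiseless piecewise-constant traces do not yield spurious machine-eps
  peaks.
* Zero-CV threshold populations reuse the median exactly rather than
  drawing `rlnorm(…, sdlog = 0)`, which returns `exp(log(m))` and can
  straddle a protocol step placed exactly at the median by one ulp.
* Ties between adjacent steps satisfying the start criterion resolve to
  the lower concentration; the ending point requires both silence and
  plateau, so a silent-but-rising step is skipped.
* `fit_hill()` flags rather than throws on non-convergence or an active
  bound; `select_model()` verifies both fits were computed on identical
  data via a numeric fingerprint.
* All concentrations are mM, times seconds, coordinates Å, throughout the
  serialization formats.

# Problem sizes and limitations

The validation suite uses 40–800 cells per simulated population, 13
concentrations × 3 replicates at 5% CV for dose-response recovery
(medians over 10–20 seeds), and 5 000-frame ensembles of 120 residues for
correlation recovery — sizes at which the recovered quantities sit well
inside the published uncertainties while the whole suite runs in a few
minutes. Beyond the generator simplifications noted above, the package
does not model photobleaching or baseline drift (no correction beyond
detrending for noise estimation), does not do spectral oscillation
analysis (the field counts peaks), fits no mechanistic allosteric model
(the Hill description is empirical), and performs no significance testing
between constructs — standard ANOVA tooling covers that and is out of
scope here.
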
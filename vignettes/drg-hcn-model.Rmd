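---
title: "A virtual DRG neuron for studying HCN-dependent excitability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual DRG neuron for studying HCN-dependent excitability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Small and medium dorsal root ganglion (DRG) neurons of Fmr1 knockout (KO)
mice — a model of Fragile X syndrome — are hyperexcitable: they fire more
action potentials (APs) at lower current, with shorter latency and reduced
rheobase, while the AP waveform itself is unchanged. The measured mechanism
is an increase in input resistance caused by reduced HCN-channel function
(smaller hyperpolarization-evoked voltage sag, reduced *Hcn1*/*Hcn4*
transcript levels), and a pan-HCN blocker (ZD7288) abolishes every
genotype difference while a Kv7 blocker (XE991) does not.

`drgephys` packages that causal chain as a testable artifact: a
conductance-based virtual DRG neuron in which the *only* genotype
difference is the HCN maximal conductance, the current-clamp protocols and
operational feature definitions used to quantify excitability, the
2^−ΔΔCt qPCR procedure, and a cohort-level statistical pipeline. Every
qualitative claim above becomes a property the test suite computes.

## The model

A single compartment obeys

$$C_m \frac{dV}{dt} = -\sum_c \bar g_c \, a_c(V,t) \,(V - E_c) + I_{\mathrm{inj}}(t)$$

with five currents: ohmic leak; transient Na⁺ ($m^3h$, Hodgkin–Huxley rate
functions); delayed-rectifier K⁺ ($n^4$); HCN (Ih, one slow activation gate
$y$); and a small M-type K⁺ current (Kv7, one slow gate $p$). Units are
mV, ms, pA, nS, pF throughout, so $\mathrm{pA/pF} = \mathrm{mV/ms}$.

Gating variables use exponential-Euler updates; the voltage uses the exact
exponential update of the instantaneously linear membrane equation, at a
fixed step of 0.025 ms recorded at 40 kHz (typical acquisition rate). The
integrator is deterministic: identical parameters, stimulus and
configuration give bit-identical traces. Halving the step changes no
reported feature beyond its test tolerance (a dedicated test checks this).

### Na⁺ and K⁺ kinetics

The classic squid-axon rate functions are reused with three free
parameters: a voltage shift of Na⁺ activation (+11.5 mV), a separate shift
of Na⁺ inactivation and the delayed rectifier (+25 mV), and a common rate
scale (2.5, standing in for the near-physiological recording temperature).
The split shift matters: with a single shift the model accommodates — the
membrane time constant of a high-resistance DRG soma (~10 ms) is so slow
that Na⁺ channels inactivate and the rectifier activates before threshold
is reached, and the cell never fires. Depolarized inactivation is also a
hallmark of the TTX-resistant Na⁺ currents that dominate small DRG
neurons.

### The HCN current

Ih is the scientific core, and three choices depart from a textbook HCN
model; all three are forced by measured properties of the real cells.

1. **Reversal near rest (−62.9 mV).** The physiological mixed-cation
   reversal is near −30 mV, but with it a conductance difference large
   enough to reproduce the rheobase and input-resistance separation drags
   the resting potential of the KO several mV below WT — and RMP is
   experimentally *unchanged* between genotypes. Placing the effective
   reversal at the resting potential collapses the tonic current component
   (which the RMP data constrain to be ≈ 0) while retaining both the
   conductance (shunt) effect and the hyperpolarization-activated inward
   sag current. This is exactly the "shunting effect" reading of Ih in
   sensory neurons.
2. **Two-component activation.** The steady state is
   $y_\infty(V) = 0.42\,B(V; -55, 9) + 0.58\,B(V; -63.5, 1.5)$ with
   $B(V; V_{1/2}, k) = 1/(1+e^{(V-V_{1/2})/k})$: a shallow, relatively
   depolarized component and a steep component that switches on just below
   rest. DRG neurons express both HCN1 (shallower, more depolarized
   activation) and HCN4 (steeper, hyperpolarized); the mixture stands for
   that channel population. Functionally the shallow component provides the
   persistent subthreshold shunt that separates WT and KO rheobase, while
   the steep component generates the voltage sag. A single sigmoid cannot
   do both: if it is positioned for the shunt, the KO's deeper voltage
   excursion during a hyperpolarizing step recruits proportionally *more*
   activation and the WT–KO sag-ratio contrast vanishes or reverses. The
   steep component must saturate within the WT's own excursion, which
   pins its half-activation just below rest and its slope at ~1.5 mV.
3. **Bell-shaped time constant** peaking at ~300 ms near −80 mV
   (60 + 240/cosh((V+80)/15) ms). HCN is slow enough to be effectively
   frozen during an AP upstroke but fast enough that sag develops within a
   600 ms step.

The maximal conductance is 16 nS in WT; the KO preset multiplies it by
0.4 and changes nothing else. The figures behind the genotype contrast
show a transcript reduction without printed fold values, so the 40% ratio
is a design choice (exposed as `ko_hcn_ratio`) that robustly separates the
genotypes while keeping the KO sag clearly nonzero.

### Leak and M current

The leak (3 nS, −63.4 mV) sets the resting potential together with Ih.
Its size matters for one subtle reason: the sag *ratio* divides the sag
amplitude by the peak deflection, and if HCN dominates the total
conductance the ratio becomes insensitive to the HCN level; an
HCN-independent background conductance restores the monotone
gbar-to-sag-ratio mapping. The M current is small (1 nS) and exists to
give the XE991 condition a real target; zeroing it barely changes any
feature, which is the experimentally observed result (Kv7 block does not
abolish the genotype differences).

## Protocols and feature definitions

The four stimulus protocols follow the experimental methods exactly:
steps of 25–150 pA (25 pA increments, 600 ms); a 0.1 pA/ms ramp with a
hyperpolarizing onset (−50 pA, 500 ms — onset amplitude and duration are
not printed in the methods and default to the test-pulse magnitude); a sag
family of −50 to −100 pA (−10 pA increments, 600 ms); and a −50 pA,
500 ms input-resistance pulse (repeatable every 5 s). All protocols carry
a 200 ms zero-current baseline so that baseline-dependent features are
well defined.

Feature definitions are operational, matching the analysis conventions of
current-clamp work:

* **AP detection** — voltage maxima above −10 mV with ≥ 20 mV prominence
  and ≥ 1 ms separation (config-exposed constants).
* **Threshold** — the voltage where dV/dt last crosses 5 mV/ms upward
  before the peak (central differences, linear interpolation at the
  crossing). Only the first AP of a sweep defines threshold, latency,
  rheobase and charge transfer, avoiding contamination by cumulative Na⁺
  inactivation.
* **Latency** — stimulus onset to first-AP threshold time.
* **Ramp rheobase** — injected current at the first-AP threshold time,
  relative to the 0 pA baseline; also reported normalized by capacitance.
* **Charge transfer** — trapezoidal ∫I dt from step onset (or ramp
  baseline-crossing) to the first-AP threshold time, in pC. For a step
  this must equal amplitude × latency, which the tests use as a
  cross-check between independently computed features.
* **AP counts** — all APs peaking within a step; for the ramp, only APs
  within the first 2 s from the beginning of the rising segment.
* **First ISI** — peak-to-peak interval of the first two APs (defined when
  a sweep has at least two APs).
* **Waveform** — peak potential, amplitude (peak − threshold), 10–90%
  rise and 90–10% fall times on the threshold-to-peak span, maximal
  upstroke speed, and duration at the +15 mV level.
* **Passive** — RMP as the 100 ms baseline mean; input resistance from
  the baseline-to-steady-state deflection of the test pulse (steady state
  = last 50 ms, reused from the sag definition for consistency); sag
  amplitude = steady state − minimum, sag ratio = 100 × amplitude /
  (baseline − minimum), with the first 2 ms after onset excluded from the
  minimum search to avoid resampling transients; capacitance from a
  single-exponential fit to the first 100 ms of the pulse, cm = τ/Rin.
  The amplifier-based capacitance measurement of the rig cannot be
  reproduced in a simulator, so the fit is the package's replacement; on
  an HCN-expressing cell the early sag contaminates it, and the estimate
  is documented as accurate only to ~15%.

Undefined features (no AP, single AP, peak below +15 mV) are flagged as
`NA`, never silently zero.

## Cell-to-cell variability

`make_genotype()` draws, per cell: an independent lognormal factor
(CV 0.2, unit mean) for every maximal conductance; a lognormal capacitance
factor (CV 0.15); and a Gaussian offset on the leak reversal (SD 1.5 mV).
All three distributions are identical in WT and KO. The conductance CV is
the primary variability model. The capacitance and leak-reversal terms
extend it for a statistical reason: real cohorts scatter in cell size and
resting potential, and the group comparisons of those quantities are only
meaningful tests of "no difference" when the within-group variance is
realistic rather than numerically degenerate (with zero variance, even a
0.1 pF estimator bias becomes a significant t-test). Capacitance and RMP
remain equal between genotypes *in distribution*, which is the
experimental observation being modeled.

With the default calibration (all of it checked by tests at cv = 0 and at
the cohort level with seed 42): the WT cell rests near −63 mV, is silent
at the 25 pA step and fires tonically from 50 pA; the KO step rheobase
sits just under 25 pA, so that with CV 0.2 about half of KO cells fire at
25 pA while no WT cell does; the genotype RMP difference is ~0.15 mV; and
the per-cell probability that a WT draw fires at 25 pA is of order 1%,
the same regime as the real data set in which no tested WT neuron fired
at that step.

## The qPCR module

`generate_ct_table()` emulates the transcript experiment: per-gene WT
baseline Ct values, KO values shifted by −log2(fold), Gaussian per-well
noise, 3 technical × 3 biological replicates, *Rpl13a* as housekeeping
gene. The default truth (Hcn1 = 0.4, Hcn4 = 0.35, Hcn2 = Hcn3 = 1) is an
illustrative reduction of the two affected isoforms — the source figures
print no fold values — and is config-exposed. `delta_ct()` averages
technical replicates and subtracts the sample's housekeeping mean;
`fold_change()` references ΔΔCt to the WT group mean (the methods do not
specify per-pair referencing), reports mean ± SEM of per-sample folds,
and tests ΔCt — not fold — with a two-sample t-test, since ΔCt is the
approximately normal scale. By construction the reference group's
geometric mean fold is exactly 1.

## Statistics

`ttest_groups()` is a two-sided pooled-variance Student's t-test (Welch
behind a flag), with documented conventions for degenerate input: zero
pooled variance gives p = 1 for equal means and p = 0 otherwise. No
multiple-testing correction is applied — each feature is tested at 0.05,
matching the source analysis. `run_experiment()` simulates independent
cohorts per genotype × drug condition (drug effects were measured on
different cells experimentally, with no within-cell washout, and the
pipeline does the same), extracts all features, and emits per-step
comparison tables. Everything is derived deterministically from the
master seed; per-cell seeds are hashed from (seed, genotype, drug, cell).

## What the synthetic data do and do not show

The generator emulates tonic-firing small/medium DRG neurons under the
four protocols with conductance-level variability. It does not emulate:
recording noise or electrode artifacts (traces are noise-free, so feature
extractors default to unsmoothed derivatives; a real-data user should
expect to need smoothing); bursting or irregular firing phenotypes; cell
size as a morphological quantity (capacitance is its only analog);
channel stochasticity; temperature sensitivity (kinetics are taken as
already at 33–34 °C); or rundown and time-dependent drift. Passing tests
therefore demonstrate that the analysis pipeline is correct and that the
HCN-shunt hypothesis is *sufficient* to reproduce the qualitative results
matrix — not that real DRG neurons contain no other contributing
mechanism.

## Numerical choices and edge cases

* Fixed-step integration at dt = 0.025 ms; settling time 1000 ms (HCN is
  slow; the post-settle |dV/dt| is recorded in the sweep metadata and
  warned about above 0.01 mV/ms).
* Multiple 5 mV/ms crossings on an upstroke: the *last* crossing before
  the peak is used (closest to the committed upstroke).
* The ramp AP-count window is anchored at the beginning of the rising
  segment, not at the baseline crossing.
* The first-ISI convention "more than 2 APs" in the source methods is
  read as "at least 2" (two peaks define one interval).
* The HCN-gradient monotonicity property (input resistance strictly
  decreasing, sag ratio strictly increasing, ramp rheobase non-decreasing,
  ramp AP count non-increasing in gbar) is evaluated with the sag ratio at
  the −100 pA step: at −50 pA the ratio saturates between 80% and 100% of
  the WT conductance (a 0.04-point inversion), while every deeper step is
  strictly monotone.
* Cohort sizes default to n = 20 per group — the per-figure n of the
  source data lives in an unavailable supplement — giving stable power
  for all the effects the tests assert at CV 0.2.
* The "~50% of KO neurons fire at 25 pA" calibration is accepted within
  ±10 percentage points at n = 20; the binomial SD at n = 20 (≈ 11
  points) makes a tighter window meaningless.

## Known limitations

* The voltage-threshold difference between genotypes (~0.5 mV
  hyperpolarized in KO) is small in this model; it reaches significance
  on the ramp but not always on steps at n = 20. Whether a pure-HCN
  mechanism should shift the measured threshold at all is genuinely open
  — threshold is defined by a dV/dt criterion, and the HCN shunt shifts
  it only indirectly. The pipeline reports the comparison either way.
* The HCN reversal placement (near rest) trades the tonic depolarizing
  component of Ih for fidelity to the RMP/shunt observations; a model of
  pacemaking or rebound bursting would need the physiological reversal
  and would then have to relax the RMP constraint.
* `estimate_capacitance()` is biased by sag on HCN-expressing cells
  (documented ~15% tolerance); it exists to give the capacitance
  comparison a simulator analog, not as a precision instrument.
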
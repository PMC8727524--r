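# drgephys

Simulation and analysis of sensory-neuron excitability in current clamp:
a conductance-based virtual dorsal root ganglion (DRG) neuron with an
explicit HCN (Ih) current, the current-clamp protocols and
action-potential feature definitions used to quantify excitability, a
2^−ΔΔCt qPCR quantification module, and a cohort-level statistical
pipeline.

## Who this is for

Electrophysiologists and computational neuroscientists who want a tested,
reproducible implementation of the causal chain behind DRG
hyperexcitability in the Fmr1-knockout (Fragile X) mouse: **reduced HCN
conductance → increased input resistance → lower rheobase and more
firing**, with the AP waveform untouched. The knockout (KO) virtual
neuron differs from wild type (WT) in exactly one parameter — the HCN
maximal conductance — so every downstream group difference is, by
construction, attributable to Ih.

## The model

A single compartment with membrane capacitance $C_m$ obeys

$$C_m \frac{dV}{dt} = -\sum_c \bar g_c\, a_c(V,t)\,(V-E_c) + I_{\mathrm{inj}}(t),$$

with leak, transient Na⁺ ($m^3h$), delayed-rectifier K⁺ ($n^4$), HCN
($y$, two-component activation standing for the HCN1/HCN4 channel mix of
DRG neurons) and M-type K⁺ ($p$) currents. Gating uses exponential-Euler
integration at a fixed 0.025 ms step (40 kHz); traces are bit-reproducible.
Units are mV / ms / pA / nS / pF throughout.

Feature extraction implements the operational definitions used in
current-clamp analysis: threshold as the last upward crossing of
dV/dt = 5 mV/ms before the AP peak; latency to the first-AP threshold;
ramp rheobase as the injected current at that threshold time; charge
transfer as ∫I dt from stimulus onset (or ramp baseline-crossing) to
threshold; sag amplitude/ratio from hyperpolarizing steps; input
resistance from a −50 pA test pulse. The statistics module reports
mean ± SEM and two-sided Student's t-tests per feature, per step.

## Worked example

```r
library(drgephys)

wt <- make_genotype("WT")   # calibrated default parameter set
ko <- make_genotype("KO")   # identical except HCN gbar x 0.4
wt
#> <neuron_params> WT
#>   cm: 25 pF
#>   leak  (leak): gbar = 3 nS, erev = -63.4 mV
#>   na    (na): gbar = 2500 nS, erev = 60 mV
#>   kdr   (kdr): gbar = 700 nS, erev = -90 mV
#>   hcn   (hcn): gbar = 16 nS, erev = -62.9 mV
#>   km    (km): gbar = 1 nS, erev = -90 mV

cfg <- sim_config()
for (cell in list(wt, ko)) {
  rin_sw  <- simulate_sweeps(cell, rin_pulse(), cfg)[[1]]
  sag_sw  <- simulate_sweeps(cell, sag_family(-100), cfg)[[1]]
  ramp_sw <- simulate_sweeps(cell, ramp_protocol(), cfg)[[1]]
  rf <- sweep_features(ramp_sw)
  cat(sprintf("%s: RMP %.1f mV | Rin %.0f MOhm | sag ratio (-100 pA) %.1f%% | ramp rheobase %.1f pA | APs in 2 s %d\n",
      cell$label, rmp(rin_sw), input_resistance(rin_sw),
      sag_metrics(sag_sw)$sag_ratio, rf$rheobase, rf$n_aps))
}
#> WT: RMP -63.1 mV | Rin 63 MOhm | sag ratio (-100 pA) 30.4% | ramp rheobase 54.5 pA | APs in 2 s 77
#> KO: RMP -63.2 mV | Rin 116 MOhm | sag ratio (-100 pA) 23.7% | ramp rheobase 34.6 pA | APs in 2 s 91
```

The KO cell has nearly double the input resistance, a smaller voltage
sag, a 20 pA lower ramp rheobase and fires more APs — while resting at
the same potential. The qPCR module quantifies a synthetic Ct table the
same way the transcripts were quantified (Rpl13a normalization, WT
reference):

```r
fc <- fold_change(delta_ct(generate_ct_table(noise_sd = 0.15, seed = 1)))
fc
#> <fold_change_result> reference group: WT
#>   Hcn1   KO fold = 0.390 +/- 0.027 (n = 3), p = 0.0002676 *
#>   Hcn2   KO fold = 0.938 +/- 0.064 (n = 3), p = 0.5178
#>   Hcn3   KO fold = 0.977 +/- 0.078 (n = 3), p = 0.7271
#>   Hcn4   KO fold = 0.365 +/- 0.029 (n = 3), p = 0.0002998 *
```

Cohort-level virtual experiments (n cells per genotype, lognormal
conductance variability, optional ZD7288/XE991 block, per-feature t-test
tables) run through `run_experiment(experiment_config(...))`; see the
vignette for the full comparison matrix and
`inst/scripts/drgephys-cli.R` for a command-line wrapper.

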
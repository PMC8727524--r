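test_that("rmp averages the baseline window", {
  t <- seq(0, 300, 0.1)
  flat <- as_sweep(t, rep(-60, length(t)))
  expect_equal(rmp(flat), -60)
  # with stimulus metadata, only the pre-onset window counts
  v <- ifelse(t < 200, -64, -80)
  sw <- as_sweep(t, v, meta = list(onset_ms = 200, dur_ms = 100,
                                   amplitude_pA = -50))
  expect_equal(rmp(sw), -64)
})

test_that("input resistance is deflection over current in megaohms", {
  cell <- passive_neuron(g_leak = 10)
  cfg <- sim_config(v_init = -65)
  sw <- simulate_sweeps(cell, rin_pulse(), cfg)[[1]]
  expect_equal(input_resistance(sw), 100, tolerance = 1)
  # independent of pulse amplitude for a passive cell (within 1%)
  rins <- vapply(c(-10, -30, -50, -100), function(a) {
    input_resistance(simulate_sweeps(cell, rin_pulse(amplitude = a), cfg)[[1]])
  }, numeric(1))
  expect_lt(diff(range(rins)) / mean(rins), 0.01)
  short <- as_sweep(seq(0, 300, 0.1), rep(-60, 3001),
                    meta = list(onset_ms = 200, dur_ms = 20,
                                amplitude_pA = -50))
  expect_error(input_resistance(short), "shorter")
})

test_that("sag metrics reproduce the defining formula exactly", {
  # baseline -60, minimum -80, steady -75 -> amplitude 5 mV, ratio 25%
  tr <- pl_trace(list(c(0, -60), c(200, -60), c(250, -80), c(400, -75),
                      c(800, -75), c(1000, -60)), dt = 0.1)
  sw <- as_sweep(tr$t, tr$v, meta = list(onset_ms = 200, dur_ms = 600,
                                         amplitude_pA = -50))
  m <- sag_metrics(sw)
  expect_equal(m$sag_amplitude, 5)
  expect_equal(m$sag_ratio, 25)
  expect_error(sag_metrics(as_sweep(tr$t, tr$v,
                                    meta = list(onset_ms = 200, dur_ms = 600,
                                                amplitude_pA = 50))),
               "hyperpolarizing")
})

test_that("sag ratio is invariant to scaling the deflection", {
  tr <- pl_trace(list(c(0, -60), c(200, -60), c(250, -80), c(400, -75),
                      c(800, -75), c(1000, -60)), dt = 0.1)
  base <- -60
  for (c_ in c(0.5, 2, 3.7)) {
    sw <- as_sweep(tr$t, base + c_ * (tr$v - base),
                   meta = list(onset_ms = 200, dur_ms = 600,
                               amplitude_pA = -50))
    expect_equal(sag_metrics(sw)$sag_ratio, 25, tolerance = 1e-10)
  }
})

test_that("sag metrics agree with a brute-force min/mean oracle", {
  sweeps <- simulate_sweeps(make_genotype("WT"), sag_family(), sim_config())
  for (sw in sweeps) {
    m <- sag_metrics(sw)
    on <- sw$meta$onset_ms
    v_min <- min(sw$v[sw$t >= on + 2 & sw$t < on + 600])
    v_steady <- mean(sw$v[sw$t >= on + 550 & sw$t < on + 600])
    v_base <- mean(sw$v[sw$t >= on - 100 & sw$t < on])
    expect_equal(m$sag_amplitude, v_steady - v_min, tolerance = 1e-10)
    expect_equal(m$sag_ratio, 100 * (v_steady - v_min) / (v_base - v_min),
                 tolerance = 1e-10)
    expect_gte(m$sag_ratio, 0)
    expect_lte(m$sag_ratio, 100)
  }
})

test_that("capacitance estimate is consistent and bounded", {
  # tau = cm_est x rin by definition
  sw <- wt_rin_sweep()
  rin <- input_resistance(sw)
  cap <- estimate_capacitance(sw, rin)
  expect_equal(cap$tau_ms, cap$cm_pF * rin / 1000, tolerance = 1e-10)
  # active cell: within 15% of the true capacitance despite sag contamination
  expect_lt(abs(cap$cm_pF - 25) / 25, 0.15)
})

test_that("passive feature table carries per-sweep sag columns", {
  cell <- make_genotype("WT")
  rin_sw <- wt_rin_sweep()
  sag_sw <- simulate_sweeps(cell, sag_family(c(-50, -100)), sim_config())
  tab <- passive_features(rin_sw, sag_sw)
  expect_true(all(c("rmp", "rin", "cm_est", "sag_amp_50", "sag_ratio_50",
                    "sag_baseline_50", "sag_amp_100", "sag_ratio_100") %in%
                    names(tab)))
  expect_gt(tab$sag_ratio_100, tab$sag_ratio_50 - 5)
  expect_gt(tab$rin, 0)
})
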
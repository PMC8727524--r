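test_that("gating curves are well-behaved over the simulated voltage range", {
  v <- seq(-120, 60, by = 1)
  for (ch in make_genotype("WT")$channels) {
    g <- gating_curves(ch, v)
    if (nrow(g) == 0) next
    expect_true(all(g$inf >= 0 & g$inf <= 1), label = ch$name)
    expect_true(all(g$tau > 0), label = ch$name)
  }
})

test_that("channel and neuron invariants are enforced", {
  expect_error(channel_spec("bad", "leak", gbar = -1, erev = -65), "gbar")
  leak <- channel_spec("leak", "leak", 2, -65)
  hcn <- make_genotype("WT")$channels$hcn
  expect_error(neuron_params(-5, list(leak, hcn)), "cm")
  expect_error(neuron_params(25, list(leak)), "HCN")
  expect_error(neuron_params(25, list(hcn)), "leak")
  expect_error(neuron_params(25, list(leak, leak, hcn)), "leak")
  expect_error(make_genotype("HET"), "should be one of")
  expect_error(sim_config(dt = 0.025, record_dt = 0.06), "multiple")
  expect_error(sim_config(settle_ms = 100), "settle")
})

test_that("passive cell obeys resting potential and Ohm's law", {
  cell <- passive_neuron(cm = 25, g_leak = 10, e_leak = -65)
  cfg <- sim_config(v_init = -65)
  base <- simulate_sweeps(cell, rin_pulse(amplitude = -50), cfg)[[1]]
  expect_equal(rmp(base), -65, tolerance = 1e-6)
  # steady-state deflection -50 pA / 10 nS = -5 mV
  v_end <- mean(base$v[base$t > 650 & base$t < 700])
  expect_equal(v_end - -65, -5, tolerance = 0.01)
  # settles to a fixed point before the stimulus
  expect_lt(abs(base$meta$post_settle_dvdt), 0.01)
})

test_that("membrane time constant of the passive cell is cm/g_L", {
  cell <- passive_neuron(cm = 25, g_leak = 2, e_leak = -65)
  sw <- simulate_sweeps(cell, rin_pulse(), sim_config(v_init = -65))[[1]]
  cap <- estimate_capacitance(sw)
  expect_equal(cap$tau_ms, 25 / 2, tolerance = 0.02 * 12.5)
  expect_equal(cap$cm_pF, 25, tolerance = 0.02 * 25)
})

test_that("genotype presets differ only in HCN conductance", {
  wt <- make_genotype("WT")
  ko <- make_genotype("KO")
  expect_equal(ko$channels$hcn$gbar / wt$channels$hcn$gbar, 0.4)
  for (nm in names(wt$channels)) {
    if (nm == "hcn") next
    expect_identical(wt$channels[[nm]], ko$channels[[nm]])
  }
  expect_identical(wt$cm, ko$cm)
})

test_that("conductance variability is seeded and deterministic", {
  a <- make_genotype("WT", variability_cv = 0.2, seed = 1)
  b <- make_genotype("WT", variability_cv = 0.2, seed = 1)
  expect_identical(a, b)
  c <- make_genotype("WT", variability_cv = 0.2, seed = 2)
  expect_false(identical(a, c))
  expect_error(make_genotype("WT", variability_cv = 0.2), "seed")
  # zero variability returns the exact preset regardless of seed
  expect_identical(make_genotype("WT"), make_genotype("WT", 0, seed = 99))
})

test_that("drug emulation zeroes the targeted conductance only", {
  wt <- make_genotype("WT")
  zd <- apply_drug(wt, "ZD7288")
  expect_equal(zd$channels$hcn$gbar, 0)
  expect_equal(zd$drug, "ZD7288")
  expect_identical(zd$channels$km, wt$channels$km)
  xe <- apply_drug(wt, "XE991")
  expect_equal(xe$channels$km$gbar, 0)
  expect_equal(xe$channels$hcn$gbar, wt$channels$hcn$gbar)
  # ZD7288 erases the genotype difference entirely (cv = 0)
  ko_zd <- apply_drug(make_genotype("KO"), "ZD7288")
  zd$label <- "KO"
  expect_identical(zd$channels, ko_zd$channels)
  expect_error(apply_drug(wt, "TTX"), "should be one of")
})

test_that("simulation is deterministic and failures are reported", {
  cell <- make_genotype("WT")
  s1 <- simulate_sweeps(cell, step_family(50), sim_config())[[1]]
  s2 <- simulate_sweeps(cell, step_family(50), sim_config())[[1]]
  expect_identical(s1$v, s2$v)
  bad <- cell
  bad$channels$na$gbar <- 1e308
  expect_error(
    suppressWarnings(simulate_sweeps(bad, step_family(50), sim_config())),
    "integration failure"
  )
})

test_that("integration converges as the step shrinks", {
  cell <- make_genotype("WT")
  coarse <- simulate_sweeps(cell, step_family(25), sim_config())[[1]]
  fine <- simulate_sweeps(cell, step_family(25),
                          sim_config(dt = 0.0025, record_dt = 0.025))[[1]]
  # subthreshold trace agrees everywhere at the common sampling grid
  expect_lt(max(abs(coarse$v - fine$v)), 0.5)
  # spiking sweep: same AP count, peak times within half a millisecond
  c100 <- simulate_sweeps(cell, step_family(100), sim_config())[[1]]
  f100 <- simulate_sweeps(cell, step_family(100),
                          sim_config(dt = 0.0025, record_dt = 0.025))[[1]]
  pc <- detect_aps(c100)
  pf <- detect_aps(f100)
  expect_equal(length(pc), length(pf))
  expect_lt(max(abs(c100$t[pc] - f100$t[pf])), 0.5)
})

test_that("hyperpolarizing steps produce sag only when HCN is present", {
  wt <- make_genotype("WT")
  sag_wt <- sag_metrics(simulate_sweeps(wt, sag_family(-50), sim_config())[[1]])
  expect_gt(sag_wt$sag_amplitude, 0.5)
  blocked <- apply_drug(wt, "ZD7288")
  sag_zd <- sag_metrics(simulate_sweeps(blocked, sag_family(-50),
                                        sim_config())[[1]])
  expect_lt(sag_zd$sag_amplitude, 0.2)
})

test_that("calibration constraints hold for the default presets", {
  counts_wt <- vapply(wt_step_sweeps(), function(s) sweep_features(s)$n_aps,
                      numeric(1))
  expect_equal(counts_wt[1], 0)     # silent at 25 pA
  expect_gte(counts_wt[2], 1)       # fires at 50 pA
  expect_true(all(diff(counts_wt[-1]) > 0)) # tonic, count grows with drive
  ko <- make_genotype("KO")
  counts_ko <- vapply(simulate_sweeps(ko, step_family(), sim_config()),
                      function(s) sweep_features(s)$n_aps, numeric(1))
  expect_true(all(counts_ko >= counts_wt))
  expect_true(all(diff(counts_ko) > 0))
  # RMP difference below 1 mV
  rmp_wt <- rmp(wt_rin_sweep())
  rmp_ko <- rmp(simulate_sweeps(ko, rin_pulse(), sim_config())[[1]])
  expect_lt(abs(rmp_wt - rmp_ko), 1)
  # AP peaks above +30 mV
  pk <- detect_aps(wt_step_sweeps()[[4]])
  expect_true(all(wt_step_sweeps()[[4]]$v[pk] > 30))
})

test_that("sweeps round-trip through the delimited text format", {
  sw <- wt_rin_sweep()
  path <- tempfile(fileext = ".tsv")
  write_sweep(sw, path)
  back <- read_sweep(path)
  expect_equal(back$v, sw$v, tolerance = 1e-12)
  expect_equal(back$meta$amplitude_pA, sw$meta$amplitude_pA)
  expect_equal(back$meta$genotype, "WT")
  unlink(c(path, paste0(path, ".meta")))
})
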
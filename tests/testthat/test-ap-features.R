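test_that("AP detection matches a threshold-crossing oracle", {
  # flat trace: nothing to detect
  flat <- as_sweep(seq(0, 100, 0.025), rep(-60, 4001))
  expect_identical(detect_aps(flat), integer(0))
  # simulated tonic firing: peak count equals -10 mV upward crossings
  for (sw in wt_step_sweeps()[c(2, 4, 6)]) {
    peaks <- detect_aps(sw)
    expect_equal(length(peaks), crossing_count(sw$v, sw$t))
    expect_true(all(diff(peaks) > 0))
    expect_true(all(sw$v[peaks] > -10))
  }
  # two constructed APs 5 ms apart are both found, in order
  a <- constructed_ap_sweep(t_knee = 20)
  b <- constructed_ap_sweep(t_knee = 25)
  t <- seq(0, 60, 0.025)
  v <- pmax(approx(a$t, a$v, t, rule = 2)$y, approx(b$t, b$v, t, rule = 2)$y)
  two <- as_sweep(t, v, meta = list(onset_ms = 0))
  expect_length(detect_aps(two), 2L)
})

test_that("threshold is the last 5 mV/ms crossing, interpolated", {
  # slope 1 mV/ms to (20 ms, -40 mV), then 10 mV/ms: threshold at the knee
  sw <- constructed_ap_sweep(pre_slope = 1, up_slope = 10)
  thr <- ap_threshold(sw, detect_aps(sw)[1])
  expect_equal(thr$threshold, -40, tolerance = 0.1)
  expect_equal(thr$threshold_time, 20, tolerance = 0.05)
  # slopes 2 then 4 mV/ms never reach the criterion
  slow <- constructed_ap_sweep(pre_slope = 2, up_slope = 4, v_peak = 0)
  pk <- which.max(slow$v)
  expect_error(ap_threshold(slow, pk), class = "drg_no_threshold")
  # simulated AP: agree with an exhaustive scan of the sampled dV/dt series
  sim <- wt_step_sweeps()[[4]]
  peaks <- detect_aps(sim)
  d <- drgephys:::central_dvdt(sim)
  for (p in peaks[1:3]) {
    j <- p
    while (j > 1 && sim$v[j - 1] <= sim$v[j]) j <- j - 1
    idx <- j:(p - 1)
    cross <- idx[d[idx] < 5 & d[idx + 1] >= 5]
    scan_t <- sim$t[cross[length(cross)]]
    thr <- ap_threshold(sim, p)
    expect_lt(abs(thr$threshold_time - scan_t), 0.026)
  }
})

test_that("waveform measures reproduce triangular-AP geometry", {
  # threshold -40, peak +40, rise 20 mV/ms, fall -20 mV/ms
  sw <- constructed_ap_sweep(pre_slope = 1, up_slope = 20, v_knee = -40,
                             v_peak = 40, down_slope = -20)
  wf <- ap_waveform_measures(sw, detect_aps(sw)[1])
  expect_equal(wf$amplitude, 80, tolerance = 0.15)
  expect_equal(wf$peak_potential, 40, tolerance = 1e-6)
  expect_equal(wf$duration_at_plus15, 2.5, tolerance = 0.01)
  expect_equal(wf$rise_time_10_90, 3.2, tolerance = 0.02)
  expect_equal(wf$fall_time_90_10, 3.2, tolerance = 0.02)
  expect_equal(wf$rising_speed, 20, tolerance = 0.5)
  # a spike peaking below +15 mV has no defined duration
  low <- constructed_ap_sweep(v_peak = 10)
  wf_low <- ap_waveform_measures(low, detect_aps(low)[1])
  expect_true(is.na(wf_low$duration_at_plus15))
})

test_that("sweep-level features follow the first-AP-only policy", {
  sim <- wt_step_sweeps()[[4]] # several APs
  peaks <- detect_aps(sim)
  expect_gte(length(peaks), 3)
  sf <- sweep_features(sim)
  first <- ap_waveform_measures(sim, peaks[1])
  expect_equal(sf$threshold, first$threshold)
  expect_equal(sf$threshold_time, first$threshold_time)
  expect_equal(sf$latency,
               first$threshold_time - sim$meta$onset_ms)
  per_ap <- attr(sf, "per_ap")
  expect_equal(nrow(per_ap), sf$n_aps)
  # a sweep with no APs flags the first-AP fields as NA
  sub <- wt_step_sweeps()[[1]]
  sf0 <- sweep_features(sub)
  expect_equal(sf0$n_aps, 0)
  expect_true(is.na(sf0$latency) && is.na(sf0$charge_transfer) &&
                is.na(sf0$threshold))
})

test_that("latency and first ISI come from threshold and peak times", {
  sw <- constructed_ap_sweep(t_knee = 230, meta = list(onset_ms = 200,
                                                       dur_ms = 600))
  expect_equal(ap_latency(sw), 30, tolerance = 0.05)
  # peaks at 250 and 280 ms -> ISI 30 ms
  a <- constructed_ap_sweep(t_knee = 245)
  t <- seq(0, 320, 0.025)
  v <- pmax(approx(a$t + 0, a$v, t, rule = 2)$y,
            approx(a$t + 30, a$v, t, rule = 2)$y)
  two <- as_sweep(t, v, meta = list(onset_ms = 0))
  pk <- detect_aps(two)
  expect_equal(first_isi(two, pk), 30, tolerance = 0.05)
  single <- constructed_ap_sweep()
  expect_true(is.na(first_isi(single)))
})

test_that("ramp rheobase and charge transfer match closed forms", {
  # ramp crossing 0 pA at t = 600, threshold at t = 1000 -> 40 pA, 8 pC
  dt <- 0.05
  t <- seq(0, 1100, dt)
  i <- pmax(-50, -50 + 0.1 * pmax(t - 100, 0))
  ap <- constructed_ap_sweep(t_knee = 1000, dt = dt)
  v <- approx(ap$t, ap$v, t, rule = 2)$y
  sw <- as_sweep(t, v, i, meta = list(
    protocol = "ramp", onset_ms = 100, ramp_start_ms = 100,
    ramp_slope = 0.1, baseline_cross_ms = 600, cm = 25))
  rr <- rheobase_ramp(sw)
  expect_equal(rr$rheobase, 40, tolerance = 0.1)
  expect_equal(rr$rheobase_norm, 40 / 25, tolerance = 0.005)
  expect_equal(charge_transfer(sw), 8, tolerance = 0.01)
  # 50 pA step, threshold 100 ms after onset -> 5 pC
  ts <- seq(0, 400, dt)
  is <- ifelse(ts >= 100, 50, 0)
  ap2 <- constructed_ap_sweep(t_knee = 200, dt = dt)
  vs <- approx(ap2$t, ap2$v, ts, rule = 2)$y
  step <- as_sweep(ts, vs, is, meta = list(onset_ms = 100, dur_ms = 300,
                                           amplitude_pA = 50))
  expect_equal(charge_transfer(step), 5, tolerance = 0.01)
})

test_that("step charge transfer equals amplitude times latency", {
  for (k in c(2, 4)) {
    sw <- wt_step_sweeps()[[k]]
    sf <- sweep_features(sw)
    expect_equal(sf$charge_transfer,
                 sw$meta$amplitude_pA * sf$latency / 1000,
                 tolerance = 1e-3)
  }
})

test_that("ramp AP counting stops 2 s after the ramp begins", {
  base <- constructed_ap_sweep(t_knee = 50)
  t <- seq(0, 3000, 0.05)
  v <- rep(-60, length(t))
  for (pt in c(1800, 1950, 2100)) {
    v <- pmax(v, approx(base$t + (500 + pt) - 54, base$v, t, rule = 2)$y)
  }
  sw <- as_sweep(t, v, meta = list(protocol = "ramp", onset_ms = 100,
                                   ramp_start_ms = 500, ramp_slope = 0.1,
                                   baseline_cross_ms = 1000))
  pk <- detect_aps(sw)
  expect_length(pk, 3L)
  expect_equal(count_aps(sw, pk), 2L)
  # step sweeps count every AP whose peak lies within the step
  expect_equal(count_aps(wt_step_sweeps()[[1]]), 0L)
  s4 <- wt_step_sweeps()[[4]]
  pk4 <- detect_aps(s4)
  on4 <- s4$meta$onset_ms
  in_step <- sum(s4$t[pk4] >= on4 & s4$t[pk4] <= on4 + s4$meta$dur_ms)
  expect_equal(count_aps(s4), in_step)
})

test_that("phase plot crosses 5 mV/ms at the reported threshold", {
  sw <- constructed_ap_sweep(pre_slope = 1, up_slope = 10)
  pp <- phase_plot(sw)
  up <- which(pp$dvdt[-nrow(pp)] < 5 & pp$dvdt[-1] >= 5)
  v_cross <- pp$v[up[length(up)]]
  expect_equal(v_cross, -40, tolerance = 0.15)
  # internal consistency on a simulated AP
  sim <- wt_step_sweeps()[[4]]
  p1 <- detect_aps(sim)[1]
  thr <- ap_threshold(sim, p1)
  win <- c(sim$t[p1] - 10, sim$t[p1])
  pps <- phase_plot(sim, win)
  ups <- which(pps$dvdt[-nrow(pps)] < 5 & pps$dvdt[-1] >= 5)
  expect_lt(abs(pps$v[ups[length(ups)]] - thr$threshold), 0.1)
})

test_that("features are invariant to time shifts and 2x resampling", {
  sw <- wt_step_sweeps()[[4]]
  ref <- sweep_features(sw)
  shifted <- sw
  shifted$t <- sw$t + 100
  shifted$meta$onset_ms <- sw$meta$onset_ms + 100
  sf_sh <- sweep_features(shifted)
  expect_equal(sf_sh$threshold, ref$threshold)
  expect_equal(sf_sh$latency, ref$latency)
  expect_equal(sf_sh$duration_at_plus15, ref$duration_at_plus15)
  # resample at twice the rate by linear interpolation
  t2 <- seq(sw$t[1], sw$t[length(sw$t)], by = (sw$t[2] - sw$t[1]) / 2)
  res <- as_sweep(t2, approx(sw$t, sw$v, t2)$y, approx(sw$t, sw$i, t2)$y,
                  meta = sw$meta)
  sf2 <- sweep_features(res)
  expect_equal(sf2$threshold, ref$threshold, tolerance = 0.1)
  expect_equal(sf2$rise_time_10_90, ref$rise_time_10_90, tolerance = 0.05)
  expect_equal(sf2$duration_at_plus15, ref$duration_at_plus15,
               tolerance = 0.05)
  expect_equal(sf2$n_aps, ref$n_aps)
})
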
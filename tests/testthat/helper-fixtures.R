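# Shared fixtures: constructed sweeps with known geometry and a cache for
# expensive cohort simulations reused across test files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

default_experiment <- function() {
  cached("default_exp", run_experiment(experiment_config()))
}

drug_experiment <- function(drug) {
  cached(paste0("exp_", drug),
         run_experiment(experiment_config(drug = drug)))
}

get_comparison <- function(exp, feature, condition) {
  cmp <- exp$comparisons
  row <- cmp[cmp$feature == feature & cmp$condition == condition, ]
  stopifnot(nrow(row) == 1L)
  row
}

# Piecewise-linear voltage trace builder: `knots` is a matrix-like list of
# (t, v) pairs; samples on a uniform dt grid.
pl_trace <- function(knots, dt = 0.025) {
  t <- seq(knots[[1]][1], knots[[length(knots)]][1], by = dt)
  tv <- vapply(knots, `[`, numeric(2), 1:2)
  v <- approx(tv[1, ], tv[2, ], xout = t)$y
  list(t = t, v = v)
}

# Single AP whose upstroke approaches at `pre_slope` mV/ms to (t_knee, v_knee)
# and then rises at `up_slope` to `v_peak`; falls at `down_slope` back to
# baseline and holds.
constructed_ap_sweep <- function(pre_slope = 1, up_slope = 10,
                                 v_base = -60, v_knee = -40, v_peak = 30,
                                 down_slope = -20, t_knee = 20, dt = 0.025,
                                 meta = list(onset_ms = 0)) {
  t_rise <- (v_peak - v_knee) / up_slope
  t_fall <- (v_base - v_peak) / down_slope
  t0 <- t_knee - (v_knee - v_base) / pre_slope
  knots <- list(c(t0 - 10, v_base), c(t0, v_base),
                c(t_knee, v_knee),
                c(t_knee + t_rise, v_peak),
                c(t_knee + t_rise + t_fall, v_base),
                c(t_knee + t_rise + t_fall + 10, v_base))
  tr <- pl_trace(knots, dt)
  as_sweep(tr$t, tr$v, meta = meta)
}

# Simulated WT sweeps reused by several feature tests.
wt_step_sweeps <- function() {
  cached("wt_steps",
         simulate_sweeps(make_genotype("WT"), step_family(), sim_config()))
}

wt_ramp_sweep <- function() {
  cached("wt_ramp",
         simulate_sweeps(make_genotype("WT"), ramp_protocol(), sim_config())[[1]])
}

wt_rin_sweep <- function() {
  cached("wt_rin",
         simulate_sweeps(make_genotype("WT"), rin_pulse(), sim_config())[[1]])
}

# Independent oracle: count upward crossings of `level` with a debounce.
crossing_count <- function(v, t, level = -10, debounce_ms = 1) {
  up <- which(v[-length(v)] < level & v[-1] >= level)
  if (length(up) <= 1L) return(length(up))
  keep <- up[1]
  for (j in up[-1]) {
    if (t[j] - t[keep[length(keep)]] >= debounce_ms) keep <- c(keep, j)
  }
  length(keep)
}

# Independent oracle for the exhaustive two-sample permutation test.
perm_test_p <- function(a, b) {
  x <- c(a, b)
  n <- length(a)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(length(x), n)
  ds <- apply(idx, 2, function(i) abs(mean(x[i]) - mean(x[-i])))
  mean(ds >= obs - 1e-12)
}
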
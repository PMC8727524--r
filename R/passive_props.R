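# Passive membrane properties: resting potential, input resistance, voltage
# sag and a capacitance estimate, from the rin_pulse and sag_family sweeps.

# Baseline window: the last `window_ms` of the pre-stimulus segment.
baseline_mean <- function(sweep, window_ms = 100) {
  on <- sweep_onset(sweep)
  if (on < window_ms) {
    if (on <= 0) stop("sweep has no zero-current baseline segment")
    window_ms <- on
  }
  sel <- sweep$t >= on - window_ms & sweep$t < on
  mean(sweep$v[sel])
}

#' Resting membrane potential
#'
#' Mean voltage over the pre-stimulus zero-current baseline (the last
#' 100 ms before stimulus onset by default). For a sweep with no stimulus
#' metadata the whole trace is treated as baseline.
#'
#' @param sweep an \code{ep_sweep}.
#' @param window_ms baseline window length, ms.
#' @return RMP in mV.
#' @export
rmp <- function(sweep, window_ms = 100) {
  if (is.null(sweep$meta$onset_ms)) return(mean(sweep$v))
  baseline_mean(sweep, window_ms)
}

#' Input resistance from a hyperpolarizing test pulse
#'
#' The voltage difference between baseline and the steady state of the pulse
#' (mean of its last \code{steady_ms}) divided by the pulse amplitude,
#' converted to megaohms.
#'
#' @param sweep a [rin_pulse()] sweep.
#' @param steady_ms terminal averaging window, ms.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sweep, steady_ms = 50) {
  on <- sweep_onset(sweep)
  dur <- sweep$meta$dur_ms
  amp <- sweep$meta$amplitude_pA
  if (is.null(dur) || is.null(amp)) {
    stop("sweep metadata lacks dur_ms/amplitude_pA")
  }
  if (dur < steady_ms) stop("pulse shorter than the steady-state window")
  if (amp == 0) stop("zero-amplitude pulse cannot give input resistance")
  sel <- sweep$t >= on + dur - steady_ms & sweep$t < on + dur
  v_steady <- mean(sweep$v[sel])
  v_base <- baseline_mean(sweep)
  (v_base - v_steady) / abs(amp) * 1000
}

#' Sag amplitude and sag ratio of a hyperpolarizing step
#'
#' Sag amplitude is the voltage difference between the lowest point of the
#' trace during the step and the steady state (mean of the last
#' \code{steady_ms} of the step). Sag ratio is
#' \code{100 * sag_amplitude / (baseline - minimum)}. The minimum search
#' skips the first \code{blank_ms} after step onset so capacitive transients
#' in resampled data cannot masquerade as the sag trough.
#'
#' @param sweep a [sag_family()] sweep (hyperpolarizing step).
#' @param steady_ms terminal averaging window, ms.
#' @param blank_ms initial blanking interval for the minimum search, ms.
#' @return List with \code{sag_amplitude} (mV), \code{sag_ratio} (\%),
#'   \code{v_min}, \code{v_steady} and \code{baseline} (mV).
#' @export
sag_metrics <- function(sweep, steady_ms = 50, blank_ms = 2) {
  on <- sweep_onset(sweep)
  dur <- sweep$meta$dur_ms
  amp <- sweep$meta$amplitude_pA
  if (is.null(dur) || is.null(amp)) {
    stop("sweep metadata lacks dur_ms/amplitude_pA")
  }
  if (amp >= 0) stop("sag_metrics expects a hyperpolarizing step")
  v_base <- baseline_mean(sweep)
  in_step <- sweep$t >= on + blank_ms & sweep$t < on + dur
  v_min <- min(sweep$v[in_step])
  sel <- sweep$t >= on + dur - steady_ms & sweep$t < on + dur
  v_steady <- mean(sweep$v[sel])
  sag_amp <- v_steady - v_min
  list(sag_amplitude = sag_amp,
       sag_ratio = 100 * sag_amp / (v_base - v_min),
       v_min = v_min, v_steady = v_steady, baseline = v_base)
}

#' Capacitance estimate from the charging transient
#'
#' Fits a single exponential \code{V(t) = V_inf + (V0 - V_inf)
#' exp(-(t - onset)/tau)} to the first \code{fit_ms} of the test-pulse
#' response and returns \code{cm = tau / Rin} (pF). In a cell with HCN
#' current the early sag contaminates the fit; the estimate is then accurate
#' only to within roughly 15\%.
#'
#' @param sweep a [rin_pulse()] sweep.
#' @param rin input resistance in MOhm, typically from
#'   [input_resistance()] on the same sweep.
#' @param fit_ms length of the fitted window after pulse onset, ms.
#' @return List with \code{cm_pF}, \code{tau_ms} and \code{converged};
#'   \code{cm_pF} is NA (flagged, with a warning) when the fit fails.
#' @export
estimate_capacitance <- function(sweep, rin = input_resistance(sweep),
                                 fit_ms = 100) {
  on <- sweep_onset(sweep)
  sel <- sweep$t >= on & sweep$t <= on + fit_ms
  t <- sweep$t[sel] - on
  v <- sweep$v[sel]
  v0 <- v[1L]
  vinf <- mean(v[t >= 0.8 * fit_ms])
  span <- v0 - vinf
  if (abs(span) < 0.1) {
    warning("no measurable charging transient; capacitance flagged NA")
    return(list(cm_pF = NA_real_, tau_ms = NA_real_, converged = FALSE))
  }
  # log-linear initialization on the early decay (exact for a pure RC cell)
  y <- (v - vinf) / span
  keep <- which(y > 0.05)
  ll <- stats::lm(log(y[keep]) ~ t[keep])
  tau0 <- -1 / unname(stats::coef(ll)[2L])
  if (!is.finite(tau0) || tau0 <= 0) {
    warning("capacitance fit did not converge; estimate flagged NA")
    return(list(cm_pF = NA_real_, tau_ms = NA_real_, converged = FALSE))
  }
  tau <- tryCatch({
    fit <- stats::nls(v ~ vinf_ + (v0_ - vinf_) * exp(-t / tau_),
                      start = list(vinf_ = vinf, v0_ = v0, tau_ = tau0),
                      control = stats::nls.control(maxiter = 200))
    unname(stats::coef(fit)["tau_"])
  }, error = function(e) tau0) # zero-residual data: keep the log-linear fit
  list(cm_pF = tau / rin * 1000, tau_ms = tau, converged = TRUE)
}

#' Passive-property table of one cell
#'
#' Convenience wrapper running [rmp()], [input_resistance()] and
#' [estimate_capacitance()] on a test-pulse sweep and [sag_metrics()] on
#' every sweep of a sag family.
#'
#' @param rin_sweep a [rin_pulse()] sweep.
#' @param sag_sweeps list of [sag_family()] sweeps (may be empty).
#' @return A one-row data frame with \code{rmp}, \code{rin}, \code{cm_est},
#'   \code{tau_ms} and, per sag sweep, \code{sag_amp_<pA>},
#'   \code{sag_ratio_<pA>} and \code{sag_baseline_<pA>} columns (baselines
#'   are reported so sag comparisons can be checked against resting-potential
#'   differences).
#' @export
passive_features <- function(rin_sweep, sag_sweeps = list()) {
  rin <- input_resistance(rin_sweep)
  cap <- estimate_capacitance(rin_sweep, rin)
  out <- data.frame(rmp = rmp(rin_sweep), rin = rin, cm_est = cap$cm_pF,
                    tau_ms = cap$tau_ms)
  for (sw in sag_sweeps) {
    amp <- abs(sw$meta$amplitude_pA)
    m <- sag_metrics(sw)
    out[[paste0("sag_amp_", amp)]] <- m$sag_amplitude
    out[[paste0("sag_ratio_", amp)]] <- m$sag_ratio
    out[[paste0("sag_baseline_", amp)]] <- m$baseline
  }
  out
}
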
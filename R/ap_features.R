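# Action-potential detection and excitability feature extraction from
# current-clamp sweeps. All sweep-level threshold/latency/rheobase/charge
# measures derive from the first AP of the sweep only, so that cumulative
# Na-channel inactivation during later spikes cannot bias them.

#' Detection settings for action potentials
#'
#' @param peak_floor minimum peak voltage for a candidate AP, mV.
#' @param prominence minimum peak prominence over the flanking troughs, mV.
#' @param min_sep_ms minimum separation between accepted peaks, ms.
#' @param dvdt_threshold depolarization-rate criterion defining the voltage
#'   threshold, mV/ms.
#' @return A list of detection constants used by the feature extractors.
#' @export
ap_detect_config <- function(peak_floor = -10, prominence = 20,
                             min_sep_ms = 1, dvdt_threshold = 5) {
  list(peak_floor = peak_floor, prominence = prominence,
       min_sep_ms = min_sep_ms, dvdt_threshold = dvdt_threshold)
}

#' Detect action potentials in a sweep
#'
#' Local voltage maxima above \code{peak_floor} with prominence of at least
#' \code{prominence} mV over the deepest flanking trough, at least
#' \code{min_sep_ms} apart (the higher peak wins), returned in time order.
#'
#' @param sweep an \code{ep_sweep}.
#' @param config an [ap_detect_config()].
#' @return Integer vector of peak sample indices (empty when no AP).
#' @export
detect_aps <- function(sweep, config = ap_detect_config()) {
  v <- sweep$v
  n <- length(v)
  if (n < 3L) return(integer(0))
  core <- 2:(n - 1L)
  cand <- core[v[core] > v[core - 1L] & v[core] >= v[core + 1L] &
                 v[core] > config$peak_floor]
  if (length(cand) == 0L) return(integer(0))

  # prominence over the lowest point separating the peak from its neighbours
  bounds <- c(1L, cand, n)
  keep <- logical(length(cand))
  for (k in seq_along(cand)) {
    left_min <- min(v[bounds[k]:cand[k]])
    right_min <- min(v[cand[k]:bounds[k + 2L]])
    keep[k] <- (v[cand[k]] - max(left_min, right_min)) >= config$prominence
  }
  cand <- cand[keep]
  if (length(cand) <= 1L) return(cand)

  # debounce: enforce minimum separation, keeping the higher peak
  dt <- sweep_dt(sweep)
  min_gap <- config$min_sep_ms / dt
  out <- cand[1L]
  for (p in cand[-1L]) {
    if (p - out[length(out)] >= min_gap) {
      out <- c(out, p)
    } else if (v[p] > v[out[length(out)]]) {
      out[length(out)] <- p
    }
  }
  out
}

central_dvdt <- function(sweep) {
  v <- sweep$v
  n <- length(v)
  dt <- sweep_dt(sweep)
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (v[2L] - v[1L]) / dt
  d[n] <- (v[n] - v[n - 1L]) / dt
  d
}

#' Voltage threshold of one action potential
#'
#' The threshold is the membrane voltage at which the depolarization rate
#' reaches 5 mV/ms on the spike upstroke. Searching backward from the peak
#' to the preceding voltage minimum, the last upward crossing of
#' \code{dV/dt = dvdt_threshold} is located on the central-difference
#' derivative and the crossing time and voltage are linearly interpolated.
#'
#' @param sweep an \code{ep_sweep}.
#' @param peak_index a peak index from [detect_aps()].
#' @param config an [ap_detect_config()].
#' @return List with \code{threshold} (mV) and \code{threshold_time} (ms).
#'   Throws an error of class \code{drg_no_threshold} when the upstroke never
#'   reaches the rate criterion.
#' @export
ap_threshold <- function(sweep, peak_index, config = ap_detect_config()) {
  v <- sweep$v
  crit <- config$dvdt_threshold
  # walk back to the trough preceding the spike
  j <- peak_index
  while (j > 1L && v[j - 1L] <= v[j]) j <- j - 1L
  lo <- j
  if (peak_index - lo < 1L) {
    stop(structure(class = c("drg_no_threshold", "error", "condition"),
                   list(message = "no upstroke samples before peak",
                        call = sys.call())))
  }
  d <- central_dvdt(sweep)
  idx <- lo:(peak_index - 1L)
  cross <- idx[d[idx] < crit & d[idx + 1L] >= crit]
  if (length(cross) == 0L) {
    if (all(d[lo:peak_index] >= crit)) {
      # already above criterion at the trough: threshold is at the trough
      return(list(threshold = v[lo], threshold_time = sweep$t[lo]))
    }
    stop(structure(class = c("drg_no_threshold", "error", "condition"),
                   list(message = sprintf(
                     "AP upstroke never reaches %g mV/ms", crit),
                     call = sys.call())))
  }
  j <- cross[length(cross)] # last upward crossing before the peak
  f <- (crit - d[j]) / (d[j + 1L] - d[j])
  list(threshold = v[j] + f * (v[j + 1L] - v[j]),
       threshold_time = sweep$t[j] + f * (sweep$t[j + 1L] - sweep$t[j]))
}

cross_time_up <- function(t, y, idx, level) {
  hits <- idx[y[idx] < level & y[idx + 1L] >= level]
  if (length(hits) == 0L) return(NA_real_)
  interp_crossing(t, y, hits[1L], level)
}

cross_time_down <- function(t, y, idx, level) {
  hits <- idx[y[idx] >= level & y[idx + 1L] < level]
  if (length(hits) == 0L) return(NA_real_)
  interp_crossing(t, y, hits[1L], level)
}

#' Waveform measures of one action potential
#'
#' Computes, for the spike at \code{peak_index}: peak time and potential,
#' voltage threshold, amplitude (peak minus threshold), 10--90\% rise time
#' and 90--10\% fall time (between the 10\% and 90\% levels of the
#' threshold-to-peak span, linearly interpolated), maximal upstroke rate, and
#' spike duration measured between the upward and downward crossings of
#' +15 mV (NA when the peak stays below +15 mV).
#'
#' @inheritParams ap_threshold
#' @return A one-row data frame with columns \code{peak_time},
#'   \code{peak_potential}, \code{threshold}, \code{threshold_time},
#'   \code{amplitude}, \code{rise_time_10_90}, \code{fall_time_90_10},
#'   \code{rising_speed}, \code{duration_at_plus15}.
#' @export
ap_waveform_measures <- function(sweep, peak_index,
                                 config = ap_detect_config()) {
  v <- sweep$v; t <- sweep$t
  thr <- ap_threshold(sweep, peak_index, config)
  peak_v <- v[peak_index]
  amp <- peak_v - thr$threshold
  l10 <- thr$threshold + 0.10 * amp
  l90 <- thr$threshold + 0.90 * amp

  # upstroke window: preceding trough -> peak
  j <- peak_index
  while (j > 1L && v[j - 1L] <= v[j]) j <- j - 1L
  up <- j:(peak_index - 1L)
  # downstroke window: peak -> following trough
  k <- peak_index
  n <- length(v)
  while (k < n && v[k + 1L] <= v[k]) k <- k + 1L
  down <- peak_index:max(peak_index, k - 1L)

  t10_up <- cross_time_up(t, v, up, l10)
  t90_up <- cross_time_up(t, v, up, l90)
  t90_dn <- cross_time_down(t, v, down, l90)
  t10_dn <- cross_time_down(t, v, down, l10)

  d <- central_dvdt(sweep)
  rising_speed <- max(d[j:peak_index])

  dur <- NA_real_
  if (peak_v >= 15) {
    t15_up <- cross_time_up(t, v, up, 15)
    t15_dn <- cross_time_down(t, v, down, 15)
    dur <- t15_dn - t15_up
  }

  data.frame(peak_time = t[peak_index], peak_potential = peak_v,
             threshold = thr$threshold, threshold_time = thr$threshold_time,
             amplitude = amp,
             rise_time_10_90 = t90_up - t10_up,
             fall_time_90_10 = t10_dn - t90_dn,
             rising_speed = rising_speed,
             duration_at_plus15 = dur)
}

# Stimulus onset for latency/charge windows; ramp sweeps use the ramp fields.
sweep_onset <- function(sweep) {
  on <- sweep$meta$onset_ms
  if (is.null(on)) stop("sweep metadata lacks onset_ms")
  on
}

is_ramp_sweep <- function(sweep) {
  identical(sweep$meta$protocol, "ramp") ||
    !is.null(sweep$meta$ramp_slope)
}

#' Count action potentials within the protocol's counting window
#'
#' Step sweeps count every AP whose peak falls inside the current step; ramp
#' sweeps count only APs whose peak occurs within the first
#' \code{window_ms} (default 2000 ms) from the beginning of the rising ramp.
#'
#' @param sweep an \code{ep_sweep}.
#' @param peaks optional precomputed [detect_aps()] result.
#' @param window_ms ramp counting window, ms.
#' @param config an [ap_detect_config()].
#' @return Integer AP count.
#' @export
count_aps <- function(sweep, peaks = detect_aps(sweep, config),
                      window_ms = 2000, config = ap_detect_config()) {
  if (length(peaks) == 0L) return(0L)
  tp <- sweep$t[peaks]
  if (is_ramp_sweep(sweep)) {
    start <- sweep$meta$ramp_start_ms
    if (is.null(start)) stop("ramp sweep metadata lacks ramp_start_ms")
    sum(tp <= start + window_ms)
  } else {
    on <- sweep_onset(sweep)
    dur <- sweep$meta$dur_ms
    if (is.null(dur)) dur <- max(sweep$t) - on
    sum(tp >= on & tp <= on + dur)
  }
}

#' First inter-AP interval
#'
#' Peak-to-peak time between the first and second action potentials;
#' \code{NA} when fewer than two APs were fired.
#'
#' @inheritParams count_aps
#' @export
first_isi <- function(sweep, peaks = detect_aps(sweep, config),
                      config = ap_detect_config()) {
  if (length(peaks) < 2L) return(NA_real_)
  sweep$t[peaks[2L]] - sweep$t[peaks[1L]]
}

#' Latency from stimulus onset to the first AP threshold
#'
#' @inheritParams count_aps
#' @return Latency in ms, or \code{NA} when the sweep has no AP.
#' @export
ap_latency <- function(sweep, peaks = detect_aps(sweep, config),
                       config = ap_detect_config()) {
  if (length(peaks) == 0L) return(NA_real_)
  thr <- ap_threshold(sweep, peaks[1L], config)
  thr$threshold_time - sweep_onset(sweep)
}

#' Ramp rheobase
#'
#' The injected current at the first AP's threshold time, relative to the
#' 0 pA pre-stimulus baseline. The capacitance-normalized rheobase (pA/pF)
#' is returned alongside when the sweep metadata carries \code{cm}.
#'
#' @inheritParams count_aps
#' @return List with \code{rheobase} (pA) and \code{rheobase_norm} (pA/pF,
#'   NA without capacitance metadata); both NA when no AP was fired.
#' @export
rheobase_ramp <- function(sweep, peaks = detect_aps(sweep, config),
                          config = ap_detect_config()) {
  if (!is_ramp_sweep(sweep)) stop("rheobase_ramp expects a ramp sweep")
  if (length(peaks) == 0L) {
    return(list(rheobase = NA_real_, rheobase_norm = NA_real_))
  }
  thr <- ap_threshold(sweep, peaks[1L], config)
  i_at <- interp_at(sweep$t, sweep$i, thr$threshold_time)
  cm <- sweep$meta$cm
  list(rheobase = i_at,
       rheobase_norm = if (is.null(cm)) NA_real_ else i_at / cm)
}

#' Rheobase charge transfer
#'
#' Trapezoidal integral of the injected current from the stimulus onset
#' (step sweeps) or from the time the ramp current crosses the 0 pA baseline
#' (ramp sweeps) to the first AP's threshold time, in pC.
#'
#' @inheritParams count_aps
#' @return Charge in pC, or \code{NA} when the sweep has no AP (or, for a
#'   ramp, when the first AP precedes the baseline crossing).
#' @export
charge_transfer <- function(sweep, peaks = detect_aps(sweep, config),
                            config = ap_detect_config()) {
  if (length(peaks) == 0L) return(NA_real_)
  thr <- ap_threshold(sweep, peaks[1L], config)
  t0 <- if (is_ramp_sweep(sweep)) {
    bc <- sweep$meta$baseline_cross_ms
    if (is.null(bc)) stop("ramp sweep metadata lacks baseline_cross_ms")
    bc
  } else {
    sweep_onset(sweep)
  }
  t1 <- thr$threshold_time
  if (t1 <= t0) return(NA_real_)
  inside <- sweep$t > t0 & sweep$t < t1
  tt <- c(t0, sweep$t[inside], t1)
  ii <- c(interp_at(sweep$t, sweep$i, t0), sweep$i[inside],
          interp_at(sweep$t, sweep$i, t1))
  trapz(tt, ii) / 1000
}

#' Phase-plane trajectory of a sweep segment
#'
#' @param sweep an \code{ep_sweep}.
#' @param window optional \code{c(t0, t1)} time window, ms (defaults to the
#'   whole sweep).
#' @return Data frame with columns \code{v} (mV) and \code{dvdt} (mV/ms),
#'   ordered in time. The voltage threshold of [ap_threshold()] is the V
#'   coordinate at which this trajectory crosses the 5 mV/ms level on the
#'   upstroke.
#' @export
phase_plot <- function(sweep, window = NULL) {
  d <- central_dvdt(sweep)
  keep <- if (is.null(window)) {
    rep(TRUE, length(sweep$t))
  } else {
    sweep$t >= window[1L] & sweep$t <= window[2L]
  }
  data.frame(v = sweep$v[keep], dvdt = d[keep])
}

#' All excitability features of one sweep
#'
#' Applies the first-AP-only policy: threshold, latency, rheobase and charge
#' transfer always derive from the sweep's first action potential.
#'
#' @inheritParams count_aps
#' @return A one-row data frame: \code{n_aps}, \code{latency},
#'   \code{first_isi}, \code{rheobase}, \code{rheobase_norm},
#'   \code{charge_transfer}, plus the first AP's waveform measures (NA-filled
#'   when the sweep has no AP). The full per-AP table is attached as the
#'   \code{"per_ap"} attribute.
#' @export
sweep_features <- function(sweep, config = ap_detect_config()) {
  peaks <- detect_aps(sweep, config)
  # keep the per-AP table consistent with the protocol's counting window
  # (step: APs peaking during the step; ramp: first 2 s of the ramp)
  if (length(peaks) > 0L) {
    tp <- sweep$t[peaks]
    if (is_ramp_sweep(sweep)) {
      start <- sweep$meta$ramp_start_ms
      if (!is.null(start)) peaks <- peaks[tp <= start + 2000]
    } else if (!is.null(sweep$meta$onset_ms)) {
      on <- sweep$meta$onset_ms
      dur <- sweep$meta$dur_ms
      if (is.null(dur)) dur <- max(sweep$t) - on
      peaks <- peaks[tp >= on & tp <= on + dur]
    }
  }
  n <- length(peaks)
  wf_na <- data.frame(peak_time = NA_real_, peak_potential = NA_real_,
                      threshold = NA_real_, threshold_time = NA_real_,
                      amplitude = NA_real_, rise_time_10_90 = NA_real_,
                      fall_time_90_10 = NA_real_, rising_speed = NA_real_,
                      duration_at_plus15 = NA_real_)
  per_ap <- if (n > 0) {
    do.call(rbind, lapply(peaks, function(p) {
      ap_waveform_measures(sweep, p, config)
    }))
  } else {
    wf_na[0, ]
  }
  ramp <- is_ramp_sweep(sweep)
  rheo <- if (ramp) rheobase_ramp(sweep, peaks, config) else {
    list(rheobase = NA_real_, rheobase_norm = NA_real_)
  }
  out <- cbind(
    data.frame(n_aps = count_aps(sweep, peaks, config = config),
               latency = if (ramp) NA_real_ else ap_latency(sweep, peaks, config),
               first_isi = first_isi(sweep, peaks, config),
               rheobase = rheo$rheobase,
               rheobase_norm = rheo$rheobase_norm,
               charge_transfer = charge_transfer(sweep, peaks, config)),
    if (n > 0) per_ap[1L, , drop = FALSE] else wf_na
  )
  rownames(out) <- NULL
  attr(out, "per_ap") <- per_ap
  out
}
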
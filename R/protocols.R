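# Current-clamp stimulus protocols. Each sweep is a contiguous sequence of
# piecewise-linear segments (t0, t1, i0, i1) in ms and pA, starting and
# ending at the 0 pA baseline.

new_protocol <- function(name, sweeps, pre_ms, post_ms) {
  structure(list(name = name, sweeps = sweeps, pre_ms = pre_ms,
                 post_ms = post_ms),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat("<stim_protocol> ", x$name, ": ", length(x$sweeps), " sweep(s), ",
      "baseline ", x$pre_ms, " ms, tail ", x$post_ms, " ms\n", sep = "")
  invisible(x)
}

seg <- function(t0, t1, i0, i1 = i0) {
  matrix(c(t0, t1, i0, i1), nrow = 1,
         dimnames = list(NULL, c("t0", "t1", "i0", "i1")))
}

#' Depolarizing step-current family
#'
#' Six 600 ms depolarizing steps from 25 to 150 pA in 25 pA increments, the
#' protocol used to count step-evoked action potentials and measure latency,
#' threshold, first inter-spike interval and charge transfer.
#'
#' @param amplitudes step amplitudes, pA.
#' @param step_ms step duration, ms.
#' @param pre_ms zero-current baseline before the step, ms.
#' @param post_ms zero-current tail after the step, ms.
#' @return A \code{stim_protocol} with one sweep per amplitude; each sweep's
#'   \code{meta} records \code{onset_ms}, \code{dur_ms} and
#'   \code{amplitude_pA}.
#' @export
step_family <- function(amplitudes = seq(25, 150, by = 25), step_ms = 600,
                        pre_ms = 200, post_ms = 200) {
  sweeps <- lapply(amplitudes, function(a) {
    list(
      segments = rbind(seg(0, pre_ms, 0),
                       seg(pre_ms, pre_ms + step_ms, a),
                       seg(pre_ms + step_ms, pre_ms + step_ms + post_ms, 0)),
      meta = list(onset_ms = pre_ms, dur_ms = step_ms, amplitude_pA = a)
    )
  })
  new_protocol("step_family", sweeps, pre_ms, post_ms)
}

#' Ramp-current injection with hyperpolarizing onset
#'
#' A single sweep: a hyperpolarizing plateau followed by a slow linear ramp
#' (0.1 pA/ms by default) that rises from the plateau level, crosses the
#' 0 pA baseline and continues beyond 250 pA above baseline. Used for ramp
#' rheobase, ramp threshold and the 2 s ramp AP count.
#'
#' @param slope ramp slope, pA/ms.
#' @param onset_pA hyperpolarizing plateau amplitude, pA (negative).
#' @param onset_ms plateau duration, ms.
#' @param ramp_ms ramp duration, ms.
#' @param pre_ms,post_ms zero-current baseline and tail, ms.
#' @return A \code{stim_protocol} with a single sweep whose \code{meta}
#'   records the ramp start time, slope, plateau level and the closed-form
#'   time at which the ramp crosses the 0 pA baseline.
#' @export
ramp_protocol <- function(slope = 0.1, onset_pA = -50, onset_ms = 500,
                          ramp_ms = 3100, pre_ms = 200, post_ms = 100) {
  stopifnot(slope > 0, onset_pA < 0)
  ramp_start <- pre_ms + onset_ms
  ramp_end <- ramp_start + ramp_ms
  i_end <- onset_pA + slope * ramp_ms
  sweeps <- list(list(
    segments = rbind(seg(0, pre_ms, 0),
                     seg(pre_ms, ramp_start, onset_pA),
                     seg(ramp_start, ramp_end, onset_pA, i_end),
                     seg(ramp_end, ramp_end + post_ms, 0)),
    meta = list(onset_ms = pre_ms, ramp_start_ms = ramp_start,
                ramp_slope = slope, onset_pA = onset_pA,
                baseline_cross_ms = ramp_start - onset_pA / slope)
  ))
  new_protocol("ramp", sweeps, pre_ms, post_ms)
}

#' Hyperpolarizing step family for voltage sag
#'
#' Six 600 ms hyperpolarizing steps from -50 to -100 pA in -10 pA
#' increments, used to quantify HCN-mediated voltage sag.
#'
#' @inheritParams step_family
#' @export
sag_family <- function(amplitudes = seq(-50, -100, by = -10), step_ms = 600,
                       pre_ms = 200, post_ms = 200) {
  stopifnot(all(amplitudes < 0))
  p <- step_family(amplitudes = amplitudes, step_ms = step_ms,
                   pre_ms = pre_ms, post_ms = post_ms)
  p$name <- "sag_family"
  p
}

#' Input-resistance test pulse
#'
#' A -50 pA, 500 ms pulse; with \code{repeats > 1} the pulse recurs every
#' 5 s (start-to-start), as delivered experimentally. The simulated cell is
#' stationary, so a single pulse is the default.
#'
#' @param amplitude pulse amplitude, pA.
#' @param dur_ms pulse duration, ms.
#' @param repeats number of pulses.
#' @param interval_ms start-to-start interval between pulses, ms.
#' @param pre_ms,post_ms zero-current baseline and tail, ms.
#' @export
rin_pulse <- function(amplitude = -50, dur_ms = 500, repeats = 1,
                      interval_ms = 5000, pre_ms = 200, post_ms = 200) {
  stopifnot(repeats >= 1)
  segs <- seg(0, pre_ms, 0)
  for (k in seq_len(repeats)) {
    start <- pre_ms + (k - 1) * interval_ms
    segs <- rbind(segs, seg(start, start + dur_ms, amplitude))
    gap_end <- if (k < repeats) pre_ms + k * interval_ms else start + dur_ms + post_ms
    segs <- rbind(segs, seg(start + dur_ms, gap_end, 0))
  }
  sweeps <- list(list(
    segments = segs,
    meta = list(onset_ms = pre_ms, dur_ms = dur_ms, amplitude_pA = amplitude,
                repeats = repeats, interval_ms = interval_ms)
  ))
  new_protocol("rin_pulse", sweeps, pre_ms, post_ms)
}

#' Sample a protocol's injected current on a uniform grid
#'
#' @param protocol a \code{stim_protocol}.
#' @param dt sampling interval, ms.
#' @return A list of data frames (one per sweep) with columns \code{time_ms}
#'   and \code{i_pA}.
#' @export
sample_protocol <- function(protocol, dt = 0.025) {
  stopifnot(inherits(protocol, "stim_protocol"), dt > 0)
  lapply(protocol$sweeps, function(sw) {
    segs <- sw$segments
    tend <- segs[nrow(segs), "t1"]
    t <- seq(0, tend, by = dt)
    data.frame(time_ms = t, i_pA = stim_current(segs, t))
  })
}

# Evaluate the piecewise-linear stimulus at arbitrary times. At a
# discontinuity the right (incoming) segment wins, matching the integrator.
stim_current <- function(segments, t) {
  i <- numeric(length(t))
  for (r in rev(seq_len(nrow(segments)))) {
    t0 <- segments[r, "t0"]; t1 <- segments[r, "t1"]
    i0 <- segments[r, "i0"]; i1 <- segments[r, "i1"]
    inside <- if (r == nrow(segments)) t >= t0 & t <= t1 else t >= t0 & t < t1
    i[inside] <- if (t1 > t0) {
      i0 + (i1 - i0) * (t[inside] - t0) / (t1 - t0)
    } else {
      i0
    }
  }
  i
}

#' Closed-form charge of every sweep of a protocol
#'
#' @param protocol a \code{stim_protocol}.
#' @return Numeric vector, one charge (pC) per sweep, from the exact
#'   piecewise-linear segment areas.
#' @export
protocol_charge <- function(protocol) {
  vapply(protocol$sweeps, function(sw) {
    segs <- sw$segments
    sum((segs[, "i0"] + segs[, "i1"]) / 2 * (segs[, "t1"] - segs[, "t0"])) / 1000
  }, numeric(1))
}
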
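#' @useDynLib drgephys, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.channel_kinds <- c(leak = 0L, na = 1L, kdr = 2L, hcn = 3L, km = 4L)

#' Ion-channel specification
#'
#' Describes one membrane current of the single-compartment model: a maximal
#' conductance, a reversal potential and a fixed-form gating scheme. Supported
#' kinds are \code{"leak"} (ohmic, no gates), \code{"na"} (transient sodium,
#' m^3 h, Hodgkin-Huxley rate functions with a voltage shift and a rate
#' scale), \code{"kdr"} (delayed-rectifier potassium, n^4), \code{"hcn"}
#' (hyperpolarization-activated cation current Ih, single activation gate with
#' a sigmoid steady state and a bell-shaped time constant) and \code{"km"}
#' (M-type potassium current carried by Kv7 channels, single slow gate).
#'
#' Units are mV for voltages, nS for conductances and ms for time constants
#' throughout the package.
#'
#' @param name channel label (any string; \code{"leak"} and \code{"hcn"} are
#'   meaningful to [neuron_params()] validation).
#' @param kind one of \code{"leak"}, \code{"na"}, \code{"kdr"}, \code{"hcn"},
#'   \code{"km"}.
#' @param gbar maximal conductance in nS (\code{>= 0}).
#' @param erev reversal potential in mV.
#' @param params named numeric vector of kinetic parameters; see Details.
#'
#' @details Kinetic parameters by kind: \code{na}/\code{kdr} take
#'   \code{vshift_m}, \code{vshift_h} (independent shifts of activation and
#'   inactivation along the voltage axis; \code{kdr} takes a single
#'   \code{vshift}) and \code{rate_scale} (multiplies all rates);
#'   \code{hcn} takes \code{frac}, \code{vhalf1}, \code{k1},
#'   \code{vhalf2}, \code{k2} (steady-state activation is the mixture
#'   \code{frac * B(vhalf1, k1) + (1 - frac) * B(vhalf2, k2)} of two
#'   Boltzmann components, both increasing with hyperpolarization, standing
#'   for the shallow HCN1-like and steep HCN4-like channel populations of
#'   DRG neurons) and \code{tau_min}, \code{tau_amp}, \code{tau_vmax},
#'   \code{tau_width} (time constant \code{tau_min + tau_amp /
#'   cosh((V - tau_vmax)/tau_width)} in ms); \code{km} takes \code{vhalf},
#'   \code{k}, \code{tau_ms}.
#' @return An object of class \code{channel_spec}.
#' @seealso [gating_curves()], [neuron_params()]
#' @export
channel_spec <- function(name, kind, gbar, erev, params = numeric(0)) {
  kind <- match.arg(kind, names(.channel_kinds))
  stopifnot(is.numeric(gbar), length(gbar) == 1L, is.finite(gbar),
            is.numeric(erev), length(erev) == 1L, is.finite(erev))
  if (gbar < 0) stop("gbar must be >= 0 (got ", gbar, " nS)")
  ch <- structure(
    list(name = as.character(name), kind = kind, gbar = gbar, erev = erev,
         params = params),
    class = "channel_spec"
  )
  validate_channel_spec(ch)
  ch
}

.channel_param_order <- list(
  leak = character(0),
  na = c("vshift_m", "vshift_h", "rate_scale"),
  kdr = c("vshift", "rate_scale"),
  hcn = c("frac", "vhalf1", "k1", "vhalf2", "k2", "tau_min", "tau_amp",
          "tau_vmax", "tau_width"),
  km = c("vhalf", "k", "tau_ms")
)

# Ordered kinetic parameter vector handed to the C++ integrator.
channel_param_vector <- function(ch) {
  want <- .channel_param_order[[ch$kind]]
  if (length(want) == 0L) return(numeric(0))
  missing <- setdiff(want, names(ch$params))
  if (length(missing)) {
    stop("channel '", ch$name, "' is missing kinetic parameter(s): ",
         paste(missing, collapse = ", "))
  }
  unname(ch$params[want])
}

validate_channel_spec <- function(ch, v = seq(-120, 60, by = 1)) {
  g <- gating_curves(ch, v)
  if (nrow(g) > 0) {
    if (any(!is.finite(g$inf)) || any(g$inf < 0 | g$inf > 1)) {
      stop("channel '", ch$name,
           "': steady-state activation outside [0, 1] on [-120, 60] mV")
    }
    if (any(!is.finite(g$tau)) || any(g$tau <= 0)) {
      stop("channel '", ch$name,
           "': non-positive gating time constant on [-120, 60] mV")
    }
  }
  invisible(ch)
}

#' Steady-state activation and time constant of a channel's gates
#'
#' @param channel a [channel_spec()].
#' @param v voltages (mV) at which to evaluate the gating functions.
#' @return A data frame with columns \code{gate} (index), \code{v},
#'   \code{inf} (dimensionless steady state) and \code{tau} (ms). Zero rows
#'   for a gateless (leak) channel.
#' @export
gating_curves <- function(channel, v = seq(-120, 60, by = 1)) {
  stopifnot(inherits(channel, "channel_spec"))
  out <- cpp_gating(.channel_kinds[[channel$kind]],
                    channel_param_vector(channel), as.numeric(v))
  ng <- nrow(out$inf)
  if (ng == 0L) {
    return(data.frame(gate = integer(0), v = numeric(0), inf = numeric(0),
                      tau = numeric(0)))
  }
  data.frame(
    gate = rep(seq_len(ng), times = length(v)),
    v = rep(as.numeric(v), each = ng),
    inf = as.numeric(out$inf),
    tau = as.numeric(out$tau)
  )
}

#' Default model parameters for a virtual DRG neuron
#'
#' The defaults describe a tonically firing small/medium DRG neuron at
#' near-physiological temperature: a 25 pF membrane with leak, transient Na,
#' delayed-rectifier K, HCN (Ih) and a small M-type K conductance. They are
#' calibrated so that (with no cell-to-cell variability) the wild-type cell
#' rests near -60 mV, stays silent at a 25 pA / 600 ms step, fires tonically
#' from 50 pA upward, and expresses a clear voltage sag on hyperpolarizing
#' steps; the knockout preset differs only in its HCN maximal conductance.
#'
#' @param cm membrane capacitance, pF.
#' @param g_leak,e_leak leak conductance (nS) and reversal (mV).
#' @param g_na,g_kdr,g_hcn,g_km maximal conductances, nS.
#' @param e_na,e_k,e_hcn reversal potentials, mV. The HCN reversal is placed
#'   close to rest so that Ih acts mainly as a resting-conductance shunt (its
#'   inward driving force grows with hyperpolarization, producing sag), the
#'   regime implicated in DRG neurons.
#' @param na_vshift_m,na_vshift_h,kdr_vshift voltage shifts of the Na
#'   activation, Na inactivation and delayed-rectifier kinetics, mV.
#' @param rate_scale multiplier on Na/K rate functions.
#' @param hcn_frac weight of the shallow depolarized HCN activation
#'   component.
#' @param hcn_vhalf1,hcn_k1,hcn_vhalf2,hcn_k2 midpoints and slopes (mV) of
#'   the two HCN activation components.
#' @param hcn_tau_min,hcn_tau_amp,hcn_tau_vmax,hcn_tau_width HCN time-constant
#'   parameters (ms, ms, mV, mV).
#' @param km_vhalf,km_k,km_tau M-current activation midpoint/slope (mV) and
#'   time constant (ms).
#' @return A named list of defaults consumed by [make_genotype()].
#' @export
default_model_params <- function(cm = 25,
                                 g_leak = 3, e_leak = -63.4,
                                 g_na = 2500, e_na = 60,
                                 g_kdr = 700, e_k = -90,
                                 g_hcn = 16, e_hcn = -62.9,
                                 g_km = 1.0,
                                 na_vshift_m = 11.5, na_vshift_h = 25,
                                 kdr_vshift = 25,
                                 rate_scale = 2.5,
                                 hcn_frac = 0.42,
                                 hcn_vhalf1 = -55, hcn_k1 = 9,
                                 hcn_vhalf2 = -63.5, hcn_k2 = 1.5,
                                 hcn_tau_min = 60, hcn_tau_amp = 240,
                                 hcn_tau_vmax = -80, hcn_tau_width = 15,
                                 km_vhalf = -35, km_k = 10, km_tau = 100) {
  as.list(environment())
}

#' Assemble a virtual neuron from capacitance and channel list
#'
#' @param cm membrane capacitance, pF (> 0).
#' @param channels list of [channel_spec()] objects; exactly one must be of
#'   kind \code{"leak"} and exactly one of kind \code{"hcn"} (its gbar may be
#'   zero).
#' @param label genotype tag, \code{"WT"} or \code{"KO"}.
#' @param drug condition tag: \code{"none"}, \code{"ZD7288"} or
#'   \code{"XE991"}.
#' @return An object of class \code{neuron_params}.
#' @export
neuron_params <- function(cm, channels, label = "WT", drug = "none") {
  stopifnot(is.numeric(cm), length(cm) == 1L, is.finite(cm))
  if (cm <= 0) stop("cm must be > 0 (got ", cm, " pF)")
  label <- match.arg(label, c("WT", "KO"))
  drug <- match.arg(drug, c("none", "ZD7288", "XE991"))
  if (!all(vapply(channels, inherits, logical(1), "channel_spec"))) {
    stop("channels must be a list of channel_spec objects")
  }
  kinds <- vapply(channels, `[[`, character(1), "kind")
  if (sum(kinds == "leak") != 1L) stop("exactly one leak channel is required")
  if (sum(kinds == "hcn") != 1L) stop("exactly one HCN channel is required")
  names(channels) <- vapply(channels, `[[`, character(1), "name")
  structure(list(cm = cm, channels = channels, label = label, drug = drug),
            class = "neuron_params")
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> ", x$label,
      if (x$drug != "none") paste0(" + ", x$drug), "\n", sep = "")
  cat("  cm: ", x$cm, " pF\n", sep = "")
  for (ch in x$channels) {
    cat(sprintf("  %-5s (%s): gbar = %.4g nS, erev = %g mV\n",
                ch$name, ch$kind, ch$gbar, ch$erev))
  }
  invisible(x)
}

build_neuron <- function(p, label = "WT", hcn_scale = 1) {
  channels <- list(
    channel_spec("leak", "leak", p$g_leak, p$e_leak),
    channel_spec("na", "na", p$g_na, p$e_na,
                 c(vshift_m = p$na_vshift_m, vshift_h = p$na_vshift_h,
                   rate_scale = p$rate_scale)),
    channel_spec("kdr", "kdr", p$g_kdr, p$e_k,
                 c(vshift = p$kdr_vshift, rate_scale = p$rate_scale)),
    channel_spec("hcn", "hcn", p$g_hcn * hcn_scale, p$e_hcn,
                 c(frac = p$hcn_frac, vhalf1 = p$hcn_vhalf1, k1 = p$hcn_k1,
                   vhalf2 = p$hcn_vhalf2, k2 = p$hcn_k2,
                   tau_min = p$hcn_tau_min, tau_amp = p$hcn_tau_amp,
                   tau_vmax = p$hcn_tau_vmax, tau_width = p$hcn_tau_width)),
    channel_spec("km", "km", p$g_km, p$e_k,
                 c(vhalf = p$km_vhalf, k = p$km_k, tau_ms = p$km_tau))
  )
  neuron_params(p$cm, channels, label = label)
}

#' Genotype presets with cell-to-cell variability
#'
#' Builds a wild-type (WT) or Fmr1-knockout (KO) virtual neuron. The KO
#' preset is identical to WT except for its HCN maximal conductance, scaled
#' by \code{ko_hcn_ratio} (default 40\% of WT), encoding the hypothesis that
#' reduced HCN channel expression is the sole intrinsic difference between
#' genotypes. Cell-to-cell variability multiplies every maximal conductance
#' by an independent lognormal factor with unit mean and coefficient of
#' variation \code{variability_cv}; capacitance is held fixed.
#'
#' @param genotype \code{"WT"} or \code{"KO"}.
#' @param variability_cv coefficient of variation of the lognormal
#'   conductance factors (\code{>= 0}; 0 returns the exact preset).
#' @param cm_cv coefficient of variation of the lognormal capacitance
#'   (cell-size) factor; capacitance scatter is shared by both genotypes and
#'   does not differ in mean. Ignored when \code{variability_cv} is 0.
#' @param e_leak_sd SD (mV) of a Gaussian per-cell offset on the leak
#'   reversal potential, representing the resting-potential scatter real
#'   cohorts show (ionic background and junction-potential variation);
#'   identical for both genotypes. Ignored when \code{variability_cv} is 0.
#' @param seed integer seed for the variability draw (required when
#'   \code{variability_cv > 0}); the draw is deterministic given the seed.
#' @param ko_hcn_ratio KO HCN conductance as a fraction of WT.
#' @param model base parameter set, see [default_model_params()].
#' @return A [neuron_params()] object.
#' @examples
#' wt <- make_genotype("WT")
#' ko <- make_genotype("KO")
#' ko$channels$hcn$gbar / wt$channels$hcn$gbar  # 0.4
#' @export
make_genotype <- function(genotype = c("WT", "KO"), variability_cv = 0,
                          seed = NULL, ko_hcn_ratio = 0.4, cm_cv = 0.15,
                          e_leak_sd = 1.5, model = default_model_params()) {
  genotype <- match.arg(genotype)
  stopifnot(variability_cv >= 0, ko_hcn_ratio > 0)
  cell <- build_neuron(model, label = genotype,
                       hcn_scale = if (genotype == "KO") ko_hcn_ratio else 1)
  if (variability_cv > 0) {
    if (is.null(seed)) stop("seed is required when variability_cv > 0")
    sdlog <- sqrt(log(1 + variability_cv^2))
    sdlog_cm <- sqrt(log(1 + cm_cv^2))
    draws <- with_seed(seed, {
      list(g = stats::rlnorm(length(cell$channels),
                             meanlog = -sdlog^2 / 2, sdlog = sdlog),
           cm = stats::rlnorm(1, meanlog = -sdlog_cm^2 / 2,
                              sdlog = sdlog_cm),
           el = stats::rnorm(1, 0, 1))
    })
    for (k in seq_along(cell$channels)) {
      cell$channels[[k]]$gbar <- cell$channels[[k]]$gbar * draws$g[k]
      if (cell$channels[[k]]$kind == "leak") {
        cell$channels[[k]]$erev <- cell$channels[[k]]$erev +
          e_leak_sd * draws$el
      }
    }
    cell$cm <- cell$cm * draws$cm
  }
  cell
}

#' Emulate bath application of a channel blocker
#'
#' \code{"ZD7288"} (pan-HCN blocker) zeroes the HCN conductance;
#' \code{"XE991"} (Kv7/M-current blocker) zeroes every M-type conductance;
#' \code{"none"} returns the cell with the drug tag cleared. All other
#' parameters are untouched.
#'
#' @param params a [neuron_params()] object.
#' @param drug \code{"none"}, \code{"ZD7288"} or \code{"XE991"}.
#' @return A modified copy of \code{params} with the drug tag set.
#' @export
apply_drug <- function(params, drug = c("none", "ZD7288", "XE991")) {
  stopifnot(inherits(params, "neuron_params"))
  drug <- match.arg(drug)
  target <- switch(drug, none = NULL, ZD7288 = "hcn", XE991 = "km")
  if (!is.null(target)) {
    for (k in seq_along(params$channels)) {
      if (params$channels[[k]]$kind == target) params$channels[[k]]$gbar <- 0
    }
  }
  params$drug <- drug
  params
}

#' Integration settings
#'
#' @param dt integration step, ms.
#' @param record_dt output sampling interval, ms; must be an integer multiple
#'   of \code{dt}. The default 0.025 ms corresponds to 40 kHz acquisition.
#' @param v_init initial voltage, mV.
#' @param settle_ms pre-stimulus equilibration with zero current, ms; at
#'   least 500 ms because HCN gating is slow.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(dt = 0.025, record_dt = dt, v_init = -60,
                       settle_ms = 1000) {
  stopifnot(dt > 0, record_dt >= dt)
  ratio <- record_dt / dt
  if (abs(ratio - round(ratio)) > 1e-8) {
    stop("record_dt must be an integer multiple of dt")
  }
  if (settle_ms < 500) stop("settle_ms must be >= 500 ms (HCN gating is slow)")
  structure(list(dt = dt, record_dt = record_dt, v_init = v_init,
                 settle_ms = settle_ms, record_every = as.integer(round(ratio))),
            class = "sim_config")
}

#' Simulate current-clamp sweeps
#'
#' Integrates the membrane equation \code{cm dV/dt = -sum(I_chan) + I_inj}
#' for every sweep of a stimulus protocol, after settling the cell at zero
#' current. Gating variables are advanced by exponential Euler; the voltage
#' uses the exact exponential update of the instantaneously linear membrane
#' equation. Integration is fully deterministic.
#'
#' @param params a [neuron_params()] object.
#' @param protocol a [stim_protocol] object (see [step_family()] and
#'   friends).
#' @param config a [sim_config()].
#' @return A list of \code{ep_sweep} objects, one per stimulus sweep, each
#'   with uniform sample times \code{t} (ms), voltage \code{v} (mV), injected
#'   current \code{i} (pA) and a \code{meta} list carrying genotype, drug,
#'   protocol name, stimulus timing and the post-settling dV/dt.
#' @export
simulate_sweeps <- function(params, protocol, config = sim_config()) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "stim_protocol"),
            inherits(config, "sim_config"))
  kinds <- vapply(params$channels, function(ch) .channel_kinds[[ch$kind]],
                  integer(1))
  gbars <- vapply(params$channels, `[[`, numeric(1), "gbar")
  erevs <- vapply(params$channels, `[[`, numeric(1), "erev")
  pvecs <- lapply(params$channels, channel_param_vector)
  lapply(seq_along(protocol$sweeps), function(s) {
    sw <- protocol$sweeps[[s]]
    res <- tryCatch(
      cpp_simulate(params$cm, kinds, gbars, erevs, pvecs, sw$segments,
                   config$dt, config$record_every, config$v_init,
                   config$settle_ms),
      error = function(e) {
        stop("sweep ", s, " of protocol '", protocol$name, "': ",
             conditionMessage(e), call. = FALSE)
      }
    )
    if (is.finite(res$post_settle_dvdt) &&
        abs(res$post_settle_dvdt) > 0.01) {
      warning("sweep ", s, ": |dV/dt| = ",
              signif(abs(res$post_settle_dvdt), 3),
              " mV/ms after settling; increase settle_ms")
    }
    meta <- c(sw$meta,
              list(protocol = protocol$name, genotype = params$label,
                   drug = params$drug, cm = params$cm, dt = config$record_dt,
                   sweep = s, post_settle_dvdt = res$post_settle_dvdt))
    new_sweep(res$t, res$v, res$i, meta)
  })
}

#' Purely passive reference cell
#'
#' A neuron with only the leak conductance (all active channels present but
#' zeroed), for which input resistance, membrane time constant and resting
#' potential have closed forms: \code{Rin = 1/g_leak}, \code{tau = cm/g_leak},
#' \code{RMP = e_leak}. Used as the analytic oracle in tests and examples.
#'
#' @param cm capacitance, pF.
#' @param g_leak leak conductance, nS.
#' @param e_leak leak reversal, mV.
#' @return A [neuron_params()] object.
#' @export
passive_neuron <- function(cm = 25, g_leak = 2, e_leak = -65) {
  p <- default_model_params(cm = cm, g_leak = g_leak, e_leak = e_leak)
  p$g_na <- 0; p$g_kdr <- 0; p$g_hcn <- 0; p$g_km <- 0
  build_neuron(p, label = "WT")
}
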
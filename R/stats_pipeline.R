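# Cohort-level virtual experiments and group statistics: mean +/- SEM and
# Student's t-test per feature, mirroring the per-step comparison structure
# of the electrophysiology figures.

#' Two-sample Student's t-test with degenerate-input conventions
#'
#' Pooled-variance (default) or Welch two-sided t-test, reported as mean
#' +/- SEM per group. Zero pooled variance is handled by convention: equal
#' means give p = 1, unequal means give p = 0.
#'
#' @param a,b numeric vectors (NA values are dropped; n >= 2 each).
#' @param var_equal pooled variance (Student) when TRUE, Welch otherwise.
#' @param alpha significance level for the \code{significant} flag.
#' @param feature,labels optional annotation carried into the result.
#' @return An object of class \code{group_comparison}: feature, labels, n,
#'   means, SEMs, t, df, p and the significance flag.
#' @export
ttest_groups <- function(a, b, var_equal = TRUE, alpha = 0.05,
                         feature = NA_character_, labels = c("A", "B")) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 non-missing values")
  }
  sems <- c(stats::sd(a) / sqrt(length(a)), stats::sd(b) / sqrt(length(b)))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    t <- if (equal) 0 else Inf
    p <- if (equal) 1 else 0
    df <- length(a) + length(b) - 2L
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    t <- unname(ht$statistic)
    df <- unname(ht$parameter)
    p <- ht$p.value
  }
  structure(list(feature = feature, labels = labels,
                 n = c(length(a), length(b)), mean = c(mean(a), mean(b)),
                 sem = sems, t = t, df = df, p = p,
                 significant = is.finite(p) && p < alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison>%s %s: %.4g +/- %.3g (n=%d) vs %s: %.4g +/- %.3g (n=%d)\n",
              if (is.na(x$feature)) "" else paste0(" ", x$feature),
              x$labels[1], x$mean[1], x$sem[1], x$n[1],
              x$labels[2], x$mean[2], x$sem[2], x$n[2]))
  cat(sprintf("  t = %.3f, df = %.2f, p = %.4g%s\n", x$t, x$df, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

comparison_row <- function(cmp, condition) {
  data.frame(feature = cmp$feature, condition = condition,
             group1 = cmp$labels[1], group2 = cmp$labels[2],
             n1 = cmp$n[1], n2 = cmp$n[2],
             mean1 = cmp$mean[1], mean2 = cmp$mean[2],
             sem1 = cmp$sem[1], sem2 = cmp$sem[2],
             t = cmp$t, df = cmp$df, p = cmp$p,
             significant = cmp$significant)
}

#' Configuration of a virtual cohort experiment
#'
#' @param n_cells cells per genotype group.
#' @param genotypes genotype labels to simulate.
#' @param drug condition applied to every cell (\code{"none"},
#'   \code{"ZD7288"} or \code{"XE991"}); drug cohorts are independent cells,
#'   as in the experiments (no within-cell washout).
#' @param variability_cv lognormal conductance CV across cells.
#' @param seed master seed; together with the configuration it fully
#'   determines all outputs.
#' @param ko_hcn_ratio KO HCN conductance as a fraction of WT.
#' @param model base model parameters ([default_model_params()]).
#' @param sim a [sim_config()].
#' @param protocols which protocols to run (subset of \code{"step"},
#'   \code{"ramp"}, \code{"sag"}, \code{"rin"}).
#' @return An object of class \code{experiment_config}.
#' @export
experiment_config <- function(n_cells = 20, genotypes = c("WT", "KO"),
                              drug = "none", variability_cv = 0.2,
                              seed = 42, ko_hcn_ratio = 0.4,
                              model = default_model_params(),
                              sim = sim_config(),
                              protocols = c("step", "ramp", "sag", "rin")) {
  stopifnot(n_cells >= 2)
  drug <- match.arg(drug, c("none", "ZD7288", "XE991"))
  protocols <- match.arg(protocols, c("step", "ramp", "sag", "rin"),
                         several.ok = TRUE)
  structure(list(n_cells = n_cells, genotypes = genotypes, drug = drug,
                 variability_cv = variability_cv, seed = seed,
                 ko_hcn_ratio = ko_hcn_ratio, model = model, sim = sim,
                 protocols = protocols),
            class = "experiment_config")
}

# Simulate one cell and extract its feature rows.
run_one_cell <- function(cell_id, genotype, cfg) {
  drug_idx <- match(cfg$drug, c("none", "ZD7288", "XE991"))
  geno_idx <- match(genotype, c("WT", "KO"))
  cell_seed <- derive_seed(cfg$seed, geno_idx, drug_idx, cell_id)
  params <- make_genotype(genotype, variability_cv = cfg$variability_cv,
                          seed = cell_seed, ko_hcn_ratio = cfg$ko_hcn_ratio,
                          model = cfg$model)
  params <- apply_drug(params, cfg$drug)
  id <- sprintf("%s_%s_c%02d", genotype, cfg$drug, cell_id)
  out <- list(step = NULL, ramp = NULL, passive = NULL)

  if ("step" %in% cfg$protocols) {
    sweeps <- simulate_sweeps(params, step_family(), cfg$sim)
    rows <- lapply(sweeps, function(sw) {
      cbind(data.frame(cell = id, genotype = genotype, drug = cfg$drug,
                       step_pA = sw$meta$amplitude_pA),
            sweep_features(sw))
    })
    out$step <- do.call(rbind, rows)
  }
  if ("ramp" %in% cfg$protocols) {
    sw <- simulate_sweeps(params, ramp_protocol(), cfg$sim)[[1L]]
    out$ramp <- cbind(data.frame(cell = id, genotype = genotype,
                                 drug = cfg$drug),
                      sweep_features(sw))
  }
  if ("rin" %in% cfg$protocols || "sag" %in% cfg$protocols) {
    rin_sw <- if ("rin" %in% cfg$protocols) {
      simulate_sweeps(params, rin_pulse(), cfg$sim)[[1L]]
    } else {
      NULL
    }
    sag_sw <- if ("sag" %in% cfg$protocols) {
      simulate_sweeps(params, sag_family(), cfg$sim)
    } else {
      list()
    }
    if (!is.null(rin_sw)) {
      out$passive <- cbind(data.frame(cell = id, genotype = genotype,
                                      drug = cfg$drug),
                           passive_features(rin_sw, sag_sw))
    }
  }
  out
}

#' Run a virtual cohort experiment
#'
#' Simulates \code{n_cells} virtual neurons per genotype under the
#' configured drug condition, runs the selected protocols, extracts all
#' excitability and passive features, and computes per-feature group
#' comparisons (per step amplitude where applicable). Cells whose
#' integration fails are logged and skipped; the run continues.
#'
#' @param config an [experiment_config()].
#' @return An object of class \code{drg_experiment}: feature tables
#'   (\code{step}, \code{ramp}, \code{passive}), the \code{comparisons} data
#'   frame (one row per feature x condition with n/mean/sem/t/df/p), the
#'   configuration, a \code{failures} data frame and a per-cell \code{log}
#'   (timestamp, status, elapsed seconds).
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  step <- list(); rampt <- list(); passive <- list()
  failures <- data.frame(cell = character(0), message = character(0))
  log <- list()
  for (g in config$genotypes) {
    for (i in seq_len(config$n_cells)) {
      t0 <- Sys.time()
      res <- tryCatch(run_one_cell(i, g, config), error = function(e) e)
      elapsed <- as.numeric(Sys.time() - t0, units = "secs")
      cell_id <- sprintf("%s_%s_c%02d", g, config$drug, i)
      ok <- !inherits(res, "error")
      log[[length(log) + 1L]] <- data.frame(
        timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"), cell = cell_id,
        status = if (ok) "ok" else "failed",
        elapsed_s = round(elapsed, 3))
      if (!ok) {
        failures <- rbind(failures,
                          data.frame(cell = cell_id,
                                     message = conditionMessage(res)))
        next
      }
      step[[length(step) + 1L]] <- res$step
      rampt[[length(rampt) + 1L]] <- res$ramp
      passive[[length(passive) + 1L]] <- res$passive
    }
  }
  exp <- structure(
    list(step = if (length(step)) do.call(rbind, step) else NULL,
         ramp = if (length(rampt)) do.call(rbind, rampt) else NULL,
         passive = if (length(passive)) do.call(rbind, passive) else NULL,
         config = config, failures = failures,
         log = do.call(rbind, log)),
    class = "drg_experiment")
  exp$comparisons <- compare_groups(exp)
  exp
}

# Build the per-feature WT-vs-KO comparison table of an experiment.
compare_groups <- function(exp, groups = c("KO", "WT"), alpha = 0.05) {
  rows <- list()
  add <- function(values, genotype, feature, condition) {
    a <- values[genotype == groups[1L]]
    b <- values[genotype == groups[2L]]
    if (sum(!is.na(a)) < 2L || sum(!is.na(b)) < 2L) return()
    cmp <- ttest_groups(a, b, alpha = alpha, feature = feature,
                        labels = groups)
    rows[[length(rows) + 1L]] <<- comparison_row(cmp, condition)
  }
  step_feats <- c("n_aps", "latency", "first_isi", "charge_transfer",
                  "threshold", "peak_potential", "amplitude",
                  "rise_time_10_90", "fall_time_90_10", "rising_speed",
                  "duration_at_plus15")
  if (!is.null(exp$step)) {
    for (amp in sort(unique(exp$step$step_pA))) {
      d <- exp$step[exp$step$step_pA == amp, ]
      for (f in step_feats) {
        add(d[[f]], d$genotype, f, paste0("step_", amp))
      }
    }
  }
  if (!is.null(exp$ramp)) {
    for (f in c("n_aps", "threshold", "rheobase", "rheobase_norm",
                "charge_transfer")) {
      add(exp$ramp[[f]], exp$ramp$genotype, f, "ramp")
    }
  }
  if (!is.null(exp$passive)) {
    for (f in setdiff(names(exp$passive), c("cell", "genotype", "drug"))) {
      add(exp$passive[[f]], exp$passive$genotype, f, "passive")
    }
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.drg_experiment <- function(x, ...) {
  cfg <- x$config
  cat("<drg_experiment> ", cfg$n_cells, " cells/group, genotypes ",
      paste(cfg$genotypes, collapse = "/"), ", drug ", cfg$drug,
      ", cv ", cfg$variability_cv, ", seed ", cfg$seed, "\n", sep = "")
  if (nrow(x$failures)) {
    cat("  integration failures:", nrow(x$failures), "\n")
  }
  if (!is.null(x$comparisons)) {
    sig <- x$comparisons[x$comparisons$significant, ]
    cat("  significant comparisons (p < 0.05):", nrow(sig), "of",
        nrow(x$comparisons), "\n")
  }
  invisible(x)
}

#' @export
summary.drg_experiment <- function(object, ...) {
  object$comparisons
}

#' Fraction of cells firing at a given step amplitude
#'
#' @param exp a [run_experiment()] result (with the step protocol).
#' @param amplitude step amplitude, pA; must be one of the simulated steps.
#' @param genotype genotype label.
#' @return Fraction of cells with at least one AP at that step.
#' @export
fraction_firing <- function(exp, amplitude, genotype) {
  stopifnot(inherits(exp, "drg_experiment"), !is.null(exp$step))
  if (!amplitude %in% exp$step$step_pA) {
    stop("amplitude ", amplitude, " pA is not part of the simulated steps")
  }
  d <- exp$step[exp$step$step_pA == amplitude &
                  exp$step$genotype == genotype, ]
  if (nrow(d) == 0L) stop("no cells of genotype ", genotype)
  mean(d$n_aps >= 1)
}

#' Write the tables of an experiment as delimited text
#'
#' Emits \code{step_features.tsv}, \code{ramp_features.tsv},
#' \code{passive_features.tsv}, \code{comparisons.tsv} and a
#' \code{manifest.txt} echoing the configuration and seed.
#'
#' @param exp a \code{drg_experiment}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(exp, dir) {
  stopifnot(inherits(exp, "drg_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  wr(exp$step, "step_features.tsv")
  wr(exp$ramp, "ramp_features.tsv")
  wr(exp$passive, "passive_features.tsv")
  wr(exp$comparisons, "comparisons.tsv")
  wr(exp$failures, "failures.tsv")
  wr(exp$log, "run_log.tsv")
  cfg <- exp$config
  writeLines(c(
    paste0("package: drgephys ",
           as.character(utils::packageVersion("drgephys"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("n_cells: ", cfg$n_cells),
    paste0("genotypes: ", paste(cfg$genotypes, collapse = ",")),
    paste0("drug: ", cfg$drug),
    paste0("variability_cv: ", cfg$variability_cv),
    paste0("seed: ", cfg$seed),
    paste0("ko_hcn_ratio: ", cfg$ko_hcn_ratio),
    paste0("protocols: ", paste(cfg$protocols, collapse = ","))
  ), file.path(dir, "manifest.txt"))
  invisible(dir)
}
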
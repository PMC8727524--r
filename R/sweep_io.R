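# The ep_sweep container and its delimited-text serialization.

new_sweep <- function(t, v, i, meta = list()) {
  stopifnot(length(t) == length(v), length(v) == length(i))
  structure(list(t = as.numeric(t), v = as.numeric(v), i = as.numeric(i),
                 meta = meta),
            class = "ep_sweep")
}

#' Construct a current-clamp sweep from raw vectors
#'
#' Mostly useful for testing and for importing externally recorded traces;
#' [simulate_sweeps()] builds these objects for simulated data.
#'
#' @param t uniform, strictly increasing sample times, ms.
#' @param v membrane voltage, mV.
#' @param i injected current, pA.
#' @param meta named list of metadata; feature extraction uses
#'   \code{onset_ms} (stimulus onset), \code{amplitude_pA} or the ramp
#'   fields \code{ramp_start_ms}, \code{ramp_slope}, \code{baseline_cross_ms},
#'   plus \code{protocol}, \code{genotype}, \code{drug}, \code{cm}.
#' @return An object of class \code{ep_sweep}.
#' @export
as_sweep <- function(t, v, i = numeric(length(t)), meta = list()) {
  if (length(t) < 3L) stop("a sweep needs at least 3 samples")
  dt <- diff(t)
  if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * max(dt)) {
    stop("sample times must be uniform and strictly increasing")
  }
  if (!all(is.finite(v)) || !all(is.finite(i))) {
    stop("voltage and current must be finite")
  }
  new_sweep(t, v, i, meta)
}

sweep_dt <- function(sweep) sweep$t[2L] - sweep$t[1L]

#' @export
print.ep_sweep <- function(x, ...) {
  cat("<ep_sweep> ", length(x$t), " samples, ",
      format(x$t[1]), "..", format(x$t[length(x$t)]), " ms",
      if (!is.null(x$meta$protocol)) paste0(", protocol ", x$meta$protocol),
      if (!is.null(x$meta$genotype)) paste0(", ", x$meta$genotype),
      "\n", sep = "")
  cat("  V range: [", round(min(x$v), 2), ", ", round(max(x$v), 2),
      "] mV; I range: [", round(min(x$i), 2), ", ", round(max(x$i), 2),
      "] pA\n", sep = "")
  invisible(x)
}

#' Plot a sweep's voltage and current traces
#'
#' @param x an \code{ep_sweep}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ep_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$t, x$v, type = "l", xlab = "", ylab = "V (mV)", ...)
  graphics::plot(x$t, x$i, type = "l", xlab = "t (ms)", ylab = "I (pA)")
  invisible(x)
}

#' Write a sweep as delimited text with a key-value sidecar
#'
#' The trace file has a header row and tab-separated columns \code{time_ms},
#' \code{v_mV}, \code{i_pA}; a \code{<path>.meta} sidecar stores the sweep
#' metadata one \code{key: value} pair per line.
#'
#' @param sweep an \code{ep_sweep}.
#' @param path output file path for the trace table.
#' @return \code{path}, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "ep_sweep"))
  df <- data.frame(time_ms = sweep$t, v_mV = sweep$v, i_pA = sweep$i)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- sweep$meta
  lines <- vapply(seq_along(meta), function(k) {
    paste0(names(meta)[k], ": ", format(meta[[k]], digits = 15))
  }, character(1))
  writeLines(lines, paste0(path, ".meta"))
  invisible(path)
}

#' Read a sweep written by [write_sweep()]
#'
#' Accepts any delimited file with \code{time_ms}, \code{v_mV} and
#' \code{i_pA} columns; the sidecar is optional.
#'
#' @param path trace table path.
#' @return An \code{ep_sweep}.
#' @export
read_sweep <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("time_ms", "v_mV", "i_pA")
  if (!all(need %in% names(df))) {
    stop("sweep file must have columns ", paste(need, collapse = ", "))
  }
  meta <- list()
  mpath <- paste0(path, ".meta")
  if (file.exists(mpath)) {
    for (line in readLines(mpath)) {
      kv <- sub(":.*$", "", line)
      val <- sub("^[^:]*: ?", "", line)
      num <- suppressWarnings(as.numeric(val))
      meta[[kv]] <- if (is.na(num)) val else num
    }
  }
  as_sweep(df$time_ms, df$v_mV, df$i_pA, meta)
}
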
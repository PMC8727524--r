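# Relative qPCR quantification by the 2^-ddCt method with Rpl13a
# normalization, plus a synthetic Ct-table generator with known truth.

.default_genes <- c("Hcn1", "Hcn2", "Hcn3", "Hcn4")
.housekeeping <- "Rpl13a"

#' Generate a synthetic qPCR cycle-threshold table
#'
#' Emulates a two-genotype qPCR experiment on the HCN isoforms with Rpl13a
#' as the housekeeping gene. Wild-type Ct values sit at a per-gene baseline;
#' knockout Ct values are shifted by \code{-log2(fold)} for each target gene
#' (a fold below 1 raises the KO Ct); Gaussian noise of SD \code{noise_sd}
#' cycles is added independently to every well. The housekeeping gene has
#' fold 1 by construction.
#'
#' @param truth named vector of true KO/WT fold changes per target gene
#'   (all \code{> 0}). The defaults (Hcn1 = 0.4, Hcn4 = 0.35, Hcn2 = Hcn3 =
#'   1) are illustrative reductions of the two affected isoforms, not
#'   measured values.
#' @param noise_sd per-well Ct noise SD, cycles.
#' @param n_bio biological replicates per genotype.
#' @param n_tech technical replicates per (sample, gene).
#' @param baseline_ct named per-gene WT baseline Ct (housekeeping included).
#' @param seed integer seed; the table is deterministic given the seed.
#' @return A data frame of class \code{ct_table} with columns \code{sample},
#'   \code{genotype}, \code{gene}, \code{replicate}, \code{ct}.
#' @export
generate_ct_table <- function(truth = c(Hcn1 = 0.4, Hcn2 = 1, Hcn3 = 1,
                                        Hcn4 = 0.35),
                              noise_sd = 0.15, n_bio = 3, n_tech = 3,
                              baseline_ct = c(Hcn1 = 24, Hcn2 = 26,
                                              Hcn3 = 28, Hcn4 = 25,
                                              Rpl13a = 18),
                              seed = 1) {
  if (any(!is.finite(truth)) || any(truth <= 0)) {
    stop("all true fold changes must be finite and > 0")
  }
  if (is.null(names(truth)) || any(names(truth) == "")) {
    stop("truth must be a named vector of per-gene fold changes")
  }
  stopifnot(n_bio >= 1, n_tech >= 1, noise_sd >= 0)
  genes <- c(names(truth), .housekeeping)
  if (!all(genes %in% names(baseline_ct))) {
    stop("baseline_ct must name every target gene and ", .housekeeping)
  }
  grid <- expand.grid(genotype = c("WT", "KO"), bio = seq_len(n_bio),
                      gene = genes, replicate = seq_len(n_tech),
                      stringsAsFactors = FALSE)
  shift <- ifelse(grid$genotype == "KO" & grid$gene != .housekeeping,
                  -log2(truth[grid$gene]), 0)
  noise <- with_seed(seed, stats::rnorm(nrow(grid), 0, noise_sd))
  out <- data.frame(
    sample = paste0(grid$genotype, grid$bio),
    genotype = grid$genotype,
    gene = grid$gene,
    replicate = grid$replicate,
    ct = unname(baseline_ct[grid$gene] + shift + noise)
  )
  out <- out[order(out$genotype, out$sample, out$gene, out$replicate), ]
  rownames(out) <- NULL
  class(out) <- c("ct_table", "data.frame")
  out
}

validate_ct_table <- function(table, housekeeping = .housekeeping) {
  need <- c("sample", "genotype", "gene", "replicate", "ct")
  if (!all(need %in% names(table))) {
    stop("Ct table must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(table$ct)) || any(table$ct <= 0 | table$ct >= 45)) {
    stop("Ct values must lie in (0, 45)")
  }
  samples <- unique(table$sample)
  has_hk <- vapply(samples, function(s) {
    housekeeping %in% table$gene[table$sample == s]
  }, logical(1))
  if (!all(has_hk)) {
    stop("sample(s) missing housekeeping gene ", housekeeping, ": ",
         paste(samples[!has_hk], collapse = ", "))
  }
  counts <- table(table$sample, table$gene)
  if (length(unique(counts[counts > 0])) > 1L) {
    stop("every (sample, gene) must have the same technical replicate count")
  }
  invisible(table)
}

#' Per-sample delta-Ct normalization
#'
#' For every sample and target gene, technical replicates are averaged and
#' the sample's mean housekeeping Ct is subtracted:
#' \code{dCt = mean(Ct_gene) - mean(Ct_housekeeping)}.
#'
#' @param table a Ct table (see [generate_ct_table()] for the format).
#' @param housekeeping housekeeping gene name.
#' @return Data frame with columns \code{sample}, \code{genotype},
#'   \code{gene}, \code{dct}, one row per (sample, target gene).
#' @export
delta_ct <- function(table, housekeeping = .housekeeping) {
  validate_ct_table(table, housekeeping)
  means <- stats::aggregate(ct ~ sample + genotype + gene, data = table,
                            FUN = mean)
  hk <- means[means$gene == housekeeping, c("sample", "ct")]
  names(hk)[2L] <- "ct_hk"
  tg <- means[means$gene != housekeeping, ]
  out <- merge(tg, hk, by = "sample", sort = FALSE)
  out$dct <- out$ct - out$ct_hk
  out <- out[order(out$gene, out$genotype, out$sample),
             c("sample", "genotype", "gene", "dct")]
  rownames(out) <- NULL
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, \code{ddCt = dCt - mean(dCt of the reference group)} and
#' \code{fold = 2^-ddCt}; the reference group's geometric mean fold is 1 by
#' construction. Group means with SEM are reported per gene, together with a
#' two-sample Student's t-test on the dCt values (dCt, not fold, is the
#' approximately normal scale).
#'
#' @param dcts output of [delta_ct()].
#' @param reference reference genotype label (fold set to 1 on average).
#' @param var_equal pooled-variance t-test (TRUE, default) or Welch.
#' @return An object of class \code{fold_change_result}: a list with
#'   \code{per_sample} (sample-level ddCt and fold) and \code{summary} (one
#'   row per gene: group means and SEM of fold, t, df, p).
#' @export
fold_change <- function(dcts, reference = "WT", var_equal = TRUE) {
  groups <- unique(dcts$genotype)
  if (!(reference %in% groups)) {
    stop("reference group '", reference, "' not present")
  }
  if (length(groups) < 2L) stop("need both genotype groups for fold change")
  per_gene <- split(dcts, dcts$gene)
  per_sample <- list()
  summ <- list()
  for (gene in names(per_gene)) {
    d <- per_gene[[gene]]
    ref_mean <- mean(d$dct[d$genotype == reference])
    d$ddct <- d$dct - ref_mean
    d$fold <- 2^(-d$ddct)
    per_sample[[gene]] <- d
    other <- setdiff(groups, reference)
    rows <- lapply(c(reference, other), function(g) {
      f <- d$fold[d$genotype == g]
      data.frame(gene = gene, genotype = g, n = length(f),
                 mean_fold = mean(f),
                 sem_fold = stats::sd(f) / sqrt(length(f)))
    })
    tt <- ttest_groups(d$dct[d$genotype == other[1L]],
                       d$dct[d$genotype == reference],
                       var_equal = var_equal)
    row <- do.call(cbind, list(
      rows[[1L]][, c("gene", "n")],
      data.frame(ref_mean_fold = rows[[1L]]$mean_fold,
                 ref_sem_fold = rows[[1L]]$sem_fold,
                 target_group = other[1L],
                 target_mean_fold = rows[[2L]]$mean_fold,
                 target_sem_fold = rows[[2L]]$sem_fold,
                 t = tt$t, df = tt$df, p = tt$p,
                 significant = tt$significant)
    ))
    summ[[gene]] <- row
  }
  structure(list(per_sample = do.call(rbind, per_sample),
                 summary = do.call(rbind, summ),
                 reference = reference),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, digits = 3, ...) {
  cat("<fold_change_result> reference group:", x$reference, "\n")
  s <- x$summary
  for (k in seq_len(nrow(s))) {
    cat(sprintf("  %-6s %s fold = %.*f +/- %.*f (n = %d), p = %.4g%s\n",
                s$gene[k], s$target_group[k], digits, s$target_mean_fold[k],
                digits, s$target_sem_fold[k], s$n[k], s$p[k],
                if (s$significant[k]) " *" else ""))
  }
  invisible(x)
}
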
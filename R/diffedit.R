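#' Differential-editing configuration
#'
#' @param min_reads Minimum coverage required in every sample for a site to
#'   be tested ("at least 10 reads in each sample"); default 10, inclusive.
#' @param sd_threshold Significance multiple; a site is called when the
#'   slope lies strictly more than this many standard errors from zero.
#'   Default 3.
#' @param level Confidence level for the per-replicate Wilks intervals that
#'   drive the regression weights; default 0.95.
#' @param rule Reading of the 3-SD rule.  `"zstat"` (default): significant
#'   iff `|slope| / se > sd_threshold`.  `"beyond_ci"` (documented
#'   variant): the slope must clear its own confidence limit by the
#'   threshold, i.e. `|slope| / se > sd_threshold + qnorm((1+level)/2)`.
#' @param weighted Use inverse-variance weights from the Wilks intervals
#'   (default); `FALSE` gives ordinary least squares for sensitivity
#'   analysis.
#' @return A list of class `diffedit_config`.
#' @export
diffedit_config <- function(min_reads = 10, sd_threshold = 3, level = 0.95,
                            rule = c("zstat", "beyond_ci"), weighted = TRUE) {
  rule <- match.arg(rule)
  stopifnot(min_reads >= 1, sd_threshold > 0, level > 0, level < 1)
  structure(list(min_reads = as.integer(min_reads),
                 sd_threshold = sd_threshold, level = level,
                 rule = rule, weighted = isTRUE(weighted)),
            class = "diffedit_config")
}

#' Coverage filter
#'
#' Retains exactly the sites covered by at least `min_reads` reads in
#' EVERY sample; site order is preserved.
#'
#' @param table A [site_count_table()].
#' @param config A [diffedit_config()].
#' @return A filtered `site_count_table`.
#' @export
coverage_filter <- function(table, config = diffedit_config()) {
  stopifnot(inherits(table, "site_count_table"))
  keep <- rowSums(table$n >= config$min_reads) == ncol(table$n)
  table[keep]
}

#' CI-weighted regression of editing frequency on group
#'
#' Computes the per-sample frequency estimate and Wilks confidence interval,
#' converts each interval to a standard deviation via [ci_to_sd()], and fits
#' weighted least squares of frequency on an intercept plus group indicator
#' with weights `1 / sigma^2` through explicit weighted normal equations.
#' With a binary covariate this is exactly the weighted difference of group
#' means; the standard error comes from `(X' W X)^{-1}` treating each
#' frequency as having variance `sigma_i^2`.
#'
#' @param k_by_sample,n_by_sample Integer vectors of edited and total counts
#'   per sample.
#' @param groups 0/1 indicator per sample (1 = case/knockout group); slope
#'   is the group-1 minus group-0 weighted mean frequency.
#' @param level CI level for the weights.
#' @param weighted If `FALSE`, all weights are 1.
#' @param ci Optional precomputed data.frame from `wilks_ci_table` with
#'   rows matching the samples (internal fast path).
#' @return A list of class `regression_result` with `slope`, `se`, `zstat`,
#'   `weights`, `f_hat`.
#' @export
site_regression <- function(k_by_sample, n_by_sample, groups, level = 0.95,
                            weighted = TRUE, ci = NULL) {
  g <- as.integer(groups)
  if (!all(g %in% c(0L, 1L))) stop("groups must be a 0/1 indicator")
  if (!any(g == 0L) || !any(g == 1L)) stop("need at least one sample per group")
  if (any(n_by_sample < 1)) stop("all samples need coverage >= 1")
  if (is.null(ci)) ci <- wilks_ci_table(k_by_sample, n_by_sample, level)
  f <- ci$f_hat
  w <- if (weighted) 1 / ci$sigma^2 else rep(1, length(f))
  # weighted normal equations for y = b0 + b1 * g
  sw  <- sum(w);      swg  <- sum(w * g)
  swy <- sum(w * f);  swgy <- sum(w * g * f)
  det <- sw * swg - swg^2          # X'WX = [[sw, swg], [swg, swg]] (g^2 = g)
  slope <- (sw * swgy - swg * swy) / det
  se <- sqrt(sw / det)             # [ (X'WX)^{-1} ]_{22}
  structure(list(slope = slope, se = se, zstat = slope / se,
                 weights = w, f_hat = f),
            class = "regression_result")
}

#' Apply the significance rule to one regression result
#'
#' Significance requires the slope to lie strictly more than
#' `sd_threshold` standard deviations from zero (`|z| > 3`; `z = 3`
#' exactly is NOT significant).  Direction is `hyper` when the case group
#' is edited more (slope > 0), `hypo` when less, `none` otherwise.
#'
#' @param reg A `regression_result`.
#' @param config A [diffedit_config()].
#' @return A list with logical `significant` and `direction`
#'   (`"hyper"`, `"hypo"` or `"none"`).
#' @export
call_site <- function(reg, config = diffedit_config()) {
  thr <- switch(config$rule,
    zstat     = config$sd_threshold,
    beyond_ci = config$sd_threshold + stats::qnorm((1 + config$level) / 2))
  sig <- is.finite(reg$zstat) && abs(reg$zstat) > thr
  dir <- if (!sig) "none" else if (reg$slope > 0) "hyper" else "hypo"
  list(significant = sig, direction = dir)
}

#' Run the replicated differential-editing test
#'
#' Applies the coverage filter, then the CI-weighted regression and the
#' 3-SD call at every retained site.  Deterministic given the table.
#'
#' @param table A [site_count_table()].  The second group level is treated
#'   as the case/knockout group (slope > 0 means hyper-edited in it).
#' @param config A [diffedit_config()].
#' @return A data.frame of class `diffedit_results`, one row per input
#'   site: site columns, `passed_coverage`, `slope`, `se`, `zstat`
#'   (NA when filtered), `significant`, `direction`.
#' @export
run_diffedit <- function(table, config = diffedit_config()) {
  stopifnot(inherits(table, "site_count_table"))
  g <- as.integer(table$samples$group) - 1L
  out <- table$sites
  ns <- nrow(out)
  out$passed_coverage <- rowSums(table$n >= config$min_reads) == ncol(table$n)
  out$slope <- out$se <- out$zstat <- rep(NA_real_, ns)
  out$significant <- rep(FALSE, ns)
  out$direction <- rep("none", ns)
  idx <- which(out$passed_coverage)
  if (length(idx)) {
    # one CI computation per unique (k, n) pair across the whole table
    kv <- as.vector(table$k[idx, , drop = FALSE])
    nv <- as.vector(table$n[idx, , drop = FALSE])
    ci_all <- wilks_ci_table(kv, nv, config$level)
    m <- length(idx)
    for (j in seq_len(m)) {
      rows <- seq(j, by = m, length.out = ncol(table$k))
      reg <- site_regression(kv[rows], nv[rows], g, level = config$level,
                             weighted = config$weighted,
                             ci = ci_all[rows, , drop = FALSE])
      cl <- call_site(reg, config)
      i <- idx[j]
      out$slope[i] <- reg$slope; out$se[i] <- reg$se; out$zstat[i] <- reg$zstat
      out$significant[i] <- cl$significant; out$direction[i] <- cl$direction
    }
  }
  attr(out, "case_group") <- levels(table$samples$group)[2]
  class(out) <- c("diffedit_results", "data.frame")
  out
}

# round half away from zero: the only rule consistent with the published
# panel percentages (16/113 -> 14, 10/113 -> 9, 22/30 -> 73)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarize differential-editing results against annotation panels
#'
#' Counts tested/significant/hyper/hypo sites, collects the distinct genes
#' with at least one significant site, and intersects them with each gene
#' panel (case-insensitively).  Percentages are rounded to the nearest
#' integer, half away from zero.  With zero significant genes the panel
#' percentages are reported as `NA` with `undefined = TRUE` rather than
#' dividing by zero.
#'
#' @param results A `diffedit_results` data.frame from [run_diffedit()].
#' @param panels A list of [gene_panel()] objects (may be empty).
#' @return A list of class `edit_summary`: `n_sites_tested`,
#'   `n_significant`, `n_hyper`, `n_hypo`, `genes`, `panel_counts`
#'   (data.frame panel/count/percent), `undefined`.
#' @export
summarize_diffedit <- function(results, panels = list()) {
  stopifnot(inherits(results, "diffedit_results"))
  sig <- results$significant
  genes <- unique(results$gene[sig & nzchar(results$gene)])
  ng <- length(genes)
  pc <- data.frame(panel = character(0), count = integer(0), percent = numeric(0))
  for (p in panels) {
    cnt <- sum(toupper(genes) %in% toupper(p$genes))
    pct <- if (ng > 0) round_half_away(100 * cnt / ng) else NA_real_
    pc <- rbind(pc, data.frame(panel = p$name, count = cnt, percent = pct))
  }
  structure(list(
    n_sites_tested = sum(results$passed_coverage),
    n_significant = sum(sig),
    n_hyper = sum(results$direction == "hyper"),
    n_hypo = sum(results$direction == "hypo"),
    genes = genes,
    panel_counts = pc,
    undefined = ng == 0
  ), class = "edit_summary")
}

#' @export
print.edit_summary <- function(x, ...) {
  cat(sprintf("tested %d sites: %d significant (%d hyper, %d hypo) in %d genes\n",
              x$n_sites_tested, x$n_significant, x$n_hyper, x$n_hypo,
              length(x$genes)))
  if (nrow(x$panel_counts)) {
    for (i in seq_len(nrow(x$panel_counts))) {
      cat(sprintf("  %s: %d gene(s)%s\n", x$panel_counts$panel[i],
                  x$panel_counts$count[i],
                  if (is.na(x$panel_counts$percent[i])) ""
                  else sprintf(" (%d%%)", x$panel_counts$percent[i])))
    }
  }
  invisible(x)
}
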
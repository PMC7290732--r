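# Percent-change test on the linear ratio scale.  The default "reciprocal"
# down rule is symmetric in an H/L swap: +20% means ratio >= 1.2 and -20%
# means ratio <= 1/1.2.  The "linear" alternative reads -20% as ratio <= 0.8.
meets_pct <- function(ratio, pct, strict = FALSE,
                      down_rule = c("reciprocal", "linear")) {
  down_rule <- match.arg(down_rule)
  up_thr <- 1 + pct / 100
  dn_thr <- if (down_rule == "reciprocal") 1 / up_thr else 1 - pct / 100
  if (strict) ratio > up_thr | ratio < dn_thr else ratio >= up_thr | ratio <= dn_thr
}

#' Pool SILAC peptide ratios to protein-level ratios
#'
#' Heavy/light ratios for all peptides belonging to a protein are pooled
#' into one ratio per protein per experiment.  The default pooling is the
#' median (robust to outlier peptides); `"mean_log"` gives the geometric
#' mean (exponentiated mean of log ratios), the MaxQuant-style alternative.
#'
#' @param peptides A [peptide_ratio_table()].
#' @param method `"median"` (default) or `"mean_log"`.
#' @return A data.frame of class `protein_ratio_table` with columns
#'   `protein`, `experiment`, `ratio`, `n_peptides`, `fold_change_pct`
#'   (signed percent change `100 * (ratio - 1)`).
#' @export
pool_ratios <- function(peptides, method = c("median", "mean_log")) {
  stopifnot(inherits(peptides, "peptide_ratio_table"))
  method <- match.arg(method)
  pool <- switch(method,
    median = function(x) stats::median(x),
    mean_log = function(x) exp(mean(log(x))))
  agg <- stats::aggregate(ratio ~ protein + experiment, data = peptides,
                          FUN = pool)
  cnt <- stats::aggregate(ratio ~ protein + experiment, data = peptides,
                          FUN = length)
  agg$n_peptides <- cnt$ratio[match(paste(agg$protein, agg$experiment),
                                    paste(cnt$protein, cnt$experiment))]
  agg$fold_change_pct <- 100 * (agg$ratio - 1)
  agg <- agg[order(agg$protein, agg$experiment), ]
  rownames(agg) <- NULL
  class(agg) <- c("protein_ratio_table", "data.frame")
  agg
}

# reshape pooled records to one row per protein with per-experiment ratios;
# proteins missing from any experiment are dropped with a message
ratios_by_experiment <- function(records) {
  stopifnot(inherits(records, "protein_ratio_table"))
  exps <- sort(unique(records$experiment))
  wide <- stats::reshape(records[, c("protein", "experiment", "ratio")],
                         idvar = "protein", timevar = "experiment",
                         direction = "wide")
  names(wide) <- sub("^ratio\\.", "", names(wide))
  complete <- stats::complete.cases(wide[exps])
  if (any(!complete)) {
    message(sum(!complete), " protein(s) absent from at least one experiment, excluded: ",
            paste(utils::head(wide$protein[!complete], 5), collapse = ", "),
            if (sum(!complete) > 5) ", ..." else "")
  }
  list(wide = wide[complete, , drop = FALSE], experiments = exps)
}

#' Replicated protein-level changes
#'
#' Calls proteins with at least `min_pct` percent change in the SAME
#' direction in BOTH (all) experiments.
#'
#' @param records A `protein_ratio_table` from [pool_ratios()].
#' @param min_pct Percent-change threshold, inclusive (default 20).
#' @param down_rule Down-regulation reading: `"reciprocal"` (default,
#'   ratio <= 1/(1 + pct/100)) or `"linear"` (ratio <= 1 - pct/100).
#' @return A data.frame of class `integration_calls`: `id`, `direction`
#'   (`up`/`down`), `category = "replicated_protein_change"`, plus one
#'   ratio column per experiment.
#' @export
replicated_changes <- function(records, min_pct = 20,
                               down_rule = c("reciprocal", "linear")) {
  down_rule <- match.arg(down_rule)
  rb <- ratios_by_experiment(records)
  wide <- rb$wide; exps <- rb$experiments
  rat <- as.matrix(wide[exps])
  ok <- if (nrow(rat)) apply(rat, 1, function(r) {
    all(meets_pct(r, min_pct, strict = FALSE, down_rule = down_rule)) &&
      (all(r > 1) || all(r < 1))
  }) else logical(0)
  ids <- wide$protein[ok]
  out <- data.frame(id = ids,
                    direction = ifelse(rat[ok, 1, drop = TRUE] > 1, "up", "down"),
                    category = rep("replicated_protein_change", length(ids)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, wide[ok, exps, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- c("integration_calls", "data.frame")
  out
}

# map protein ids to gene symbols; mapping is a data.frame(protein, gene)
# or NULL when protein ids already are gene symbols
map_genes <- function(proteins, mapping) {
  if (is.null(mapping)) return(proteins)
  g <- mapping$gene[match(proteins, mapping$protein)]
  if (anyNA(g)) {
    message(sum(is.na(g)), " unmapped protein(s) excluded: ",
            paste(utils::head(proteins[is.na(g)], 5), collapse = ", "))
  }
  g
}

#' Concordant mRNA/protein changes
#'
#' Calls genes whose protein changed by strictly more than `protein_pct`
#' percent in at least one experiment, whose mRNA test has `p < mrna_p`,
#' and whose protein and mRNA changes share a direction.
#'
#' @param records A `protein_ratio_table`.
#' @param mrna_stats data.frame with columns `gene`, `log2fc`, `pvalue`.
#' @param mapping Optional data.frame `protein`, `gene`; `NULL` if protein
#'   ids are gene symbols.
#' @param protein_pct Protein threshold, strict (default 15).
#' @param mrna_p mRNA significance threshold (default 0.05).
#' @param down_rule See [replicated_changes()].
#' @return An `integration_calls` data.frame with
#'   `category = "concordant_mrna_protein"`.
#' @export
concordant_mrna_protein <- function(records, mrna_stats, mapping = NULL,
                                    protein_pct = 15, mrna_p = 0.05,
                                    down_rule = c("reciprocal", "linear")) {
  down_rule <- match.arg(down_rule)
  rb <- ratios_by_experiment(records)
  wide <- rb$wide; exps <- rb$experiments
  gene <- map_genes(wide$protein, mapping)
  keep <- !is.na(gene)
  wide <- wide[keep, , drop = FALSE]; gene <- gene[keep]
  m <- match(toupper(gene), toupper(mrna_stats$gene))
  has_mrna <- !is.na(m)
  rat <- as.matrix(wide[exps])
  prot_dir <- ifelse(rowMeans(log(rat)) > 0, 1, -1)
  prot_hit <- if (nrow(rat)) apply(rat, 1, function(r)
    any(meets_pct(r, protein_pct, strict = TRUE, down_rule = down_rule)))
  else logical(0)
  mrna_sig <- has_mrna & mrna_stats$pvalue[m] < mrna_p
  mrna_dir <- sign(mrna_stats$log2fc[m])
  ok <- prot_hit & mrna_sig & !is.na(mrna_dir) & mrna_dir == prot_dir
  ok[is.na(ok)] <- FALSE
  ids <- gene[ok]
  out <- data.frame(id = ids,
                    direction = ifelse(prot_dir[ok] > 0, "up", "down"),
                    category = rep("concordant_mrna_protein", length(ids)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, wide[ok, exps, drop = FALSE],
               mrna_log2fc = mrna_stats$log2fc[m][ok],
               mrna_pvalue = mrna_stats$pvalue[m][ok])
  rownames(out) <- NULL
  class(out) <- c("integration_calls", "data.frame")
  out
}

#' Protein-changed / mRNA-unchanged candidates
#'
#' Calls proteins with at least `min_pct` percent concordant change in
#' both experiments whose mRNA is unchanged — operationalized as `p >=
#' mrna_p` AND `|log2 FC| < log2(fc_limit)`, the differential-expression
#' convention inverted.  Upregulated calls are flagged as potential
#' ubiquitin-ligase substrate candidates (protein up with mRNA flat is the
#' signature of lost degradation).
#'
#' @inheritParams concordant_mrna_protein
#' @param min_pct Protein threshold, inclusive, both experiments
#'   (default 20).
#' @param fc_limit mRNA fold-change bound defining "unchanged"
#'   (default 1.2).
#' @return An `integration_calls` data.frame with
#'   `category = "protein_only_candidate"` and a `candidate_substrate`
#'   flag on upregulated calls.
#' @export
protein_only_candidates <- function(records, mrna_stats, mapping = NULL,
                                    min_pct = 20, mrna_p = 0.05,
                                    fc_limit = 1.2,
                                    down_rule = c("reciprocal", "linear")) {
  down_rule <- match.arg(down_rule)
  rep_calls <- replicated_changes(records, min_pct, down_rule)
  gene <- map_genes(rep_calls$id, mapping)
  keep <- !is.na(gene)
  rep_calls <- rep_calls[keep, , drop = FALSE]; gene <- gene[keep]
  m <- match(toupper(gene), toupper(mrna_stats$gene))
  unchanged <- !is.na(m) &
    mrna_stats$pvalue[m] >= mrna_p &
    abs(mrna_stats$log2fc[m]) < log2(fc_limit)
  out <- rep_calls[unchanged, , drop = FALSE]
  out$id <- gene[unchanged]
  out$category <- "protein_only_candidate"
  out$candidate_substrate <- out$direction == "up"
  rownames(out) <- NULL
  out
}

#' Annotation percentages for integration calls
#'
#' For each direction (`up`, `down`) and overall, counts calls, panel
#' members among them (case-insensitive), and the percentage rounded to
#' the nearest integer (half away from zero).  Zero calls in a stratum
#' give `NA` percent with `undefined = TRUE` rather than a division error.
#'
#' @param calls An `integration_calls` data.frame.
#' @param panels A list of [gene_panel()] objects.
#' @return A data.frame: `stratum`, `panel`, `n_calls`, `count`,
#'   `percent`, `undefined`.
#' @export
annotate_percentages <- function(calls, panels) {
  strata <- list(up = calls$id[calls$direction == "up"],
                 down = calls$id[calls$direction == "down"],
                 overall = calls$id)
  rows <- list()
  for (s in names(strata)) {
    ids <- unique(strata[[s]])
    for (p in panels) {
      cnt <- sum(toupper(ids) %in% toupper(p$genes))
      und <- length(ids) == 0
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, panel = p$name, n_calls = length(ids), count = cnt,
        percent = if (und) NA_real_ else round_half_away(100 * cnt / length(ids)),
        undefined = und, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
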
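# small in-code fixtures shared across test files

make_sites <- function(n, gene = sprintf("G%02d", seq_len(n))) {
  data.frame(chrom = "chr1", pos = seq_len(n) * 10L, ref = "A", alt = "G",
             strand = "+", gene = gene, stringsAsFactors = FALSE)
}

make_samples <- function(per_group = 2, groups = c("WT", "KO")) {
  data.frame(
    sample = paste0(rep(groups, each = per_group), seq_len(per_group)),
    group = factor(rep(groups, each = per_group), levels = groups))
}

# 2-site, 4-sample table with easy numbers
tiny_table <- function() {
  site_count_table(
    make_sites(2),
    make_samples(2),
    k = matrix(c(1L, 2L, 1L, 2L, 5L, 6L, 5L, 6L), 2, 4),
    n = matrix(20L, 2, 4))
}

write_tiny_counts_tsv <- function(path, shuffle = FALSE) {
  df <- data.frame(
    chrom = c("chr1", "chr1"), pos = c(10L, 20L), ref = "A", alt = "G",
    strand = "+", gene = c("G01", "G02"),
    WT1_edited = c(1L, 2L), WT1_total = c(20L, 20L),
    WT2_edited = c(1L, 2L), WT2_total = c(20L, 20L),
    KO1_edited = c(5L, 6L), KO1_total = c(20L, 20L),
    KO2_edited = c(5L, 6L), KO2_total = c(20L, 20L))
  if (shuffle) df <- df[2:1, ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_design <- function() {
  data.frame(sample = c("WT1", "WT2", "KO1", "KO2"),
             group = c("WT", "WT", "KO", "KO"))
}

# expression fixture: 4 genes x 4 samples, one gene below 1 everywhere
tiny_expr <- function() {
  vals <- rbind(
    Alpha = c(5, 6, 50, 60),
    Beta  = c(0.2, 0.5, 0.9, 0.4),   # < 1 in all samples
    Gamma = c(0.2, 3.0, 0.9, 0.5),
    Delta = c(2, 2, 2, 2))
  meta <- data.frame(sample = c("WT1", "WT2", "AS1", "AS2"),
                     group = c("WT", "WT", "AS", "AS"),
                     sex = c("M", "M", "M", "M"))
  expression_matrix(vals, meta)
}
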
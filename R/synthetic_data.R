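#' Pileup simulation configuration
#'
#' States the data-generating world for replicated editing pileups: per-site
#' baseline editing frequencies drawn from `Beta(base_freq_shape1,
#' base_freq_shape2)` (default `Beta(1, 9)` — most editing frequencies are
#' low), per-sample coverage from a Poisson or negative-binomial model, and
#' edited counts binomial or beta-binomial with intra-site correlation
#' `rho` (`rho = 0` = pure binomial).  Non-null sites carry a group effect
#' of `delta_f` added to the case-group frequency.
#'
#' @param n_sites Total number of simulated sites.
#' @param n_null_sites Number of those with zero group effect.
#' @param samples_per_group Replicates per group (two groups).
#' @param coverage_mean Mean sequencing depth.
#' @param coverage_model `"poisson"` or `"nbinom"`.
#' @param coverage_dispersion Negative-binomial size parameter (used only
#'   for `"nbinom"`).
#' @param base_freq_shape1,base_freq_shape2 Beta parameters of the baseline
#'   frequency distribution.
#' @param delta_f Injected case-group frequency shift at non-null sites.
#' @param overdispersion_rho Beta-binomial intra-site correlation in
#'   `[0, 1)`.
#' @param seed RNG seed; generators are pure functions of their config.
#' @return A list of class `pileup_sim_config`.
#' @export
pileup_sim_config <- function(n_sites = 1000, n_null_sites = n_sites,
                              samples_per_group = 4, coverage_mean = 50,
                              coverage_model = c("poisson", "nbinom"),
                              coverage_dispersion = 10,
                              base_freq_shape1 = 1, base_freq_shape2 = 9,
                              delta_f = 0, overdispersion_rho = 0,
                              seed = 1) {
  coverage_model <- match.arg(coverage_model)
  stopifnot(n_null_sites <= n_sites, samples_per_group >= 1,
            coverage_mean > 0, overdispersion_rho >= 0,
            overdispersion_rho < 1)
  structure(as.list(environment()), class = "pileup_sim_config")
}

# beta-binomial draws parameterized by mean f and correlation rho:
# alpha = f (1 - rho) / rho, beta = (1 - f) (1 - rho) / rho
rbetabinom <- function(m, size, f, rho) {
  if (rho == 0) return(stats::rbinom(m, size, f))
  a <- f * (1 - rho) / rho
  b <- (1 - f) * (1 - rho) / rho
  p <- ifelse(f <= 0, 0, ifelse(f >= 1, 1, stats::rbeta(m, a, b)))
  stats::rbinom(m, size, p)
}

#' Simulate replicated editing pileups with known truth
#'
#' @param config A [pileup_sim_config()].
#' @return A list with `table` (a [site_count_table()]; group levels
#'   `WT` then `KO`, so `KO` is the case group) and `truth` (data.frame
#'   `site`, `gene`, `base_freq`, `true_delta`, `is_null`).
#' @export
simulate_pileups <- function(config = pileup_sim_config()) {
  stopifnot(inherits(config, "pileup_sim_config"))
  set.seed(config$seed)
  ns <- config$n_sites
  spg <- config$samples_per_group
  nsamp <- 2L * spg
  base_f <- stats::rbeta(ns, config$base_freq_shape1, config$base_freq_shape2)
  is_null <- rep(c(TRUE, FALSE), c(config$n_null_sites, ns - config$n_null_sites))
  delta <- ifelse(is_null, 0, config$delta_f)
  f_case <- base_f + delta
  if (any(f_case < 0 | f_case > 1)) {
    warning("base_freq + delta_f truncated to [0, 1] at ",
            sum(f_case < 0 | f_case > 1), " site(s)")
    f_case <- pmin(pmax(f_case, 0), 1)
  }
  delta <- f_case - base_f
  n <- switch(config$coverage_model,
    poisson = stats::rpois(ns * nsamp, config$coverage_mean),
    nbinom  = stats::rnbinom(ns * nsamp, size = config$coverage_dispersion,
                             mu = config$coverage_mean))
  n <- matrix(n, ns, nsamp)
  groups <- rep(c(0L, 1L), each = spg)
  k <- matrix(0L, ns, nsamp)
  for (j in seq_len(nsamp)) {
    f <- if (groups[j] == 1L) f_case else base_f
    k[, j] <- rbetabinom(ns, n[, j], f, config$overdispersion_rho)
  }
  # editing sites are A->G on either strand; gene labels cycle so several
  # sites share a gene, as real transcripts do
  genes <- sprintf("Gene%03d", ((seq_len(ns) - 1L) %% max(1L, ns %/% 3L)) + 1L)
  sites <- data.frame(
    chrom = "chr1", pos = seq_len(ns) * 100L, ref = "A", alt = "G",
    strand = "+", gene = genes, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample = c(sprintf("WT%d", seq_len(spg)), sprintf("KO%d", seq_len(spg))),
    group = factor(rep(c("WT", "KO"), each = spg), levels = c("WT", "KO")))
  tab <- site_count_table(sites, samples, k, n)
  truth <- data.frame(site = site_key(sites), gene = genes,
                      base_freq = base_f, true_delta = delta,
                      is_null = is_null, stringsAsFactors = FALSE)
  list(table = tab, truth = truth)
}

#' Simulate a two-group expression matrix with a known informative subset
#'
#' Baseline expression is log-normal (per-gene log-mean drawn once, unit
#' log-SD within gene); the first `n_informative` genes receive a
#' case-group shift of `shift_sd_units` standard deviations on the log
#' scale.  Samples are male by default; `n_female` per group exercises the
#' male-only preprocessing filter.
#'
#' @param n_genes,n_informative Gene counts (`n_informative <= n_genes`).
#' @param shift_sd_units Group shift in log-scale SD units.
#' @param samples_per_group Samples per group.
#' @param n_female Female samples per group (default 0).
#' @param seed RNG seed.
#' @return A list with `expr` (an [expression_matrix()], groups `WT`/`AS`)
#'   and `truth` (data.frame `gene`, `is_informative`, `true_shift`).
#' @export
simulate_expression <- function(n_genes = 100, n_informative = 5,
                                shift_sd_units = 4, samples_per_group = 6,
                                n_female = 0, seed = 1) {
  stopifnot(n_informative <= n_genes, n_female <= samples_per_group)
  set.seed(seed)
  nsamp <- 2L * samples_per_group
  genes <- sprintf("Gene%04d", seq_len(n_genes))
  mu <- stats::rnorm(n_genes, mean = 2, sd = 1)   # log-scale baseline means
  z <- matrix(stats::rnorm(n_genes * nsamp, mean = mu, sd = 1), n_genes, nsamp)
  info <- seq_len(n_informative)
  case <- (samples_per_group + 1L):nsamp
  z[info, case] <- z[info, case] + shift_sd_units
  vals <- exp(z)
  rownames(vals) <- genes
  sex <- rep("M", nsamp)
  if (n_female > 0) {
    sex[c(seq_len(n_female), samples_per_group + seq_len(n_female))] <- "F"
  }
  meta <- data.frame(
    sample = c(sprintf("WT%d", seq_len(samples_per_group)),
               sprintf("AS%d", seq_len(samples_per_group))),
    group = factor(rep(c("WT", "AS"), each = samples_per_group),
                   levels = c("WT", "AS")),
    sex = sex, stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes,
                      is_informative = seq_len(n_genes) %in% info,
                      true_shift = ifelse(seq_len(n_genes) %in% info,
                                          shift_sd_units, 0))
  list(expr = expression_matrix(vals, meta), truth = truth)
}

#' Simulate a multi-peptide SILAC ratio table with known protein truth
#'
#' Each protein has a true H/L ratio of 1 (null) or `1 + true_pct_change /
#' 100` up, `1 / (1 + true_pct_change / 100)` down (changed proteins split
#' evenly, concordant across experiments).  Peptide ratios are log-normal
#' around the true ratio with log-SD `noise_sd`.
#'
#' @param n_proteins,n_changed Protein counts (`n_changed <= n_proteins`).
#' @param true_pct_change Planted percent change.
#' @param peptides_per_protein Peptides per protein per experiment.
#' @param noise_sd Log-scale peptide noise SD (0 = noiseless).
#' @param n_experiments Number of SILAC experiments (default 2).
#' @param seed RNG seed.
#' @return A list with `peptides` (a [peptide_ratio_table()]) and `truth`
#'   (data.frame `protein`, `true_ratio`, `is_null`, `direction`).
#' @export
simulate_silac <- function(n_proteins = 500, n_changed = 30,
                           true_pct_change = 25, peptides_per_protein = 8,
                           noise_sd = 0.1, n_experiments = 2, seed = 1) {
  stopifnot(n_changed <= n_proteins)
  set.seed(seed)
  prot <- sprintf("P%04d", seq_len(n_proteins))
  dir <- rep("none", n_proteins)
  if (n_changed > 0) {
    n_up <- ceiling(n_changed / 2)
    dir[seq_len(n_changed)] <- rep(c("up", "down"),
                                   c(n_up, n_changed - n_up))
  }
  r <- 1 + true_pct_change / 100
  true_ratio <- ifelse(dir == "up", r, ifelse(dir == "down", 1 / r, 1))
  recs <- expand.grid(peptide_i = seq_len(peptides_per_protein),
                      protein = prot,
                      experiment = sprintf("exp%d", seq_len(n_experiments)),
                      stringsAsFactors = FALSE)
  tr <- true_ratio[match(recs$protein, prot)]
  recs$ratio <- tr * exp(stats::rnorm(nrow(recs), 0, noise_sd))
  recs$peptide <- paste0(recs$protein, "_pep", recs$peptide_i)
  peptides <- peptide_ratio_table(
    recs[, c("protein", "peptide", "ratio", "experiment")])
  truth <- data.frame(protein = prot, true_ratio = true_ratio,
                      is_null = dir == "none", direction = dir,
                      stringsAsFactors = FALSE)
  list(peptides = peptides, truth = truth)
}
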
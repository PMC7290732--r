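test_that("coverage filter is inclusive and quantifies over every sample", {
  sites <- make_sites(3)
  n <- rbind(c(10L, 10L, 10L, 10L),    # boundary: retained
             c(50L, 50L, 9L, 50L),     # one sample below: removed
             c(11L, 12L, 13L, 14L))
  tab <- site_count_table(sites, make_samples(2), matrix(0L, 3, 4), n)
  kept <- coverage_filter(tab, diffedit_config(min_reads = 10))
  expect_equal(kept$sites$pos, sites$pos[c(1, 3)])
})

test_that("coverage filter matches the generator truth on a synthetic table", {
  set.seed(9)
  sites <- make_sites(100)
  n <- matrix(sample(10:80, 400, replace = TRUE), 100, 4)
  low <- sample(100, 37)
  n[cbind(low, sample(4, 37, replace = TRUE))] <- sample(0:9, 37, replace = TRUE)
  tab <- site_count_table(sites, make_samples(2), matrix(0L, 100, 4), n)
  expect_equal(nrow(coverage_filter(tab)$sites), 63L)
})

test_that("site_regression reduces to the group mean difference with equal weights", {
  r <- site_regression(c(2L, 2L, 6L, 6L), c(20L, 20L, 20L, 20L), c(0, 0, 1, 1))
  expect_equal(r$slope, 0.2)
  expect_gt(r$zstat, 0)
  # identical frequencies in both groups: exact null
  r0 <- site_regression(c(3L, 3L, 3L, 3L), c(30L, 30L, 30L, 30L), c(0, 0, 1, 1))
  expect_equal(r0$slope, 0)
  expect_false(call_site(r0)$significant)
})

test_that("site_regression matches an explicit weighted-normal-equations oracle", {
  k <- c(3L, 8L, 1L, 20L, 15L, 9L); n <- c(25L, 60L, 12L, 80L, 44L, 30L)
  g <- c(0, 0, 0, 1, 1, 1)
  r <- site_regression(k, n, g)
  # independent oracle: dense matrix algebra on the same weights
  ci <- editscan:::wilks_ci_table(k, n)
  W <- diag(1 / ci$sigma^2)
  X <- cbind(1, g)
  XtWX <- t(X) %*% W %*% X
  beta <- solve(XtWX, t(X) %*% W %*% ci$f_hat)
  expect_equal(r$slope, unname(beta[2, 1]), tolerance = 1e-10)
  expect_equal(r$se, sqrt(solve(XtWX)[2, 2]), tolerance = 1e-10)
  # slope also equals lm's WLS coefficient
  fit <- stats::lm(ci$f_hat ~ g, weights = 1 / ci$sigma^2)
  expect_equal(r$slope, unname(stats::coef(fit)[2]), tolerance = 1e-10)
})

test_that("call_site uses a strict 3-SD rule with sign-based direction", {
  mk <- function(z) structure(list(slope = z, se = 1, zstat = z),
                              class = "regression_result")
  expect_false(call_site(mk(3.0))$significant)     # strictly more than 3
  expect_true(call_site(mk(3.0000001))$significant)
  cl <- call_site(mk(-4.2))
  expect_true(cl$significant)
  expect_equal(cl$direction, "hypo")
  expect_equal(call_site(mk(0))$direction, "none")
})

test_that("run_diffedit recovers injected effects with correct direction", {
  sim <- simulate_pileups(pileup_sim_config(
    n_sites = 120, n_null_sites = 80, delta_f = 0.3, coverage_mean = 100,
    samples_per_group = 3, seed = 5))
  res <- run_diffedit(sim$table)
  eff <- !sim$truth$is_null
  expect_gte(mean(res$significant[eff]), 0.9)
  expect_true(all(res$direction[eff & res$significant] == "hyper"))
})

test_that("run_diffedit rejects a single group and passes empty tables through", {
  tab <- tiny_table()
  one <- tab
  one$samples$group <- factor(rep("WT", 4))
  expect_error(site_count_table(one$sites, one$samples, one$k, one$n),
               "two groups")
  empty <- tab[integer(0)]
  expect_equal(nrow(run_diffedit(empty)), 0L)
})

test_that("label swap negates slopes and swaps hyper/hypo exactly", {
  sim <- simulate_pileups(pileup_sim_config(
    n_sites = 80, n_null_sites = 60, delta_f = 0.25, coverage_mean = 60,
    samples_per_group = 3, seed = 13))
  tab <- sim$table
  res <- run_diffedit(tab)
  flipped <- site_count_table(
    tab$sites,
    transform(tab$samples, group = factor(group, levels = rev(levels(group)))),
    tab$k, tab$n)
  res2 <- run_diffedit(flipped)
  expect_equal(res2$slope, -res$slope, tolerance = 1e-12)
  expect_equal(res2$zstat, -res$zstat, tolerance = 1e-12)
  expect_equal(sum(res2$direction == "hyper"), sum(res$direction == "hypo"))
  expect_equal(sum(res2$direction == "hypo"), sum(res$direction == "hyper"))
})

test_that("hyper + hypo = significant and filtered sites carry no calls", {
  sim <- simulate_pileups(pileup_sim_config(
    n_sites = 150, n_null_sites = 100, delta_f = 0.2, coverage_mean = 15,
    samples_per_group = 3, seed = 31))
  res <- run_diffedit(sim$table)
  s <- summarize_diffedit(res)
  expect_equal(s$n_hyper + s$n_hypo, s$n_significant)
  expect_false(any(res$significant & !res$passed_coverage))
  expect_true(all(is.na(res$slope[!res$passed_coverage])))
})

test_that("power is monotone in coverage and effect size", {
  power_at <- function(cov, delta, seed = 17) {
    sim <- simulate_pileups(pileup_sim_config(
      n_sites = 150, n_null_sites = 0, delta_f = delta, coverage_mean = cov,
      samples_per_group = 4, seed = seed))
    res <- run_diffedit(sim$table)
    mean(res$significant[res$passed_coverage])
  }
  expect_lte(power_at(50, 0.1), power_at(200, 0.1))
  expect_lte(power_at(50, 0.1), power_at(50, 0.3))
})

test_that("summaries intersect panels with published rounding", {
  # percent = nearest integer, half away from zero
  expect_equal(editscan:::round_half_away(100 * 16 / 113), 14)
  expect_equal(editscan:::round_half_away(100 * 10 / 113), 9)
  expect_equal(editscan:::round_half_away(-0.5), -1)

  sim <- simulate_pileups(pileup_sim_config(
    n_sites = 60, n_null_sites = 30, delta_f = 0.35, coverage_mean = 150,
    samples_per_group = 3, seed = 8))
  res <- run_diffedit(sim$table)
  sig_genes <- unique(res$gene[res$significant])
  panel <- gene_panel("apoptosis", sig_genes[seq_len(min(3, length(sig_genes)))])
  s <- summarize_diffedit(res, list(panel))
  expect_equal(s$panel_counts$count, min(3, length(sig_genes)))
  expect_equal(s$panel_counts$percent,
               editscan:::round_half_away(100 * s$panel_counts$count /
                                            length(s$genes)))
  # degenerate: no significant sites -> flagged, no division error
  none <- run_diffedit(tiny_table())
  none$significant <- FALSE; none$direction <- "none"
  s0 <- summarize_diffedit(none, list(panel))
  expect_true(s0$undefined)
  expect_true(is.na(s0$panel_counts$percent))
})

test_that("the beyond_ci rule variant is stricter than the default", {
  cfgz <- diffedit_config(rule = "zstat")
  cfgc <- diffedit_config(rule = "beyond_ci")
  mk <- function(z) structure(list(slope = z, se = 1, zstat = z),
                              class = "regression_result")
  expect_true(call_site(mk(4), cfgz)$significant)
  expect_false(call_site(mk(4), cfgc)$significant)   # needs > 3 + 1.96
  expect_true(call_site(mk(5), cfgc)$significant)
})
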
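test_that("preprocess subsets to males, filters low genes, logs values", {
  ex <- tiny_expr()
  pre <- preprocess_expression(ex)
  expect_false("Beta" %in% rownames(pre$values))      # < 1 in all samples
  expect_true("Gamma" %in% rownames(pre$values))      # one sample >= 1
  expect_equal(unname(pre$values["Delta", 1]), log(3))  # ln(x + 1)
  # zero maps to zero
  v <- ex$values; v["Delta", 1] <- 0
  pre2 <- preprocess_expression(expression_matrix(v, ex$meta))
  expect_equal(unname(pre2$values["Delta", 1]), 0)

  meta_f <- ex$meta; meta_f$sex <- "F"
  expect_error(preprocess_expression(expression_matrix(ex$values, meta_f)),
               "male")
  meta_g <- ex$meta; meta_g$sex <- c("M", "M", "F", "F")
  expect_error(preprocess_expression(expression_matrix(ex$values, meta_g)),
               "group")
})

test_that("female samples are removed exactly", {
  sim <- simulate_expression(n_genes = 20, n_informative = 0,
                             samples_per_group = 4, n_female = 2, seed = 2)
  pre <- preprocess_expression(sim$expr)
  expect_equal(ncol(pre$values), 4L)
  expect_true(all(pre$meta$sex == "M"))
})

test_that("panel restriction intersects case-insensitively", {
  pre <- preprocess_expression(tiny_expr())
  p <- gene_panel("test", c("ALPHA", "gamma", "Missing1"))
  expect_message(sub <- restrict_to_panel(pre, p), "absent")
  expect_setequal(rownames(sub$values), c("Alpha", "Gamma"))
  expect_error(restrict_to_panel(pre, gene_panel("x", "Nowhere")), "no genes")
})

test_that("iterative selection is deterministic and obeys the sum rule", {
  sim <- simulate_expression(n_genes = 30, n_informative = 3,
                             shift_sd_units = 4, seed = 6)
  pre <- preprocess_expression(sim$expr)
  cfg <- rf_config(n_iterations = 25, trees_per_forest = 50,
                   top_k_per_iteration = 5, n_select = 3, seed = 11)
  s1 <- iterative_rf_select(pre, cfg)
  s2 <- iterative_rf_select(pre, cfg)
  expect_identical(s1$selection_freq, s2$selection_freq)
  expect_identical(s1$selected, s2$selected)
  # sum of recorded counts = iterations * min(top_k, n_genes)
  expect_equal(sum(s1$selection_freq) * cfg$n_iterations,
               cfg$n_iterations * 5)
})

test_that("single-iteration selection frequencies are 0/1 and top_k caps at p", {
  sim <- simulate_expression(n_genes = 8, n_informative = 2, seed = 3)
  pre <- preprocess_expression(sim$expr)
  s <- iterative_rf_select(pre, rf_config(n_iterations = 1,
                                          trees_per_forest = 30,
                                          top_k_per_iteration = 3,
                                          n_select = 2, seed = 4))
  expect_true(all(s$selection_freq %in% c(0, 1)))
  expect_warning(
    iterative_rf_select(pre, rf_config(n_iterations = 1, trees_per_forest = 10,
                                       top_k_per_iteration = 50, n_select = 2,
                                       seed = 4)),
    "exceeds")
})

test_that("informative genes win the selection frequencies", {
  sim <- simulate_expression(n_genes = 60, n_informative = 4,
                             shift_sd_units = 4, seed = 19)
  pre <- preprocess_expression(sim$expr)
  s <- iterative_rf_select(pre, rf_config(n_iterations = 60,
                                          trees_per_forest = 150,
                                          n_select = 4, seed = 19))
  expect_setequal(s$selected, sim$truth$gene[sim$truth$is_informative])
})

test_that("shuffled labels give no dominant gene", {
  sim <- simulate_expression(n_genes = 40, n_informative = 4,
                             shift_sd_units = 4, seed = 23)
  pre <- preprocess_expression(sim$expr)
  set.seed(23)
  null_meta <- pre$meta
  null_meta$group <- sample(null_meta$group)          # break the association
  null_expr <- expression_matrix(pre$values, null_meta)
  s <- iterative_rf_select(null_expr, rf_config(n_iterations = 60,
                                                trees_per_forest = 150,
                                                n_select = 4, seed = 23))
  # permutation reference for the maximum selection frequency
  ref <- vapply(1:8, function(i) {
    set.seed(100 + i)
    m <- pre$meta; m$group <- sample(m$group)
    max(iterative_rf_select(expression_matrix(pre$values, m),
                            rf_config(n_iterations = 60,
                                      trees_per_forest = 150,
                                      n_select = 4,
                                      seed = 100 + i))$selection_freq)
  }, 0)
  expect_lte(max(s$selection_freq), max(ref) + 0.15)
})

test_that("LDA validation separates what is separable", {
  # keep features < samples so the pooled covariance has full rank
  sim <- simulate_expression(n_genes = 5, n_informative = 5,
                             shift_sd_units = 6, seed = 29)
  pre <- preprocess_expression(sim$expr)
  expect_equal(lda_validate(pre), 1.0)

  # uninformative single constant gene: majority-class accuracy
  vals <- matrix(3, 1, 6, dimnames = list("Flat", NULL))
  meta <- data.frame(sample = paste0("s", 1:6),
                     group = c("WT", "WT", "WT", "WT", "AS", "AS"),
                     sex = "M")
  expect_equal(lda_validate(expression_matrix(vals, meta)), 4 / 6)
})

test_that("LDA on random labels sits near chance in expectation", {
  accs <- vapply(1:6, function(s) {
    sim <- simulate_expression(n_genes = 50, n_informative = 0,
                               samples_per_group = 3, seed = 200 + s)
    lda_validate(preprocess_expression(sim$expr))
  }, 0)
  expect_lt(mean(accs), 0.8)
  expect_gt(mean(accs), 0.2)
})

test_that("PCA projection is centered, oriented and degenerate-safe", {
  sim <- simulate_expression(n_genes = 20, n_informative = 20,
                             shift_sd_units = 6, seed = 37)
  pre <- preprocess_expression(sim$expr)
  pc <- pca_project(pre)
  # PC1 separates the groups with a margin
  expect_true(max(pc$PC1[pc$group == "WT"]) < min(pc$PC1[pc$group == "AS"]) ||
              min(pc$PC1[pc$group == "WT"]) > max(pc$PC1[pc$group == "AS"]))
  # identical samples: all scores zero
  vals <- matrix(2, 4, 4, dimnames = list(paste0("g", 1:4), NULL))
  meta <- data.frame(sample = paste0("s", 1:4),
                     group = rep(c("A", "B"), 2), sex = "M")
  pc0 <- pca_project(expression_matrix(vals, meta))
  expect_true(all(pc0$PC1 == 0) && all(pc0$PC2 == 0))
  expect_true(attr(pc0, "degenerate"))
  # duplicating every sample leaves original scores unchanged
  dup_vals <- cbind(pre$values, pre$values)
  dup_meta <- rbind(pre$meta, transform(pre$meta, sample = paste0(sample, "b")))
  dup_vals <- matrix(dup_vals, nrow(pre$values),
                     dimnames = list(rownames(pre$values), dup_meta$sample))
  pc2 <- pca_project(expression_matrix(dup_vals, dup_meta))
  expect_equal(pc2$PC1[seq_len(nrow(pc))], pc$PC1, tolerance = 1e-8)
})

test_that("select_markers runs the full stage end to end", {
  sim <- simulate_expression(n_genes = 50, n_informative = 5,
                             shift_sd_units = 6, seed = 41)
  panel <- gene_panel("apoptosis", sim$truth$gene[1:20])
  sel <- select_markers(sim$expr, panel,
                        rf_config(n_iterations = 40, trees_per_forest = 100,
                                  n_select = 5, seed = 41))
  expect_setequal(sel$selected, sim$truth$gene[sim$truth$is_informative])
  expect_equal(sel$lda_accuracy, 1.0)
  expect_equal(nrow(sel$pc_scores), 12L)
})
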
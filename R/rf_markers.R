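#' Preprocess a hippocampal-style expression matrix
#'
#' Subsets to male samples, removes genes whose expression is below 1 in
#' ALL retained samples, and transforms the remaining values to the
#' natural-log scale as `ln(x + 1)` (the +1 offset keeps FPKM zeros
#' finite and maps 0 to 0).
#'
#' @param expr An [expression_matrix()].
#' @return A preprocessed `expression_matrix` (values on the log scale).
#' @export
preprocess_expression <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  males <- expr$meta$sex == "M"
  if (!any(males)) stop("no male samples to analyze")
  meta <- expr$meta[males, , drop = FALSE]
  meta$group <- droplevels(meta$group)
  if (nlevels(meta$group) < 2L) {
    stop("a group is absent after male-only subsetting")
  }
  vals <- expr$values[, males, drop = FALSE]
  keep <- rowSums(vals >= 1) > 0          # drop genes < 1 in all samples
  vals <- log1p(vals[keep, , drop = FALSE])
  expression_matrix(vals, meta)
}

#' Restrict an expression matrix to a gene panel
#'
#' Keeps the intersection of matrix genes and panel genes, matched
#' case-insensitively (symbols are stored verbatim).  Panel genes absent
#' from the matrix are reported with a message.
#'
#' @param expr An [expression_matrix()].
#' @param panel A [gene_panel()].
#' @return The restricted `expression_matrix`.
#' @export
restrict_to_panel <- function(expr, panel) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(panel, "gene_panel"))
  hit <- toupper(rownames(expr$values)) %in% toupper(panel$genes)
  if (!any(hit)) stop("panel '", panel$name, "' has no genes in the matrix")
  absent <- panel$genes[!(toupper(panel$genes) %in% toupper(rownames(expr$values)))]
  if (length(absent)) {
    message("panel '", panel$name, "': ", length(absent),
            " gene(s) absent from the matrix")
  }
  expression_matrix(expr$values[hit, , drop = FALSE], expr$meta)
}

#' Iterative random-forest configuration
#'
#' @param n_iterations Number of independent forest fits whose top features
#'   are tallied (default 10000).
#' @param trees_per_forest Trees per forest (default 500).
#' @param top_k_per_iteration Features recorded per fit, ranked by
#'   importance (default 10).
#' @param n_select Panel size to emit (40 for the apoptosis panel and 10
#'   for proliferation in the reference analysis; default 10).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param importance `"gini"` (mean decrease in impurity, default) or
#'   `"permutation"` (out-of-bag accuracy drop).
#' @param seed Master seed; each iteration derives its own sub-seed.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_iterations = 10000, trees_per_forest = 500,
                      top_k_per_iteration = 10, n_select = 10,
                      mtry = NULL, importance = c("gini", "permutation"),
                      seed = 1) {
  importance <- match.arg(importance)
  stopifnot(n_iterations >= 1, trees_per_forest >= 1,
            top_k_per_iteration >= 1, n_select >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 trees_per_forest = as.integer(trees_per_forest),
                 top_k_per_iteration = as.integer(top_k_per_iteration),
                 n_select = as.integer(n_select), mtry = mtry,
                 importance = importance, seed = as.integer(seed)),
            class = "rf_config")
}

#' Iterative random-forest marker selection
#'
#' Fits `n_iterations` random forests on the (genes x samples) matrix with
#' fresh sub-seeds, records the `top_k_per_iteration` genes by importance
#' in each fit, and ranks genes by the fraction of iterations in which
#' they were recorded.  The `n_select` genes with the highest selection
#' frequency form the marker panel (ties broken lexicographically by gene
#' symbol).
#'
#' @param expr A preprocessed [expression_matrix()] (two groups).
#' @param config An [rf_config()].
#' @return A list of class `marker_selection`: `selection_freq` (named,
#'   sorted decreasing), `selected`, `config`.
#' @export
iterative_rf_select <- function(expr, config = rf_config()) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(config, "rf_config"))
  y <- as.integer(expr$meta$group) - 1L
  if (length(unique(y)) != 2L) stop("two classes required")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  x <- t(expr$values)                       # samples x genes
  genes <- colnames(x)
  p <- length(genes)
  top_k <- config$top_k_per_iteration
  if (top_k > p) {
    warning("top_k_per_iteration (", top_k, ") exceeds gene count (", p,
            "); recording all genes each iteration")
    top_k <- p
  }
  mtry <- if (is.null(config$mtry)) max(1L, floor(sqrt(p))) else as.integer(config$mtry)
  counts <- integer(p)
  for (it in seq_len(config$n_iterations)) {
    sub_seed <- (config$seed * 2654435761 + it * 40503) %% 2^31
    imp <- cpp_rf_importance(x, y, config$trees_per_forest, mtry,
                             sub_seed, config$importance)
    # lexicographic tie-break inside each iteration, too
    top <- order(-imp, genes)[seq_len(top_k)]
    counts[top] <- counts[top] + 1L
  }
  freq <- counts / config$n_iterations
  names(freq) <- genes
  ord <- order(-freq, genes)
  freq <- freq[ord]
  n_sel <- min(config$n_select, p)
  structure(list(selection_freq = freq,
                 selected = names(freq)[seq_len(n_sel)],
                 config = config),
            class = "marker_selection")
}

#' @export
print.marker_selection <- function(x, ...) {
  cat(sprintf("marker_selection: %d gene(s) over %d iterations; top: %s\n",
              length(x$selected), x$config$n_iterations,
              paste(utils::head(x$selected, 5), collapse = ", ")))
  invisible(x)
}

# linear discriminant training on samples x features x with 0/1 labels;
# pooled within-class covariance ridge-regularized by eps = 1e-6 tr(S)/d
# so that p >= n stays solvable.  Returns a classify(xnew) function, or
# NULL when the covariance is degenerate (caller falls back to centroids).
lda_train <- function(x, y, ridge = 1e-6) {
  d <- ncol(x)
  m0 <- colMeans(x[y == 0L, , drop = FALSE])
  m1 <- colMeans(x[y == 1L, , drop = FALSE])
  cc <- x
  cc[y == 0L, ] <- sweep(x[y == 0L, , drop = FALSE], 2, m0)
  cc[y == 1L, ] <- sweep(x[y == 1L, , drop = FALSE], 2, m1)
  S <- crossprod(cc) / max(1L, nrow(x) - 2L)
  tr <- sum(diag(S))
  if (tr <= 0) return(NULL)
  S <- S + diag(ridge * tr / d, d)
  w <- tryCatch(solve(S, m1 - m0), error = function(e) NULL)
  if (is.null(w)) return(NULL)
  # threshold from class means and log prior odds
  c0 <- sum(w * (m0 + m1)) / 2 - log(sum(y == 1L) / sum(y == 0L))
  function(xnew) as.integer(drop(xnew %*% w) > c0)
}

#' Leave-one-out LDA validation of a marker panel
#'
#' Leave-one-out cross-validated linear-discriminant accuracy on the
#' selected-gene matrix.  The pooled within-class covariance is ridge-
#' regularized (`epsilon = 1e-6 * trace / dim`) so more genes than samples
#' is handled; when a training class degenerates to one sample or the
#' covariance has zero trace, classification falls back to the nearest
#' class centroid (ties go to the majority training class).
#'
#' @param expr An [expression_matrix()] restricted to the selected genes.
#' @return Accuracy in `[0, 1]`.
#' @export
lda_validate <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- t(expr$values)
  y <- as.integer(expr$meta$group) - 1L
  if (length(unique(y)) != 2L) stop("two classes required")
  n <- nrow(x)
  correct <- 0L
  for (i in seq_len(n)) {
    xt <- x[-i, , drop = FALSE]; yt <- y[-i]
    cls <- NULL
    if (min(table(yt)) >= 2L) cls <- lda_train(xt, yt)
    if (is.null(cls)) {
      # nearest-centroid fallback
      m0 <- colMeans(xt[yt == 0L, , drop = FALSE])
      m1 <- colMeans(xt[yt == 1L, , drop = FALSE])
      d0 <- sum((x[i, ] - m0)^2); d1 <- sum((x[i, ] - m1)^2)
      pred <- if (d1 < d0) 1L else if (d0 < d1) 0L else
        as.integer(sum(yt == 1L) > sum(yt == 0L))
    } else {
      pred <- cls(x[i, , drop = FALSE])
    }
    correct <- correct + (pred == y[i])
  }
  correct / n
}

#' Project samples onto the first two principal components
#'
#' Per-gene centered singular-value decomposition of the selected-gene
#' matrix.  Sign convention: each loading vector is oriented so its sum is
#' non-negative, making the projection deterministic.  If fewer than two
#' non-degenerate dimensions exist, the second component is reported as
#' zeros and the result carries `attr(, "degenerate") = TRUE`.
#'
#' @param expr An [expression_matrix()].
#' @return A data.frame `sample`, `group`, `PC1`, `PC2`.
#' @export
pca_project <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  x <- t(expr$values)                     # samples x genes
  if (nrow(x) < 2L) stop("need at least 2 samples")
  xc <- sweep(x, 2, colMeans(x))
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > max(tol, 1e-12))
  scores <- matrix(0, nrow(x), 2)
  degenerate <- rank < 2L
  for (comp in seq_len(min(2L, rank))) {
    v <- sv$v[, comp]
    s <- if (sum(v) < 0) -1 else 1        # deterministic orientation
    scores[, comp] <- s * xc %*% v
  }
  out <- data.frame(sample = expr$meta$sample, group = expr$meta$group,
                    PC1 = scores[, 1], PC2 = scores[, 2])
  attr(out, "degenerate") <- degenerate
  out
}

#' Run the full marker-selection stage
#'
#' Preprocess, restrict to a panel, select markers by iterative random
#' forest, validate with leave-one-out LDA, and project on the first two
#' PCs — the complete hippocampal marker workflow for one panel.
#'
#' @param expr A raw [expression_matrix()].
#' @param panel A [gene_panel()].
#' @param config An [rf_config()].
#' @return A `marker_selection` with `lda_accuracy` and `pc_scores` filled.
#' @export
select_markers <- function(expr, panel, config = rf_config()) {
  pre <- preprocess_expression(expr)
  sub <- restrict_to_panel(pre, panel)
  sel <- iterative_rf_select(sub, config)
  hit <- toupper(rownames(sub$values)) %in% toupper(sel$selected)
  chosen <- expression_matrix(sub$values[hit, , drop = FALSE], sub$meta)
  sel$lda_accuracy <- lda_validate(chosen)
  sel$pc_scores <- pca_project(chosen)
  sel
}
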
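#' Binomial log-likelihood
#'
#' Log-likelihood of a binomial proportion `p` given `k` successes out of
#' `n` trials, up to the binomial coefficient (which cancels in likelihood
#' ratios).  Uses the convention `0 * log(0) = 0`, and returns `-Inf` when
#' `p = 0` with `k > 0` or `p = 1` with `k < n`.
#'
#' @param k Number of edited reads (0 <= k <= n).
#' @param n Total coverage (n >= 1).
#' @param p Editing probability in `[0, 1]`.  May be a vector.
#' @return `k*log(p) + (n-k)*log(1-p)`, vectorized over `p`.
#' @export
#' @examples
#' binomial_loglik(5, 10, 0.5)  # 10 * log(0.5)
binomial_loglik <- function(k, n, p) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n < 1 || k < 0 || k > n) {
    stop("binomial_loglik: require 0 <= k <= n and n >= 1 (got k=", k,
         ", n=", n, ")")
  }
  if (any(p < 0 | p > 1)) stop("binomial_loglik: p must lie in [0, 1]")
  out <- numeric(length(p))
  for (i in seq_along(p)) {
    pi <- p[i]
    t1 <- if (k == 0) 0 else k * log(pi)          # 0*log(0) = 0
    t2 <- if (k == n) 0 else (n - k) * log1p(-pi)
    out[i] <- t1 + t2
  }
  out
}

#' Wilks likelihood-ratio confidence interval for a binomial proportion
#'
#' Inverts the binomial likelihood-ratio test: the interval is the set of
#' `p` with `2 * (l(f_hat) - l(p)) <= qchisq(level, df = 1)`, where `f_hat
#' = k/n` is the maximum-likelihood editing frequency.  Bounds are located
#' by bisection on each side of `f_hat` (the deviance is monotone on either
#' side) to absolute tolerance `1e-8`.  `lower` is exactly 0 iff `k = 0`
#' and `upper` is exactly 1 iff `k = n`.
#'
#' @param k Edited-read count.
#' @param n Total coverage (>= 1).
#' @param level Confidence level, default 0.95.
#' @return An object of class `editing_ci`: a list with `f_hat`, `lower`,
#'   `upper`, `level`, `k`, `n`.
#' @export
#' @examples
#' wilks_ci(5, 10)
wilks_ci <- function(k, n, level = 0.95) {
  if (length(k) != 1L || length(n) != 1L) stop("wilks_ci is scalar; see wilks_ci_table")
  if (n < 1 || k < 0 || k > n) stop("wilks_ci: require 0 <= k <= n, n >= 1")
  if (level <= 0 || level >= 1) stop("wilks_ci: level must be in (0, 1)")
  f_hat <- k / n
  q <- stats::qchisq(level, df = 1)
  ll_hat <- binomial_loglik(k, n, f_hat)
  # deviance D(p) = 2 * (ll_hat - ll(p)); root of D(p) - q on each side
  dev <- function(p) 2 * (ll_hat - binomial_loglik(k, n, p))
  tol <- 1e-8
  bisect <- function(lo, hi, increasing) {
    # find p with dev(p) = q; dev is monotone on [lo, hi]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      d <- dev(mid)
      below <- d <= q
      if (increasing) {            # dev grows toward hi
        if (below) lo <- mid else hi <- mid
      } else {                     # dev shrinks toward hi
        if (below) hi <- mid else lo <- mid
      }
    }
    (lo + hi) / 2
  }
  lower <- if (k == 0) 0 else bisect(0, f_hat, increasing = FALSE)
  upper <- if (k == n) 1 else bisect(f_hat, 1, increasing = TRUE)
  structure(
    list(f_hat = f_hat, lower = lower, upper = upper,
         level = level, k = k, n = n),
    class = "editing_ci"
  )
}

#' @export
print.editing_ci <- function(x, ...) {
  cat(sprintf("editing frequency %.6g  [%0.6g, %0.6g]  (%g%% Wilks LRT CI, k=%d, n=%d)\n",
              x$f_hat, x$lower, x$upper, 100 * x$level, x$k, x$n))
  invisible(x)
}

#' Map a confidence interval to a standard-deviation-scale weight
#'
#' Converts a Wilks interval into an approximate standard deviation of the
#' frequency estimate, `sigma = (upper - lower) / (2 * z)` with `z` the
#' standard-normal `(1 + level)/2` quantile.  The result is floored at
#' `1 / (2n)` so that boundary sites (`k = 0` or `k = n`, where one bound
#' sits on the parameter-space boundary) never receive infinite weight in
#' the downstream regression.
#'
#' @param ci An `editing_ci` object from [wilks_ci()].
#' @return A positive scalar standard deviation.
#' @export
ci_to_sd <- function(ci) {
  stopifnot(inherits(ci, "editing_ci"))
  z <- stats::qnorm((1 + ci$level) / 2)
  max((ci$upper - ci$lower) / (2 * z), 1 / (2 * ci$n))
}

# CI bounds and sigma for a set of (k, n) pairs, computed once per unique
# pair.  Internal workhorse for run_diffedit on large tables.
wilks_ci_table <- function(k, n, level = 0.95) {
  stopifnot(length(k) == length(n))
  key <- paste(k, n)
  uk <- !duplicated(key)
  res <- vapply(which(uk), function(i) {
    ci <- wilks_ci(k[i], n[i], level)
    c(ci$lower, ci$upper, ci_to_sd(ci))
  }, numeric(3))
  idx <- match(key, key[uk])
  data.frame(
    k = k, n = n, f_hat = k / n,
    lower = res[1L, idx], upper = res[2L, idx], sigma = res[3L, idx]
  )
}
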
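# Rank statistics used in the performance analyses. Definitions are pinned
# (mid-ranks, t approximation, exact signed-rank distribution by
# convolution) so results are bit-stable across platforms.

#' Spearman rank correlation with t-approximation p-value
#'
#' Mid-ranks for ties, Pearson correlation on the ranks, two-sided p from
#' `t = rho sqrt((n-2)/(1-rho^2))` with `n - 2` degrees of freedom.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`.
#' @return List with `rho` and `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' `V` is the sum of ranks (mid-ranks for tied magnitudes) of positive
#' differences `after - before`. Zero differences are dropped under the
#' classic policy, or kept in the ranking but excluded from `V` under
#' Pratt's. The two-sided p-value is exact for `n <= exact_limit` retained
#' pairs — computed from the full sign-flip distribution, which a
#' generating-function convolution enumerates — and a normal approximation
#' with tie correction otherwise.
#'
#' @param before,after Paired numeric vectors.
#' @param zero_policy `"wilcoxon"` (drop zero differences) or `"pratt"`.
#' @param exact_limit Largest `n` for the exact distribution (default 25).
#' @return List with `V`, `p_value`, `n` (retained pairs) and `method`.
#' @export
wilcoxon_signed_rank <- function(before, after,
                                 zero_policy = c("wilcoxon", "pratt"),
                                 exact_limit = 25L) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(length(before) == length(after))
  d <- after - before
  if (all(d == 0)) stop("all differences are zero")
  if (zero_policy == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
    active <- rep(TRUE, length(d))
  } else {
    r <- rank(abs(d))
    active <- d != 0
  }
  V <- sum(r[active & d > 0])
  n <- sum(active)
  if (n <= exact_limit) {
    # exact null distribution of V over the 2^n sign assignments of the
    # active ranks; doubling makes mid-ranks integral
    r2 <- round(2 * r[active])
    f <- c(1, numeric(sum(r2)))
    for (ri in r2) {
      g <- f
      g[(ri + 1):length(f)] <- g[(ri + 1):length(f)] + f[1:(length(f) - ri)]
      f <- g
    }
    f <- f / 2^n
    v2 <- round(2 * V)
    mu <- sum(r2) / 2
    extreme <- abs(seq_along(f) - 1 - mu) >= abs(v2 - mu) - 1e-9
    p <- min(1, sum(f[extreme]))
    method <- "exact"
  } else {
    mu <- sum(r[active]) / 2
    ties <- table(r[active])
    sigma2 <- sum(r[active]^2) / 4
    z <- (V - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    p <- min(1, p)
    method <- "normal"
  }
  list(V = V, p_value = p, n = n, method = method)
}

#' Brown-Forsythe (Levene-on-medians) test for equal spread
#'
#' One-way ANOVA F statistic on the absolute deviations from the group
#' medians, `z_ij = |x_ij - median_j|`.
#'
#' @param groups List of numeric vectors, each of length >= 2.
#' @return List with `W` (the F statistic), `p_value`, `df1`, `df2`.
#' @export
levene_median_test <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
  z <- unlist(lapply(groups, function(x) abs(x - stats::median(x))))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  n <- length(z); k <- nlevels(g)
  zbar <- mean(z)
  zg <- tapply(z, g, mean)
  ssb <- sum(lengths(groups) * (zg - zbar)^2)
  ssw <- sum((z - zg[g])^2)
  if (ssw == 0) {
    if (ssb == 0) return(list(W = 0, p_value = 1, df1 = k - 1, df2 = n - k))
    stop("degenerate input: zero within-group spread in |x - median|")
  }
  W <- (ssb / (k - 1)) / (ssw / (n - k))
  list(W = W, p_value = stats::pf(W, k - 1, n - k, lower.tail = FALSE),
       df1 = k - 1, df2 = n - k)
}
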
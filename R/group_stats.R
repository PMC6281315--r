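#' One-tailed exact Wilcoxon matched-pairs test
#'
#' Differences are `after - before`; zero differences are dropped (Wilcoxon
#' convention). For `n <= 25` pairs without ties in the absolute differences
#' the p-value comes from the exact signed-rank distribution; with ties and
#' `n <= 20` it is computed by full enumeration of all `2^n` sign
#' assignments of the mid-ranked absolute differences; otherwise the normal
#' approximation with continuity and tie correction is used. With all `n`
#' differences in the stated direction the exact one-tailed p is `2^(-n)` —
#' 0.03125 at n = 5, 0.015625 at n = 6, 0.00390625 at n = 8.
#'
#' @param before,after Paired numeric vectors (per-recording values).
#' @param direction `"less"` tests whether `after` tends below `before`
#'   (a reduction); `"greater"` the opposite.
#' @return List with `statistic` (W+, sum of ranks of positive differences),
#'   `p` (one-tailed), `n` (pairs after dropping zeros), `method`.
#' @export
wilcoxon_one_tailed <- function(before, after, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  stopifnot(length(before) == length(after))
  d <- as.numeric(after) - as.numeric(before)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate pairs: all differences are zero")
  if (n < 5L) warning("fewer than 5 non-zero pairs; test is very low powered")
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  # one-tailed in the requested direction: small W+ favours "less"
  w_obs <- if (direction == "less") w_pos else sum(rk) - w_pos
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25L) {
    p <- stats::psignrank(w_obs, n)
    method <- "exact_signed_rank"
  } else if (ties && n <= 20L) {
    p <- signed_rank_enum_p(rk, w_obs)
    method <- "exact_enumeration"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (w_obs - mu + 0.5) / sqrt(sig2)
    p <- stats::pnorm(z)
    method <- "normal_approx"
  }
  list(statistic = w_pos, p = min(1, max(p, .Machine$double.xmin)), n = n, method = method)
}

# P(W <= w_obs) over all 2^n sign assignments of the given ranks
signed_rank_enum_p <- function(rk, w_obs) {
  n <- length(rk)
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(m %*% rk)
  mean(w_all <= w_obs + 1e-9)
}

#' One-tailed Mann-Whitney U test
#'
#' `U` counts pairs `(x_i, y_j)` with `x_i > y_j` (ties count 1/2). Without
#' ties and `n + m <= 40` the exact U distribution is used; with ties and
#' `choose(n+m, n) <= 2e5` the permutation distribution is fully enumerated
#' over group assignments of the mid-ranked pooled sample; otherwise the
#' normal approximation with tie correction applies.
#'
#' @param x,y Numeric vectors for the two groups (n, m >= 3).
#' @param direction `"less"` tests whether `x` tends below `y`; `"greater"`
#'   the opposite.
#' @return List with `statistic` (U for x over y), `p` (one-tailed), `n`,
#'   `m`, `method`.
#' @export
mann_whitney_one_tailed <- function(x, y, direction = c("less", "greater")) {
  direction <- match.arg(direction)
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x); m <- length(y)
  if (n == 0L || m == 0L) stop("empty group")
  if (n < 3L || m < 3L) warning("fewer than 3 observations in a group")
  rk <- rank(c(x, y))
  u_x <- sum(rk[seq_len(n)]) - n * (n + 1) / 2 # pairs with x > y (ties 1/2)
  u_obs <- if (direction == "less") u_x else n * m - u_x
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n + m <= 40L) {
    p <- stats::pwilcox(u_obs, n, m)
    method <- "exact_rank_sum"
  } else if (ties && choose(n + m, n) <= 2e5) {
    # with ties the U distribution need not be symmetric: use P(U_x <= u) for
    # "less" and P(U_x >= u) for "greater" (identical to P(U_y <= n m - u))
    p <- rank_sum_enum_p(rk, n, u_x, lower = direction == "less")
    method <- "exact_enumeration"
  } else {
    mu <- n * m / 2
    N <- n + m
    tie_tab <- table(rk)
    sig2 <- n * m / 12 * (N + 1 - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (u_obs - mu + 0.5) / sqrt(sig2)
    p <- stats::pnorm(z)
    method <- "normal_approx"
  }
  list(statistic = u_x, p = min(1, max(p, .Machine$double.xmin)), n = n, m = m,
       method = method)
}

# tail probability of U over all assignments of n of the pooled ranks to x
rank_sum_enum_p <- function(rk, n, u_obs, lower = TRUE) {
  combs <- utils::combn(length(rk), n)
  u_all <- colSums(matrix(rk[combs], nrow = n)) - n * (n + 1) / 2
  if (lower) mean(u_all <= u_obs + 1e-9) else mean(u_all >= u_obs - 1e-9)
}

#' Normalise a binned time-course to its control window
#'
#' Every bin is divided by the mean of the first `control_window` bins, so the
#' control-window mean of the output is exactly 1. Idempotent: normalising an
#' already-normalised series is the identity.
#'
#' @param bins Numeric vector of per-bin values (control bins first).
#' @param control_window Number of leading control bins (default 5).
#' @return Normalised numeric vector.
#' @export
normalize_timecourse <- function(bins, control_window = 5L) {
  if (length(bins) < control_window)
    stop(sprintf("need at least %d control bins", control_window))
  ctrl <- mean(bins[seq_len(control_window)])
  if (!is.finite(ctrl) || ctrl <= 0) stop("control-window mean must be > 0")
  bins / ctrl
}

#' Percent change between a before and an after mean
#'
#' Reported with the reduction-positive sign convention: `100 * (before -
#' after) / before`, so a drop from 10 to 6 is a 40% reduction and an increase
#' yields a negative value.
#'
#' @param before_mean,after_mean Positive scalar summaries.
#' @return Percent reduction (negative for increases).
#' @export
percent_change <- function(before_mean, after_mean) {
  if (!is.finite(before_mean) || before_mean <= 0) stop("before_mean must be > 0")
  100 * (before_mean - after_mean) / before_mean
}

#' Mean and standard error of the mean
#' @param x Numeric vector.
#' @return List with `mean`, `sem`, `n`.
#' @export
mean_sem <- function(x) {
  x <- x[is.finite(x)]
  list(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}
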
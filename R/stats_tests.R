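#' Mann-Whitney U test (exact small-sample or normal approximation)
#'
#' The U statistic counts pairs where an `x` observation exceeds a `y`
#' observation, with ties contributing one half. In exact mode the null
#' distribution of U is obtained by enumerating all `choose(n+m, n)`
#' assignments of the pooled mid-ranks to the first group, so ties are
#' handled exactly; the two-sided p-value sums the probability of all
#' splits at least as far from the null mean `nm/2` as the observed U.
#' Approximate mode uses the normal approximation with the usual tie
#' correction of the variance and a 0.5 continuity correction.
#'
#' @param x,y Nonempty numeric vectors.
#' @param mode `"exact"` (requires combined n at most 20) or
#'   `"approximate"`.
#' @return List with `U` (for the first sample) and `p_two_sided`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4), mode = "exact") # p = 1/3
#' @export
mann_whitney <- function(x, y, mode = c("exact", "approximate")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y))
    stop("both groups must be nonempty", call. = FALSE)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled) # mid-ranks for ties
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  if (mode == "exact") {
    if (n + m > 20)
      stop("exact mode requires combined sample size <= 20", call. = FALSE)
    splits <- utils::combn(n + m, n)
    U_all <- colSums(matrix(r[splits], nrow = n)) - n * (n + 1) / 2
    center <- n * m / 2
    eps <- 1e-9
    p <- mean(abs(U_all - center) >= abs(U_obs - center) - eps)
  } else {
    mu <- n * m / 2
    nt <- n + m
    ties <- table(pooled)
    sigma2 <- n * m / 12 *
      ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sigma2 <= 0) return(list(U = U_obs, p_two_sided = 1))
    z <- (abs(U_obs - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  list(U = U_obs, p_two_sided = p)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the hypergeometric null with both margins
#' fixed, defined by the "as or less probable" rule: the sum of the
#' probabilities of all tables with the same margins whose probability
#' does not exceed (within a small relative tolerance) that of the
#' observed table.
#'
#' @param table 2x2 matrix (or object coercible to one) of nonnegative
#'   integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(1, 0, 4, 11), nrow = 2)) # 0.3125
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2, 2)))
    stop("table must be 2x2", call. = FALSE)
  if (any(tb < 0) || any(tb != round(tb)))
    stop("cells must be nonnegative integers", call. = FALSE)
  r1 <- sum(tb[1, ]); c1 <- sum(tb[, 1]); nt <- sum(tb)
  if (nt == 0) return(1)
  support <- max(0, c1 - (nt - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, nt - r1, c1)
  p_obs <- stats::dhyper(tb[1, 1], r1, nt - r1, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(1, p)
}
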
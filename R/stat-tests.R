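#' Two-tailed Fisher exact test by full hypergeometric enumeration
#'
#' Tests association in a 2x2 contingency table (rows = groups, columns =
#' positive/negative). With both margins fixed, the first cell follows a
#' hypergeometric distribution; the two-sided p-value is the sum of the
#' point probabilities of every table (with the same margins) whose point
#' probability does not exceed that of the observed table. Ties in point
#' probability are accepted within a relative tolerance of 1e-12, because
#' tables on opposite tails can have mathematically equal probabilities
#' that differ only in floating point.
#'
#' This is the dominant two-sided convention (the one used by common
#' analysis software); it is implemented here by direct enumeration over
#' the feasible range of the first cell, with probabilities computed from
#' log-binomial coefficients.
#'
#' @param table A 2x2 matrix or data frame of nonnegative integer counts
#'   `rbind(c(a, b), c(c, d))`, or a length-4 vector `c(a, b, c, d)`.
#' @return A list with `p_value`, `odds_ratio` (sample cross-product
#'   ratio, `NA` when undefined), and `table`.
#' @examples
#' # AR-v567es-positive single CTCs, CRPC (6/53) vs NEPC (10/17)
#' fisher_exact_two_tailed(rbind(c(6, 47), c(10, 7)))$p_value
#' @export
fisher_exact_two_tailed <- function(table) {
  x <- as.integer(round(as.numeric(as.matrix(table))))
  if (length(x) != 4) stop("need a 2x2 table")
  if (any(x < 0)) stop("counts must be nonnegative")
  m <- matrix(x, nrow = 2)
  a <- m[1, 1]; b <- m[1, 2]; cc <- m[2, 1]; d <- m[2, 2]
  N <- a + b + cc + d
  if (N < 1) stop("table total must be >= 1")
  r1 <- a + b          # row-1 margin
  c1 <- a + cc         # column-1 margin
  lo <- max(0L, r1 + c1 - N)
  hi <- min(r1, c1)
  support <- lo:hi
  logp <- lchoose(c1, support) + lchoose(N - c1, r1 - support) -
    lchoose(N, r1)
  p <- exp(logp)
  p_obs <- p[support == a]
  p_value <- min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
  or <- if (b * cc > 0) (a * d) / (b * cc) else NA_real_
  list(p_value = p_value, odds_ratio = or, table = m)
}

#' Mann-Whitney U test (two-sided) with exact small-sample branch
#'
#' Rank-sum comparison of two independent samples, as used for group
#' comparisons of log2-transformed expression counts. The U statistic is
#' computed from midranks (average ranks for ties). For small samples
#' (`n_x + n_y <= exact_max`, default 12) the null distribution of U is
#' obtained by full enumeration of all group assignments of the pooled
#' ranks, and the two-sided p-value is twice the smaller tail probability,
#' capped at 1. For larger samples the normal approximation is used with
#' the tie-corrected variance and a 0.5 continuity correction.
#'
#' @param x,y Nonempty numeric samples.
#' @param exact_max Total-sample-size ceiling for the exact branch
#'   (default 12).
#' @return A list with `U` (for the first sample), `p_value`, and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(x, y, exact_max = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))  # midranks
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (N <= exact_max) {
    idx <- utils::combn(N, nx)
    us <- colSums(matrix(r[idx], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p_lo <- mean(us <= u_obs + eps)
    p_hi <- mean(us >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(U = u_obs, p_value = p, method = "exact"))
  }
  mu <- nx * ny / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nx * ny / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) {  # all values identical
    return(list(U = u_obs, p_value = 1, method = "normal_approx"))
  }
  z <- (u_obs - mu - sign(u_obs - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = u_obs, p_value = p, method = "normal_approx")
}

#' Log2 transform of nonnegative counts
#'
#' `log2(count + offset)`; the default offset of 1 maps zero counts to
#' zero on the transformed scale.
#'
#' @param raw_counts Nonnegative numeric vector.
#' @param offset Pseudocount added before the logarithm (default 1).
#' @return Transformed numeric vector.
#' @export
log2_transform <- function(raw_counts, offset = 1) {
  raw_counts <- as.numeric(raw_counts)
  if (any(raw_counts < 0, na.rm = TRUE)) stop("counts must be nonnegative")
  log2(raw_counts + offset)
}
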
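#' Two-sided Fisher exact test for a 2x2 table
#'
#' Computes the two-sided p value as the sum of probabilities, under the
#' hypergeometric distribution with the observed margins fixed, of every
#' table whose probability does not exceed that of the observed table
#' (with a small relative tolerance to absorb floating-point ties). A
#' table with any zero margin carries no information and returns p = 1.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return two-sided p value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))  # ~0.4857
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0) ||
      any(tab != floor(tab)) || any(!is.finite(tab))) {
    stop("`tab` must be a 2x2 matrix of nonnegative integers",
         call. = FALSE)
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  lo <- max(0L, c1 - r2)
  hi <- min(c1, r1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

## Rank-sum U statistic of sample a within the pooled midranks.
u_statistic <- function(ranks, idx_a) {
  n1 <- length(idx_a)
  sum(ranks[idx_a]) - n1 * (n1 + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' For small samples (combined n <= `exact_max`, default 12) the p value
#' is exact: all assignments of the pooled midranks to the two groups are
#' enumerated and the two-sided p is the permutation probability of a U
#' statistic at least as far from its null mean `n1 n2 / 2` as observed.
#' For larger samples a tie-corrected normal approximation is used.
#'
#' @param a,b numeric samples.
#' @param exact_max largest combined sample size for exact enumeration.
#' @return list with `u` (U statistic of `a`), `p`, and `method`.
#' @examples
#' mann_whitney_u(1:3, 4:6)$p  # exact: 2/20 = 0.1
#' @export
mann_whitney_u <- function(a, b, exact_max = 12L) {
  if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- u_statistic(r, seq_len(n1))
  mu <- n1 * n2 / 2
  if (N <= exact_max) {
    splits <- combn(N, n1)
    us <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(u = u, p = p, method = "exact"))
  }
  ties <- table(pooled)
  tie_adj <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_adj)
  if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal"))
  z <- (u - mu) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}
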
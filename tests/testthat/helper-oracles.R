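# Independent brute-force oracles used across the test suite.

# Two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, probabilities from log-binomial-coefficient products.
fisher_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  a_range <- max(0, c1 - r2):min(c1, r1)
  logp <- vapply(a_range, function(a) {
    lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1)
  }, numeric(1))
  p_obs <- logp[a_range == tab[1, 1]]
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-7)])))
}

# Two-sided exact Mann-Whitney p by bitmask enumeration of every
# assignment of the pooled observations to group A.
mwu_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  stopifnot(N <= 14)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  us <- c()
  for (mask in 0:(2^N - 1)) {
    bits <- as.logical(bitwAnd(mask, 2^(0:(N - 1))))
    if (sum(bits) != n1) next
    us <- c(us, sum(r[bits]) - n1 * (n1 + 1) / 2)
  }
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Exact null distribution of the Mann-Whitney U for untied ranks 1..N,
# built by the knapsack/generating-function recursion (independent of the
# engine's subset enumeration). Returns a function mapping the ranks
# assigned to group A to the two-sided p value.
mwu_exact_distribution <- function(N, n1) {
  offset <- n1 * (n1 + 1) / 2
  maxs <- sum((N - n1 + 1):N)
  ways <- matrix(0, nrow = n1 + 1, ncol = maxs + 1)
  ways[1, 1] <- 1
  for (i in seq_len(N)) {
    for (k in rev(seq_len(min(n1, i)))) {
      if (i <= maxs) {
        ways[k + 1, (i + 1):(maxs + 1)] <-
          ways[k + 1, (i + 1):(maxs + 1)] + ways[k, 1:(maxs + 1 - i)]
      }
    }
  }
  counts <- ways[n1 + 1, ]          # counts[s + 1] = #subsets with sum s
  total <- choose(N, n1)
  mu <- n1 * (N - n1) / 2
  u_all <- (0:maxs) - offset        # U value for each rank sum
  function(a_ranks) {
    u_obs <- sum(a_ranks) - offset
    sum(counts[abs(u_all - mu) >= abs(u_obs - mu) - 1e-9]) / total
  }
}

# Small labelled time-course set built directly (bypasses generators).
make_tcs <- function(profiles, grid = c(0, 3, 6, 12, 24)) {
  ids <- names(profiles)
  long <- do.call(rbind, lapply(ids, function(id) {
    data.frame(course_id = id, cell_line = "lineA", drug = "5FU",
               dose_level = "high", antibody = id, time_h = grid,
               log2fc = profiles[[id]], stringsAsFactors = FALSE)
  }))
  rppadyn:::new_timecourse_set(long, grid)
}
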
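# Independent brute-force oracles used across the suite. Each one is a
# deliberately naive computation kept separate from the package internals.

# Benjamini-Hochberg step-up by direct definition: sort, multiply by m/rank,
# take suffix minima, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Exact two-sided Mann-Whitney p by exhaustive label enumeration: assign
# every C(n1+n2, n1) labeling, compute U for the first group, and take the
# doubled smaller tail (capped at 1) of the permutation distribution.
mw_exact_oracle <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  u_of <- function(idx) {
    r <- rank(x)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- utils::combn(seq_along(x), n1, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# AUC by exhaustive pairwise comparison, ties counting one half.
auc_pairwise_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) for (n in neg)
    s <- s + (p > n) + 0.5 * (p == n)
  s / (length(pos) * length(neg))
}

# Log-rank by the textbook O/E/V table over distinct event times.
logrank_oracle <- function(ta, ea, tb, eb) {
  times <- sort(unique(c(ta[ea == 1], tb[eb == 1])))
  O <- E <- V <- 0
  for (t in times) {
    n1 <- sum(ta >= t); n2 <- sum(tb >= t); n <- n1 + n2
    d1 <- sum(ta == t & ea == 1); d2 <- sum(tb == t & eb == 1)
    d <- d1 + d2
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  chi2 <- (O - E)^2 / V
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

# Hypergeometric upper tail by enumerating every possible draw of size n
# from a universe of size N containing K marked elements.
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(overlaps >= k)
}

# Compact cohort builder for unit tests.
make_cohort <- function(values, labels, id = "test") {
  if (is.null(rownames(values)))
    rownames(values) <- paste0("miR-", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  cohort_matrix(values, labels, id)
}
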
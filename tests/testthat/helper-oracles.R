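# Independent brute-force oracles, deliberately naive: plain loops and
# textbook formulas, sharing no code with the implementation they check.

oracle_energy <- function(s) {
  tot <- 0
  for (v in s) tot <- tot + v * v
  tot
}

oracle_entropy <- function(s, n_bins = 10L) {
  lo <- min(s); hi <- max(s)
  if (lo == hi) return(0)
  counts <- integer(n_bins)
  for (v in s) {
    b <- floor((v - lo) / (hi - lo) * n_bins) + 1L
    if (b > n_bins) b <- n_bins
    counts[b] <- counts[b] + 1L
  }
  tot <- 0
  for (cnt in counts) {
    if (cnt > 0) {
      p <- cnt / length(s)
      tot <- tot - p * log(p)
    }
  }
  tot
}

oracle_deriv <- function(s) {
  tot <- 0
  for (i in 2:length(s)) tot <- tot + abs(s[i] - s[i - 1])
  tot / (length(s) - 1)
}

oracle_skewness <- function(v) {
  mu <- sum(v) / length(v)
  m2 <- sum((v - mu)^2) / length(v)
  m3 <- sum((v - mu)^3) / length(v)
  if (m2 == 0) 0 else m3 / m2^(3 / 2)
}

oracle_system_matrix <- function(V, labels, systems) {
  m <- length(systems)
  M <- matrix(0, m, m)
  for (a in seq_len(m)) {
    for (b in seq_len(m)) {
      Pa <- which(labels == systems[a])
      Pb <- which(labels == systems[b])
      tot <- 0
      for (i in Pa) for (j in Pb) tot <- tot + V[i, j]
      M[a, b] <- tot / (length(Pa) * length(Pb))
    }
  }
  M
}

oracle_unfold <- function(A) {
  n <- dim(A)[1]
  out <- NULL
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      out <- rbind(out, A[i, j, ])
    }
  }
  out
}

# exact two-sided rank-sum p by enumerating all group assignments
oracle_ranksum_p <- function(x1, x2) {
  vals <- c(x1, x2)
  n1 <- length(x1)
  rk <- rank(vals)
  obs <- sum(rk[seq_len(n1)])
  mu <- n1 * (length(vals) + 1) / 2
  combos <- combn(length(vals), n1)
  stat <- apply(combos, 2, function(idx) sum(rk[idx]))
  mean(abs(stat - mu) >= abs(obs - mu))
}

# brute-force window placements: slide a window one step at a time
oracle_windows <- function(n_samples, window_len, step) {
  starts <- integer(0)
  s <- 1L
  while (s + window_len - 1L <= n_samples) {
    starts <- c(starts, s)
    s <- s + step
  }
  starts
}
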
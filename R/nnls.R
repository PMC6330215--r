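# Multiple-right-hand-side nonnegative least squares on the normal
# equations: minimize ||A Y - B||_F^2 subject to Y >= 0, given AtA = A'A
# (k x k) and AtB = A'B. Block principal pivoting (Kim & Park) with the
# standard full-exchange / backup rules, grouping columns that share a
# passive set so each distinct set is factorized once. Columns that exhaust
# the pivoting budget fall back to a single-column Lawson-Hanson active-set
# solve. Exact subproblem solutions are what make the alternating NMF
# objective provably non-increasing.

nnls_bpp <- function(AtA, AtB) {
  k <- nrow(AtA)
  n <- ncol(AtB)
  stopifnot(ncol(AtA) == k, nrow(AtB) == k)
  tol <- 1e-12 * max(1, max(abs(AtB)))
  Y <- matrix(0, k, n)
  G <- -AtB                       # gradient AtA %*% Y - AtB at Y = 0
  Fmask <- matrix(FALSE, k, n)    # passive (free) sets
  alpha <- rep(3L, n)
  beta_ <- rep(k + 1L, n)
  max_outer <- 10L * k + 100L

  solve_cols <- function(cols) {
    # cols share one passive set; refit those columns exactly
    Fset <- Fmask[, cols[1]]
    Y[, cols] <<- 0
    if (any(Fset)) {
      M <- AtA[Fset, Fset, drop = FALSE]
      rhs <- AtB[Fset, cols, drop = FALSE]
      sol <- tryCatch(solve(M, rhs), error = function(e) {
        solve(M + diag(1e-10 * max(diag(M), 1), sum(Fset)), rhs)
      })
      Y[Fset, cols] <<- sol
    }
    G[, cols] <<- AtA %*% Y[, cols, drop = FALSE] - AtB[, cols, drop = FALSE]
  }

  unresolved <- integer(0)
  for (iter in seq_len(max_outer)) {
    infeas <- (Fmask & (Y < -tol)) | (!Fmask & (G < -tol))
    ninf <- colSums(infeas)
    active <- which(ninf > 0L)
    if (!length(active)) break
    if (iter == max_outer) { unresolved <- active; break }
    for (jj in active) {
      v <- infeas[, jj]
      if (ninf[jj] < beta_[jj]) {
        beta_[jj] <- ninf[jj]; alpha[jj] <- 3L
      } else if (alpha[jj] > 0L) {
        alpha[jj] <- alpha[jj] - 1L
      } else {
        # backup rule: flip only the infeasible variable of largest index
        r <- max(which(v)); v[] <- FALSE; v[r] <- TRUE
      }
      Fmask[v, jj] <- !Fmask[v, jj]
    }
    pat <- colSums(Fmask[, active, drop = FALSE] *
                     2^(seq_len(k) - 1))  # cheap pattern key (k small)
    for (p in unique(pat)) solve_cols(active[pat == p])
  }
  for (jj in unresolved) {
    Y[, jj] <- nnls_active_set(AtA, AtB[, jj])
  }
  Y[Y < 0] <- 0
  Y
}

# Classic Lawson-Hanson active-set NNLS on the normal equations; used as a
# safety net for pathological columns.
nnls_active_set <- function(AtA, atb, max_iter = 30L * nrow(AtA)) {
  k <- nrow(AtA)
  P <- logical(k)
  y <- numeric(k)
  tol <- 1e-12 * max(1, max(abs(atb)))
  for (it in seq_len(max_iter)) {
    g <- atb - AtA %*% y
    cand <- which(!P & g > tol)
    if (!length(cand)) break
    P[cand[which.max(g[cand])]] <- TRUE
    repeat {
      z <- numeric(k)
      M <- AtA[P, P, drop = FALSE]
      z[P] <- tryCatch(solve(M, atb[P]), error = function(e) {
        solve(M + diag(1e-10 * max(diag(M), 1), sum(P)), atb[P])
      })
      if (all(z[P] > 0)) { y <- z; break }
      neg <- which(P)[z[which(P)] <= 0]
      a <- min(y[neg] / (y[neg] - z[neg]))
      y <- y + a * (z - y)
      P[y <= tol & P] <- FALSE
      y[!P] <- 0
    }
  }
  pmax(y, 0)
}
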
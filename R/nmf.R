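#' Penalized sparse-NMF objective
#'
#' The factorization objective: `0.5 * ||X - W H||_F^2 + eta * ||W||_F^2 +
#' beta * sum_j (sum_i H[i, j])^2`. The `beta` term is the squared L1 norm
#' of each coefficient column, which drives column-wise sparsity of H; the
#' `eta` ridge bounds the edge strengths collected in W.
#'
#' @param X nonnegative data matrix (edges x columns).
#' @param W,H nonnegative factor matrices (edges x k, k x columns).
#' @param eta ridge penalty on W (>= 0).
#' @param beta sparsity penalty on H columns (>= 0).
#' @return nonnegative scalar.
#' @export
nmf_objective <- function(X, W, H, eta = 0, beta = 0) {
  stopifnot(nrow(W) == nrow(X), ncol(H) == ncol(X), ncol(W) == nrow(H),
            eta >= 0, beta >= 0)
  if (any(W < 0) || any(H < 0)) stop("W and H must be entrywise nonnegative")
  R <- X - W %*% H
  0.5 * sum(R^2) + eta * sum(W^2) + beta * sum(colSums(H)^2)
}

#' Deterministic NNDSVD initialization
#'
#' Nonnegative double singular value decomposition: the leading component is
#' built from the absolute leading singular vectors; every later component
#' keeps the dominant nonnegative section (positive or negative part,
#' whichever carries more mass) of its singular-vector pair and zeros the
#' rest. Plain variant (zeros are kept, not mean-filled): the alternating
#' solver tolerates zero blocks, and keeping zeros preserves determinism.
#' Sign ambiguity is resolved toward the section with larger `||u+|| ||v+||`
#' product, ties to positive, so identical input gives bit-identical output.
#'
#' @param X nonnegative matrix.
#' @param k number of components, `k <= min(dim(X))`.
#' @return list with nonnegative `W0` (rows(X) x k) and `H0` (k x cols(X)).
#' @export
nndsvd_init <- function(X, k) {
  stopifnot(k >= 1, k <= min(dim(X)))
  if (any(X < 0)) stop("X must be nonnegative")
  sv <- svd(X, nu = k, nv = k)
  W0 <- matrix(0, nrow(X), k)
  H0 <- matrix(0, k, ncol(X))
  W0[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H0[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (k >= 2) {
    rank_tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
    dropped <- 0L
    for (j in 2:k) {
      if (sv$d[j] <= rank_tol) { dropped <- dropped + 1L; next }
      u <- sv$u[, j]; v <- sv$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      if (nup * nvp >= nun * nvn) {
        sig <- nup * nvp
        if (sig > 0) {
          W0[, j] <- sqrt(sv$d[j] * sig) * up / nup
          H0[j, ] <- sqrt(sv$d[j] * sig) * vp / nvp
        }
      } else {
        sig <- nun * nvn
        W0[, j] <- sqrt(sv$d[j] * sig) * un / nun
        H0[j, ] <- sqrt(sv$d[j] * sig) * vn / nvn
      }
    }
    if (dropped > 0L) {
      warning(dropped, " component(s) beyond the numerical rank of X were ",
              "zero-padded")
    }
  }
  list(W0 = W0, H0 = H0)
}

#' Fit the sparse NMF by alternating nonnegative least squares
#'
#' Alternates exact solutions of the two convex subproblems. The H update
#' solves `min_{H>=0} ||[W; sqrt(2 beta) 1_k'] H - [X; 0]||_F^2` and the W
#' update solves `min_{W>=0} ||[H'; sqrt(2 eta) I_k] W' - [X'; 0]||_F^2`;
#' these augmentations make each stationary point a stationary point of
#' [nmf_objective()], so the objective trace is non-increasing by
#' construction. Initialization is the deterministic [nndsvd_init()].
#' Reported subgraphs are sorted by descending total coefficient mass
#' (row sums of H): the factorization is permutation-invariant, and a fixed
#' reporting order makes runs comparable.
#'
#' @param X nonnegative matrix (a bare matrix or a `cohort_matrix`).
#' @param k number of subgraphs.
#' @param beta sparsity penalty on H columns.
#' @param eta ridge penalty on W; default `max(X)^2`.
#' @param tol relative objective-change stopping threshold.
#' @param max_iter maximum number of ANLS sweeps.
#' @return an `nmf_result`: `W`, `H`, `objective_trace`, `converged`,
#'   `config`, and `kkt` (see [kkt_check()]).
#' @export
nmf_fit <- function(X, k, beta = 0, eta = NULL, tol = 1e-6, max_iter = 200L) {
  cmap <- NULL
  if (inherits(X, "cohort_matrix")) { cmap <- X$column_map; X <- X$values }
  stopifnot(is.matrix(X), all(is.finite(X)), k >= 1, beta >= 0,
            tol > 0, max_iter >= 1)
  if (any(X < 0)) stop("X must be nonnegative")
  if (is.null(eta)) eta <- max(X)^2
  stopifnot(eta >= 0)

  init <- nndsvd_init(X, k)
  W <- init$W0
  H <- init$H0
  ones <- matrix(1, k, k)
  trace <- numeric(0)
  f_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # W step: AtA = H H' + 2 eta I, AtB = H X'
    HHt <- tcrossprod(H)
    HXt <- tcrossprod(H, X)
    W <- t(nnls_bpp(HHt + 2 * eta * diag(k), HXt))
    # H step last, so the returned H is exactly optimal for the returned
    # W (this is what makes projection of a training block reproduce it)
    WtW <- crossprod(W)
    WtX <- crossprod(W, X)
    H <- nnls_bpp(WtW + 2 * beta * ones, WtX)
    # direct residual evaluation: the trace identity
    # ||X||^2 - 2 tr(H'W'X) + tr(W'W HH') cancels catastrophically once
    # the fit is tight, which would make the trace look non-monotone
    f <- 0.5 * sum((X - W %*% H)^2) +
      eta * sum(W^2) + beta * sum(colSums(H)^2)
    trace <- c(trace, f)
    if (is.finite(f_prev) &&
        abs(f_prev - f) <= tol * max(f_prev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    f_prev <- f
  }

  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  res <- structure(list(W = W, H = H, objective_trace = trace,
                        converged = converged, column_map = cmap,
                        config = list(k = k, beta = beta, eta = eta,
                                      tol = tol, max_iter = max_iter)),
                   class = "nmf_result")
  res$kkt <- kkt_check(X, W, H, eta, beta)
  res
}

#' @export
print.nmf_result <- function(x, ...) {
  cat("nmf_result: k =", x$config$k, "| beta =", x$config$beta,
      "| eta =", format(x$config$eta, digits = 4), "\n")
  cat("  ", length(x$objective_trace), "sweeps,",
      if (x$converged) "converged" else "max_iter reached",
      "| final objective", format(tail(x$objective_trace, 1), digits = 8), "\n")
  invisible(x)
}

#' First-order (KKT) optimality measures of a factor pair
#'
#' Gradients of [nmf_objective()]: `G_W = (W H - X) H' + 2 eta W` and
#' `G_H = W'(W H - X) + 2 beta 1 (1' H)`. At a constrained stationary point,
#' free entries have zero gradient and zero entries have nonnegative
#' gradient. Returns the worst violations, scaled by the gradient magnitude.
#'
#' @param X,W,H,eta,beta as in [nmf_objective()].
#' @return list with `min_active_gradient` (most negative scaled gradient
#'   over zero entries; >= 0 at optimality) and `max_free_gradient`
#'   (largest scaled |gradient| over positive entries; ~ 0 at optimality).
#' @export
kkt_check <- function(X, W, H, eta = 0, beta = 0) {
  R <- W %*% H - X
  GW <- R %*% t(H) + 2 * eta * W
  GH <- crossprod(W, R) + 2 * beta * matrix(colSums(H), nrow(H), ncol(H),
                                            byrow = TRUE)
  # scale by the characteristic gradient magnitude of the data (the
  # gradients at the zero factors), not by the near-zero gradients of a
  # tight fit
  scale <- max(abs(crossprod(W, X)), abs(tcrossprod(X, H)),
               .Machine$double.eps)
  act <- c(GW[W == 0], GH[H == 0])
  fre <- c(abs(GW[W > 0]), abs(GH[H > 0]))
  list(min_active_gradient = if (length(act)) min(act) / scale else 0,
       max_free_gradient = if (length(fre)) max(fre) / scale else 0,
       gradient_scale = scale)
}

#' Project new connectivity data onto a fixed subgraph basis
#'
#' Solves, for each column of `C_new`, the same augmented nonnegative
#' least-squares problem used for the H update with W held fixed (the eta
#' ridge plays no role in the H subproblem). Used to score subjects that
#' were not part of the factorized cohort.
#'
#' @param C_new an `edge_time_matrix`, `cohort_matrix`, or bare matrix whose
#'   row count equals `nrow(W)`.
#' @param W fixed nonnegative basis.
#' @param beta sparsity penalty matching the original fit.
#' @return nonnegative coefficient matrix, k x ncol(C_new).
#' @export
nmf_project <- function(C_new, W, beta = 0) {
  if (inherits(C_new, "edge_time_matrix") || inherits(C_new, "cohort_matrix")) {
    C_new <- C_new$values
  }
  stopifnot(is.matrix(C_new), nrow(C_new) == nrow(W), beta >= 0)
  k <- ncol(W)
  nnls_bpp(crossprod(W) + 2 * beta * matrix(1, k, k), crossprod(W, C_new))
}

#' Select the number of subgraphs (and sparsity) by masked holdout
#'
#' Default method: a stated fraction of entries of X is masked, masked
#' entries are replaced by their column means (computed from the retained
#' entries) during fitting, and the mean-squared reconstruction error on
#' the masked entries is reported per candidate; the minimizer is returned.
#' Raw training error cannot have an interior optimum in k, which is why a
#' holdout criterion is needed. The `elbow` alternative fits on the full
#' matrix and picks the k of maximum discrete curvature of the training
#' error curve.
#'
#' @param X nonnegative matrix or `cohort_matrix`.
#' @param k_grid integer candidates for the number of subgraphs.
#' @param beta_grid candidates for the sparsity penalty.
#' @param method `"holdout"` (default) or `"elbow"`.
#' @param holdout_frac fraction of entries masked under `"holdout"`.
#' @param eta ridge used during selection fits (default 0: selection
#'   compares reconstruction fidelity on held-out entries, which a strong
#'   ridge would distort; the final fit may still use the `max(X)^2` rule).
#' @param seed integer seed for the holdout mask.
#' @param tol,max_iter passed to [nmf_fit()].
#' @return list with `k`, `beta`, `error_surface` (k x beta matrix of
#'   criterion values) and `method`.
#' @export
select_hyperparameters <- function(X, k_grid, beta_grid = 0,
                                   method = c("holdout", "elbow"),
                                   holdout_frac = 0.1, eta = 0, seed = 1L,
                                   tol = 1e-5, max_iter = 100L) {
  if (inherits(X, "cohort_matrix")) X <- X$values
  method <- match.arg(method)
  stopifnot(length(k_grid) >= 1, length(beta_grid) >= 1,
            all(k_grid >= 1), all(beta_grid >= 0),
            holdout_frac > 0, holdout_frac < 1)
  k_grid <- sort(unique(as.integer(k_grid)))
  beta_grid <- sort(unique(beta_grid))
  surf <- matrix(NA_real_, length(k_grid), length(beta_grid),
                 dimnames = list(paste0("k", k_grid), paste0("beta", beta_grid)))
  if (length(k_grid) == 1L && length(beta_grid) == 1L) {
    return(list(k = k_grid, beta = beta_grid, error_surface = surf,
                method = method))
  }
  if (method == "holdout") {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    mask <- sample.int(length(X), size = max(1L, round(holdout_frac * length(X))))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    Ximp <- X
    obs_mean <- mean(X[-mask])
    hold_col <- (mask - 1L) %/% nrow(X) + 1L
    for (cc in unique(hold_col)) {
      rows_masked <- mask[hold_col == cc] - (cc - 1L) * nrow(X)
      obs <- X[-rows_masked, cc]
      Ximp[rows_masked, cc] <- if (length(obs)) mean(obs) else obs_mean
    }
    truth <- X[mask]
    for (a in seq_along(k_grid)) {
      for (b in seq_along(beta_grid)) {
        fit <- nmf_fit(Ximp, k = k_grid[a], beta = beta_grid[b], eta = eta,
                       tol = tol, max_iter = max_iter)
        pred <- (fit$W %*% fit$H)[mask]
        surf[a, b] <- mean((truth - pred)^2)
      }
    }
    best <- arrayInd(which.min(surf), dim(surf))
    return(list(k = k_grid[best[1]], beta = beta_grid[best[2]],
                error_surface = surf, method = method))
  }
  # elbow: training error vs k at the smallest beta candidate
  err <- numeric(length(k_grid))
  for (a in seq_along(k_grid)) {
    fit <- nmf_fit(X, k = k_grid[a], beta = beta_grid[1], eta = eta,
                   tol = tol, max_iter = max_iter)
    err[a] <- mean((X - fit$W %*% fit$H)^2)
    surf[a, 1] <- err[a]
  }
  if (length(k_grid) >= 3) {
    curv <- diff(diff(err))
    k_best <- k_grid[which.max(curv) + 1L]
  } else {
    k_best <- k_grid[which.min(err)]
  }
  list(k = k_best, beta = beta_grid[1], error_surface = surf, method = method)
}
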
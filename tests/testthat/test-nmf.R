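test_that("objective matches hand arithmetic and degenerate cases", {
  X <- matrix(c(1, 3, 2, 4), 2)        # [[1,2],[3,4]] row-wise
  W <- matrix(c(1, 1), 2)
  H <- matrix(c(1, 1), 1)
  # residual [[0,1],[2,3]] -> 0.5*14 = 7; eta*||W||^2 = 2; beta*(1+1) = 2
  expect_equal(nmf_objective(X, W, H, eta = 1, beta = 1), 11)
  expect_equal(nmf_objective(X, 0 * W, 0 * H), 0.5 * sum(X^2))
  expect_equal(nmf_objective(W %*% H, W, H), 0)
  expect_error(nmf_objective(X, -W, H), "nonnegative")
})

test_that("NNDSVD is nonnegative, deterministic, and exact at rank one", {
  set.seed(1)
  u <- runif(8); v <- runif(12)
  X1 <- outer(u, v)
  init <- nndsvd_init(X1, 1)
  expect_lt(norm(X1 - init$W0 %*% init$H0, "F") / norm(X1, "F"), 1e-8)

  X <- matrix(runif(60), 6)
  a <- nndsvd_init(X, 3)
  b <- nndsvd_init(X, 3)
  expect_identical(a, b)
  expect_true(all(a$W0 >= 0) && all(a$H0 >= 0))
  expect_warning(nndsvd_init(X1, 3), "zero-padded")
})

test_that("planted factorization is recovered on a small noiseless cohort", {
  co <- tiny_cohort(n_regions = 16, k_true = 3, n_subjects = 6, noise_sd = 0,
                    seed = 3)
  X <- concatenate_cohort(co$edges)
  fit <- nmf_fit(X, k = 3, beta = 0, eta = 0, tol = 1e-10, max_iter = 500)
  relerr <- norm(X$values - fit$W %*% fit$H, "F") / norm(X$values, "F")
  expect_lt(relerr, 1e-6)
  mt <- match_subgraphs(fit$W, co$ground_truth$basis_true)
  expect_gt(min(mt$correlation), 0.99)
})

test_that("every fit honors the nonnegativity and monotonicity contracts", {
  set.seed(9)
  X <- matrix(rexp(30 * 40), 30)
  for (par in list(list(k = 2, beta = 0, eta = 0),
                   list(k = 3, beta = 0.1, eta = 0),
                   list(k = 4, beta = 0.01, eta = NULL))) {
    fit <- nmf_fit(X, k = par$k, beta = par$beta, eta = par$eta)
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-8 * pmax(tr[-length(tr)], 1)))
    expect_gt(fit$kkt$min_active_gradient, -1e-4)
  }
})

test_that("sparsity of H is non-decreasing in beta", {
  set.seed(10)
  X <- matrix(rexp(20 * 30), 20)
  frac_zero <- sapply(c(0, 0.1, 1), function(b) {
    fit <- nmf_fit(X, k = 3, beta = b, eta = 0)
    mean(fit$H < 1e-8 * max(fit$H))
  })
  expect_true(all(diff(frac_zero) >= 0))
})

test_that("ANLS reaches at least the objective of multiplicative restarts", {
  mu_nmf <- function(X, k, n_iter = 500, seed) {
    set.seed(seed)
    W <- matrix(runif(nrow(X) * k) + 0.1, nrow(X))
    H <- matrix(runif(k * ncol(X)) + 0.1, k)
    eps <- 1e-12
    for (i in seq_len(n_iter)) {
      H <- H * crossprod(W, X) / (crossprod(W) %*% H + eps)
      W <- W * tcrossprod(X, H) / (W %*% tcrossprod(H) + eps)
    }
    0.5 * sum((X - W %*% H)^2)
  }
  set.seed(12)
  X <- matrix(rexp(48), 6)             # 6 x 8
  best_mu <- min(sapply(1:50, function(s) mu_nmf(X, 2, seed = 100 + s)))
  fit <- nmf_fit(X, k = 2, beta = 0, eta = 0, tol = 1e-12, max_iter = 500)
  expect_lte(tail(fit$objective_trace, 1), best_mu * (1 + 1e-6))
})

test_that("projection reproduces training coefficients and handles zeros", {
  co <- tiny_cohort(n_regions = 12, k_true = 2, n_subjects = 5,
                    noise_sd = 0.02, seed = 15)
  X <- concatenate_cohort(co$edges)
  fit <- nmf_fit(X, k = 2, beta = 0.05, eta = 0, tol = 1e-9, max_iter = 400)
  T_ <- ncol(co$edges[[1]])
  blk <- fit$H[, seq_len(T_), drop = FALSE]
  proj <- nmf_project(co$edges[[1]], fit$W, beta = 0.05)
  expect_equal(proj, blk, tolerance = 1e-6)
  z <- nmf_project(matrix(0, nrow(fit$W), 2), fit$W, beta = 0.05)
  expect_true(all(z == 0))
  set.seed(16)
  r <- nmf_project(matrix(rexp(nrow(fit$W) * 3), ncol = 3), fit$W)
  expect_true(all(r >= 0))
})

test_that("hyperparameter selection degenerates gracefully", {
  set.seed(17)
  X <- matrix(rexp(20 * 15), 20)
  one <- select_hyperparameters(X, k_grid = 3, beta_grid = 0.1)
  expect_equal(one$k, 3L)
  expect_equal(one$beta, 0.1)
})

test_that("training reconstruction error is non-increasing in k", {
  co <- tiny_cohort(n_regions = 12, k_true = 3, n_subjects = 4,
                    noise_sd = 0.05, seed = 18)
  X <- concatenate_cohort(co$edges)$values
  errs <- sapply(1:5, function(k) {
    fit <- nmf_fit(X, k = k, beta = 0, eta = 0, tol = 1e-8, max_iter = 300)
    mean((X - fit$W %*% fit$H)^2)
  })
  expect_true(all(diff(errs) <= 1e-10))
})
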
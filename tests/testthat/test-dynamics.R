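test_that("energy, entropy and derivative match their closed forms", {
  expect_equal(signal_energy(rep(0, 5)), 0)
  expect_equal(signal_energy(c(1, 2, 2)), 9)
  expect_equal(signal_entropy(rep(2, 10)), 0)
  expect_equal(signal_entropy(rep(c(0, 1), 10)), log(2))
  # 50 points spread uniformly over 10 bins, 5 per bin
  u <- rep(seq(0.05, 0.95, by = 0.1), each = 5)
  expect_equal(signal_entropy(u), log(10))
  expect_equal(mean_abs_derivative(rep(3, 4)), 0)
  expect_equal(mean_abs_derivative(c(0, 1, 0, 1)), 1)
  expect_error(signal_entropy(c(1, 2), n_bins = 1))
})

test_that("dynamics statistics agree with brute-force loop oracles", {
  set.seed(1)
  for (case in 1:100) {
    s <- rexp(sample(10:60, 1))
    expect_equal(signal_energy(s), oracle_energy(s), tolerance = 1e-12)
    expect_equal(signal_entropy(s), oracle_entropy(s), tolerance = 1e-12)
    expect_equal(mean_abs_derivative(s), oracle_deriv(s), tolerance = 1e-12)
  }
})

test_that("entropy is affine-invariant while energy scales quadratically", {
  set.seed(2)
  for (case in 1:20) {
    s <- rexp(40)
    a <- runif(1, 0.5, 3)
    b <- runif(1, -1, 1)
    expect_equal(signal_entropy(a * s + b), signal_entropy(s),
                 tolerance = 1e-12)
    expect_equal(signal_energy(a * s), a^2 * signal_energy(s),
                 tolerance = 1e-10)
  }
})

test_that("standardization yields unit means, idempotently", {
  set.seed(3)
  k <- 3; T_ <- 20; S <- 4
  H <- matrix(rexp(k * T_ * S), k)
  cm <- data.frame(column = seq_len(ncol(H)),
                   subject = rep(paste0("s", 1:S), each = T_))
  std <- standardize_coefficients(H, cm)
  expect_equal(nrow(std$skipped), 0L)
  for (s in paste0("s", 1:S)) {
    cols <- cm$column[cm$subject == s]
    expect_equal(rowMeans(std$H_std[, cols]), rep(1, k), tolerance = 1e-12)
  }
  again <- standardize_coefficients(std$H_std, cm)
  expect_equal(again$H_std, std$H_std, tolerance = 1e-12)
  H[2, cm$subject == "s2"] <- 0
  flagged <- standardize_coefficients(H, cm)
  expect_equal(flagged$skipped$subject, "s2")
  expect_equal(flagged$skipped$subgraph, 2L)
})

test_that("the dynamics summary tabulates per subject and subgraph", {
  co <- tiny_cohort(n_subjects = 4, seed = 5)
  gt <- co$ground_truth
  H <- do.call(cbind, gt$coeffs_true)
  cm <- data.frame(column = seq_len(ncol(H)),
                   subject = rep(names(co$edges), each = gt$params$n_windows))
  summ <- dynamics_summary(H, cm,
                           groups = setNames(as.character(co$group_labels),
                                             names(co$edges)),
                           motion = co$motion)
  expect_equal(nrow(summ), 4 * gt$params$k_true)
  i <- which(summ$subject == names(co$edges)[2] & summ$subgraph == 1)
  expect_equal(summ$energy[i], sum(gt$coeffs_true[[2]][1, ]^2))
  expect_true(all(c("group", "motion") %in% names(summ)))
})

test_that("a perfectly log-linear energy-entropy relation gives r = 1", {
  summ <- data.frame(subject = rep("s1", 4), subgraph = 1:4,
                     energy = c(1, 10, 100, 1000),
                     entropy = log(c(1, 10, 100, 1000)) * 0.3 + 0.1)
  rel <- energy_entropy_relation(summ)
  expect_equal(rel$r, 1, tolerance = 1e-12)
  expect_error(energy_entropy_relation(summ[1:2, ]), "at least 3")
})

test_that("rank-sum comparison matches the exact enumeration oracle", {
  g <- factor(rep(c("a", "b"), each = 3), levels = c("a", "b"))
  res <- group_compare(c(1, 2, 3, 4, 5, 6), g)
  expect_equal(res$p, oracle_ranksum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_lt(res$z, 0)   # second group has larger ranks
  res2 <- group_compare(c(4, 5, 6, 1, 2, 3), g)
  expect_gt(res2$z, 0)
  same <- suppressWarnings(
    group_compare(rep(c(1, 2, 3, 4), 2),
                  factor(rep(c("a", "b"), each = 4), levels = c("a", "b"))))
  expect_equal(same$z, 0, tolerance = 1e-8)
  expect_gt(same$p, 0.9)
  expect_error(group_compare(1:4, factor(rep("a", 4))), "two groups")
})

test_that("rank-sum p agrees with enumeration across random small samples", {
  set.seed(6)
  for (case in 1:10) {
    x1 <- round(rexp(4), 3)
    x2 <- round(rexp(5) + 0.2, 3)
    res <- group_compare(c(x1, x2),
                         factor(rep(c("g1", "g2"), c(4, 5)),
                                levels = c("g1", "g2")))
    expect_equal(res$p, oracle_ranksum_p(x1, x2), tolerance = 1e-12)
  }
})

test_that("shuffle null separates structured from unstructured coefficients", {
  # couple scale and switching across subgraphs: high-scale rows also toggle
  set.seed(7)
  k <- 8; T_ <- 51; S <- 8
  cm <- data.frame(column = seq_len(T_ * S),
                   subject = rep(paste0("s", 1:S), each = T_))
  H <- matrix(0, k, T_ * S)
  scales <- 2^seq(0, 3.5, length.out = k)
  occupancy <- seq(0.08, 0.5, length.out = k)  # drives entropy upward
  for (s in 1:S) {
    for (g in 1:k) {
      st <- runif(T_) < occupancy[g]
      H[g, (s - 1) * T_ + seq_len(T_)] <- ifelse(st, 1, 0.2) * scales[g]
    }
  }
  res <- shuffle_null_correlation(H, cm, n_perm = 499, seed = 8)
  expect_lte(res$p, 0.01)
  expect_gt(res$observed_r, 0.9)
  # observed statistic equals the summary-table route
  rel <- energy_entropy_relation(dynamics_summary(H, cm))
  expect_equal(res$observed_r, rel$r, tolerance = 1e-12)
  # decision is stable across permutation budgets
  res2 <- shuffle_null_correlation(H, cm, n_perm = 199, seed = 9)
  expect_lte(res2$p, 0.05)
})

test_that("motion checks report exact correlations and guard degeneracy", {
  set.seed(10)
  motion <- runif(20, 0, 0.3)
  summ <- data.frame(subject = paste0("s", 1:20), subgraph = 1,
                     standardized_energy = motion,        # r = 1 by design
                     standardized_entropy = rnorm(20),
                     motion = motion)
  mc <- motion_check(summ)
  expect_equal(mc$r[mc$metric == "standardized_energy"], 1,
               tolerance = 1e-12)
  summ$motion <- 0.2
  expect_error(motion_check(summ), "zero variance")
})

test_that("behavior association finds planted signal but not pure age effects", {
  set.seed(11)
  n <- 200
  age <- runif(n, 8, 22)
  flex <- rnorm(n)
  beh_signal <- flex + rnorm(n)            # signal-to-noise 1
  res <- behavior_association(flex, beh_signal, age, n_perm = 499, seed = 12)
  expect_lte(res$p, 0.05)
  expect_gt(res$partial_r, 0.3)
  beh_age <- 0.8 * age + rnorm(n)          # age-driven only
  res2 <- behavior_association(rnorm(n), beh_age, age, n_perm = 499,
                               seed = 13)
  expect_gt(res2$p, 0.05)
})

test_that("behavior permutation test is calibrated at the source", {
  set.seed(14)
  rejections <- 0
  for (rep in 1:20) {
    n <- 40
    age <- runif(n, 8, 22)
    flex <- rnorm(n)
    beh <- sample(flex + rnorm(n))          # permuted at source
    p <- behavior_association(flex, beh, age, n_perm = 199,
                              seed = 500 + rep)$p
    rejections <- rejections + (p <= 0.05)
  }
  expect_lte(rejections, 4)
})
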
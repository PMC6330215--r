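test_that("generators are bit-identical under a fixed seed", {
  part <- even_partition(12, 3)
  a <- make_ground_truth(part, 3, n_subjects = 6, seed = 5)
  b <- make_ground_truth(part, 3, n_subjects = 6, seed = 5)
  expect_identical(a, b)
  ea <- render_connectivity(a, noise_sd = 0.1, seed = 9)
  eb <- render_connectivity(b, noise_sd = 0.1, seed = 9)
  expect_identical(ea, eb)
})

test_that("ground truth honors its invariants", {
  part <- even_partition(12, 3)
  gt <- make_ground_truth(part, 3, n_subjects = 6, seed = 2)
  expect_true(all(gt$basis_true >= 0))
  expect_true(all(vapply(gt$coeffs_true, function(H) all(H >= 0),
                         logical(1))))
  expect_true(gt$effect_subgraph >= 1 && gt$effect_subgraph <= 3)
  expect_length(gt$supports[[gt$effect_subgraph]], 2L)  # spans two systems
  expect_true(all(lengths(gt$supports) <= 2))
  expect_error(make_ground_truth(part, 99, n_subjects = 4),
               "available system supports")
  expect_error(make_ground_truth(part, 2, n_subjects = 4,
                                 energy_ratio = 0), "positive")
})

test_that("planted energy ratio lands in the squared scaling band", {
  gt <- make_ground_truth(even_partition(8, 2), 2, n_subjects = 100,
                          energy_ratio = 2, seed = 3)
  e <- vapply(gt$coeffs_true,
              function(H) oracle_energy(H[gt$effect_subgraph, ]),
              numeric(1))
  g <- gt$group_labels
  ratio <- mean(e[g == "adult"]) / mean(e[g == "child"])
  expect_gt(ratio, 1.8^2)
  expect_lt(ratio, 2.2^2)
})

test_that("no planted effect means equal group energies within noise", {
  gt <- make_ground_truth(even_partition(8, 2), 2, n_subjects = 200,
                          energy_ratio = 1, switching_increment = 0,
                          seed = 4)
  e <- vapply(gt$coeffs_true,
              function(H) oracle_energy(H[gt$effect_subgraph, ]),
              numeric(1))
  g <- gt$group_labels
  ratio <- mean(e[g == "adult"]) / mean(e[g == "child"])
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)
})

test_that("zero switching without silent windows gives constant series", {
  gt <- make_ground_truth(even_partition(8, 2), 2, n_subjects = 10,
                          switching_prob = 0, switching_increment = 0,
                          silent_frac = 0, seed = 5)
  for (H in gt$coeffs_true) {
    for (g in 1:2) {
      expect_equal(sd(H[g, ]), 0)
      expect_equal(signal_entropy(H[g, ]), 0)
    }
  }
})

test_that("the adult-child energy gap grows with the planted ratio", {
  gap <- vapply(c(1, 1.5, 2), function(r) {
    gt <- make_ground_truth(even_partition(8, 2), 2, n_subjects = 200,
                            energy_ratio = r, seed = 6)
    e <- vapply(gt$coeffs_true,
                function(H) signal_energy(H[gt$effect_subgraph, ]),
                numeric(1))
    g <- gt$group_labels
    mean(e[g == "adult"]) - mean(e[g == "child"])
  }, numeric(1))
  expect_true(all(diff(gap) > 0))
})

test_that("two-bin entropy approaches ln 2 at maximal switching", {
  gt <- make_ground_truth(even_partition(8, 2), 2, n_subjects = 50,
                          n_windows = 400, switching_prob = 0.5,
                          switching_increment = 0, silent_frac = 0, seed = 7)
  h <- vapply(gt$coeffs_true,
              function(H) signal_entropy(H[1, ], n_bins = 2), numeric(1))
  expect_equal(mean(h), log(2), tolerance = 0.01)
})

test_that("rendered connectivity realizes basis times coefficients", {
  gt <- make_ground_truth(even_partition(10, 2), 2, n_subjects = 4, seed = 8)
  clean <- render_connectivity(gt, noise_sd = 0)
  for (s in 1:4) {
    expect_equal(clean[[s]], gt$basis_true %*% gt$coeffs_true[[s]])
  }
  noisy <- render_connectivity(gt, noise_sd = 0.05, seed = 11)
  expect_true(all(vapply(noisy, function(M) all(M >= 0), logical(1))))
  # relative Frobenius error equals its elementwise recomputation
  WH <- gt$basis_true %*% gt$coeffs_true[[1]]
  direct <- sqrt(sum((noisy[[1]] - WH)^2)) / sqrt(sum(WH^2))
  expect_equal(norm(noisy[[1]] - WH, "F") / norm(WH, "F"), direct,
               tolerance = 1e-12)
})

test_that("a constant single subgraph renders proportional columns", {
  gt <- make_ground_truth(even_partition(6, 1), 1, n_subjects = 2,
                          switching_prob = 0, switching_increment = 0,
                          silent_frac = 0, seed = 9)
  M <- render_connectivity(gt, noise_sd = 0)[[1]]
  lev <- gt$coeffs_true[[1]][1, 1]
  for (j in seq_len(ncol(M))) {
    expect_equal(M[, j], gt$basis_true[, 1] * lev)
  }
})

test_that("the motion confound is visible before regression, gone after", {
  co <- simulate_cohort(n_regions = 8, n_systems = 2, k_true = 2,
                        n_subjects = 100, n_windows = 20,
                        noise_sd = 0.02, motion_slope = 0.8, seed = 10)
  em <- sapply(co$edges, rowMeans)
  pre <- apply(em, 1, cor, y = co$motion)
  expect_true(all(pre > 0))
  zero <- simulate_cohort(n_regions = 8, n_systems = 2, k_true = 2,
                          n_subjects = 10, n_windows = 20,
                          noise_sd = 0, motion_slope = 0, seed = 10)
  base <- render_connectivity(zero$ground_truth, noise_sd = 0)
  expect_equal(zero$edges, base)     # slope 0 leaves edges untouched
})

test_that("cohorts round-trip through the text container", {
  co <- tiny_cohort(n_regions = 8, k_true = 2, n_subjects = 3,
                    noise_sd = 0.02, seed = 12)
  dir <- file.path(tempdir(), "cohort-roundtrip")
  unlink(dir, recursive = TRUE)
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$metadata$subject_id, names(co$edges))
  expect_equal(back$metadata$group, as.character(co$group_labels))
  expect_equal(unname(back$edges[[2]]), unname(co$edges[[2]]),
               tolerance = 1e-8)
  expect_equal(back$basis_true, co$ground_truth$basis_true,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back$coeffs_true[[1]], co$ground_truth$coeffs_true[[1]],
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(as.character(back$partition$node_to_system),
               as.character(co$partition$node_to_system))
})

test_that("behavior scores track planted flexibility and age", {
  co <- simulate_cohort(n_regions = 8, n_systems = 2, k_true = 2,
                        n_subjects = 200, seed = 13)
  expect_length(co$behavior, 200)
  expect_gt(cor(co$behavior, co$flexibility_true), 0.3)
  expect_gt(cor(co$behavior, co$ages), 0.1)
})
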
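test_that("sliding windows reproduce the canonical layout and count", {
  w <- sliding_windows(120, 20, 0.9)
  expect_equal(nrow(w), 51L)
  expect_equal(w$start[1:3], c(1L, 3L, 5L))
  expect_equal(w$end[1], 20L)
  expect_equal(nrow(sliding_windows(20, 20, 0.9)), 1L)
  expect_equal(nrow(sliding_windows(40, 20, 0.9)),
               length(oracle_windows(40, 20, 2)))
  expect_error(sliding_windows(19, 20, 0.9), "smaller than window_len")
  expect_error(sliding_windows(100, 20, 0.99), "rounds to zero")
})

test_that("window count matches brute-force enumeration on a grid", {
  for (n in c(20, 23, 37, 60)) {
    for (wl in c(5, 10, 20)) {
      for (ov in c(0, 0.5, 0.9)) {
        if (n < wl) next
        step <- round(wl * (1 - ov))
        if (step < 1) next
        w <- sliding_windows(n, wl, ov)
        ref <- oracle_windows(n, wl, step)
        expect_equal(w$start, ref,
                     info = sprintf("n=%d wl=%d ov=%.1f", n, wl, ov))
      }
    }
  }
})

test_that("unfold follows the lexicographic pair convention and inverts", {
  ep <- edge_pairs(3)
  expect_equal(ep, cbind(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)))
  # N = 4 is where lexicographic differs from column-major upper triangle
  ep4 <- edge_pairs(4)
  expect_equal(ep4[, 1], c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(ep4[, 2], c(2L, 3L, 4L, 3L, 4L, 4L))

  set.seed(11)
  A <- array(0, dim = c(5, 5, 2))
  for (l in 1:2) A[, , l] <- random_symmetric(5, seed = 20 + l)
  ml <- structure(list(values = A, windows = sliding_windows(10, 5, 0),
                       node_ids = paste0("n", 1:5),
                       degenerate = rep(FALSE, 5)),
                  class = "multilayer_network")
  C <- unfold_layers(ml)
  expect_equal(C$values, oracle_unfold(A))
  back <- fold_layers(C)
  expect_equal(back$values, A)
  w <- runif(10)
  expect_equal(unfold_subgraph(fold_subgraph(w)), w)
})

test_that("asymmetric layers are rejected", {
  A <- array(runif(18), dim = c(3, 3, 2))
  ml <- structure(list(values = A, windows = NULL, node_ids = NULL,
                       degenerate = rep(FALSE, 3)),
                  class = "multilayer_network")
  expect_error(unfold_layers(ml), "asymmetric")
})

test_that("layer normalization hits unit mean exactly and is idempotent", {
  mk <- function(vals) {
    A <- array(0, dim = c(3, 3, 1))
    A[, , 1] <- fold_subgraph(vals)
    structure(list(values = A, windows = NULL, node_ids = NULL,
                   degenerate = rep(FALSE, 3)),
              class = "multilayer_network")
  }
  expect_equal(unfold_subgraph(normalize_layers(mk(c(1, 3, 2)))$values[, , 1]),
               c(0.5, 1.5, 1.0))
  expect_equal(unfold_subgraph(normalize_layers(mk(rep(0.5, 3)))$values[, , 1]),
               rep(1, 3))
  set.seed(4)
  m <- mk(runif(3, 0.1, 2))
  n1 <- normalize_layers(m)
  expect_equal(mean(unfold_subgraph(n1$values[, , 1])), 1, tolerance = 1e-12)
  n2 <- normalize_layers(n1)
  expect_equal(n2$values, n1$values)
  expect_error(normalize_layers(mk(rep(0, 3))), "layer 1")
})

test_that("motion regression removes an exactly linear confound", {
  set.seed(5)
  motion <- runif(6, 0, 0.3)
  a <- matrix(runif(20, 0.5, 1), 4)    # intercepts
  b <- matrix(runif(20, -1, 1), 4)     # slopes
  edges <- lapply(motion, function(m) a + b * m)
  out <- regress_motion(edges, motion)
  for (s in seq_along(out)) {
    expect_equal(out[[s]], pmax(a, 0), tolerance = 1e-10)
  }
})

test_that("motion regression guards zero-variance motion", {
  edges <- replicate(3, matrix(runif(6), 2), simplify = FALSE)
  expect_warning(out <- regress_motion(edges, rep(0.1, 3)), "zero variance")
  expect_identical(out, edges)
})

test_that("a planted motion confound is detectable and then removed", {
  # edges bounded away from zero, so the check isolates the regression
  # itself from the clipping rule (clipping under heavy zero-inflation is
  # exercised in the acceptance suite through the full coherence path)
  set.seed(31)
  S <- 200; E <- 30; T_ <- 10
  motion <- rgamma(S, shape = 4, rate = 4 / 0.12)
  base <- lapply(seq_len(S), function(s) 0.5 + 0.1 * matrix(rexp(E * T_), E))
  edges <- Map(function(b, m) b + 0.5 * m, base, motion)
  pre <- apply(sapply(edges, rowMeans), 1, cor, y = motion)
  expect_true(all(pre > 0))
  cleaned <- regress_motion(edges, motion)
  post <- apply(sapply(cleaned, rowMeans), 1, cor, y = motion)
  expect_lt(max(abs(post)), 0.05)
  # per-cell correlations vanish as well when nothing is clipped
  r11 <- cor(vapply(cleaned, function(m) m[1, 1], numeric(1)), motion)
  expect_lt(abs(r11), 1e-10)
})

test_that("concatenation preserves blocks and the column map inverts", {
  co <- tiny_cohort(n_subjects = 3, n_regions = 8, k_true = 2, seed = 13)
  X <- concatenate_cohort(co$edges)
  T_ <- ncol(co$edges[[1]])
  expect_equal(ncol(X$values), 3 * T_)
  expect_equal(X$values[, seq_len(T_)], co$edges[[1]])
  # every column equals its source window bit-exactly
  for (j in sample(ncol(X$values), 10)) {
    m <- X$column_map[j, ]
    expect_identical(X$values[, j], co$edges[[m$subject]][, m$window])
  }
  one <- concatenate_cohort(co$edges[1])
  expect_equal(one$values, co$edges[[1]])
  bad <- co$edges
  bad[[2]] <- bad[[2]][, -1]
  expect_error(concatenate_cohort(bad), "sub-002")
})
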
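# Small seeded fixtures shared across test files.

tiny_cohort <- function(n_regions = 20L, n_systems = 4L, k_true = 3L,
                        n_subjects = 8L, noise_sd = 0, seed = 7L, ...) {
  simulate_cohort(n_regions = n_regions, n_systems = n_systems,
                  k_true = k_true, n_subjects = n_subjects,
                  noise_sd = noise_sd, seed = seed, ...)
}

random_symmetric <- function(n, seed = 1L) {
  set.seed(seed)
  V <- matrix(runif(n * n), n)
  V <- (V + t(V)) / 2
  diag(V) <- 0
  V
}
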
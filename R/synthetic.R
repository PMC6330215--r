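#' Evenly sized node-to-system partition
#'
#' Convenience constructor for synthetic cohorts: `n_regions` nodes split
#' into `n_systems` contiguous, (near-)equal systems labeled `sys01, ...`.
#'
#' @param n_regions number of nodes.
#' @param n_systems number of systems (<= n_regions).
#' @return a [system_partition()].
#' @export
even_partition <- function(n_regions, n_systems) {
  stopifnot(n_systems >= 1, n_systems <= n_regions)
  lab <- sort(sprintf("sys%02d", rep(seq_len(n_systems), length.out = n_regions)))
  system_partition(lab, sprintf("n%03d", seq_len(n_regions)))
}

# Two-state symmetric Markov chain of expression values: toggles between
# `low` and `high` with per-window probability `p`, started from the
# stationary half/half distribution.
two_state_chain <- function(n, p, low, high) {
  st <- integer(n)
  st[1] <- rbinom(1L, 1L, 0.5)
  if (n > 1) {
    tog <- runif(n - 1L) < p
    for (t in 2:n) st[t] <- if (tog[t - 1L]) 1L - st[t - 1L] else st[t - 1L]
  }
  ifelse(st == 1L, high, low)
}

#' Generate planted ground truth for a synthetic cohort
#'
#' Plants `k_true` nonnegative subgraphs, each supported on one or two
#' systems of the partition, and per-subject coefficient time courses built
#' as two-state (high/low) Markov chains with toggle probability
#' `switching_prob`. The two-state model separates the two quantities the
#' dynamics statistics measure: the state levels set the energy, the
#' switching probability sets the entropy. Subgraph 1 is the designated
#' "executive-like" effect subgraph: it spans two systems, and for
#' adult-group subjects its high state is scaled by `energy_ratio` while its
#' switching probability is raised by `switching_increment`, so both the
#' planted energy and the planted entropy are larger in adults.
#'
#' @param partition a [system_partition()] defining the node geometry.
#' @param k_true number of planted subgraphs (at most the number of single
#'   systems plus system pairs).
#' @param n_windows number of coefficient windows per subject (default 51).
#' @param n_subjects number of subjects.
#' @param group_labels optional factor with levels `child`, `adult`;
#'   defaults to the first half `child`, second half `adult`.
#' @param energy_ratio multiplicative adult-group effect on the effect
#'   subgraph's high state (> 0; 1 means no effect).
#' @param switching_prob per-window toggle probability for all subjects.
#' @param switching_increment additive increase of the effect subgraph's
#'   toggle probability in the adult group (0 means no entropy effect).
#' @param low_state,high_state the two coefficient levels.
#' @param silent_frac fraction of windows per (subject, subgraph) series
#'   set to exactly zero (fixed count, random positions). Strictly positive
#'   coefficients would make the planted factorization non-unique (any
#'   mixing `W[, i] + e * W[, j]` with `e <= low_state / high_state` keeps
#'   both factors nonnegative); a few exact-zero windows per series anchor
#'   it. The count is fixed, not Bernoulli, so the silent mass adds no
#'   between-subject entropy variance.
#' @param seed integer seed; identical seeds give identical output.
#' @return a `ground_truth`: `basis_true` (E x k), `region_loadings`
#'   (N x k), `supports` (list of system label sets), `coeffs_true` (list of
#'   k x T matrices per subject), `effect_subgraph` (= 1), `group_labels`,
#'   `partition`, `params`, `seed`.
#' @export
make_ground_truth <- function(partition, k_true, n_windows = 51L,
                              n_subjects, group_labels = NULL,
                              energy_ratio = 1.5, switching_prob = 0.10,
                              switching_increment = 0.20,
                              low_state = 0.3, high_state = 1.0,
                              silent_frac = 0.06, seed = 1L) {
  stopifnot(inherits(partition, "system_partition"), k_true >= 1,
            n_windows >= 2, n_subjects >= 1,
            switching_prob >= 0, switching_prob <= 1,
            switching_increment >= 0,
            switching_prob + switching_increment <= 1,
            low_state >= 0, high_state > low_state,
            silent_frac >= 0, silent_frac < 1)
  if (energy_ratio <= 0) stop("energy_ratio must be positive")
  m <- length(partition$systems)
  singles <- lapply(partition$systems, identity)
  pairs <- if (m >= 2) {
    combn(partition$systems, 2L, simplify = FALSE)
  } else {
    list()
  }
  candidates <- c(pairs, singles)  # pairs first: effect subgraph is spread
  if (k_true > length(candidates)) {
    stop("k_true = ", k_true, " exceeds the ", length(candidates),
         " available system supports (systems plus system pairs)")
  }
  if (is.null(group_labels)) {
    group_labels <- factor(rep(c("child", "adult"),
                               c(ceiling(n_subjects / 2),
                                 floor(n_subjects / 2))),
                           levels = c("child", "adult"))
  }
  group_labels <- factor(group_labels, levels = c("child", "adult"))
  stopifnot(length(group_labels) == n_subjects, !anyNA(group_labels))

  set.seed(seed)
  sup_idx <- c(1L, if (k_true > 1) 1L + sample.int(length(candidates) - 1L,
                                                   k_true - 1L))
  supports <- candidates[sup_idx]
  n <- length(partition$node_to_system)
  # Regions of a system claimed by several subgraphs are split evenly among
  # them, so region supports are disjoint across subgraphs. Disjoint
  # supports make the planted factorization identifiable (each subgraph
  # owns anchor edges); real subgraphs can overlap in space, which this
  # generator deliberately does not emulate.
  U <- matrix(0, n, k_true)
  for (sys in partition$systems) {
    claim <- which(vapply(supports, function(sp) sys %in% sp, logical(1)))
    if (!length(claim)) next
    regions <- which(partition$node_to_system == sys)
    owner <- claim[ceiling(seq_along(regions) * length(claim) /
                             length(regions))]
    for (g in claim) {
      mine <- regions[owner == g]
      U[mine, g] <- runif(length(mine), 0.5, 1)
    }
  }
  short <- which(colSums(U > 0) < 2)
  if (length(short)) {
    stop("subgraph(s) ", paste(short, collapse = ", "),
         " received fewer than 2 regions; use fewer subgraphs or larger systems")
  }
  ep <- edge_pairs(n)
  basis_true <- U[ep[, 1], , drop = FALSE] * U[ep[, 2], , drop = FALSE]

  n_silent <- if (silent_frac > 0) {
    max(1L, round(silent_frac * n_windows))
  } else 0L
  coeffs_true <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    Hs <- matrix(0, k_true, n_windows)
    adult <- group_labels[s] == "adult"
    for (g in seq_len(k_true)) {
      p <- switching_prob
      hi <- high_state
      if (adult && g == 1L) {
        p <- switching_prob + switching_increment
        hi <- high_state * energy_ratio
      }
      v <- two_state_chain(n_windows, p, low_state, hi)
      if (n_silent > 0L) v[sample.int(n_windows, n_silent)] <- 0
      Hs[g, ] <- v
    }
    coeffs_true[[s]] <- Hs
  }
  structure(list(basis_true = basis_true, region_loadings = U,
                 supports = supports, coeffs_true = coeffs_true,
                 effect_subgraph = 1L, group_labels = group_labels,
                 partition = partition,
                 params = list(k_true = k_true, n_windows = n_windows,
                               n_subjects = n_subjects,
                               energy_ratio = energy_ratio,
                               switching_prob = switching_prob,
                               switching_increment = switching_increment,
                               low_state = low_state,
                               high_state = high_state),
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", nrow(x$region_loadings), "regions,",
      x$params$k_true, "planted subgraphs,", x$params$n_subjects,
      "subjects x", x$params$n_windows, "windows\n")
  cat("  effect subgraph", x$effect_subgraph, "on systems {",
      paste(x$supports[[x$effect_subgraph]], collapse = ", "),
      "}; energy_ratio =", x$params$energy_ratio,
      ", switching", x$params$switching_prob, "->",
      x$params$switching_prob + x$params$switching_increment, "(adult)\n")
  invisible(x)
}

#' Render per-subject edge-time connectivity from planted ground truth
#'
#' Each subject's E x T connectivity equals `basis_true %*% coeffs_true`
#' plus additive Gaussian noise clipped at zero, preserving nonnegativity
#' with the same one-line rule the pipeline itself uses.
#'
#' @param gt a [make_ground_truth()] object.
#' @param noise_sd standard deviation of the additive noise (>= 0).
#' @param seed integer seed (default derived from the ground-truth seed).
#' @return named list of nonnegative E x T matrices, one per subject.
#' @export
render_connectivity <- function(gt, noise_sd = 0, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), noise_sd >= 0)
  if (is.null(seed)) seed <- gt$seed + 1000L
  set.seed(seed)
  out <- vector("list", gt$params$n_subjects)
  for (s in seq_along(out)) {
    if (ncol(gt$basis_true) != nrow(gt$coeffs_true[[s]])) {
      stop("basis and coefficient dimensions disagree for subject ", s)
    }
    M <- gt$basis_true %*% gt$coeffs_true[[s]]
    if (noise_sd > 0) {
      M <- M + matrix(rnorm(length(M), sd = noise_sd), nrow(M))
      M[M < 0] <- 0
    }
    out[[s]] <- M
  }
  names(out) <- sprintf("sub-%03d", seq_along(out))
  out
}

#' Render region BOLD-like time series realizing the planted structure
#'
#' Each planted subgraph gets one band-limited latent oscillator per
#' subject; a region's series is the loading-weighted sum of the latents of
#' the subgraphs it belongs to, with the latent's per-sample amplitude
#' proportional to the square root of the planted coefficient (interpolated
#' at window centers), plus white noise. Windowed in-band coherence of two
#' regions sharing a subgraph therefore rises with the planted coefficient.
#' No hemodynamics or scanner artifacts are modeled.
#'
#' @param gt a [make_ground_truth()] object.
#' @param tr_seconds sampling interval in seconds.
#' @param band numeric length-2 coherence band in Hz (inside the Nyquist
#'   range given `tr_seconds`).
#' @param noise_sd white-noise standard deviation added to every region.
#' @param window_len,overlap_frac window geometry; the series length is
#'   exactly enough samples for `n_windows` sliding windows.
#' @param seed integer seed (default derived from the ground-truth seed).
#' @return a `synthetic_cohort`: `series` (list of regions x samples
#'   matrices), `partition`, `group_labels`, `ages`, `ground_truth`,
#'   `tr_seconds`, and empty `motion`/`behavior` slots.
#' @export
render_bold <- function(gt, tr_seconds = 3, band = c(0.02, 0.08),
                        noise_sd = 0.1, window_len = 20L,
                        overlap_frac = 0.9, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth"), length(band) == 2, noise_sd >= 0)
  nyq <- 1 / (2 * tr_seconds)
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < nyq)) {
    stop("band must lie strictly inside (0, Nyquist = ", nyq, " Hz)")
  }
  if (is.null(seed)) seed <- gt$seed + 2000L
  set.seed(seed)
  T_ <- gt$params$n_windows
  step <- round(window_len * (1 - overlap_frac))
  if (step < 1) stop("window step rounds to zero")
  n_samp <- window_len + (T_ - 1L) * step
  if (n_samp < window_len) stop("fewer samples than one window")
  win <- sliding_windows(n_samp, window_len, overlap_frac)
  centers <- (win$start + win$end) / 2
  n <- nrow(gt$region_loadings)
  k <- gt$params$k_true

  band_noise <- function(n_samp) {
    e <- rnorm(n_samp)
    fe <- fft(e)
    fr <- seq(0, n_samp - 1) / (n_samp * tr_seconds)
    fr <- pmin(fr, 1 / tr_seconds - fr)     # two-sided frequency axis
    mask <- fr >= band[1] & fr <= band[2]
    z <- Re(fft(fe * mask, inverse = TRUE)) / n_samp
    s <- sd(z)
    if (s == 0) stop("band too narrow for the series length")
    z / s
  }

  series <- vector("list", gt$params$n_subjects)
  for (s in seq_along(series)) {
    lat <- matrix(0, k, n_samp)
    for (g in seq_len(k)) {
      amp <- approx(centers, sqrt(gt$coeffs_true[[s]][g, ]),
                    xout = seq_len(n_samp), rule = 2)$y
      lat[g, ] <- amp * band_noise(n_samp)
    }
    out <- gt$region_loadings %*% lat
    if (noise_sd > 0) out <- out + matrix(rnorm(length(out), sd = noise_sd),
                                          nrow = n)
    rownames(out) <- gt$partition$node_ids
    series[[s]] <- out
  }
  names(series) <- sprintf("sub-%03d", seq_along(series))
  ages <- ifelse(gt$group_labels == "child",
                 runif(length(gt$group_labels), 8.17, 11.42),
                 runif(length(gt$group_labels), 19.58, 22.58))
  structure(list(series = series, partition = gt$partition,
                 group_labels = gt$group_labels, ages = ages,
                 motion = NULL, behavior = NULL, edges = NULL,
                 ground_truth = gt, tr_seconds = tr_seconds, band = band),
            class = "synthetic_cohort")
}

#' Add a known motion confound to a cohort's connectivity
#'
#' Draws nonnegative per-subject motion scalars (gamma distributed, mean
#' 0.12, emulating mean RMS displacement in mm) and adds `slope * motion`
#' to every edge value of that subject before clipping at zero. Creates a
#' known across-subject confound that [regress_motion()] must remove.
#'
#' @param cohort a `synthetic_cohort` carrying rendered `edges`.
#' @param slope confound strength (edge units per motion unit; may be 0).
#' @param seed integer seed for the motion draws.
#' @return the cohort with `motion` set and `edges` shifted and clipped.
#' @export
attach_motion_confound <- function(cohort, slope, seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"), is.numeric(slope),
            length(slope) == 1, is.finite(slope))
  if (is.null(cohort$edges)) {
    stop("cohort has no rendered edges; call render_connectivity first")
  }
  if (is.null(seed)) seed <- cohort$ground_truth$seed + 3000L
  set.seed(seed)
  S <- length(cohort$edges)
  motion <- rgamma(S, shape = 4, rate = 4 / 0.12)
  for (s in seq_len(S)) {
    M <- cohort$edges[[s]] + slope * motion[s]
    M[M < 0] <- 0
    cohort$edges[[s]] <- M
  }
  cohort$motion <- setNames(motion, names(cohort$edges))
  cohort
}

#' Add a behavior score driven by planted flexibility and age
#'
#' Behavior is generated as `z(flexibility) + age_coef * z(age) + noise`,
#' where flexibility is the histogram entropy of the subject's standardized
#' effect-subgraph coefficients. With `noise_sd = 1` the flexibility signal
#' and the noise have equal variance (signal-to-noise 1). Exercises the
#' age-residualized association test.
#'
#' @param cohort a `synthetic_cohort` (with `ages`).
#' @param age_coef weight of the age effect on behavior.
#' @param noise_sd behavior noise standard deviation.
#' @param seed integer seed.
#' @return the cohort with `behavior` (and `flexibility_true`) set.
#' @export
attach_behavior <- function(cohort, age_coef = 0.5, noise_sd = 1,
                            seed = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  gt <- cohort$ground_truth
  if (is.null(seed)) seed <- gt$seed + 4000L
  set.seed(seed)
  flex <- vapply(gt$coeffs_true, function(Hs) {
    v <- Hs[gt$effect_subgraph, ]
    signal_entropy(v / mean(v))
  }, numeric(1))
  zf <- if (sd(flex) > 0) (flex - mean(flex)) / sd(flex) else flex * 0
  za <- (cohort$ages - mean(cohort$ages)) / sd(cohort$ages)
  cohort$flexibility_true <- flex
  cohort$behavior <- zf + age_coef * za + rnorm(length(flex), sd = noise_sd)
  cohort
}

#' One-call synthetic cohort with planted ground truth
#'
#' Builds an even partition, plants ground truth, renders edge-level
#' connectivity (and optionally region series), draws motion (optionally
#' confounded) and behavior. The default geometry (40 regions, 4 systems,
#' 4 subgraphs, 51 windows, 40 subjects) is a desk-scale cohort that keeps
#' the canonical window count.
#'
#' @param n_regions,n_systems,k_true,n_subjects,n_windows cohort geometry.
#' @param energy_ratio,switching_prob,switching_increment planted group
#'   effect (see [make_ground_truth()]).
#' @param noise_sd edge-noise standard deviation for
#'   [render_connectivity()].
#' @param motion_slope strength of the motion confound (0 = none; motion
#'   scalars are drawn either way).
#' @param render_series also render region time series with [render_bold()].
#' @param seed master seed.
#' @return a `synthetic_cohort` with `edges`, `motion`, `behavior`, `ages`,
#'   `ground_truth` (and `series` when requested).
#' @export
simulate_cohort <- function(n_regions = 40L, n_systems = 4L, k_true = 4L,
                            n_subjects = 40L, n_windows = 51L,
                            energy_ratio = 1.5, switching_prob = 0.10,
                            switching_increment = 0.20, noise_sd = 0.05,
                            motion_slope = 0, render_series = FALSE,
                            seed = 1L) {
  part <- even_partition(n_regions, n_systems)
  gt <- make_ground_truth(part, k_true, n_windows = n_windows,
                          n_subjects = n_subjects,
                          energy_ratio = energy_ratio,
                          switching_prob = switching_prob,
                          switching_increment = switching_increment,
                          seed = seed)
  edges <- render_connectivity(gt, noise_sd = noise_sd)
  if (render_series) {
    cohort <- render_bold(gt)
  } else {
    set.seed(gt$seed + 2000L)
    ages <- ifelse(gt$group_labels == "child",
                   runif(n_subjects, 8.17, 11.42),
                   runif(n_subjects, 19.58, 22.58))
    cohort <- structure(list(series = NULL, partition = part,
                             group_labels = gt$group_labels, ages = ages,
                             motion = NULL, behavior = NULL, edges = NULL,
                             ground_truth = gt),
                        class = "synthetic_cohort")
  }
  cohort$edges <- edges
  cohort <- attach_motion_confound(cohort, slope = motion_slope)
  cohort <- attach_behavior(cohort)
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  gt <- x$ground_truth
  cat("synthetic_cohort:", gt$params$n_subjects, "subjects (",
      sum(x$group_labels == "child"), "child /",
      sum(x$group_labels == "adult"), "adult ),",
      nrow(gt$region_loadings), "regions,",
      gt$params$k_true, "planted subgraphs\n")
  if (!is.null(x$series)) cat("  series:", nrow(x$series[[1]]), "x",
                              ncol(x$series[[1]]), "per subject\n")
  if (!is.null(x$edges)) cat("  edges:", nrow(x$edges[[1]]), "x",
                             ncol(x$edges[[1]]), "per subject\n")
  invisible(x)
}
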
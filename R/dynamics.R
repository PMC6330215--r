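#' Signal energy of a coefficient series
#'
#' Sum of squared time-dependent coefficients, `sum(s^2)`: the overall
#' level of expression of one subgraph in one subject. Scales quadratically
#' under scalar multiplication of the series.
#'
#' @param s nonnegative numeric series.
#' @return nonnegative scalar.
#' @export
signal_energy <- function(s) {
  stopifnot(is.numeric(s), all(is.finite(s)))
  sum(s^2)
}

#' Histogram entropy of a coefficient series
#'
#' Shannon entropy (natural log) of the empirical distribution over
#' `n_bins` equal-width bins spanning the series' own `[min, max]`:
#' `-sum(P * log(P))` over nonempty bins, with `P` the bin counts divided by
#' the series length. Because binning adapts to the range, the estimator is
#' invariant to affine rescaling; it quantifies switching between expression
#' levels, not their magnitude. A constant series has zero range and its
#' entropy is defined as 0 (the limiting value).
#'
#' @param s numeric series, length >= 2.
#' @param n_bins number of histogram bins (>= 2).
#' @return nonnegative scalar, at most `log(n_bins)`.
#' @export
signal_entropy <- function(s, n_bins = 10L) {
  stopifnot(is.numeric(s), length(s) >= 2, all(is.finite(s)), n_bins >= 2)
  rng <- range(s)
  if (rng[1] == rng[2]) return(0)
  u <- (s - rng[1]) / (rng[2] - rng[1])
  idx <- pmin(n_bins, floor(u * n_bins) + 1L)
  P <- tabulate(idx, n_bins) / length(s)
  P <- P[P > 0]
  -sum(P * log(P))
}

#' Mean absolute temporal derivative of a coefficient series
#'
#' Mean absolute first difference between adjacent coefficients; a direct
#' measure of how fast expression changes from window to window.
#'
#' @param s numeric series, length >= 2.
#' @return nonnegative scalar.
#' @export
mean_abs_derivative <- function(s) {
  stopifnot(is.numeric(s), length(s) >= 2, all(is.finite(s)))
  mean(abs(diff(s)))
}

#' Standardize coefficients by their per-subject, per-subgraph mean
#'
#' Divides every (subject, subgraph) coefficient sequence by its own mean,
#' so each sequence has mean exactly 1 afterwards. This removes differences
#' in baseline expression and makes between-subject comparisons relative
#' rather than absolute. Idempotent. A `per_subject_only` variant divides
#' by the subject's mean across all subgraphs instead.
#'
#' @param H coefficient matrix, k x (T*S).
#' @param column_map data.frame with `column` and `subject` mapping columns
#'   of H to subjects (as produced by [concatenate_cohort()]).
#' @param per_subject_only divide by per-subject means pooled over
#'   subgraphs instead of per-(subject, subgraph) means.
#' @return list with `H_std` (same shape; sequences with zero mean are left
#'   unscaled and reported) and `skipped` (data.frame of zero-mean pairs).
#' @export
standardize_coefficients <- function(H, column_map, per_subject_only = FALSE) {
  stopifnot(is.matrix(H), nrow(column_map) == ncol(H))
  subjects <- unique(column_map$subject)
  H_std <- H
  skipped <- list()
  for (s in subjects) {
    cols <- column_map$column[column_map$subject == s]
    if (per_subject_only) {
      m <- mean(H[, cols])
      if (m > 0) H_std[, cols] <- H[, cols] / m
      else skipped[[length(skipped) + 1L]] <-
          data.frame(subject = s, subgraph = NA_integer_)
      next
    }
    for (g in seq_len(nrow(H))) {
      m <- mean(H[g, cols])
      if (m > 0) {
        H_std[g, cols] <- H[g, cols] / m
      } else {
        skipped[[length(skipped) + 1L]] <- data.frame(subject = s, subgraph = g)
      }
    }
  }
  list(H_std = H_std,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(subject = character(0), subgraph = integer(0)))
}

#' Per-subject, per-subgraph dynamics summary
#'
#' Tabulates energy, histogram entropy and mean absolute derivative of each
#' (subject, subgraph) coefficient sequence, together with the standardized
#' energy and entropy computed after per-(subject, subgraph) mean division.
#'
#' @param H coefficient matrix, k x (T*S).
#' @param column_map column-to-subject map (see [concatenate_cohort()]).
#' @param groups optional per-subject group labels (named by subject id or
#'   in `unique(column_map$subject)` order).
#' @param motion optional per-subject motion scalars (same conventions).
#' @param n_bins histogram bins for the entropy estimator.
#' @return data.frame, one row per (subject, subgraph), with columns
#'   `subject`, `subgraph`, `energy`, `entropy`, `mean_abs_derivative`,
#'   `standardized_energy`, `standardized_entropy`, plus `group` and
#'   `motion` when supplied.
#' @export
dynamics_summary <- function(H, column_map, groups = NULL, motion = NULL,
                             n_bins = 10L) {
  stopifnot(is.matrix(H), nrow(column_map) == ncol(H))
  subjects <- unique(column_map$subject)
  std <- standardize_coefficients(H, column_map)$H_std
  per_subject <- function(vec, what) {
    if (is.null(vec)) return(NULL)
    if (!is.null(names(vec))) {
      if (!all(subjects %in% names(vec))) {
        stop("names of ", what, " do not cover all subjects")
      }
      vec[subjects]
    } else {
      stopifnot(length(vec) == length(subjects))
      vec
    }
  }
  groups <- per_subject(groups, "groups")
  motion <- per_subject(motion, "motion")
  rows <- vector("list", length(subjects) * nrow(H))
  r <- 0L
  for (si in seq_along(subjects)) {
    cols <- column_map$column[column_map$subject == subjects[si]]
    for (g in seq_len(nrow(H))) {
      sser <- H[g, cols]
      zser <- std[g, cols]
      r <- r + 1L
      rows[[r]] <- data.frame(
        subject = subjects[si], subgraph = g,
        energy = signal_energy(sser),
        entropy = signal_entropy(sser, n_bins),
        mean_abs_derivative = mean_abs_derivative(sser),
        standardized_energy = signal_energy(zser),
        standardized_entropy = signal_entropy(zser, n_bins))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(groups)) out$group <- rep(as.character(groups), each = nrow(H))
  if (!is.null(motion)) out$motion <- rep(motion, each = nrow(H))
  out
}

#' Correlation between log subgraph energy and entropy
#'
#' Averages energy and entropy across subjects within each subgraph and
#' returns the Pearson correlation between log mean energy and mean
#' entropy over subgraphs, with the two-sided parametric p value. A strong
#' positive correlation indicates that strongly expressed subgraphs also
#' switch expression levels more.
#'
#' @param summary a [dynamics_summary()] data.frame (>= 3 subgraphs).
#' @param energy_col,entropy_col which columns to relate.
#' @return list with `r`, `p`, and the per-subgraph `means` table.
#' @export
energy_entropy_relation <- function(summary, energy_col = "energy",
                                    entropy_col = "entropy") {
  stopifnot(all(c("subject", "subgraph", energy_col, entropy_col) %in%
                  names(summary)))
  sg <- sort(unique(summary$subgraph))
  if (length(sg) < 3) stop("need at least 3 subgraphs")
  mean_e <- vapply(sg, function(g)
    mean(summary[[energy_col]][summary$subgraph == g]), numeric(1))
  mean_h <- vapply(sg, function(g)
    mean(summary[[entropy_col]][summary$subgraph == g]), numeric(1))
  if (any(mean_e <= 0)) stop("all per-subgraph mean energies must be positive")
  if (sd(log(mean_e)) == 0 || sd(mean_h) == 0) {
    stop("zero variance across subgraphs in energy or entropy")
  }
  ct <- cor.test(log(mean_e), mean_h)
  list(r = unname(ct$estimate), p = ct$p.value,
       means = data.frame(subgraph = sg, mean_energy = mean_e,
                          mean_entropy = mean_h))
}

#' Element-shuffle permutation null for the energy-entropy correlation
#'
#' Shuffles all entries of the coefficient matrix jointly (shape preserved,
#' elements moved across rows and columns), recomputes the per-subgraph
#' energy-entropy correlation each time, and reports the add-one smoothed
#' fraction of permuted `|r|` at least as large as the observed `|r|`.
#'
#' @param H coefficient matrix, k x (T*S), k >= 3.
#' @param column_map column-to-subject map.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param n_bins histogram bins for the entropy estimator.
#' @return list with `observed_r`, `p`, `n_perm` and the vector of `null_r`.
#' @export
shuffle_null_correlation <- function(H, column_map, n_perm = 1000L,
                                     seed = NULL, n_bins = 10L) {
  stopifnot(n_perm >= 100)
  subj_cols <- split(column_map$column, column_map$subject)
  obs <- energy_entropy_r(H, subj_cols, n_bins)
  if (!is.finite(obs)) stop("observed correlation is degenerate")
  if (!is.null(seed)) set.seed(seed)
  null_r <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    Hp <- matrix(sample(H), nrow(H), ncol(H))
    r <- energy_entropy_r(Hp, subj_cols, n_bins)
    null_r[p] <- if (is.finite(r)) r else 0
  }
  list(observed_r = obs,
       p = (1 + sum(abs(null_r) >= abs(obs))) / (n_perm + 1),
       n_perm = n_perm, null_r = null_r)
}

# light-weight per-subgraph mean-energy / mean-entropy correlation; the
# same quantity energy_entropy_relation() reports, without the summary
# table (the permutation nulls recompute it thousands of times)
energy_entropy_r <- function(H, subj_cols, n_bins) {
  k <- nrow(H)
  me <- mh <- matrix(0, k, length(subj_cols))
  for (s in seq_along(subj_cols)) {
    block <- H[, subj_cols[[s]], drop = FALSE]
    me[, s] <- rowSums(block^2)
    mh[, s] <- apply(block, 1L, signal_entropy, n_bins = n_bins)
  }
  e <- rowMeans(me)
  h <- rowMeans(mh)
  if (any(e <= 0) || sd(h) == 0 || sd(log(e)) == 0) return(NA_real_)
  cor(log(e), h)
}

#' Two-group Wilcoxon rank-sum comparison
#'
#' Rank-sum z statistic with tie correction and continuity correction,
#' signed so that z is negative when the second-listed group has the larger
#' ranks (group medians are reported alongside so direction is unambiguous).
#' The p value uses the exact rank-sum distribution when both groups are
#' small and untied (via [stats::wilcox.test()]), otherwise the tie-corrected
#' normal approximation.
#'
#' @param values numeric vector, one value per subject.
#' @param groups two-level factor (or coercible); level order defines the
#'   sign convention.
#' @return list with `z`, `p`, `medians` (named per group) and `n`.
#' @export
group_compare <- function(values, groups) {
  g <- if (is.factor(groups)) droplevels(groups) else factor(groups, levels = unique(groups))
  if (nlevels(g) != 2) stop("exactly two groups are required")
  n1 <- sum(g == levels(g)[1]); n2 <- sum(g == levels(g)[2])
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 subjects")
  stopifnot(length(values) == length(g), all(is.finite(values)))
  rk <- rank(values)
  W1 <- sum(rk[g == levels(g)[1]])
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    z <- 0
  } else {
    d <- W1 - mu
    z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  }
  p <- wilcox.test(values[g == levels(g)[1]], values[g == levels(g)[2]],
                   exact = NULL, correct = TRUE)$p.value
  list(z = z, p = p,
       medians = setNames(c(median(values[g == levels(g)[1]]),
                            median(values[g == levels(g)[2]])), levels(g)),
       n = setNames(c(n1, n2), levels(g)))
}

#' Correlation of dynamics metrics with subject motion
#'
#' Pearson correlation (with two-sided p) of each requested metric against
#' per-subject motion, within one subgraph. Used as a negative control: the
#' pipeline's motion regression should leave these near zero.
#'
#' @param summary a [dynamics_summary()] with a `motion` column.
#' @param subgraph which subgraph to check (default 1).
#' @param metrics summary columns to correlate with motion.
#' @return data.frame with `metric`, `r`, `p`.
#' @export
motion_check <- function(summary, subgraph = 1L,
                         metrics = c("standardized_energy",
                                     "standardized_entropy")) {
  stopifnot("motion" %in% names(summary), all(metrics %in% names(summary)))
  d <- summary[summary$subgraph == subgraph, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 subjects")
  if (sd(d$motion) == 0) stop("motion has zero variance across subjects")
  res <- lapply(metrics, function(mcol) {
    if (sd(d[[mcol]]) == 0) stop("metric ", mcol, " has zero variance")
    ct <- cor.test(d[[mcol]], d$motion)
    data.frame(metric = mcol, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

#' Age-residualized behavior association with permutation p value
#'
#' Residualizes both the flexibility measure (entropy of projected subgraph
#' weights by default, or the mean absolute derivative) and the behavior
#' score on age by ordinary least squares (with intercept), correlates the
#' residuals, and assesses significance by permuting the residualized
#' behavior across subjects.
#'
#' @param flexibility numeric per-subject flexibility values.
#' @param behavior numeric per-subject behavior scores.
#' @param age numeric per-subject ages.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `partial_r`, `p`, `n_perm`.
#' @export
behavior_association <- function(flexibility, behavior, age,
                                 n_perm = 1000L, seed = NULL) {
  stopifnot(length(flexibility) == length(behavior),
            length(behavior) == length(age), length(age) >= 10,
            n_perm >= 100)
  rf <- residuals(lm(flexibility ~ age))
  rb <- residuals(lm(behavior ~ age))
  if (sd(rf) == 0 || sd(rb) == 0) stop("zero residual variance")
  obs <- cor(rf, rb)
  if (!is.null(seed)) set.seed(seed)
  null_r <- vapply(seq_len(n_perm),
                   function(i) cor(rf, sample(rb)), numeric(1))
  list(partial_r = obs,
       p = (1 + sum(abs(null_r) >= abs(obs))) / (n_perm + 1),
       n_perm = n_perm)
}
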
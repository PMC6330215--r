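#' Node-to-system partition
#'
#' An a-priori assignment of every network node to one labeled cognitive
#' system (for the 264-node functional parcellation this is the familiar
#' 13-system assignment; synthetic cohorts use smaller partitions).
#'
#' @param systems character or factor of system labels, one per node.
#' @param node_ids optional node identifiers (defaults to `n1, n2, ...`).
#' @return a `system_partition`: list with `node_to_system` (factor),
#'   `node_ids`, `systems` (ordered unique labels) and `sizes`.
#' @export
system_partition <- function(systems, node_ids = NULL) {
  f <- if (is.factor(systems)) droplevels(systems) else factor(systems)
  if (anyNA(f)) stop("every node must carry a system label")
  if (is.null(node_ids)) node_ids <- paste0("n", seq_along(f))
  stopifnot(length(node_ids) == length(f))
  structure(list(node_to_system = f, node_ids = as.character(node_ids),
                 systems = levels(f), sizes = as.integer(table(f))),
            class = "system_partition")
}

#' Read a node-to-system partition from a TSV file
#'
#' Expects columns `node_id` and `system` (header required).
#'
#' @param path TSV file path.
#' @return a [system_partition()].
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("partition file not found: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node_id", "system") %in% names(d))) {
    stop("partition TSV must have columns 'node_id' and 'system'")
  }
  system_partition(d$system, d$node_id)
}

#' Write a partition to TSV
#' @param partition a [system_partition()].
#' @param path output file path.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "system_partition"))
  write.table(data.frame(node_id = partition$node_ids,
                         system = as.character(partition$node_to_system)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.system_partition <- function(x, ...) {
  cat("system_partition:", length(x$node_to_system), "nodes in",
      length(x$systems), "systems\n")
  print(setNames(x$sizes, x$systems))
  invisible(x)
}

#' Within- and between-system connectivity of a subgraph
#'
#' Collapses an N x N subgraph V onto the m x m system matrix. Diagonal
#' entries are the within-system connectivity `R_s = sum_{i,j in P_s} V_ij /
#' |P_s|^2` (both orientations of each undirected edge counted; the zero
#' diagonal of V contributes nothing, so an all-ones system of size n yields
#' `1 - 1/n`, the formula's documented ceiling). Off-diagonal entries are
#' the between-system connectivity `I_st = sum_{i in P_s, j in P_t} V_ij /
#' (|P_s| |P_t|)`.
#'
#' @param V symmetric N x N matrix with zero diagonal (see
#'   [fold_subgraph()]).
#' @param partition a [system_partition()] covering all N nodes.
#' @return an m x m symmetric `system_matrix` with system dimnames.
#' @export
system_matrix <- function(V, partition) {
  stopifnot(inherits(partition, "system_partition"), is.matrix(V),
            nrow(V) == ncol(V))
  if (nrow(V) != length(partition$node_to_system)) {
    stop("V has ", nrow(V), " nodes but the partition labels ",
         length(partition$node_to_system))
  }
  lab <- partition$node_to_system
  agg <- rowsum(t(rowsum(V, lab)), lab)        # sum_{i in s, j in t} V_ij
  agg <- agg[partition$systems, partition$systems, drop = FALSE]
  M <- agg / outer(partition$sizes, partition$sizes)
  dimnames(M) <- list(partition$systems, partition$systems)
  structure(M, class = c("system_matrix", "matrix"))
}

#' Locality skewness of a system matrix
#'
#' Sample skewness (third standardized moment, bias-uncorrected) of the
#' m(m-1)/2 off-diagonal upper-triangle entries of the system matrix.
#' Localized subgraphs concentrate weight in few system pairs and are
#' strongly right-skewed; distributed subgraphs are not. A zero-variance
#' input returns 0 by convention.
#'
#' @param M a [system_matrix()] (m >= 3 so at least 3 off-diagonal values).
#' @return scalar skewness.
#' @export
locality_skewness <- function(M) {
  stopifnot(nrow(M) == ncol(M))
  if (nrow(M) < 3) stop("need at least 3 systems (3 off-diagonal values)")
  v <- M[upper.tri(M)]
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  if (s2 == 0) return(0)
  mean((v - mu)^3) / s2^1.5
}

#' Label-permutation significance of system expression in a subgraph
#'
#' The per-system statistic is the column sum of the full symmetric system
#' matrix (its within-system diagonal entry plus all between-system terms).
#' The null is the same statistic under uniformly random permutations of
#' the node-to-system labels (system sizes preserved by construction); a
#' system is flagged when its observed statistic exceeds the one-sided 95th
#' percentile of its own null. Flags are uncorrected for multiple
#' comparisons and intended for reporting which systems dominate a
#' subgraph, not for thresholding the matrices themselves.
#'
#' @param V symmetric N x N subgraph matrix with zero diagonal.
#' @param partition a [system_partition()].
#' @param n_perm number of label permutations (>= 100).
#' @param alpha one-sided level for the percentile rule.
#' @param seed integer seed for the permutations.
#' @return data.frame with `system`, `statistic`, `null_p95` (the
#'   `1 - alpha` null quantile), `p_value` (add-one smoothed) and
#'   `significant`; the null statistics are attached as attribute `"null"`.
#' @export
significant_systems <- function(V, partition, n_perm = 1000L, alpha = 0.05,
                                seed = NULL) {
  stopifnot(inherits(partition, "system_partition"), n_perm >= 100)
  if (length(partition$systems) < 2) stop("need at least 2 distinct systems")
  obs <- colSums(system_matrix(V, partition))
  m <- length(obs)
  if (!is.null(seed)) set.seed(seed)
  lab <- partition$node_to_system
  null_mat <- matrix(NA_real_, n_perm, m)
  for (p in seq_len(n_perm)) {
    perm <- system_partition(sample(lab), partition$node_ids)
    null_mat[p, ] <- colSums(system_matrix(V, perm))[partition$systems]
  }
  thr_idx <- ceiling((1 - alpha) * n_perm)
  null_p95 <- apply(null_mat, 2L, function(z) sort(z)[thr_idx])
  pval <- (1 + colSums(sweep(null_mat, 2L, obs, `>=`))) / (n_perm + 1)
  out <- data.frame(system = partition$systems, statistic = as.numeric(obs),
                    null_p95 = null_p95, p_value = pval,
                    significant = as.numeric(obs) > null_p95)
  attr(out, "null") <- null_mat
  out
}
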
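#' Lexicographic node-pair index for the upper triangle
#'
#' Enumerates the E = N(N-1)/2 unordered node pairs (i, j), i < j, in the
#' fixed lexicographic order (1,2), (1,3), ..., (1,N), (2,3), ... used by
#' every fold/unfold operation in the package. A fixed convention is what
#' makes the edge-vector representation of a network invertible.
#'
#' @param n_nodes number of network nodes (>= 2).
#' @return integer matrix with columns `i`, `j` and one row per edge.
#' @export
edge_pairs <- function(n_nodes) {
  stopifnot(is.numeric(n_nodes), length(n_nodes) == 1L, n_nodes >= 2)
  n_nodes <- as.integer(n_nodes)
  i <- rep.int(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(a) (a + 1L):n_nodes),
              use.names = FALSE)
  cbind(i = i, j = j)
}

#' Number of nodes implied by an edge-vector length
#'
#' @param n_edges length of an upper-triangle edge vector.
#' @return integer N with N(N-1)/2 == n_edges; errors if `n_edges` is not a
#'   triangular number.
#' @export
n_nodes_from_edges <- function(n_edges) {
  n <- (1 + sqrt(1 + 8 * n_edges)) / 2
  if (abs(n - round(n)) > 1e-8) {
    stop("edge vector length ", n_edges, " is not a triangular number N(N-1)/2")
  }
  as.integer(round(n))
}

#' Fold an edge vector into a symmetric adjacency matrix
#'
#' Inverse of unfolding: places the E = N(N-1)/2 edge weights of one
#' subgraph (one basis column) back into an N x N symmetric matrix with a
#' zero diagonal, following the lexicographic pair order of [edge_pairs()].
#'
#' @param w numeric edge vector of triangular-number length.
#' @param node_ids optional node names for the dimnames.
#' @return N x N symmetric numeric matrix with zero diagonal.
#' @export
fold_subgraph <- function(w, node_ids = NULL) {
  stopifnot(is.numeric(w))
  n <- n_nodes_from_edges(length(w))
  ep <- edge_pairs(n)
  V <- matrix(0, n, n)
  V[ep] <- w
  V[ep[, c(2L, 1L)]] <- w
  if (!is.null(node_ids)) dimnames(V) <- list(node_ids, node_ids)
  V
}

#' Extract the upper-triangle edge vector of a symmetric matrix
#'
#' @param V symmetric matrix with (structurally) zero diagonal.
#' @param tol symmetry tolerance; asymmetry beyond it is an error.
#' @return numeric edge vector in [edge_pairs()] order.
#' @export
unfold_subgraph <- function(V, tol = 1e-8) {
  stopifnot(is.matrix(V), nrow(V) == ncol(V))
  asym <- max(abs(V - t(V)))
  if (asym > tol * max(1, max(abs(V)))) {
    stop("matrix is asymmetric beyond tolerance (max |V - t(V)| = ",
         format(asym), ")")
  }
  V[edge_pairs(nrow(V))]
}
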
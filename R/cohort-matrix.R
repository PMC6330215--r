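#' Unfold a multilayer network into an edges x windows matrix
#'
#' Takes the upper triangle of every layer (the unique connections of the
#' symmetric network) and stacks them as rows in the lexicographic pair
#' order of [edge_pairs()], one column per window. This is the per-subject
#' functional connectivity matrix C.
#'
#' @param A a `multilayer_network` (layers symmetric within `tol`).
#' @param tol symmetry tolerance.
#' @return an `edge_time_matrix`: list with `values` (E x T), `edge_index`
#'   (the pair matrix), `node_ids` and `windows`.
#' @export
unfold_layers <- function(A, tol = 1e-8) {
  stopifnot(inherits(A, "multilayer_network"))
  d <- dim(A$values)
  n <- d[1]
  ep <- edge_pairs(n)
  V <- matrix(A$values, nrow = n * n)
  asym <- max(abs(V[ep[, 1] + (ep[, 2] - 1L) * n, , drop = FALSE] -
                  V[ep[, 2] + (ep[, 1] - 1L) * n, , drop = FALSE]))
  if (asym > tol * max(1, max(abs(V)))) {
    stop("layers asymmetric beyond tolerance (max deviation ", format(asym), ")")
  }
  structure(list(values = V[ep[, 1] + (ep[, 2] - 1L) * n, , drop = FALSE],
                 edge_index = ep, node_ids = A$node_ids, windows = A$windows),
            class = "edge_time_matrix")
}

#' Fold an edge-time matrix back into a multilayer network
#'
#' Exact inverse of [unfold_layers()] on symmetric zero-diagonal layers.
#'
#' @param C an `edge_time_matrix`.
#' @return a `multilayer_network`.
#' @export
fold_layers <- function(C) {
  stopifnot(inherits(C, "edge_time_matrix"))
  n <- n_nodes_from_edges(nrow(C$values))
  A <- array(0, dim = c(n, n, ncol(C$values)))
  for (l in seq_len(ncol(C$values))) {
    A[, , l] <- fold_subgraph(C$values[, l])
  }
  structure(list(values = A, windows = C$windows, node_ids = C$node_ids,
                 degenerate = rep(FALSE, n)),
            class = "multilayer_network")
}

#' @export
print.edge_time_matrix <- function(x, ...) {
  cat("edge_time_matrix:", nrow(x$values), "edges x", ncol(x$values),
      "windows\n")
  invisible(x)
}

#' Regress a scalar motion covariate out of every edge across subjects
#'
#' For each (edge, window) cell an ordinary least-squares fit of edge value
#' on the per-subject motion scalar is computed across subjects; the fitted
#' slope component `b * motion` is removed while the intercept is retained,
#' so edges keep their nonnegative scale. Negative residual values (rare)
#' are clipped to zero. Motion with zero variance across subjects makes the
#' fit undefined; the data are then returned unchanged with a warning.
#'
#' @param cohort_edges list of `edge_time_matrix` objects (or bare E x T
#'   matrices), one per subject, with identical dimensions.
#' @param motion numeric vector of per-subject motion scalars.
#' @return list of the same shape with the motion component removed.
#' @export
regress_motion <- function(cohort_edges, motion) {
  stopifnot(length(cohort_edges) == length(motion), length(motion) >= 3,
            all(is.finite(motion)))
  mats <- lapply(cohort_edges, function(c) {
    if (inherits(c, "edge_time_matrix")) c$values else c
  })
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("subjects disagree in edge/window dimensions")
  }
  mc <- motion - mean(motion)
  denom <- sum(mc^2)
  if (denom == 0) {
    warning("motion has zero variance across subjects; regression skipped")
    return(cohort_edges)
  }
  slope <- Reduce(`+`, Map(function(m, w) m * w, mats, mc)) / denom
  out <- cohort_edges
  for (s in seq_along(mats)) {
    res <- mats[[s]] - slope * motion[s]
    res[res < 0] <- 0
    if (inherits(out[[s]], "edge_time_matrix")) {
      out[[s]]$values <- res
    } else {
      out[[s]] <- res
    }
  }
  out
}

#' Concatenate per-subject edge-time matrices into the cohort matrix X
#'
#' Column blocks follow subject order; the invertible `column_map` records
#' which (subject, window) each column came from. All entries must be
#' nonnegative (clip upstream, in [regress_motion()], before this step).
#'
#' @param cohort_edges list of `edge_time_matrix` objects or E x T matrices.
#' @param subject_ids optional character vector of subject identifiers.
#' @return a `cohort_matrix`: list with `values` (E x T*S), `column_map`
#'   (data.frame: column, subject, window), `subject_order`, `edge_index`.
#' @export
concatenate_cohort <- function(cohort_edges, subject_ids = NULL) {
  stopifnot(length(cohort_edges) >= 1)
  if (is.null(subject_ids)) {
    subject_ids <- names(cohort_edges) %||%
      sprintf("sub-%03d", seq_along(cohort_edges))
  }
  stopifnot(length(subject_ids) == length(cohort_edges))
  mats <- lapply(cohort_edges, function(c) {
    if (inherits(c, "edge_time_matrix")) c$values else c
  })
  dims <- vapply(mats, dim, integer(2))
  bad <- which(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])
  if (length(bad)) {
    stop("subject ", subject_ids[bad[1]], " has dimensions ",
         dims[1, bad[1]], "x", dims[2, bad[1]], ", expected ",
         dims[1, 1], "x", dims[2, 1])
  }
  X <- do.call(cbind, mats)
  if (any(X < 0)) stop("negative entries in cohort matrix; clip before concatenation")
  T_ <- dims[2, 1]
  ei <- if (inherits(cohort_edges[[1]], "edge_time_matrix")) {
    cohort_edges[[1]]$edge_index
  } else {
    edge_pairs(n_nodes_from_edges(dims[1, 1]))
  }
  structure(list(values = X,
                 column_map = data.frame(
                   column = seq_len(ncol(X)),
                   subject = rep(subject_ids, each = T_),
                   window = rep.int(seq_len(T_), length(mats))),
                 subject_order = subject_ids,
                 edge_index = ei),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat("cohort_matrix:", nrow(x$values), "edges x", ncol(x$values),
      "columns (", length(x$subject_order), "subjects x",
      ncol(x$values) / length(x$subject_order), "windows )\n")
  invisible(x)
}
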
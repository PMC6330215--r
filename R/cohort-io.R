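#' Write a synthetic cohort to a directory of plain-text files
#'
#' Layout: `partition.tsv` (node_id, system), `metadata.tsv` (subject_id,
#' group, age, motion, behavior), `ground_truth/basis.tsv` (E x k, header =
#' subgraph ids), `ground_truth/coeffs.tsv` (long: subject_id, subgraph,
#' window, value), `edges/<subject>.tsv` (E x T) and/or
#' `series/<subject>.tsv` (samples x regions, header = node ids), plus a
#' `manifest.json` with the generator parameters.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- cohort$ground_truth
  write_partition(cohort$partition, file.path(dir, "partition.tsv"))
  S <- gt$params$n_subjects
  ids <- names(gt$coeffs_true) %||% sprintf("sub-%03d", seq_len(S))
  meta <- data.frame(subject_id = ids,
                     group = as.character(cohort$group_labels),
                     age = cohort$ages %||% rep(NA_real_, S),
                     motion = unname(cohort$motion %||% rep(NA_real_, S)),
                     behavior = cohort$behavior %||% rep(NA_real_, S))
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gdir <- file.path(dir, "ground_truth")
  dir.create(gdir, showWarnings = FALSE)
  basis <- gt$basis_true
  colnames(basis) <- sprintf("subgraph%02d", seq_len(ncol(basis)))
  write.table(basis, file.path(gdir, "basis.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  co <- do.call(rbind, lapply(seq_len(S), function(s) {
    Hs <- gt$coeffs_true[[s]]
    data.frame(subject_id = ids[s],
               subgraph = rep(seq_len(nrow(Hs)), ncol(Hs)),
               window = rep(seq_len(ncol(Hs)), each = nrow(Hs)),
               value = as.vector(Hs))
  }))
  write.table(co, file.path(gdir, "coeffs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$edges)) {
    edir <- file.path(dir, "edges")
    dir.create(edir, showWarnings = FALSE)
    for (s in seq_len(S)) {
      write.table(cohort$edges[[s]], file.path(edir, paste0(ids[s], ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  if (!is.null(cohort$series)) {
    sdir <- file.path(dir, "series")
    dir.create(sdir, showWarnings = FALSE)
    for (s in seq_len(S)) {
      write.table(t(cohort$series[[s]]),
                  file.path(sdir, paste0(ids[s], ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(
    c(gt$params, list(seed = gt$seed, effect_subgraph = gt$effect_subgraph,
                      supports = lapply(gt$supports, as.character))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `partition`, `metadata` (data.frame), `edges` and/or
#'   `series` (named lists of matrices), `basis_true`, `coeffs_true` and
#'   `params`. This is the on-disk view; it carries enough to rerun every
#'   downstream stage.
#' @export
read_cohort <- function(dir) {
  if (!dir.exists(dir)) stop("cohort directory not found: ", dir)
  partition <- read_partition(file.path(dir, "partition.tsv"))
  meta <- read.delim(file.path(dir, "metadata.tsv"), stringsAsFactors = FALSE)
  out <- list(partition = partition, metadata = meta)
  gfile <- file.path(dir, "ground_truth", "basis.tsv")
  if (file.exists(gfile)) {
    out$basis_true <- as.matrix(read.delim(gfile, check.names = FALSE))
    co <- read.delim(file.path(dir, "ground_truth", "coeffs.tsv"),
                     stringsAsFactors = FALSE)
    out$coeffs_true <- lapply(split(co, factor(co$subject_id,
                                               levels = meta$subject_id)),
                              function(d) {
      k <- max(d$subgraph); T_ <- max(d$window)
      H <- matrix(0, k, T_)
      H[cbind(d$subgraph, d$window)] <- d$value
      H
    })
  }
  edir <- file.path(dir, "edges")
  if (dir.exists(edir)) {
    out$edges <- lapply(setNames(meta$subject_id, meta$subject_id),
                        function(id) {
      as.matrix(read.delim(file.path(edir, paste0(id, ".tsv")),
                           header = FALSE))
    })
  }
  sdir <- file.path(dir, "series")
  if (dir.exists(sdir)) {
    out$series <- lapply(setNames(meta$subject_id, meta$subject_id),
                         function(id) {
      t(as.matrix(read.delim(file.path(sdir, paste0(id, ".tsv")),
                             check.names = FALSE)))
    })
  }
  mfile <- file.path(dir, "manifest.json")
  if (file.exists(mfile)) out$params <- jsonlite::read_json(mfile,
                                                            simplifyVector = TRUE)
  out
}
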
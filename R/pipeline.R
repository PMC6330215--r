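#' Match fitted subgraphs to reference subgraphs
#'
#' Greedy maximum-correlation assignment between the columns of a fitted
#' basis and a reference basis (scale-free: Pearson correlation is
#' invariant to the per-column rescaling that NMF leaves undetermined).
#' Repeatedly picks the highest remaining correlation pair.
#'
#' @param W fitted basis (E x k).
#' @param W_ref reference basis (E x k_ref).
#' @return data.frame with `fitted`, `reference` and `correlation`, one row
#'   per matched pair (min(k, k_ref) rows).
#' @export
match_subgraphs <- function(W, W_ref) {
  stopifnot(nrow(W) == nrow(W_ref))
  C <- suppressWarnings(cor(W, W_ref))
  C[!is.finite(C)] <- -Inf
  n <- min(ncol(W), ncol(W_ref))
  out <- data.frame(fitted = integer(n), reference = integer(n),
                    correlation = numeric(n))
  for (r in seq_len(n)) {
    idx <- arrayInd(which.max(C), dim(C))
    out$fitted[r] <- idx[1]
    out$reference[r] <- idx[2]
    out$correlation[r] <- C[idx]
    C[idx[1], ] <- -Inf
    C[, idx[2]] <- -Inf
  }
  out[order(out$reference), ]
}

#' Pipeline configuration
#'
#' One declarative object holding every stage's settings; `run_pipeline()`
#' derives each stage's seed from the single `seed`, so one integer
#' reproduces the whole run.
#'
#' @param out_dir output directory for all stages.
#' @param cohort named list of [simulate_cohort()] arguments (geometry and
#'   planted effects).
#' @param partition_path optional TSV overriding the generated partition.
#' @param coherence a [coherence_config()] (used when the cohort renders
#'   region series; the edge-level fast path skips the coherence stage).
#' @param nmf named list: `k`, `beta`, `eta` (NULL = `max(X)^2` rule),
#'   `tol`, `max_iter`.
#' @param analysis named list: `n_bins`, `n_perm`, `alpha`.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            cohort = list(),
                            partition_path = NULL,
                            coherence = coherence_config(),
                            nmf = list(k = 4L, beta = 0.01, eta = NULL,
                                       tol = 1e-6, max_iter = 200L),
                            analysis = list(n_bins = 10L, n_perm = 1000L,
                                            alpha = 0.05),
                            seed = 1L) {
  cohort <- modifyList(list(n_regions = 40L, n_systems = 4L, k_true = 4L,
                            n_subjects = 40L, n_windows = 51L,
                            energy_ratio = 1.5, switching_prob = 0.10,
                            switching_increment = 0.20, noise_sd = 0.05,
                            motion_slope = 0, render_series = FALSE),
                       cohort)
  nmf <- modifyList(list(k = 4L, beta = 0.01, eta = NULL, tol = 1e-6,
                         max_iter = 200L), nmf)
  analysis <- modifyList(list(n_bins = 10L, n_perm = 1000L, alpha = 0.05),
                         analysis)
  structure(list(out_dir = out_dir, cohort = cohort,
                 partition_path = partition_path, coherence = coherence,
                 nmf = nmf, analysis = analysis, seed = as.integer(seed)),
            class = "pipeline_config")
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort pipeline
#'
#' Stages: simulate the cohort; build the cohort matrix (wavelet-coherence
#' networks when region series are rendered, otherwise the edge-level fast
#' path), including motion regression and concatenation; factorize;
#' map subgraphs onto the system partition; analyze expression dynamics
#' (energy-entropy relation with its shuffle null, group comparisons of the
#' effect subgraph, motion checks). Every stage writes TSV/JSON outputs
#' under `cfg$out_dir` and a manifest entry with md5 hashes, so a rerun
#' with the same config and seed reproduces all numeric outputs
#' bit-for-bit.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest (also written to `manifest.json`): per-stage output
#'   paths, hashes, and headline results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$partition_path) && !file.exists(cfg$partition_path)) {
    stop("partition file not found: ", cfg$partition_path)
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, outputs, extra = list()) {
    files <- unlist(outputs, use.names = FALSE)
    manifest$stages[[name]] <<- c(list(
      outputs = files,
      md5 = unname(md5sum(files)),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 3)), extra)
  }

  # -- simulate ---------------------------------------------------------
  cohort <- do.call(simulate_cohort, c(cfg$cohort, list(seed = cfg$seed)))
  if (!is.null(cfg$partition_path)) {
    cohort$partition <- read_partition(cfg$partition_path)
  }
  cdir <- file.path(cfg$out_dir, "01_cohort")
  write_cohort(cohort, cdir)
  stage("simulate", file.path(cdir, c("partition.tsv", "metadata.tsv")))

  # -- build networks ---------------------------------------------------
  if (!is.null(cohort$series)) {
    edges <- lapply(cohort$series, function(s) {
      unfold_layers(normalize_layers(build_multilayer(s, cfg$coherence)))
    })
  } else {
    edges <- cohort$edges
  }
  edges <- regress_motion(edges, cohort$motion)
  X <- concatenate_cohort(edges, names(cohort$edges))
  ndir <- file.path(cfg$out_dir, "02_networks")
  dir.create(ndir, showWarnings = FALSE)
  xfile <- write_tsv(as.data.frame(X$values), file.path(ndir, "X.tsv"))
  cmfile <- write_tsv(X$column_map, file.path(ndir, "column_map.tsv"))
  stage("build_networks", c(xfile, cmfile),
        list(dims = dim(X$values)))

  # -- decompose --------------------------------------------------------
  fit <- nmf_fit(X, k = cfg$nmf$k, beta = cfg$nmf$beta, eta = cfg$nmf$eta,
                 tol = cfg$nmf$tol, max_iter = cfg$nmf$max_iter)
  fdir <- file.path(cfg$out_dir, "03_nmf")
  dir.create(fdir, showWarnings = FALSE)
  wfile <- write_tsv(as.data.frame(fit$W), file.path(fdir, "W.tsv"))
  hfile <- write_tsv(as.data.frame(fit$H), file.path(fdir, "H.tsv"))
  tfile <- write_tsv(data.frame(sweep = seq_along(fit$objective_trace),
                                objective = fit$objective_trace),
                     file.path(fdir, "objective_trace.tsv"))
  stage("decompose", c(wfile, hfile, tfile),
        list(converged = fit$converged,
             final_objective = tail(fit$objective_trace, 1)))

  # -- map systems ------------------------------------------------------
  sdir <- file.path(cfg$out_dir, "04_systems")
  dir.create(sdir, showWarnings = FALSE)
  set.seed(cfg$seed + 10L)
  sys_files <- character(0)
  sig_rows <- list()
  skew <- numeric(cfg$nmf$k)
  for (g in seq_len(cfg$nmf$k)) {
    V <- fold_subgraph(fit$W[, g], cohort$partition$node_ids)
    M <- system_matrix(V, cohort$partition)
    f <- write_tsv(as.data.frame(unclass(M)),
                   file.path(sdir, sprintf("system_matrix_%02d.tsv", g)))
    sys_files <- c(sys_files, f)
    skew[g] <- if (length(cohort$partition$systems) >= 3)
      locality_skewness(M) else NA_real_
    sig <- significant_systems(V, cohort$partition,
                               n_perm = cfg$analysis$n_perm,
                               alpha = cfg$analysis$alpha)
    sig$subgraph <- g
    sig_rows[[g]] <- sig
  }
  sigfile <- write_tsv(do.call(rbind, sig_rows),
                       file.path(sdir, "significance.tsv"))
  skfile <- write_tsv(data.frame(subgraph = seq_len(cfg$nmf$k),
                                 locality_skewness = skew),
                      file.path(sdir, "skewness.tsv"))
  stage("map_systems", c(sys_files, sigfile, skfile))

  # -- analyze ----------------------------------------------------------
  adir <- file.path(cfg$out_dir, "05_dynamics")
  dir.create(adir, showWarnings = FALSE)
  summ <- dynamics_summary(fit$H, X$column_map,
                           groups = setNames(as.character(cohort$group_labels),
                                             names(cohort$edges)),
                           motion = cohort$motion,
                           n_bins = cfg$analysis$n_bins)
  sfile <- write_tsv(summ, file.path(adir, "dynamics.tsv"))
  results <- list()
  if (cfg$nmf$k >= 3) {
    results$energy_entropy <- tryCatch({
      rel <- energy_entropy_relation(summ)
      shuf <- shuffle_null_correlation(fit$H, X$column_map,
                                       n_perm = cfg$analysis$n_perm,
                                       seed = cfg$seed + 20L,
                                       n_bins = cfg$analysis$n_bins)
      list(r = rel$r, p_parametric = rel$p, p_shuffle = shuf$p)
    }, error = function(e) list(degenerate = conditionMessage(e)))
  }
  mt <- match_subgraphs(fit$W, cohort$ground_truth$basis_true)
  eff <- mt$fitted[mt$reference == cohort$ground_truth$effect_subgraph]
  eff_rows <- summ[summ$subgraph == eff, ]
  degenerate_test <- list(z = NA_real_, p = NA_real_)
  ge <- tryCatch(suppressWarnings(
    group_compare(eff_rows$standardized_energy,
                  factor(eff_rows$group, levels = c("child", "adult")))),
    error = function(e) degenerate_test)
  gh <- tryCatch(suppressWarnings(
    group_compare(eff_rows$standardized_entropy,
                  factor(eff_rows$group, levels = c("child", "adult")))),
    error = function(e) degenerate_test)
  results$effect_subgraph <- eff
  results$group_energy <- list(z = ge$z, p = ge$p)
  results$group_entropy <- list(z = gh$z, p = gh$p)
  mc <- tryCatch(motion_check(summ, subgraph = eff), error = function(e)
    data.frame(metric = character(0), r = numeric(0), p = numeric(0)))
  gfile <- write_tsv(data.frame(metric = c("standardized_energy",
                                           "standardized_entropy"),
                                z = c(ge$z, gh$z), p = c(ge$p, gh$p)),
                     file.path(adir, "group_tests.tsv"))
  mfile <- write_tsv(mc, file.path(adir, "motion_checks.tsv"))
  rjson <- file.path(adir, "results.json")
  jsonlite::write_json(results, rjson, auto_unbox = TRUE, digits = NA)
  stage("analyze", c(sfile, gfile, mfile, rjson), list(results = results))

  manifest$config <- list(cohort = cfg$cohort, nmf = cfg$nmf,
                          analysis = cfg$analysis)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}

#' Render summary figures and tables for a completed run
#'
#' Reads the stage TSVs under `out_dir` and writes a `report/`
#' subdirectory: per-subgraph system-matrix heat maps, the energy-entropy
#' scatter (one point per subgraph), group box summaries of the effect
#' subgraph, and a `summary.tsv` whose values are copied unmodified from
#' the stage outputs. Degenerate (zero-variance) metrics are flagged in
#' `notes.txt` instead of crashing.
#'
#' @param out_dir directory of a completed [run_pipeline()] run.
#' @return path of the report directory, invisibly.
#' @export
make_report <- function(out_dir) {
  man_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest found under ", out_dir)
  rdir <- file.path(out_dir, "report")
  dir.create(rdir, showWarnings = FALSE)
  notes <- character(0)

  sys_files <- sort(list.files(file.path(out_dir, "04_systems"),
                               pattern = "^system_matrix_", full.names = TRUE))
  for (f in sys_files) {
    M <- as.matrix(read.delim(f))
    png(file.path(rdir, sub("\\.tsv$", ".png", basename(f))),
        width = 480, height = 480)
    par(mar = c(5, 5, 2, 1))
    image(seq_len(nrow(M)), seq_len(ncol(M)), M, xlab = "system",
          ylab = "system", main = basename(f), axes = FALSE)
    axis(1, seq_len(nrow(M)), colnames(M), las = 2)
    axis(2, seq_len(ncol(M)), colnames(M), las = 2)
    box()
    dev.off()
  }

  dyn <- read.delim(file.path(out_dir, "05_dynamics", "dynamics.tsv"),
                    stringsAsFactors = FALSE)
  agg_e <- tapply(dyn$energy, dyn$subgraph, mean)
  agg_h <- tapply(dyn$entropy, dyn$subgraph, mean)
  if (all(agg_e > 0) && sd(agg_h) > 0 && sd(log(agg_e)) > 0) {
    png(file.path(rdir, "energy_entropy.png"), width = 480, height = 480)
    plot(log(agg_e), agg_h, pch = 19, xlab = "log mean energy",
         ylab = "mean entropy", main = "per-subgraph energy vs entropy")
    dev.off()
  } else {
    notes <- c(notes, "energy-entropy scatter skipped: degenerate metrics")
  }

  if ("group" %in% names(dyn)) {
    grp <- read.delim(file.path(out_dir, "05_dynamics", "group_tests.tsv"),
                      stringsAsFactors = FALSE)
    man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
    eff <- man$stages$analyze$results$effect_subgraph %||% 1L
    d <- dyn[dyn$subgraph == eff, ]
    if (length(unique(d$group)) == 2 && sd(d$standardized_energy) > 0) {
      png(file.path(rdir, "group_effect.png"), width = 720, height = 400)
      par(mfrow = c(1, 2))
      boxplot(standardized_energy ~ group, data = d,
              main = "standardized energy")
      boxplot(standardized_entropy ~ group, data = d,
              main = "standardized entropy")
      dev.off()
    } else {
      notes <- c(notes, "group boxplots skipped: degenerate group metrics")
    }
    write_tsv(grp, file.path(rdir, "summary.tsv"))
  }
  writeLines(if (length(notes)) notes else "ok", file.path(rdir, "notes.txt"))
  invisible(rdir)
}
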
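#' Build a pipeline run configuration
#'
#' Stage parameters default to the standard settings of the method: 50 bp
#' windows, 200 bp fragments, minimum region size 150 bp, join gap 200 bp,
#' per-level signal FDR 0.10, phase-1 q <= 0.01, phase-2 nominal p <= 0.01,
#' 12 training pairs, 1000 classifier restarts.
#'
#' @param simulate a \code{\link{simulation_config}} to generate the input
#'   cohort, or NULL to read counts/metadata from \code{counts_path} and
#'   \code{samples_path}.
#' @param counts_path,samples_path input TSV paths (used when
#'   \code{simulate} is NULL).
#' @param gene_model a \code{\link{gene_model}} (or GTF path) for the
#'   annotation stage; NULL skips annotation.
#' @param outdir output directory; NULL disables file output.
#' @param seed run seed for the split and the classifier restarts.
#' @param window_size,fragment_size,cutoff_fdr,signal_fdr,join_gap,min_region_size
#'   region-calling parameters.
#' @param alpha_q,p_max,n_train phase-1/phase-2 parameters.
#' @param n_restarts,learning_rate,max_epochs,max_rank,manual_dims
#'   classifier-stage parameters; \code{manual_dims} overrides automatic
#'   component selection.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(simulate = NULL, counts_path = NULL,
                       samples_path = NULL, gene_model = NULL,
                       outdir = NULL, seed = 1L,
                       window_size = 50, fragment_size = 200,
                       cutoff_fdr = 0.05, signal_fdr = 0.10,
                       join_gap = 200, min_region_size = 150,
                       alpha_q = 0.01, p_max = 0.01, n_train = 12,
                       n_restarts = 1000, learning_rate = 0.05,
                       max_epochs = 5000, max_rank = 10,
                       manual_dims = NULL) {
  stopifnot(window_size > 0, fragment_size > 0, cutoff_fdr > 0,
            signal_fdr > 0, join_gap >= 0, min_region_size > 0,
            alpha_q >= 0, p_max >= 0, n_train > 0, n_restarts > 0)
  if (is.null(simulate) && (is.null(counts_path) || is.null(samples_path))) {
    stop("either a simulation config or counts/samples paths are required",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "run_config")
}

#' Load a pipeline run configuration from YAML
#'
#' Top-level keys mirror the arguments of \code{\link{run_config}}; a
#' \code{simulate:} block is passed to \code{\link{simulation_config}}
#' (its \code{spikes:} list entries become \code{\link{spike_spec}}s).
#'
#' @param path YAML file.
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    sim <- y$simulate
    if (!is.null(sim$chrom_lengths)) sim$chrom_lengths <- unlist(sim$chrom_lengths)
    if (!is.null(sim$spikes)) {
      sim$spikes <- lapply(sim$spikes, function(s) do.call(spike_spec, s))
    }
    y$simulate <- do.call(simulation_config, sim)
  }
  do.call(run_config, y)
}

#' Write a run configuration as YAML
#' @param config a \code{run_config}.
#' @param path output path.
#' @export
write_run_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$simulate)) {
    sim <- unclass(y$simulate)
    sim$chrom_lengths <- as.list(sim$chrom_lengths)
    sim$spikes <- lapply(sim$spikes, unclass)
    y$simulate <- sim
  }
  if (!is.null(y$gene_model) && !is.character(y$gene_model)) {
    y$gene_model <- NULL # in-memory models are not serialized
  }
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Run the full three-phase DhMR pipeline
#'
#' Executes simulate (optional) -> normalize -> filter -> join -> phase-1
#' discovery -> phase-2 validation -> PCA + classifier -> annotation
#' (optional), writing stage outputs and a JSON run summary when
#' \code{config$outdir} is set. Empty intermediate results short-circuit
#' the remaining stages gracefully.
#'
#' @param config a \code{\link{run_config}}.
#' @return the run summary (list), invisibly when \code{outdir} is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$outdir
  if (!is.null(out)) dir.create(out, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, writer) {
    if (!is.null(out)) writer(file.path(out, name))
  }
  summary <- list(
    package_version = as.character(utils::packageVersion("twindhmr")),
    seed = config$seed,
    thresholds = config[c("window_size", "fragment_size", "cutoff_fdr",
                          "signal_fdr", "join_gap", "min_region_size",
                          "alpha_q", "p_max", "n_train", "n_restarts")],
    stages = list())
  stage <- function(name, value) {
    summary$stages[[name]] <<- value
  }

  # --- input cohort ------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- simulate_cohort(config$simulate)
    wcm <- cohort$counts
    samples <- cohort$samples
    emit("truth.tsv", function(p) write_samples_tsv(cohort$truth, p))
    stage("simulate", list(n_samples = nrow(samples),
                           n_windows = nrow(wcm$counts),
                           n_spikes = nrow(cohort$truth)))
  } else {
    wcm <- read_counts_tsv(config$counts_path)
    samples <- read_samples_tsv(config$samples_path)
    stage("input", list(n_samples = nrow(samples),
                        n_windows = nrow(wcm$counts)))
  }
  emit("samples.tsv", function(p) write_samples_tsv(samples, p))

  wcm$size_factors <- estimate_size_factors(wcm)
  samples$size_factor <-
    wcm$size_factors[match(samples$sample_id, wcm$sample_ids)]
  stage("normalize", list(size_factor_range =
                            range(wcm$size_factors)))

  split <- split_cohort(samples, n_train = config$n_train,
                        seed = config$seed)
  stage("split", list(training = split$training_pairs,
                      validation = split$validation_pairs,
                      generalization = split$generalization_pairs))

  subset_wcm <- function(x, ids) {
    keep <- x$sample_ids %in% ids
    window_counts(x$windows, x$counts[, keep, drop = FALSE],
                  sample_ids = x$sample_ids[keep],
                  size_factors = x$size_factors[keep])
  }
  train_samples <- subset_samples(samples, split$training_pairs)
  wcm_train <- subset_wcm(wcm, train_samples$sample_id)

  # --- region calling on the training cohort -----------------------------
  signal <- filter_noise_windows(wcm_train, train_samples,
                                 signal_fdr = config$signal_fdr,
                                 cutoff_fdr = config$cutoff_fdr)
  stage("filter", list(n_signal_windows = nrow(signal)))
  regions <- join_candidate_regions(signal, join_gap = config$join_gap,
                                    min_region_size = config$min_region_size)
  stage("join", list(n_candidate_regions = nrow(regions)))
  if (!is.null(out) && nrow(regions)) {
    emit("candidate_regions.bed", function(p) write_regions_bed(regions, p))
  }
  finish <- function() {
    if (!is.null(out)) {
      write_json_artifact(summary, file.path(out, "run_summary.json"))
      return(invisible(summary))
    }
    summary
  }
  if (nrow(regions) == 0L) {
    stage("short_circuit", "no candidate regions")
    return(finish())
  }

  # --- phase 1 / phase 2 -------------------------------------------------
  train_matrix <- aggregate_region_counts(wcm_train, regions)
  records <- discover_phase1(train_matrix, regions, train_samples,
                             alpha_q = config$alpha_q)
  stage("phase1", list(n_tested = nrow(records),
                       n_selected = sum(records$selected)))
  emit("phase1_records.tsv", function(p) {
    write_samples_tsv(records[, setdiff(names(records), "member_windows")], p)
  })
  if (sum(records$selected) == 0L) {
    stage("short_circuit", "no phase-1 selections")
    return(finish())
  }
  val_samples <- subset_samples(samples, split$validation_pairs)
  wcm_val <- subset_wcm(wcm, val_samples$sample_id)
  val_matrix <- aggregate_region_counts(wcm_val, regions)
  rownames(val_matrix) <- rownames(train_matrix)
  validated <- validate_phase2(records, val_matrix, val_samples,
                               p_max = config$p_max)
  confirmed <- validated[validated$confirmed, , drop = FALSE]
  stage("phase2", list(n_validated = nrow(validated),
                       n_confirmed = nrow(confirmed)))
  emit("phase2_records.tsv", function(p) {
    write_samples_tsv(validated[, setdiff(names(validated), "member_windows")], p)
  })
  if (nrow(confirmed) < 2L) {
    stage("short_circuit", "fewer than 2 confirmed DhMRs")
    return(finish())
  }

  # --- phase 3: PCA transfer + classifier --------------------------------
  mz_samples <- subset_samples(samples, c(split$training_pairs,
                                          split$validation_pairs))
  wcm_mz <- subset_wcm(wcm, mz_samples$sample_id)
  feat_mz <- build_feature_matrix(confirmed, wcm_mz, mz_samples)
  transform <- fit_pca(feat_mz)
  transform$selected_dims <- config$manual_dims %||%
    select_separating_dimensions(transform, mz_samples$role,
                                 max_rank = config$max_rank)
  emit("pca_transform.json", function(p) write_pca_transform(transform, p))
  scores_mz <- project_samples(
    transform, build_feature_matrix(confirmed, wcm_mz, mz_samples,
                                    center = transform$center,
                                    scale = transform$scale))
  stage("pca", list(selected_dims = transform$selected_dims,
                    variance_explained =
                      (transform$sdev^2 / sum(transform$sdev^2))[
                        transform$selected_dims]))

  dz_samples <- subset_samples(samples, split$generalization_pairs)
  summary_classifier <- NULL
  if (nrow(dz_samples) >= 4L) {
    wcm_dz <- subset_wcm(wcm, dz_samples$sample_id)
    feat_dz <- build_feature_matrix(confirmed, wcm_dz, dz_samples,
                                    center = transform$center,
                                    scale = transform$scale)
    scores_dz <- project_samples(transform, feat_dz)
    clf <- fit_binary_linear_classifier(
      scores_dz, dz_samples$role, n_restarts = config$n_restarts,
      seed = config$seed, learning_rate = config$learning_rate,
      max_epochs = config$max_epochs)
    decomp <- decompose_boundary_transform(clf)
    metric_list <- function(m) m[c("sensitivity", "specificity", "ppv",
                                   "npv", "auc", "tp", "fp", "tn", "fn")]
    perf <- list(
      dz = metric_list(evaluate_classifier(clf, scores_dz, dz_samples$role)),
      mz = metric_list(evaluate_classifier(clf, scores_mz, mz_samples$role)),
      combined = metric_list(evaluate_classifier(
        clf, rbind(scores_mz, scores_dz),
        c(mz_samples$role, dz_samples$role))))
    summary_classifier <- list(
      weights = list(w1 = clf$w1, w2 = clf$w2, b = clf$b),
      boundary = list(slope = clf$slope, intercept = clf$intercept),
      decomposition = decomp[c("rotation_deg_clockwise",
                               "vertical_translation")],
      performance = perf)
    emit("classifier.json", function(p) {
      write_json_artifact(summary_classifier, p)
    })
    if (!is.null(out)) {
      sc <- rbind(data.frame(cohort = "MZ", sample_id = mz_samples$sample_id,
                             role = mz_samples$role, scores_mz),
                  data.frame(cohort = "DZ", sample_id = dz_samples$sample_id,
                             role = dz_samples$role, scores_dz))
      names(sc)[4:5] <- c("score1", "score2")
      emit("scores.tsv", function(p) write_samples_tsv(sc, p))
    }
  }
  stage("classifier", summary_classifier %||% "skipped (no DZ cohort)")

  # --- annotation --------------------------------------------------------
  gm <- config$gene_model
  if (!is.null(gm)) {
    if (is.character(gm)) gm <- read_gene_model(gm)
    ann <- annotate_regions(confirmed, gm)
    asum <- summarize_annotations(ann)
    emit("annotations.tsv", function(p) write_samples_tsv(ann, p))
    emit("annotation_summary.tsv", function(p) {
      write_samples_tsv(asum$table, p)
    })
    stage("annotate", list(totals = as.list(asum$totals),
                           n_categories =
                             sum(asum$table$level == "category")))
  }
  finish()
}
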
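#' Random pair-level cohort split
#'
#' Splits the monozygotic pairs into a training and a validation cohort
#' (pairs are never separated); all dizygotic pairs form the generalization
#' cohort. Deterministic given the seed.
#'
#' @param samples cohort metadata with \code{pair_id} and \code{zygosity}.
#' @param n_train number of MZ training pairs (default 12).
#' @param seed RNG seed for the split.
#' @return list of class \code{cohort_split}: \code{training_pairs},
#'   \code{validation_pairs}, \code{generalization_pairs}, \code{seed}.
#' @export
split_cohort <- function(samples, n_train = 12, seed = 1L) {
  mz <- unique(samples$pair_id[samples$zygosity == "MZ"])
  dz <- unique(samples$pair_id[samples$zygosity == "DZ"])
  if (length(mz) < n_train + 1) {
    stop("need at least ", n_train + 1, " MZ pairs (", n_train,
         " training + >= 1 validation); have ", length(mz), call. = FALSE)
  }
  training <- with_seed(seed, sort(sample(mz, n_train)))
  structure(list(training_pairs = training,
                 validation_pairs = setdiff(mz, training),
                 generalization_pairs = dz,
                 seed = as.integer(seed)),
            class = "cohort_split")
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("cohort_split:", length(x$training_pairs), "training,",
      length(x$validation_pairs), "validation,",
      length(x$generalization_pairs), "generalization pairs (seed",
      x$seed, ")\n")
  invisible(x)
}

# Subset metadata rows (and keep ordering) for a set of pair ids.
subset_samples <- function(samples, pair_ids) {
  samples[samples$pair_id %in% pair_ids, , drop = FALSE]
}

#' Phase-2 validation of discovered DhMRs
#'
#' Re-tests each phase-1-selected region on the held-out validation cohort
#' and keeps records whose nominal p-value is at most \code{p_max} and
#' whose fitted validation group effect has the same sign as the training
#' pattern. The default validation test is the pair-matched group model
#' (model 1): with a validation cohort of seven pairs the fully adjusted
#' model leaves a single residual degree of freedom and has essentially no
#' power, while covariate robustness is already enforced by the phase-1
#' all-model selection. The fully adjusted test remains available via
#' \code{model = 3}.
#'
#' @param records phase-1 records from \code{\link{discover_phase1}}.
#' @param region_matrix validation-cohort regions x samples counts (row
#'   names matching \code{records} row names).
#' @param samples validation-cohort metadata.
#' @param p_max nominal p-value threshold (keep p <= p_max; default 0.01).
#' @param model covariate model for the validation test (default 1).
#' @return the selected records with added \code{p_val}, \code{log2fc_val},
#'   and \code{confirmed} columns.
#' @export
validate_phase2 <- function(records, region_matrix, samples, p_max = 0.01,
                            model = 1) {
  sel <- records[records$selected, , drop = FALSE]
  if (nrow(sel) == 0L) {
    sel$p_val <- numeric(0); sel$log2fc_val <- numeric(0)
    sel$confirmed <- logical(0)
    return(sel)
  }
  ids <- rownames(sel)
  missing <- setdiff(ids, rownames(region_matrix))
  if (length(missing)) {
    warning(length(missing), " region(s) absent from the validation matrix; ",
            "excluded")
    sel <- sel[!ids %in% missing, , drop = FALSE]
    ids <- rownames(sel)
  }
  spec <- model_spec(model)
  alpha <- estimate_dispersions(region_matrix[ids, , drop = FALSE], samples)
  p_val <- lfc_val <- numeric(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    res <- anodev_group_test(region_matrix[ids[i], ], samples, spec,
                             dispersion = alpha[i])
    p_val[i] <- res$p_value
    lfc_val[i] <- res$log2fc_model
  }
  train_sign <- ifelse(sel$pattern == "hyper", 1, -1)
  sel$p_val <- p_val
  sel$log2fc_val <- lfc_val
  sel$confirmed <- p_val <= p_max & sign(lfc_val) == train_sign
  sel
}
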
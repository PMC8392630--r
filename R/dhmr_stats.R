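#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment: sort p ascending, q_(i) = min_{j>=i} p_(j) * m / j,
#' capped at 1 and mapped back to input order (delegated to
#' \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values, same order as input.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Covariate model specification
#'
#' Model 1 adjusts for nothing beyond the matched-pair factor; model 2 adds
#' the five leukocyte fractions (granulocytes omitted to avoid collinearity
#' with the unit-sum constraint); model 3 adds age.
#'
#' @param model_id 1, 2 or 3.
#' @param include_pair_factor include a fixed effect per twin pair
#'   (default TRUE, respecting the matched design).
#' @return list with \code{model_id}, \code{covariates},
#'   \code{include_pair_factor}.
#' @export
model_spec <- function(model_id, include_pair_factor = TRUE) {
  leuk <- c("cd8t", "cd4t", "nk", "bcell", "mono")
  covs <- switch(as.character(model_id),
                 "1" = character(0),
                 "2" = leuk,
                 "3" = c(leuk, "age"),
                 stop("model_id must be 1, 2 or 3", call. = FALSE))
  list(model_id = as.integer(model_id), covariates = covs,
       include_pair_factor = isTRUE(include_pair_factor))
}

#' Fit a negative-binomial GLM with fixed dispersion
#'
#' Log link, IRLS fitting, dispersion alpha held fixed (variance
#' mu + alpha mu^2); alpha = 0 degenerates to the Poisson family.
#'
#' @param y non-negative integer response.
#' @param design model matrix including the intercept.
#' @param offsets per-observation log offsets (e.g. log size factors).
#' @param dispersion NB dispersion alpha >= 0.
#' @return list with \code{coefficients}, \code{loglik}, \code{deviance},
#'   \code{fitted}, \code{converged}.
#' @export
fit_nb_glm <- function(y, design, offsets = NULL, dispersion = 0) {
  design <- as.matrix(design)
  if (any(y < 0)) stop("counts must be non-negative", call. = FALSE)
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    stop("design is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fam <- if (dispersion <= 1e-12) {
    poisson(link = "log")
  } else {
    MASS::negative.binomial(theta = 1 / dispersion, link = "log")
  }
  fit <- suppressWarnings(glm.fit(
    x = design, y = y, offset = offsets, family = fam,
    control = list(epsilon = 1e-10, maxit = 100)))
  mu <- fit$fitted.values
  ll <- if (dispersion <= 1e-12) {
    sum(stats::dpois(y, lambda = mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / dispersion, mu = mu, log = TRUE))
  }
  list(coefficients = fit$coefficients, loglik = ll,
       deviance = fit$deviance, fitted = mu,
       converged = isTRUE(fit$converged))
}

#' Moment-matching NB dispersion
#'
#' Fits a Poisson GLM on the supplied design and chooses alpha so that the
#' Pearson second-moment statistic matches its residual degrees of freedom:
#' sum[(y - mu)^2 / (mu + alpha mu^2)] = n - p - 1, with one degree of
#' freedom reserved for the dispersion parameter itself (without that
#' reservation the estimate is biased low at the small per-region sample
#' sizes of a twin cohort, which inflates the deviance test). The result is
#' floored at 1e-8 and shared between the full and reduced fits of a
#' region, so the deviance difference isolates the tested term.
#'
#' @param y non-negative integer counts (>= 4 samples).
#' @param design model matrix.
#' @param offsets log offsets.
#' @return dispersion alpha >= 1e-8.
#' @export
estimate_dispersion <- function(y, design, offsets = NULL) {
  if (length(y) < 4) stop("need at least 4 samples", call. = FALSE)
  design <- as.matrix(design)
  fit <- fit_nb_glm(y, design, offsets, dispersion = 0)
  mu <- pmax(fit$fitted, 1e-10)
  n <- length(y)
  p <- qr(design)$rank
  df <- max(n - p - 1, 1)
  pearson <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - df
  if (pearson(1e-8) <= 0) return(1e-8) # under-dispersed: Poisson floor
  if (pearson(100) > 0) return(100)
  stats::uniroot(pearson, c(1e-8, 100), tol = 1e-8)$root
}

#' Moderated per-region dispersions for a cohort
#'
#' Per-region dispersions from \code{\link{estimate_dispersion}} on the
#' pair + group design are shrunk toward the cohort median with
#' \code{prior_df} pseudo-degrees of freedom:
#' alpha* = (prior_df * median + df * alpha) / (prior_df + df). With a
#' dozen twin pairs the per-region estimate has few residual degrees of
#' freedom; borrowing strength across regions stabilizes it the way
#' common/tagwise dispersion estimation does in standard count-based
#' differential analysis. The moderated value is shared by all covariate
#' models of a region.
#'
#' @param region_matrix regions x samples count matrix.
#' @param samples cohort metadata (pair_id, role, optionally size_factor).
#' @param prior_df prior degrees of freedom for shrinkage (default 20).
#' @param include_pair_factor include the pair factor in the design.
#' @return numeric vector of moderated dispersions, one per region.
#' @export
estimate_dispersions <- function(region_matrix, samples, prior_df = 20,
                                 include_pair_factor = TRUE) {
  spec <- model_spec(1, include_pair_factor = include_pair_factor)
  dm <- .anodev_design(samples, spec)
  sf <- samples$size_factor %||% rep(1, nrow(samples))
  offsets <- log(sf)
  alpha <- apply(region_matrix, 1, function(y) {
    tryCatch(estimate_dispersion(y, dm$full, offsets),
             error = function(e) NA_real_)
  })
  common <- median(alpha, na.rm = TRUE)
  if (!is.finite(common)) common <- 1e-8
  alpha[is.na(alpha)] <- common
  df <- max(nrow(samples) - ncol(dm$full) - 1, 1)
  (prior_df * common + df * alpha) / (prior_df + df)
}

# Build the design matrices for the full (with group) and reduced models.
.anodev_design <- function(samples, spec) {
  df <- data.frame(group = as.integer(samples$role == "case"))
  rhs <- "group"
  reduced_rhs <- "1"
  if (spec$include_pair_factor) {
    df$pair <- factor(samples$pair_id)
    rhs <- c("pair", rhs)
    reduced_rhs <- "pair"
  }
  absorbed <- character(0)
  if (length(spec$covariates)) {
    miss <- setdiff(spec$covariates, names(samples))
    if (length(miss)) {
      stop("samples metadata missing covariate(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    covs <- spec$covariates
    if (spec$include_pair_factor) {
      # covariates constant within every pair are absorbed by the pair
      # factor (e.g. age of co-twins) and must leave the design
      absorbed <- covs[vapply(covs, function(cv) {
        all(tapply(samples[[cv]], samples$pair_id,
                   function(v) diff(range(v))) < 1e-10)
      }, logical(1))]
      covs <- setdiff(covs, absorbed)
    }
    for (cv in covs) df[[cv]] <- samples[[cv]]
    rhs <- c(rhs, covs)
    reduced_rhs <- paste(c(reduced_rhs, covs), collapse = " + ")
  }
  full <- stats::model.matrix(
    stats::as.formula(paste("~", paste(rhs, collapse = " + "))), df)
  reduced <- stats::model.matrix(
    stats::as.formula(paste("~", reduced_rhs)), df)
  list(full = full, reduced = reduced, absorbed = absorbed)
}

#' Analysis-of-deviance group test for one region
#'
#' Fits nested NB GLMs with and without the case/control group term (shared
#' method-of-moments dispersion, log size-factor offsets, optional pair
#' factor and covariates per \code{\link{model_spec}}) and compares their
#' deviances against chi-squared with 1 df.
#'
#' @param y region counts, one per sample, aligned with \code{samples} rows.
#' @param samples metadata (needs \code{pair_id}, \code{role}, covariates,
#'   and \code{size_factor} unless \code{size_factors} is given).
#' @param model a \code{\link{model_spec}} or a model id (1, 2, 3).
#' @param size_factors optional per-sample size factors.
#' @param dispersion optional fixed dispersion (estimated when NULL).
#' @return list: \code{p_value}; \code{log2fc} (observed, from mean
#'   normalized counts with pseudocount 0.5); \code{group_coefficient}
#'   (fitted log-scale group effect); \code{log2fc_model}
#'   (\code{group_coefficient}/log 2); \code{dispersion}; \code{flagged}
#'   (TRUE when a fit failed and p was set to 1).
#' @export
anodev_group_test <- function(y, samples, model = 1, size_factors = NULL,
                              dispersion = NULL) {
  spec <- if (is.list(model)) model else model_spec(model)
  if (length(y) != nrow(samples)) {
    stop("y must align with samples rows", call. = FALSE)
  }
  if (!all(c("case", "control") %in% samples$role)) {
    stop("both case and control samples are required", call. = FALSE)
  }
  sf <- size_factors %||% samples$size_factor %||% rep(1, length(y))
  offsets <- log(sf)
  dm <- .anodev_design(samples, spec)
  r <- y / sf
  m1 <- mean(r[samples$role == "case"])
  m0 <- mean(r[samples$role == "control"])
  log2fc_obs <- log2((m1 + 0.5) / (m0 + 0.5))
  res <- tryCatch({
    alpha <- dispersion %||% estimate_dispersion(y, dm$full, offsets)
    full <- fit_nb_glm(y, dm$full, offsets, alpha)
    reduced <- fit_nb_glm(y, dm$reduced, offsets, alpha)
    if (!full$converged || !reduced$converged) {
      stop("fit did not converge")
    }
    dstat <- max(0, reduced$deviance - full$deviance)
    coef_g <- unname(full$coefficients["group"])
    list(p_value = pchisq(dstat, df = 1, lower.tail = FALSE),
         log2fc = log2fc_obs, group_coefficient = coef_g,
         log2fc_model = coef_g / log(2), dispersion = alpha,
         deviance_stat = dstat, flagged = FALSE)
  }, error = function(e) {
    warning("region marked untestable: ", conditionMessage(e), call. = FALSE)
    list(p_value = 1, log2fc = log2fc_obs, group_coefficient = 0,
         log2fc_model = 0, dispersion = NA_real_, deviance_stat = 0,
         flagged = TRUE)
  })
  res
}

#' Phase-1 DhMR discovery across three covariate models
#'
#' Runs the analysis-of-deviance group test for every region under models
#' 1, 2 and 3 (with moderated per-region dispersions from
#' \code{\link{estimate_dispersions}}, shared across the three models of a
#' region), applies Benjamini-Hochberg within each model across regions,
#' and selects regions with q <= \code{alpha_q} in all three models whose
#' fitted group effects agree in sign. The sign sets the region's pattern
#' (hyper = higher in cases).
#'
#' @param region_matrix regions x samples count matrix (row names are
#'   region ids).
#' @param regions data.frame of region coordinates (same row order).
#' @param samples training-cohort metadata with covariates and size factors.
#' @param alpha_q per-model q-value threshold (default 0.01).
#' @param include_pair_factor passed to \code{\link{model_spec}}.
#' @return data.frame of DhMR records: coordinates, pattern, observed
#'   log2fc, per-model log2fc/p/q, \code{selected} flag; carries
#'   \code{member_windows} when present in \code{regions}.
#' @export
discover_phase1 <- function(region_matrix, regions, samples,
                            alpha_q = 0.01, include_pair_factor = TRUE) {
  n_reg <- nrow(region_matrix)
  stopifnot(n_reg == nrow(regions))
  if (n_reg == 0L) {
    out <- regions[0, c("chrom", "start", "end"), drop = FALSE]
    out$pattern <- character(0)
    out$selected <- logical(0)
    return(out)
  }
  specs <- lapply(1:3, model_spec, include_pair_factor = include_pair_factor)
  # fail fast on missing covariates
  .anodev_design(samples, specs[[3]])
  alpha <- estimate_dispersions(region_matrix, samples,
                                include_pair_factor = include_pair_factor)
  p <- lfc <- matrix(NA_real_, nrow = n_reg, ncol = 3)
  obs_lfc <- numeric(n_reg)
  for (i in seq_len(n_reg)) {
    for (m in 1:3) {
      res <- anodev_group_test(region_matrix[i, ], samples, specs[[m]],
                               dispersion = alpha[i])
      p[i, m] <- res$p_value
      lfc[i, m] <- res$log2fc_model
      if (m == 1) obs_lfc[i] <- res$log2fc
    }
  }
  q <- apply(p, 2, benjamini_hochberg)
  q <- matrix(q, nrow = n_reg)
  sgn <- sign(lfc)
  consistent <- sgn[, 1] != 0 & sgn[, 1] == sgn[, 2] & sgn[, 2] == sgn[, 3]
  selected <- consistent & rowSums(q <= alpha_q) == 3
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end,
                    pattern = ifelse(sgn[, 1] > 0, "hyper", "hypo"),
                    log2fc = obs_lfc,
                    lfc_m1 = lfc[, 1], lfc_m2 = lfc[, 2], lfc_m3 = lfc[, 3],
                    p_m1 = p[, 1], p_m2 = p[, 2], p_m3 = p[, 3],
                    q_m1 = q[, 1], q_m2 = q[, 2], q_m3 = q[, 3],
                    selected = selected, stringsAsFactors = FALSE)
  if ("member_windows" %in% names(regions)) {
    out$member_windows <- regions$member_windows
  }
  rownames(out) <- rownames(region_matrix)
  out
}
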
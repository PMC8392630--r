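#' Normalized, standardized region features for PCA
#'
#' Per region, feature = z-score of log2(normalized count + 1). When
#' \code{center}/\code{scale} are NULL they are computed from this (fitting)
#' cohort and attached as attributes; for projection cohorts the fitting
#' cohort's values must be passed so the transform is portable.
#'
#' @param records confirmed DhMR records carrying \code{member_windows}.
#' @param x \code{\link{window_counts}} for the cohort (size factors
#'   estimated if absent).
#' @param samples cohort metadata (defines sample order: \code{x} columns).
#' @param center,scale optional named per-region vectors from the fitting
#'   cohort.
#' @return samples x regions numeric matrix with attributes \code{center},
#'   \code{scale}.
#' @export
build_feature_matrix <- function(records, x, samples = NULL,
                                 center = NULL, scale = NULL) {
  rc <- aggregate_region_counts(x, records)
  sf <- x$size_factors %||% estimate_size_factors(x)
  feat <- t(log2(sweep(rc, 2, sf, "/") + 1)) # samples x regions
  if (is.null(center)) {
    center <- colMeans(feat)
    scale <- apply(feat, 2, sd)
    zero <- scale <= 1e-12
    if (any(zero)) {
      warning(sum(zero), " region(s) with zero variance dropped from features")
      feat <- feat[, !zero, drop = FALSE]
      center <- center[!zero]; scale <- scale[!zero]
    }
  } else {
    missing <- setdiff(names(center), colnames(feat))
    if (length(missing)) {
      stop("regions missing from projection cohort: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    feat <- feat[, names(center), drop = FALSE]
  }
  z <- sweep(sweep(feat, 2, center, "-"), 2, scale, "/")
  attr(z, "center") <- center
  attr(z, "scale") <- scale
  z
}

#' Fit a portable PCA transform
#'
#' Principal components of the sample covariance (divisor n - 1) of the
#' feature matrix. Sign convention: each loading column's
#' largest-magnitude entry is positive. The returned transform freezes the
#' feature centering/scaling (taken from the matrix attributes when
#' present) and the loadings, so held-out cohorts can be projected without
#' refitting.
#'
#' @param features samples x regions matrix (see
#'   \code{\link{build_feature_matrix}}).
#' @return list of class \code{pca_transform}: \code{region_ids},
#'   \code{center}, \code{scale}, \code{pca_center}, \code{loadings},
#'   \code{sdev}, \code{scores}, \code{selected_dims} (NULL until chosen).
#' @export
fit_pca <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3) stop("need at least 3 samples", call. = FALSE)
  if (ncol(features) < 2) stop("need at least 2 regions", call. = FALSE)
  pr <- prcomp(features, center = TRUE, scale. = FALSE)
  if (all(pr$sdev < 1e-12)) stop("degenerate feature matrix (rank 0)", call. = FALSE)
  # deterministic sign: largest-|loading| entry of each column positive
  flip <- apply(pr$rotation, 2, function(col) {
    sign(col[which.max(abs(col))])
  })
  flip[flip == 0] <- 1
  loadings <- sweep(pr$rotation, 2, flip, "*")
  scores <- sweep(pr$x, 2, flip, "*")
  structure(list(
    region_ids = colnames(features),
    center = attr(features, "center") %||%
      setNames(rep(0, ncol(features)), colnames(features)),
    scale = attr(features, "scale") %||%
      setNames(rep(1, ncol(features)), colnames(features)),
    pca_center = pr$center,
    loadings = loadings, sdev = pr$sdev, scores = scores,
    selected_dims = NULL), class = "pca_transform")
}

#' Select the components that best separate cases from controls
#'
#' Deterministic surrogate for visual component selection: among the first
#' \code{max_rank} components, each is scored by the absolute standardized
#' mean difference of its fitting-cohort scores between cases and controls;
#' the top \code{n_dims} are returned (ordered by score, ties broken by the
#' lower component index). A manual override simply assigns
#' \code{transform$selected_dims} directly.
#'
#' @param transform a \code{\link{fit_pca}} result.
#' @param labels logical (TRUE = case) or character \code{"case"}/
#'   \code{"control"}, aligned with the fitting cohort rows.
#' @param n_dims number of components to select (default 2).
#' @param max_rank how many leading components to consider (default 10).
#' @return integer vector of component indices, best first.
#' @export
select_separating_dimensions <- function(transform, labels, n_dims = 2,
                                         max_rank = 10) {
  is_case <- if (is.logical(labels)) labels else labels == "case"
  if (!any(is_case) || all(is_case)) {
    stop("both cases and controls are required", call. = FALSE)
  }
  k <- min(max_rank, ncol(transform$scores))
  if (n_dims > k) {
    stop("n_dims exceeds the ", k, " available components", call. = FALSE)
  }
  smd <- vapply(seq_len(k), function(j) {
    s <- transform$scores[, j]
    n1 <- sum(is_case); n0 <- sum(!is_case)
    pooled <- sqrt(((n1 - 1) * var(s[is_case]) +
                    (n0 - 1) * var(s[!is_case])) / (n1 + n0 - 2))
    if (pooled <= 1e-12) return(0)
    abs(mean(s[is_case]) - mean(s[!is_case])) / pooled
  }, numeric(1))
  ord <- order(-smd, seq_len(k)) # ties -> lower index first
  ord[seq_len(n_dims)]
}

#' Project samples onto the selected components
#'
#' Applies the frozen transform (feature center/scale already applied by
#' \code{\link{build_feature_matrix}}, then PCA centering and loadings) to
#' any cohort; nothing is refit.
#'
#' @param transform a \code{pca_transform} with \code{selected_dims} set.
#' @param features matrix built with the transform's center/scale.
#' @return samples x 2 score matrix (columns named after the components).
#' @export
project_samples <- function(transform, features) {
  dims <- transform$selected_dims
  if (is.null(dims)) stop("transform has no selected_dims", call. = FALSE)
  missing <- setdiff(transform$region_ids, colnames(features))
  if (length(missing)) {
    stop("features missing region(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  f <- features[, transform$region_ids, drop = FALSE]
  s <- sweep(f, 2, transform$pca_center, "-") %*%
    transform$loadings[, dims, drop = FALSE]
  colnames(s) <- paste0("PC", dims)
  s
}

# Mann-Whitney AUC of continuous scores u for binary labels (ties = 1/2).
.rank_auc <- function(u, is_case) {
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(u)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit a single-node tanh linear classifier with restart selection
#'
#' One unit, output tanh(w1 s1 + w2 s2 + b), targets +/-1, full-batch
#' gradient descent on squared error with a fixed learning rate. All
#' restarts are initialized U(-1, 1) from the run seed and trained in
#' parallel (vectorized); the returned classifier maximizes
#' (sensitivity, AUC, specificity) lexicographically on the fitting cohort.
#' The decision boundary w1 s1 + w2 s2 + b = 0 is also reported as slope
#' m = -w1/w2 and intercept c = -b/w2 in the score plane.
#'
#' @param scores samples x 2 matrix of component scores.
#' @param labels logical (TRUE = case) or \code{"case"}/\code{"control"}.
#' @param n_restarts number of random restarts (default 1000).
#' @param seed RNG seed controlling every restart.
#' @param learning_rate gradient-descent step size (default 0.05).
#' @param max_epochs maximum full-batch epochs per restart (default 5000).
#' @return list of class \code{linear_classifier}: \code{w1}, \code{w2},
#'   \code{b}, \code{slope}, \code{intercept}, fitting-cohort
#'   \code{metrics}, and training metadata.
#' @export
fit_binary_linear_classifier <- function(scores, labels, n_restarts = 1000,
                                         seed = 1L, learning_rate = 0.05,
                                         max_epochs = 5000) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2)
  is_case <- if (is.logical(labels)) labels else labels == "case"
  if (!any(is_case) || all(is_case)) {
    stop("both classes must be present", call. = FALSE)
  }
  n <- nrow(scores)
  X <- cbind(scores, 1)
  Y <- matrix(ifelse(is_case, 1, -1), nrow = n, ncol = n_restarts)
  W <- with_seed(seed, matrix(runif(n_restarts * 3, -1, 1), ncol = 3))
  A <- NULL
  for (epoch in seq_len(max_epochs)) {
    A <- tanh(X %*% t(W))
    G <- crossprod(X, (A - Y) * (1 - A^2)) * (2 / n) # 3 x restarts
    W <- W - learning_rate * t(G)
    if (epoch %% 100 == 0 && max(abs(G)) < 1e-10) break
  }
  A <- tanh(X %*% t(W))
  pred_case <- A > 0
  n1 <- sum(is_case); n0 <- n - n1
  sens <- colSums(pred_case[is_case, , drop = FALSE]) / n1
  spec <- colSums(!pred_case[!is_case, , drop = FALSE]) / n0
  auc <- apply(A, 2, .rank_auc, is_case = is_case)
  best <- order(-sens, -auc, -spec, seq_len(n_restarts))[1]
  w <- unname(W[best, ])
  u <- A[, best]
  metrics <- evaluate_classifier(list(w1 = w[1], w2 = w[2], b = w[3]),
                                 scores, is_case)
  structure(list(
    w1 = w[1], w2 = w[2], b = w[3],
    slope = if (abs(w[2]) > 1e-12) -w[1] / w[2] else Inf,
    intercept = if (abs(w[2]) > 1e-12) -w[3] / w[2] else NA_real_,
    metrics = metrics,
    training = list(seed = as.integer(seed), n_restarts = n_restarts,
                    learning_rate = learning_rate, max_epochs = max_epochs,
                    selected_restart = best,
                    selection = c(sensitivity = sens[best], auc = auc[best],
                                  specificity = spec[best]))),
    class = "linear_classifier")
}

#' @export
print.linear_classifier <- function(x, ...) {
  cat(sprintf("linear_classifier: tanh(%.4f*s1 + %.4f*s2 + %.4f)\n",
              x$w1, x$w2, x$b))
  cat(sprintf("  boundary: s2 = %.4f + %.4f*s1\n", x$intercept, x$slope))
  m <- x$metrics
  cat(sprintf("  fit metrics: sens %.3f, spec %.3f, AUC %.3f\n",
              m$sensitivity, m$specificity, m$auc))
  invisible(x)
}

#' Evaluate a linear classifier on a cohort
#'
#' Confusion counts at the tanh-output sign threshold (output > 0 predicts
#' case) and rank-based (Mann-Whitney) AUC on the continuous unit output
#' with ties contributing 1/2.
#'
#' @param classifier a \code{linear_classifier} (or any list with
#'   \code{w1}, \code{w2}, \code{b}).
#' @param scores samples x 2 score matrix.
#' @param labels logical (TRUE = case) or \code{"case"}/\code{"control"}.
#' @return list of class \code{classifier_metrics}: sensitivity,
#'   specificity, ppv, npv, auc, and confusion counts tp/fp/tn/fn.
#' @export
evaluate_classifier <- function(classifier, scores, labels) {
  scores <- as.matrix(scores)
  is_case <- if (is.logical(labels)) labels else labels == "case"
  u <- tanh(scores[, 1] * classifier$w1 + scores[, 2] * classifier$w2 +
            classifier$b)
  pred <- u > 0
  tp <- sum(pred & is_case); fp <- sum(pred & !is_case)
  tn <- sum(!pred & !is_case); fn <- sum(!pred & is_case)
  auc <- .rank_auc(u, is_case)
  if (is.na(auc)) warning("single-class labels: AUC undefined")
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  structure(list(
    sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn), auc = auc,
    tp = tp, fp = fp, tn = tn, fn = fn), class = "classifier_metrics")
}

#' Decompose a decision boundary into rotation plus translation
#'
#' Expresses a boundary line s2 = c + m s1 as a clockwise rotation of the
#' reference boundary (the vertical line through the origin) about the
#' origin, followed by a vertical translation: a clockwise rotation by
#' theta = atan2(1, m) takes the vertical line to a line of slope m, and
#' the translation is c. The rotation-matrix round trip is checked
#' numerically and its residual returned.
#'
#' @param target a \code{linear_classifier} or a list with \code{slope}
#'   and \code{intercept}.
#' @return list: \code{rotation_deg_clockwise}, \code{vertical_translation},
#'   \code{residual} (round-trip slope error), \code{vertical_target}
#'   (TRUE when the target is itself vertical and the translation is along
#'   s1 instead).
#' @export
decompose_boundary_transform <- function(target) {
  m <- target$slope
  if (!is.finite(m)) {
    # vertical target: no rotation; shift along s1 by its s1-intercept
    s1_shift <- if (abs(target$w1) > 1e-12) -target$b / target$w1 else 0
    warning("target boundary is vertical; translation reported along s1")
    return(list(rotation_deg_clockwise = 0, vertical_translation = 0,
                residual = 0, vertical_target = TRUE,
                s1_translation = s1_shift))
  }
  theta <- atan2(1, m)
  # clockwise rotation of the vertical direction (0, 1) by theta
  v <- c(sin(theta), cos(theta))
  residual <- abs(v[2] / v[1] - m)
  if (residual > 1e-9) {
    warning("rotation round-trip residual ", signif(residual, 3))
  }
  list(rotation_deg_clockwise = theta * 180 / pi,
       vertical_translation = target$intercept,
       residual = residual, vertical_target = FALSE)
}
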
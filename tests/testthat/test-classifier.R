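# Small confirmed-record + cohort fixture for the feature/PCA stages.
feature_fixture <- function(n_pairs = 6, n_regions = 5, seed = 61) {
  samples <- toy_samples(n_pairs, seed = seed)
  n_win <- n_regions * 4
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_win * 2 * n_pairs, mu = 60, size = 8),
                nrow = n_win)
  })
  colnames(m) <- samples$sample_id
  wcm <- window_counts(make_windows(c(chrF = n_win * 50), 50), m)
  wcm$size_factors <- estimate_size_factors(wcm)
  records <- data.frame(chrom = "chrF",
                        start = seq(0, by = 200, length.out = n_regions),
                        end = seq(200, by = 200, length.out = n_regions),
                        pattern = "hyper")
  records$member_windows <- lapply(seq_len(n_regions),
                                   function(i) (4 * i - 3):(4 * i))
  list(records = records, wcm = wcm, samples = samples)
}

test_that("fitting-cohort features are standardized and portable", {
  fx <- feature_fixture()
  z <- build_feature_matrix(fx$records, fx$wcm, fx$samples)
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), rep(1, ncol(z)), tolerance = 1e-12)

  # doubling one sample's counts while doubling its size factor leaves its
  # features unchanged
  wcm2 <- fx$wcm
  wcm2$counts[, 1] <- wcm2$counts[, 1] * 2L
  wcm2$size_factors[1] <- wcm2$size_factors[1] * 2
  z2 <- build_feature_matrix(fx$records, wcm2, fx$samples,
                             center = attr(z, "center"),
                             scale = attr(z, "scale"))
  zref <- build_feature_matrix(fx$records, fx$wcm, fx$samples,
                               center = attr(z, "center"),
                               scale = attr(z, "scale"))
  expect_equal(z2[1, ], zref[1, ], tolerance = 1e-12)

  # projection with stored center/scale equals hand arithmetic
  rc <- aggregate_region_counts(fx$wcm, fx$records)
  hand <- (log2(rc[, 3] / fx$wcm$size_factors[3] + 1) - attr(z, "center")) /
    attr(z, "scale")
  expect_equal(unname(zref[3, ]), unname(hand), tolerance = 1e-12)
})

test_that("PCA matches closed-form and SVD oracles", {
  # two variables with sample covariance [[2,1],[1,2]]
  base <- cbind(c(1, -1, 0, 0), c(0, 0, 1, -1)) / sqrt(2) # unit columns
  L <- chol(matrix(c(2, 1, 1, 2), 2)) * sqrt(3) # divisor n-1 = 3
  x <- base %*% L # exact sample covariance [[2,1],[1,2]]
  tr <- fit_pca(x)
  expect_equal(tr$sdev^2, c(3, 1), tolerance = 1e-10)
  expect_equal(abs(tr$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  expect_equal(abs(tr$loadings[, 2]), rep(1 / sqrt(2), 2), tolerance = 1e-10)
  # sign rule: largest-magnitude entry positive
  expect_true(all(apply(tr$loadings, 2,
                        function(cl) cl[which.max(abs(cl))] > 0)))

  # random matrix: orthonormal loadings, reconstruction, SVD variances
  set.seed(62)
  y <- matrix(rnorm(12 * 6), 12, 6)
  try2 <- fit_pca(y)
  expect_equal(crossprod(try2$loadings), diag(6), tolerance = 1e-10,
               ignore_attr = TRUE)
  yc <- sweep(y, 2, colMeans(y))
  recon <- try2$scores %*% t(try2$loadings)
  expect_equal(recon, yc, tolerance = 1e-8, ignore_attr = TRUE)
  sv <- svd(yc)$d
  expect_equal(try2$sdev^2, sv^2 / (nrow(y) - 1), tolerance = 1e-8)
  expect_error(fit_pca(matrix(0, 4, 3)), "degenerate")
})

test_that("separating-dimension selection finds planted structure", {
  set.seed(63)
  labels <- rep(c("case", "control"), 20)
  # five orthogonal directions with decreasing variance; group separation
  # planted on components 1 and 4
  base <- matrix(rnorm(40 * 5), 40, 5) %*% diag(c(8, 4, 2, 1, 0.5))
  base[, 1] <- base[, 1] + ifelse(labels == "case", 8, -8)
  base[, 4] <- base[, 4] + ifelse(labels == "case", 1.5, -1.5)
  tr <- fit_pca(base)
  dims <- select_separating_dimensions(tr, labels)
  expect_setequal(dims, c(1, 4))

  # single-component separation is ranked first
  tr1 <- fit_pca(base[, 1:3])
  expect_equal(select_separating_dimensions(tr1, labels, n_dims = 1), 1L)

  # exact ties resolve to the lower component index
  tr_tie <- list(scores = cbind(c(1, 1, -1, -1), c(1, 1, -1, -1),
                                c(1, -1, 1, -1)))
  dims_tie <- select_separating_dimensions(tr_tie,
                                           c(TRUE, TRUE, FALSE, FALSE),
                                           n_dims = 2, max_rank = 3)
  expect_equal(dims_tie, c(1L, 2L))
  expect_error(select_separating_dimensions(tr_tie, rep(TRUE, 4)),
               "both cases and controls")
})

test_that("projection reuses the frozen transform verbatim", {
  fx <- feature_fixture(n_pairs = 8)
  z <- build_feature_matrix(fx$records, fx$wcm, fx$samples)
  tr <- fit_pca(z)
  tr$selected_dims <- c(1, 2)
  # projecting the fitting cohort reproduces the stored scores
  sc <- project_samples(tr, z)
  expect_equal(unname(sc), unname(tr$scores[, 1:2]), tolerance = 1e-10)
  # a sample sitting at the center maps to the origin
  at_center <- matrix(tr$pca_center, nrow = 1,
                      dimnames = list("x", names(tr$pca_center)))
  expect_equal(unname(project_samples(tr, at_center)), matrix(0, 1, 2),
               tolerance = 1e-12)
  # manual arithmetic for a held-out vector
  v <- z[2, , drop = FALSE] * 0.7
  hand <- (as.numeric(v) - tr$pca_center) %*% tr$loadings[, 1:2]
  expect_equal(unname(project_samples(tr, v)), unname(hand),
               tolerance = 1e-12)
  # region mismatch is refused
  bad <- z[, -1, drop = FALSE]
  expect_error(project_samples(tr, bad), "missing region")
})

test_that("a separable toy is classified perfectly and deterministically", {
  withr::with_seed(64, {
    s1 <- c(rnorm(15, 3, 0.5), rnorm(15, -3, 0.5))
    s2 <- rnorm(30)
  })
  scores <- cbind(s1, s2)
  labels <- rep(c("case", "control"), each = 15)
  clf <- fit_binary_linear_classifier(scores, labels, n_restarts = 50,
                                      seed = 7)
  m <- clf$metrics
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$auc, 1)
  clf2 <- fit_binary_linear_classifier(scores, labels, n_restarts = 50,
                                       seed = 7)
  expect_identical(c(clf$w1, clf$w2, clf$b), c(clf2$w1, clf2$w2, clf2$b))
  expect_error(fit_binary_linear_classifier(scores, rep("case", 30)),
               "both classes")
})

test_that("restart selection approaches a dense boundary grid search", {
  withr::with_seed(65, {
    scores <- rbind(cbind(rnorm(12, 1), rnorm(12, 0.5)),
                    cbind(rnorm(12, -1), rnorm(12, -0.5)))
  })
  labels <- rep(c("case", "control"), each = 12)
  clf <- fit_binary_linear_classifier(scores, labels, n_restarts = 400,
                                      seed = 3)
  # oracle: dense grid over boundary direction and offset. An unconstrained
  # grid is dominated by degenerate all-positive boundaries (sensitivity 1,
  # specificity 0), which squared-error training never converges to, so the
  # comparison uses (a) the best achievable ranking (AUC over directions)
  # and (b) the balanced-accuracy optimum among grid boundaries.
  is_case <- labels == "case"
  best_auc <- 0
  for (th in seq(0, 2 * pi, length.out = 361)) {
    w <- c(cos(th), sin(th))
    proj <- drop(scores %*% w)
    r <- rank(proj); n1 <- sum(is_case)
    auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * sum(!is_case))
    best_auc <- max(best_auc, auc)
  }
  expect_gte(clf$metrics$auc, best_auc - 0.05)
  # two spherical Gaussians with means +-(1, 0.5): the optimal boundary
  # direction is the mean difference; the fitted weights should align
  w_hat <- c(clf$w1, clf$w2) / sqrt(clf$w1^2 + clf$w2^2)
  w_opt <- c(1, 0.5) / sqrt(1.25)
  angle <- acos(min(1, abs(sum(w_hat * w_opt)))) * 180 / pi
  expect_lt(angle, 25)
})

test_that("classifier metrics follow the confusion and rank definitions", {
  clf <- list(w1 = 1, w2 = 0, b = 0)
  scores <- cbind(c(2, 1, -1, -2), c(0, 0, 0, 0))
  m <- evaluate_classifier(clf, scores, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(m$auc, 1); expect_equal(m$sensitivity, 1)
  expect_equal(m$ppv, 1); expect_equal(m$npv, 1)
  # all-identical scores: AUC 1/2 by the tie convention
  m2 <- evaluate_classifier(clf, cbind(rep(1, 6), 0),
                            rep(c(TRUE, FALSE), 3))
  expect_equal(m2$auc, 0.5)
  expect_warning(evaluate_classifier(clf, scores, rep(TRUE, 4)),
                 "single-class")
})

test_that("rank AUC equals trapezoidal ROC integration", {
  set.seed(66)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    u <- tanh(rnorm(n))
    if (i %% 3 == 0) u <- round(u, 1) # force ties
    is_case <- rbinom(n, 1, 0.5) == 1
    if (!any(is_case) || all(is_case)) next
    m <- evaluate_classifier(list(w1 = 1, w2 = 0, b = 0),
                             cbind(atanh(u), 0), is_case)
    expect_equal(m$auc, auc_trapezoid(u, is_case), tolerance = 1e-10)
    # AUC invariant under strictly monotone transforms of the output
    m3 <- evaluate_classifier(list(w1 = 3, w2 = 0, b = 0),
                              cbind(atanh(u), 0), is_case)
    expect_equal(m3$auc, m$auc, tolerance = 1e-12)
  }
})

test_that("boundary decomposition is a clockwise rotation plus translation", {
  d0 <- decompose_boundary_transform(list(slope = 0, intercept = 0))
  expect_equal(d0$rotation_deg_clockwise, 90)
  expect_equal(d0$vertical_translation, 0)
  d1 <- decompose_boundary_transform(list(slope = 1, intercept = 2))
  expect_equal(d1$rotation_deg_clockwise, 45)
  expect_equal(d1$vertical_translation, 2)
  # reference boundary geometry: slope 0.214, intercept 0.664
  d2 <- decompose_boundary_transform(list(slope = 0.214, intercept = 0.664))
  expect_equal(d2$rotation_deg_clockwise, 77.9205, tolerance = 1e-4)
  expect_equal(d2$vertical_translation, 0.664)
  expect_lte(d2$residual, 1e-9)
  # rotation-matrix round trip: rotating the vertical unit vector clockwise
  # by theta must land on the target direction
  th <- d2$rotation_deg_clockwise * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2) # clockwise
  v <- R %*% c(0, 1)
  expect_equal(v[2] / v[1], 0.214, tolerance = 1e-9)
  # negative slope rotates past 90 degrees
  d3 <- decompose_boundary_transform(list(slope = -1, intercept = 0))
  expect_equal(d3$rotation_deg_clockwise, 135)
  # vertical target flagged
  expect_warning(
    dv <- decompose_boundary_transform(list(slope = Inf, w1 = 2, b = -4)),
    "vertical")
  expect_true(dv$vertical_target)
  expect_equal(dv$s1_translation, 2)
})
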
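test_that("windows tile each chromosome from zero", {
  w <- make_windows(c(chrA = 120, chrB = 100), window_size = 50)
  expect_equal(nrow(w), 3 + 2)
  wa <- w[w$chrom == "chrA", ]
  expect_equal(wa$start, c(0, 50, 100))
  expect_equal(wa$end, c(50, 100, 120)) # last window truncated
  # partition: contiguous, non-overlapping
  expect_true(all(wa$start[-1] == wa$end[-nrow(wa)]))
})

test_that("a fragment counts in every window it overlaps", {
  fr <- list(s1 = data.frame(chrom = "chrA", start = 100, end = 300))
  wcm <- bin_fragments(fr, c(chrA = 500), window_size = 50)
  hit <- wcm$windows$start %in% c(100, 150, 200, 250)
  expect_equal(wcm$counts[hit, 1], rep(1L, 4))
  expect_true(all(wcm$counts[!hit, 1] == 0L))

  # empty fragment list -> all-zero matrix with ceiling(len/50) windows
  empty <- bin_fragments(list(s1 = data.frame(chrom = character(0),
                                              start = numeric(0),
                                              end = numeric(0))),
                         c(chrA = 501), window_size = 50)
  expect_equal(nrow(empty$counts), 11)
  expect_true(all(empty$counts == 0))
})

test_that("read starts extend fragment_size in the 5' to 3' direction", {
  fr <- list(s1 = data.frame(chrom = "chrA", start = c(100, 399),
                             strand = c("+", "-")))
  wcm <- bin_fragments(fr, c(chrA = 1000), window_size = 50,
                       fragment_size = 200)
  # plus read: [100, 300); minus read at 399: [200, 400)
  plus_windows <- wcm$windows$start %in% c(100, 150, 200, 250)
  minus_windows <- wcm$windows$start %in% c(200, 250, 300, 350)
  expect_true(all(wcm$counts[plus_windows, 1] >= 1))
  expect_true(all(wcm$counts[minus_windows, 1] >= 1))
  expect_equal(sum(wcm$counts[, 1]), 8)
})

test_that("binning matches a brute-force overlap count on random fragments", {
  set.seed(31)
  lens <- c(chrA = 5000, chrB = 3000)
  fr <- data.frame(chrom = sample(names(lens), 1000, replace = TRUE))
  fr$start <- floor(runif(1000, 0, lens[fr$chrom] - 200))
  fr$end <- fr$start + 200
  wcm <- bin_fragments(list(s = fr), lens, window_size = 50)
  # oracle: per fragment, count windows with >= 1 bp intersection
  w <- wcm$windows
  total <- 0L
  for (i in seq_len(nrow(fr))) {
    same <- w$chrom == fr$chrom[i]
    total <- total + sum(pmin(w$end[same], fr$end[i]) -
                           pmax(w$start[same], fr$start[i]) > 0)
  }
  expect_equal(sum(wcm$counts), total)
  expect_error(bin_fragments(list(s = data.frame(chrom = "chrX", start = 0,
                                                 end = 200)),
                             lens), "unknown chromosome")
})

test_that("median-of-ratios size factors follow the closed form", {
  w <- make_windows(c(chrA = 150), 50)
  # identical columns -> all factors 1
  m <- matrix(c(5L, 9L, 2L), nrow = 3, ncol = 3)
  colnames(m) <- paste0("s", 1:3)
  expect_equal(unname(estimate_size_factors(window_counts(w, m))), rep(1, 3))
  # hand-computed: (1,2,3) and (2,4,6) -> (1/sqrt 2, sqrt 2)
  m2 <- cbind(s1 = c(1L, 2L, 3L), s2 = c(2L, 4L, 6L))
  sf <- estimate_size_factors(window_counts(w, m2))
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  # scaling equivariance: scaling one sample by 10 scales its factor
  # relative to every other sample by 10 and leaves the others' ratios alone
  m3 <- cbind(m2, s3 = c(3L, 5L, 8L))
  sf3 <- estimate_size_factors(window_counts(w, m3))
  m3b <- m3; m3b[, 1] <- m3b[, 1] * 10L
  sf3b <- estimate_size_factors(window_counts(w, m3b))
  expect_equal((sf3b[1] / sf3b[2]) / (sf3[1] / sf3[2]), 10,
               ignore_attr = TRUE)
  expect_equal(sf3b[2] / sf3b[3], sf3[2] / sf3[3], ignore_attr = TRUE)
  # no all-positive reference window -> error
  m4 <- cbind(s1 = c(0L, 1L, 0L), s2 = c(1L, 0L, 1L))
  expect_error(estimate_size_factors(window_counts(w, m4)), "pre-filter")
})

test_that("size factors agree with the DESeq reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(77)
  m <- matrix(rnbinom(2000, mu = 30 * rep(runif(4, 0.5, 2), each = 500),
                      size = 5), ncol = 4)
  colnames(m) <- paste0("s", 1:4)
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("sample cutoffs match brute-force enumeration", {
  # lambda ~ 0.1 with 500 planted windows of count 3
  n_win <- 10000
  counts <- integer(n_win)
  counts[1:500] <- 3L
  set.seed(5)
  counts[501:n_win] <- rpois(n_win - 500, 0.05)
  w <- make_windows(c(chrA = n_win * 50), 50)
  wcm <- window_counts(w, cbind(s1 = counts))
  cut <- sample_cutoffs(wcm, cutoff_fdr = 0.05)
  # oracle: evaluate the expected/observed ratio for each c directly
  lambda <- sum(counts) / n_win
  oracle <- NA
  for (c0 in 1:10) {
    ratio <- n_win * ppois(c0 - 1, lambda, lower.tail = FALSE) /
      max(sum(counts >= c0), 1)
    if (ratio <= 0.05) { oracle <- c0; break }
  }
  expect_equal(unname(cut[1]), oracle)

  # all-zero sample: cutoff 1, can never nominate a window
  wcm2 <- window_counts(w, cbind(s1 = counts, s2 = integer(n_win)))
  expect_warning(cut2 <- sample_cutoffs(wcm2), "no counts")
  expect_equal(unname(cut2["s2"]), 1L)
  surv <- attr(cut2, "surviving")
  expect_true(all(counts[surv] >= cut2["s1"]))
  expect_equal(sort(surv), which(counts >= cut2["s1"]))
})

test_that("identical case and control columns yield no signal windows", {
  samples <- toy_samples(4)
  n_win <- 200
  set.seed(8)
  base <- matrix(rnbinom(n_win * 4, mu = 30, size = 5), nrow = n_win)
  m <- base[, rep(1:4, each = 2)] # case column == control column per pair
  colnames(m) <- samples$sample_id
  wcm <- window_counts(make_windows(c(chrA = n_win * 50), 50), m)
  sig <- filter_noise_windows(wcm, samples)
  expect_equal(nrow(sig), 0L)
})

test_that("strongly spiked windows are flagged with the hyper pattern", {
  n_pairs <- 12
  samples <- toy_samples(n_pairs)
  n_win <- 5000
  set.seed(9)
  mu <- matrix(50, n_win, 2 * n_pairs)
  spiked <- 1:10
  mu[spiked, samples$role == "case"] <- 50 * 8
  m <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.1), nrow = n_win)
  colnames(m) <- samples$sample_id
  wcm <- window_counts(make_windows(c(chrA = n_win * 50), 50), m)
  sig <- filter_noise_windows(wcm, samples, signal_fdr = 0.10)
  flagged_spiked <- sig[sig$window %in% spiked, ]
  expect_gte(nrow(flagged_spiked), 9)
  expect_true(all(flagged_spiked$pattern == "hyper"))
})

test_that("null simulations respect the signal FDR", {
  n_pairs <- 12
  samples <- toy_samples(n_pairs)
  n_win <- 5000
  set.seed(10)
  m <- matrix(rnbinom(n_win * 2 * n_pairs, mu = 50, size = 1 / 0.1),
              nrow = n_win)
  colnames(m) <- samples$sample_id
  wcm <- window_counts(make_windows(c(chrA = n_win * 50), 50), m)
  sig <- filter_noise_windows(wcm, samples, signal_fdr = 0.10)
  # false-flag fraction bounded by 2 x signal_fdr plus binomial slack
  bound <- 2 * 0.10 + 2 * sqrt(0.10 * 0.90 / n_win)
  expect_lte(nrow(sig) / n_win, bound)
})

test_that("window joining follows the gap and size rules", {
  sig <- data.frame(chrom = "chrA", start = c(0, 200), end = c(50, 250),
                    pattern = "hyper", window = c(1L, 5L))
  reg <- join_candidate_regions(sig, join_gap = 200, min_region_size = 150)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 0); expect_equal(reg$end, 250)
  expect_equal(reg$member_windows[[1]], c(1L, 5L))

  # lone 50 bp window dropped
  lone <- data.frame(chrom = "chrA", start = 0, end = 50, pattern = "hyper")
  expect_equal(nrow(join_candidate_regions(lone)), 0L)

  # different patterns never join
  mixed <- data.frame(chrom = "chrA", start = c(0, 100), end = c(50, 150),
                      pattern = c("hyper", "hypo"))
  expect_equal(nrow(join_candidate_regions(mixed)), 0L)

  # gap strictly greater than join_gap splits; short remnant is dropped
  far <- data.frame(chrom = "chrA", start = c(0, 100, 200, 451),
                    end = c(50, 150, 250, 501), pattern = "hyper")
  reg2 <- join_candidate_regions(far, join_gap = 200, min_region_size = 150)
  expect_equal(reg2$start, 0)
  expect_equal(reg2$end, 250)
})

test_that("joining matches the quadratic-time oracle on random windows", {
  set.seed(12)
  for (rep in 1:5) {
    starts <- sort(sample(seq(0, 20000, by = 50), 200))
    sig <- data.frame(chrom = sample(c("chrA", "chrB"), 200, TRUE),
                      start = starts, end = starts + 50,
                      pattern = sample(c("hyper", "hypo"), 200, TRUE))
    sig <- sig[!duplicated(sig[, c("chrom", "start")]), ]
    ours <- join_candidate_regions(sig)
    oracle <- merge_bruteforce(sig)
    expect_equal(ours[, c("chrom", "start", "end", "pattern")], oracle,
                 ignore_attr = TRUE)
    # idempotence: feeding regions back in reproduces them
    again <- join_candidate_regions(
      data.frame(chrom = ours$chrom, start = ours$start, end = ours$end,
                 pattern = ours$pattern))
    expect_equal(again[, c("chrom", "start", "end", "pattern")],
                 ours[, c("chrom", "start", "end", "pattern")])
  }
})

test_that("region counts aggregate member windows exactly", {
  samples <- toy_samples(2)
  m <- matrix(1:16, nrow = 4)
  colnames(m) <- samples$sample_id
  wcm <- window_counts(make_windows(c(chrA = 200), 50), m)
  regions <- data.frame(chrom = "chrA", start = 0, end = 100,
                        pattern = "hyper")
  regions$member_windows <- list(c(1L, 2L))
  agg <- aggregate_region_counts(wcm, regions)
  expect_equal(unname(agg[1, ]), colSums(m[1:2, ]), ignore_attr = TRUE)
  # empty regions -> empty matrix
  expect_equal(nrow(aggregate_region_counts(wcm, regions[0, ])), 0L)
  # unknown window index -> error
  bad <- regions; bad$member_windows <- list(c(1L, 99L))
  expect_error(aggregate_region_counts(wcm, bad), "unknown window")
})

test_that("overlap detection matches the all-pairs oracle", {
  # half-open semantics
  a <- data.frame(chrom = "chr1", start = 0, end = 100)
  b <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(nrow(overlap_regions(a, b)), 0L)
  b2 <- data.frame(chrom = "chr1", start = 50, end = 150)
  hit <- overlap_regions(a, b2)
  expect_equal(hit$overlap_bp, 50L)
  set.seed(13)
  ra <- data.frame(chrom = sample(c("c1", "c2"), 60, TRUE),
                   start = sample(0:5000, 60))
  ra$end <- ra$start + sample(50:500, 60, TRUE)
  rb <- data.frame(chrom = sample(c("c1", "c2"), 60, TRUE),
                   start = sample(0:5000, 60))
  rb$end <- rb$start + sample(50:500, 60, TRUE)
  ours <- overlap_regions(ra, rb)
  oracle <- overlap_bruteforce(ra, rb)
  oracle <- oracle[order(oracle$query, oracle$subject), ]
  expect_equal(ours, oracle, ignore_attr = TRUE)
})
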
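# Shared fixtures and independent brute-force oracles for the test suite.

# Minimal twin-cohort metadata with Dirichlet-ish leukocyte fractions.
toy_samples <- function(n_pairs, zygosity = "MZ", seed = 1) {
  withr::with_seed(seed, {
    pair_id <- sprintf("%s%02d", zygosity, seq_len(n_pairs))
    df <- data.frame(
      sample_id = as.vector(rbind(paste0(pair_id, "_case"),
                                  paste0(pair_id, "_ctrl"))),
      pair_id = rep(pair_id, each = 2),
      zygosity = rep(zygosity, 2 * n_pairs),
      role = rep(c("case", "control"), n_pairs),
      stringsAsFactors = FALSE)
    g <- matrix(rgamma(2 * n_pairs * 6, c(8, 15, 5, 5, 7, 60)),
                ncol = 6, byrow = TRUE)
    g <- g / rowSums(g)
    df$cd8t <- g[, 1]; df$cd4t <- g[, 2]; df$nk <- g[, 3]
    df$bcell <- g[, 4]; df$mono <- g[, 5]
    df$age <- rep(runif(n_pairs, 55, 65), each = 2)
    df$size_factor <- 1
    df
  })
}

# Region-level NB counts with optional per-region case/control log2 effects.
# Returns list(matrix = regions x samples, samples, log2fc = truth vector).
toy_region_cohort <- function(n_regions, n_pairs, baseline = 100,
                              dispersion = 0.3, pair_sd = 0.4,
                              log2fc = numeric(n_regions), seed = 1,
                              zygosity = "MZ") {
  samples <- toy_samples(n_pairs, zygosity = zygosity, seed = seed + 1000)
  withr::with_seed(seed, {
    m <- matrix(0L, nrow = n_regions, ncol = 2 * n_pairs)
    is_case <- samples$role == "case"
    for (i in seq_len(n_regions)) {
      pe <- rep(rnorm(n_pairs, sd = pair_sd), each = 2)
      eta <- log(baseline) + pe + ifelse(is_case, log2fc[i] * log(2), 0)
      m[i, ] <- if (dispersion > 0) {
        rnbinom(2 * n_pairs, size = 1 / dispersion, mu = exp(eta))
      } else {
        rpois(2 * n_pairs, exp(eta))
      }
    }
    colnames(m) <- samples$sample_id
    rownames(m) <- sprintf("chrT:%d-%d", 1000 * seq_len(n_regions),
                           1000 * seq_len(n_regions) + 300)
    list(matrix = m, samples = samples, log2fc = log2fc)
  })
}

region_df_from_matrix <- function(m) {
  ids <- rownames(m)
  parts <- regmatches(ids, regexec("^(.+):(\\d+)-(\\d+)$", ids))
  data.frame(chrom = vapply(parts, `[`, "", 2),
             start = as.numeric(vapply(parts, `[`, "", 3)),
             end = as.numeric(vapply(parts, `[`, "", 4)),
             stringsAsFactors = FALSE)
}

# --- independent oracles -------------------------------------------------

# Literal step-up definition of Benjamini-Hochberg.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  q
}

# Quadratic-time merger of same-pattern signal windows.
merge_bruteforce <- function(signal, join_gap = 200, min_region_size = 150) {
  if (nrow(signal) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), pattern = character(0)))
  }
  out <- list()
  for (ch in unique(signal$chrom)) {
    for (pat in unique(signal$pattern)) {
      sub <- signal[signal$chrom == ch & signal$pattern == pat, , drop = FALSE]
      if (nrow(sub) == 0L) next
      sub <- sub[order(sub$start), , drop = FALSE]
      grp <- integer(nrow(sub)); grp[1] <- 1L
      for (i in seq_len(nrow(sub))[-1]) {
        prev_end <- max(sub$end[grp == grp[i - 1]])
        grp[i] <- if (sub$start[i] - prev_end <= join_gap) grp[i - 1]
                  else grp[i - 1] + 1L
      }
      for (g in unique(grp)) {
        s <- min(sub$start[grp == g]); e <- max(sub$end[grp == g])
        if (e - s >= min_region_size) {
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, start = s, end = e, pattern = pat,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), pattern = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# All-pairs interval overlap (half-open).
overlap_bruteforce <- function(a, b) {
  hits <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
        if (ov > 0) {
          hits[[length(hits) + 1L]] <- data.frame(query = i, subject = j,
                                                  overlap_bp = ov)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = integer(0)))
  }
  do.call(rbind, hits)
}

# Trapezoidal area under the empirical ROC curve.
auc_trapezoid <- function(u, is_case) {
  thr <- sort(unique(u), decreasing = TRUE)
  tpr <- vapply(c(Inf, thr), function(t) mean(u[is_case] >= t), numeric(1))
  fpr <- vapply(c(Inf, thr), function(t) mean(u[!is_case] >= t), numeric(1))
  tpr <- c(tpr, 1); fpr <- c(fpr, 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Reference composition of a 102-region DhMR set by annotation category,
# subtype and nearest-gene type (84 hyper / 18 hypo; 47 intergenic, 49
# intron, 2 each exon/TSS/TTS), used as a worked example by the summary
# accounting checks.
table1_records <- function() {
  spec <- list(
    list("exon", "hyper", c(`ncRNA` = 1, `protein-coding` = 1)),
    list("intergenic", "hyper",
         c(`ncRNA` = 13, `protein-coding` = 26, `pseudo` = 3)),
    list("intergenic", "hypo", c(`ncRNA` = 1, `protein-coding` = 4)),
    list("intron", "hyper",
         c(`ncRNA` = 10, `protein-coding` = 25, `pseudo` = 1, `snoRNA` = 1)),
    list("intron", "hypo",
         c(`ncRNA` = 1, `protein-coding` = 10, `pseudo` = 1)),
    list("TSS", "hyper", c(`pseudo` = 1)),
    list("TSS", "hypo", c(`protein-coding` = 1)),
    list("TTS", "hyper", c(`protein-coding` = 2)))
  rows <- lapply(spec, function(s) {
    data.frame(category = s[[1]], pattern = s[[2]],
               gene_type = rep(names(s[[3]]), s[[3]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Toy gene model: one coding + one ncRNA transcript on chrG (+/-) strands.
#   geneA (+, protein_coding): tx [1000, 9000), exons [1000,2000) [4000,5000)
#     [8000,9000), CDS [1500, 8500)
#   geneB (-, lincRNA): tx [20000, 24000), exons [20000,21000) [23000,24000)
#   geneC (+, pseudogene): tx [40000, 41000), single exon
toy_gene_model <- function() {
  tx <- data.frame(
    tx_id = c("txA", "txB", "txC"),
    gene_id = c("geneA", "geneB", "geneC"),
    gene_type = c("protein_coding", "lincRNA", "pseudogene"),
    chrom = "chrG", strand = c("+", "-", "+"),
    start = c(1000, 20000, 40000), end = c(9000, 24000, 41000),
    cds_start = c(1500, NA, NA), cds_end = c(8500, NA, NA),
    stringsAsFactors = FALSE)
  ex <- data.frame(
    tx_id = c("txA", "txA", "txA", "txB", "txB", "txC"),
    start = c(1000, 4000, 8000, 20000, 23000, 40000),
    end = c(2000, 5000, 9000, 21000, 24000, 41000))
  gene_model(tx, ex)
}
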
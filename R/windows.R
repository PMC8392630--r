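#' Tile chromosomes into fixed-width windows
#'
#' Windows tile each chromosome from position 0 in steps of
#' \code{window_size}; the last window is truncated at the chromosome end,
#' giving \code{ceiling(length / window_size)} windows per chromosome.
#' Chromosomes are ordered by name so the tiling is sorted.
#'
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param window_size window width in bp (default 50).
#' @return data.frame of window intervals (0-based half-open).
#' @export
make_windows <- function(chrom_lengths, window_size = 50) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths)))) {
    stop("chrom_lengths must be a named vector", call. = FALSE)
  }
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (window_size <= 0) stop("window_size must be > 0", call. = FALSE)
  chroms <- sort(names(chrom_lengths))
  pieces <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(0L, len - 1L, by = window_size)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + window_size, len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Window-by-sample count matrix
#'
#' @param windows data.frame of window intervals (sorted, non-overlapping).
#' @param counts integer matrix, windows x samples.
#' @param sample_ids character vector of sample ids (columns of counts).
#' @param size_factors optional positive per-sample scaling factors.
#' @return an object of class \code{window_counts}.
#' @export
window_counts <- function(windows, counts, sample_ids = colnames(counts),
                          size_factors = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(windows)) {
    stop("counts rows must match windows", call. = FALSE)
  }
  if (is.null(sample_ids)) stop("sample_ids required", call. = FALSE)
  if (length(sample_ids) != ncol(counts)) {
    stop("sample_ids must match counts columns", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
    size_factors <- setNames(as.numeric(size_factors), sample_ids)
  }
  colnames(counts) <- sample_ids
  structure(list(windows = windows, counts = counts,
                 sample_ids = as.character(sample_ids),
                 size_factors = size_factors),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat("window_counts:", nrow(x$counts), "windows x", ncol(x$counts),
      "samples;", length(unique(x$windows$chrom)), "chromosome(s)\n")
  cat("  total fragments counted:", sum(x$counts), "\n")
  if (!is.null(x$size_factors)) {
    cat("  size factors:", paste(signif(x$size_factors, 3), collapse = " "), "\n")
  }
  invisible(x)
}

#' Bin fragments into window counts
#'
#' Each fragment increments the count of every window it overlaps by at
#' least 1 bp. Records without an \code{end} column are treated as read
#' starts and extended to \code{fragment_size} in the 5'->3' direction of
#' their strand (unstranded reads extend rightwards).
#'
#' @param fragments named list (one element per sample) of data.frames with
#'   columns \code{chrom}, \code{start} and optionally \code{end},
#'   \code{strand}. Coordinates 0-based half-open.
#' @param chrom_lengths named vector of chromosome lengths.
#' @param window_size window width in bp.
#' @param fragment_size length used to extend read starts.
#' @return a \code{\link{window_counts}} object.
#' @export
bin_fragments <- function(fragments, chrom_lengths, window_size = 50,
                          fragment_size = 200) {
  windows <- make_windows(chrom_lengths, window_size)
  wgr <- as_granges0(windows)
  counts <- matrix(0L, nrow = nrow(windows), ncol = length(fragments))
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    if (is.null(fr) || nrow(fr) == 0L) next
    bad <- setdiff(unique(fr$chrom), names(chrom_lengths))
    if (length(bad)) {
      stop("fragments on unknown chromosome(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    if (!"end" %in% names(fr)) {
      strand <- if ("strand" %in% names(fr)) fr$strand else "*"
      minus <- strand == "-"
      start <- ifelse(minus, fr$start - fragment_size + 1, fr$start)
      end <- ifelse(minus, fr$start + 1, fr$start + fragment_size)
      fr <- data.frame(chrom = fr$chrom, start = start, end = end)
    }
    # clip to chromosome bounds
    lim <- chrom_lengths[fr$chrom]
    fr$start <- pmax(fr$start, 0)
    fr$end <- pmin(fr$end, lim)
    fr <- fr[fr$end > fr$start, , drop = FALSE]
    if (nrow(fr) == 0L) next
    fgr <- as_granges0(fr)
    counts[, i] <- counts[, i] +
      GenomicRanges::countOverlaps(wgr, fgr, minoverlap = 1L,
                                   ignore.strand = TRUE)
  }
  ids <- names(fragments) %||% paste0("sample", seq_along(fragments))
  window_counts(windows, counts, sample_ids = ids)
}

#' Median-of-ratios size factors
#'
#' DESeq-style library-size normalization: reference windows are those with
#' a positive count in every sample; each sample's factor is the median of
#' its counts divided by the per-window geometric mean across samples.
#'
#' @param x a \code{window_counts} object or a count matrix.
#' @return named numeric vector of positive size factors.
#' @export
estimate_size_factors <- function(x) {
  counts <- if (inherits(x, "window_counts")) x$counts else as.matrix(x)
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    stop("no window has a positive count in every sample; ",
         "pre-filter low-coverage windows before normalization",
         call. = FALSE)
  }
  lc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(lc)
  factors <- apply(lc, 2, function(col) exp(median(col - loggeo)))
  setNames(factors, colnames(counts))
}

#' Sample-specific Poisson count cutoffs
#'
#' For sample s with genome-wide mean rate lambda_s, the cutoff is the
#' smallest integer c >= 1 at which the Poisson-expected number of windows
#' with count >= c, divided by the observed number (floored at 1), drops to
#' \code{cutoff_fdr} or below. A window survives filtering when its count
#' reaches the cutoff in at least one sample.
#'
#' @param x a \code{window_counts} object.
#' @param cutoff_fdr expected/observed ratio threshold (default 0.05).
#' @return integer vector of per-sample cutoffs, with attribute
#'   \code{surviving}: indices of windows passing in >= 1 sample.
#' @export
sample_cutoffs <- function(x, cutoff_fdr = 0.05) {
  counts <- x$counts
  n_win <- nrow(counts)
  cutoffs <- integer(ncol(counts))
  for (s in seq_len(ncol(counts))) {
    cs <- counts[, s]
    if (all(cs == 0)) {
      warning("sample ", colnames(counts)[s],
              " has no counts; cutoff set to 1")
      cutoffs[s] <- 1L
      next
    }
    lambda <- sum(cs) / n_win
    c_max <- max(stats::qpois(1 - 1e-12, lambda), max(cs)) + 2L
    tab <- tabulate(cs + 1L, nbins = max(cs) + 1L) # counts of value 0..max
    for (c0 in seq_len(c_max)) {
      expected <- n_win * ppois(c0 - 1, lambda, lower.tail = FALSE)
      observed <- if (c0 > max(cs)) 0L else sum(tab[(c0 + 1L):length(tab)])
      if (expected / max(observed, 1L) <= cutoff_fdr) {
        cutoffs[s] <- c0
        break
      }
    }
    if (cutoffs[s] == 0L) cutoffs[s] <- c_max
  }
  cutoffs <- setNames(as.integer(cutoffs), colnames(counts))
  surv <- which(rowSums(sweep(counts, 2, cutoffs, ">=")) > 0)
  attr(cutoffs, "surviving") <- surv
  cutoffs
}

# Vectorized two-group NB Wald test on normalized counts for one stratum of
# windows. Returns two-sided p-values and hyper/hypo pattern.
.window_wald <- function(r_case, r_ctrl) {
  n1 <- ncol(r_case); n0 <- ncol(r_ctrl)
  m1 <- rowMeans(r_case); m0 <- rowMeans(r_ctrl)
  ss <- rowSums((r_case - m1)^2) + rowSums((r_ctrl - m0)^2)
  s2 <- ss / (n1 + n0 - 2)
  mbar <- (n1 * m1 + n0 * m0) / (n1 + n0)
  alpha <- ifelse(mbar > 0, pmax(0, (s2 - mbar) / mbar^2), 0)
  v1 <- (m1 + alpha * m1^2) / n1
  v0 <- (m0 + alpha * m0^2) / n0
  vlog <- v1 / (m1 + 0.5)^2 + v0 / (m0 + 0.5)^2
  z <- ifelse(vlog > 0, (log(m1 + 0.5) - log(m0 + 0.5)) / sqrt(vlog), 0)
  list(p = 2 * pnorm(-abs(z)), m1 = m1, m0 = m0, mbar = mbar)
}

#' Identify signal windows by stratified per-count-level FDR
#'
#' Windows passing the sample-specific cutoffs are tested case vs control
#' (normalized counts, method-of-moments NB dispersion, Wald test on the
#' log mean difference), stratified by integer-rounded mean normalized count
#' level, and Benjamini-Hochberg adjusted within each level. Signal windows
#' are those at or above the lowest level whose minimum q-value falls below
#' \code{signal_fdr}, with their own q below \code{signal_fdr}.
#'
#' @param x a \code{window_counts} object (size factors estimated if absent).
#' @param samples sample metadata with \code{sample_id} and \code{role}
#'   (\code{"case"}/\code{"control"}); rows matched to \code{x$sample_ids}.
#' @param signal_fdr per-level FDR threshold (default 0.10).
#' @param cutoff_fdr passed to \code{\link{sample_cutoffs}}.
#' @return data.frame of signal windows: window index, coordinates, pattern
#'   (\code{"hyper"}/\code{"hypo"}), p, q, count level and mean level.
#' @export
filter_noise_windows <- function(x, samples, signal_fdr = 0.10,
                                 cutoff_fdr = 0.05) {
  idx <- match(x$sample_ids, samples$sample_id)
  if (anyNA(idx)) stop("samples metadata missing some sample ids", call. = FALSE)
  role <- samples$role[idx]
  if (sum(role == "case") < 2 || sum(role == "control") < 2) {
    stop("need at least 2 case and 2 control samples", call. = FALSE)
  }
  sf <- x$size_factors %||% estimate_size_factors(x)
  cuts <- sample_cutoffs(x, cutoff_fdr)
  surv <- attr(cuts, "surviving")
  empty <- data.frame(window = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      pattern = character(0), p = numeric(0), q = numeric(0),
                      level = integer(0), mean_level = numeric(0))
  if (length(surv) == 0L) return(empty)
  r <- sweep(x$counts[surv, , drop = FALSE], 2, sf, "/")
  w <- .window_wald(r[, role == "case", drop = FALSE],
                    r[, role == "control", drop = FALSE])
  level <- as.integer(round(w$mbar))
  q <- rep(NA_real_, length(level))
  for (lv in unique(level)) {
    sel <- level == lv
    q[sel] <- benjamini_hochberg(w$p[sel])
  }
  lv_min <- tapply(q, level, min)
  qualifying <- as.integer(names(lv_min))[lv_min < signal_fdr]
  if (length(qualifying) == 0L) return(empty)
  l_star <- min(qualifying)
  keep <- level >= l_star & q < signal_fdr & w$m1 != w$m0
  out <- data.frame(
    window = surv[keep],
    chrom = x$windows$chrom[surv[keep]],
    start = x$windows$start[surv[keep]],
    end = x$windows$end[surv[keep]],
    pattern = ifelse(w$m1[keep] > w$m0[keep], "hyper", "hypo"),
    p = w$p[keep], q = q[keep], level = level[keep],
    mean_level = w$mbar[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Join signal windows into candidate regions
#'
#' Same-chromosome, same-pattern signal windows whose gap (next start minus
#' previous end) is at most \code{join_gap} bp are merged; merged regions
#' shorter than \code{min_region_size} bp are discarded. A gap exactly equal
#' to \code{join_gap} is joined.
#'
#' @param signal data.frame from \code{\link{filter_noise_windows}} (needs
#'   \code{chrom}, \code{start}, \code{end}, \code{pattern}; optional
#'   \code{window}, \code{q}).
#' @param join_gap maximum joinable gap in bp (default 200).
#' @param min_region_size minimum region length in bp (default 150).
#' @return data.frame of candidate regions with \code{member_windows}
#'   (list of window indices) and \code{score} (-log10 min member q, when
#'   q is available), sorted by coordinate.
#' @export
join_candidate_regions <- function(signal, join_gap = 200,
                                   min_region_size = 150) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), pattern = character(0),
                      n_windows = integer(0), score = numeric(0))
  empty$member_windows <- list()
  if (is.null(signal) || nrow(signal) == 0L) return(empty)
  has_win <- "window" %in% names(signal)
  has_q <- "q" %in% names(signal)
  regions <- list()
  for (key in unique(paste(signal$chrom, signal$pattern))) {
    sub <- signal[paste(signal$chrom, signal$pattern) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    run_start <- sub$start[1]; run_end <- sub$end[1]
    rows <- list()
    flush <- function(rs, re, mem) {
      data.frame(chrom = sub$chrom[1], start = rs, end = re,
                 pattern = sub$pattern[1], n_windows = length(mem),
                 score = if (has_q) -log10(max(min(sub$q[mem]), 1e-300)) else NA_real_,
                 member_windows = I(list(
                   if (has_win) sub$window[mem] else mem)),
                 stringsAsFactors = FALSE)
    }
    mem_idx <- 1L
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - run_end <= join_gap) {
        run_end <- max(run_end, sub$end[i])
        mem_idx <- c(mem_idx, i)
      } else {
        rows[[length(rows) + 1L]] <- flush(run_start, run_end, mem_idx)
        run_start <- sub$start[i]; run_end <- sub$end[i]; mem_idx <- i
      }
    }
    rows[[length(rows) + 1L]] <- flush(run_start, run_end, mem_idx)
    regions[[length(regions) + 1L]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, regions)
  out <- out[out$end - out$start >= min_region_size, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sum window counts over candidate regions
#'
#' @param x a \code{window_counts} object the regions were built from.
#' @param regions data.frame with a \code{member_windows} list column of
#'   window indices into \code{x}.
#' @return integer matrix, regions x samples; row names \code{chrom:start-end}.
#' @export
aggregate_region_counts <- function(x, regions) {
  if (nrow(regions) == 0L) {
    return(matrix(0L, nrow = 0, ncol = ncol(x$counts),
                  dimnames = list(NULL, x$sample_ids)))
  }
  if (!"member_windows" %in% names(regions)) {
    stop("regions must carry member_windows indices", call. = FALSE)
  }
  out <- matrix(0L, nrow = nrow(regions), ncol = ncol(x$counts))
  for (i in seq_len(nrow(regions))) {
    mw <- regions$member_windows[[i]]
    if (any(mw < 1L | mw > nrow(x$counts))) {
      stop("region ", i, " references unknown window index", call. = FALSE)
    }
    out[i, ] <- colSums(x$counts[mw, , drop = FALSE])
  }
  dimnames(out) <- list(region_ids(regions), x$sample_ids)
  out
}

#' Region identifiers of the form chrom:start-end
#' @param regions data.frame with chrom/start/end.
#' @return character vector.
#' @export
region_ids <- function(regions) {
  if (nrow(regions) == 0L) return(character(0))
  paste0(regions$chrom, ":", regions$start, "-", regions$end)
}
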
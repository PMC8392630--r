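#' Specification of a spiked differential region
#'
#' @param chrom,start,end spike interval (0-based half-open).
#' @param log2fc log2 fold change in cases vs controls; positive values are
#'   hyper-hydroxymethylated in cases, negative hypo.
#' @param penetrance fraction of twin pairs carrying the effect.
#' @return a list of class \code{spike_spec}.
#' @export
spike_spec <- function(chrom, start, end, log2fc, penetrance = 1.0) {
  if (!is.finite(log2fc)) stop("log2fc must be finite", call. = FALSE)
  if (penetrance <= 0 || penetrance > 1) {
    stop("penetrance must be in (0, 1]", call. = FALSE)
  }
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 log2fc = log2fc, penetrance = penetrance),
            class = "spike_spec")
}

#' Configuration for the synthetic twin-cohort generator
#'
#' Window means follow a log-link model: log mu = log(baseline_mean) +
#' pair effect + library-size offset + spike effect (case co-twin of carrier
#' pairs only) + covariate effect; counts are negative binomial with
#' variance mu + dispersion * mu^2. Pair effects are drawn per window and
#' pair and shared by both co-twins, emulating the within-pair correlation
#' of local 5hmC levels that the matched design exploits.
#'
#' @param seed RNG seed; all output is deterministic given the config.
#' @param chrom_lengths named vector of chromosome lengths in bp. The
#'   default is a 5 Mb toy genome of two chromosomes.
#' @param n_pairs_mz,n_pairs_dz numbers of monozygotic / dizygotic pairs.
#' @param window_size,fragment_size bp (defaults 50 and 200).
#' @param baseline_mean expected fragments per window per sample.
#' @param dispersion NB dispersion alpha >= 0 (0 degenerates to Poisson).
#' @param pair_effect_sd SD of the per-pair, per-window log-scale effect.
#' @param libsize_cv coefficient of variation of per-sample library scaling.
#' @param spikes list of \code{\link{spike_spec}} objects.
#' @param covariate_model list with elements \code{leukocyte_alpha}
#'   (Dirichlet concentrations for cd8t, cd4t, nk, bcell, mono,
#'   granulocytes; default matches granulocyte-dominant adult blood),
#'   \code{age_range} (default 55-65 years, shared within pair),
#'   \code{confound_coef} (log-scale slope linking one covariate to all
#'   window means; default 0) and \code{confound_covariate}.
#' @param emit_fragments if TRUE, counts are defined by binning simulated
#'   fragments so the fragment/count round trip is exact.
#' @return a list of class \code{sim_config}.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chrA = 3e6, chrB = 2e6),
                              n_pairs_mz = 19L, n_pairs_dz = 19L,
                              window_size = 50L, fragment_size = 200L,
                              baseline_mean = 20, dispersion = 0.3,
                              pair_effect_sd = 0.3, libsize_cv = 0.2,
                              spikes = list(),
                              covariate_model = list(),
                              emit_fragments = FALSE) {
  if (any(chrom_lengths <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  if (n_pairs_mz + n_pairs_dz <= 0) {
    stop("at least one twin pair is required", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  if (baseline_mean <= 0) stop("baseline_mean must be > 0", call. = FALSE)
  for (sp in spikes) {
    if (!inherits(sp, "spike_spec")) stop("spikes must be spike_spec objects", call. = FALSE)
    if (!sp$chrom %in% names(chrom_lengths)) {
      stop("spike on unknown chromosome ", sp$chrom, call. = FALSE)
    }
    if (sp$start < 0 || sp$end > chrom_lengths[[sp$chrom]]) {
      stop("spike interval outside chromosome ", sp$chrom, call. = FALSE)
    }
  }
  if (length(spikes) > 1) {
    sdf <- do.call(rbind, lapply(spikes, function(s) {
      data.frame(chrom = s$chrom, start = s$start, end = s$end)
    }))
    ov <- overlap_regions(sdf, sdf)
    ov <- ov[ov$query < ov$subject, , drop = FALSE]
    if (nrow(ov)) {
      stop("overlapping spike intervals: spikes ", ov$query[1], " and ",
           ov$subject[1], call. = FALSE)
    }
  }
  cm <- covariate_model
  cm$leukocyte_alpha <- cm$leukocyte_alpha %||%
    c(cd8t = 8, cd4t = 15, nk = 5, bcell = 5, mono = 7, gran = 60)
  cm$age_range <- cm$age_range %||% c(55, 65)
  cm$confound_coef <- cm$confound_coef %||% 0
  cm$confound_covariate <- cm$confound_covariate %||% "cd4t"
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_pairs_mz = as.integer(n_pairs_mz),
                 n_pairs_dz = as.integer(n_pairs_dz),
                 window_size = window_size, fragment_size = fragment_size,
                 baseline_mean = baseline_mean, dispersion = dispersion,
                 pair_effect_sd = pair_effect_sd, libsize_cv = libsize_cv,
                 spikes = spikes, covariate_model = cm,
                 emit_fragments = isTRUE(emit_fragments)),
            class = "sim_config")
}

# Dirichlet draw via independent gammas, one row per sample.
.rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

#' Simulate a discordant twin cohort
#'
#' Generates sample metadata (pair structure, zygosity, case/control roles,
#' five leukocyte fractions, age), per-window negative-binomial counts under
#' the log-link model of \code{\link{simulation_config}}, and a ground-truth
#' table of realized spike effects. With \code{emit_fragments = TRUE} the
#' generator instead draws per-window fragment anchors, lays 200 bp
#' fragments down uniformly within each anchor window, and defines the count
#' matrix by binning those fragments, so re-binning reproduces it exactly.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return list of class \code{twin_cohort}: \code{counts}
#'   (\code{\link{window_counts}}), \code{samples} (metadata data.frame),
#'   \code{truth} (realized spikes), \code{fragments} (per-sample interval
#'   lists or NULL), \code{config}.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    windows <- make_windows(config$chrom_lengths, config$window_size)
    n_win <- nrow(windows)
    n_pairs <- config$n_pairs_mz + config$n_pairs_dz
    zyg <- rep(c("MZ", "DZ"), c(config$n_pairs_mz, config$n_pairs_dz))
    pair_id <- sprintf("%s%02d", zyg, c(seq_len(config$n_pairs_mz),
                                        seq_len(config$n_pairs_dz)))
    samples <- data.frame(
      sample_id = as.vector(rbind(paste0(pair_id, "_case"),
                                  paste0(pair_id, "_ctrl"))),
      pair_id = rep(pair_id, each = 2),
      zygosity = rep(zyg, each = 2),
      role = rep(c("case", "control"), n_pairs),
      stringsAsFactors = FALSE)
    n_samp <- nrow(samples)

    # covariates: leukocyte fractions per sample, age shared within pair
    leuk <- .rdirichlet(n_samp, config$covariate_model$leukocyte_alpha)
    samples$cd8t <- leuk[, "cd8t"]; samples$cd4t <- leuk[, "cd4t"]
    samples$nk <- leuk[, "nk"]; samples$bcell <- leuk[, "bcell"]
    samples$mono <- leuk[, "mono"]
    age_pair <- runif(n_pairs, config$covariate_model$age_range[1],
                      config$covariate_model$age_range[2])
    samples$age <- rep(age_pair, each = 2)

    # per-sample library scaling with the requested CV, mean 1
    if (config$libsize_cv > 0) {
      sig <- sqrt(log(1 + config$libsize_cv^2))
      libsize <- rlnorm(n_samp, meanlog = -sig^2 / 2, sdlog = sig)
    } else {
      libsize <- rep(1, n_samp)
    }

    # per-window, per-pair random effect shared by both co-twins
    eta <- matrix(log(config$baseline_mean), nrow = n_win, ncol = n_samp)
    if (config$pair_effect_sd > 0) {
      pe <- matrix(rnorm(n_win * n_pairs, sd = config$pair_effect_sd),
                   nrow = n_win)
      eta <- eta + pe[, rep(seq_len(n_pairs), each = 2), drop = FALSE]
    }
    eta <- sweep(eta, 2, log(libsize), "+")

    cc <- config$covariate_model$confound_coef
    if (cc != 0) {
      xcov <- samples[[config$covariate_model$confound_covariate]]
      eta <- sweep(eta, 2, cc * (xcov - mean(xcov)), "+")
    }

    # spike effects: case co-twin of carrier pairs only
    truth <- list()
    wgr <- as_granges0(windows)
    case_col <- which(samples$role == "case")
    for (k in seq_along(config$spikes)) {
      sp <- config$spikes[[k]]
      hit <- S4Vectors::queryHits(GenomicRanges::findOverlaps(
        wgr, as_granges0(data.frame(chrom = sp$chrom, start = sp$start,
                                    end = sp$end)),
        minoverlap = 1L, ignore.strand = TRUE))
      carriers <- which(runif(n_pairs) <= sp$penetrance)
      if (length(hit) && length(carriers)) {
        cols <- case_col[carriers]
        eta[hit, cols] <- eta[hit, cols] + sp$log2fc * log(2)
      }
      truth[[k]] <- data.frame(
        spike = k, chrom = sp$chrom, start = sp$start, end = sp$end,
        log2fc = sp$log2fc, penetrance = sp$penetrance,
        n_carrier_pairs = length(carriers),
        carrier_pairs = paste(pair_id[carriers], collapse = ","),
        n_windows = length(hit), stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(spike = integer(0), chrom = character(0),
                 start = numeric(0), end = numeric(0), log2fc = numeric(0),
                 penetrance = numeric(0), n_carrier_pairs = integer(0),
                 carrier_pairs = character(0), n_windows = integer(0))

    mu <- exp(eta)
    draws <- if (config$dispersion > 0) {
      rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
    } else {
      rpois(length(mu), lambda = mu)
    }
    anchors <- matrix(as.integer(draws), nrow = n_win)

    fragments <- NULL
    if (config$emit_fragments) {
      fragments <- vector("list", n_samp)
      names(fragments) <- samples$sample_id
      clipped <- 0L
      for (s in seq_len(n_samp)) {
        nz <- which(anchors[, s] > 0L)
        if (!length(nz)) {
          fragments[[s]] <- data.frame(chrom = character(0),
                                       start = numeric(0), end = numeric(0))
          next
        }
        reps <- anchors[nz, s]
        wch <- rep(windows$chrom[nz], reps)
        ws <- rep(windows$start[nz], reps)
        we <- rep(windows$end[nz], reps)
        fs <- ws + floor(runif(length(ws)) * (we - ws))
        fe <- fs + config$fragment_size
        lim <- config$chrom_lengths[wch]
        clipped <- clipped + sum(fe > lim)
        fe <- pmin(fe, lim)
        fr <- data.frame(chrom = wch, start = fs, end = fe,
                         stringsAsFactors = FALSE)
        fragments[[s]] <- sort_intervals(fr)
        rownames(fragments[[s]]) <- NULL
      }
      if (clipped > 0L) {
        message(clipped, " fragment(s) clipped at chromosome ends")
      }
      wcm <- bin_fragments(fragments, config$chrom_lengths,
                           window_size = config$window_size,
                           fragment_size = config$fragment_size)
      wcm$sample_ids <- samples$sample_id
      colnames(wcm$counts) <- samples$sample_id
    } else {
      wcm <- window_counts(windows, anchors, sample_ids = samples$sample_id)
    }

    structure(list(counts = wcm, samples = samples, truth = truth,
                   fragments = fragments, config = config),
              class = "twin_cohort")
  })
}

#' @export
print.twin_cohort <- function(x, ...) {
  cat("twin_cohort:", nrow(x$samples) / 2, "pairs (",
      sum(x$samples$zygosity == "MZ") / 2, "MZ,",
      sum(x$samples$zygosity == "DZ") / 2, "DZ );",
      nrow(x$counts$counts), "windows;", nrow(x$truth), "spike(s)\n")
  invisible(x)
}

#' Per-sample fragment interval lists of a simulated cohort
#'
#' Fragments are only available when the cohort was generated with
#' \code{emit_fragments = TRUE}; in that mode re-binning them reproduces the
#' cohort's count matrix exactly.
#'
#' @param cohort a \code{twin_cohort}.
#' @return named list of data.frames (chrom, start, end).
#' @export
emit_fragments <- function(cohort) {
  stopifnot(inherits(cohort, "twin_cohort"))
  if (is.null(cohort$fragments)) {
    stop("cohort was generated without fragment emission; ",
         "set emit_fragments = TRUE in the simulation config", call. = FALSE)
  }
  cohort$fragments
}
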
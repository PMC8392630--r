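# Strict TSV reading with file/line context on failure.
.read_tsv_strict <- function(path, what, col_names, header = TRUE) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- tryCatch(
    read.table(path, sep = "\t", header = header, stringsAsFactors = FALSE,
               comment.char = "", quote = ""),
    error = function(e) {
      stop("malformed ", what, " file ", path, ": ", conditionMessage(e),
           call. = FALSE)
    })
  if (!is.null(col_names)) {
    if (header) {
      miss <- setdiff(col_names, names(df))
      if (length(miss)) {
        stop(what, " file ", path, " missing column(s): ",
             paste(miss, collapse = ", "), call. = FALSE)
      }
    } else {
      if (ncol(df) < length(col_names)) {
        stop(what, " file ", path, " has ", ncol(df), " columns; expected >= ",
             length(col_names), call. = FALSE)
      }
      names(df)[seq_along(col_names)] <- col_names
    }
  }
  df
}

#' Read a BED file of intervals
#'
#' 0-based half-open coordinates; columns beyond the first six are ignored.
#' @param path BED file path.
#' @return data.frame with chrom, start, end and (when present) name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  df <- .read_tsv_strict(path, "BED", c("chrom", "start", "end"),
                         header = FALSE)
  extra <- c("name", "score", "strand")
  have <- min(ncol(df) - 3L, 3L)
  if (have > 0) names(df)[4:(3 + have)] <- extra[seq_len(have)]
  bad <- which(!is.numeric(df$start) | !is.numeric(df$end) |
               df$start < 0 | df$end <= df$start)
  if (length(bad)) {
    stop("BED file ", path, ": invalid interval at line ", bad[1],
         call. = FALSE)
  }
  df[, seq_len(3 + have), drop = FALSE]
}

#' Write intervals as BED
#'
#' @param df data.frame with chrom, start, end; optional name, score,
#'   strand columns are written when present.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  out <- df[, cols, drop = FALSE]
  if ("score" %in% names(out)) out$score <- signif(out$score, 10)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write candidate/DhMR regions as BED with pattern and score
#'
#' The name field carries the hyper/hypo pattern; the score is
#' -log10 of the minimum member q-value when available.
#' @param regions region data.frame with chrom/start/end/pattern.
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom, start = regions$start,
                   end = regions$end,
                   name = regions$pattern %||% ".",
                   score = regions$score %||% 0)
  df$score[!is.finite(df$score)] <- 0
  write_bed(df, path)
}

#' Read a two-column chromosome sizes file
#' @param path TSV with chromosome name and length.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- .read_tsv_strict(path, "chrom sizes", c("chrom", "length"),
                         header = FALSE)
  if (any(df$length <= 0)) stop("chromosome lengths must be > 0", call. = FALSE)
  setNames(as.numeric(df$length), df$chrom)
}

#' Write a window count matrix as TSV
#' @param x a \code{\link{window_counts}} object.
#' @param path output path (columns chrom, start, end, then samples).
#' @export
write_counts_tsv <- function(x, path) {
  df <- cbind(x$windows[, c("chrom", "start", "end")],
              as.data.frame(x$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a window count matrix from TSV
#' @param path TSV with chrom, start, end, then one column per sample.
#' @return a \code{\link{window_counts}} object.
#' @export
read_counts_tsv <- function(path) {
  df <- .read_tsv_strict(path, "count matrix", c("chrom", "start", "end"))
  samp <- setdiff(names(df), c("chrom", "start", "end"))
  if (!length(samp)) stop("count matrix has no sample columns", call. = FALSE)
  counts <- as.matrix(df[, samp, drop = FALSE])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  window_counts(df[, c("chrom", "start", "end")],
                matrix(as.integer(counts), ncol = length(samp)),
                sample_ids = samp)
}

#' Write sample metadata as TSV
#' @param samples metadata data.frame.
#' @param path output path.
#' @export
write_samples_tsv <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata from TSV
#' @param path TSV with sample_id, pair_id, zygosity, role and covariates.
#' @return data.frame.
#' @export
read_samples_tsv <- function(path) {
  df <- .read_tsv_strict(path, "sample metadata",
                         c("sample_id", "pair_id", "zygosity", "role"))
  bad_role <- !df$role %in% c("case", "control")
  if (any(bad_role)) {
    stop("sample metadata ", path, ": invalid role at line ",
         which(bad_role)[1] + 1L, call. = FALSE)
  }
  df
}

#' Read a region table, optionally converting 1-based inclusive coordinates
#'
#' @param path TSV with chrom, start, end (header required).
#' @param one_based if TRUE, input rows are 1-based inclusive and converted
#'   to 0-based half-open: (1, 100) -> [0, 100).
#' @return data.frame of intervals.
#' @export
read_regions_table <- function(path, one_based = FALSE) {
  df <- .read_tsv_strict(path, "regions", c("chrom", "start", "end"))
  if (one_based) df$start <- df$start - 1
  genomic_intervals(df$chrom, df$start, df$end)
}

#' Write an R object as a JSON artifact
#'
#' Floats are serialized with 10 significant digits.
#' @param x list-like object.
#' @param path output path.
#' @export
write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Serialize a PCA transform to JSON
#' @param transform a \code{pca_transform}.
#' @param path output path.
#' @export
write_pca_transform <- function(transform, path) {
  write_json_artifact(list(
    region_ids = transform$region_ids,
    center = unname(transform$center),
    scale = unname(transform$scale),
    pca_center = unname(transform$pca_center),
    loadings = apply(transform$loadings, 1, as.numeric, simplify = FALSE),
    sdev = transform$sdev,
    selected_dims = transform$selected_dims), path)
}

#' Read a PCA transform from JSON
#' @param path JSON produced by \code{\link{write_pca_transform}}.
#' @return a \code{pca_transform} (without fitting-cohort scores).
#' @export
read_pca_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  loadings <- do.call(rbind, lapply(seq_len(length(j$region_ids)),
                                    function(i) j$loadings[[i]]))
  rownames(loadings) <- j$region_ids
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  structure(list(
    region_ids = j$region_ids,
    center = setNames(j$center, j$region_ids),
    scale = setNames(j$scale, j$region_ids),
    pca_center = setNames(j$pca_center, j$region_ids),
    loadings = loadings, sdev = j$sdev, scores = NULL,
    selected_dims = j$selected_dims), class = "pca_transform")
}

#' Write per-sample fragments as 6-column BED files
#'
#' One file per sample, named \code{<sample_id>.bed}, in \code{dir}.
#' @param fragments named list of fragment data.frames.
#' @param dir output directory (created if needed).
#' @return character vector of written paths.
#' @export
write_fragments_bed <- function(fragments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(fragments))
  for (i in seq_along(fragments)) {
    fr <- fragments[[i]]
    df <- data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
                     name = names(fragments)[i], score = 0, strand = "*")
    paths[i] <- file.path(dir, paste0(names(fragments)[i], ".bed"))
    write_bed(df, paths[i])
  }
  paths
}
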
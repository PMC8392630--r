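#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open (BED convention): a region
#' \code{[start, end)} covers bases \code{start .. end - 1}.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, \code{0 <= start < end}.
#' @param strand optional strand, one of \code{"+"}, \code{"-"}, \code{"*"}.
#' @return a \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{strand}.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chrom names must be non-empty", call. = FALSE)
  }
  if (any(start < 0) || any(start >= end)) {
    stop("intervals require 0 <= start < end", call. = FALSE)
  }
  data.frame(chrom = chrom, start = start, end = end,
             strand = rep_len(as.character(strand), length(chrom)),
             stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> GRanges (1-based closed) for overlap work.
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
}

# GRanges -> 0-based half-open data.frame.
as_intervals0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Report all overlapping pairs between two region sets
#'
#' Half-open semantics: \code{[0,100)} and \code{[100,200)} do not overlap.
#' Used to compare DhMR sets (e.g. against an external region list).
#'
#' @param a,b data.frames with \code{chrom}, \code{start}, \code{end}.
#' @return data.frame with columns \code{query} (row index in \code{a}),
#'   \code{subject} (row index in \code{b}) and \code{overlap_bp}.
#' @export
overlap_regions <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(query = integer(0), subject = integer(0),
                      overlap_bp = integer(0)))
  }
  hits <- GenomicRanges::findOverlaps(as_granges0(a), as_granges0(b),
                                      minoverlap = 1L, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  out <- data.frame(query = qi, subject = si, overlap_bp = as.integer(ov))
  out[order(out$query, out$subject), , drop = FALSE]
}
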
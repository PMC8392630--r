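#' Default biotype dictionary
#'
#' Maps gene-model biotype strings to the four reported gene types;
#' anything unmapped becomes \code{"other"}.
#' @return named character vector.
#' @export
default_biotype_map <- function() {
  c(protein_coding = "protein-coding", `protein-coding` = "protein-coding",
    lincRNA = "ncRNA", lncRNA = "ncRNA", ncRNA = "ncRNA",
    antisense = "ncRNA", miRNA = "ncRNA",
    pseudogene = "pseudo", processed_pseudogene = "pseudo",
    unprocessed_pseudogene = "pseudo", pseudo = "pseudo",
    snoRNA = "snoRNA")
}

#' Build a gene model from transcript and exon tables
#'
#' @param transcripts data.frame with \code{tx_id}, \code{gene_id},
#'   \code{gene_type} (raw biotype; mapped via \code{biotype_map}),
#'   \code{chrom}, \code{strand} (\code{"+"}/\code{"-"}), \code{start},
#'   \code{end} (transcript span, 0-based half-open), and optional
#'   \code{cds_start}/\code{cds_end} (NA for non-coding transcripts).
#' @param exons data.frame with \code{tx_id}, \code{start}, \code{end}.
#' @param biotype_map named vector mapping biotypes to
#'   ncRNA/protein-coding/pseudo/snoRNA; unmapped -> "other".
#' @return list of class \code{gene_model}.
#' @export
gene_model <- function(transcripts, exons,
                       biotype_map = default_biotype_map()) {
  stopifnot(all(c("tx_id", "gene_id", "gene_type", "chrom", "strand",
                  "start", "end") %in% names(transcripts)),
            all(c("tx_id", "start", "end") %in% names(exons)))
  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop("transcript strand must be '+' or '-'", call. = FALSE)
  }
  if (!"cds_start" %in% names(transcripts)) transcripts$cds_start <- NA_real_
  if (!"cds_end" %in% names(transcripts)) transcripts$cds_end <- NA_real_
  span <- transcripts[match(exons$tx_id, transcripts$tx_id), ]
  if (any(exons$start < span$start | exons$end > span$end)) {
    stop("exon outside its transcript span", call. = FALSE)
  }
  mapped <- unname(biotype_map[transcripts$gene_type])
  transcripts$gene_type <- ifelse(is.na(mapped), "other", mapped)
  structure(list(transcripts = transcripts, exons = exons),
            class = "gene_model")
}

#' Read a gene model from a GTF file
#'
#' Uses \pkg{rtracklayer} for parsing. Transcript spans come from
#' \code{transcript} records (or the union of exons when absent), CDS
#' extents from \code{CDS} records; missing biotype attributes map to
#' gene type \code{"other"} with a warning.
#'
#' @param path GTF file path.
#' @param biotype_attr attribute holding the biotype (default
#'   \code{"gene_biotype"}, falling back to \code{"transcript_biotype"}
#'   then \code{"gene_type"}).
#' @param biotype_map see \code{\link{gene_model}}.
#' @return a \code{gene_model}.
#' @export
read_gene_model <- function(path, biotype_attr = "gene_biotype",
                            biotype_map = default_biotype_map()) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  get_attr <- function(i) {
    for (key in unique(c(biotype_attr, "transcript_biotype", "gene_type"))) {
      if (key %in% names(meta) && !is.na(meta[[key]][i])) return(meta[[key]][i])
    }
    NA_character_
  }
  tx_rows <- which(meta$type == "transcript")
  exon_rows <- which(meta$type == "exon")
  cds_rows <- which(meta$type == "CDS")
  tx_of <- function(rows) as.character(meta$transcript_id[rows])
  if (length(tx_rows) == 0L) { # derive spans from exons
    ids <- unique(tx_of(exon_rows))
    tx_rows <- vapply(ids, function(id) exon_rows[tx_of(exon_rows) == id][1],
                      integer(1))
  }
  bts <- vapply(tx_rows, get_attr, character(1))
  if (anyNA(bts)) {
    warning(sum(is.na(bts)), " transcript(s) without a biotype attribute; ",
            "gene type set to 'other'")
    bts[is.na(bts)] <- "unknown"
  }
  span_for <- function(id, rows) {
    sub <- rows[tx_of(rows) == id]
    c(min(GenomicRanges::start(gr)[sub]) - 1, max(GenomicRanges::end(gr)[sub]))
  }
  ids <- tx_of(tx_rows)
  spans <- t(vapply(ids, span_for, numeric(2), rows = exon_rows))
  cds <- t(vapply(ids, function(id) {
    sub <- cds_rows[tx_of(cds_rows) == id]
    if (!length(sub)) return(c(NA_real_, NA_real_))
    c(min(GenomicRanges::start(gr)[sub]) - 1, max(GenomicRanges::end(gr)[sub]))
  }, numeric(2)))
  transcripts <- data.frame(
    tx_id = ids,
    gene_id = as.character(meta$gene_id[tx_rows]),
    gene_type = bts,
    chrom = as.character(GenomicRanges::seqnames(gr)[tx_rows]),
    strand = as.character(GenomicRanges::strand(gr)[tx_rows]),
    start = spans[, 1], end = spans[, 2],
    cds_start = cds[, 1], cds_end = cds[, 2],
    stringsAsFactors = FALSE)
  exons <- data.frame(
    tx_id = tx_of(exon_rows),
    start = GenomicRanges::start(gr)[exon_rows] - 1,
    end = GenomicRanges::end(gr)[exon_rows],
    stringsAsFactors = FALSE)
  gene_model(transcripts, exons, biotype_map)
}

#' Annotate regions against a gene model
#'
#' Assignment is by region midpoint with precedence TSS > TTS > exon
#' (5'UTR > 3'UTR > coding exon > non-coding exon) > intron > intergenic.
#' Promoter-TSS and TTS windows are strand-aware offsets around the
#' transcription start/termination sites. Exons of non-coding transcripts
#' map to the \code{"non-coding"} category. The nearest gene is the one
#' whose TSS is closest to the region midpoint; the signed distance is
#' negative upstream of the TSS in transcript orientation.
#'
#' @param regions data.frame with \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open) and optionally \code{pattern}.
#' @param model a \code{\link{gene_model}}.
#' @param promoter_window strand-aware window around the TSS (default
#'   c(-1000, 100)).
#' @param tts_window strand-aware window around the TTS (default
#'   c(-100, 1000)).
#' @param strict error (rather than warn) on unknown chromosomes.
#' @return data.frame of annotation records: coordinates, \code{pattern}
#'   (if present), \code{category}, \code{gene_id}, \code{gene_type},
#'   \code{distance_to_tss}.
#' @export
annotate_regions <- function(regions, model,
                             promoter_window = c(-1000, 100),
                             tts_window = c(-100, 1000), strict = FALSE) {
  tx <- model$transcripts
  ex <- model$exons
  tss <- ifelse(tx$strand == "+", tx$start, tx$end - 1)
  tts <- ifelse(tx$strand == "+", tx$end - 1, tx$start)
  n <- nrow(regions)
  category <- character(n); gene_id <- character(n)
  gene_type <- character(n); dist_tss <- numeric(n)
  for (i in seq_len(n)) {
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    chrom_ok <- tx$chrom == regions$chrom[i]
    if (!regions$chrom[i] %in% tx$chrom) {
      msg <- paste0("region chromosome ", regions$chrom[i],
                    " absent from gene model")
      if (strict) stop(msg, call. = FALSE)
      warning(msg, "; annotated intergenic")
    }
    # signed strand-aware offsets to every TSS/TTS
    d_tss <- ifelse(tx$strand == "+", mid - tss, tss - mid)
    d_tts <- ifelse(tx$strand == "+", mid - tts, tts - mid)
    in_prom <- chrom_ok & d_tss >= promoter_window[1] & d_tss <= promoter_window[2]
    in_tts <- chrom_ok & d_tts >= tts_window[1] & d_tts <= tts_window[2]
    in_span <- chrom_ok & tx$start <= mid & mid < tx$end
    exon_hit <- rep(FALSE, nrow(tx))
    for (j in which(in_span)) {
      sub <- ex[ex$tx_id == tx$tx_id[j], , drop = FALSE]
      exon_hit[j] <- any(sub$start <= mid & mid < sub$end)
    }
    exon_cat <- function() {
      cats <- vapply(which(exon_hit), function(j) {
        if (is.na(tx$cds_start[j])) return("non-coding")
        if (tx$strand[j] == "+") {
          if (mid < tx$cds_start[j]) "5'UTR"
          else if (mid >= tx$cds_end[j]) "3'UTR"
          else "exon"
        } else {
          if (mid >= tx$cds_end[j]) "5'UTR"
          else if (mid < tx$cds_start[j]) "3'UTR"
          else "exon"
        }
      }, character(1))
      for (c0 in c("5'UTR", "3'UTR", "exon", "non-coding")) {
        if (c0 %in% cats) return(c0)
      }
      "exon"
    }
    category[i] <- if (any(in_prom)) "TSS"
      else if (any(in_tts)) "TTS"
      else if (any(exon_hit)) exon_cat()
      else if (any(in_span)) "intron"
      else "intergenic"
    if (any(chrom_ok)) {
      cand <- which(chrom_ok)
      best <- cand[order(abs(d_tss[cand]), tx$gene_id[cand])][1]
      gene_id[i] <- tx$gene_id[best]
      gene_type[i] <- tx$gene_type[best]
      dist_tss[i] <- d_tss[best]
    } else {
      gene_id[i] <- NA_character_; gene_type[i] <- NA_character_
      dist_tss[i] <- NA_real_
    }
  }
  out <- data.frame(chrom = regions$chrom, start = regions$start,
                    end = regions$end, stringsAsFactors = FALSE)
  if ("pattern" %in% names(regions)) out$pattern <- regions$pattern
  out$category <- category
  out$gene_id <- gene_id
  out$gene_type <- gene_type
  out$distance_to_tss <- dist_tss
  out
}

#' Summarize annotation records by category and gene type
#'
#' Produces the standard accounting table: counts and percentages per
#' annotation category for all regions and for the hyper/hypo subtypes
#' (category percentages over each column total), with a gene-type
#' breakdown within each category (percentages within the category).
#'
#' @param records annotation records with \code{category}, \code{pattern}
#'   (\code{"hyper"}/\code{"hypo"}) and \code{gene_type}.
#' @return list of class \code{annotation_summary}: \code{totals}
#'   (n and percentage of hyper/hypo among all records) and \code{table}
#'   (one row per category and per gene type within category, with
#'   \code{n_all}/\code{pct_all}, \code{n_hyper}/\code{pct_hyper},
#'   \code{n_hypo}/\code{pct_hypo}).
#' @export
summarize_annotations <- function(records) {
  empty <- structure(list(
    totals = data.frame(n_all = 0L, n_hyper = 0L, n_hypo = 0L,
                        pct_hyper = NA_real_, pct_hypo = NA_real_),
    table = data.frame(level = character(0), category = character(0),
                       gene_type = character(0))),
    class = "annotation_summary")
  if (is.null(records) || nrow(records) == 0L) return(empty)
  cats <- c("exon", "intergenic", "intron", "TSS", "TTS",
            "5'UTR", "3'UTR", "non-coding")
  cats <- cats[cats %in% records$category]
  types <- c("ncRNA", "protein-coding", "pseudo", "snoRNA", "other")
  cols <- list(all = rep(TRUE, nrow(records)),
               hyper = records$pattern == "hyper",
               hypo = records$pattern == "hypo")
  tot <- vapply(cols, sum, numeric(1))
  pct <- function(n, d) ifelse(d > 0, 100 * n / d, NA_real_)
  rows <- list()
  for (cat0 in cats) {
    in_cat <- records$category == cat0
    nc <- vapply(cols, function(m) sum(in_cat & m), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      level = "category", category = cat0, gene_type = NA_character_,
      n_all = nc[["all"]], pct_all = pct(nc[["all"]], tot[["all"]]),
      n_hyper = nc[["hyper"]], pct_hyper = pct(nc[["hyper"]], tot[["hyper"]]),
      n_hypo = nc[["hypo"]], pct_hypo = pct(nc[["hypo"]], tot[["hypo"]]),
      stringsAsFactors = FALSE)
    for (ty in types[types %in% records$gene_type[in_cat]]) {
      in_ty <- in_cat & records$gene_type == ty
      nt <- vapply(cols, function(m) sum(in_ty & m), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        level = "gene_type", category = cat0, gene_type = ty,
        n_all = nt[["all"]], pct_all = pct(nt[["all"]], nc[["all"]]),
        n_hyper = nt[["hyper"]], pct_hyper = pct(nt[["hyper"]], nc[["hyper"]]),
        n_hypo = nt[["hypo"]], pct_hypo = pct(nt[["hypo"]], nc[["hypo"]]),
        stringsAsFactors = FALSE)
    }
  }
  totals <- data.frame(
    n_all = tot[["all"]], n_hyper = tot[["hyper"]], n_hypo = tot[["hypo"]],
    pct_hyper = pct(tot[["hyper"]], tot[["all"]]),
    pct_hypo = pct(tot[["hypo"]], tot[["all"]]))
  structure(list(totals = totals, table = do.call(rbind, rows)),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  t0 <- x$totals
  cat(sprintf("annotation_summary: %d regions (%d hyper [%.1f%%], %d hypo [%.1f%%])\n",
              t0$n_all, t0$n_hyper, t0$pct_hyper, t0$n_hypo, t0$pct_hypo))
  if (nrow(x$table)) {
    tb <- x$table
    tb$pct_all <- round(tb$pct_all, 1)
    tb$pct_hyper <- round(tb$pct_hyper, 1)
    tb$pct_hypo <- round(tb$pct_hypo, 1)
    print(tb, row.names = FALSE)
  }
  invisible(x)
}
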
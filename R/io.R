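## Readers and writers for the standard formats (FASTA, GTF/GFF, BAM, BED,
## TSV) plus the gene-model container shared by all analysis modules.
## Internally every coordinate is 0-based half-open; 1-based conventions are
## converted at the file boundary only.

#' Construct gene models from a transcript table
#'
#' @param transcripts tibble with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `exons` (list of 2-column start/end matrices, 0-based
#'   half-open) and `cds` (same shape; 0-row matrix when non-coding).
#' @return object of class `gene_models`: list with `transcripts` and a
#'   derived per-gene `genes` tibble (locus span).
#' @export
gene_models <- function(transcripts) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "strand",
                  "exons", "cds") %in% names(transcripts)))
  if (nrow(transcripts) == 0L) {
    return(structure(list(
      genes = tibble(gene_id = character(0), chrom = character(0),
                     start = integer(0), end = integer(0),
                     strand = character(0)),
      transcripts = transcripts), class = "gene_models"))
  }
  for (i in seq_len(nrow(transcripts))) {
    ex <- transcripts$exons[[i]]
    if (nrow(ex) == 0L) stopf("transcript '%s' has no exons",
                              transcripts$transcript_id[i])
    check_interval(ex[, 1], ex[, 2], "exon")
    cds <- transcripts$cds[[i]]
    if (nrow(cds) > 0L) check_interval(cds[, 1], cds[, 2], "CDS")
  }
  tx_start <- vapply(transcripts$exons, function(e) min(e[, 1]), numeric(1))
  tx_end <- vapply(transcripts$exons, function(e) max(e[, 2]), numeric(1))
  genes <- tibble(gene_id = transcripts$gene_id, chrom = transcripts$chrom,
                  strand = transcripts$strand,
                  start = tx_start, end = tx_end) %>%
    group_by(.data$gene_id) %>%
    summarise(chrom = .data$chrom[1], start = as.integer(min(.data$start)),
              end = as.integer(max(.data$end)), strand = .data$strand[1],
              .groups = "drop") %>%
    arrange(.data$chrom, .data$start)
  structure(list(genes = genes, transcripts = transcripts),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d transcripts\n",
              nrow(x$genes), nrow(x$transcripts)))
  invisible(x)
}

#' Read gene models from a GTF/GFF file
#'
#' Uses exon and CDS records grouped by `transcript_id` and `gene_id`.
#'
#' @param path GTF or GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!"transcript_id" %in% names(df)) stopf("annotation lacks transcript_id")
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  df$start0 <- df$start - 1L
  tx <- split(df, df$transcript_id)
  rows <- lapply(tx, function(d) {
    ex <- d[d$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start0), , drop = FALSE]
    cd <- d[d$type == "CDS", , drop = FALSE]
    cd <- cd[order(cd$start0), , drop = FALSE]
    tibble(transcript_id = d$transcript_id[1],
           gene_id = as.character(d$gene_id[1]),
           chrom = as.character(d$seqnames[1]),
           strand = as.character(d$strand[1]),
           exons = list(cbind(start = ex$start0, end = ex$end)),
           cds = list(cbind(start = cd$start0, end = cd$end)))
  })
  gene_models(bind_rows(rows))
}

#' Write gene models to a GTF file
#'
#' @param models a [gene_models()] object.
#' @param path output path (.gtf).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  tx <- models$transcripts
  recs <- lapply(seq_len(nrow(tx)), function(i) {
    ex <- tx$exons[[i]]; cd <- tx$cds[[i]]
    mk <- function(m, type, phase = NA_integer_) {
      if (nrow(m) == 0L) return(NULL)
      GenomicRanges::GRanges(tx$chrom[i],
        IRanges::IRanges(m[, 1] + 1L, m[, 2]), strand = tx$strand[i],
        type = type, gene_id = tx$gene_id[i],
        transcript_id = tx$transcript_id[i], phase = phase)
    }
    phase <- if (nrow(cd) > 0L) {
      lens <- cd[, 2] - cd[, 1]
      if (tx$strand[i] == "-") lens <- rev(lens)
      ph <- (3L - cumsum(c(0L, lens[-length(lens)])) %% 3L) %% 3L
      if (tx$strand[i] == "-") rev(ph) else ph
    } else {
      integer(0)
    }
    c(mk(ex, "exon"), mk(cd, "CDS", phase))
  })
  gr <- do.call(c, unlist(recs, use.names = FALSE))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a genome FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of chromosome sequences (upper case).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  x <- toupper(as.character(ss))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a genome character vector to FASTA
#' @param genome named character vector.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read long-read alignments from a BAM file
#'
#' Loads primary alignments with sequence and CIGAR, plus per-read numeric
#' tags for poly(A) tail length, channel and start time when present.
#'
#' @param path indexed BAM file.
#' @param sample_id label stored in the `sample_id` column.
#' @param tags named character vector mapping fields to BAM tag names;
#'   default `c(tail_length = "pa", channel = "ch", start_time = "st")`.
#' @return a [drs_reads()] tibble.
#' @export
read_reads_bam <- function(path, sample_id,
                           tags = c(tail_length = "pa", channel = "ch",
                                    start_time = "st")) {
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "strand", "seq"),
    tag = unname(tags),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isUnmappedQuery = FALSE))
  b <- Rsamtools::scanBam(path, param = param)[[1]]
  tagval <- function(key, default) {
    v <- b$tag[[tags[[key]]]]
    if (is.null(v)) rep(default, length(b$qname)) else v
  }
  drs_reads(read_id = b$qname, sample_id = sample_id,
            chrom = as.character(b$rname), start = b$pos - 1L,
            strand = as.character(b$strand), cigar = b$cigar,
            seq = as.character(b$seq),
            tail_length = as.numeric(tagval("tail_length", NA_real_)),
            channel = as.integer(tagval("channel", NA_integer_)),
            start_time = as.numeric(tagval("start_time", NA_real_)))
}

#' Write a read table to a sorted, indexed BAM file
#'
#' @param reads a [drs_reads()] tibble.
#' @param path output BAM path (".bam" appended if missing).
#' @param genome named character vector (for `@SQ` lengths) or a named
#'   integer vector of chromosome lengths.
#' @return path to the sorted indexed BAM, invisibly.
#' @export
write_reads_bam <- function(reads, path, genome) {
  lens <- if (is.character(genome)) nchar(genome) else genome
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  tagf <- function(ok, fmt, val) ifelse(ok, sprintf(fmt, val), NA)
  tag_cols <- cbind(tagf(!is.na(reads$tail_length), "pa:f:%g", reads$tail_length),
                    tagf(!is.na(reads$channel), "ch:i:%d", reads$channel),
                    tagf(!is.na(reads$start_time), "st:f:%g", reads$start_time))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    tg <- tag_cols[i, ]
    paste(c(reads$read_id[i], if (reads$strand[i] == "+") 0L else 16L,
            reads$chrom[i], reads$start[i] + 1L, 60L, reads$cigar[i],
            "*", 0L, 0L,
            if (is.na(reads$seq[i])) "*" else reads$seq[i], "*",
            tg[!is.na(tg)]), collapse = "\t")
  }, "")
  writeLines(c(hdr, body), sam)
  dest <- sub("\\.bam$", "", path)
  out <- Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  invisible(out)
}

#' Write genomic sites/intervals as 6-column BED
#'
#' Input coordinates are already 0-based half-open, matching BED.
#'
#' @param x tibble with `chrom`, `start`, `end` and optionally `name`,
#'   `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_interval(x$start, x$end, "BED interval")
  bed <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = if ("name" %in% names(x)) x$name else ".",
                    score = if ("score" %in% names(x)) x$score else 0,
                    strand = if ("strand" %in% names(x)) x$strand else ".")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a 6-column BED file
#' @param path BED path.
#' @return tibble with chrom, start, end, name, score, strand.
#' @export
read_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[seq_len(min(6L, ncol(bed)))] <-
    c("chrom", "start", "end", "name", "score", "strand")[seq_len(min(6L, ncol(bed)))]
  as_tibble(bed)
}

#' Write a result table as TSV with a header line
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  x <- as.data.frame(x)
  listcols <- vapply(x, is.list, logical(1))
  x <- x[, !listcols, drop = FALSE]
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV result table
#' @param path TSV path.
#' @return tibble.
#' @export
read_result_tsv <- function(path) {
  as_tibble(read.delim(path, stringsAsFactors = FALSE))
}
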
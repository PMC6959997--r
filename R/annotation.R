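## Annotation flattening and read-to-gene assignment.

FEATURE_LEVELS <- c("5UTR", "CDS", "intron", "3UTR", "upstream", "downstream")

#' Flatten gene models to per-base feature labels
#'
#' Each gene is reduced to a single per-base label track over its locus plus
#' flanking regions. Exonic annotation takes priority over intronic, and CDS
#' over UTR, when transcripts of the same gene disagree. UTR side (5' vs 3')
#' is resolved strand-aware relative to the transcript's CDS span; exons of
#' transcripts without any CDS are labelled `3UTR`. Bases within `flank` nt
#' outside the locus are labelled `upstream`/`downstream` (strand-aware).
#'
#' @param models a [gene_models()] object.
#' @param flank flank size in nt (default 200).
#' @return object of class `flat_annotation`: named list (by gene) with
#'   `chrom`, `strand`, `start` (0-based coordinate of the first label) and
#'   `labels` (character vector over `start:(start+length-1)`).
#' @export
flatten_annotation <- function(models, flank = 200L) {
  stopifnot(flank >= 0)
  tx_by_gene <- split(seq_len(nrow(models$transcripts)),
                      models$transcripts$gene_id)
  out <- lapply(seq_len(nrow(models$genes)), function(g) {
    gene <- models$genes[g, ]
    g0 <- max(0L, gene$start - as.integer(flank))
    g1 <- gene$end + as.integer(flank)
    width <- g1 - g0
    # rank: CDS 1 < UTR 2 < intron 3 < flank 4 ; lower wins
    rank <- rep(4L, width)
    label <- rep(if (gene$strand == "+") "downstream" else "upstream", width)
    label[seq_len(gene$start - g0)] <-
      if (gene$strand == "+") "upstream" else "downstream"
    for (ti in tx_by_gene[[gene$gene_id]]) {
      ex <- models$transcripts$exons[[ti]]
      cd <- models$transcripts$cds[[ti]]
      tx0 <- min(ex[, 1]); tx1 <- max(ex[, 2])
      # transcript-span bases default to intron, exons overwrite below
      idx <- (tx0 - g0 + 1L):(tx1 - g0)
      upd <- rank[idx] > 3L
      label[idx][upd] <- "intron"; rank[idx][upd] <- 3L
      if (nrow(cd) > 0L) { cds0 <- min(cd[, 1]); cds1 <- max(cd[, 2]) }
      for (e in seq_len(nrow(ex))) {
        pos <- ex[e, 1]:(ex[e, 2] - 1L)
        lab <- if (nrow(cd) == 0L) {
          rep("3UTR", length(pos))
        } else {
          ifelse(pos < cds0, if (gene$strand == "+") "5UTR" else "3UTR",
          ifelse(pos >= cds1, if (gene$strand == "+") "3UTR" else "5UTR",
                 "intron"))  # CDS-span exonic bases outside CDS = CDS intron
        }
        rk <- ifelse(lab == "intron", 3L, 2L)
        idx <- pos - g0 + 1L
        upd <- rank[idx] > rk
        label[idx][upd] <- lab[upd]; rank[idx][upd] <- rk[upd]
      }
      if (nrow(cd) > 0L) {
        for (e in seq_len(nrow(cd))) {
          idx <- (cd[e, 1] - g0 + 1L):(cd[e, 2] - g0)
          upd <- rank[idx] > 1L
          label[idx][upd] <- "CDS"; rank[idx][upd] <- 1L
        }
      }
    }
    list(gene_id = gene$gene_id, chrom = gene$chrom, strand = gene$strand,
         start = g0, labels = label)
  })
  names(out) <- models$genes$gene_id
  structure(out, class = "flat_annotation")
}

#' Look up the flattened feature label at positions of one gene
#'
#' @param flat a [flatten_annotation()] result.
#' @param gene_id gene identifier.
#' @param pos 0-based genomic positions.
#' @return character vector of labels; `NA` outside the flanked locus.
#' @export
flat_feature <- function(flat, gene_id, pos) {
  fa <- flat[[gene_id]]
  if (is.null(fa)) stopf("gene '%s' not in flattened annotation", gene_id)
  idx <- pos - fa$start + 1L
  ok <- idx >= 1L & idx <= length(fa$labels)
  out <- rep(NA_character_, length(pos))
  out[ok] <- fa$labels[idx[ok]]
  out
}

#' Assign reads to genes by fractional overlap
#'
#' A read is assigned to every same-strand gene whose locus span overlaps the
#' read's aligned (exonic) blocks by more than `min_frac` of the read's
#' aligned length. Reads may be assigned to zero, one or several genes.
#'
#' @param reads a [drs_reads()] tibble.
#' @param models a [gene_models()] object.
#' @param min_frac overlap fraction threshold (default 0.2, strict `>`).
#' @return tibble with columns `read` (row index into `reads`), `read_id`,
#'   `sample_id`, `gene_id`, `overlap` (nt) and `frac`.
#' @export
assign_reads_to_genes <- function(reads, models, min_frac = 0.2) {
  genes <- models$genes
  if (nrow(genes) == 0L || nrow(reads) == 0L) {
    return(tibble(read = integer(0), read_id = character(0),
                  sample_id = character(0), gene_id = character(0),
                  overlap = integer(0), frac = numeric(0)))
  }
  blocks <- read_blocks(reads)
  nb <- vapply(blocks, nrow, integer(1))
  bmat <- do.call(rbind, blocks)
  ridx <- rep(seq_len(nrow(reads)), nb)
  bgr <- GenomicRanges::GRanges(reads$chrom[ridx],
    IRanges::IRanges(bmat[, "start"] + 1L, bmat[, "end"]),
    strand = reads$strand[ridx])
  ggr <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end), strand = genes$strand)
  hits <- GenomicRanges::findOverlaps(bgr, ggr)
  if (length(hits) == 0L) {
    return(tibble(read = integer(0), read_id = character(0),
                  sample_id = character(0), gene_id = character(0),
                  overlap = integer(0), frac = numeric(0)))
  }
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(bgr)[S4Vectors::queryHits(hits)],
    IRanges::ranges(ggr)[S4Vectors::subjectHits(hits)]))
  df <- tibble(read = ridx[S4Vectors::queryHits(hits)],
               gene = S4Vectors::subjectHits(hits), overlap = ov) %>%
    group_by(.data$read, .data$gene) %>%
    summarise(overlap = sum(.data$overlap), .groups = "drop")
  alen <- aligned_length(reads)
  df$frac <- df$overlap / alen[df$read]
  df <- df[df$frac > min_frac, , drop = FALSE]
  tibble(read = df$read, read_id = reads$read_id[df$read],
         sample_id = reads$sample_id[df$read],
         gene_id = genes$gene_id[df$gene],
         overlap = as.integer(df$overlap), frac = df$frac) %>%
    arrange(.data$read, .data$gene_id)
}

#' Per-read error rates and substitution spectrum
#'
#' Decomposes each alignment into matches, mismatches, insertions and
#' deletions relative to the reference, normalised by the read's aligned
#' length, and aggregates a reference-base by observed-category matrix.
#' Requires the query sequence; reads without one raise an error naming the
#' read.
#'
#' @param reads a [drs_reads()] tibble with `seq`.
#' @param genome named character vector of reference sequences.
#' @return list with `per_read` (tibble: counts, rates, identity) and
#'   `by_ref_base` (4 x 6 matrix: reference A/C/G/T vs observed
#'   A/C/G/U/ins/del).
#' @export
read_error_spectrum <- function(reads, genome) {
  no_seq <- is.na(reads$seq) | reads$seq == "*"
  if (any(no_seq)) {
    stopf("cannot compute error spectrum: read '%s' lacks an aligned query sequence",
          reads$read_id[which(no_seq)[1]])
  }
  obs_levels <- c("A", "C", "G", "U", "ins", "del")
  agg <- matrix(0L, 4, 6, dimnames = list(DNA_BASES, obs_levels))
  ops_all <- cigar_ops(reads$cigar)
  res <- lapply(seq_len(nrow(reads)), function(i) {
    co <- ops_all[[i]]
    rpos <- reads$start[i]; qpos <- 1L
    nmatch <- 0L; nmis <- 0L; nins <- 0L; ndel <- 0L
    ref <- genome[[reads$chrom[i]]]
    for (j in seq_along(co$op)) {
      op <- co$op[j]; len <- co$len[j]
      if (op %in% c("M", "=", "X")) {
        q <- strsplit(substr(reads$seq[i], qpos, qpos + len - 1L), "")[[1]]
        r <- strsplit(substr(ref, rpos + 1L, rpos + len), "")[[1]]
        same <- q == r
        nmatch <- nmatch + sum(same); nmis <- nmis + sum(!same)
        qq <- chartr("T", "U", q)
        ok <- r %in% DNA_BASES & qq %in% c("A", "C", "G", "U")
        tab <- table(factor(r[ok], DNA_BASES), factor(qq[ok], obs_levels))
        agg[, ] <<- agg + as.integer(tab)
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "I") {
        nins <- nins + len
        b <- substr(ref, rpos, rpos)  # base preceding the insertion
        if (b %in% DNA_BASES) agg[b, "ins"] <<- agg[b, "ins"] + len
        qpos <- qpos + len
      } else if (op == "D") {
        ndel <- ndel + len
        r <- strsplit(substr(ref, rpos + 1L, rpos + len), "")[[1]]
        for (b in r[r %in% DNA_BASES]) agg[b, "del"] <<- agg[b, "del"] + 1L
        rpos <- rpos + len
      } else if (op == "N") {
        rpos <- rpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      }
    }
    c(nmatch, nmis, nins, ndel)
  })
  m <- do.call(rbind, res)
  alen <- aligned_length(reads)
  per_read <- tibble(read_id = reads$read_id, sample_id = reads$sample_id,
                     matches = m[, 1], mismatches = m[, 2],
                     insertions = m[, 3], deletions = m[, 4],
                     aligned_length = alen,
                     identity = m[, 1] / alen,
                     mismatch_rate = m[, 2] / alen,
                     ins_rate = m[, 3] / alen,
                     del_rate = m[, 4] / alen)
  list(per_read = per_read, by_ref_base = agg)
}
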
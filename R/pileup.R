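## Per-position basecall profiles.
##
## Every covered reference position of every read is assigned exactly one of
## five categories: the called base (A, C, G, U) or "indel". A deletion
## spanning a position, or an insertion immediately following it, maps the
## position to "indel" (the insertion overrides the base call, so each read
## contributes one category per position). Intron (N) gaps leave positions
## uncovered. This contract differs from samtools-style pileups, which count
## insertions in addition to the base call, so the pileup is built here by
## walking each read's CIGAR.

base_code <- function(chars) {
  code <- match(chartr("Tt", "Uu", toupper(chars)), CATEGORIES[1:4])
  code  # NA for ambiguous bases (treated as uncovered)
}

#' Per-read basecall category matrix over a region
#'
#' @param reads a [drs_reads()] tibble with `seq`.
#' @param chrom,start,end region (0-based half-open).
#' @return integer matrix (reads x positions) with values 0 (uncovered) or
#'   1..5 indexing `A, C, G, U, indel`.
#' @export
read_category_matrix <- function(reads, chrom, start, end) {
  check_interval(start, end, "region")
  width <- end - start
  cm <- matrix(0L, nrow(reads), width)
  onreg <- which(reads$chrom == chrom & reads$start < end & reads$end > start)
  ops_all <- cigar_ops(reads$cigar[onreg])
  for (k in seq_along(onreg)) {
    i <- onreg[k]
    if (is.na(reads$seq[i]) || reads$seq[i] == "*") {
      stopf("read '%s' lacks a query sequence; cannot build basecall profile",
            reads$read_id[i])
    }
    co <- ops_all[[k]]
    rpos <- reads$start[i]; qpos <- 1L
    row <- cm[i, ]
    for (j in seq_along(co$op)) {
      op <- co$op[j]; len <- co$len[j]
      if (op %in% c("M", "=", "X")) {
        p0 <- max(rpos, start); p1 <- min(rpos + len, end)
        if (p1 > p0) {
          qoff <- qpos + (p0 - rpos)
          q <- strsplit(substr(reads$seq[i], qoff, qoff + (p1 - p0) - 1L),
                        "")[[1]]
          code <- base_code(q)
          idx <- (p0 - start + 1L):(p1 - start)
          row[idx] <- ifelse(is.na(code), 0L, code)
        }
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        p0 <- max(rpos, start); p1 <- min(rpos + len, end)
        if (p1 > p0) row[(p0 - start + 1L):(p1 - start)] <- 5L
        rpos <- rpos + len
      } else if (op == "I") {
        # indel category at the position immediately preceding the insertion
        p <- rpos - 1L
        if (p >= start && p < end && rpos > reads$start[i]) {
          row[p - start + 1L] <- 5L
        }
        qpos <- qpos + len
      } else if (op == "N") {
        rpos <- rpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      }
    }
    cm[i, ] <- row
  }
  cm
}

# 5 x width count matrix from a category matrix (rows A,C,G,U,indel)
category_counts <- function(cm) {
  out <- matrix(0L, 5L, ncol(cm), dimnames = list(CATEGORIES, NULL))
  for (k in 1:5) out[k, ] <- .colSums(cm == k, nrow(cm), ncol(cm))
  out
}

#' Build per-sample basecall profiles for a region
#'
#' Counts each read's category at every reference position of the region and
#' keeps positions whose pooled coverage (across the samples supplied, i.e.
#' replicates of one condition) meets `min_coverage`.
#'
#' @param reads a [drs_reads()] tibble; replicates distinguished by
#'   `sample_id`.
#' @param chrom,start,end region (0-based half-open).
#' @param min_coverage pooled coverage floor; default 11 (strictly more than
#'   10 reads).
#' @return list with `pos` (0-based positions kept), `samples` (named list
#'   of 5 x n_pos count matrices) and `pooled` (their sum).
#' @export
build_profiles <- function(reads, chrom, start, end, min_coverage = 11L) {
  stopifnot(min_coverage >= 1)
  cm <- read_category_matrix(reads, chrom, start, end)
  ids <- unique(reads$sample_id)
  samples <- lapply(ids, function(s) {
    category_counts(cm[reads$sample_id == s, , drop = FALSE])
  })
  names(samples) <- ids
  pooled <- Reduce(`+`, samples)
  keep <- colSums(pooled) >= min_coverage
  list(pos = (start:(end - 1L))[keep],
       samples = lapply(samples, function(m) m[, keep, drop = FALSE]),
       pooled = pooled[, keep, drop = FALSE])
}
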
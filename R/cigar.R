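## Aligned-read model.
##
## Reads live in an ordinary tibble ("drs_reads"): one row per alignment with
## 0-based half-open reference coordinates, the CIGAR string, the query
## sequence in reference orientation, and optional per-read tags (poly(A)
## tail length, pore channel, start time). Exonic blocks and intron chains
## are derived from the CIGAR on demand.

#' Construct a read table
#'
#' @param read_id,sample_id,chrom,strand character vectors.
#' @param start 0-based inclusive alignment start on the reference.
#' @param cigar CIGAR strings (ops MIDNS=X supported).
#' @param seq query sequence in reference orientation, or NA.
#' @param tail_length poly(A) tail estimate in nt, or NA.
#' @param channel pore channel, or NA.
#' @param start_time sequencing start time in seconds, or NA.
#' @return tibble with class `drs_reads`; `end` is computed from the CIGAR.
#' @export
drs_reads <- function(read_id, sample_id, chrom, start, strand, cigar,
                      seq = NA_character_, tail_length = NA_real_,
                      channel = NA_integer_, start_time = NA_real_) {
  n <- length(read_id)
  x <- tibble(
    read_id = as.character(read_id),
    sample_id = rep_len(as.character(sample_id), n),
    chrom = rep_len(as.character(chrom), n),
    start = as.integer(start),
    strand = rep_len(as.character(strand), n),
    cigar = as.character(cigar),
    seq = rep_len(as.character(seq), n),
    tail_length = rep_len(as.numeric(tail_length), n),
    channel = rep_len(as.integer(channel), n),
    start_time = rep_len(as.numeric(start_time), n)
  )
  x$end <- x$start + cigar_ref_length(x$cigar)
  check_interval(x$start, x$end, "read alignment")
  if (!all(x$strand %in% c("+", "-"))) stopf("read strand must be '+' or '-'")
  class(x) <- c("drs_reads", class(x))
  x[, c("read_id", "sample_id", "chrom", "start", "end", "strand", "cigar",
        "seq", "tail_length", "channel", "start_time")]
}

# parse CIGAR strings into list of list(len = int vector, op = char vector)
cigar_ops <- function(cigar) {
  lens <- regmatches(cigar, gregexpr("[0-9]+", cigar))
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))
  Map(function(l, o) list(len = as.integer(l), op = o), lens, ops)
}

# reference-consumed length of each CIGAR (M, D, N, =, X)
cigar_ref_length <- function(cigar) {
  vapply(cigar_ops(cigar), function(co) {
    sum(co$len[co$op %in% c("M", "D", "N", "=", "X")])
  }, integer(1))
}

# exonic blocks per read: reference segments between N gaps,
# as a list of 2-column (start, end) matrices, 0-based half-open
read_blocks_one <- function(start, co) {
  pos <- start
  bs <- integer(0); be <- integer(0)
  cur_start <- pos
  has_block <- FALSE
  for (i in seq_along(co$op)) {
    op <- co$op[i]; len <- co$len[i]
    if (op %in% c("M", "D", "=", "X")) {
      if (!has_block) { cur_start <- pos; has_block <- TRUE }
      pos <- pos + len
    } else if (op == "N") {
      if (has_block) { bs <- c(bs, cur_start); be <- c(be, pos); has_block <- FALSE }
      pos <- pos + len
    }
  }
  if (has_block) { bs <- c(bs, cur_start); be <- c(be, pos) }
  cbind(start = bs, end = be)
}

#' Exonic blocks of each read
#'
#' @param reads a `drs_reads` tibble.
#' @return list (one per read) of 2-column matrices of 0-based half-open
#'   reference segments separated by intron (`N`) gaps.
#' @export
read_blocks <- function(reads) {
  Map(read_blocks_one, reads$start, cigar_ops(reads$cigar))
}

#' Intron chain of each read
#'
#' @inheritParams read_blocks
#' @return list of 2-column matrices of intron (N gap) intervals; 0-row
#'   matrix for intronless reads.
#' @export
read_introns <- function(reads) {
  lapply(read_blocks(reads), function(b) {
    if (nrow(b) < 2L) return(cbind(start = integer(0), end = integer(0)))
    cbind(start = unname(b[-nrow(b), "end"]), end = unname(b[-1L, "start"]))
  })
}

#' Aligned length of each read (sum of exonic block lengths)
#' @inheritParams read_blocks
#' @return integer vector.
#' @export
aligned_length <- function(reads) {
  vapply(read_blocks(reads), function(b) sum(b[, "end"] - b[, "start"]),
         integer(1))
}

#' Strand-aware 3' end position of each read
#'
#' For "+" reads this is `end - 1` (the last aligned base); for "-" reads it
#' is `start`.
#' @inheritParams read_blocks
#' @return integer vector of 0-based positions.
#' @export
three_prime_pos <- function(reads) {
  ifelse(reads$strand == "+", reads$end - 1L, reads$start)
}

#' Strand-aware 5' end position of each read
#' @inheritParams read_blocks
#' @return integer vector of 0-based positions.
#' @export
five_prime_pos <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}
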
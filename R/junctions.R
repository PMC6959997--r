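## Splice-junction extraction, U2/U12 classification by PWM score, intron
## chain set comparison and frameshift (NMD candidate) screening.

#' Extract splice junctions from read intron chains
#'
#' Unique (donor, acceptor, strand) junctions with supporting read counts.
#' Junctions at the same coordinates on opposite strands are counted
#' independently. The donor is the intron boundary at the 5' side of the
#' transcript (the intron start on "+", the intron end on "-").
#'
#' @param reads a [drs_reads()] tibble.
#' @return tibble `chrom`, `start`, `end` (intron, 0-based half-open),
#'   `strand`, `donor`, `acceptor` (0-based first/last intron base, strand
#'   aware), `count`.
#' @export
extract_junctions <- function(reads) {
  introns <- read_introns(reads)
  ni <- vapply(introns, nrow, integer(1))
  if (sum(ni) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), donor = integer(0),
                  acceptor = integer(0), count = integer(0)))
  }
  m <- do.call(rbind, introns)
  jx <- tibble(chrom = rep(reads$chrom, ni), start = m[, "start"],
               end = m[, "end"], strand = rep(reads$strand, ni)) %>%
    group_by(.data$chrom, .data$start, .data$end, .data$strand) %>%
    summarise(count = n(), .groups = "drop")
  jx$donor <- ifelse(jx$strand == "+", jx$start, jx$end - 1L)
  jx$acceptor <- ifelse(jx$strand == "+", jx$end - 1L, jx$start)
  arrange(jx, .data$chrom, .data$start, .data$strand) %>%
    select("chrom", "start", "end", "strand", "donor", "acceptor", "count")
}

#' Flanking sequences of a junction
#'
#' Donor window: 3 exonic nt to 10 intronic nt around the donor site (13
#' nt); acceptor window: 14 intronic nt to 3 exonic nt (17 nt); both in
#' transcript orientation.
#'
#' @param junction one row of an [extract_junctions()] tibble.
#' @param genome named character vector.
#' @return list with `donor_seq` (13 nt), `acceptor_seq` (17 nt) and
#'   `canonical` (intron starts GT and ends AG, transcript sense).
#' @export
junction_flanks <- function(junction, genome) {
  ch <- junction$chrom; s <- junction$start; e <- junction$end
  if (junction$strand == "+") {
    donor_seq <- genome_seq(genome, ch, s - 3L, s + 10L)
    acceptor_seq <- genome_seq(genome, ch, e - 14L, e + 3L)
    intron5 <- genome_seq(genome, ch, s, s + 2L)
    intron3 <- genome_seq(genome, ch, e - 2L, e)
  } else {
    donor_seq <- genome_seq(genome, ch, e - 10L, e + 3L, strand = "-")
    acceptor_seq <- genome_seq(genome, ch, s - 3L, s + 14L, strand = "-")
    intron5 <- genome_seq(genome, ch, e - 2L, e, strand = "-")
    intron3 <- genome_seq(genome, ch, s, s + 2L, strand = "-")
  }
  list(donor_seq = donor_seq, acceptor_seq = acceptor_seq,
       canonical = intron5 == "GT" && intron3 == "AG")
}

# normalise a positive raw PWM score into the 50-100 range; non-positive
# scores are not normalised (returned NA)
normalise_pwm_score <- function(score, max_score) {
  ifelse(score > 0, 50 + 50 * score / max_score, NA_real_)
}

#' Classify a splice junction as U2, U12 or unclassified
#'
#' Scores the donor and acceptor flanking windows against the four supplied
#' PWMs. Positive raw scores are normalised into the range 50-100 by linear
#' scaling against each PWM's maximum attainable score. Junctions with
#' normalised U12 donor score > 75 and U12 acceptor score > 65 are U12;
#' otherwise junctions with U2 donor and acceptor scores > 60 are U2; the
#' rest are unclassified.
#'
#' @param junction one row of an [extract_junctions()] tibble.
#' @param genome named character vector.
#' @param pwms named list with elements `u2_donor`, `u2_acceptor`,
#'   `u12_donor`, `u12_acceptor` ([pwm()] objects of widths 13, 17, 13,
#'   17).
#' @return list with `class` (`"U2"`, `"U12"`, `"unclassified"`),
#'   `canonical`, and the four normalised scores.
#' @export
classify_junction <- function(junction, genome, pwms) {
  need <- c("u2_donor", "u2_acceptor", "u12_donor", "u12_acceptor")
  if (!all(need %in% names(pwms))) stopf("pwms must contain %s",
                                         paste(need, collapse = ", "))
  fl <- junction_flanks(junction, genome)
  score1 <- function(seq, p) {
    if (nchar(seq) != p$width) {
      stopf("PWM '%s' width %d does not match window length %d",
            p$name, p$width, nchar(seq))
    }
    raw <- scan_pwm(seq, p, threshold = -Inf)$score[1]
    normalise_pwm_score(raw, max_pwm_score(p))
  }
  sc <- c(u2_donor = score1(fl$donor_seq, pwms$u2_donor),
          u2_acceptor = score1(fl$acceptor_seq, pwms$u2_acceptor),
          u12_donor = score1(fl$donor_seq, pwms$u12_donor),
          u12_acceptor = score1(fl$acceptor_seq, pwms$u12_acceptor))
  cls <- if (!is.na(sc["u12_donor"]) && !is.na(sc["u12_acceptor"]) &&
             sc["u12_donor"] > 75 && sc["u12_acceptor"] > 65) {
    "U12"
  } else if (!is.na(sc["u2_donor"]) && !is.na(sc["u2_acceptor"]) &&
             sc["u2_donor"] > 60 && sc["u2_acceptor"] > 60) {
    "U2"
  } else {
    "unclassified"
  }
  list(class = cls, canonical = fl$canonical, scores = sc)
}

#' Unique intron-chain sets per source and their intersections
#'
#' Each source (a read table or a [gene_models()] annotation) contributes
#' the set of unique ordered intron chains; intronless reads/transcripts
#' are not counted. All intersection sizes over source subsets are
#' reported, UpSet style (exclusive membership patterns).
#'
#' @param sources named list of [drs_reads()] tibbles and/or
#'   [gene_models()] objects.
#' @return list with `chains` (named list of character vectors, one chain
#'   string per unique chain) and `intersections` (tibble: one row per
#'   membership pattern with `sources` and `n`).
#' @export
intron_chain_sets <- function(sources) {
  if (length(sources) == 0L) stopf("at least one source required")
  chain_of <- function(chrom, strand, introns) {
    keep <- vapply(introns, nrow, integer(1)) > 0L
    vapply(which(keep), function(i) {
      m <- introns[[i]]
      paste0(chrom[i], ":", strand[i], ":",
             paste(sprintf("%d-%d", m[, "start"], m[, "end"]), collapse = ";"))
    }, "")
  }
  chains <- lapply(sources, function(s) {
    if (inherits(s, "gene_models")) {
      tx <- s$transcripts
      introns <- lapply(tx$exons, function(e) {
        if (nrow(e) < 2L) return(cbind(start = integer(0), end = integer(0)))
        cbind(start = e[-nrow(e), 2], end = e[-1L, 1])
      })
      unique(chain_of(tx$chrom, tx$strand, introns))
    } else {
      unique(chain_of(s$chrom, s$strand, read_introns(s)))
    }
  })
  all_chains <- unique(unlist(chains, use.names = FALSE))
  member <- vapply(chains, function(cs) all_chains %in% cs,
                   logical(length(all_chains)))
  member <- matrix(member, nrow = length(all_chains),
                   dimnames = list(NULL, names(sources)))
  pattern <- apply(member, 1, function(r) {
    paste(names(sources)[r], collapse = "&")
  })
  inter <- tibble(sources = names(table(pattern)),
                  n = as.integer(table(pattern))) %>%
    arrange(dplyr::desc(.data$n))
  list(chains = chains, intersections = inter)
}

#' Screen reads for frameshifting splice patterns (NMD candidates)
#'
#' Retains reads overlapping both the annotated start and stop codon of a
#' transcript, measures the spliced length of the annotated ORF interval
#' along the read's exon structure, and flags reads where that length is
#' not divisible by three (a splicing-induced frameshift relative to the
#' annotation). Transcripts without a CDS are skipped.
#'
#' @param reads a [drs_reads()] tibble.
#' @param models a [gene_models()] object (CDS intervals span start to stop
#'   codon).
#' @return tibble per (read, transcript) pair evaluated: `read_id`,
#'   `transcript_id`, `gene_id`, `orf_length`, `frameshift` (logical).
#' @export
nmd_frameshift_screen <- function(reads, models) {
  tx <- models$transcripts
  blocks <- read_blocks(reads)
  rows <- list()
  for (t in seq_len(nrow(tx))) {
    cd <- tx$cds[[t]]
    if (nrow(cd) == 0L) next
    cds0 <- min(cd[, 1]); cds1 <- max(cd[, 2])
    # start/stop codons: first/last 3 nt of the CDS span, strand aware
    if (tx$strand[t] == "+") {
      start_cod <- c(cds0, cds0 + 3L); stop_cod <- c(cds1 - 3L, cds1)
    } else {
      start_cod <- c(cds1 - 3L, cds1); stop_cod <- c(cds0, cds0 + 3L)
    }
    cand <- which(reads$chrom == tx$chrom[t] & reads$strand == tx$strand[t] &
                    reads$start <= cds0 & reads$end >= cds1)
    for (i in cand) {
      b <- blocks[[i]]
      ov <- function(int) sum(pmax(0L, pmin(b[, "end"], int[2]) -
                                     pmax(b[, "start"], int[1])))
      if (ov(start_cod) < 3L || ov(stop_cod) < 3L) next  # codon not covered
      orf_len <- ov(c(cds0, cds1))
      rows[[length(rows) + 1L]] <- tibble(
        read_id = reads$read_id[i], transcript_id = tx$transcript_id[t],
        gene_id = tx$gene_id[t], orf_length = orf_len,
        frameshift = orf_len %% 3L != 0L)
    }
  }
  bind_rows(rows)
}
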
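## 3' end and poly(A) tail statistics: per-gene differential 3' position
## profiles with shift localisation, tail-length KS tests, 3' peak calling,
## nearest-peak distances, internal-priming screening, over-splitting
## detection and isoform collapsing.

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_x - ECDF_y|`; p-value from the asymptotic two-sample
#' Kolmogorov distribution by default (robust to the heavy ties of
#' single-base 3' end data), or the exact distribution for small untied
#' samples.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact use the exact null distribution (default `FALSE`).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y, exact = FALSE) {
  if (length(x) == 0L || length(y) == 0L) stopf("KS test requires non-empty samples")
  kt <- suppressWarnings(ks.test(x, y, exact = exact))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Differential 3' end usage for one gene
#'
#' KS test on the two conditions' 3' end coordinates plus localisation of
#' the change: the normalised single-base histogram of the reference
#' condition is subtracted from the mutant's, and the minimum/maximum of the
#' difference profile give the positions of most reduced and most increased
#' usage. Ties are broken toward the reference condition's modal 3' end,
#' then toward the smaller coordinate. `delta` is the strand-aware signed
#' distance from the reduced to the increased position: negative values are
#' proximal shifts (toward the 5' end of the gene).
#'
#' @param ends_ref,ends_mut integer 3' end positions per condition.
#' @param strand gene strand ("+" or "-").
#' @param smooth_sigma Gaussian bandwidth (nt) applied to the difference
#'   profile before locating its extrema (default 5 nt); suppresses
#'   single-base count noise at the cost of a small outward bias that grows
#'   with the bandwidth. Set 0 to disable.
#' @return list with `D`, `p`, `pos_reduced`, `pos_increased`, `delta`,
#'   `n_ref`, `n_mut`.
#' @export
diff_three_prime <- function(ends_ref, ends_mut, strand = "+",
                             smooth_sigma = 5) {
  if (length(ends_ref) == 0L || length(ends_mut) == 0L) {
    return(list(D = NA_real_, p = NA_real_, pos_reduced = NA_integer_,
                pos_increased = NA_integer_, delta = NA_real_,
                n_ref = length(ends_ref), n_mut = length(ends_mut),
                untestable = TRUE))
  }
  ks <- ks_two_sample(ends_ref, ends_mut)
  lo <- min(ends_ref, ends_mut); hi <- max(ends_ref, ends_mut)
  pos <- lo:hi
  h_ref <- tabulate(ends_ref - lo + 1L, nbins = hi - lo + 1L)
  h_mut <- tabulate(ends_mut - lo + 1L, nbins = hi - lo + 1L)
  diff <- h_mut / sum(h_mut) - h_ref / sum(h_ref)
  if (smooth_sigma > 0 && length(diff) > 2L) {
    diff <- smooth_gaussian(diff, smooth_sigma)
  }
  ref_mode <- pos[which.max(h_ref)]
  pick <- function(cand) {
    d <- abs(cand - ref_mode)
    cand[d == min(d)][1]
  }
  pos_inc <- pick(pos[diff == max(diff)])
  pos_red <- pick(pos[diff == min(diff)])
  delta <- if (strand == "+") pos_inc - pos_red else pos_red - pos_inc
  list(D = ks$D, p = ks$p, pos_reduced = pos_red, pos_increased = pos_inc,
       delta = delta, n_ref = length(ends_ref), n_mut = length(ends_mut),
       untestable = FALSE)
}

#' Test all genes for 3' end shifts between conditions
#'
#' Runs [diff_three_prime()] per gene with reads assigned by
#' [assign_reads_to_genes()], BH-corrects across genes, and flags genes with
#' `q < fdr` and `|delta| > min_shift`.
#'
#' @param reads_ref,reads_mut reads per condition.
#' @param models a [gene_models()] object.
#' @param min_shift minimum absolute shift in nt (default 13, strict `>`).
#' @param fdr BH threshold (default 0.05).
#' @param min_reads minimum reads per condition per gene (default 10).
#' @return tibble per testable gene with KS statistics, shift positions,
#'   `delta`, `q` and `sig`.
#' @export
test_three_prime_shifts <- function(reads_ref, reads_mut, models,
                                    min_shift = 13, fdr = 0.05,
                                    min_reads = 10L) {
  a_ref <- assign_reads_to_genes(reads_ref, models)
  a_mut <- assign_reads_to_genes(reads_mut, models)
  e_ref <- three_prime_pos(reads_ref); e_mut <- three_prime_pos(reads_mut)
  genes <- models$genes
  rows <- lapply(seq_len(nrow(genes)), function(g) {
    gid <- genes$gene_id[g]
    er <- e_ref[a_ref$read[a_ref$gene_id == gid]]
    em <- e_mut[a_mut$read[a_mut$gene_id == gid]]
    if (length(er) < min_reads || length(em) < min_reads) return(NULL)
    d <- diff_three_prime(er, em, genes$strand[g])
    tibble(gene_id = gid, chrom = genes$chrom[g], strand = genes$strand[g],
           n_ref = d$n_ref, n_mut = d$n_mut, D = d$D, p = d$p,
           pos_reduced = d$pos_reduced, pos_increased = d$pos_increased,
           delta = d$delta)
  })
  res <- bind_rows(rows)
  if (nrow(res) == 0L) return(res)
  res$q <- bh_correct(res$p)
  res$sig <- res$q < fdr & abs(res$delta) > min_shift
  res
}

#' Upper-tail hypergeometric enrichment test
#'
#' Tests whether `flagged` genes are enriched for `annotated` genes against
#' a `background` population (e.g. all expressed genes).
#'
#' @param flagged,annotated,background character vectors of gene ids;
#'   `flagged` and `annotated` must be subsets of `background`.
#' @return list with `overlap`, `expected` and `p`
#'   (`P(X >= overlap)`).
#' @export
enrichment_hypergeom <- function(flagged, annotated, background) {
  if (length(background) == 0L) stopf("empty background population")
  if (!all(flagged %in% background) || !all(annotated %in% background)) {
    stopf("flagged and annotated gene sets must be subsets of the background")
  }
  flagged <- unique(flagged); annotated <- unique(annotated)
  background <- unique(background)
  k <- length(intersect(flagged, annotated))
  m <- length(annotated); n <- length(background) - m
  s <- length(flagged)
  list(overlap = k, expected = s * m / length(background),
       p = phyper(k - 1L, m, n, s, lower.tail = FALSE))
}

#' Per-gene poly(A) tail length comparison
#'
#' KS test on per-read tail-length tags between conditions, per gene, with
#' BH correction across genes. Genes with fewer than `min_reads` tagged
#' reads in either condition are skipped with a warning.
#'
#' @param reads_ref,reads_mut reads per condition with `tail_length` tags.
#' @param models a [gene_models()] object.
#' @param min_reads minimum tagged reads per condition (default 20).
#' @param fdr BH threshold (default 0.05).
#' @return tibble per tested gene: `gene_id`, `n_ref`, `n_mut`,
#'   `median_ref`, `median_mut`, `D`, `p`, `q`, `sig`.
#' @export
test_tail_lengths <- function(reads_ref, reads_mut, models, min_reads = 20L,
                              fdr = 0.05) {
  a_ref <- assign_reads_to_genes(reads_ref, models)
  a_mut <- assign_reads_to_genes(reads_mut, models)
  skipped <- character(0)
  rows <- lapply(models$genes$gene_id, function(gid) {
    tr <- reads_ref$tail_length[a_ref$read[a_ref$gene_id == gid]]
    tm <- reads_mut$tail_length[a_mut$read[a_mut$gene_id == gid]]
    tr <- tr[!is.na(tr)]; tm <- tm[!is.na(tm)]
    if (length(tr) < min_reads || length(tm) < min_reads) {
      skipped <<- c(skipped, gid)
      return(NULL)
    }
    ks <- ks_two_sample(tr, tm)
    tibble(gene_id = gid, n_ref = length(tr), n_mut = length(tm),
           median_ref = median(tr), median_mut = median(tm),
           D = ks$D, p = ks$p)
  })
  if (length(skipped) > 0L) {
    warnf("%d gene(s) skipped for insufficient tagged reads", length(skipped))
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0L) return(res)
  res$q <- bh_correct(res$p)
  res$sig <- res$q < fdr
  res
}

#' Call 3' end peaks
#'
#' Single-base 3' end positions supported by at least `min_reads` reads,
#' per chromosome and strand.
#'
#' @param reads a [drs_reads()] tibble.
#' @param min_reads support threshold (default 3).
#' @return tibble `chrom`, `pos` (0-based), `strand`, `n`.
#' @export
call_end_peaks <- function(reads, min_reads = 3L) {
  stopifnot(min_reads >= 1)
  tibble(chrom = reads$chrom, pos = three_prime_pos(reads),
         strand = reads$strand) %>%
    group_by(.data$chrom, .data$strand, .data$pos) %>%
    summarise(n = n(), .groups = "drop") %>%
    filter(.data$n >= min_reads) %>%
    arrange(.data$chrom, .data$pos) %>%
    select("chrom", "pos", "strand", "n")
}

#' Signed distance from each query position to the nearest target
#'
#' Matching is per chromosome and strand; the signed distance is
#' `target - query` (0 when coincident, negative when the nearest target is
#' upstream in genomic coordinates). Queries on a chromosome/strand absent
#' from the targets get `NA`.
#'
#' @param query,target tibbles with `chrom`, `pos`, `strand`.
#' @return `query` with a `distance` column appended.
#' @export
nearest_distance <- function(query, target) {
  if (nrow(query) == 0L || nrow(target) == 0L) {
    stopf("both query and target peak sets must be non-empty")
  }
  key <- function(x) paste(x$chrom, x$strand)
  tsplit <- split(target$pos, key(target))
  dist <- vapply(seq_len(nrow(query)), function(i) {
    tp <- tsplit[[key(query[i, ])]]
    if (is.null(tp)) return(NA_real_)
    d <- tp - query$pos[i]
    d[which.min(abs(d))]
  }, numeric(1))
  query$distance <- dist
  query
}

#' Screen for potential internal-priming sites at oligo(A) runs
#'
#' Locates runs of six or more consecutive adenosines (transcribed-strand
#' sense; runs longer than six count once, anchored at their first base)
#' within annotated CDS regions, and counts reads whose 3' end falls within
#' `window` nt of each run.
#'
#' @param reads a [drs_reads()] tibble.
#' @param models a [gene_models()] object.
#' @param genome named character vector.
#' @param window distance window in nt (default 20).
#' @return tibble per oligo(A) run: `gene_id`, `chrom`, `start` (anchor,
#'   0-based), `strand`, `terminal_exon`, `n_reads` and per-sample support
#'   `n_samples`.
#' @export
internal_priming_screen <- function(reads, models, genome, window = 20L) {
  stopifnot(window >= 0)
  ends <- three_prime_pos(reads)
  tx <- models$transcripts
  runs <- lapply(seq_len(nrow(tx)), function(i) {
    cd <- tx$cds[[i]]
    if (nrow(cd) == 0L) return(NULL)
    ex <- tx$exons[[i]]
    last_exon <- if (tx$strand[i] == "+") ex[nrow(ex), , drop = FALSE] else ex[1, , drop = FALSE]
    found <- lapply(seq_len(nrow(cd)), function(e) {
      s <- genome_seq(genome, tx$chrom[i], cd[e, 1], cd[e, 2])
      pat <- if (tx$strand[i] == "+") "A{6,}" else "T{6,}"
      m <- gregexpr(pat, s)[[1]]
      if (m[1] == -1L) return(NULL)
      tibble(gene_id = tx$gene_id[i], chrom = tx$chrom[i],
             start = unname(cd[e, 1]) + as.integer(m) - 1L,
             strand = tx$strand[i])
    })
    found <- bind_rows(found)
    if (nrow(found) == 0L) return(NULL)
    found$terminal_exon <- found$start >= last_exon[1, 1] &
      found$start < last_exon[1, 2]
    found
  })
  runs <- distinct(bind_rows(runs))
  if (nrow(runs) == 0L) return(runs)
  runs$n_reads <- 0L
  runs$n_samples <- 0L
  for (i in seq_len(nrow(runs))) {
    hit <- reads$chrom == runs$chrom[i] & reads$strand == runs$strand[i] &
      abs(ends - runs$start[i]) <= window
    runs$n_reads[i] <- sum(hit)
    runs$n_samples[i] <- length(unique(reads$sample_id[hit]))
  }
  runs
}

#' Detect candidate over-split read pairs
#'
#' Over-splitting is an instrument artefact in which the signal from one
#' molecule is split into consecutive reads from the same pore that align
#' adjacently. Reads are sorted by start time within each (sample, channel);
#' a consecutive pair is flagged when the second read's alignment start lies
#' within `[min_gap, max_gap]` nt of the first read's alignment end on the
#' same chromosome and strand.
#'
#' @param reads a [drs_reads()] tibble with `channel` and `start_time`.
#' @param min_gap,max_gap genomic gap bounds in nt (defaults -10 and 1000).
#' @return list with `pairs` (tibble of flagged pairs with `gap`),
#'   `n_pairs` (consecutive pairs examined) and `frac_reads` (fraction of
#'   reads in a flagged pair).
#' @export
detect_oversplitting <- function(reads, min_gap = -10L, max_gap = 1000L) {
  miss <- is.na(reads$channel) | is.na(reads$start_time)
  if (any(miss)) {
    stopf("sample '%s' lacks channel/start_time tags required for over-splitting detection",
          reads$sample_id[which(miss)[1]])
  }
  ord <- order(reads$sample_id, reads$channel, reads$start_time)
  r <- reads[ord, ]
  i <- seq_len(nrow(r) - 1L)
  consec <- r$sample_id[i] == r$sample_id[i + 1L] &
    r$channel[i] == r$channel[i + 1L]
  gap <- r$start[i + 1L] - r$end[i]
  flag <- consec & r$chrom[i] == r$chrom[i + 1L] &
    r$strand[i] == r$strand[i + 1L] & gap >= min_gap & gap <= max_gap
  pairs <- tibble(sample_id = r$sample_id[i][flag],
                  channel = r$channel[i][flag],
                  read_id1 = r$read_id[i][flag],
                  read_id2 = r$read_id[i + 1L][flag],
                  gap = gap[flag])
  list(pairs = pairs, n_pairs = sum(consec),
       frac_reads = if (nrow(reads) > 0) 2 * nrow(pairs) / nrow(reads) else 0)
}

#' Collapse reads into isoform clusters
#'
#' Reads are grouped by exact intron-chain identity, and each group is
#' subdivided by 3' end position using Gaussian-smoothed local-minimum
#' clustering (default sigma 100 nt, no minimum cluster size). The longest
#' aligned read of each cluster is its representative.
#'
#' @param reads a [drs_reads()] tibble.
#' @param sigma 3' clustering bandwidth in nt (default 100).
#' @return tibble per read: `read_id`, `cluster`, `representative`
#'   (logical).
#' @export
collapse_isoforms <- function(reads, sigma = 100) {
  introns <- read_introns(reads)
  chain <- vapply(introns, function(m) {
    paste(sprintf("%d-%d", m[, "start"], m[, "end"]), collapse = ";")
  }, "")
  key <- paste(reads$chrom, reads$strand, chain, sep = "|")
  alen <- aligned_length(reads)
  cluster <- character(nrow(reads))
  for (k in unique(key)) {
    idx <- which(key == k)
    cl <- cluster_three_prime_ends(reads[idx, ], sigma = sigma,
                                   min_cluster = 1L)
    cluster[idx] <- paste0(match(k, unique(key)), ".",
                           sub("^pA", "", cl$assignment))
  }
  rep_flag <- logical(nrow(reads))
  for (cid in unique(cluster)) {
    idx <- which(cluster == cid)
    rep_flag[idx[which.max(alen[idx])]] <- TRUE
  }
  tibble(read_id = reads$read_id, cluster = cluster,
         representative = rep_flag)
}
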
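## The differential basecall-error m6A caller.
##
## Pipeline per reference position with sufficient coverage in both
## conditions: 2 x 5 G-test on condition-aggregated basecall profiles; a
## p < 0.05 prefilter; replicate homogeneity filtering (sites where the sum
## of within-condition homogeneity G statistics exceeds the between-condition
## G are dropped); Benjamini-Hochberg correction over surviving positions;
## and a Haldane-corrected log2 fold change in the mismatch:match ratio,
## oriented so values > 1 mean the error rate is reduced in the mutant (the
## modification was present in the reference condition).

regions_from_reads <- function(...) {
  reads <- bind_rows(...)
  reads %>%
    group_by(.data$chrom) %>%
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
}

#' Call differential basecall-error (m6A) sites between two conditions
#'
#' @param reads_ref reads from the modification-positive condition
#'   (replicates distinguished by `sample_id`).
#' @param reads_mut reads from the modification-deficient (writer mutant)
#'   condition.
#' @param genome named character vector of reference sequences.
#' @param regions optional tibble (`chrom`, `start`, `end`) of regions to
#'   test, e.g. gene loci; defaults to the per-chromosome span of the reads.
#'   Regions are processed independently; BH correction is applied jointly.
#' @param min_coverage pooled per-condition coverage floor (default 11,
#'   i.e. strictly more than 10 reads).
#' @param p_prefilter p-value prefilter applied before the homogeneity test
#'   (default 0.05).
#' @param fdr BH threshold for significance (default 0.05).
#' @param min_lfc absolute log2 fold-change threshold (default 1).
#' @return tibble with one row per tested position: `chrom`, `pos` (0-based),
#'   `ref_base`, per-condition coverage and error counts, `G`, `df`, `p`,
#'   `hom_G_sum`, `hom_filtered`, `q`, `log2fc`, `direction`
#'   (`reduced_error_in_mutant` / `increased_error_in_mutant`) and `sig`.
#' @export
call_error_sites <- function(reads_ref, reads_mut, genome, regions = NULL,
                             min_coverage = 11L, p_prefilter = 0.05,
                             fdr = 0.05, min_lfc = 1) {
  if (is.null(regions)) regions <- regions_from_reads(reads_ref, reads_mut)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    call_error_sites_region(reads_ref, reads_mut, genome,
                            regions$chrom[i], regions$start[i],
                            regions$end[i], min_coverage, p_prefilter)
  })
  res <- bind_rows(out)
  if (nrow(res) == 0L) {
    warnf("no positions passed the coverage floor; empty result")
    return(res)
  }
  # BH across every G-tested position; the prefilter and homogeneity filter
  # then gate which corrected positions may be called significant
  res$q <- NA_real_
  tested <- !is.na(res$p)
  res$q[tested] <- bh_correct(res$p[tested])
  surv <- tested & res$p < p_prefilter & !res$hom_filtered
  res$sig <- surv & res$q < fdr & abs(res$log2fc) > min_lfc
  res
}

call_error_sites_region <- function(reads_ref, reads_mut, genome, chrom,
                                    start, end, min_coverage, p_prefilter) {
  if (!chrom %in% names(genome)) stopf("region chromosome '%s' not in reference", chrom)
  end <- min(end, nchar(genome[[chrom]]))
  pr <- build_profiles(reads_ref[reads_ref$chrom == chrom, ], chrom, start,
                       end, min_coverage)
  pm <- build_profiles(reads_mut[reads_mut$chrom == chrom, ], chrom, start,
                       end, min_coverage)
  pos <- intersect(pr$pos, pm$pos)
  if (length(pos) == 0L) return(tibble())
  ir <- match(pos, pr$pos); im <- match(pos, pm$pos)
  cref <- pr$pooled[, ir, drop = FALSE]
  cmut <- pm$pooled[, im, drop = FALSE]
  gt <- g_test_two_cond(cref, cmut)
  # homogeneity statistics (needed only where the prefilter passes)
  hom <- g_hom_vec(lapply(pr$samples, function(m) m[, ir, drop = FALSE])) +
    g_hom_vec(lapply(pm$samples, function(m) m[, im, drop = FALSE]))
  ref_base <- strsplit(substr(genome[[chrom]], min(pos) + 1L, max(pos) + 1L),
                       "")[[1]][pos - min(pos) + 1L]
  ref_code <- base_code(ref_base)
  m_ref <- cref[cbind(ref_code, seq_along(pos))]
  m_mut <- cmut[cbind(ref_code, seq_along(pos))]
  cov_ref <- colSums(cref); cov_mut <- colSums(cmut)
  mm_ref <- cov_ref - m_ref; mm_mut <- cov_mut - m_mut
  lfc <- haldane_log2fc(mm_ref, m_ref, mm_mut, m_mut)
  prefilt <- !is.na(gt$p) & gt$p < p_prefilter
  tibble(chrom = chrom, pos = pos, ref_base = chartr("T", "U", ref_base),
         cov_ref = cov_ref, cov_mut = cov_mut,
         err_ref = mm_ref, err_mut = mm_mut,
         G = gt$G, df = gt$df, p = gt$p,
         hom_G_sum = ifelse(prefilt, hom, NA_real_),
         hom_filtered = prefilt & hom > gt$G,
         log2fc = lfc,
         direction = ifelse(lfc > 0, "reduced_error_in_mutant",
                            "increased_error_in_mutant"))
}

#' Expand and merge called sites, attaching genomic sequence
#'
#' Sites are expanded by `pad` nt in each direction, clipped to the
#' reference bounds (with a warning), and overlapping or adjacent intervals
#' are unioned. The genome sequence of each merged interval is attached
#' (reverse-complemented for "-" strand sites).
#'
#' @param sites tibble with `chrom`, `pos` (0-based single-base sites) and
#'   optionally `strand`.
#' @param genome named character vector of reference sequences.
#' @param pad expansion in nt (default 5).
#' @return tibble `chrom`, `start`, `end`, `strand`, `n_sites`, `seq`.
#' @export
merge_sites <- function(sites, genome, pad = 5L) {
  stopifnot(pad >= 0)
  if (nrow(sites) == 0L) {
    return(tibble(chrom = character(0), start = integer(0), end = integer(0),
                  strand = character(0), n_sites = integer(0),
                  seq = character(0)))
  }
  strand <- if ("strand" %in% names(sites)) sites$strand else "+"
  start <- sites$pos - pad
  end <- sites$pos + 1L + pad
  lens <- nchar(genome)[sites$chrom]
  if (any(start < 0 | end > lens)) {
    warnf("%d padded site(s) clipped to reference bounds",
          sum(start < 0 | end > lens))
  }
  start <- pmax(start, 0L)
  end <- pmin(end, lens)
  gr <- GenomicRanges::GRanges(sites$chrom, IRanges::IRanges(start + 1L, end),
                               strand = strand)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE)
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(red)),
                start = GenomicRanges::start(red) - 1L,
                end = GenomicRanges::end(red),
                strand = as.character(GenomicRanges::strand(red)),
                n_sites = lengths(S4Vectors::mcols(red)$revmap))
  out$strand[out$strand == "*"] <- "+"
  out$seq <- vapply(seq_len(nrow(out)), function(i) {
    genome_seq(genome, out$chrom[i], out$start[i], out$end[i], out$strand[i])
  }, "")
  arrange(out, .data$chrom, .data$start)
}

#' Bootstrapped subsampling power analysis for site detection
#'
#' For each combination of read depth and dilution rate, draws `n_boot`
#' random subsamples of `depth` reads per condition (without replacement),
#' replacing `floor(rate * depth)` of the modification-positive sample's
#' reads with reads from the negative sample to emulate reduced
#' stoichiometry, then reruns the differential-error test on the region.
#' Detection succeeds when any position within `target_pos` is significant
#' (BH q below `fdr` and `|log2fc| > min_lfc`).
#'
#' @param reads_pos,reads_neg reads of the modification-positive and
#'   -negative samples (single replicate each).
#' @param genome named character vector.
#' @param chrom,start,end region tested.
#' @param target_pos 0-based positions counted as the target site/motif.
#' @param depths integer vector of per-condition read depths.
#' @param rates dilution rates in `[0, 1)`.
#' @param n_boot bootstraps per combination (default 500).
#' @param seed RNG seed.
#' @param min_coverage,fdr,min_lfc as in [call_error_sites()].
#' @return tibble `depth`, `rate`, `n_boot`, `detected`, `freq`.
#' @export
subsample_power <- function(reads_pos, reads_neg, genome, chrom, start, end,
                            target_pos, depths, rates = 0, n_boot = 500L,
                            seed = 1L, min_coverage = 11L, fdr = 0.05,
                            min_lfc = 1) {
  if (any(rates < 0 | rates >= 1)) stopf("dilution rates must be in [0, 1)")
  n_pos <- nrow(reads_pos); n_neg <- nrow(reads_neg)
  if (any(depths > n_pos)) {
    stopf("depth %d exceeds the %d reads available in the positive sample",
          max(depths), n_pos)
  }
  if (any(depths > n_neg)) {
    stopf("depth %d exceeds the %d reads available in the negative sample",
          max(depths), n_neg)
  }
  end <- min(end, nchar(genome[[chrom]]))
  cmp <- read_category_matrix(reads_pos, chrom, start, end)
  cmn <- read_category_matrix(reads_neg, chrom, start, end)
  pos_all <- start:(end - 1L)
  ref_base <- strsplit(genome_seq(genome, chrom, start, end), "")[[1]]
  ref_code <- base_code(ref_base)
  target_idx <- which(pos_all %in% target_pos)
  grid <- expand.grid(depth = as.integer(depths), rate = as.numeric(rates))
  with_seed(seed, {
    grid$detected <- vapply(seq_len(nrow(grid)), function(g) {
      d <- grid$depth[g]; r <- grid$rate[g]
      n_repl <- floor(r * d)
      hits <- 0L
      for (b in seq_len(n_boot)) {
        ipos <- sample.int(n_pos, d - n_repl)
        irep <- if (n_repl > 0) sample.int(n_neg, n_repl) else integer(0)
        ineg <- sample.int(n_neg, d)
        c_pos <- category_counts(cmp[ipos, , drop = FALSE]) +
          category_counts(cmn[irep, , drop = FALSE])
        c_neg <- category_counts(cmn[ineg, , drop = FALSE])
        keep <- colSums(c_pos) >= min_coverage & colSums(c_neg) >= min_coverage
        if (!any(keep)) next
        gt <- g_test_two_cond(c_pos[, keep, drop = FALSE],
                              c_neg[, keep, drop = FALSE])
        ok <- !is.na(gt$p)
        if (!any(ok)) next
        q <- rep(NA_real_, length(gt$p))
        q[ok] <- bh_correct(gt$p[ok])
        rc <- ref_code[keep]
        m_p <- c_pos[, keep, drop = FALSE][cbind(rc, seq_along(rc))]
        m_n <- c_neg[, keep, drop = FALSE][cbind(rc, seq_along(rc))]
        lfc <- haldane_log2fc(colSums(c_pos[, keep, drop = FALSE]) - m_p, m_p,
                              colSums(c_neg[, keep, drop = FALSE]) - m_n, m_n)
        sig <- !is.na(q) & q < fdr & abs(lfc) > min_lfc
        if (any(sig & which(keep) %in% target_idx)) hits <- hits + 1L
      }
      hits
    }, integer(1))
  })
  tibble(depth = grid$depth, rate = grid$rate, n_boot = as.integer(n_boot),
         detected = grid$detected, freq = grid$detected / n_boot)
}
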
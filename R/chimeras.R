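## Readthrough chimeric RNA detection: reads spanning adjacent same-strand
## gene loci are classified as chimeric and attributed to the most upstream
## gene; per-gene chimeric:non-chimeric ratios are compared between
## conditions with bootstrap resampling, a KS test and a fold-change rule.

#' Classify reads as chimeric or non-chimeric per gene
#'
#' A read overlapping two or more *adjacent* same-strand gene loci, each by
#' more than 20% of its aligned length, is chimeric and attributed to the
#' most upstream of those genes (strand-aware). Reads overlapping exactly
#' one gene are non-chimeric. Reads touching genes in `exclude` (e.g.
#' tandem duplicates) are dropped, as are multi-gene reads whose genes are
#' not adjacent (ambiguous). Adjacency means consecutive in coordinate
#' order among same-strand genes on the chromosome.
#'
#' @param reads a [drs_reads()] tibble.
#' @param models a [gene_models()] object.
#' @param exclude character vector of gene ids to exclude.
#' @param min_frac per-gene overlap fraction (default 0.2, strict `>`).
#' @return list with `reads` (tibble: `read`, `read_id`, `sample_id`,
#'   `gene_id`, `chimeric`) and `counts` (per gene: `n_chimeric`,
#'   `n_single`).
#' @export
classify_chimeric <- function(reads, models, exclude = character(0),
                              min_frac = 0.2) {
  asn <- assign_reads_to_genes(reads, models, min_frac = min_frac)
  genes <- models$genes
  # rank of each gene along its chromosome/strand, in coordinate order
  ord <- order(genes$chrom, genes$strand, genes$start)
  rank <- integer(nrow(genes))
  grp <- paste(genes$chrom, genes$strand)[ord]
  rank[ord] <- stats::ave(seq_along(ord), grp, FUN = seq_along)
  gene_rank <- setNames(rank, genes$gene_id)
  gene_strand <- setNames(genes$strand, genes$gene_id)
  gene_start <- setNames(genes$start, genes$gene_id)
  drop_reads <- unique(asn$read[asn$gene_id %in% exclude])
  asn <- asn[!asn$read %in% drop_reads, , drop = FALSE]
  per_read <- split(asn$gene_id, asn$read)
  rows <- lapply(names(per_read), function(r) {
    gids <- per_read[[r]]
    ri <- as.integer(r)
    if (length(gids) == 1L) {
      return(tibble(read = ri, gene_id = gids, chimeric = FALSE))
    }
    rk <- sort(gene_rank[gids])
    if (any(diff(rk) == 1L)) {
      # attributed to the most upstream gene: lowest start on "+",
      # highest end on "-"
      up <- if (gene_strand[gids[1]] == "+") {
        gids[which.min(gene_start[gids])]
      } else {
        gids[which.max(gene_start[gids])]
      }
      tibble(read = ri, gene_id = up, chimeric = TRUE)
    } else {
      NULL  # multi-gene but non-adjacent: ambiguous, dropped
    }
  })
  cls <- bind_rows(rows)
  cls$read_id <- reads$read_id[cls$read]
  cls$sample_id <- reads$sample_id[cls$read]
  counts <- cls %>%
    group_by(.data$gene_id) %>%
    summarise(n_chimeric = sum(.data$chimeric),
              n_single = sum(!.data$chimeric), .groups = "drop")
  list(reads = cls[, c("read", "read_id", "sample_id", "gene_id", "chimeric")],
       counts = counts)
}

#' Bootstrap test for increased chimeric RNA formation at one gene
#'
#' Per condition, `n_boot` subsamples of `floor(frac * N)` reads are drawn
#' without replacement and the Haldane-corrected chimeric:non-chimeric ratio
#' `(c + 0.5) / (nc + 0.5)` computed for each. The two conditions' ratio
#' distributions are compared with a KS test, and all `n_boot^2` pairwise
#' cross-condition comparisons give the fraction with a strictly more than
#' two-fold ratio increase in the mutant. Because reads are exchangeable
#' given their binary chimeric label, the subsampled chimeric count is drawn
#' from the hypergeometric distribution, which is exactly equivalent to
#' subsampling reads.
#'
#' @param n_chim_ref,n_single_ref chimeric / non-chimeric read counts in the
#'   reference condition.
#' @param n_chim_mut,n_single_mut counts in the mutant condition.
#' @param n_boot bootstraps per condition (default 50).
#' @param frac subsample fraction in (0, 1] (default 0.75).
#' @param seed RNG seed.
#' @return list with `D`, `p`, `frac_boot_ge2`, `ratio_fc` (point-estimate
#'   Haldane fold change), counts, and `untestable`.
#' @export
bootstrap_chimera_test <- function(n_chim_ref, n_single_ref, n_chim_mut,
                                   n_single_mut, n_boot = 50L, frac = 0.75,
                                   seed = NULL) {
  if (n_boot < 2L) stopf("n_boot must be >= 2")
  if (frac <= 0 || frac > 1) stopf("frac must be in (0, 1]")
  n_ref <- n_chim_ref + n_single_ref
  n_mut <- n_chim_mut + n_single_mut
  if (n_ref == 0L || n_mut == 0L) {
    return(list(D = NA_real_, p = NA_real_, frac_boot_ge2 = NA_real_,
                ratio_fc = NA_real_, untestable = TRUE))
  }
  with_seed(seed, {
    draw <- function(nc, ns) {
      m <- floor(frac * (nc + ns))
      c_sub <- rhyper(n_boot, nc, ns, m)
      (c_sub + 0.5) / (m - c_sub + 0.5)
    }
    r_ref <- draw(n_chim_ref, n_single_ref)
    r_mut <- draw(n_chim_mut, n_single_mut)
  })
  ks <- ks_two_sample(r_ref, r_mut)
  frac_ge2 <- mean(outer(r_mut, r_ref, `/`) > 2)
  ratio_fc <- ((n_chim_mut + 0.5) / (n_single_mut + 0.5)) /
    ((n_chim_ref + 0.5) / (n_single_ref + 0.5))
  list(D = ks$D, p = ks$p, frac_boot_ge2 = frac_ge2, ratio_fc = ratio_fc,
       untestable = FALSE)
}

#' Genome-wide chimeric readthrough test
#'
#' Classifies reads per condition with [classify_chimeric()], runs
#' [bootstrap_chimera_test()] per gene, BH-corrects the KS p-values, and
#' flags genes satisfying the three-part rule: more than one chimeric read
#' in the mutant, a more than two-fold ratio increase in more than half the
#' bootstrap comparisons, and `q < fdr`.
#'
#' @param reads_ref,reads_mut reads per condition (replicates pooled).
#' @param models a [gene_models()] object.
#' @param exclude gene ids excluded from classification.
#' @param n_boot,frac bootstrap parameters (defaults 50 and 0.75).
#' @param fdr BH threshold (default 0.05).
#' @param seed RNG seed.
#' @return tibble per gene with counts, `D`, `p`, `q`, `frac_boot_ge2`,
#'   `ratio_fc` and `flagged`.
#' @export
test_chimeras <- function(reads_ref, reads_mut, models,
                          exclude = character(0), n_boot = 50L, frac = 0.75,
                          fdr = 0.05, seed = 1L) {
  c_ref <- classify_chimeric(reads_ref, models, exclude)$counts
  c_mut <- classify_chimeric(reads_mut, models, exclude)$counts
  gids <- union(c_ref$gene_id, c_mut$gene_id)
  getc <- function(tab, gid, col) {
    v <- tab[[col]][tab$gene_id == gid]
    if (length(v) == 0L) 0L else v
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(gids)))
  rows <- lapply(seq_along(gids), function(i) {
    gid <- gids[i]
    ncr <- getc(c_ref, gid, "n_chimeric"); nsr <- getc(c_ref, gid, "n_single")
    ncm <- getc(c_mut, gid, "n_chimeric"); nsm <- getc(c_mut, gid, "n_single")
    bt <- bootstrap_chimera_test(ncr, nsr, ncm, nsm, n_boot = n_boot,
                                 frac = frac, seed = seeds[i])
    tibble(gene_id = gid, n_chimeric_ref = ncr, n_single_ref = nsr,
           n_chimeric_mut = ncm, n_single_mut = nsm,
           D = bt$D, p = bt$p, frac_boot_ge2 = bt$frac_boot_ge2,
           ratio_fc = bt$ratio_fc, untestable = isTRUE(bt$untestable))
  })
  res <- bind_rows(rows)
  res$q <- NA_real_
  ok <- !res$untestable & !is.na(res$p)
  res$q[ok] <- bh_correct(res$p[ok])
  res$flagged <- !res$untestable & res$n_chimeric_mut > 1L &
    !is.na(res$frac_boot_ge2) & res$frac_boot_ge2 > 0.5 &
    !is.na(res$q) & res$q < fdr
  arrange(res, .data$gene_id)
}
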
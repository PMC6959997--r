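## Seeded synthetic-data generator with planted ground truth.
##
## Miniature genomes and alignments are simulated at the pileup level: each
## read carries a per-base basecall category (match, mismatch, insertion,
## deletion) drawn from background error rates, with elevated
## condition-specific mismatch probability at planted modification sites.
## 3' ends, poly(A) tail tags, chimeric reads spanning adjacent genes and
## over-split read pairs are planted per configuration. All draws derive
## from a single seed; identical configurations give identical output.

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated under:
#' 20 genes of 1-3 kb, 4 replicates x 2 conditions, 100-300 reads per gene
#' per sample, DRS-like background error (3% mismatch, 1.5% insertion,
#' 2.5% deletion per base), one planted modification site per gene with
#' 30% mismatch in the modification-positive ("ref") condition vs 5% in the
#' writer mutant ("mut"), and 3' end jitter with a 13 nt standard deviation.
#'
#' @param seed master RNG seed.
#' @param n_genes number of genes (all on "+", laid out on one chromosome).
#' @param gene_length min/max gene length in nt.
#' @param gene_gap intergenic gap in nt.
#' @param n_reads min/max reads per gene per sample (drawn once per gene).
#' @param n_reps replicates per condition.
#' @param error_rates named background per-base rates
#'   (`mismatch`, `ins`, `del`).
#' @param site_motif DNA motif planted at modification sites; the modified
#'   adenosine is at `site_offset` (0-based within the motif).
#' @param site_offset see `site_motif`.
#' @param sites_per_gene planted sites per gene (0 for a null genome).
#' @param site_mismatch named per-condition mismatch probability at planted
#'   sites (`ref`, `mut`).
#' @param site_neighbor_decay multipliers on the excess mismatch probability
#'   at offsets 0, +/-1, +/-2 from the modified base (default
#'   `c(1, 0.5, 0.25)`): roughly five nucleotides occupy the pore at once,
#'   so a modification perturbs basecalls of its neighbours too.
#' @param site_stoichiometry fraction of modification-positive reads
#'   carrying the modification.
#' @param three_prime_sd 3' end jitter standard deviation in nt.
#' @param five_prime_trunc mean exponential 5' truncation in nt.
#' @param shift_genes indices of genes with a planted 3' shift in the
#'   mutant.
#' @param shift_delta planted shift in nt (negative = proximal).
#' @param shift_frac fraction of mutant reads using the shifted site.
#' @param tail_modes poly(A) tail mixture modes in nt.
#' @param tail_sd tail mixture component standard deviation.
#' @param tail_weights named list of per-condition mixture weights.
#' @param chimera_rate named per-condition per-read probability of reading
#'   through into the next gene.
#' @param chimera_genes gene indices eligible for chimera planting
#'   (default all with a downstream neighbour).
#' @param oversplit_rate fraction of reads split into consecutive pairs.
#' @param introns list (by gene index) of intron 2-column matrices in
#'   gene-relative coordinates, or NULL for intronless genes.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 42L, n_genes = 20L,
                       gene_length = c(1000L, 3000L), gene_gap = 300L,
                       n_reads = c(100L, 300L), n_reps = 4L,
                       error_rates = c(mismatch = 0.03, ins = 0.015,
                                       del = 0.025),
                       site_motif = "AAACT", site_offset = 2L,
                       sites_per_gene = 1L,
                       site_mismatch = c(ref = 0.30, mut = 0.05),
                       site_neighbor_decay = c(1, 0.5, 0.25),
                       site_stoichiometry = 1.0,
                       three_prime_sd = 13, five_prime_trunc = 150,
                       shift_genes = integer(0), shift_delta = -30L,
                       shift_frac = 0.4,
                       tail_modes = c(20, 40, 60), tail_sd = 5,
                       tail_weights = list(ref = c(1, 1, 1) / 3,
                                           mut = c(1, 1, 1) / 3),
                       chimera_rate = c(ref = 0, mut = 0),
                       chimera_genes = NULL,
                       oversplit_rate = 0,
                       introns = NULL) {
  stopifnot(all(error_rates >= 0), sum(error_rates) < 1,
            all(site_mismatch >= 0 & site_mismatch <= 1),
            site_stoichiometry >= 0, site_stoichiometry <= 1,
            all(chimera_rate >= 0 & chimera_rate < 1),
            oversplit_rate >= 0, oversplit_rate < 1,
            all(vapply(tail_weights, function(w) {
              abs(sum(w) - 1) < 1e-9
            }, logical(1))))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a reference genome and annotation with planted motifs
#'
#' Genes are laid out head to tail on one chromosome ("chrS", "+" strand),
#' each with a single transcript whose exon spans the locus and whose CDS
#' covers the central portion (so UTRs, flanks and oligo(A) screens are
#' exercised). The site motif is written into the sequence at each planted
#' position; a truth table records every planted site.
#'
#' @param config a [sim_config()].
#' @return `sim_genome` list: `genome` (named character), `models`
#'   ([gene_models()]), `truth` (list of tibbles: `sites`, `shifts`,
#'   `chimeras`), `gene_reads` (reads per gene per sample) and `config`.
#' @export
sim_genome <- function(config) {
  cfg <- config
  with_seed(cfg$seed, {
    lens <- round(runif(cfg$n_genes, cfg$gene_length[1], cfg$gene_length[2]))
    n_reads_gene <- round(runif(cfg$n_genes, cfg$n_reads[1], cfg$n_reads[2]))
    starts <- cfg$gene_gap + c(0, cumsum(lens[-cfg$n_genes] + cfg$gene_gap))
    chrom_len <- starts[cfg$n_genes] + lens[cfg$n_genes] + cfg$gene_gap
    seq_chars <- sample(DNA_BASES, chrom_len, replace = TRUE)
    site_rows <- list()
    motif <- strsplit(cfg$site_motif, "")[[1]]
    for (g in seq_len(cfg$n_genes)) {
      if (cfg$sites_per_gene < 1L) next
      offs <- round(lens[g] * seq(0.6, 0.85,
                                  length.out = cfg$sites_per_gene))
      for (o in offs) {
        mstart <- starts[g] + o
        seq_chars[(mstart + 1L):(mstart + length(motif))] <- motif
        site_rows[[length(site_rows) + 1L]] <- tibble(
          gene_id = sprintf("gene%02d", g), chrom = "chrS",
          pos = mstart + cfg$site_offset, motif_start = mstart,
          motif = cfg$site_motif, strand = "+")
      }
    }
    genome <- setNames(paste(seq_chars, collapse = ""), "chrS")
    tx <- lapply(seq_len(cfg$n_genes), function(g) {
      s <- starts[g]; e <- starts[g] + lens[g]
      cds0 <- s + round(0.15 * lens[g])
      cds1 <- cds0 + (round(0.5 * lens[g]) %/% 3L) * 3L
      intr <- if (!is.null(cfg$introns) && length(cfg$introns) >= g &&
                  !is.null(cfg$introns[[g]])) {
        cfg$introns[[g]] + s
      } else {
        cbind(start = integer(0), end = integer(0))
      }
      bounds <- c(s, t(intr), e)
      exons <- cbind(start = bounds[seq(1, length(bounds), 2)],
                     end = bounds[seq(2, length(bounds), 2)])
      tibble(transcript_id = sprintf("gene%02d.1", g),
             gene_id = sprintf("gene%02d", g), chrom = "chrS",
             strand = "+", exons = list(exons),
             cds = list(cbind(start = cds0, end = cds1)))
    })
    models <- gene_models(bind_rows(tx))
    shifts <- if (length(cfg$shift_genes) > 0) {
      tibble(gene_id = sprintf("gene%02d", cfg$shift_genes),
             delta = cfg$shift_delta, frac = cfg$shift_frac)
    } else {
      tibble(gene_id = character(0), delta = integer(0), frac = numeric(0))
    }
    chim_genes <- if (is.null(cfg$chimera_genes)) {
      seq_len(cfg$n_genes - 1L)
    } else {
      intersect(cfg$chimera_genes, seq_len(cfg$n_genes - 1L))
    }
    chimeras <- tibble(gene_id = sprintf("gene%02d", chim_genes),
                       rate_ref = cfg$chimera_rate[["ref"]],
                       rate_mut = cfg$chimera_rate[["mut"]])
    sites_tab <- if (length(site_rows) > 0) {
      bind_rows(site_rows)
    } else {
      tibble(gene_id = character(0), chrom = character(0), pos = integer(0),
             motif_start = integer(0), motif = character(0),
             strand = character(0))
    }
    list2 <- list(genome = genome, models = models,
                  truth = list(sites = sites_tab,
                               shifts = shifts, chimeras = chimeras),
                  gene_reads = n_reads_gene, config = cfg)
    structure(list2, class = "sim_genome")
  })
}

# simulate one read's basecall categories, sequence and CIGAR over
# reference span [s, e); site_pos/site_p: planted positions and their
# mismatch probabilities (already resolved for this read)
sim_read_alignment <- function(ref_chars, s, e, er, site_pos, site_p) {
  L <- e - s
  u <- runif(L)
  # 1 = match, 2 = mismatch, 3 = ins-after, 4 = del
  cat <- 1L + (u < er[1] + er[2] + er[3]) + (u < er[2] + er[3]) +
    (u < er[3])
  if (length(site_pos) > 0) {
    idx <- site_pos - s + 1L
    on <- idx >= 1L & idx <= L
    cat[idx[on]] <- ifelse(runif(sum(on)) < site_p[on], 2L, 1L)
  }
  cat[c(1L, L)] <- pmin(cat[c(1L, L)], 2L)  # alignments end in M
  bases <- ref_chars[(s + 1L):e]
  code <- match(bases, DNA_BASES)
  mm <- which(cat == 2L)
  if (length(mm) > 0) {
    bases[mm] <- DNA_BASES[(code[mm] - 1L +
                              sample.int(3L, length(mm), replace = TRUE)) %% 4L + 1L]
  }
  ins <- which(cat == 3L)
  del <- cat == 4L
  qparts <- bases
  if (length(ins) > 0) {
    qparts[ins] <- paste0(bases[ins],
                          sample(DNA_BASES, length(ins), replace = TRUE))
  }
  seqc <- paste(qparts[!del], collapse = "")
  op <- ifelse(del, "D", "M")
  tok <- rbind(op, NA_character_)
  tok[2L, ins] <- "I"
  tok <- tok[!is.na(tok)]
  r <- rle(tok)
  cigar <- paste0(r$lengths, r$values, collapse = "")
  list(seq = seqc, cigar = cigar)
}

#' Simulate reads for one sample
#'
#' @param sim a [sim_genome()] result.
#' @param condition `"ref"` (modification positive) or `"mut"`.
#' @param replicate replicate number (1-based).
#' @return a [drs_reads()] tibble with `sample_id` =
#'   `"<condition>_<replicate>"`.
#' @export
sim_reads <- function(sim, condition, replicate) {
  cfg <- sim$config
  if (!condition %in% c("ref", "mut")) stopf("condition must be 'ref' or 'mut'")
  cond_idx <- match(condition, c("ref", "mut"))
  seed <- (cfg$seed + 7919L * cond_idx + 104729L * replicate) %% 2000000000L
  genes <- sim$models$genes
  ref_chars <- strsplit(sim$genome[["chrS"]], "")[[1]]
  er <- unname(cfg$error_rates[c("mismatch", "ins", "del")])
  sites <- sim$truth$sites
  shift_ids <- sim$truth$shifts$gene_id
  with_seed(seed, {
    rows <- list()
    for (g in seq_len(nrow(genes))) {
      gid <- genes$gene_id[g]
      n <- sim$gene_reads[g]
      gsites <- sites[sites$gene_id == gid, , drop = FALSE]
      chim_ok <- g < nrow(genes) &&
        gid %in% sim$truth$chimeras$gene_id
      chim_p <- if (chim_ok) cfg$chimera_rate[[condition]] else 0
      is_chim <- runif(n) < chim_p
      # 3' ends
      shifted <- condition == "mut" & gid %in% shift_ids &
        runif(n) < cfg$shift_frac
      base_end <- genes$end[g] - 1L
      ends <- base_end + ifelse(shifted, cfg$shift_delta, 0L) +
        round(rnorm(n, 0, cfg$three_prime_sd))
      ends <- pmin(pmax(ends, genes$start[g] + 100L),
                   nchar(sim$genome[["chrS"]]) - 2L)
      # chimeric reads run through into the middle of the next gene
      if (any(is_chim)) {
        nxt_end <- genes$start[g + 1L] +
          round(0.6 * (genes$end[g + 1L] - genes$start[g + 1L]))
        ends[is_chim] <- pmin(nxt_end + round(rnorm(sum(is_chim), 0,
                                                    cfg$three_prime_sd)),
                              nchar(sim$genome[["chrS"]]) - 2L)
      }
      starts <- genes$start[g] +
        pmin(round(stats::rexp(n, 1 / cfg$five_prime_trunc)),
             round(0.3 * (genes$end[g] - genes$start[g])))
      # modification signature: full effect at the modified base, decaying
      # excess at +/-1 and +/-2 nt; stoichiometry applies per "ref" read
      decay <- cfg$site_neighbor_decay
      offs <- -(length(decay) - 1L):(length(decay) - 1L)
      pos_exp <- as.integer(outer(gsites$pos, offs, `+`))
      mult <- rep(decay[abs(offs) + 1L], each = nrow(gsites))
      site_rate <- function(p_cond) {
        pmax(er[1], er[1] + (p_cond - er[1]) * mult)
      }
      p_on <- site_rate(cfg$site_mismatch[[condition]])
      p_off <- site_rate(cfg$site_mismatch[["mut"]])
      aln <- lapply(seq_len(n), function(i) {
        sp <- p_on
        if (condition == "ref" && length(sp) > 0 &&
            runif(1) > cfg$site_stoichiometry) {
          sp <- p_off
        }
        sim_read_alignment(ref_chars, starts[i], ends[i] + 1L, er,
                           pos_exp, sp)
      })
      tails <- {
        comp <- sample.int(length(cfg$tail_modes), n, replace = TRUE,
                           prob = cfg$tail_weights[[condition]])
        pmax(1, rnorm(n, cfg$tail_modes[comp], cfg$tail_sd))
      }
      rows[[g]] <- tibble(
        read_id = sprintf("%s/%s_r%d/%04d", gid, condition, replicate,
                          seq_len(n)),
        chrom = "chrS", start = starts, strand = "+",
        cigar = vapply(aln, `[[`, "", "cigar"),
        seq = vapply(aln, `[[`, "", "seq"),
        tail_length = round(tails, 1))
    }
    df <- bind_rows(rows)
    nr <- nrow(df)
    df$channel <- sample.int(512L, nr, replace = TRUE)
    df$start_time <- round(cumsum(stats::rexp(nr, 1 / 2)), 3)
    reads <- drs_reads(df$read_id, sprintf("%s_%d", condition, replicate),
                       df$chrom, df$start, df$strand, df$cigar, df$seq,
                       df$tail_length, df$channel, df$start_time)
    if (cfg$oversplit_rate > 0) reads <- plant_oversplits(reads, cfg)
    reads
  })
}

# split a fraction of reads into consecutive same-channel pairs with
# adjacent alignments (the over-splitting artefact)
plant_oversplits <- function(reads, cfg) {
  n_split <- floor(cfg$oversplit_rate * nrow(reads))
  if (n_split == 0L) return(reads)
  cand <- which(reads$end - reads$start > 400L)
  victims <- sample(cand, min(n_split, length(cand)))
  extra <- list()
  for (i in victims) {
    span <- reads$end[i] - reads$start[i]
    cut <- reads$start[i] + round(runif(1, 0.3, 0.7) * span)
    gap <- sample(0:50, 1)
    t1 <- trim_alignment(reads[i, ], reads$start[i], cut)
    t2 <- trim_alignment(reads[i, ], cut + gap, reads$end[i])
    t2$start_time <- reads$start_time[i] + 0.001
    t1$read_id <- paste0(reads$read_id[i], "/split1")
    t2$read_id <- paste0(reads$read_id[i], "/split2")
    extra[[length(extra) + 1L]] <- bind_rows(t1, t2)
    reads$read_id[i] <- NA_character_
  }
  out <- bind_rows(reads[!is.na(reads$read_id), ], bind_rows(extra))
  class(out) <- c("drs_reads", class(tibble()))
  out
}

# clip one aligned read to reference window [w0, w1); returns a 1-row tibble
trim_alignment <- function(read, w0, w1) {
  co <- cigar_ops(read$cigar)[[1]]
  rpos <- read$start; qpos <- 1L
  ops <- character(0); lens <- integer(0); qs <- NULL; qe <- 0L
  for (j in seq_along(co$op)) {
    op <- co$op[j]; len <- co$len[j]
    rc <- if (op %in% c("M", "D", "N", "=", "X")) len else 0L
    qc <- if (op %in% c("M", "I", "S", "=", "X")) len else 0L
    o0 <- max(rpos, w0); o1 <- min(rpos + rc, w1)
    if (op %in% c("M", "=", "X") && o1 > o0) {
      ops <- c(ops, "M"); lens <- c(lens, o1 - o0)
      qa <- qpos + (o0 - rpos)
      if (is.null(qs)) qs <- qa
      qe <- qa + (o1 - o0) - 1L
    } else if (op == "D" && o1 > o0 && !is.null(qs)) {
      ops <- c(ops, "D"); lens <- c(lens, o1 - o0)
    } else if (op == "I" && rpos > w0 && rpos <= w1 && !is.null(qs)) {
      ops <- c(ops, "I"); lens <- c(lens, len)
      qe <- qe + len
    }
    rpos <- rpos + rc; qpos <- qpos + qc
  }
  # drop trailing non-M ops
  while (length(ops) > 0 && ops[length(ops)] != "M") {
    if (ops[length(ops)] == "I") qe <- qe - lens[length(lens)]
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  cig <- paste0(lens, ops, collapse = "")
  out <- read
  out$start <- max(read$start, w0)
  out$end <- out$start + sum(lens[ops %in% c("M", "D")])
  out$cigar <- cig
  out$seq <- substr(read$seq, qs, qe)
  out
}

#' Simulate a full two-condition experiment
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `models`, `truth`, `config`, and `reads`: a
#'   list with elements `ref` and `mut`, each a single [drs_reads()] tibble
#'   with replicates distinguished by `sample_id`.
#' @export
sim_experiment <- function(config) {
  sg <- sim_genome(config)
  reads <- lapply(c(ref = "ref", mut = "mut"), function(cond) {
    bind_rows(lapply(seq_len(config$n_reps), function(r) {
      sim_reads(sg, cond, r)
    }))
  })
  list(genome = sg$genome, models = sg$models, truth = sg$truth,
       config = config, reads = reads)
}

#' Truth tables of a simulated experiment
#'
#' @param sim a [sim_genome()] or [sim_experiment()] result.
#' @return list of tibbles: `sites`, `shifts`, `chimeras`.
#' @export
truth_tables <- function(sim) sim$truth

#' Write a simulated experiment to disk
#'
#' FASTA + GTF + one sorted indexed BAM per sample + truth TSVs.
#'
#' @param experiment a [sim_experiment()] result.
#' @param dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_simulation <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = write_genome(experiment$genome, file.path(dir, "genome.fa")),
    annotation = write_annotation(experiment$models,
                                  file.path(dir, "annotation.gtf")))
  for (cond in names(experiment$reads)) {
    rd <- experiment$reads[[cond]]
    for (s in unique(rd$sample_id)) {
      p <- write_reads_bam(rd[rd$sample_id == s, ],
                           file.path(dir, paste0(s, ".bam")),
                           experiment$genome)
      paths[[s]] <- p
    }
  }
  for (tt in names(experiment$truth)) {
    p <- file.path(dir, sprintf("truth_%s.tsv", tt))
    write_result_tsv(experiment$truth[[tt]], p)
    paths[[paste0("truth_", tt)]] <- p
  }
  invisible(paths)
}
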
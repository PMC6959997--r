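## End-to-end orchestration: simulate or load alignments, call differential
## error sites, phase them with poly(A) clusters, test 3' shifts, tail
## lengths and chimeras, extract junctions, and write TSV/BED outputs plus
## a machine-readable JSON summary.

#' Pipeline run configuration
#'
#' Thresholds default to the method's standard constants: coverage > 10
#' reads, FDR 0.05, |log2FC| > 1, 3' shift > 13 nt, chimera rule (> 1
#' chimeric read, >= 2-fold in > 50% of bootstraps, FDR < 0.05), poly(A)
#' cluster minimum 10 reads, smoothing sigmas 13 nt (poly(A) clusters) and
#' 100 nt (isoform collapsing), site padding 5 nt.
#'
#' @param out_dir output directory.
#' @param simulate a [sim_config()] to generate inputs, or `NULL` to read
#'   from files.
#' @param bam_ref,bam_mut BAM paths per condition (one per replicate;
#'   ignored when simulating).
#' @param genome_fasta,annotation_gtf reference paths (ignored when
#'   simulating).
#' @param seed RNG seed for the stochastic stages.
#' @param min_coverage,fdr,min_lfc,min_shift,sigma_polya,min_cluster,pad,
#'   n_boot,boot_frac threshold overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, simulate = NULL, bam_ref = character(0),
                       bam_mut = character(0), genome_fasta = NULL,
                       annotation_gtf = NULL, seed = 1L,
                       min_coverage = 11L, fdr = 0.05, min_lfc = 1,
                       min_shift = 13, sigma_polya = 13, min_cluster = 10L,
                       pad = 5L, n_boot = 50L, boot_frac = 0.75) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (1) input (simulation or BAM/FASTA/GTF); (2) differential error
#' site calling; (3) site merging with sequence extraction; (4) phasing of
#' significant sites with poly(A) clusters; (5) 3' end shift tests; (6)
#' poly(A) tail length tests; (7) chimeric readthrough tests; (8) junction
#' extraction. Every stage writes a TSV (sites also as BED) into
#' `config$out_dir`, and a `summary.json` captures headline numbers,
#' thresholds and the seed. When simulating, planted-truth recall is added
#' to the summary.
#'
#' @param config a [run_config()].
#' @return list with all stage results and the `summary`, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  logf("nanodrs %s; seed=%d; fdr=%g; min_lfc=%g; min_shift=%g; min_coverage=%d",
       as.character(utils::packageVersion("nanodrs")), config$seed,
       config$fdr, config$min_lfc, config$min_shift, config$min_coverage)
  if (!is.null(config$simulate)) {
    exp <- sim_experiment(config$simulate)
    genome <- exp$genome; models <- exp$models
    reads_ref <- exp$reads$ref; reads_mut <- exp$reads$mut
    truth <- exp$truth
    logf("simulated %d genes, %d + %d reads", nrow(models$genes),
         nrow(reads_ref), nrow(reads_mut))
  } else {
    for (p in c(config$bam_ref, config$bam_mut, config$genome_fasta,
                config$annotation_gtf)) {
      if (!file.exists(p)) stopf("input file not found: %s", p)
    }
    genome <- read_genome(config$genome_fasta)
    models <- read_annotation(config$annotation_gtf)
    load_all <- function(paths, cond) {
      bind_rows(lapply(seq_along(paths), function(i) {
        read_reads_bam(paths[i], sprintf("%s_%d", cond, i))
      }))
    }
    reads_ref <- load_all(config$bam_ref, "ref")
    reads_mut <- load_all(config$bam_mut, "mut")
    truth <- NULL
  }
  regions <- models$genes[, c("chrom", "start", "end")]

  sites <- call_error_sites(reads_ref, reads_mut, genome, regions,
                            min_coverage = config$min_coverage,
                            fdr = config$fdr, min_lfc = config$min_lfc)
  write_result_tsv(sites, file.path(config$out_dir, "error_sites.tsv"))
  sig <- sites[sites$sig, , drop = FALSE]
  if (nrow(sig) > 0) {
    write_bed(tibble(chrom = sig$chrom, start = sig$pos,
                     end = sig$pos + 1L, name = "error_site",
                     score = round(pmin(1000, sig$G)), strand = "+"),
              file.path(config$out_dir, "error_sites.bed"))
  }
  merged <- merge_sites(tibble(chrom = sig$chrom, pos = sig$pos), genome,
                        pad = config$pad)
  write_result_tsv(merged, file.path(config$out_dir, "merged_sites.tsv"))
  logf("error sites: %d tested, %d significant, %d merged intervals",
       nrow(sites), nrow(sig), nrow(merged))

  phasing <- test_phasing(reads_ref, sig[, c("chrom", "pos")],
                          sigma = config$sigma_polya,
                          min_cluster = config$min_cluster, fdr = config$fdr)
  write_result_tsv(phasing[, setdiff(names(phasing), "profiles")],
                   file.path(config$out_dir, "phasing.tsv"))

  shifts <- test_three_prime_shifts(reads_ref, reads_mut, models,
                                    min_shift = config$min_shift,
                                    fdr = config$fdr)
  write_result_tsv(shifts, file.path(config$out_dir, "three_prime_shifts.tsv"))

  tails <- test_tail_lengths(reads_ref, reads_mut, models, fdr = config$fdr)
  write_result_tsv(tails, file.path(config$out_dir, "tail_lengths.tsv"))

  chim <- test_chimeras(reads_ref, reads_mut, models, n_boot = config$n_boot,
                        frac = config$boot_frac, fdr = config$fdr,
                        seed = config$seed)
  write_result_tsv(chim, file.path(config$out_dir, "chimeras.tsv"))

  jx <- extract_junctions(bind_rows(reads_ref, reads_mut))
  write_result_tsv(jx, file.path(config$out_dir, "junctions.tsv"))

  summary <- list(
    seed = config$seed,
    thresholds = list(min_coverage = config$min_coverage, fdr = config$fdr,
                      min_lfc = config$min_lfc, min_shift = config$min_shift,
                      min_cluster = config$min_cluster,
                      sigma_polya = config$sigma_polya, pad = config$pad),
    n_positions_tested = nrow(sites), n_sites_significant = nrow(sig),
    n_merged_intervals = nrow(merged),
    n_sites_phased = sum(phasing$sig, na.rm = TRUE),
    n_genes_shifted = sum(shifts$sig, na.rm = TRUE),
    n_genes_proximal_shift = sum(shifts$sig & shifts$delta < 0, na.rm = TRUE),
    n_genes_tail_change = sum(tails$sig, na.rm = TRUE),
    n_genes_chimeric = sum(chim$flagged, na.rm = TRUE),
    n_junctions = nrow(jx))
  if (!is.null(truth) && nrow(truth$sites) > 0) {
    hit <- vapply(seq_len(nrow(truth$sites)), function(i) {
      any(sig$chrom == truth$sites$chrom[i] &
            abs(sig$pos - truth$sites$pos[i]) <= 2L)
    }, logical(1))
    summary$site_recall <- mean(hit)
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logf("done: %d significant sites, %d shifted genes, %d chimeric genes",
       nrow(sig), summary$n_genes_shifted, summary$n_genes_chimeric)
  invisible(list(sites = sites, merged = merged, phasing = phasing,
                 shifts = shifts, tails = tails, chimeras = chim,
                 junctions = jx, summary = summary))
}
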
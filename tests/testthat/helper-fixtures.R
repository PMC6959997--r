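# Shared miniature fixtures, built in code. Cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small planted-site experiment shared by several test files
small_planted_exp <- function() {
  cached("small_planted", function() {
    sim_experiment(sim_config(seed = 11, n_genes = 4,
                              gene_length = c(800, 1200),
                              n_reads = c(120, 150), n_reps = 2))
  })
}

# simple two-gene annotation for assignment/flattening tests:
# geneA [100, 1100) + with CDS [300, 900); geneB [2000, 3000) +
toy_models <- function() {
  gene_models(tibble::tibble(
    transcript_id = c("tA.1", "tB.1"),
    gene_id = c("geneA", "geneB"),
    chrom = "chr1", strand = "+",
    exons = list(cbind(start = 100L, end = 1100L),
                 cbind(start = 2000L, end = 3000L)),
    cds = list(cbind(start = 300L, end = 900L),
               cbind(start = 2200L, end = 2800L))))
}

# an unspliced read with an all-match CIGAR
plain_read <- function(id, start, len, strand = "+", chrom = "chr1",
                       sample = "s1", seq = NA_character_, ...) {
  drs_reads(read_id = id, sample_id = sample, chrom = chrom, start = start,
            strand = strand, cigar = sprintf("%dM", len), seq = seq, ...)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
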
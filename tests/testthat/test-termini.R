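# 3' end and poly(A) statistics.

test_that("KS statistic and exact p match the enumeration oracle", {
  ks <- ks_two_sample(1:3, 4:6, exact = TRUE)
  expect_equal(ks$D, 1)
  expect_equal(ks$p, 0.1)
  expect_equal(oracle_ks_exact(1:3, 4:6), 0.1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(ks_two_sample(numeric(0), 1:3), "non-empty")
  set.seed(51)
  for (i in 1:20) {
    x <- sample(1:100, 4); y <- sample(101:200, 4)
    got <- ks_two_sample(x, y, exact = TRUE)
    expect_equal(got$p, oracle_ks_exact(x, y), tolerance = 1e-12)
  }
})

test_that("KS rejection rate under the null is close to alpha", {
  set.seed(52)
  p <- replicate(1000, ks_two_sample(rnorm(40), rnorm(40))$p)
  rej <- mean(p < 0.05)
  expect_lt(abs(rej - 0.05), 0.025)
})

test_that("point-mass shift localisation and sign convention", {
  d <- diff_three_prime(rep(500L, 40), rep(480L, 40), strand = "+")
  expect_equal(d$pos_increased, 480L)
  expect_equal(d$pos_reduced, 500L)
  expect_equal(d$delta, -20L)
  # mirrored coordinates on the minus strand flip nothing numerically but
  # the sign convention keeps "proximal" negative
  dm <- diff_three_prime(rep(500L, 40), rep(520L, 40), strand = "-")
  expect_equal(dm$delta, -20L)
  expect_equal(diff_three_prime(rep(10L, 30), rep(10L, 30), "+")$D, 0)
})

test_that("planted proximal shift is recovered and null genes stay silent", {
  # sharp poly(A) sites (3 nt jitter): localisation accuracy is bounded by
  # the per-site end noise, see the methods vignette
  cfg <- sim_config(seed = 61, n_genes = 6, gene_length = c(900, 1200),
                    n_reads = c(100, 130), n_reps = 2, sites_per_gene = 0,
                    three_prime_sd = 3,
                    shift_genes = 1:3, shift_delta = -30L, shift_frac = 0.4)
  exp <- sim_experiment(cfg)
  res <- test_three_prime_shifts(exp$reads$ref, exp$reads$mut, exp$models)
  shifted <- res[res$gene_id %in% exp$truth$shifts$gene_id, ]
  nulls <- res[!res$gene_id %in% exp$truth$shifts$gene_id, ]
  expect_true(all(shifted$sig))
  expect_true(all(abs(shifted$delta - (-30)) <= 3))
  expect_true(all(!nulls$sig))
})

test_that("shift detection rate reaches 95% over simulation repeats", {
  set.seed(62)
  deltas <- integer(0); detected <- logical(0)
  for (rep in 1:40) {
    ref <- as.integer(round(rnorm(200, 1000, 3)))
    mut <- as.integer(ifelse(runif(200) < 0.4,
                             round(rnorm(200, 970, 3)),
                             round(rnorm(200, 1000, 3))))
    d <- diff_three_prime(ref, mut, "+")
    detected <- c(detected, d$p < 0.05 / 40 && abs(d$delta) > 13)
    deltas <- c(deltas, d$delta)
  }
  expect_gte(mean(detected & abs(deltas - (-30)) <= 3), 0.95)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  bg <- sprintf("g%03d", 1:100)
  annotated <- bg[1:50]
  flagged <- bg[1:10]
  res <- enrichment_hypergeom(flagged, annotated, bg)
  expect_equal(res$overlap, 10L)
  expect_equal(res$p, choose(50, 10) / choose(100, 10))
  expect_equal(res$p, oracle_hyper_upper(10, 50, 50, 10))
  # degenerate: everything flagged and annotated
  expect_equal(enrichment_hypergeom(bg, bg, bg)$p, 1)
  # overlap at expectation sits in the central band
  res2 <- enrichment_hypergeom(c(bg[1:10], bg[51:60]), annotated, bg)
  expect_equal(res2$p, oracle_hyper_upper(10, 50, 50, 20))
  expect_gt(res2$p, 0.4); expect_lt(res2$p, 0.75)
  expect_error(enrichment_hypergeom("x", "y", character(0)), "background")
  expect_error(enrichment_hypergeom("zz", annotated, bg), "subsets")
})

test_that("tail-length test flags loss of short-tail modes", {
  cfg <- sim_config(seed = 63, n_genes = 3, gene_length = c(800, 1000),
                    n_reads = c(300, 320), n_reps = 1, sites_per_gene = 0,
                    tail_weights = list(ref = c(1, 1, 1) / 3,
                                        mut = c(0.05, 0.15, 0.8)))
  exp <- sim_experiment(cfg)
  res <- test_tail_lengths(exp$reads$ref, exp$reads$mut, exp$models)
  expect_true(all(res$sig))
  expect_true(all(res$median_mut > res$median_ref))
})

test_that("identical tail distributions are not flagged and missing tags skip", {
  cfg <- sim_config(seed = 64, n_genes = 3, gene_length = c(800, 1000),
                    n_reads = c(150, 170), n_reps = 1, sites_per_gene = 0)
  exp <- sim_experiment(cfg)
  res <- test_tail_lengths(exp$reads$ref, exp$reads$mut, exp$models)
  expect_true(all(!res$sig))
  # strip tags from one condition: genes are skipped with a warning
  mut2 <- exp$reads$mut
  mut2$tail_length <- NA_real_
  expect_warning(res2 <- test_tail_lengths(exp$reads$ref, mut2, exp$models),
                 "skipped")
  expect_equal(nrow(res2), 0L)
})

test_that("end peaks require the stated read support", {
  reads <- plain_read(sprintf("r%d", 1:5), c(0L, 0L, 0L, 50L, 50L), 100L)
  peaks <- call_end_peaks(reads, min_reads = 3L)
  expect_equal(peaks$pos, 99L)
  expect_equal(peaks$n, 3L)
})

test_that("peak calling equals a brute-force counter on random data", {
  set.seed(65)
  starts <- sample(0:500, 300, replace = TRUE)
  reads <- plain_read(sprintf("r%d", 1:300), as.integer(starts), 100L)
  peaks <- call_end_peaks(reads, min_reads = 3L)
  tab <- table(starts + 99L)
  want <- sort(as.integer(names(tab)[tab >= 3]))
  expect_equal(peaks$pos, want)
})

test_that("nearest-peak distances are signed and match brute force", {
  q <- tibble::tibble(chrom = "chr1", pos = c(100L, 90L), strand = "+")
  t <- tibble::tibble(chrom = "chr1", pos = c(90L, 120L), strand = "+")
  nd <- nearest_distance(q, t)
  expect_equal(nd$distance, c(-10, 0))
  set.seed(66)
  q2 <- tibble::tibble(chrom = "chr1", pos = sample(1:1000, 50), strand = "+")
  t2 <- tibble::tibble(chrom = "chr1", pos = sample(1:1000, 50), strand = "+")
  nd2 <- nearest_distance(q2, t2)
  for (i in seq_len(50)) {
    d <- t2$pos - q2$pos[i]
    expect_equal(nd2$distance[i], d[which.min(abs(d))])
  }
  # strand/chromosome absent from targets -> missing
  q3 <- tibble::tibble(chrom = "chr2", pos = 5L, strand = "+")
  expect_true(is.na(nearest_distance(q3, t)$distance))
})

test_that("internal priming screen finds A6 runs and counts nearby ends", {
  genome <- c(chr1 = paste0(strrep("C", 400), "AAAAAA", strrep("C", 594)))
  # two-exon gene: the A6 run sits in the CDS of the first exon, so it is
  # not in the terminal exon
  models <- gene_models(tibble::tibble(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
    exons = list(cbind(start = c(0L, 700L), end = c(600L, 1000L))),
    cds = list(cbind(start = 300L, end = 500L))))
  # one read ends 5 nt downstream of the run anchor, one 30 nt away
  reads <- plain_read(c("near", "far"), c(305L, 330L), 100L)
  res <- internal_priming_screen(reads, models, genome, window = 20L)
  expect_equal(res$start, 400L)
  expect_equal(res$n_reads, 1L)
  expect_false(res$terminal_exon)
})

test_that("A6 run discovery equals a regex oracle on a random genome", {
  set.seed(67)
  genome <- c(chr1 = random_dna(20000))
  models <- gene_models(tibble::tibble(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
    exons = list(cbind(start = 0L, end = 20000L)),
    cds = list(cbind(start = 0L, end = 20000L))))
  reads <- plain_read("r1", 0L, 100L)
  res <- internal_priming_screen(reads, models, genome, window = 20L)
  m <- gregexpr("A{6,}", genome[[1]])[[1]]
  expect_equal(res$start, as.integer(m) - 1L)
})

test_that("over-splitting flags respect the exact gap boundaries", {
  mk_pair <- function(gap, id) {
    drs_reads(paste0(id, c("_1", "_2")), "s1", "chr1",
              c(0L, 500L + gap), "+", c("500M", "200M"),
              channel = 7L, start_time = c(1, 2))
  }
  flagged_gap <- function(gap) {
    nrow(detect_oversplitting(mk_pair(gap, "p"))$pairs) == 1L
  }
  expect_true(flagged_gap(5L))
  expect_true(flagged_gap(-10L))
  expect_true(flagged_gap(1000L))
  expect_false(flagged_gap(-11L))
  expect_false(flagged_gap(1001L))
  expect_false(flagged_gap(2000L))
})

test_that("over-splitting output is independent of read input order", {
  set.seed(68)
  reads <- drs_reads(sprintf("r%d", 1:40), "s1", "chr1",
                     as.integer(sample(0:5000, 40)), "+", "300M",
                     channel = sample(1:4, 40, replace = TRUE),
                     start_time = runif(40))
  a <- detect_oversplitting(reads)
  b <- detect_oversplitting(reads[sample(40), ])
  expect_equal(a$pairs[order(a$pairs$read_id1), ],
               b$pairs[order(b$pairs$read_id1), ])
  expect_equal(a$n_pairs, b$n_pairs)
  # missing tags error names the sample
  bad <- reads; bad$channel <- NA_integer_
  expect_error(detect_oversplitting(bad), "s1")
})

test_that("isoform collapsing groups by intron chain then 3' end", {
  reads <- drs_reads(
    sprintf("r%d", 1:5), "s1", "chr1",
    c(0L, 0L, 0L, 0L, 0L), "+",
    c("100M50N100M",      # chain A, end 249
      "100M50N110M",      # chain A, end 259 (10 nt away -> same cluster)
      "100M50N600M",      # chain A, end 749 (far -> new cluster)
      "100M60N100M",      # chain B
      "250M"))            # intronless
  cl <- collapse_isoforms(reads, sigma = 100)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_true(cl$cluster[3] != cl$cluster[1])
  expect_true(cl$cluster[4] != cl$cluster[1])
  expect_true(cl$cluster[5] != cl$cluster[4])
  # representative is the longest aligned read of its cluster
  expect_true(cl$representative[2])
  expect_false(cl$representative[1])
})

test_that("well-separated 3' modes split an intron-chain group", {
  set.seed(69)
  ends <- c(round(rnorm(50, 300, 10)), round(rnorm(50, 800, 10)))
  reads <- drs_reads(sprintf("r%d", 1:100), "s1", "chr1", 0L, "+",
                     sprintf("20M30N%dM", as.integer(ends) - 49L))
  cl <- collapse_isoforms(reads, sigma = 100)
  expect_equal(length(unique(cl$cluster)), 2L)
})
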
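# Junction extraction, U2/U12 classification, intron-chain sets and the
# frameshift screen.

test_that("junctions are extracted with counts, strands kept separate", {
  reads <- drs_reads(
    sprintf("r%d", 1:5), "s1", "chr1", 0L,
    c("+", "+", "+", "-", "+"),
    c("50M100N50M", "50M100N50M", "50M100N50M", "50M100N50M", "200M"))
  jx <- extract_junctions(reads)
  expect_equal(nrow(jx), 2L)
  plus <- jx[jx$strand == "+", ]
  minus <- jx[jx$strand == "-", ]
  expect_equal(plus$count, 3L)
  expect_equal(minus$count, 1L)
  expect_equal(plus$start, 50L)
  expect_equal(plus$end, 150L)
  expect_equal(plus$donor, 50L)
  expect_equal(plus$acceptor, 149L)
  expect_equal(minus$donor, 149L)
  expect_equal(minus$acceptor, 50L)
})

test_that("junction counts conserve per-read intron totals", {
  set.seed(91)
  cigars <- vapply(1:30, function(i) {
    n_introns <- sample(0:3, 1)
    parts <- c("40M", rep(c("100N", "40M"), n_introns))
    paste(parts, collapse = "")
  }, "")
  reads <- drs_reads(sprintf("r%d", 1:30), "s1", "chr1",
                     as.integer(sample(0:50, 30, replace = TRUE) * 10L),
                     "+", cigars)
  jx <- extract_junctions(reads)
  expect_equal(sum(jx$count), sum(lengths(read_introns(reads)) / 2))
})

test_that("extraction equals brute-force gap parsing on random fixtures", {
  set.seed(92)
  starts <- as.integer(sample(0:100, 20, replace = TRUE))
  reads <- drs_reads(sprintf("r%d", 1:20), "s1", "chr1", starts, "+",
                     "30M50N30M")
  jx <- extract_junctions(reads)
  want <- table(starts + 30L)
  expect_equal(jx$start, as.integer(names(want)))
  expect_equal(jx$count, as.integer(want))
})

# toy splice-site PWMs: strong consensus log-odds matrices over the exact
# donor (13 nt) and acceptor (17 nt) windows of a constructed intron
toy_junction_setup <- function() {
  # intron [60, 160) on "+": donor window = genome[57..69], acceptor
  # window = genome[146..162]
  genome_chars <- strsplit(random_dna(300, seed = 93), "")[[1]]
  genome_chars[61:62] <- c("G", "T")   # canonical donor GT
  genome_chars[159:160] <- c("A", "G") # canonical acceptor AG
  genome <- c(chr1 = paste(genome_chars, collapse = ""))
  consensus_pwm <- function(seq, name) {
    chars <- strsplit(seq, "")[[1]]
    m <- matrix(-1, 4, length(chars),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_along(chars)) m[chars[j], j] <- 3
    pwm(m, name)
  }
  donor_seq <- substr(genome, 58, 70)
  acc_seq <- substr(genome, 147, 163)
  list(genome = genome,
       junction = tibble::tibble(chrom = "chr1", start = 60L, end = 160L,
                                 strand = "+", donor = 60L, acceptor = 159L),
       pwms_u2max = list(u2_donor = consensus_pwm(donor_seq, "u2d"),
                         u2_acceptor = consensus_pwm(acc_seq, "u2a"),
                         u12_donor = consensus_pwm(strrep("C", 13), "u12d"),
                         u12_acceptor = consensus_pwm(strrep("C", 17), "u12a")),
       donor_seq = donor_seq, acc_seq = acc_seq)
}

test_that("flanking windows are cut exactly and canonicity detected", {
  setup <- toy_junction_setup()
  fl <- junction_flanks(setup$junction[1, ], setup$genome)
  expect_equal(nchar(fl$donor_seq), 13L)
  expect_equal(nchar(fl$acceptor_seq), 17L)
  expect_equal(fl$donor_seq, unname(setup$donor_seq))
  expect_equal(fl$acceptor_seq, unname(setup$acc_seq))
  expect_true(fl$canonical)
  # minus strand: windows are reverse-complemented, GT..AG in transcript
  # sense means CT..AC on the forward genome
  gm <- strsplit(setup$genome[[1]], "")[[1]]
  gm[61:62] <- c("C", "T"); gm[159:160] <- c("A", "C")
  genome_m <- c(chr1 = paste(gm, collapse = ""))
  jm <- setup$junction; jm$strand <- "-"
  flm <- junction_flanks(jm[1, ], genome_m)
  expect_true(flm$canonical)
  expect_equal(flm$donor_seq, unname(revcomp(substr(genome_m, 151, 163))))
})

test_that("a junction matching the U2 consensus classifies as U2 at 100/100", {
  setup <- toy_junction_setup()
  cls <- classify_junction(setup$junction[1, ], setup$genome,
                           setup$pwms_u2max)
  expect_equal(cls$class, "U2")
  expect_equal(unname(cls$scores["u2_donor"]), 100)
  expect_equal(unname(cls$scores["u2_acceptor"]), 100)
  expect_true(cls$canonical)
})

test_that("U12 thresholds take precedence and non-positive scores drop out", {
  setup <- toy_junction_setup()
  # swap: U12 matrices match the junction, U2 matrices match nothing
  pwms <- list(u2_donor = setup$pwms_u2max$u12_donor,
               u2_acceptor = setup$pwms_u2max$u12_acceptor,
               u12_donor = setup$pwms_u2max$u2_donor,
               u12_acceptor = setup$pwms_u2max$u2_acceptor)
  cls <- classify_junction(setup$junction[1, ], setup$genome, pwms)
  expect_equal(cls$class, "U12")
  expect_gt(cls$scores["u12_donor"], 75)
  expect_gt(cls$scores["u12_acceptor"], 65)
  # non-positive raw scores are never normalised -> unclassified
  neg <- function(w) pwm(matrix(-1, 4, w,
                                dimnames = list(c("A", "C", "G", "T"), NULL)))
  all_neg <- list(u2_donor = neg(13), u2_acceptor = neg(17),
                  u12_donor = neg(13), u12_acceptor = neg(17))
  cls2 <- classify_junction(setup$junction[1, ], setup$genome, all_neg)
  expect_equal(cls2$class, "unclassified")
  expect_true(all(is.na(cls2$scores)))
})

test_that("classification is invariant to scaling a PWM by a constant", {
  setup <- toy_junction_setup()
  scaled <- setup$pwms_u2max
  scaled$u2_donor <- pwm(scaled$u2_donor$matrix * 7, "u2d_scaled")
  a <- classify_junction(setup$junction[1, ], setup$genome, setup$pwms_u2max)
  b <- classify_junction(setup$junction[1, ], setup$genome, scaled)
  expect_equal(a$scores, b$scores)
  expect_equal(a$class, b$class)
})

test_that("PWM/window width mismatch is an error", {
  setup <- toy_junction_setup()
  bad <- setup$pwms_u2max
  bad$u2_donor <- pwm(bad$u2_donor$matrix[, 1:5], "short")
  expect_error(classify_junction(setup$junction[1, ], setup$genome, bad),
               "width")
})

test_that("intron chain sets deduplicate, skip intronless, intersect", {
  mk <- function(ids, cigars, start = 0L) {
    drs_reads(ids, "s", "chr1", start, "+", cigars)
  }
  s1 <- mk(c("a", "b", "c"), c("10M20N10M", "10M20N10M", "40M"))
  s2 <- mk(c("d", "e"), c("10M20N10M", "10M30N10M"))
  s3 <- mk("f", "10M30N10M")
  res <- intron_chain_sets(list(one = s1, two = s2, three = s3))
  expect_length(res$chains$one, 1L)  # duplicates collapse, intronless gone
  expect_length(res$chains$two, 2L)
  inter <- res$intersections
  expect_equal(inter$n[inter$sources == "one&two"], 1L)
  expect_equal(inter$n[inter$sources == "two&three"], 1L)
  # brute-force set algebra over the three toy sources
  all_chains <- unique(unlist(res$chains))
  expect_equal(sum(inter$n), length(all_chains))
})

test_that("annotation sources contribute transcript intron chains", {
  models <- gene_models(tibble::tibble(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
    exons = list(cbind(start = c(0L, 30L), end = c(10L, 40L))),
    cds = list(cbind(start = 0L, end = 40L))))
  reads <- drs_reads("a", "s", "chr1", 0L, "+", "10M20N10M")
  res <- intron_chain_sets(list(ann = models, reads = reads))
  expect_equal(res$chains$ann, res$chains$reads)
})

test_that("frameshift screen flags ORF lengths not divisible by three", {
  # CDS [30, 930): length 900, divisible by 3
  models <- gene_models(tibble::tibble(
    transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
    exons = list(cbind(start = 0L, end = 1000L)),
    cds = list(cbind(start = 30L, end = 930L))))
  full <- drs_reads("full", "s", "chr1", 0L, "+", "1000M")
  # a 50 nt exon skip inside the CDS: 850 remaining -> mod 3 = 1
  skip50 <- drs_reads("skip50", "s", "chr1", 0L, "+", "400M50N550M")
  # a 51 nt skip keeps the frame
  skip51 <- drs_reads("skip51", "s", "chr1", 0L, "+", "400M51N549M")
  # a read missing the start codon is not evaluated
  late <- drs_reads("late", "s", "chr1", 100L, "+", "900M")
  res <- nmd_frameshift_screen(rbind(full, skip50, skip51, late), models)
  expect_setequal(res$read_id, c("full", "skip50", "skip51"))
  expect_false(res$frameshift[res$read_id == "full"])
  expect_true(res$frameshift[res$read_id == "skip50"])
  expect_equal(res$orf_length[res$read_id == "skip50"], 850L)
  expect_false(res$frameshift[res$read_id == "skip51"])
  # transcripts without CDS are skipped
  nocds <- gene_models(tibble::tibble(
    transcript_id = "t2", gene_id = "g2", chrom = "chr1", strand = "+",
    exons = list(cbind(start = 0L, end = 1000L)),
    cds = list(cbind(start = integer(0), end = integer(0)))))
  expect_equal(nrow(nmd_frameshift_screen(full, nocds)), 0L)
})
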
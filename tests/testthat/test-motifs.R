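# PWM scanning, poly(A) hexamer set, dinucleotide shuffles, enrichment
# profiles and metagene densities.

toy_pwm <- function() {
  # consensus ACGT, strong log-odds
  m <- matrix(-2, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 2; m["C", 2] <- 2; m["G", 3] <- 2; m["T", 4] <- 2
  pwm(m, "toy")
}

test_that("PWM scanning scores the consensus maximally", {
  p <- toy_pwm()
  expect_equal(max_pwm_score(p), 8)
  hits <- scan_pwm("ACGT", p, threshold = -Inf)
  expect_equal(hits$score, 8)
  # uniform PWM scores identically at every offset
  u <- pwm(matrix(1, 4, 3, dimnames = list(c("A", "C", "G", "U"), NULL)))
  hits_u <- scan_pwm("ACGTACGT", u, threshold = -Inf)
  expect_true(all(hits_u$score == 3))
  expect_equal(nrow(hits_u), 6L)
  # shorter sequence than the PWM: no hits
  expect_equal(nrow(scan_pwm("AC", p)), 0L)
})

test_that("ambiguous bases score the position mean", {
  p <- toy_pwm()
  hits <- scan_pwm("NCGT", p, threshold = -Inf)
  expect_equal(hits$score, mean(c(2, -2, -2, -2)) + 6)
})

test_that("scan hits equal a brute-force per-offset oracle", {
  set.seed(81)
  p <- toy_pwm()
  for (i in 1:20) {
    s <- random_dna(50)
    hits <- scan_pwm(s, p, threshold = 2)
    chars <- strsplit(s, "")[[1]]
    want_scores <- vapply(1:(50 - 3), function(o) {
      sum(vapply(1:4, function(j) p$matrix[chars[o + j - 1], j], numeric(1)))
    }, numeric(1))
    want <- which(want_scores >= 2) - 1L
    expect_equal(hits$offset, want)
    expect_equal(hits$score, want_scores[want + 1L])
  }
})

test_that("RNA and DNA alphabets are interchangeable in scanning", {
  p <- toy_pwm()
  expect_equal(scan_pwm("ACGU", p, threshold = -Inf)$score, 8)
})

test_that("the poly(A) hexamer family has exactly the stated members", {
  hx <- pas_hexamer_set()
  expect_length(hx, 18L)
  expect_true(all(c("AAUAAA", "UAUAAA", "AACAAA", "AAGAAA") %in% hx))
  expect_false("AAAAAA" %in% hx)
  expect_true(all(nchar(hx) == 6L))
  # every member is within Hamming distance 1 of the canonical signal
  hd <- vapply(hx, function(h) {
    sum(strsplit(h, "")[[1]] != strsplit("AAUAAA", "")[[1]])
  }, integer(1))
  expect_true(all(hd <= 1L))
  expect_equal(anyDuplicated(hx), 0L)
})

test_that("dinucleotide shuffle preserves composition and terminals exactly", {
  expect_equal(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  expect_equal(dinucleotide_shuffle("ACGT", seed = 1), "ACGT")
  # AATAAT has exactly three valid arrangements (exhaustive enumeration of
  # A....T orderings preserving the dinucleotide multiset); all occur
  middle <- unique(combinat_perms(c("A", "A", "A", "T")))
  cands <- vapply(middle, function(m) paste0("A", paste(m, collapse = ""), "T"), "")
  valid <- cands[vapply(cands, function(x) {
    identical(dinuc_counts(x), dinuc_counts("AATAAT"))
  }, logical(1))]
  expect_setequal(valid, c("AATAAT", "AAATAT", "ATAAAT"))
  draws <- vapply(1:200, function(s) dinucleotide_shuffle("AATAAT", seed = s),
                  "")
  expect_true(all(draws %in% valid))
  expect_true(all(valid %in% draws))
  set.seed(82)
  for (i in 1:1000) {
    s <- random_dna(sample(10:60, 1))
    sh <- dinucleotide_shuffle(s, seed = i)
    expect_identical(dinuc_counts(sh), dinuc_counts(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    n <- nchar(s)
    expect_identical(substr(sh, n, n), substr(s, n, n))
  }
})

test_that("planted AAUAAA produces a sharp enrichment peak at its offset", {
  set.seed(83)
  # 100 nt windows with the canonical signal planted at offset 31
  # (19 nt upstream of a cleavage site at the window centre)
  windows <- vapply(1:30, function(i) {
    s <- strsplit(random_dna(100), "")[[1]]
    s[32:37] <- c("A", "A", "T", "A", "A", "A")
    paste(s, collapse = "")
  }, "")
  enr <- hexamer_enrichment(windows, n_shuffles = 50, seed = 9)
  can <- enr[enr$motif_group == "AAUAAA", ]
  expect_equal(can$offset[which.max(can$log2_enrichment)], 31L)
  expect_gt(max(can$log2_enrichment), 3)
})

test_that("windows without any A yield floor-level enrichment", {
  windows <- rep(strrep("C", 60), 5)
  enr <- hexamer_enrichment(windows, n_shuffles = 10, seed = 10)
  expect_true(all(enr$observed == 0))
  expect_true(all(enr$log2_enrichment == 0))  # log2(0.5/0.5)
})

test_that("a shuffle profiled against shuffles shows no enrichment", {
  set.seed(84)
  base <- vapply(1:20, function(i) random_dna(80), "")
  windows <- vapply(seq_along(base), function(i) {
    dinucleotide_shuffle(base[i], seed = 1000 + i)
  }, "")
  enr <- hexamer_enrichment(windows, n_shuffles = 60, seed = 11)
  expect_lt(mean(abs(enr$log2_enrichment)), 0.6)
})

test_that("enrichment is invariant to window order", {
  set.seed(85)
  windows <- vapply(1:10, function(i) random_dna(50), "")
  a <- hexamer_enrichment(windows, n_shuffles = 20, seed = 12)
  b <- hexamer_enrichment(rev(windows), n_shuffles = 20, seed = 12)
  expect_equal(a$observed, b$observed)
  expect_equal(a$expected, b$expected)
  expect_error(hexamer_enrichment(c("AAAA", "AAAAA")), "equal length")
})

test_that("metagene density is strand-aware and matches offset counting", {
  anchors <- tibble::tibble(chrom = "chr1", pos = c(100L, 500L),
                            strand = c("+", "-"))
  features <- tibble::tibble(chrom = "chr1", pos = c(100L, 510L))
  md <- metagene_density(features, anchors, span = 20L)
  # feature at its own anchor -> offset 0; "-" anchor flips +10 to -10
  expect_equal(md$count[md$offset == 0], 1L)
  expect_equal(md$count[md$offset == -10], 1L)
  expect_equal(md$count[md$offset == 10], 0L)
  expect_equal(sum(md$density), 1)
  set.seed(86)
  anch <- tibble::tibble(chrom = "chr1", pos = sample(200:800, 20),
                         strand = sample(c("+", "-"), 20, replace = TRUE))
  feat <- tibble::tibble(chrom = "chr1", pos = sample(1:1000, 200,
                                                      replace = TRUE))
  md2 <- metagene_density(feat, anch, span = 50L)
  want <- integer(101)
  for (i in seq_len(nrow(anch))) {
    d <- feat$pos - anch$pos[i]
    if (anch$strand[i] == "-") d <- -d
    d <- d[abs(d) <= 50]
    for (x in d) want[x + 51L] <- want[x + 51L] + 1L
  }
  expect_equal(md2$count, want)
})

test_that("PWM files round-trip through the tab-delimited dialect", {
  p <- toy_pwm()
  path <- file.path(tempdir(), "toy_pwm.tsv")
  write_pwm(p, path)
  back <- read_pwm(path)
  expect_equal(back$matrix, p$matrix)
  expect_equal(back$width, 4L)
})

test_that("minimal MEME motif files are parsed into log-odds PWMs", {
  path <- file.path(tempdir(), "motif.meme")
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF DRACH", "letter-probability matrix: alength= 4 w= 2 nsites= 10",
    " 0.970 0.010 0.010 0.010", " 0.010 0.010 0.010 0.970"), path)
  p <- read_pwm(path)
  expect_equal(p$name, "DRACH")
  expect_equal(p$width, 2L)
  # consensus AT scores highest
  hits <- scan_pwm("GGATGG", p, threshold = -Inf)
  expect_equal(hits$offset[which.max(hits$score)], 2L)
})
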
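## Sequence-level analyses around called sites: PWM scanning, the poly(A)
## signal hexamer family, dinucleotide-preserving shuffles, hexamer
## enrichment profiles and metagene densities.

#' Construct a position weight matrix
#'
#' @param matrix numeric matrix with rows `A`, `C`, `G`, `T` (or `U`) and
#'   one column per motif position; entries are additive scores
#'   (e.g. log-odds).
#' @param name motif name.
#' @return object of class `pwm`.
#' @export
pwm <- function(matrix, name = "motif") {
  m <- as.matrix(matrix)
  rownames(m) <- chartr("U", "T", toupper(rownames(m)))
  if (!identical(sort(rownames(m)), DNA_BASES)) {
    stopf("PWM rows must be A, C, G, T/U")
  }
  m <- m[DNA_BASES, , drop = FALSE]
  if (any(!is.finite(m))) stopf("PWM scores must be finite")
  structure(list(name = name, matrix = m, width = ncol(m)), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s': width %d, max score %.3f\n", x$name, x$width,
              max_pwm_score(x)))
  invisible(x)
}

#' Maximum attainable additive score of a PWM
#' @param x a [pwm()] object.
#' @return numeric scalar.
#' @export
max_pwm_score <- function(x) sum(apply(x$matrix, 2, max))

#' Read a PWM from a tab-delimited file or minimal MEME motif file
#'
#' The tab-delimited dialect has a header `A C G T` (or `U`) and one row of
#' scores per motif position. MEME files are parsed for the first
#' letter-probability matrix; probabilities are converted to log2 odds
#' against `background` with a pseudo-count.
#'
#' @param path input file.
#' @param name motif name (default: file stem or the MEME motif name).
#' @param background background base frequencies for MEME probability
#'   matrices (default uniform).
#' @param pseudo pseudo-probability added before the log (default 1e-3).
#' @return a [pwm()] object.
#' @export
read_pwm <- function(path, name = NULL, background = rep(0.25, 4),
                     pseudo = 1e-3) {
  lines <- readLines(path)
  if (any(grepl("^MEME version", lines))) {
    mi <- grep("^MOTIF", lines)[1]
    if (is.na(mi)) stopf("no MOTIF record in MEME file '%s'", path)
    if (is.null(name)) name <- strsplit(trimws(lines[mi]), "\\s+")[[1]][2]
    li <- grep("^letter-probability matrix", lines)[1]
    rows <- list()
    for (j in (li + 1):length(lines)) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
      if (length(v) != 4L || any(is.na(v))) break
      rows[[length(rows) + 1L]] <- v
    }
    probs <- do.call(rbind, rows)
    scores <- t(log2((probs + pseudo) / rep(background, each = nrow(probs))))
    rownames(scores) <- DNA_BASES
    return(pwm(scores, name))
  }
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pwm(t(as.matrix(tab)), name)
}

#' Write a PWM to the tab-delimited dialect
#' @param x a [pwm()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  write.table(t(x$matrix), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Scan a sequence with a PWM
#'
#' Additive per-offset scores; ambiguous bases contribute the mean score of
#' their position. Sequences shorter than the PWM yield no hits.
#'
#' @param sequence character scalar (DNA or RNA alphabet).
#' @param x a [pwm()] object.
#' @param threshold minimum score to report; default 60% of the maximum
#'   attainable score.
#' @return tibble `offset` (0-based start), `score`.
#' @export
scan_pwm <- function(sequence, x, threshold = 0.6 * max_pwm_score(x)) {
  s <- chartr("Uu", "Tt", toupper(sequence))
  n <- nchar(s)
  w <- x$width
  if (n < w) return(tibble(offset = integer(0), score = numeric(0)))
  chars <- strsplit(s, "")[[1]]
  code <- match(chars, DNA_BASES)
  colmean <- colMeans(x$matrix)
  score_at <- matrix(0, nrow = n, ncol = w)
  for (j in seq_len(w)) {
    v <- x$matrix[, j][code]
    v[is.na(code)] <- colmean[j]
    score_at[, j] <- v
  }
  offsets <- 0:(n - w)
  total <- vapply(offsets, function(o) {
    sum(score_at[cbind(o + seq_len(w), seq_len(w))])
  }, numeric(1))
  hit <- total >= threshold
  tibble(offset = offsets[hit], score = total[hit])
}

#' The poly(A) signal hexamer family
#'
#' `AAUAAA` plus every hexamer at Hamming distance one (single
#' substitution), excluding `AAAAAA`: exactly 18 hexamers, RNA alphabet.
#'
#' @return character vector of 18 hexamers.
#' @export
pas_hexamer_set <- function() {
  base <- "AAUAAA"
  out <- base
  for (i in 1:6) {
    for (b in c("A", "C", "G", "U")) {
      if (substr(base, i, i) == b) next
      v <- base
      substr(v, i, i) <- b
      out <- c(out, v)
    }
  }
  setdiff(unique(out), "AAAAAA")
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Random Eulerian-path shuffle on the dinucleotide transition multigraph:
#' the output has exactly the input's dinucleotide multiset and the same
#' first and last nucleotide. Edge orders are randomly permuted and the
#' walk retried on dead ends, giving a random valid arrangement.
#'
#' @param sequence character scalar, length >= 2.
#' @param seed RNG seed (optional).
#' @return shuffled character scalar.
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2L) stopf("sequence must have length >= 2")
  with_seed(seed, {
    from <- chars[-n]; to <- chars[-1L]
    verts <- unique(chars)
    edges <- split(to, factor(from, levels = verts))
    n_edges <- lengths(edges)
    for (attempt in seq_len(1000L)) {
      bag <- lapply(edges, function(e) sample(e, length(e)))
      ptr <- setNames(rep(1L, length(verts)), verts)
      path <- character(n)
      path[1] <- chars[1]
      cur <- chars[1]
      ok <- TRUE
      for (i in 2:n) {
        if (ptr[cur] > n_edges[[cur]]) { ok <- FALSE; break }
        nxt <- bag[[cur]][ptr[cur]]
        ptr[cur] <- ptr[cur] + 1L
        path[i] <- nxt
        cur <- nxt
      }
      if (ok) return(paste(path, collapse = ""))
    }
  })
  stopf("failed to find an Eulerian rearrangement (pathological input?)")
}

# count occurrences of any of `motifs` starting at each offset of each
# window; lookahead regex so overlapping self-matches are counted too
count_motif_starts <- function(windows, motifs) {
  w <- nchar(windows[1])
  k <- nchar(motifs[1])
  counts <- integer(w - k + 1L)
  for (s in windows) {
    for (m in motifs) {
      hits <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1]]
      hits <- hits[hits > 0]
      counts[hits] <- counts[hits] + 1L
    }
  }
  counts
}

#' Positional hexamer enrichment against dinucleotide-preserving shuffles
#'
#' Counts motif starts at each offset of equal-length windows (e.g. 100 nt
#' windows centred on m6A motifs), estimates the expected count per offset
#' as the median over `n_shuffles` dinucleotide-preserving shuffles of every
#' window, and reports `log2((obs + 0.5) / (median_expected + 0.5))`. The
#' canonical `AAUAAA` is profiled separately from the 17 related hexamers.
#'
#' @param windows character vector of equal-length sequences (DNA or RNA).
#' @param n_shuffles shuffles per window (default 1000).
#' @param seed RNG seed.
#' @param motifs hexamer set (default [pas_hexamer_set()]).
#' @return tibble `offset` (0-based window offset), `motif_group`
#'   (`AAUAAA` / `related`), `observed`, `expected`, `log2_enrichment`.
#' @export
hexamer_enrichment <- function(windows, n_shuffles = 1000L, seed = 1L,
                               motifs = pas_hexamer_set()) {
  if (length(windows) == 0L) stopf("no windows supplied")
  if (length(unique(nchar(windows))) != 1L) {
    stopf("windows must have equal length")
  }
  windows <- chartr("Uu", "Tt", toupper(windows))
  motifs_dna <- chartr("U", "T", motifs)
  groups <- list(AAUAAA = "AATAAA",
                 related = setdiff(motifs_dna, "AATAAA"))
  obs <- lapply(groups, function(m) count_motif_starts(windows, m))
  exp_counts <- with_seed(seed, {
    lapply(groups, function(m) {
      draws <- matrix(0L, n_shuffles, length(obs[[1]]))
      for (r in seq_len(n_shuffles)) {
        shuf <- vapply(windows, dinucleotide_shuffle, "", USE.NAMES = FALSE)
        draws[r, ] <- count_motif_starts(shuf, m)
      }
      draws
    })
  })
  rows <- lapply(names(groups), function(g) {
    med <- apply(exp_counts[[g]], 2, median)
    tibble(offset = seq_along(obs[[g]]) - 1L, motif_group = g,
           observed = obs[[g]], expected = med,
           log2_enrichment = log2((obs[[g]] + 0.5) / (med + 0.5)))
  })
  bind_rows(rows)
}

#' Metagene density of features around stranded anchors
#'
#' Strand-aware relative offsets of features around anchor positions
#' (offsets flip sign on "-" anchors), histogrammed over `[-span, span]`
#' and normalised to sum to one.
#'
#' @param features tibble with `chrom`, `pos`.
#' @param anchors tibble with `chrom`, `pos`, `strand`.
#' @param span half-width in nt (default 500).
#' @return tibble `offset`, `count`, `density`.
#' @export
metagene_density <- function(features, anchors, span = 500L) {
  offsets <- integer(0)
  for (i in seq_len(nrow(anchors))) {
    f <- features$pos[features$chrom == anchors$chrom[i]]
    d <- f - anchors$pos[i]
    if (anchors$strand[i] == "-") d <- -d
    offsets <- c(offsets, d[abs(d) <= span])
  }
  counts <- tabulate(offsets + span + 1L, nbins = 2L * span + 1L)
  tibble(offset = -span:span, count = counts,
         density = if (sum(counts) > 0) counts / sum(counts) else counts)
}
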
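#' Reverse complement of a DNA/RNA string
#'
#' @param x character vector of sequences (A/C/G/T/U/N, case-insensitive).
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTUacgtun", "TGCAAtgcaan", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

# run a block with a local, restored RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_interval <- function(start, end, what = "interval") {
  if (any(is.na(start)) || any(is.na(end)) || any(start < 0) || any(start >= end)) {
    stopf("malformed %s: require 0 <= start < end (half-open)", what)
  }
  invisible(TRUE)
}

#' Extract subsequence from an in-memory genome
#'
#' The genome is a named character vector of chromosome sequences; coordinates
#' are 0-based half-open. On strand "-" the reverse complement is returned.
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates.
#' @param strand "+" (default) or "-".
#' @return character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stopf("chromosome '%s' not in genome", chrom)
  check_interval(start, end)
  if (end > nchar(genome[[chrom]])) stopf("interval beyond end of '%s'", chrom)
  s <- substr(genome[[chrom]], start + 1L, end)
  if (identical(strand, "-")) revcomp(s) else s
}

# discrete Gaussian smoothing with a +/- 4 sigma truncated kernel,
# zero-padded at the edges
smooth_gaussian <- function(x, sigma) {
  half <- as.integer(ceiling(4 * sigma))
  kernel <- dnorm(-half:half, sd = sigma)
  kernel <- kernel / sum(kernel)
  out <- as.numeric(stats::filter(c(rep(0, half), x, rep(0, half)),
                                  kernel, sides = 2L))
  out[(half + 1L):(half + length(x))]
}

# leftmost index of each strict-local-minimum plateau of a numeric vector
local_minima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer(0))
  i <- 2:(k - 1L)
  is_min <- r$values[i] < r$values[i - 1L] & r$values[i] < r$values[i + 1L]
  starts[i][is_min]
}
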
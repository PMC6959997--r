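## Log-likelihood ratio (G) tests on basecall contingency tables, replicate
## homogeneity statistics, multiple-testing correction and the
## Haldane-corrected log2 fold change.

#' G-test of independence on a K x C contingency table
#'
#' Computes `G = 2 * sum(O * ln(O/E))` over cells with observed count > 0,
#' with expected counts from row/column marginals. Columns whose total is
#' zero are dropped and the degrees of freedom reduced accordingly; no
#' Williams or Yates correction is applied. A table with fewer than two rows
#' with positive totals is degenerate and raises an error. When all counts
#' fall in a single column the test is untestable: `df = 0` and `p = NA`.
#'
#' @param table non-negative integer matrix (rows = conditions/clusters,
#'   columns = basecall categories).
#' @return list with `G`, `df` and `p` (upper chi-square tail; `NA` when
#'   `df == 0`).
#' @export
g_test <- function(table) {
  x <- as.matrix(table)
  if (any(is.na(x)) || any(x < 0)) stopf("contingency table must be non-negative")
  x <- x[rowSums(x) > 0, , drop = FALSE]
  if (nrow(x) < 2L) stopf("degenerate table: need at least two rows with positive totals")
  x <- x[, colSums(x) > 0, drop = FALSE]
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  E <- outer(rowSums(x), colSums(x)) / sum(x)
  pos <- x > 0
  G <- 2 * sum(x[pos] * log(x[pos] / E[pos]))
  list(G = G, df = df,
       p = if (df == 0L) NA_real_ else pchisq(G, df, lower.tail = FALSE))
}

# vectorised 2 x 5 G-test across positions: c1, c2 are 5 x W count matrices
# (one per condition). Returns G, df, p vectors; p is NA where either
# condition has zero coverage or df == 0.
g_test_two_cond <- function(c1, c2) {
  n1 <- colSums(c1); n2 <- colSums(c2)
  s <- c1 + c2
  tot <- n1 + n2
  xlogx <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  e1 <- sweep(s, 2, n1 / pmax(tot, 1), "*")
  e2 <- sweep(s, 2, n2 / pmax(tot, 1), "*")
  G <- 2 * (colSums(xlogx(c1, e1)) + colSums(xlogx(c2, e2)))
  df <- pmax(colSums(s > 0) - 1L, 0L)
  p <- rep(NA_real_, length(G))
  testable <- n1 > 0 & n2 > 0 & df > 0
  p[testable] <- pchisq(G[testable], df[testable], lower.tail = FALSE)
  list(G = G, df = df, p = p)
}

# vectorised within-condition homogeneity G across positions: `counts` is a
# list of per-replicate 5 x W matrices. Degenerate positions (fewer than two
# replicates with coverage) contribute G = 0.
g_hom_vec <- function(counts) {
  if (length(counts) < 2L) return(rep(0, ncol(counts[[1]])))
  s <- Reduce(`+`, counts)
  tot <- colSums(s)
  G <- rep(0, ncol(s))
  for (cm in counts) {
    nr <- colSums(cm)
    e <- sweep(s, 2, nr / pmax(tot, 1), "*")
    pos <- cm > 0
    contrib <- matrix(0, nrow(cm), ncol(cm))
    contrib[pos] <- cm[pos] * log(cm[pos] / e[pos])
    G <- G + 2 * colSums(contrib)
  }
  G
}

#' Replicate homogeneity filter for a tested position
#'
#' Within each condition, a replicate x 5 G statistic measures disagreement
#' between replicates. If the summed within-condition homogeneity G exceeds
#' the between-condition G, the between-condition signal is weaker than the
#' replicate noise and the site is dropped. Conditions with a single
#' replicate contribute G = 0.
#'
#' @param replicate_tables list (one element per condition) of matrices with
#'   one row per replicate and 5 category columns.
#' @param between_G the between-condition G statistic at the position.
#' @return list with `hom_G_sum` and `keep` (logical).
#' @export
homogeneity_filter <- function(replicate_tables, between_G) {
  hom <- vapply(replicate_tables, function(tab) {
    tab <- as.matrix(tab)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) return(0)
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2L) return(0)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    pos <- tab > 0
    2 * sum(tab[pos] * log(tab[pos] / E[pos]))
  }, numeric(1))
  s <- sum(hom)
  list(hom_G_sum = s, keep = s <= between_G)
}

#' Benjamini-Hochberg corrected q-values
#'
#' Step-up false discovery rate correction, order-preserving with the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`; `NA`/`NaN` raise an
#'   error.
#' @return numeric vector of q-values.
#' @export
bh_correct <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stopf("p-values must be finite and in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Haldane-corrected log2 fold change of the mismatch:match ratio
#'
#' `log2(((mm_ref + 0.5)/(m_ref + 0.5)) / ((mm_mut + 0.5)/(m_mut + 0.5)))`,
#' where `ref` is the condition with the modification present (e.g. a
#' complemented line) and `mut` the writer mutant. "Mismatch" pools the four
#' non-reference categories including indel. The 0.5 offset is applied
#' unconditionally, so the value is finite for every count configuration.
#' Values above 1 indicate an error rate at least two-fold reduced in the
#' mutant.
#'
#' @param mm_ref,m_ref mismatch and match counts in the
#'   modification-positive condition.
#' @param mm_mut,m_mut mismatch and match counts in the mutant.
#' @return numeric vector of log2 fold changes.
#' @export
haldane_log2fc <- function(mm_ref, m_ref, mm_mut, m_mut) {
  if (any(c(mm_ref, m_ref, mm_mut, m_mut) < 0)) stopf("counts must be >= 0")
  log2(((mm_ref + 0.5) / (m_ref + 0.5)) / ((mm_mut + 0.5) / (m_mut + 0.5)))
}
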
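# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and, where possible, the base R
# functions the package delegates to).

# G statistic by direct cell-wise summation
oracle_g <- function(tab) {
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  total <- sum(tab)
  g <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      o <- tab[i, j]
      if (o > 0) {
        e <- sum(tab[i, ]) * sum(tab[, j]) / total
        g <- g + o * log(o / e)
      }
    }
  }
  list(G = 2 * g, df = (nrow(tab) - 1) * (ncol(tab) - 1))
}

# upper chi-square tail for integer df <= 4 from closed forms; erfc via the
# incomplete-gamma continued fraction (modified Lentz), no pnorm/pchisq
oracle_erfc <- function(x) {
  # erfc(x) = gamma_upper(1/2, x^2) / sqrt(pi), continued fraction for the
  # upper incomplete gamma function (valid for x > 0)
  if (x == 0) return(1)
  if (x < 0) return(2 - oracle_erfc(-x))
  a <- 0.5; xx <- x^2
  tiny <- 1e-300
  b <- xx + 1 - a
  c <- 1 / tiny
  d <- 1 / b
  h <- d
  for (i in 1:200) {
    an <- -i * (i - a)
    b <- b + 2
    d <- an * d + b
    if (abs(d) < tiny) d <- tiny
    c <- b + an / c
    if (abs(c) < tiny) c <- tiny
    d <- 1 / d
    del <- d * c
    h <- h * del
    if (abs(del - 1) < 1e-15) break
  }
  exp(-xx + a * log(xx) - lgamma(a)) * h
}

oracle_chisq_upper <- function(x, df) {
  stopifnot(df >= 1, df <= 4)
  switch(df,
         oracle_erfc(sqrt(x / 2)),                               # df = 1
         exp(-x / 2),                                            # df = 2
         oracle_erfc(sqrt(x / 2)) +
           sqrt(2 * x / pi) * exp(-x / 2),                       # df = 3
         exp(-x / 2) * (1 + x / 2))                              # df = 4
}

# Benjamini-Hochberg by the literal step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest p down
  for (i in (m - 1):1) {
    if (m == 1) break
    q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# exact two-sample KS p-value by enumeration of all assignments of the
# pooled sample to the two groups (no ties assumed)
oracle_ks_exact <- function(x, y) {
  ks_d <- function(a, b) {
    v <- sort(unique(c(a, b)))
    max(abs(ecdf_at(a, v) - ecdf_at(b, v)))
  }
  ecdf_at <- function(s, v) vapply(v, function(t) mean(s <= t), numeric(1))
  d_obs <- ks_d(x, y)
  pooled <- c(x, y)
  n <- length(x)
  combos <- utils::combn(length(pooled), n)
  ds <- apply(combos, 2, function(idx) ks_d(pooled[idx], pooled[-idx]))
  mean(ds >= d_obs - 1e-12)
}

# hypergeometric upper tail P(X >= k) by direct summation of choose() terms
oracle_hyper_upper <- function(k, n_annot, n_other, n_drawn) {
  tot <- n_annot + n_other
  kk <- k:min(n_annot, n_drawn)
  sum(choose(n_annot, kk) * choose(n_other, n_drawn - kk)) /
    choose(tot, n_drawn)
}

# all permutations of a small character vector (recursive)
combinat_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# dinucleotide count table of a sequence
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(table(character(0)))
  table(paste0(ch[-length(ch)], ch[-1]))
}
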
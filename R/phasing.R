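## Phasing of modification signal with poly(A)-site choice: reads are
## clustered by 3' end position using local minima of a Gaussian-smoothed
## single-base histogram, and the basecall profiles of the clusters at an
## already-called error site are compared with an N x 5 G-test.

#' Cluster reads by 3' end position
#'
#' Builds a single-base histogram of 3' end positions, convolves it with a
#' Gaussian kernel (truncated at +/- 4 sigma), cuts at strict local minima
#' of the smoothed density (plateaus cut at their leftmost base), and drops
#' clusters with fewer than `min_cluster` reads.
#'
#' @param ends integer vector of 0-based 3' end positions (one per read), or
#'   a [drs_reads()] tibble (ends taken via [three_prime_pos()]).
#' @param sigma Gaussian smoothing bandwidth in nt (default 13).
#' @param min_cluster minimum reads per retained cluster (default 10).
#' @return object of class `polya_clusters`: list with `clusters` (tibble:
#'   `label`, `start`, `end`, `n`, `mode`), `assignment` (cluster label per
#'   input read, `NA` for reads in discarded clusters) and `cut_points`.
#' @export
cluster_three_prime_ends <- function(ends, sigma = 13, min_cluster = 10L) {
  stopifnot(sigma > 0)
  if (is.data.frame(ends)) ends <- three_prime_pos(ends)
  if (length(ends) == 0L) stopf("no reads to cluster")
  half <- as.integer(ceiling(4 * sigma))
  lo <- min(ends) - half; hi <- max(ends) + half
  counts <- tabulate(ends - lo + 1L, nbins = hi - lo + 1L)
  sm <- smooth_gaussian(counts, sigma)
  cuts <- local_minima(sm) + lo - 1L  # leftmost base of each minimum plateau
  breaks <- c(lo - 1L, cuts, hi + 1L)
  cl <- findInterval(ends, breaks + 0.5)
  sizes <- tabulate(cl, nbins = length(breaks) - 1L)
  keep <- which(sizes >= min_cluster)
  labels <- rep(NA_character_, length(ends))
  rows <- lapply(seq_along(keep), function(k) {
    i <- keep[k]
    members <- cl == i
    labels[members] <<- sprintf("pA%d", k)
    tab <- table(ends[members])
    mode_pos <- as.integer(names(tab)[which.max(tab)])  # leftmost modal tie
    tibble(label = sprintf("pA%d", k),
           start = min(ends[members]), end = max(ends[members]) + 1L,
           n = sum(members), mode = mode_pos)
  })
  structure(list(clusters = bind_rows(rows), assignment = labels,
                 cut_points = cuts, sigma = sigma,
                 min_cluster = as.integer(min_cluster)),
            class = "polya_clusters")
}

#' @export
print.polya_clusters <- function(x, ...) {
  cat(sprintf("polya_clusters: %d cluster(s), %d assigned read(s)\n",
              nrow(x$clusters), sum(!is.na(x$assignment))))
  invisible(x)
}

#' Test association between basecall profile and poly(A) cluster at a site
#'
#' Builds the 5-category basecall profile of each retained 3' cluster at the
#' given position and tests profile-by-cluster independence with an N x 5
#' G-test. Only positions already called as differential error sites should
#' be supplied (the caller's responsibility). With fewer than two clusters
#' covering the site the result is marked untestable rather than an error.
#'
#' @param reads the reads that were clustered (same order as the clustering
#'   input).
#' @param clusters a [cluster_three_prime_ends()] result for `reads`.
#' @param chrom,pos site position (0-based).
#' @return list with `G`, `df`, `p`, `untestable` (logical) and `profiles`
#'   (cluster x 5 count matrix).
#' @export
phase_test <- function(reads, clusters, chrom, pos) {
  cm <- read_category_matrix(reads, chrom, pos, pos + 1L)
  lab <- clusters$assignment
  keep <- !is.na(lab) & cm[, 1] > 0L
  labs <- clusters$clusters$label
  prof <- t(vapply(labs, function(l) {
    tabulate(cm[keep & lab == l, 1], nbins = 5L)
  }, integer(5)))
  colnames(prof) <- CATEGORIES
  covered <- rowSums(prof) > 0
  if (sum(covered) < 2L) {
    return(list(G = NA_real_, df = NA_integer_, p = NA_real_,
                untestable = TRUE, profiles = prof))
  }
  gt <- g_test(prof[covered, , drop = FALSE])
  list(G = gt$G, df = gt$df, p = gt$p, untestable = is.na(gt$p),
       profiles = prof)
}

#' Phase called error sites with poly(A)-site choice across genes
#'
#' For each site, clusters the modification-positive condition's reads
#' overlapping the site by 3' end and runs [phase_test()]; BH correction is
#' applied across all tested sites.
#'
#' @param reads reads of the modification-positive condition.
#' @param sites tibble of called sites with `chrom` and `pos`.
#' @param sigma,min_cluster clustering parameters (defaults 13 nt, 10
#'   reads).
#' @param fdr BH significance threshold (default 0.05).
#' @return tibble per site: `chrom`, `pos`, `n_clusters`, `G`, `df`, `p`,
#'   `q`, `sig`, `untestable`, plus a `profiles` list-column.
#' @export
test_phasing <- function(reads, sites, sigma = 13, min_cluster = 10L,
                         fdr = 0.05) {
  if (nrow(sites) == 0L) {
    return(tibble(chrom = character(0), pos = integer(0),
                  n_clusters = integer(0), G = numeric(0), df = integer(0),
                  p = numeric(0), untestable = logical(0),
                  profiles = list(), q = numeric(0), sig = logical(0)))
  }
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    ov <- reads$chrom == sites$chrom[i] & reads$start <= sites$pos[i] &
      reads$end > sites$pos[i]
    sub <- reads[ov, , drop = FALSE]
    if (nrow(sub) == 0L) {
      return(tibble(chrom = sites$chrom[i], pos = sites$pos[i],
                    n_clusters = 0L, G = NA_real_, df = NA_integer_,
                    p = NA_real_, untestable = TRUE, profiles = list(NULL)))
    }
    cl <- cluster_three_prime_ends(sub, sigma = sigma,
                                   min_cluster = min_cluster)
    pt <- phase_test(sub, cl, sites$chrom[i], sites$pos[i])
    tibble(chrom = sites$chrom[i], pos = sites$pos[i],
           n_clusters = nrow(cl$clusters), G = pt$G, df = pt$df, p = pt$p,
           untestable = pt$untestable, profiles = list(pt$profiles))
  })
  res <- bind_rows(rows)
  res$q <- NA_real_
  ok <- !res$untestable & !is.na(res$p)
  res$q[ok] <- bh_correct(res$p[ok])
  res$sig <- !is.na(res$q) & res$q < fdr
  res
}

#' Pairwise cluster comparisons at a phased site
#'
#' Follow-up 2 x 5 G-tests between every pair of clusters, BH-corrected.
#'
#' @param profiles cluster x 5 count matrix (from [phase_test()]).
#' @param fdr BH threshold (default 0.05).
#' @return tibble `cluster1`, `cluster2`, `G`, `p`, `q`, `sig`.
#' @export
phase_pairwise <- function(profiles, fdr = 0.05) {
  labs <- rownames(profiles)
  cmb <- utils::combn(seq_len(nrow(profiles)), 2L)
  rows <- lapply(seq_len(ncol(cmb)), function(k) {
    i <- cmb[1, k]; j <- cmb[2, k]
    gt <- tryCatch(g_test(profiles[c(i, j), , drop = FALSE]),
                   error = function(e) list(G = NA_real_, df = NA_integer_,
                                            p = NA_real_))
    tibble(cluster1 = labs[i], cluster2 = labs[j], G = gt$G, p = gt$p)
  })
  res <- bind_rows(rows)
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- bh_correct(res$p[ok])
  res$sig <- !is.na(res$q) & res$q < fdr
  res
}
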
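#' Allele frequencies by group
#'
#' Frequency of the counted (oriented) allele among non-missing allele copies,
#' per group and locus. Haploid (mito) loci contribute one copy per
#' individual, diploid loci two.
#'
#' @param gm a `genotype_matrix`
#' @param grouping named character vector mapping individual ids to group
#'   labels; individuals absent from `grouping` are ignored
#' @return an object of class `freq_table`: list with matrices `freq`
#'   (groups x loci; NA where a group has no typed copies) and `n` (non-missing
#'   allele-copy counts)
#' @export
allele_freqs <- function(gm, grouping) {
  ids <- names(grouping)
  stopifnot(!is.null(ids), all(ids %in% rownames(gm$geno)))
  groups <- unique(grouping)
  p <- ploidy(gm)
  freq <- matrix(NA_real_, length(groups), ncol(gm$geno),
                 dimnames = list(groups, colnames(gm$geno)))
  n <- matrix(0L, length(groups), ncol(gm$geno),
              dimnames = dimnames(freq))
  for (g in groups) {
    sub <- gm$geno[ids[grouping == g], , drop = FALSE]
    copies <- colSums(!is.na(sub)) * p
    hits <- colSums(sub, na.rm = TRUE)
    n[g, ] <- as.integer(copies)
    freq[g, ] <- ifelse(copies > 0, hits / copies, NA_real_)
  }
  structure(list(freq = freq, n = n), class = "freq_table")
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d groups x %d loci\n",
              nrow(x$freq), ncol(x$freq)))
  invisible(x)
}

#' Per-locus allele-frequency difference between two groups
#'
#' @param freqs a `freq_table`
#' @param groupA,groupB group labels present in `freqs`
#' @return named numeric vector of |f_A - f_B| per locus (NA where either
#'   frequency is missing)
#' @export
afd <- function(freqs, groupA, groupB) {
  stopifnot(all(c(groupA, groupB) %in% rownames(freqs$freq)))
  abs(freqs$freq[groupA, ] - freqs$freq[groupB, ])
}

# ---------------------------------------------------------------------------
# Weir & Cockerham FST
# ---------------------------------------------------------------------------

# per-locus variance components a, b, c of the 1984 estimator for two
# populations given dosage matrices (diploid loci only)
wc_components <- function(gA, gB) {
  nA <- colSums(!is.na(gA))
  nB <- colSums(!is.na(gB))
  pA <- colMeans(gA, na.rm = TRUE) / 2
  pB <- colMeans(gB, na.rm = TRUE) / 2
  hA <- colMeans(gA == 1L, na.rm = TRUE)
  hB <- colMeans(gB == 1L, na.rm = TRUE)
  r <- 2
  nbar <- (nA + nB) / r
  nc <- (r * nbar - (nA^2 + nB^2) / (r * nbar)) / (r - 1)
  pbar <- (nA * pA + nB * pB) / (r * nbar)
  s2 <- (nA * (pA - pbar)^2 + nB * (pB - pbar)^2) / ((r - 1) * nbar)
  hbar <- (nA * hA + nB * hB) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Weir & Cockerham (1984) FST between two groups
#'
#' Variance-components estimator theta per locus and over loci (ratio of
#' summed components), with an optional permutation test shuffling group
#' labels. Loci monomorphic across both groups contribute zero to both the
#' numerator and denominator and are effectively excluded; haploid (mito)
#' loci are excluded, as the estimator assumes diploid genotypes.
#'
#' @param gm a `genotype_matrix`
#' @param idsA,idsB individual ids of two non-overlapping groups (>= 2 each)
#' @param n_perm number of label permutations (0 = no test); the p-value uses
#'   the add-one rule p = (1 + #\{theta* >= theta\}) / (n_perm + 1)
#' @return list `theta` (multi-locus), `theta_locus` (per locus), `p`
#'   (permutation p or NA)
#' @export
wc_fst <- function(gm, idsA, idsB, n_perm = 0) {
  stopifnot(length(idsA) >= 2, length(idsB) >= 2,
            length(intersect(idsA, idsB)) == 0)
  dip <- gm$loci$type != "mito"
  gA <- gm$geno[idsA, dip, drop = FALSE]
  gB <- gm$geno[idsB, dip, drop = FALSE]
  multi_theta <- function(gA, gB) {
    k <- wc_components(gA, gB)
    denom <- k$a + k$b + k$c
    ok <- is.finite(denom) & denom != 0
    list(theta = sum(k$a[ok]) / sum(denom[ok]),
         theta_locus = ifelse(is.finite(denom) & denom != 0,
                              k$a / denom, NA_real_))
  }
  obs <- multi_theta(gA, gB)
  pval <- NA_real_
  if (n_perm > 0) {
    pool <- rbind(gA, gB)
    nA <- nrow(gA)
    hits <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(nrow(pool))
      th <- multi_theta(pool[idx[seq_len(nA)], , drop = FALSE],
                        pool[idx[-seq_len(nA)], , drop = FALSE])$theta
      if (!is.na(th) && th >= obs$theta) hits <- hits + 1L
    }
    pval <- (1 + hits) / (n_perm + 1)
  }
  list(theta = obs$theta, theta_locus = obs$theta_locus, p = pval)
}

#' Loci badly typed within a set of individuals
#'
#' Convenience screen used before reference-differentiation computations:
#' returns the loci whose missing fraction within `ids` exceeds `max_frac`
#' (e.g. markers unreliable in *M. trossulus* samples).
#'
#' @param gm a `genotype_matrix`
#' @param ids individual ids defining the screen set
#' @param max_frac maximum tolerated missing fraction (default 0.3)
#' @return character vector of locus names to drop
#' @export
loci_high_missing <- function(gm, ids, max_frac = 0.3) {
  sub <- gm$geno[ids, , drop = FALSE]
  colnames(sub)[colMeans(is.na(sub)) > max_frac]
}

# ---------------------------------------------------------------------------
# Hardy-Weinberg Monte-Carlo tests
# ---------------------------------------------------------------------------

hwe_chisq_stat <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  o <- c(n0, n1, n2)
  sum((o - e)^2 / e, na.rm = TRUE)
}

#' Monte-Carlo Hardy-Weinberg tests with Benjamini-Yekutieli correction
#'
#' For each diploid locus, compares observed genotype counts to Hardy-Weinberg
#' expectations from the observed allele counts with a chi-square statistic;
#' the null distribution is obtained by randomly re-pairing the group's allele
#' copies `B` times. P-values use the add-one rule and are adjusted across
#' loci with the Benjamini-Yekutieli step-up (which is valid under arbitrary
#' dependence between loci). Monomorphic loci get p = 1 and are flagged.
#'
#' @param gm a `genotype_matrix`
#' @param ids individual ids of the tested group (>= 5)
#' @param B Monte-Carlo replicates (default 1e4)
#' @return data.frame `locus`, `stat`, `p`, `q_by`, `monomorphic`
#' @export
hwe_mc_test <- function(gm, ids, B = 1e4) {
  stopifnot(length(ids) >= 5)
  dip <- which(gm$loci$type != "mito")
  loci <- colnames(gm$geno)[dip]
  out <- data.frame(locus = loci, stat = NA_real_, p = NA_real_,
                    q_by = NA_real_, monomorphic = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(dip)) {
    d <- gm$geno[ids, dip[i]]
    d <- d[!is.na(d)]
    n0 <- sum(d == 0L); n1 <- sum(d == 1L); n2 <- sum(d == 2L)
    n <- length(d)
    if (n == 0 || n1 + n2 == 0 || n0 + n1 == 0) {
      out$p[i] <- 1
      out$monomorphic[i] <- TRUE
      next
    }
    stat <- hwe_chisq_stat(n0, n1, n2)
    copies <- c(rep(0L, 2 * n0 + n1), rep(1L, n1 + 2 * n2))
    hits <- 0L
    for (b in seq_len(B)) {
      perm <- sample(copies)
      g <- perm[seq(1, 2 * n, 2)] + perm[seq(2, 2 * n, 2)]
      s <- hwe_chisq_stat(sum(g == 0L), sum(g == 1L), sum(g == 2L))
      if (s >= stat - 1e-12) hits <- hits + 1L
    }
    out$stat[i] <- stat
    out$p[i] <- (1 + hits) / (B + 1)
  }
  out$q_by <- stats::p.adjust(out$p, method = "BY")
  out
}

# ---------------------------------------------------------------------------
# Ancestry-level comparisons (thin delegations)
# ---------------------------------------------------------------------------

#' Compare ancestry levels across populations
#'
#' Thin delegation to standard nonparametric routines: per ancestry source, a
#' Kruskal-Wallis one-way test of Q across populations
#' ([stats::kruskal.test()]), followed by pairwise two-sample Wilcoxon
#' rank-sum tests ([stats::pairwise.wilcox.test()]) with Benjamini-Yekutieli
#' correction as the post hoc. No bespoke statistics are computed here.
#'
#' @param Q numeric matrix individuals x sources of ancestry fractions
#' @param population factor/character of population labels per individual
#' @return list per source: `kruskal` (htest) and `pairwise` (matrix of
#'   BY-adjusted p-values)
#' @export
compare_ancestry_levels <- function(Q, population) {
  stopifnot(nrow(Q) == length(population))
  population <- as.factor(population)
  out <- lapply(colnames(Q), function(src) {
    list(
      kruskal = stats::kruskal.test(Q[, src], population),
      pairwise = suppressWarnings(
        stats::pairwise.wilcox.test(Q[, src], population,
                                    p.adjust.method = "BY", exact = FALSE)
      )$p.value
    )
  })
  names(out) <- colnames(Q)
  out
}
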
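#' Admixture events
#'
#' An admixture event bundles everything needed to compute per-locus
#' distortions for one admixed population: the set of admixed individuals,
#' the binding of each ancestry component to a reference lineage of the panel
#' (including the "local edulis" choice -- e.g. the South-European lineage
#' for the French port populations, the North-European one for the Norwegian
#' introductions, and the known L3 parent for laboratory crosses), and the
#' mean ancestry vector Q-bar over those components.
#'
#' @param label event label (e.g. "havre", "LOF", "BCG")
#' @param ids character vector of admixed individual ids
#' @param panel a `lineage_panel` (oriented the same way as the genotypes)
#' @param bindings named character vector: ancestry component -> panel lineage
#'   (e.g. `c(edu = "edu_eu_south", gallo_atl = "gallo_atl", gallo_med =
#'   "gallo_med")`)
#' @param Qbar named numeric over the same components, on the simplex: the
#'   mean ancestry of the admixed individuals
#' @param type admixture type used by [run_comparison_grid()] (e.g. "dock",
#'   "norway", "natural", "F2", "BC")
#' @param background parental-background label used to class comparisons
#'   (e.g. "med" for Med. *M. galloprovincialis* x S-Eu. *M. edulis* events,
#'   "atl" for Atl. *M. galloprovincialis* events)
#' @return an object of class `admixture_event`
#' @export
admixture_event <- function(label, ids, panel, bindings, Qbar,
                            type = NA_character_,
                            background = NA_character_) {
  stopifnot(setequal(names(bindings), names(Qbar)))
  stopifnot(all(bindings %in% rownames(panel$freq)))
  if (any(Qbar < -1e-9) || abs(sum(Qbar) - 1) > 1e-6) {
    stop("Qbar must lie on the simplex")
  }
  f <- panel$freq[bindings, , drop = FALSE]
  rownames(f) <- names(bindings)
  structure(list(label = label, ids = ids, f_src = f,
                 Qbar = Qbar[names(bindings)], type = type,
                 background = background),
            class = "admixture_event")
}

#' @export
print.admixture_event <- function(x, ...) {
  cat(sprintf("<admixture_event> %s (%s): %d individuals; Qbar = %s\n",
              x$label, x$type, length(x$ids),
              paste(sprintf("%s %.2f", names(x$Qbar), x$Qbar),
                    collapse = ", ")))
  invisible(x)
}

#' Expected allele frequencies under genome-wide mean ancestry
#'
#' The null of the concordance analysis: with no locus-specific forces, an
#' admixed population's allele frequency at every locus is the mean of the
#' bound parental frequencies weighted by the population's mean ancestries,
#' `f_exp = sum_k f_k * Qbar_k`.
#'
#' @param event an [admixture_event()]
#' @return named numeric of f_exp per locus (NA where a bound source lacks a
#'   frequency)
#' @export
expected_freqs <- function(event) {
  as.numeric(event$Qbar %*% event$f_src) -> fe
  names(fe) <- colnames(event$f_src)
  fe
}

#' Per-locus distortions from ancestry-weighted expectations
#'
#' `D = f_obs - f_exp` per locus, where `f_obs` is computed from the admixed
#' individuals only and `f_exp` from [expected_freqs()]. The haploid
#' mitochondrial marker participates with haploid allele counting.
#'
#' @param event an [admixture_event()]
#' @param freqs a `freq_table` containing a row for the event (frequencies of
#'   the event's admixed individuals only)
#' @param group row of `freqs` holding the event's observed frequencies
#'   (default the event label)
#' @return a `distortion_table`: data.frame `locus`, `f_obs`, `f_exp`, `D`
#' @export
distortions <- function(event, freqs, group = event$label) {
  stopifnot(group %in% rownames(freqs$freq))
  fe <- expected_freqs(event)
  loci <- intersect(names(fe), colnames(freqs$freq))
  fo <- freqs$freq[group, loci]
  out <- data.frame(locus = loci, f_obs = unname(fo),
                    f_exp = unname(fe[loci]),
                    D = unname(fo - fe[loci]),
                    stringsAsFactors = FALSE)
  class(out) <- c("distortion_table", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Cross-event correlation of distortions
# ---------------------------------------------------------------------------

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub))
  }
  out
}

#' Correlate distortions between two admixture events
#'
#' Pearson correlation of per-locus distortions over the loci shared (and
#' non-missing) between two events, with a two-sided permutation test that
#' shuffles the locus pairing of the second table. With at most
#' `exact_max` shared loci the permutation null is enumerated exhaustively
#' (the p-value is then the exact proportion of pairings with |r*| >= |r|);
#' otherwise `n_perm` random pairings are drawn and the add-one rule applies.
#'
#' @param tableA,tableB `distortion_table`s
#' @param n_perm random permutations (default 5e4)
#' @param seed RNG seed (optional)
#' @param exact_max exhaustive-enumeration threshold (default 8 shared loci)
#' @return list `r`, `p`, `n_loci`, `exact`; `r` is NA with a
#'   `zero_variance` flag when either D vector is constant
#' @export
correlate_events <- function(tableA, tableB, n_perm = 5e4, seed = NULL,
                             exact_max = 8L) {
  if (!is.null(seed)) set.seed(seed)
  shared <- intersect(tableA$locus[!is.na(tableA$D)],
                      tableB$locus[!is.na(tableB$D)])
  if (length(shared) < 5) stop("fewer than 5 shared loci with distortions")
  a <- tableA$D[match(shared, tableA$locus)]
  b <- tableB$D[match(shared, tableB$locus)]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, p = NA_real_, n_loci = length(shared),
                exact = FALSE, zero_variance = TRUE))
  }
  r <- stats::cor(a, b)
  n <- length(shared)
  # only sum(a * b[perm]) varies under permutation
  za <- (a - mean(a)) / stats::sd(a)
  zb <- (b - mean(b)) / stats::sd(b)
  r_of <- function(idx) sum(za * zb[idx]) / (n - 1)
  if (n <= exact_max) {
    perms <- all_perms(n)
    rstar <- apply(perms, 1, r_of)
    p <- mean(abs(rstar) >= abs(r) - 1e-12)
    exact <- TRUE
  } else {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      if (abs(r_of(sample.int(n))) >= abs(r) - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    exact <- FALSE
  }
  list(r = r, p = p, n_loci = n, exact = exact, zero_variance = FALSE)
}

# ---------------------------------------------------------------------------
# Empirical Brown's Method
# ---------------------------------------------------------------------------

#' Combine dependent p-values with the Empirical Brown's Method
#'
#' Fisher's statistic `T = -2 sum log p_i` has null distribution chi-square
#' with 2m df only for independent tests. The Empirical Brown's Method
#' estimates the dependence from per-test data vectors sharing a common index
#' (here: per-locus contributions to each correlation): each vector is pushed
#' through its empirical CDF, transformed to `w = -2 log(ECDF)`, and the
#' covariances `cov(w_i, w_j)` rescale T to `c * chisq_f` with
#' `Var T = 4m + 2 sum_{i<j} cov_ij`, `f = 2 (2m)^2 / Var T`,
#' `c = Var T / (4m)`. With positive dependence this inflates `c` and deflates
#' `f`, penalising redundant tests; under independence it reduces to Fisher.
#' When `c < 1` (net negative covariance) the Fisher scaling is kept, as in
#' the reference formulation. With fewer than 3 shared index points the
#' covariance is not estimable and the method falls back to plain Fisher with
#' a warning.
#'
#' @param p_values numeric vector of m >= 1 p-values
#' @param data_vectors numeric matrix m x s: per-test data over s shared index
#'   points (ignored for m = 1)
#' @return list `p` (combined), `p_fisher`, `c`, `df`
#' @export
combine_pvalues_brown <- function(p_values, data_vectors = NULL) {
  m <- length(p_values)
  stopifnot(m >= 1, all(p_values > 0 & p_values <= 1))
  T_obs <- -2 * sum(log(p_values))
  p_fisher <- stats::pchisq(T_obs, df = 2 * m, lower.tail = FALSE)
  if (m == 1) {
    return(list(p = p_values, p_fisher = p_fisher, c = 1, df = 2))
  }
  fallback <- is.null(data_vectors) || ncol(data_vectors) < 3
  if (fallback) {
    warning("fewer than 3 shared index points; falling back to Fisher")
    return(list(p = p_fisher, p_fisher = p_fisher, c = 1, df = 2 * m))
  }
  stopifnot(nrow(data_vectors) == m)
  s <- ncol(data_vectors)
  w <- t(apply(data_vectors, 1, function(x) {
    -2 * log(stats::ecdf(x)(x))
  }))
  cv <- stats::cov(t(w))
  var_T <- 4 * m + 2 * sum(cv[upper.tri(cv)])
  cc <- var_T / (4 * m)
  df <- 2 * (2 * m)^2 / var_T
  if (cc < 1) { # net negative dependence: keep the Fisher scaling
    cc <- 1
    df <- 2 * m
  }
  list(p = stats::pchisq(T_obs / cc, df = df, lower.tail = FALSE),
       p_fisher = p_fisher, c = cc, df = df)
}

# ---------------------------------------------------------------------------
# Comparison grid
# ---------------------------------------------------------------------------

#' Default comparison-class rule
#'
#' Pairs of events of the same type are `intra`; pairs of different types
#' sharing the Atlantic *M. galloprovincialis* background are `inter_atl`;
#' pairs sharing the Mediterranean background are `inter_med`; pairs with
#' different backgrounds are `inter_lineages`.
#' @param eventA,eventB `admixture_event`s
#' @export
default_pair_class <- function(eventA, eventB) {
  if (identical(eventA$type, eventB$type)) return("intra")
  if (identical(eventA$background, eventB$background)) {
    return(paste0("inter_", eventA$background))
  }
  "inter_lineages"
}

#' Correlation grid over admixture events with per-class combined p-values
#'
#' Computes the distortion correlation for every pair of events falling in a
#' comparison class, then combines each class's p-values with the Empirical
#' Brown's Method. The EBM data vector of a pair is the element-wise product
#' of the two events' standardised D vectors over the loci shared by all
#' pairs in the class -- the per-locus contribution to that pair's
#' correlation, which carries the between-pair dependence (the same event
#' appears in several pairs).
#'
#' @param events named list of [admixture_event()]s
#' @param tables named list of matching `distortion_table`s
#' @param pair_class function(eventA, eventB) -> class label or NA to skip
#'   (default [default_pair_class()])
#' @param n_perm permutations per pair test (default 5e4)
#' @param seed RNG seed (optional)
#' @return list `pairs` (data.frame eventA, eventB, class, r, p, n_loci) and
#'   `classes` (data.frame class, n_pairs, p_combined, p_fisher)
#' @export
run_comparison_grid <- function(events, tables,
                                pair_class = default_pair_class,
                                n_perm = 5e4, seed = NULL) {
  stopifnot(identical(names(events), names(tables)))
  if (!is.null(seed)) set.seed(seed)
  labs <- names(events)
  pairs <- utils::combn(labs, 2)
  res <- data.frame(eventA = character(), eventB = character(),
                    class = character(), r = numeric(), p = numeric(),
                    n_loci = integer(), stringsAsFactors = FALSE)
  for (k in seq_len(ncol(pairs))) {
    ea <- pairs[1, k]; eb <- pairs[2, k]
    cls <- pair_class(events[[ea]], events[[eb]])
    if (is.na(cls)) next
    ce <- correlate_events(tables[[ea]], tables[[eb]], n_perm = n_perm)
    res[nrow(res) + 1L, ] <- list(ea, eb, cls, ce$r, ce$p, ce$n_loci)
  }
  cls_out <- data.frame(class = character(), n_pairs = integer(),
                        p_combined = numeric(), p_fisher = numeric(),
                        stringsAsFactors = FALSE)
  for (cls in unique(res$class)) {
    sub <- res[res$class == cls, ]
    common <- Reduce(intersect, lapply(seq_len(nrow(sub)), function(i) {
      ta <- tables[[sub$eventA[i]]]; tb <- tables[[sub$eventB[i]]]
      intersect(ta$locus[!is.na(ta$D)], tb$locus[!is.na(tb$D)])
    }))
    dv <- NULL
    if (length(common) >= 3) {
      dv <- t(sapply(seq_len(nrow(sub)), function(i) {
        ta <- tables[[sub$eventA[i]]]; tb <- tables[[sub$eventB[i]]]
        a <- ta$D[match(common, ta$locus)]
        b <- tb$D[match(common, tb$locus)]
        as.numeric(scale(a)) * as.numeric(scale(b))
      }))
    }
    cmb <- if (nrow(sub) == 1) {
      list(p = sub$p, p_fisher = sub$p)
    } else {
      combine_pvalues_brown(sub$p, dv)
    }
    cls_out[nrow(cls_out) + 1L, ] <- list(cls, nrow(sub), cmb$p,
                                          cmb$p_fisher)
  }
  list(pairs = res, classes = cls_out)
}
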
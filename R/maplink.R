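#' Marker filters for F2 linkage mapping
#'
#' Applies the three admission filters for two-point mapping in an F2
#' intercross: the marker must be heterozygous in every F1 parent (otherwise
#' it is uninformative and produces spurious distortion), the parental
#' species must differ in allele frequency by at least `afd_min`, and the F2
#' missing fraction must not exceed `miss_max`. Every exclusion is logged
#' with its reason.
#'
#' @param f2 a `genotype_matrix` of F2 offspring
#' @param f1_parents a `genotype_matrix` of the F1 parents (same loci)
#' @param panel a `lineage_panel` with the two parental lineages
#' @param parents character(2): the parental lineage labels
#' @param afd_min minimum parental allele-frequency difference (default 0.2;
#'   a marker at 0.19 is removed)
#' @param miss_max maximum F2 missing fraction (default 0.10)
#' @return data.frame `locus`, `keep`, `reason` ("" when kept)
#' @export
filter_map_markers <- function(f2, f1_parents, panel, parents,
                               afd_min = 0.2, miss_max = 0.10) {
  loci <- colnames(f2$geno)
  stopifnot(all(loci %in% colnames(f1_parents$geno)),
            all(loci %in% colnames(panel$freq)),
            all(parents %in% rownames(panel$freq)))
  reason <- character(length(loci))
  f1g <- f1_parents$geno[, loci, drop = FALSE]
  het_all <- apply(f1g, 2, function(d) all(!is.na(d) & d == 1L))
  daf <- abs(panel$freq[parents[1], loci] - panel$freq[parents[2], loci])
  missf <- colMeans(is.na(f2$geno[, loci, drop = FALSE]))
  reason[!het_all] <- "not het in all F1"
  reason[reason == "" & daf < afd_min] <- sprintf("AFD < %.2f", afd_min)
  reason[reason == "" & missf > miss_max] <-
    sprintf("missing > %.0f%%", 100 * miss_max)
  out <- data.frame(locus = loci, keep = reason == "", reason = reason,
                    stringsAsFactors = FALSE)
  if (!any(out$keep)) stop("no markers pass the map filters")
  out
}

#' Mendelian segregation tests in F2s
#'
#' Chi-square tests of observed F2 dosage counts against the 1:2:1
#' expectation, with Holm step-down control of the family-wise error rate.
#' Markers typed in fewer than `min_n` offspring are skipped and flagged.
#'
#' @param f2 a `genotype_matrix` of F2 offspring (oriented dosages)
#' @param alpha family-wise level for the Holm decisions (default 0.05)
#' @param min_n minimum typed offspring (default 10)
#' @return data.frame `locus`, `n`, `stat`, `p`, `p_holm`, `reject`,
#'   `skipped`
#' @export
segregation_test <- function(f2, alpha = 0.05, min_n = 10) {
  nuc <- f2$loci$type != "mito"
  loci <- colnames(f2$geno)[nuc]
  out <- data.frame(locus = loci, n = NA_integer_, stat = NA_real_,
                    p = NA_real_, p_holm = NA_real_, reject = FALSE,
                    skipped = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(loci)) {
    d <- f2$geno[, loci[i]]
    d <- d[!is.na(d)]
    out$n[i] <- length(d)
    if (length(d) < min_n) {
      out$skipped[i] <- TRUE
      next
    }
    o <- c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
    e <- length(d) * c(1, 2, 1) / 4
    out$stat[i] <- sum((o - e)^2 / e)
    out$p[i] <- stats::pchisq(out$stat[i], df = 2, lower.tail = FALSE)
  }
  tested <- !out$skipped
  out$p_holm[tested] <- stats::p.adjust(out$p[tested], method = "holm")
  out$reject <- !out$skipped & out$p_holm <= alpha
  out
}

# F2 intercross joint genotype probabilities (coupling phase) and expected
# recombinant-gamete counts per cell, from enumeration of gamete pairs
f2_two_locus <- function(r) {
  # gamete (x, y) probabilities: parental (1-r)/2 each, recombinant r/2 each
  gam <- expand.grid(x = 0:1, y = 0:1)
  gam$pr <- ifelse(gam$x == gam$y, (1 - r) / 2, r / 2)
  gam$rec <- as.numeric(gam$x != gam$y)
  probs <- matrix(0, 3, 3)
  recs <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    a <- gam$x[i] + gam$x[j]
    b <- gam$y[i] + gam$y[j]
    pr <- gam$pr[i] * gam$pr[j]
    probs[a + 1, b + 1] <- probs[a + 1, b + 1] + pr
    recs[a + 1, b + 1] <- recs[a + 1, b + 1] +
      pr * (gam$rec[i] + gam$rec[j])
  }
  list(probs = probs, e_rec = recs / probs)
}

#' Two-point recombination fraction in an F2 intercross
#'
#' Maximum-likelihood estimate of the recombination fraction between two
#' oriented markers in coupling phase, via EM over the phase ambiguity of the
#' double heterozygote class, with a LOD score against free recombination
#' (r = 0.5).
#'
#' @param genoA,genoB integer dosage vectors of the two markers over the same
#'   offspring
#' @param tol EM convergence tolerance (default 1e-8)
#' @return list `r` (in \[0, 0.5\]), `lod`, `n` (jointly typed offspring),
#'   `insufficient` (TRUE when n < 20)
#' @export
est_rf_f2 <- function(genoA, genoB, tol = 1e-8) {
  ok <- !is.na(genoA) & !is.na(genoB)
  a <- genoA[ok]; b <- genoB[ok]
  n <- length(a)
  counts <- matrix(0, 3, 3)
  for (k in seq_len(n)) counts[a[k] + 1, b[k] + 1] <-
      counts[a[k] + 1, b[k] + 1] + 1
  r <- 0.25
  for (it in 1:1000) {
    tl <- f2_two_locus(r)
    r_new <- sum(counts * tl$e_rec) / (2 * n)
    r_new <- min(max(r_new, 1e-6), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  ll <- function(r) sum(counts * log(f2_two_locus(r)$probs))
  lod <- (ll(r) - ll(0.5)) / log(10)
  list(r = r, lod = lod, n = n, insufficient = n < 20)
}

#' Pairwise recombination fractions for a marker set
#'
#' @param f2 a `genotype_matrix` of F2 offspring
#' @param loci markers to include (default all nuclear)
#' @return list of matrices `r` and `lod` (markers x markers)
#' @export
rf_matrix <- function(f2, loci = NULL) {
  if (is.null(loci)) loci <- colnames(f2$geno)[f2$loci$type != "mito"]
  k <- length(loci)
  r <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  lod <- matrix(NA_real_, k, k, dimnames = list(loci, loci))
  diag(r) <- 0
  diag(lod) <- Inf
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    e <- est_rf_f2(f2$geno[, loci[i]], f2$geno[, loci[j]])
    r[i, j] <- r[j, i] <- e$r
    lod[i, j] <- lod[j, i] <- e$lod
  }
  list(r = r, lod = lod)
}

# sum of adjacent recombination fractions along an order
order_cost <- function(r, ord) {
  sum(r[cbind(ord[-length(ord)], ord[-1])])
}

# best within-group order: exhaustive for <= 7 markers, else greedy
# nearest-neighbour from every start plus 2-opt refinement
best_order <- function(r) {
  k <- nrow(r)
  if (k <= 2) return(seq_len(k))
  if (k <= 7) {
    perms <- all_perms(k)
    costs <- apply(perms, 1, function(o) order_cost(r, o))
    ord <- perms[which.min(costs), ]
  } else {
    best <- NULL; best_cost <- Inf
    for (start in seq_len(k)) {
      ord <- start
      left <- setdiff(seq_len(k), start)
      while (length(left)) {
        nxt <- left[which.min(r[ord[length(ord)], left])]
        ord <- c(ord, nxt)
        left <- setdiff(left, nxt)
      }
      improved <- TRUE
      while (improved) {
        improved <- FALSE
        for (i in seq_len(k - 1)) for (j in (i + 1):k) {
          cand <- ord
          cand[i:j] <- rev(cand[i:j])
          if (order_cost(r, cand) < order_cost(r, ord) - 1e-12) {
            ord <- cand
            improved <- TRUE
          }
        }
      }
      cst <- order_cost(r, ord)
      if (cst < best_cost) { best <- ord; best_cost <- cst }
    }
    ord <- best
  }
  # canonical orientation: lexicographically smaller end label first
  labs <- rownames(r)
  if (labs[ord[k]] < labs[ord[1]]) ord <- rev(ord)
  ord
}

#' Build a genetic map from pairwise recombination fractions
#'
#' Single-linkage grouping of markers connected by LOD >= `lod_group` and
#' r <= `rmax_group`, ordering within groups (exhaustive search up to 7
#' markers, greedy seriation with 2-opt beyond), and Haldane positions
#' `d = -ln(1 - 2 r) / 2` cumulated along the order.
#'
#' @param rf output of [rf_matrix()] (list with `r` and `lod` matrices)
#' @param lod_group minimum LOD to link two markers (default 3)
#' @param rmax_group maximum r to link two markers (default 0.35)
#' @return a [genetic_map()]; groups are named `"LG01"`, ... in order of
#'   first marker label
#' @export
build_map <- function(rf, lod_group = 3, rmax_group = 0.35) {
  labs <- rownames(rf$r)
  k <- length(labs)
  adj <- rf$lod >= lod_group & rf$r <= rmax_group
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # stable group ids: order components by their smallest marker label
  first_lab <- vapply(seq_len(max(comp)),
                      function(cc) min(labs[comp == cc]), character(1))
  remap <- order(order(first_lab))
  markers <- data.frame(locus = character(), group = character(),
                        cM = numeric(), stringsAsFactors = FALSE)
  for (cc in seq_len(max(comp))) {
    members <- which(comp == cc)
    sub_r <- rf$r[members, members, drop = FALSE]
    ord <- best_order(sub_r)
    rr <- pmin(sub_r[cbind(ord[-length(ord)], ord[-1])], 0.49)
    d_cM <- 100 * (-0.5 * log(1 - 2 * rr))
    pos <- cumsum(c(0, d_cM))
    markers <- rbind(markers, data.frame(
      locus = labs[members][ord],
      group = sprintf("LG%02d", remap[cc]),
      cM = pos, stringsAsFactors = FALSE
    ))
  }
  genetic_map(markers)
}

#' The unlinked marker set
#'
#' One marker per linkage group: the one with the least missing data; markers
#' without a linkage group are all retained (assumed unlinked).
#'
#' @param gm a `genotype_matrix` with linkage groups in its loci metadata
#' @return character vector of marker names
#' @export
unlinked_markers <- function(gm) {
  missf <- colMeans(is.na(gm$geno))
  grp <- gm$loci$linkage_group
  keep <- colnames(gm$geno)[is.na(grp)]
  for (g in unique(stats::na.omit(grp))) {
    members <- colnames(gm$geno)[!is.na(grp) & grp == g]
    keep <- c(keep, members[which.min(missf[members])])
  }
  keep
}

# ---------------------------------------------------------------------------
# Admixture linkage disequilibrium and dating
# ---------------------------------------------------------------------------

#' Burrows composite LD against map distance
#'
#' Phase-free composite linkage disequilibrium `Delta = cov(X, Y) / 2`
#' between dosage vectors, computed for every pair of mapped nuclear markers
#' (within linkage groups by default), paired with their map distance in
#' Morgans. In a recently admixed population Delta is dominated by admixture
#' LD, which decays with distance at a rate set by the number of generations
#' since admixture.
#'
#' @param gm a `genotype_matrix` of admixed individuals
#' @param map a [genetic_map()] covering (a subset of) the markers
#' @param within_groups_only only intra-group pairs (default TRUE)
#' @return data.frame `locusA`, `locusB`, `group`, `dist_M`, `delta`, `n`
#' @export
admixture_ld <- function(gm, map, within_groups_only = TRUE) {
  mk <- map$markers[map$markers$locus %in% colnames(gm$geno), ]
  mk <- mk[gm$loci$type[match(mk$locus, gm$loci$locus)] != "mito", ]
  if (nrow(mk) < 2) stop("fewer than 2 mapped markers")
  out <- data.frame(locusA = character(), locusB = character(),
                    group = character(), dist_M = numeric(),
                    delta = numeric(), n = integer(),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mk) - 1)) for (j in (i + 1):nrow(mk)) {
    same <- mk$group[i] == mk$group[j]
    if (within_groups_only && !same) next
    a <- gm$geno[, mk$locus[i]]
    b <- gm$geno[, mk$locus[j]]
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 3) next
    n <- sum(ok)
    delta <- stats::cov(a[ok], b[ok]) * (n - 1) / n / 2
    out[nrow(out) + 1L, ] <- list(
      mk$locus[i], mk$locus[j],
      if (same) mk$group[i] else NA_character_,
      if (same) abs(mk$pos_M[i] - mk$pos_M[j]) else Inf, # unlinked: c = 1/2
      delta, n
    )
  }
  if (nrow(out) == 0) stop("no mapped marker pairs")
  out
}

# least-squares fit of delta ~ D0 * k(d)^g for the chosen decay kernel:
# haldane uses the exact per-generation retention (1 - c(d)) under the
# Haldane mapping, exponential the small-distance approximation exp(-d)
ald_ls_fit <- function(d, delta, decay, g_grid = seq(0, 60, by = 0.25)) {
  kfun <- if (decay == "haldane") function(d) (1 + exp(-2 * d)) / 2
          else function(d) exp(-d)
  kd <- kfun(d)
  sse_of <- function(g) {
    x <- kd^g
    D0 <- max(sum(delta * x) / sum(x * x), 0)
    sum((delta - D0 * x)^2)
  }
  sse <- vapply(g_grid, sse_of, numeric(1))
  g0 <- g_grid[which.min(sse)]
  opt <- stats::optim(g0, sse_of, method = "L-BFGS-B", lower = 0,
                      upper = max(g_grid))
  g_hat <- opt$par
  x <- kd^g_hat
  D0 <- max(sum(delta * x) / sum(x * x), 0)
  list(g = g_hat, D0 = D0, sse = opt$value)
}

#' Date admixture from the decay of admixture LD
#'
#' Fits `Delta(d) = D0 * (1 - c(d))^g` by least squares to the composite-LD
#' versus map-distance pairs of an admixed population, where `c(d)` is the
#' Haldane recombination fraction at distance `d` Morgans: each generation of
#' random mating multiplies admixture LD between a pair by `(1 - c)`, so `g`
#' estimates the number of generations since a single admixture pulse
#' (equivalently, breakpoints accumulate per Morgan at a rate that grows with
#' `g`). `decay = "exponential"` uses the small-distance approximation
#' `D0 * exp(-g d)` instead. Confidence intervals come from bootstrap
#' resampling of individuals.
#'
#' @param gm a `genotype_matrix` of admixed individuals
#' @param map a [genetic_map()]
#' @param decay `"haldane"` (default) or `"exponential"`
#' @param n_boot bootstrap replicates over individuals (default 200)
#' @param use_abs fit |Delta| instead of Delta (makes the fit invariant to
#'   per-locus allele flips; default FALSE, assuming oriented alleles)
#' @param conf CI level (default 0.95)
#' @param seed RNG seed (optional)
#' @return object of class `ald_fit`: list `g_hat`, `D0`, `ci`, `n_pairs`,
#'   `range_M`, `decay`, `boot_g`
#' @export
estimate_admixture_time <- function(gm, map, decay = c("haldane",
                                                       "exponential"),
                                    n_boot = 200, use_abs = FALSE,
                                    conf = 0.95, seed = NULL) {
  decay <- match.arg(decay)
  if (!is.null(seed)) set.seed(seed)
  pairs <- admixture_ld(gm, map)
  if (nrow(pairs) < 5) stop("need at least 5 mapped pairs")
  rng <- diff(range(pairs$dist_M[is.finite(pairs$dist_M)]))
  if (!is.finite(rng) || rng < 0.1) {
    stop(sprintf(
      "ALD distances span only %.3f M; dating is not identifiable", rng))
  }
  dd <- if (use_abs) abs(pairs$delta) else pairs$delta
  fit <- ald_ls_fit(pairs$dist_M, dd, decay)
  boot_g <- rep(NA_real_, n_boot)
  ids <- rownames(gm$geno)
  pos <- match(c(pairs$locusA, pairs$locusB), colnames(gm$geno))
  la <- pos[seq_len(nrow(pairs))]
  lb <- pos[-seq_len(nrow(pairs))]
  for (b in seq_len(n_boot)) {
    take <- sample(length(ids), replace = TRUE)
    g2 <- gm$geno[take, , drop = FALSE]
    delta_b <- vapply(seq_len(nrow(pairs)), function(k) {
      a <- g2[, la[k]]; bb <- g2[, lb[k]]
      ok <- !is.na(a) & !is.na(bb)
      n <- sum(ok)
      if (n < 3) return(NA_real_)
      stats::cov(a[ok], bb[ok]) * (n - 1) / n / 2
    }, numeric(1))
    ok <- !is.na(delta_b)
    if (sum(ok) < 5) next
    db <- if (use_abs) abs(delta_b[ok]) else delta_b[ok]
    boot_g[b] <- ald_ls_fit(pairs$dist_M[ok], db, decay,
                            g_grid = seq(0, 60, by = 1))$g
  }
  qs <- stats::quantile(boot_g, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE)
  ci <- c(min(qs[1], fit$g), max(qs[2], fit$g))
  structure(list(g_hat = fit$g, D0 = fit$D0, ci = unname(ci),
                 n_pairs = nrow(pairs),
                 range_M = range(pairs$dist_M), decay = decay,
                 boot_g = boot_g),
            class = "ald_fit")
}

#' @export
print.ald_fit <- function(x, ...) {
  cat(sprintf(
    "<ald_fit> g = %.1f generations (%.0f%% CI %.1f-%.1f), D0 = %.4f, %d pairs\n",
    x$g_hat, 95, x$ci[1], x$ci[2], x$D0, x$n_pairs))
  invisible(x)
}
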
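#' Ancestry profiles
#'
#' Per-individual ancestry fractions Q over K named source lineages (rows on
#' the unit simplex), with the log-likelihood at convergence and the number of
#' informative allele copies used.
#'
#' @param Q numeric matrix individuals x sources, rows summing to 1
#' @param loglik numeric vector of per-individual log-likelihoods
#' @param n_copies integer vector of non-missing allele copies used
#' @param flat logical vector flagging individuals with a flat likelihood
#' @export
ancestry_profile <- function(Q, loglik = NULL, n_copies = NULL, flat = NULL) {
  stopifnot(is.matrix(Q), !is.null(colnames(Q)))
  if (any(abs(rowSums(Q) - 1) > 1e-8)) {
    stop("Q rows must sum to 1")
  }
  structure(list(
    Q = Q,
    loglik = if (is.null(loglik)) rep(NA_real_, nrow(Q)) else loglik,
    n_copies = if (is.null(n_copies)) rep(NA_integer_, nrow(Q)) else n_copies,
    flat = if (is.null(flat)) rep(FALSE, nrow(Q)) else flat
  ), class = "ancestry_profile")
}

#' @export
print.ancestry_profile <- function(x, ...) {
  cat(sprintf("<ancestry_profile> %d individuals, sources: %s\n",
              nrow(x$Q), paste(colnames(x$Q), collapse = ", ")))
  cat("mean Q:", sprintf("%.3f", colMeans(x$Q)), "\n")
  invisible(x)
}

# clamp reference frequencies away from 0/1 so no genotype has -Inf
# log-likelihood under any source
clamp_freqs <- function(f, eps = 1e-3) {
  clamped <- f < eps | f > 1 - eps
  f[f < eps] <- eps
  f[f > 1 - eps] <- 1 - eps
  attr(f, "clamped") <- clamped
  f
}

#' Supervised maximum-likelihood ancestry estimation
#'
#' Estimates each individual's ancestry vector Q over K source lineages by
#' maximising, with EM, the likelihood of its allele copies under the mixture
#' `P(allele) = sum_k q_k f_k(allele)` with reference frequencies `f_k` held
#' fixed. Each non-missing diploid genotype contributes two allele copies and
#' the haploid mitochondrial marker one. This is the deterministic supervised
#' counterpart of Bayesian admixture clustering with fixed reference panels:
#' with references pinned, the per-individual likelihood is the same and EM
#' finds its maximum directly.
#'
#' The EM log-likelihood is non-decreasing at every iteration; convergence is
#' declared when the change drops below `tol`. Reference frequencies exactly
#' 0 or 1 are clamped to `[eps, 1 - eps]` and flagged. Individuals whose
#' typed loci carry identical frequencies in every source have a flat
#' likelihood: they are returned as uniform Q with `flat = TRUE`.
#'
#' @param gm a `genotype_matrix` (alleles oriented consistently with `panel`)
#' @param panel a `lineage_panel` covering all of `gm`'s loci
#' @param sources character vector (K >= 2) of panel lineages to mix
#' @param tol convergence tolerance on the log-likelihood (default 1e-6)
#' @param max_iter maximum EM iterations (default 5000)
#' @param eps frequency clamp (default 1e-3)
#' @param trace if TRUE, attach the per-iteration log-likelihood trajectories
#'   as attribute `"trace"` (used to assert monotonicity)
#' @return an [ancestry_profile()]
#' @export
estimate_q_supervised <- function(gm, panel, sources, tol = 1e-6,
                                  max_iter = 5000, eps = 1e-3, trace = FALSE) {
  K <- length(sources)
  stopifnot(K >= 2, all(sources %in% rownames(panel$freq)))
  loci <- colnames(gm$geno)
  miss <- setdiff(loci, colnames(panel$freq))
  if (length(miss)) stop(sprintf("locus '%s' has no panel frequency", miss[1]))
  FF <- clamp_freqs(panel$freq[sources, loci, drop = FALSE], eps)
  if (anyNA(FF)) stop("panel frequencies missing for some source x locus")
  p <- ploidy(gm)
  n <- nrow(gm$geno)
  Q <- matrix(NA_real_, n, K, dimnames = list(rownames(gm$geno), sources))
  ll <- numeric(n)
  ncop <- integer(n)
  flat <- logical(n)
  traces <- if (trace) vector("list", n) else NULL
  A <- t(FF)       # loci x K: P(allele = 1 | source)
  B <- 1 - A       # P(allele = 0 | source)
  for (i in seq_len(n)) {
    g <- gm$geno[i, ]
    ok <- !is.na(g)
    w1 <- as.numeric(g[ok])                  # copies of the counted allele
    w0 <- as.numeric(p[ok] - g[ok])          # copies of the other allele
    Ai <- A[ok, , drop = FALSE]
    Bi <- B[ok, , drop = FALSE]
    ncop[i] <- sum(w1 + w0)
    if (ncop[i] == 0) {
      Q[i, ] <- 1 / K; flat[i] <- TRUE
      next
    }
    if (max(apply(Ai, 1, function(r) diff(range(r)))) < 1e-12) {
      # every source identical at every typed locus: likelihood flat in q
      Q[i, ] <- 1 / K
      flat[i] <- TRUE
      ll[i] <- sum(w1 * log(Ai[, 1]) + w0 * log(Bi[, 1]))
      next
    }
    q <- rep(1 / K, K)
    last <- -Inf
    tr <- numeric(0)
    for (it in seq_len(max_iter)) {
      m1 <- Ai %*% q  # per-locus mixture prob of allele 1
      m0 <- Bi %*% q
      cur <- sum(w1 * log(m1) + w0 * log(m0))
      if (trace) tr <- c(tr, cur)
      if (cur - last < tol && it > 1) break
      last <- cur
      # E-step responsibilities, aggregated with copy weights; M-step mean
      r1 <- sweep(Ai, 1, m1, "/") * q[col(Ai)]
      r0 <- sweep(Bi, 1, m0, "/") * q[col(Bi)]
      q <- as.numeric(colSums(w1 * r1 + w0 * r0)) / ncop[i]
      q <- q / sum(q)
    }
    Q[i, ] <- q
    ll[i] <- cur
    if (trace) traces[[i]] <- tr
  }
  out <- ancestry_profile(Q, loglik = ll, n_copies = ncop, flat = flat)
  attr(out, "clamped_loci") <- loci[colSums(attr(FF, "clamped")) > 0]
  if (trace) attr(out, "trace") <- traces
  out
}

#' Classification EM without admixture
#'
#' Hard-assignment counterpart of the no-admixture clustering model:
#' alternates (i) assigning every individual to the cluster maximising its
#' genotype log-likelihood under Hardy-Weinberg with the cluster's allele
#' frequencies and (ii) re-estimating cluster frequencies from current
#' members with an add-1/2 pseudocount per allele. Stops at a fixed point of
#' the assignments or after `max_iter` sweeps; the result is deterministic
#' given the initial assignment. An emptied cluster is re-seeded with the
#' worst-fitting individual and flagged.
#'
#' @param gm a `genotype_matrix`
#' @param K number of clusters
#' @param init integer vector of initial cluster indices (1..K, all present)
#' @param max_iter maximum sweeps (default 200)
#' @return list `assign` (integer per individual), `freq` (K x loci cluster
#'   frequencies), `loglik` (total at fixed point), `reseeded` (logical)
#' @export
cluster_no_admixture <- function(gm, K, init, max_iter = 200) {
  n <- nrow(gm$geno)
  stopifnot(length(init) == n, all(init %in% seq_len(K)),
            all(seq_len(K) %in% init))
  p <- ploidy(gm)
  g <- gm$geno
  assign <- as.integer(init)
  reseeded <- FALSE
  est_freq <- function(assign) {
    f <- matrix(NA_real_, K, ncol(g), dimnames = list(NULL, colnames(g)))
    for (k in seq_len(K)) {
      sub <- g[assign == k, , drop = FALSE]
      hits <- colSums(sub, na.rm = TRUE)
      copies <- colSums(!is.na(sub)) * p
      f[k, ] <- (hits + 0.5) / (copies + 1)
    }
    f
  }
  ll_matrix <- function(f) {
    # individuals x clusters genotype log-likelihood under HWE
    out <- matrix(0, n, K)
    for (k in seq_len(K)) {
      lp <- matrix(0, n, ncol(g))
      fk <- f[k, ]
      for (j in seq_len(ncol(g))) {
        d <- g[, j]
        if (p[j] == 2L) {
          probs <- c((1 - fk[j])^2, 2 * fk[j] * (1 - fk[j]), fk[j]^2)
        } else {
          probs <- c(1 - fk[j], fk[j])
        }
        lp[, j] <- ifelse(is.na(d), 0, log(probs[d + 1L]))
      }
      out[, k] <- rowSums(lp)
    }
    out
  }
  for (it in seq_len(max_iter)) {
    f <- est_freq(assign)
    llm <- ll_matrix(f)
    new_assign <- max.col(llm, ties.method = "first")
    for (k in seq_len(K)) {
      if (!any(new_assign == k)) {
        worst <- which.min(llm[cbind(seq_len(n), new_assign)])
        new_assign[worst] <- k
        reseeded <- TRUE
      }
    }
    if (all(new_assign == assign)) break
    assign <- new_assign
  }
  f <- est_freq(assign)
  llm <- ll_matrix(f)
  list(assign = assign, freq = f,
       loglik = sum(llm[cbind(seq_len(n), assign)]), reseeded = reseeded)
}

#' Build a clean reference set and recompute panel frequencies
#'
#' Drops a-priori reference candidates whose ancestry in their putative
#' cluster falls below `purity` (removing migrants and hybrids from the
#' panel), flags the individuals whose ancestry from excluded sympatric
#' sources (e.g. *M. trossulus*) exceeds `excl_max` for removal from the
#' reduced data set, and recomputes reference allele frequencies from the
#' survivors.
#'
#' @param gm a `genotype_matrix`
#' @param profile an [ancestry_profile()] covering the candidates
#' @param putative named character vector id -> putative source (a column of
#'   `profile$Q`)
#' @param purity minimum ancestry in the putative cluster (default 0.85; an
#'   individual at 0.84 is removed)
#' @param excl_sources sources whose carriers are excluded from the reduced
#'   data set (default none)
#' @param excl_max ancestry threshold for that exclusion (default 0.10:
#'   individuals strictly above are dropped)
#' @return list `reference_ids` (named by source), `panel` (recomputed
#'   `lineage_panel`, `low_n` attribute flags lineages with < 10 survivors),
#'   `reduced_ids` (ids of `profile` passing the exclusion screen)
#' @export
build_reference_set <- function(gm, profile, putative, purity = 0.85,
                                excl_sources = character(0), excl_max = 0.10) {
  ids <- names(putative)
  stopifnot(all(ids %in% rownames(profile$Q)),
            all(putative %in% colnames(profile$Q)))
  own_q <- profile$Q[cbind(ids, putative)]
  keep <- ids[own_q >= purity]
  putative <- putative[keep]
  reduced_ids <- rownames(profile$Q)
  if (length(excl_sources)) {
    stopifnot(all(excl_sources %in% colnames(profile$Q)))
    excl_q <- rowSums(profile$Q[, excl_sources, drop = FALSE])
    reduced_ids <- reduced_ids[excl_q <= excl_max]
    keep <- intersect(keep, reduced_ids)
    putative <- putative[keep]
  }
  ft <- allele_freqs(gm, putative)
  counts <- table(putative)
  low_n <- names(counts)[counts < 10]
  if (length(low_n)) {
    warning(sprintf("reference lineage(s) with < 10 survivors: %s",
                    paste(low_n, collapse = ", ")))
  }
  lin <- data.frame(lineage = rownames(ft$freq), level = "L3",
                    parent = "root", stringsAsFactors = FALSE)
  pan <- lineage_panel(ft$freq, lin, n = ft$n)
  attr(pan, "low_n") <- low_n
  list(
    reference_ids = split(names(putative), putative),
    panel = pan,
    reduced_ids = reduced_ids
  )
}

#' Hybrid-class posteriors from two parental frequency vectors
#'
#' Posterior over the six early-generation hybrid classes
#' \{Pure1, F1, F2, BC1, BC2, Pure2\} given two parental allele-frequency
#' vectors. Each class has fixed expected proportions of per-locus ancestry
#' pairs over (AA, AB, BB) -- Pure1 (1,0,0), F1 (0,1,0), F2 (1/4,1/2,1/4),
#' BC1 (1/2,1/2,0), BC2 (0,1/2,1/2), Pure2 (0,0,1) -- and per-locus genotype
#' probabilities mix independent Bernoulli draws from `fA`/`fB` per ancestry
#' copy. Posterior is proportional to prior times the product over non-missing
#' nuclear loci. Parental frequencies are treated as known; their sampling
#' uncertainty is not integrated over (a flagged simplification relative to
#' full Bayesian hybrid classification).
#'
#' @param gm a `genotype_matrix` (nuclear loci used; mito excluded)
#' @param fA,fB named per-locus frequencies of the counted allele in the two
#'   parental lineages
#' @param prior prior over the six classes (default uniform)
#' @param eps frequency clamp (default 1e-3)
#' @return object of class `hybrid_class_posterior`: matrix individuals x 6
#'   classes; attribute `uninformative` flags fA == fB everywhere
#' @export
hybrid_class_posterior <- function(gm, fA, fB, prior = NULL, eps = 1e-3) {
  classes <- c("Pure1", "F1", "F2", "BC1", "BC2", "Pure2")
  mix <- rbind(
    Pure1 = c(1, 0, 0), F1 = c(0, 1, 0), F2 = c(1, 2, 1) / 4,
    BC1 = c(1, 1, 0) / 2, BC2 = c(0, 1, 1) / 2, Pure2 = c(0, 0, 1)
  )
  if (is.null(prior)) prior <- rep(1 / 6, 6)
  stopifnot(length(prior) == 6, abs(sum(prior) - 1) < 1e-8)
  nuc <- gm$loci$type != "mito"
  loci <- colnames(gm$geno)[nuc]
  stopifnot(all(loci %in% names(fA)), all(loci %in% names(fB)))
  a <- clamp_freqs(fA[loci], eps)
  b <- clamp_freqs(fB[loci], eps)
  uninformative <- max(abs(a - b)) < 1e-12
  # genotype probability by ancestry pair: rows AA, AB, BB; cols dosage 0,1,2
  gp <- function(j) {
    rbind(
      AA = c((1 - a[j])^2, 2 * a[j] * (1 - a[j]), a[j]^2),
      AB = c((1 - a[j]) * (1 - b[j]),
             a[j] * (1 - b[j]) + b[j] * (1 - a[j]),
             a[j] * b[j]),
      BB = c((1 - b[j])^2, 2 * b[j] * (1 - b[j]), b[j]^2)
    )
  }
  n <- nrow(gm$geno)
  logpost <- matrix(rep(log(prior), each = n), n, 6,
                    dimnames = list(rownames(gm$geno), classes))
  for (j in seq_along(loci)) {
    d <- gm$geno[, loci[j]]
    pj <- mix %*% gp(j)   # classes x dosages
    contrib <- log(pj)[, d + 1L, drop = FALSE]  # classes x individuals
    contrib[, is.na(d)] <- 0
    logpost <- logpost + t(contrib)
  }
  post <- exp(logpost - apply(logpost, 1, max))
  post <- post / rowSums(post)
  structure(post, class = c("hybrid_class_posterior", "matrix"),
            uninformative = uninformative)
}

#' Merge ancestry components into composite sources
#'
#' Sums Q components over a partition of the sources, e.g. building the
#' composite *M. edulis* ancestry `Q_edu = Q_edu_eu_south + Q_edu_am` from
#' the two *M. edulis* clusters.
#'
#' @param profile an [ancestry_profile()]
#' @param grouping named list: new label -> character vector of sources; must
#'   partition the profile's sources
#' @return an [ancestry_profile()] over the merged sources
#' @export
composite_q <- function(profile, grouping) {
  members <- unlist(grouping, use.names = FALSE)
  if (anyDuplicated(members) ||
      !setequal(members, colnames(profile$Q))) {
    stop("grouping must partition the profile's sources")
  }
  Qm <- sapply(grouping, function(src) {
    rowSums(profile$Q[, src, drop = FALSE])
  })
  if (!is.matrix(Qm)) Qm <- matrix(Qm, nrow = 1, dimnames = list(
    rownames(profile$Q), names(grouping)))
  rownames(Qm) <- rownames(profile$Q)
  ancestry_profile(Qm, loglik = profile$loglik, n_copies = profile$n_copies,
                   flat = profile$flat)
}
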
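#' Genetic maps
#'
#' Ordered markers on linkage groups with Haldane map positions. Positions are
#' centimorgans in files and Morgans internally. Markers without a map
#' position are treated as unlinked: each becomes its own zero-length
#' pseudo-group, which under Poisson recombination segregates independently
#' of everything else (50% recombination).
#'
#' @param markers data.frame with columns `locus`, `group`, `cM`; `group`/`cM`
#'   may be NA for unlinked markers.
#' @param lengths optional named numeric of group lengths in Morgans; defaults
#'   to each group's largest marker position.
#' @return an object of class `genetic_map`
#' @export
genetic_map <- function(markers, lengths = NULL) {
  stopifnot(all(c("locus", "group", "cM") %in% names(markers)))
  m <- markers
  unl <- is.na(m$group) | is.na(m$cM)
  m$group <- as.character(m$group)
  m$group[unl] <- paste0("un_", m$locus[unl])
  m$cM[unl] <- 0
  if (any(m$cM < 0)) stop("map positions must be non-negative")
  m$pos_M <- m$cM / 100
  grp_max <- tapply(m$pos_M, m$group, max)
  if (is.null(lengths)) {
    lengths <- grp_max
  } else {
    miss <- setdiff(unique(m$group), names(lengths))
    add <- grp_max[miss]
    lengths <- c(lengths, add)
    if (any(grp_max > lengths[names(grp_max)] + 1e-12)) {
      stop("marker position beyond its group length")
    }
  }
  m <- m[order(m$group, m$pos_M), ]
  structure(list(markers = m, lengths = lengths[unique(m$group)]),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d markers, %d groups, %.2f M total\n",
              nrow(x$markers), length(x$lengths), sum(x$lengths)))
  invisible(x)
}

#' Total map length in Morgans
#' @param map a `genetic_map`
#' @export
map_length <- function(map) sum(map$lengths)

# ---------------------------------------------------------------------------
# Tract sets
# ---------------------------------------------------------------------------

#' Ancestry tract sets
#'
#' The true ancestral origin of every chromosome segment in a simulated
#' population: per linkage group, per chromosome copy, ordered tracts
#' `(start, end, source)` in Morgans that tile `[0, L]`. This is the physical
#' object behind "breakpoints per Morgan": each boundary between tracts of
#' different ancestral source is one junction laid down by recombination in an
#' admixed genome.
#'
#' @name tract_set
NULL

# internal constructor: groups is a named list of list(bp, src, off) in the
# flat layout used by the C++ core (src here is the source index, not the
# founder-copy label); sources is the source label vector.
new_tract_set <- function(groups, lengths, ids, sources) {
  structure(list(groups = groups, lengths = lengths, ids = ids,
                 sources = sources),
            class = "tract_set")
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("<tract_set> %d individuals, %d groups, sources: %s\n",
              length(x$ids), length(x$groups),
              paste(x$sources, collapse = ", ")))
  invisible(x)
}

# merge adjacent tracts with equal labels within each copy
merge_flat_tracts <- function(bp, lab, off) {
  nb <- numeric(0); nl <- integer(0); no <- integer(length(off))
  for (k in seq_len(length(off) - 1L)) {
    idx <- (off[k] + 1L):off[k + 1L]
    b <- bp[idx]; l <- lab[idx]
    keep <- c(l[-1] != l[-length(l)], TRUE)
    nb <- c(nb, b[keep]); nl <- c(nl, l[keep])
    no[k + 1L] <- length(nb)
  }
  list(bp = nb, lab = nl, off = no)
}

#' Junction counts per chromosome copy
#'
#' @param ts a `tract_set`
#' @return integer matrix, chromosome copies (2 per individual) x linkage
#'   groups, of ancestry-switch counts.
#' @export
junction_counts <- function(ts) {
  ng <- length(ts$groups)
  ncopies <- 2L * length(ts$ids)
  out <- matrix(0L, ncopies, ng,
                dimnames = list(NULL, names(ts$groups)))
  for (g in seq_len(ng)) {
    off <- ts$groups[[g]]$off
    out[, g] <- diff(off) - 1L
  }
  out
}

#' True tract-length-weighted ancestry fractions
#'
#' @param ts a `tract_set`
#' @return numeric matrix individuals x sources summing to 1 by row. Groups
#'   are weighted by their map length; if the whole map has zero length (all
#'   markers unlinked), each group-copy counts equally.
#' @export
true_ancestry <- function(ts) {
  n <- length(ts$ids)
  K <- length(ts$sources)
  acc <- matrix(0, n, K, dimnames = list(ts$ids, ts$sources))
  zero_len <- sum(ts$lengths) == 0
  for (g in seq_along(ts$groups)) {
    grp <- ts$groups[[g]]
    ntr <- diff(grp$off)
    copy_of <- rep(seq_len(2L * n), ntr)
    ind_of <- (copy_of + 1L) %/% 2L
    # start of tract t is end of previous tract within the same copy
    st <- c(0, grp$bp[-length(grp$bp)])
    st[grp$off[-length(grp$off)] + 1L] <- 0
    w <- if (zero_len) rep(1, length(grp$bp)) else grp$bp - st
    for (k in seq_len(K)) {
      sel <- grp$lab == k
      if (any(sel)) {
        acc[, k] <- acc[, k] +
          unname(tapply2(w[sel], ind_of[sel], n))
      }
    }
  }
  sweep(acc, 1, rowSums(acc), "/")
}

# sum x by integer group index over 1..n (fast tapply)
tapply2 <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Check the tract tiling invariant
#'
#' Tracts must tile `[0, L]` without gaps or overlaps and adjacent tracts must
#' differ in source.
#' @param ts a `tract_set`
#' @return TRUE invisibly; stops otherwise
#' @export
validate_tracts <- function(ts) {
  for (g in seq_along(ts$groups)) {
    grp <- ts$groups[[g]]
    L <- ts$lengths[g]
    for (k in seq_len(length(grp$off) - 1L)) {
      idx <- (grp$off[k] + 1L):grp$off[k + 1L]
      b <- grp$bp[idx]
      if (any(diff(b) <= 0)) stop("tracts not strictly increasing")
      if (abs(b[length(b)] - L) > 1e-9) stop("tracts do not end at group length")
      l <- grp$lab[idx]
      if (length(l) > 1 && any(l[-1] == l[-length(l)])) {
        stop("adjacent tracts share a source")
      }
    }
  }
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Hybrid swarm simulation
# ---------------------------------------------------------------------------

#' Configuration for a hybrid-swarm simulation
#'
#' @param q0 named numeric of founding mixture proportions over source
#'   lineages; must sum to 1.
#' @param g generations of random mating since admixture (>= 0; `g = 0`
#'   returns the founding generation itself).
#' @param N census size per generation (>= 2).
#' @param genetic_map a [genetic_map()] covering the simulated loci.
#' @param selection optional data.frame `locus`, `s` of per-locus viability
#'   coefficients: fitness multipliers 1, 1 + s/2, 1 + s by dosage of the
#'   counted allele, acting between birth and reproduction.
#' @param migration optional list `rate` (fraction in \[0,1\] of individuals
#'   replaced each generation) and `source` (pure source lineage of the
#'   migrants).
#' @param mito_locus optional name of a haploid maternally inherited locus
#'   (present in the panel, absent from the map).
#' @param seed RNG seed (optional).
#' @export
swarm_config <- function(q0, g, N, genetic_map, selection = NULL,
                         migration = NULL, mito_locus = NULL, seed = NULL) {
  stopifnot(!is.null(names(q0)), all(q0 >= 0), abs(sum(q0) - 1) < 1e-8)
  stopifnot(g >= 0, N >= 2)
  if (!is.null(migration)) {
    stopifnot(migration$rate >= 0, migration$rate <= 1,
              is.character(migration$source))
  }
  list(q0 = q0, g = as.integer(g), N = as.integer(N), map = genetic_map,
       selection = selection, migration = migration,
       mito_locus = mito_locus, seed = seed)
}

# draw fresh pure-source founder haplotypes for `idx` individuals; returns
# updated state. state holds: founder_freq (panel rows for sources), hap
# (founder haplotype matrix copies x loci), founder_source (int per copy).
add_founders <- function(state, n_new, source_idx) {
  probs <- state$founder_freq[source_idx, , drop = FALSE]
  newhap <- matrix(stats::rbinom(length(probs), 1L, as.vector(probs)),
                   nrow = n_new)
  state$hap <- rbind(state$hap, newhap)
  state$founder_source <- c(state$founder_source, source_idx)
  state
}

#' Simulate a hybrid swarm forward in time
#'
#' Founds a population of `N` individuals whose haplotypes are pure-source
#' draws from the panel (each chromosome copy's source drawn independently
#' from `q0`), then runs `g` generations of discrete, monoecious random mating
#' without selfing. Gametes recombine with Poisson crossover counts (group
#' length in Morgans) and uniform breakpoint positions (Haldane model, no
#' interference). Optional multiplicative viability selection and per
#' generation replacement of individuals by pure-source migrants.
#'
#' @param panel a `lineage_panel` containing all sources in `cfg$q0`
#' @param cfg a [swarm_config()]
#' @return list with elements `gm` (a `genotype_matrix` of the final
#'   generation), `tracts` (a `tract_set` of true source tracts), and `Q`
#'   (true tract-length-weighted ancestry fractions, individuals x sources).
#' @export
simulate_swarm <- function(panel, cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sources <- names(cfg$q0)
  stopifnot(all(sources %in% rownames(panel$freq)))
  map <- cfg$map
  loci <- map$markers$locus
  stopifnot(all(loci %in% colnames(panel$freq)))
  if (!is.null(cfg$mito_locus)) {
    stopifnot(cfg$mito_locus %in% colnames(panel$freq),
              !(cfg$mito_locus %in% loci))
  }
  N <- cfg$N
  K <- length(sources)
  state <- list(
    founder_freq = panel$freq[sources, loci, drop = FALSE],
    hap = matrix(integer(0), 0, length(loci)),
    founder_source = integer(0)
  )
  # founding generation: source per chromosome copy iid from q0
  copy_src <- sample.int(K, 2L * N, replace = TRUE, prob = cfg$q0)
  state <- add_founders(state, 2L * N, copy_src)
  groups <- names(map$lengths)
  pop <- lapply(groups, function(g) {
    list(bp = rep(map$lengths[[g]], 2L * N),
         lab = seq_len(2L * N),
         off = 0:(2L * N))
  })
  names(pop) <- groups
  # mitochondria: maternal, haploid; founder mito source follows copy 1
  mito_src <- copy_src[seq(1, 2L * N, by = 2)]
  mito_allele <- NULL
  if (!is.null(cfg$mito_locus)) {
    fm <- panel$freq[sources, cfg$mito_locus]
    mito_allele <- stats::rbinom(N, 1L, fm[mito_src])
  }
  sel <- cfg$selection
  sel_idx <- if (!is.null(sel)) match(sel$locus, loci) else integer(0)
  if (length(sel_idx) && anyNA(sel_idx)) stop("selected locus not on the map")
  marker_pos <- split(map$markers$pos_M, map$markers$group)[groups]
  marker_col <- split(match(map$markers$locus, loci),
                      map$markers$group)[groups]

  dosages <- function() {
    g <- matrix(0L, N, length(loci))
    for (gi in seq_along(groups)) {
      labs <- labels_at(pop[[gi]]$bp, pop[[gi]]$lab, pop[[gi]]$off,
                        marker_pos[[gi]])
      al <- matrix(state$hap[cbind(as.vector(labs),
                                   rep(marker_col[[gi]], each = nrow(labs)))],
                   nrow(labs), length(marker_col[[gi]]))
      g[, marker_col[[gi]]] <- al[seq(1, 2 * N, 2), , drop = FALSE] +
        al[seq(2, 2 * N, 2), , drop = FALSE]
    }
    g
  }

  for (gen in seq_len(cfg$g)) {
    w <- rep(1, N)
    if (length(sel_idx)) {
      d <- dosages()[, sel_idx, drop = FALSE]
      for (k in seq_along(sel_idx)) {
        w <- w * c(1, 1 + sel$s[k] / 2, 1 + sel$s[k])[d[, k] + 1L]
      }
      if (all(w <= 0)) stop("empty population after selection")
    }
    mother <- sample.int(N, N, replace = TRUE, prob = w)
    father <- sample.int(N, N, replace = TRUE, prob = w)
    while (any(same <- father == mother)) { # no selfing
      father[same] <- sample.int(N, sum(same), replace = TRUE, prob = w)
    }
    for (gi in seq_along(groups)) {
      pop[[gi]] <- next_gen_group(pop[[gi]]$bp, pop[[gi]]$lab, pop[[gi]]$off,
                                  map$lengths[[gi]], mother, father)
    }
    mito_src <- mito_src[mother]
    if (!is.null(mito_allele)) mito_allele <- mito_allele[mother]
    mig <- cfg$migration
    if (!is.null(mig) && mig$rate > 0) {
      n_mig <- stats::rbinom(1, N, mig$rate)
      if (n_mig > 0) {
        repl <- sample.int(N, n_mig)
        src_k <- match(mig$source, sources)
        if (is.na(src_k)) stop("migration source must be one of the q0 sources")
        first <- nrow(state$hap) + 1L
        state <- add_founders(state, 2L * n_mig, rep(src_k, 2L * n_mig))
        newlab <- first:(first + 2L * n_mig - 1L)
        for (gi in seq_along(groups)) {
          p <- pop[[gi]]
          for (r in seq_along(repl)) {
            i <- repl[r]
            for (cpy in 1:2) {
              idx <- (p$off[2 * i - 2 + cpy] + 1L):p$off[2 * i - 1 + cpy]
              # replace the copy by a single pure tract; tract counts shrink
              p$bp <- append(p$bp[-idx], map$lengths[[gi]],
                             after = p$off[2 * i - 2 + cpy])
              p$lab <- append(p$lab[-idx], newlab[2 * r - 2 + cpy],
                              after = p$off[2 * i - 2 + cpy])
              removed <- length(idx) - 1L
              p$off[(2 * i - 1 + cpy):length(p$off)] <-
                p$off[(2 * i - 1 + cpy):length(p$off)] - removed
            }
          }
          pop[[gi]] <- p
        }
        mito_src[repl] <- src_k
        if (!is.null(mito_allele)) {
          fm <- panel$freq[sources, cfg$mito_locus]
          mito_allele[repl] <- stats::rbinom(n_mig, 1L, fm[src_k])
        }
      }
    }
  }

  geno <- dosages()
  ids <- sprintf("ind_%04d", seq_len(N))
  all_loci <- loci
  loci_df <- data.frame(
    locus = loci, type = "nuclear",
    linkage_group = map$markers$group[match(loci, map$markers$locus)],
    cM = map$markers$cM[match(loci, map$markers$locus)],
    stringsAsFactors = FALSE
  )
  if (!is.null(cfg$mito_locus)) {
    geno <- cbind(geno, mito_allele)
    all_loci <- c(loci, cfg$mito_locus)
    loci_df <- rbind(loci_df, data.frame(
      locus = cfg$mito_locus, type = "mito",
      linkage_group = NA_character_, cM = NA_real_
    ))
  }
  dimnames(geno) <- list(ids, all_loci)
  gm <- genotype_matrix(geno, loci = loci_df, site = rep("swarm", N))
  # convert founder-copy labels to source tracts
  src_groups <- lapply(seq_along(groups), function(gi) {
    p <- pop[[gi]]
    merge_flat_tracts(p$bp, state$founder_source[p$lab], p$off)
  })
  names(src_groups) <- groups
  ts <- new_tract_set(
    lapply(src_groups, function(x) list(bp = x$bp, lab = x$lab, off = x$off)),
    lengths = map$lengths, ids = ids, sources = sources
  )
  list(gm = gm, tracts = ts, Q = true_ancestry(ts))
}

# ---------------------------------------------------------------------------
# Laboratory crosses
# ---------------------------------------------------------------------------

#' Simulate laboratory crosses between two pure lineages
#'
#' `F1` unites one fresh pure gamete from each parental lineage. `F2` mates
#' F1s; by default one F1 dam with five F1 sires, matching the classic
#' experimental design. `BCG` backcrosses F1 sires to pure dams of lineage B
#' (the *galloprovincialis* direction); `BCF1` is the reciprocal, one F1 dam
#' crossed to pure lineage-B sires. The mitochondrial marker, when present,
#' follows the dam.
#'
#' @param panel a `lineage_panel`
#' @param design one of `"F1"`, `"F2"`, `"BCG"`, `"BCF1"`
#' @param n_offspring number of offspring to produce
#' @param map a [genetic_map()] of the nuclear loci
#' @param parents character(2): lineages (A, B); A is the F1 dam side
#' @param n_sires number of sires in the F2/backcross design (default 5)
#' @param mito_locus optional haploid maternal locus
#' @param seed RNG seed (optional)
#' @return a `genotype_matrix` of the offspring; for designs with F1 parents
#'   (`F2`, `BCG`, `BCF1`) their genotypes are attached as attribute
#'   `"f1_parents"` (a `genotype_matrix`), as the F1-heterozygosity map
#'   filter needs them
#' @export
simulate_cross <- function(panel, design, n_offspring, map, parents,
                           n_sires = 5L, mito_locus = NULL, seed = NULL) {
  if (!design %in% c("F1", "F2", "BCG", "BCF1")) {
    stop(sprintf("unknown cross design '%s'", design))
  }
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(parents) == 2, all(parents %in% rownames(panel$freq)))
  loci <- map$markers$locus
  fr <- panel$freq[parents, loci, drop = FALSE]
  groups <- names(map$lengths)
  n <- as.integer(n_offspring)

  pure_hap <- function(k, m) { # m haplotypes from parent lineage k
    matrix(stats::rbinom(m * length(loci), 1L, rep(fr[k, ], each = m)), m)
  }
  # F1 individuals as a tract population: copy 1 = lineage A, copy 2 = B
  make_f1_pop <- function(m) {
    hapA <- pure_hap(1L, m)
    hapB <- pure_hap(2L, m)
    hap <- matrix(NA_integer_, 2 * m, length(loci))
    hap[seq(1, 2 * m, 2), ] <- hapA
    hap[seq(2, 2 * m, 2), ] <- hapB
    pop <- lapply(groups, function(g) {
      list(bp = rep(map$lengths[[g]], 2 * m), lab = seq_len(2 * m),
           off = 0:(2 * m))
    })
    names(pop) <- groups
    list(hap = hap, pop = pop)
  }
  gamete_alleles <- function(f1, mothers) {
    # one gamete per entry of mothers from the F1 population; returns
    # length(mothers) x loci allele matrix
    out <- matrix(NA_integer_, length(mothers), length(loci))
    for (gi in seq_along(groups)) {
      p <- f1$pop[[gi]]
      sel <- map$markers$group == groups[gi]
      pos <- map$markers$pos_M[sel]
      cols <- match(map$markers$locus[sel], loci)
      # make_gamete via next_gen_group with father = mother (only copy 1 used)
      ng <- next_gen_group(p$bp, p$lab, p$off, map$lengths[[gi]],
                           mothers, mothers)
      labs <- labels_at(ng$bp, ng$lab, ng$off, pos)
      lab1 <- labs[seq(1, nrow(labs), 2), , drop = FALSE]
      out[, cols] <- matrix(
        f1$hap[cbind(as.vector(lab1), rep(cols, each = nrow(lab1)))],
        nrow(lab1))
    }
    out
  }

  f1_gm <- NULL
  f1_geno_of <- function(f1) {
    m <- nrow(f1$hap) / 2L
    g <- f1$hap[seq(1, 2 * m, 2), , drop = FALSE] +
      f1$hap[seq(2, 2 * m, 2), , drop = FALSE]
    dimnames(g) <- list(sprintf("f1_parent_%02d", seq_len(m)), loci)
    genotype_matrix(g, site = rep("F1", m))
  }
  if (design == "F1") {
    geno <- pure_hap(1L, n) + pure_hap(2L, n)
    mito_from <- rep(1L, n)
  } else if (design == "F2") {
    f1 <- make_f1_pop(1L + n_sires)
    dam <- rep(1L, n)
    sire <- sample.int(n_sires, n, replace = TRUE) + 1L
    geno <- gamete_alleles(f1, dam) + gamete_alleles(f1, sire)
    mito_from <- rep(1L, n) # dam is an F1 whose own dam was lineage A
    f1_gm <- f1_geno_of(f1)
  } else if (design == "BCG") {
    f1 <- make_f1_pop(n_sires)
    sire <- sample.int(n_sires, n, replace = TRUE)
    geno <- pure_hap(2L, n) + gamete_alleles(f1, sire)
    mito_from <- rep(2L, n) # dams are pure lineage B
    f1_gm <- f1_geno_of(f1)
  } else { # BCF1: one F1 dam x pure lineage-B sires
    f1 <- make_f1_pop(1L)
    geno <- gamete_alleles(f1, rep(1L, n)) + pure_hap(2L, n)
    mito_from <- rep(1L, n)
    f1_gm <- f1_geno_of(f1)
  }

  ids <- sprintf("%s_%04d", tolower(design), seq_len(n))
  all_loci <- loci
  loci_df <- data.frame(
    locus = loci, type = "nuclear",
    linkage_group = map$markers$group[match(loci, map$markers$locus)],
    cM = map$markers$cM[match(loci, map$markers$locus)],
    stringsAsFactors = FALSE
  )
  if (!is.null(mito_locus)) {
    stopifnot(mito_locus %in% colnames(panel$freq))
    fm <- panel$freq[parents, mito_locus]
    mito <- stats::rbinom(n, 1L, fm[mito_from])
    geno <- cbind(geno, mito)
    all_loci <- c(loci, mito_locus)
    loci_df <- rbind(loci_df, data.frame(
      locus = mito_locus, type = "mito", linkage_group = NA_character_,
      cM = NA_real_
    ))
  }
  dimnames(geno) <- list(ids, all_loci)
  out <- genotype_matrix(geno, loci = loci_df, site = rep(design, n))
  attr(out, "f1_parents") <- f1_gm
  out
}

# ---------------------------------------------------------------------------
# Transect sampling
# ---------------------------------------------------------------------------

#' Simulate allele counts along a geographic transect
#'
#' Draws per-site allele counts from a cline: `hits ~ Binomial(2 n, p(x))`
#' with `p(x)` given by [cline_predict()].
#'
#' @param model a [cline_model()]
#' @param site_positions numeric vector of site distances (km)
#' @param n_per_site individuals sampled per site (scalar or vector)
#' @param seed RNG seed (optional)
#' @return data.frame `site`, `x`, `hits`, `n_copies`
#' @export
simulate_transect <- function(model, site_positions, n_per_site, seed = NULL) {
  stopifnot(all(is.finite(site_positions)), all(n_per_site >= 1))
  if (!is.null(seed)) set.seed(seed)
  n <- rep_len(n_per_site, length(site_positions))
  p <- cline_predict(model, site_positions)
  data.frame(
    site = sprintf("site_%02d", seq_along(site_positions)),
    x = site_positions,
    hits = stats::rbinom(length(p), 2L * n, p),
    n_copies = 2L * n
  )
}
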
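diag_panel <- function(seed = 2) {
  tree <- list(name = "root", children = list(
    list(name = "A", F = 0.4, level = "L2"),
    list(name = "B", F = 0.4, level = "L2")
  ))
  make_panel(list(n_loci = 36, lineage_tree = tree, focal = c("A", "B"),
                  afd_min = 0.9, seed = seed))
}

test_that("map filters exclude non-het, low-AFD and gappy markers with reasons", {
  pan <- diag_panel()
  pan$freq["A", 1:3] <- c(0.5, 0.50, 0.3)
  pan$freq["B", 1:3] <- c(0.5, 0.69, 0.3)   # AFD 0, 0.19, 0
  map <- mapping_map()
  f2 <- simulate_cross(pan, "F2", 60, map, parents = c("A", "B"), seed = 10)
  f1p <- attr(f2, "f1_parents")
  f1p$geno[, "L002"] <- 1L                  # het everywhere: AFD rule decides
  f1p$geno[, "L005"] <- 0L                  # homozygous in one F1 parent
  f2$geno[1:10, "L006"] <- NA               # 17% missing
  res <- filter_map_markers(f2, f1p, pan, c("A", "B"))
  expect_false(res$keep[res$locus == "L005"])
  expect_match(res$reason[res$locus == "L005"], "not het")
  expect_false(res$keep[res$locus == "L002"])   # AFD 0.19 < 0.2: removed
  expect_match(res$reason[res$locus == "L002"], "AFD")
  expect_false(res$keep[res$locus == "L006"])
  expect_match(res$reason[res$locus == "L006"], "missing")
})

test_that("segregation tests flag gross distortion but not 1:2:1 counts", {
  mk_f2 <- function(counts_by_locus) {
    g <- do.call(cbind, lapply(counts_by_locus, function(k) {
      sample(c(rep(0L, k[1]), rep(1L, k[2]), rep(2L, k[3])))
    }))
    colnames(g) <- sprintf("m%d", seq_along(counts_by_locus))
    rownames(g) <- sprintf("i%03d", seq_len(nrow(g)))
    genotype_matrix(g)
  }
  set.seed(11)
  f2 <- mk_f2(list(c(28, 57, 29), c(80, 30, 4)))
  res <- segregation_test(f2)
  expect_gt(res$p[1], 0.5)
  expect_true(res$reject[2])
  expect_lt(res$p[2], 1e-10)
  # markers with too few typed offspring are skipped
  f2$geno[11:114, "m1"] <- NA
  res2 <- segregation_test(f2, min_n = 20)
  expect_true(res2$skipped[1])
})

test_that("Holm step-down decisions match the hand computation", {
  p <- c(0.001, 0.02, 0.04, 0.2)
  # hand: sorted p_(i) compared stepwise -> adjusted (m - i + 1) * p_(i),
  # cummax'd: 0.004, 0.06, 0.08, 0.2
  hand <- cummax(p * c(4, 3, 2, 1))
  expect_equal(stats::p.adjust(p, "holm"), hand, tolerance = 1e-12)
  expect_identical(stats::p.adjust(p, "holm") <= 0.05,
                   c(TRUE, FALSE, FALSE, FALSE))
})

test_that("two-point rf: duplicates collapse to zero, unlinked stay at one half", {
  set.seed(12)
  a <- sample(0:2, 114, replace = TRUE, prob = c(1, 2, 1))
  dup <- est_rf_f2(a, a)
  expect_lt(dup$r, 1e-4)
  expect_gt(dup$lod, 10)
  # independent markers across 100 replicates: r near 0.5, LOD < 3
  hits <- 0
  for (rep in 1:100) {
    x <- sample(0:2, 114, replace = TRUE, prob = c(1, 2, 1))
    y <- sample(0:2, 114, replace = TRUE, prob = c(1, 2, 1))
    e <- est_rf_f2(x, y)
    hits <- hits + (e$r > 0.35 && e$lod < 3)
  }
  expect_gte(hits, 95)
  # sparse joint typing is flagged
  expect_true(est_rf_f2(a[1:15], a[1:15])$insufficient)
})

test_that("rf estimates match a grid-search likelihood oracle at r = 0.2", {
  pan <- diag_panel()
  two_mk <- genetic_map(data.frame(locus = c("L001", "L002"), group = "c1",
                                   cM = c(0, 100 * 0.5 * -log(1 - 2 * 0.2))))
  devs <- numeric(40)
  set.seed(13)
  for (rep in 1:40) {
    f2 <- simulate_cross(pan, "F2", 114, two_mk, parents = c("A", "B"),
                         seed = 1000 + rep)
    f2o <- orient_alleles(f2, pan, "A", "B")
    e <- est_rf_f2(f2o$geno[, 1], f2o$geno[, 2])
    # oracle: direct likelihood maximisation on a fine r grid
    counts <- table(factor(f2o$geno[, 1], 0:2), factor(f2o$geno[, 2], 0:2))
    ll <- function(r) {
      gam <- expand.grid(x = 0:1, y = 0:1)
      gam$pr <- ifelse(gam$x == gam$y, (1 - r) / 2, r / 2)
      pr <- matrix(0, 3, 3)
      for (i in 1:4) for (j in 1:4) {
        pr[gam$x[i] + gam$x[j] + 1, gam$y[i] + gam$y[j] + 1] <-
          pr[gam$x[i] + gam$x[j] + 1, gam$y[i] + gam$y[j] + 1] +
          gam$pr[i] * gam$pr[j]
      }
      sum(counts * log(pr))
    }
    grid <- seq(0.001, 0.5, by = 0.001)
    r_oracle <- grid[which.max(vapply(grid, ll, numeric(1)))]
    expect_lt(abs(e$r - r_oracle), 0.0015)
    devs[rep] <- e$r - 0.2
  }
  expect_lt(abs(stats::median(devs)), 0.05)
})

test_that("map construction groups and orders markers correctly", {
  # three markers with additive adjacent rf pick the middle one
  r <- matrix(c(0, 0.10, 0.18,
                0.10, 0, 0.10,
                0.18, 0.10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  lod <- matrix(10, 3, 3, dimnames = dimnames(r))
  bm <- build_map(list(r = r, lod = lod))
  expect_equal(length(bm$lengths), 1L)
  expect_identical(bm$markers$locus, c("a", "b", "c"))
  # with all LOD below threshold every marker is its own group
  lod0 <- matrix(1, 3, 3, dimnames = dimnames(r))
  bm0 <- build_map(list(r = r, lod = lod0))
  expect_equal(length(bm0$lengths), 3L)
  # Haldane positions are monotone in r
  d <- diff(bm$markers$cM)
  expect_equal(d[1], 100 * -0.5 * log(1 - 2 * 0.10), tolerance = 1e-9)
})

test_that("map construction is invariant to marker input order", {
  pan <- diag_panel()
  map <- mapping_map()
  f2 <- simulate_cross(pan, "F2", 114, map, parents = c("A", "B"), seed = 14)
  flt <- filter_map_markers(f2, attr(f2, "f1_parents"), pan, c("A", "B"))
  keep <- flt$locus[flt$keep]
  f2o <- orient_alleles(f2, pan, "A", "B")
  rf <- rf_matrix(f2o, loci = keep)
  bm1 <- build_map(rf)
  perm <- sample(length(keep))
  rf2 <- list(r = rf$r[perm, perm], lod = rf$lod[perm, perm])
  bm2 <- build_map(rf2)
  expect_identical(bm1$markers$locus, bm2$markers$locus)
  expect_equal(bm1$markers$cM, bm2$markers$cM, tolerance = 1e-9)
})

test_that("simulated multi-group genomes are partitioned correctly", {
  pan <- diag_panel()
  map <- mapping_map()
  truth_groups <- map$markers$group
  names(truth_groups) <- map$markers$locus
  ok <- 0
  n_rep <- 25
  for (rep in seq_len(n_rep)) {
    f2 <- simulate_cross(pan, "F2", 114, map, parents = c("A", "B"),
                         seed = 2000 + rep)
    flt <- filter_map_markers(f2, attr(f2, "f1_parents"), pan, c("A", "B"))
    keep <- flt$locus[flt$keep]
    f2o <- orient_alleles(f2, pan, "A", "B")
    bm <- build_map(rf_matrix(f2o, loci = keep))
    tg <- table(bm$markers$group, truth_groups[bm$markers$locus])
    ok <- ok + (nrow(tg) == length(unique(truth_groups[keep])) &&
                  all(rowSums(tg > 0) == 1))
  }
  expect_gte(ok, ceiling(0.9 * n_rep) - 1)
})

test_that("the unlinked set keeps the least-missing marker per group", {
  g <- matrix(1L, 10, 4, dimnames = list(sprintf("i%02d", 1:10),
                                         c("a", "b", "c", "d")))
  g[1:3, 1] <- NA
  g[1, 2] <- NA
  gm <- genotype_matrix(g, loci = data.frame(
    locus = c("a", "b", "c", "d"), type = "nuclear",
    linkage_group = c("g1", "g1", "g2", NA), cM = c(0, 10, 0, NA)))
  expect_setequal(unlinked_markers(gm), c("b", "c", "d"))
})

test_that("composite LD is maximal for duplicated markers, null in pure groups", {
  pan <- study_panel(n_loci = 40, afd_min = 0.8, seed = 15)
  map40 <- study_map(40, n_groups = 4)
  sw <- quick_swarm(pan, q_med = 0.5, g = 2, N = 400, seed = 16, map = map40)
  gmo <- orient_alleles(sw$gm, pan, "edu_eu_south", "gallo_med")
  x <- gmo$geno[, 1]
  n <- length(x)
  self_delta <- stats::cov(x, x) * (n - 1) / n / 2
  pairs <- admixture_ld(gmo, map40)
  expect_lte(max(pairs$delta), self_delta + 1e-9)
  # pure parental population: no admixture LD
  pure <- quick_swarm(pan, q_med = 1, g = 1, N = 500, seed = 17, map = map40)
  po <- orient_alleles(pure$gm, pan, "edu_eu_south", "gallo_med")
  pp <- admixture_ld(po, map40)
  se <- 1 / sqrt(500)  # loose bound on cov/2 of dosages for 0/2-ish markers
  expect_lt(mean(abs(pp$delta)), 3 * se)
})

test_that("a freshly founded swarm has strong, distance-independent LD", {
  pan <- study_panel(n_loci = 40, afd_min = 0.8, seed = 18)
  map40 <- study_map(40, n_groups = 4)
  sw <- quick_swarm(pan, q_med = 0.5, g = 0, N = 500, seed = 19, map = map40)
  gmo <- orient_alleles(sw$gm, pan, "edu_eu_south", "gallo_med")
  pairs <- admixture_ld(gmo, map40)
  expect_true(all(pairs$delta > 0))
  near <- mean(pairs$delta[pairs$dist_M < 0.3])
  far <- mean(pairs$delta[pairs$dist_M > 0.7])
  expect_lt(abs(near - far) / near, 0.25)
})

test_that("ALD dating recovers zero for founding swarms and scales with g", {
  pan <- study_panel(n_loci = 76, afd_min = 0.75, seed = 7)
  map76 <- study_map(76)
  ghat_of <- function(g, seed) {
    sw <- quick_swarm(pan, q_med = 0.5, g = g, N = 500, seed = seed,
                      map = map76)
    gmo <- orient_alleles(sw$gm, pan, "edu_eu_south", "gallo_med")
    estimate_admixture_time(gmo, map76, n_boot = 30, seed = seed + 1)
  }
  zero <- ghat_of(0, 20)
  expect_lt(zero$g_hat, 1)
  # doubling g roughly halves the distance at which LD drops to D0/e
  f5 <- ghat_of(5, 30)
  f10 <- ghat_of(10, 40)
  d_e <- function(fit) {
    # distance where the fitted curve reaches D0/e
    kf <- function(d) (1 + exp(-2 * d)) / 2
    uniroot(function(d) kf(d)^fit$g_hat - exp(-1), c(1e-3, 10))$root
  }
  expect_gt(f10$g_hat, f5$g_hat)
  ratio <- d_e(f10) / d_e(f5)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})

test_that("dating is invariant to allele flips when fitting magnitudes", {
  pan <- study_panel(n_loci = 40, afd_min = 0.8, seed = 21)
  map40 <- study_map(40, n_groups = 4)
  sw <- quick_swarm(pan, q_med = 0.5, g = 6, N = 400, seed = 22, map = map40)
  gmo <- orient_alleles(sw$gm, pan, "edu_eu_south", "gallo_med")
  flip <- gmo
  flip$geno[, 1:10] <- 2L - flip$geno[, 1:10]
  a <- estimate_admixture_time(gmo, map40, n_boot = 0, use_abs = TRUE)
  b <- estimate_admixture_time(flip, map40, n_boot = 0, use_abs = TRUE)
  expect_equal(a$g_hat, b$g_hat, tolerance = 1e-6)
  # degenerate geometry is rejected
  flat_map <- genetic_map(data.frame(locus = sprintf("L%03d", 1:6),
                                     group = "c1", cM = rep(0, 6)))
  expect_error(estimate_admixture_time(gmo, flat_map), "identifiable")
})
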
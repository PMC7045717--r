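toy_panel <- function(fA, fB, loci = sprintf("m%d", seq_along(fA))) {
  freq <- rbind(A = fA, B = fB)
  colnames(freq) <- loci
  lineage_panel(freq, data.frame(lineage = c("A", "B"), level = "L2",
                                 parent = "root"))
}

test_that("EM pins ancestry at the likelihood vertex for diagnostic alleles", {
  pan <- toy_panel(c(0.999, 0.999, 0.999), c(0.001, 0.001, 0.001))
  g <- rbind(pure = c(2L, 2L, 2L))
  colnames(g) <- colnames(pan$freq)
  pr <- estimate_q_supervised(genotype_matrix(g), pan, c("A", "B"))
  expect_gt(pr$Q["pure", "A"], 0.99)
  expect_false(pr$flat[1])
})

test_that("identical source frequencies yield a flagged flat likelihood", {
  pan <- toy_panel(c(0.4, 0.6), c(0.4, 0.6))
  g <- rbind(x = c(1L, 2L))
  colnames(g) <- colnames(pan$freq)
  pr <- estimate_q_supervised(genotype_matrix(g), pan, c("A", "B"))
  expect_equal(unname(pr$Q["x", ]), c(0.5, 0.5))
  expect_true(pr$flat[1])
})

test_that("EM optimum matches a fine grid search of the likelihood", {
  pan <- toy_panel(c(0.9, 0.3, 0.7), c(0.2, 0.8, 0.4))
  g <- rbind(i1 = c(2L, 1L, 1L), i2 = c(0L, 2L, 1L), i3 = c(1L, 1L, 2L))
  colnames(g) <- colnames(pan$freq)
  gm <- genotype_matrix(g)
  pr <- estimate_q_supervised(gm, pan, c("A", "B"), tol = 1e-12)
  fA <- pan$freq["A", ]; fB <- pan$freq["B", ]
  for (i in 1:3) {
    w1 <- g[i, ]; w0 <- 2 - g[i, ]
    ll <- function(q) sum(w1 * log(q * fA + (1 - q) * fB) +
                            w0 * log(q * (1 - fA) + (1 - q) * (1 - fB)))
    qs <- seq(0, 1, by = 0.001)
    q_grid <- qs[which.max(vapply(qs, ll, numeric(1)))]
    expect_lt(abs(pr$Q[i, "A"] - q_grid), 0.002)
    # EM likelihood is at least the grid's best
    expect_gte(pr$loglik[i], ll(q_grid) - 1e-9)
  }
})

test_that("EM log-likelihood is monotone non-decreasing every iteration", {
  pan <- study_panel(n_loci = 40, afd_min = 0.6, seed = 23)
  sw <- quick_swarm(pan, g = 4, N = 30, seed = 24, map = study_map(40))
  pr <- estimate_q_supervised(sw$gm, pan, c("gallo_med", "edu_eu_south"),
                              trace = TRUE)
  for (tr in attr(pr, "trace")) {
    if (length(tr) > 1) expect_true(all(diff(tr) >= -1e-9))
  }
})

test_that("supervised EM recovers simulated swarm ancestry", {
  pan <- study_panel(n_loci = 76, afd_min = 0.75, seed = 7)
  sw <- quick_swarm(pan, q_med = 0.7, g = 6, N = 200, seed = 11)
  pr <- estimate_q_supervised(sw$gm, pan, c("gallo_med", "edu_eu_south"))
  err <- mean(abs(pr$Q[, "gallo_med"] - sw$Q[, "gallo_med"]))
  expect_lt(err, 0.05)
})

test_that("EM is invariant to locus order and source relabelling", {
  pan <- study_panel(n_loci = 30, afd_min = 0.6, seed = 25)
  sw <- quick_swarm(pan, g = 3, N = 40, seed = 26, map = study_map(30))
  pr <- estimate_q_supervised(sw$gm, pan, c("gallo_med", "edu_eu_south"))
  perm <- sample(ncol(sw$gm$geno))
  gm2 <- sw$gm
  gm2$geno <- gm2$geno[, perm]
  gm2$loci <- gm2$loci[perm, ]
  gm2$orientation <- gm2$orientation[perm]
  pr2 <- estimate_q_supervised(gm2, pan, c("gallo_med", "edu_eu_south"))
  expect_equal(pr2$Q, pr$Q, tolerance = 1e-8)
  pr3 <- estimate_q_supervised(sw$gm, pan, c("edu_eu_south", "gallo_med"))
  expect_equal(pr3$Q[, c("gallo_med", "edu_eu_south")], pr$Q,
               tolerance = 1e-6)
})

test_that("ancestry error shrinks as panel informativeness grows", {
  errs <- sapply(c(0.4, 0.8), function(afd) {
    pan <- study_panel(n_loci = 76, afd_min = afd, seed = 27)
    sw <- quick_swarm(pan, q_med = 0.7, g = 6, N = 150, seed = 28)
    pr <- estimate_q_supervised(sw$gm, pan, c("gallo_med", "edu_eu_south"))
    mean(abs(pr$Q[, "gallo_med"] - sw$Q[, "gallo_med"]))
  })
  expect_lt(errs[2], errs[1])
})

test_that("no-admixture classification separates well-differentiated lineages", {
  pan <- study_panel(n_loci = 40, afd_min = 0.8, seed = 29)
  a <- quick_swarm(pan, q_med = 1, g = 0, N = 50, seed = 30,
                   map = study_map(40))
  b <- quick_swarm(pan, q_med = 0, g = 0, N = 50, seed = 31,
                   map = study_map(40))
  geno <- rbind(a$gm$geno, b$gm$geno)
  rownames(geno) <- sprintf("i%03d", 1:100)
  gm <- genotype_matrix(geno)
  init <- rep(1:2, 50)  # deliberately scrambled initial assignment
  res <- cluster_no_admixture(gm, 2, init)
  truth <- rep(1:2, each = 50)
  agreement <- max(mean(res$assign == truth), mean(res$assign == 3 - truth))
  expect_equal(agreement, 1)
  # permuting init labels permutes output labels identically
  res2 <- cluster_no_admixture(gm, 2, 3 - init)
  expect_identical(res2$assign, 3L - res$assign)
  # K = 1: everyone in one cluster, frequencies near observed
  res1 <- cluster_no_admixture(gm, 1, rep(1L, 100))
  expect_true(all(res1$assign == 1L))
  f_obs <- colMeans(gm$geno) / 2
  expect_equal(unname(res1$freq[1, ]), unname((f_obs * 200 + 0.5) / 201),
               tolerance = 1e-12)
})

test_that("reference-set construction applies the purity and exclusion rules", {
  pan <- study_panel(n_loci = 40, afd_min = 0.8, seed = 33)
  sw <- quick_swarm(pan, q_med = 1, g = 0, N = 60, seed = 34,
                    map = study_map(40))
  ids <- rownames(sw$gm$geno)
  Q <- cbind(gallo_med = rep(0.95, 60), edu_eu_south = rep(0.02, 60),
             tross = rep(0.03, 60))
  Q[1, ] <- c(0.84, 0.13, 0.03)   # below purity: dropped
  Q[2, ] <- c(0.86, 0.03, 0.11)   # trossulus over 10%: dropped
  rownames(Q) <- ids
  pr <- ancestry_profile(Q / rowSums(Q))
  rs <- build_reference_set(sw$gm, pr,
                            putative = setNames(rep("gallo_med", 60), ids),
                            purity = 0.85, excl_sources = "tross",
                            excl_max = 0.10)
  expect_false(ids[1] %in% rs$reference_ids$gallo_med)
  expect_false(ids[2] %in% rs$reference_ids$gallo_med)
  expect_false(ids[2] %in% rs$reduced_ids)
  expect_true(ids[3] %in% rs$reference_ids$gallo_med)
})

test_that("filtering contaminated candidates moves panel frequencies toward truth", {
  pan <- study_panel(n_loci = 60, afd_min = 0.8, seed = 35)
  pure <- quick_swarm(pan, q_med = 1, g = 0, N = 95, seed = 36,
                      map = study_map(60))
  hyb <- quick_swarm(pan, q_med = 0.5, g = 1, N = 5, seed = 37,
                     map = study_map(60))
  geno <- rbind(pure$gm$geno, hyb$gm$geno)
  rownames(geno) <- sprintf("i%03d", 1:100)
  gm <- genotype_matrix(geno)
  pr <- estimate_q_supervised(gm, pan, c("gallo_med", "edu_eu_south"))
  putative <- setNames(rep("gallo_med", 100), rownames(geno))
  rs <- build_reference_set(gm, pr, putative, purity = 0.85)
  f_true <- pan$freq["gallo_med", colnames(gm$geno)]
  before <- allele_freqs(gm, putative)
  err_before <- sum(abs(before$freq["gallo_med", ] - f_true))
  err_after <- sum(abs(rs$panel$freq["gallo_med", ] - f_true))
  expect_lt(err_after, err_before)
})

test_that("hybrid classes are recovered for crosses between diagnostic parents", {
  pan <- study_panel(n_loci = 76, afd_min = 0.75, seed = 7)
  fA <- pan$freq["edu_eu_south", ]
  fB <- pan$freq["gallo_med", ]
  map76 <- study_map(76)
  parents <- c("edu_eu_south", "gallo_med")
  f1 <- simulate_cross(pan, "F1", 100, map76, parents = parents, seed = 40)
  post <- hybrid_class_posterior(f1, fA, fB)
  expect_true(all(post[, "F1"] > 0.99))
  bcg <- simulate_cross(pan, "BCG", 200, map76, parents = parents, seed = 41)
  postb <- hybrid_class_posterior(bcg, fA, fB)
  modal <- colnames(postb)[max.col(postb)]
  expect_gte(mean(modal == "BC2"), 0.95)
  pure <- quick_swarm(pan, q_med = 1, g = 0, N = 50, seed = 42)
  postp <- hybrid_class_posterior(pure$gm, fA, fB)
  expect_true(all(max.col(postp) == which(colnames(postp) == "Pure2")))
  expect_true(all(postp[, "Pure2"] > 0.99))
  # identical parental frequencies: posterior equals prior, flagged
  postu <- hybrid_class_posterior(f1, fA, fA)
  expect_true(attr(postu, "uninformative"))
  expect_equal(unname(postu[1, ]), rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("composite ancestry sums components exactly", {
  Q <- rbind(i1 = c(edu_eu_south = 0.25, edu_am = 0.02,
                    gallo_atl = 0.04, gallo_med = 0.69))
  pr <- ancestry_profile(Q)
  cq <- composite_q(pr, list(edu = c("edu_eu_south", "edu_am"),
                             gallo_atl = "gallo_atl",
                             gallo_med = "gallo_med"))
  expect_equal(unname(cq$Q["i1", "edu"]), 0.27)
  expect_equal(sum(cq$Q), 1)
  # identity grouping leaves the profile unchanged
  idg <- as.list(colnames(Q))
  names(idg) <- colnames(Q)
  expect_equal(composite_q(pr, idg)$Q, pr$Q)
  # non-partition grouping is rejected
  expect_error(composite_q(pr, list(edu = c("edu_eu_south", "edu_am"))),
               "partition")
})
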
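toy_event <- function(Qbar, f, ids = c("x1", "x2")) {
  # f: list of per-source frequency vectors over shared loci
  freq <- do.call(rbind, f)
  lineage_panel(freq, data.frame(lineage = rownames(freq), level = "L2",
                                 parent = "root")) -> pan
  bindings <- setNames(rownames(freq), names(Qbar))
  admixture_event("toy", ids, pan, bindings, Qbar)
}

test_that("expected frequencies follow the ancestry-weighted mixture exactly", {
  f <- list(edu = c(m1 = 0.1), atl = c(m1 = 0.8), med = c(m1 = 0.9))
  names(f$edu) <- names(f$atl) <- names(f$med) <- "m1"
  ev <- toy_event(c(edu = 0.27, atl = 0.04, med = 0.69), f)
  expect_equal(unname(expected_freqs(ev)["m1"]), 0.68, tolerance = 1e-12)
  # simplex vertex: f_exp is the local-edulis frequency exactly
  ev2 <- toy_event(c(edu = 1, atl = 0, med = 0), f)
  expect_equal(unname(expected_freqs(ev2)["m1"]), 0.1, tolerance = 1e-15)
  # all sources equal: f_exp equals the common value for any Qbar
  f3 <- list(edu = c(m1 = 0.42), atl = c(m1 = 0.42), med = c(m1 = 0.42))
  ev3 <- toy_event(c(edu = 0.2, atl = 0.5, med = 0.3), f3)
  expect_equal(unname(expected_freqs(ev3)["m1"]), 0.42, tolerance = 1e-15)
})

test_that("distortions are observed minus expected, with missing propagation", {
  f <- list(edu = c(m1 = 0.2, m2 = 0.5), med = c(m1 = 0.9, m2 = 0.5))
  ev <- toy_event(c(edu = 0.5, med = 0.5), f)
  freq <- rbind(toy = c(m1 = 0.75, m2 = NA))
  ft <- structure(list(freq = freq, n = freq * 0 + 10), class = "freq_table")
  dt <- distortions(ev, ft)
  expect_equal(dt$D[dt$locus == "m1"], 0.75 - 0.55, tolerance = 1e-12)
  expect_true(is.na(dt$D[dt$locus == "m2"]))
  expect_true(all(stats::na.omit(dt$D) >= -1 & stats::na.omit(dt$D) <= 1))
})

test_that("a neutral swarm shows no systematic distortion", {
  pan <- study_panel(n_loci = 76, afd_min = 0.75, seed = 7)
  sw <- quick_swarm(pan, q_med = 0.7, g = 6, N = 300, seed = 50)
  pr <- estimate_q_supervised(sw$gm, pan, c("gallo_med", "edu_eu_south"))
  ev <- admixture_event("swarm", rownames(sw$gm$geno), pan,
                        bindings = c(gallo_med = "gallo_med",
                                     edu_eu_south = "edu_eu_south"),
                        Qbar = colMeans(pr$Q))
  ft <- allele_freqs(sw$gm, one_group(sw$gm, "swarm"))
  dt <- distortions(ev, ft)
  se <- stats::sd(dt$D) / sqrt(nrow(dt))
  expect_lt(abs(mean(dt$D)), 2 * se + 0.01)
})

test_that("viability selection shows up as the top distortion", {
  pan <- study_panel(n_loci = 40, afd_min = 0.75, seed = 51)
  map40 <- study_map(40)
  hits <- 0
  for (rep in 1:10) {
    cfg <- swarm_config(q0 = c(gallo_med = 0.5, edu_eu_south = 0.5), g = 10,
                        N = 500, genetic_map = map40,
                        selection = data.frame(locus = "L020", s = 0.5),
                        seed = 60 + rep)
    sw <- simulate_swarm(pan, cfg)
    gmo <- orient_alleles(sw$gm, pan, "edu_eu_south", "gallo_med")
    pano <- orient_panel(pan, "edu_eu_south", "gallo_med")
    pr <- estimate_q_supervised(gmo, pano, c("gallo_med", "edu_eu_south"))
    ev <- admixture_event("swarm", rownames(gmo$geno), pano,
                          bindings = c(gallo_med = "gallo_med",
                                       edu_eu_south = "edu_eu_south"),
                          Qbar = colMeans(pr$Q))
    ft <- allele_freqs(gmo, one_group(gmo, "swarm"))
    dt <- distortions(ev, ft)
    hits <- hits + (dt$locus[which.max(abs(dt$D))] == "L020")
  }
  expect_gte(hits, 8)
})

test_that("event correlations hit the algebraic extremes", {
  set.seed(52)
  dt <- data.frame(locus = sprintf("L%02d", 1:20), f_obs = NA, f_exp = NA,
                   D = rnorm(20, 0, 0.1))
  class(dt) <- c("distortion_table", "data.frame")
  anti <- dt
  anti$D <- -dt$D
  expect_equal(correlate_events(dt, dt, n_perm = 100)$r, 1)
  expect_equal(correlate_events(dt, anti, n_perm = 100)$r, -1)
  flat <- dt
  flat$D <- 0.05
  expect_true(correlate_events(dt, flat, n_perm = 100)$zero_variance)
  expect_error(correlate_events(dt[1:4, ], dt[1:4, ]), "5 shared loci")
})

test_that("random-permutation p agrees with exhaustive enumeration at 7 loci", {
  set.seed(53)
  mk <- function(d) {
    out <- data.frame(locus = sprintf("L%02d", seq_along(d)),
                      f_obs = NA, f_exp = NA, D = d)
    class(out) <- c("distortion_table", "data.frame")
    out
  }
  a <- mk(rnorm(7))
  b <- mk(0.6 * a$D + rnorm(7, 0, 0.5))
  exact <- correlate_events(a, b, exact_max = 8)
  expect_true(exact$exact)
  mc <- correlate_events(a, b, n_perm = 2e4, seed = 54, exact_max = 0)
  expect_false(mc$exact)
  # Monte-Carlo agrees with enumeration within 3 binomial SE
  se <- sqrt(exact$p * (1 - exact$p) / 2e4)
  expect_lt(abs(mc$p - exact$p), 3 * se + 1e-4)
  # symmetry of the statistic
  expect_equal(correlate_events(b, a, exact_max = 8)$r, exact$r)
})

test_that("correlation p-values are uniform for independent events", {
  pan <- study_panel(n_loci = 30, afd_min = 0.75, seed = 55)
  set.seed(56)
  mk <- function(d) {
    out <- data.frame(locus = colnames(pan$freq), f_obs = NA, f_exp = NA,
                      D = d)
    class(out) <- c("distortion_table", "data.frame")
    out
  }
  ps <- replicate(200, {
    correlate_events(mk(rnorm(30, 0, 0.05)), mk(rnorm(30, 0, 0.05)),
                     n_perm = 400)$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("Empirical Brown's method reduces to Fisher under independence", {
  set.seed(57)
  m <- 5
  dv <- matrix(rnorm(m * 200), m, 200)   # independent data vectors
  p <- runif(m, 0.01, 0.5)
  res <- combine_pvalues_brown(p, dv)
  expect_lt(abs(res$p - res$p_fisher) / res$p_fisher, 0.10)
  # m = 1: combined p is the input p
  expect_equal(combine_pvalues_brown(0.037, matrix(rnorm(10), 1))$p, 0.037)
})

test_that("duplicated tests are not double counted, matching the reference EBM", {
  # reference implementation of the method, written independently
  ebm_oracle <- function(p, dat) {
    m <- nrow(dat)
    w <- t(apply(dat, 1, function(x) {
      fn <- ecdf(x)
      -2 * log(fn(x))
    }))
    covmat <- cov(t(w))
    var_T <- 4 * m + 2 * sum(covmat[upper.tri(covmat)])
    cc <- var_T / (4 * m)
    df <- 2 * (2 * m)^2 / var_T
    if (cc < 1) { cc <- 1; df <- 2 * m }
    T_obs <- -2 * sum(log(p))
    pchisq(T_obs / cc, df = df, lower.tail = FALSE)
  }
  set.seed(58)
  x <- rnorm(100)
  dat <- rbind(x, x)        # two perfectly duplicated tests
  p <- c(0.02, 0.02)
  res <- combine_pvalues_brown(p, dat)
  expect_equal(res$p, ebm_oracle(p, dat), tolerance = 1e-12)
  # no double counting: the combined p stays at the single test's order
  # (finite-sample ECDF variance leaves it a few percent below the ideal
  # equality; Fisher would wrongly square it to 0.0066)
  expect_gt(res$p, 0.85 * 0.02)
  expect_lt(res$p, 1.15 * 0.02)
  # positive dependence is penalised relative to Fisher
  expect_gte(res$p, res$p_fisher)
})

test_that("few shared loci fall back to Fisher with a warning", {
  expect_warning(
    res <- combine_pvalues_brown(c(0.05, 0.1), matrix(rnorm(4), 2, 2)),
    "falling back to Fisher"
  )
  expect_equal(res$p, res$p_fisher)
})

test_that("comparison grid classifies pairs and combines within classes", {
  pan <- study_panel(n_loci = 30, afd_min = 0.75, seed = 59)
  mk_event <- function(label, type, background, seed) {
    sw <- quick_swarm(pan, q_med = 0.6, g = 4, N = 150, seed = seed,
                      map = study_map(30))
    pr <- estimate_q_supervised(sw$gm, pan, c("gallo_med", "edu_eu_south"))
    ev <- admixture_event(label, rownames(sw$gm$geno), pan,
                          bindings = c(gallo_med = "gallo_med",
                                       edu_eu_south = "edu_eu_south"),
                          Qbar = colMeans(pr$Q), type = type,
                          background = background)
    ft <- allele_freqs(sw$gm, one_group(sw$gm, label))
    list(event = ev, table = distortions(ev, ft, group = label))
  }
  e1 <- mk_event("p1", "dock", "med", 70)
  e2 <- mk_event("p2", "dock", "med", 71)
  e3 <- mk_event("n1", "norway", "atl", 72)
  events <- list(p1 = e1$event, p2 = e2$event, n1 = e3$event)
  tables <- list(p1 = e1$table, p2 = e2$table, n1 = e3$table)
  res <- run_comparison_grid(events, tables, n_perm = 500, seed = 73)
  expect_setequal(res$pairs$class, c("intra", "inter_lineages"))
  expect_equal(nrow(res$pairs), 3)
  # a single-pair class reports the pair's p unchanged
  intra <- res$classes[res$classes$class == "intra", ]
  expect_equal(intra$p_combined,
               res$pairs$p[res$pairs$class == "intra"])
})
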
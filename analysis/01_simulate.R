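#!/usr/bin/env Rscript
# Stage 1: simulate the study system with known truth.
#
# Five "port" populations are disjoint samples from one shared admixed pool
# (Mediterranean-like x southern-edulis-like, ~70/30), emulating saltatory
# colonisation of ports from a single admixture event. Two "Norway-like"
# populations are independent admixtures of the Atlantic-like lineage with
# northern edulis. Laboratory crosses (F1, F2, BCG, BCF1) and a geographic
# transect with a toy port cost grid complete the inputs.

source(file.path("analysis", "common.R"))

panel <- make_study_panel()
map <- make_study_map()
write_panel(panel, file.path(SIM_DIR, "panel.tsv"))

cat("== simulating the shared dock-mussel pool ==\n")
pool_cfg <- swarm_config(
  q0 = c(gallo_med = 0.7, edu_eu_south = 0.3), g = 8, N = 2000,
  genetic_map = map, mito_locus = "mito601", seed = SEED + 1
)
pool <- simulate_swarm(panel, pool_cfg)
idx <- split(seq_len(2000), rep(seq_along(PORTS), length.out = 2000))
for (k in seq_along(PORTS)) {
  take <- idx[[k]][1:250]
  gm <- pool$gm
  gm$geno <- gm$geno[take, , drop = FALSE]
  rownames(gm$geno) <- sprintf("%s_%03d", PORTS[k], seq_along(take))
  gm$site <- rep(PORTS[k], length(take))
  write_genotypes(gm, file.path(SIM_DIR, sprintf("%s.csv", PORTS[k])), "csv")
  q <- pool$Q[take, , drop = FALSE]
  rownames(q) <- rownames(gm$geno)
  utils::write.table(
    data.frame(id = rownames(q), q, check.names = FALSE),
    file.path(SIM_DIR, sprintf("%s_truth_q.tsv", PORTS[k])),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  cat(sprintf("  %s: %d individuals, true Q_med = %.3f\n", PORTS[k],
              length(take), mean(q[, "gallo_med"])))
}
jc <- junction_counts(pool$tracts)
utils::write.table(
  data.frame(group = colnames(jc), mean_junctions = colMeans(jc)),
  file.path(SIM_DIR, "pool_junctions.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE
)
cat(sprintf("  pool mean junctions per copy per Morgan: %.2f (g = 8)\n",
            mean(jc)))

cat("== simulating independent Norway-like admixtures ==\n")
for (k in seq_along(NORWAY)) {
  cfg <- swarm_config(
    q0 = c(gallo_atl = 0.45, edu_eu_north = 0.55), g = 6, N = 300,
    genetic_map = map, mito_locus = "mito601", seed = SEED + 10 + k
  )
  sw <- simulate_swarm(panel, cfg)
  gm <- sw$gm
  rownames(gm$geno) <- sprintf("%s_%03d", NORWAY[k], seq_len(nrow(gm$geno)))
  gm$site <- rep(NORWAY[k], nrow(gm$geno))
  write_genotypes(gm, file.path(SIM_DIR, sprintf("%s.csv", NORWAY[k])), "csv")
  cat(sprintf("  %s: true Q_atl = %.3f\n", NORWAY[k],
              mean(sw$Q[, "gallo_atl"])))
}

cat("== simulating laboratory crosses ==\n")
for (design in c("F1", "F2", "BCG", "BCF1")) {
  n <- if (design == "F2") 114 else 80
  cr <- simulate_cross(panel, design, n, map,
                       parents = c("edu_eu_south", "gallo_med"),
                       mito_locus = "mito601", seed = SEED + 20)
  write_genotypes(cr, file.path(SIM_DIR, sprintf("cross_%s.csv", design)),
                  "csv")
  f1p <- attr(cr, "f1_parents")
  if (!is.null(f1p) && design == "F2") {
    write_genotypes(f1p, file.path(SIM_DIR, "cross_F2_f1parents.csv"), "csv")
  }
  cat(sprintf("  %s: %d offspring\n", design, n))
}

cat("== simulating a port-entrance transect ==\n")
cline_truth <- cline_model(centre = 2, width = 1.5, pmin = 0.1, pmax = 0.9)
x <- seq(-3, 7, length.out = 15)
per_locus <- lapply(1:10, function(k) {
  tr <- simulate_transect(cline_truth, x, n_per_site = 40,
                          seed = SEED + 30 + k)
  tr$locus <- sprintf("L%03d", k)
  tr
})
utils::write.table(do.call(rbind, per_locus),
                   file.path(SIM_DIR, "transect_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("  15 sites, 10 loci, true centre %.1f km, width %.1f km\n",
            cline_truth$centre, cline_truth$width))

grid <- make_cost_grid("wall", c(9, 15), cell_km = 0.5)
saveRDS_path <- file.path(SIM_DIR, "port_grid.tsv")
utils::write.table(
  data.frame(row = row(grid$water)[!grid$water],
             col = col(grid$water)[!grid$water]),
  saveRDS_path, sep = "\t", quote = FALSE, row.names = FALSE
)
cat("stage 1 complete; inputs written under", SIM_DIR, "\n")
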
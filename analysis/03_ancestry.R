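#!/usr/bin/env Rscript
# Stage 3: ancestry. Supervised EM ancestry against the four reference
# lineages (K = 4), composite edulis ancestry, recovery against simulated
# truth for the ports, hybrid-class posteriors for the laboratory crosses,
# and nonparametric comparisons of ancestry levels between ports.

source(file.path("analysis", "common.R"))
panel <- make_study_panel()
gm <- read_genotypes(file.path(RESULTS, "genotypes_qc.csv"), "csv",
                     loci = utils::read.table(
                       file.path(RESULTS, "marker_meta.tsv"),
                       header = TRUE, sep = "\t", stringsAsFactors = FALSE))

K4 <- c("edu_eu_south", "edu_am", "gallo_atl", "gallo_med")
pr <- estimate_q_supervised(gm, panel, K4)
cq <- composite_q(pr, list(edu = c("edu_eu_south", "edu_am"),
                           gallo_atl = "gallo_atl",
                           gallo_med = "gallo_med"))

qdf <- data.frame(id = rownames(pr$Q), site = gm$site, pr$Q,
                  Q_edu = cq$Q[, "edu"], check.names = FALSE)
utils::write.table(qdf, file.path(RESULTS, "q_values.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("mean ancestry by population:\n")
agg <- aggregate(pr$Q, by = list(site = gm$site), FUN = mean)
print(agg, digits = 3)

# recovery against simulated truth (ports only; truth recorded in stage 1)
errs <- sapply(PORTS, function(p) {
  tq <- utils::read.table(file.path(SIM_DIR, sprintf("%s_truth_q.tsv", p)),
                          header = TRUE, sep = "\t")
  ids <- intersect(tq$id, rownames(pr$Q))
  mean(abs(pr$Q[ids, "gallo_med"] -
             tq$gallo_med[match(ids, tq$id)]))
})
cat(sprintf("mean |Q_hat - truth| per port: %s\n",
            paste(sprintf("%s %.3f", PORTS, errs), collapse = ", ")))

# hybrid-class posteriors for the crosses (diagnostic parental panels)
fA <- panel_freq(panel, "edu_eu_south")
fB <- panel_freq(panel, "gallo_med")
cls <- do.call(rbind, lapply(c("F1", "F2", "BCG", "BCF1"), function(d) {
  cr <- read_genotypes(file.path(SIM_DIR, sprintf("cross_%s.csv", d)), "csv")
  post <- hybrid_class_posterior(cr, fA, fB)
  data.frame(id = rownames(post), design = d,
             modal = colnames(post)[max.col(post)],
             p_modal = post[cbind(seq_len(nrow(post)), max.col(post))])
}))
utils::write.table(cls, file.path(RESULTS, "classes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("modal hybrid class by design:\n")
print(table(cls$design, cls$modal))

# ancestry-level comparisons between the five ports
port_ids <- gm$site %in% PORTS
cmp <- compare_ancestry_levels(pr$Q[port_ids, , drop = FALSE],
                               gm$site[port_ids])
kw <- data.frame(source = names(cmp),
                 kruskal_p = vapply(cmp, function(x) x$kruskal$p.value, 1))
utils::write.table(kw, file.path(RESULTS, "ancestry_comparisons.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("Kruskal-Wallis across ports (per source):\n")
print(kw, digits = 3, row.names = FALSE)
cat("note: ports are subsamples of one pool, so differences reflect\n",
    "sampling only and large p-values are expected\n")
cat("stage 3 complete\n")
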
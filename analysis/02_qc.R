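#!/usr/bin/env Rscript
# Stage 2: quality control. Reads the simulated genotype tables, resolves a
# duplicated control individual, applies the missing-data thresholds (10%
# per locus, 30% per individual), screens Hardy-Weinberg equilibrium in each
# population with Monte-Carlo tests and a Benjamini-Yekutieli correction,
# and writes the pooled, oriented matrix.

source(file.path("analysis", "common.R"))
panel <- make_study_panel()

pops <- c(PORTS, NORWAY)
mats <- lapply(pops, function(p) {
  read_genotypes(file.path(SIM_DIR, sprintf("%s.csv", p)), "csv")
})
geno <- do.call(rbind, lapply(mats, function(m) m$geno))
site <- unlist(lapply(mats, function(m) m$site))
# marker metadata: map positions for the nuclear loci, haploid flag for the
# maternal mitochondrial marker (the CSV dialect does not carry ploidy)
map <- make_study_map()
loci_meta <- data.frame(
  locus = colnames(geno),
  type = ifelse(colnames(geno) == "mito601", "mito", "nuclear"),
  linkage_group = map$markers$group[match(colnames(geno),
                                          map$markers$locus)],
  cM = map$markers$cM[match(colnames(geno), map$markers$locus)],
  stringsAsFactors = FALSE
)
gm <- genotype_matrix(geno, loci = loci_meta, site = site)
cat(sprintf("pooled: %d individuals x %d loci\n", nrow(geno), ncol(geno)))

# a duplicated genotyping control: re-insert the first individual under a new
# id with extra missingness, then resolve the pair
dup <- gm$geno[1, , drop = FALSE]
dup[1, 1:8] <- NA
rownames(dup) <- "havre_001_ctrl"
gm <- genotype_matrix(rbind(gm$geno, dup), loci = loci_meta,
                      site = c(gm$site, gm$site[1]))
gm <- dedupe_controls(gm, cbind("havre_001", "havre_001_ctrl"))
rep <- attr(gm, "dedupe_report")
cat(sprintf("duplicate control resolved: kept %s, %d mismatches\n",
            rep$kept, rep$mismatches))

gm <- filter_missing(gm, locus_max = 0.10, indiv_max = 0.30)
cat(sprintf("after missing-data filters: %d x %d\n",
            nrow(gm$geno), ncol(gm$geno)))

gm <- orient_alleles(gm, panel, "edu_eu_south", "gallo_med")

hwe <- do.call(rbind, lapply(pops, function(p) {
  ids <- rownames(gm$geno)[gm$site == p]
  res <- hwe_mc_test(gm, ids, B = 2000)
  res$group <- p
  res
}))
utils::write.table(hwe[, c("locus", "group", "stat", "p", "q_by")],
                   file.path(RESULTS, "hwe.tsv"), sep = "\t", quote = FALSE,
                   row.names = FALSE)
flagged <- unique(hwe$locus[hwe$q_by < 0.05])
cat(sprintf("HWE screen: %d locus flags at BY 5%% (%s)\n", length(flagged),
            paste(head(flagged, 5), collapse = ", ")))

write_genotypes(gm, file.path(RESULTS, "genotypes_qc.csv"), "csv")
utils::write.table(gm$loci, file.path(RESULTS, "marker_meta.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("stage 2 complete\n")
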
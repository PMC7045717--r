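# Shared simulation fixtures: a two-lineage tree for focal admixture, the
# four-lineage tree mirroring the study system, and standard map layouts.

two_lineage_tree <- function(F = 0.3) {
  list(name = "root", children = list(
    list(name = "edu_eu_south", F = F, level = "L2"),
    list(name = "gallo_med", F = F, level = "L2")
  ))
}

four_lineage_tree <- function() {
  list(name = "root", children = list(
    list(name = "edu", F = 0.5, level = "L1", children = list(
      list(name = "edu_eu_south", F = 0.1, level = "L2"),
      list(name = "edu_am", F = 0.1, level = "L2")
    )),
    list(name = "gallo", F = 0.5, level = "L1", children = list(
      list(name = "gallo_atl", F = 0.1, level = "L2"),
      list(name = "gallo_med", F = 0.1, level = "L2")
    ))
  ))
}

# 76 ancestry-informative loci between the focal pair, as in the study panel
study_panel <- function(n_loci = 76, afd_min = 0.75, seed = 7,
                        tree = two_lineage_tree(),
                        focal = c("edu_eu_south", "gallo_med")) {
  make_panel(list(n_loci = n_loci, lineage_tree = tree, focal = focal,
                  afd_min = afd_min, seed = seed))
}

# n_loci markers spread over 8 linkage groups of 1 Morgan
study_map <- function(n_loci = 76, n_groups = 8, length_cM = 100) {
  per <- ceiling(n_loci / n_groups)
  grp <- rep(sprintf("chr%d", seq_len(n_groups)), each = per)[seq_len(n_loci)]
  pos <- unlist(lapply(table(factor(grp, unique(grp))), function(k) {
    seq(0, length_cM, length.out = k)
  }))
  genetic_map(data.frame(locus = sprintf("L%03d", seq_len(n_loci)),
                         group = grp, cM = unname(pos)))
}

# mapping design: 36 markers on 5 groups of 50 cM (dense enough that the
# F1-heterozygosity filter leaves no large gaps)
mapping_map <- function() {
  sizes <- c(8, 8, 8, 6, 6)
  genetic_map(data.frame(
    locus = sprintf("L%03d", 1:36),
    group = rep(sprintf("c%d", 1:5), sizes),
    cM = unlist(lapply(sizes, function(k) seq(0, 50, length.out = k)))
  ))
}

# a quick neutral swarm with its supervised ancestry estimate
quick_swarm <- function(panel, q_med = 0.7, g = 6, N = 200, seed = 11,
                        map = study_map(ncol(panel$freq))) {
  cfg <- swarm_config(q0 = c(gallo_med = q_med, edu_eu_south = 1 - q_med),
                      g = g, N = N, genetic_map = map, seed = seed)
  simulate_swarm(panel, cfg)
}

# named grouping vector: all individuals of gm into one group
one_group <- function(gm, label = "grp") {
  stats::setNames(rep(label, nrow(gm$geno)), rownames(gm$geno))
}
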
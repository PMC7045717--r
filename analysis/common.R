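# Shared configuration for the analysis drivers: the lineage hierarchy, the
# ancestry-informative panel, marker map and global seed. Every driver
# sources this file and communicates with the others only through files
# under results/.

library(admixrep)

SEED <- 20190101L
RESULTS <- "results"
SIM_DIR <- file.path(RESULTS, "sim")
dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)

# lineage hierarchy: two species, four focal lineages (L2), mirroring the
# reference system of an edulis-like and a galloprovincialis-like species
LINEAGE_TREE <- list(name = "root", children = list(
  list(name = "edu", F = 0.5, level = "L1", children = list(
    list(name = "edu_eu_south", F = 0.15, level = "L2"),
    list(name = "edu_eu_north", F = 0.15, level = "L2"),
    list(name = "edu_am", F = 0.2, level = "L2")
  )),
  list(name = "gallo", F = 0.5, level = "L1", children = list(
    list(name = "gallo_atl", F = 0.2, level = "L2"),
    list(name = "gallo_med", F = 0.2, level = "L2")
  ))
))

make_study_panel <- function() {
  # the empirical panel was ascertained to resolve several lineage contrasts
  # at once; emulate it as a union of pair-ascertained subsets
  blocks <- list(
    list(n = 40, focal = c("edu_eu_south", "gallo_med"), afd = 0.7),
    list(n = 19, focal = c("gallo_atl", "gallo_med"), afd = 0.5),
    list(n = 9,  focal = c("edu_eu_south", "edu_am"), afd = 0.5),
    list(n = 9,  focal = c("edu_eu_south", "edu_eu_north"), afd = 0.4)
  )
  freqs <- lapply(seq_along(blocks), function(k) {
    b <- blocks[[k]]
    make_panel(list(n_loci = b$n, lineage_tree = LINEAGE_TREE,
                    focal = b$focal, afd_min = b$afd,
                    seed = SEED + k))$freq
  })
  # one Atl/Med-informative locus plays the female-mitochondrial marker and
  # goes last; the 76 nuclear loci keep names L001..L076
  freq <- cbind(freqs[[1]], freqs[[2]][, -1, drop = FALSE], freqs[[3]],
                freqs[[4]], freqs[[2]][, 1, drop = FALSE])
  colnames(freq) <- c(sprintf("L%03d", 1:76), "mito601")
  nodes <- make_panel(list(n_loci = 1, lineage_tree = LINEAGE_TREE,
                           focal = c("edu_eu_south", "gallo_med"),
                           afd_min = 0, seed = SEED))$lineages
  pan <- lineage_panel(freq, nodes)
  orient_panel(pan, "edu_eu_south", "gallo_med")
}

make_study_map <- function() {
  # 76 nuclear markers on 8 groups of 1 Morgan (mito601 is unmapped)
  genetic_map(data.frame(
    locus = sprintf("L%03d", 1:76),
    group = rep(sprintf("chr%d", 1:8), each = 10)[1:76],
    cM = rep(seq(0, 100, length.out = 10), 8)[1:76]
  ))
}

PORTS <- c("havre", "cher", "stmalo", "brest", "stnaz")
NORWAY <- c("LOF", "GAS")
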